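# Shared fixtures and independent oracles (brute-force / closed-form),
# deliberately written without reusing the package's internals.

KE <- 332.0636
KB <- 0.0019872041

# --- independent bond-graph distances (Floyd-Warshall, tiny n) -------------
oracle_graph_dist <- function(bonds, n) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_len(nrow(bonds))) {
    d[bonds$i[r], bonds$j[r]] <- 1
    d[bonds$j[r], bonds$i[r]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# naive double-loop Coulomb with Amber exclusions
oracle_coulomb <- function(xyz, q, bonds, scee = 1.2) {
  n <- nrow(xyz)
  gd <- oracle_graph_dist(bonds, n)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (gd[i, j] <= 2) next
    w <- if (gd[i, j] == 3) 1 / scee else 1
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- e + w * KE * q[i] * q[j] / r
  }
  e
}

oracle_lj <- function(xyz, rmin_half, eps, bonds, scnb = 2.0) {
  n <- nrow(xyz)
  gd <- oracle_graph_dist(bonds, n)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (gd[i, j] <= 2) next
    w <- if (gd[i, j] == 3) 1 / scnb else 1
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rm <- rmin_half[i] + rmin_half[j]
    ee <- sqrt(eps[i] * eps[j])
    e <- e + w * ee * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

# term-by-term bonded energy
oracle_bonded <- function(xyz, ff) {
  e <- 0
  for (r in seq_len(nrow(ff$bonds))) {
    b <- ff$bonds[r, ]
    d <- sqrt(sum((xyz[b$i, ] - xyz[b$j, ])^2))
    e <- e + b$kb * (d - b$b0)^2
  }
  for (r in seq_len(nrow(ff$angles))) {
    a <- ff$angles[r, ]
    v1 <- xyz[a$i, ] - xyz[a$j, ]; v2 <- xyz[a$k, ] - xyz[a$j, ]
    th <- acos(max(-1, min(1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2)))))
    e <- e + a$ktheta * (th - a$theta0)^2
  }
  for (r in seq_len(nrow(ff$dihedrals))) {
    dd <- ff$dihedrals[r, ]
    b1 <- xyz[dd$j, ] - xyz[dd$i, ]; b2 <- xyz[dd$k, ] - xyz[dd$j, ]
    b3 <- xyz[dd$l, ] - xyz[dd$k, ]
    n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
    n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
    m1 <- c(n1[2]*b2[3]-n1[3]*b2[2], n1[3]*b2[1]-n1[1]*b2[3], n1[1]*b2[2]-n1[2]*b2[1])
    m1 <- m1 / sqrt(sum(b2^2))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    e <- e + dd$vn2 * (1 + cos(dd$n * phi - dd$gamma))
  }
  e
}

# --- RMSD oracle: direct minimization over rotations -----------------------
oracle_min_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  rotmat <- function(p) {  # axis-angle (Rodrigues)
    th <- sqrt(sum(p^2))
    if (th < 1e-12) return(diag(3))
    k <- p / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  f <- function(p) {
    R <- rotmat(p)
    sqrt(mean(rowSums((a %*% t(R) - b)^2)))
  }
  set.seed(42)
  best <- Inf
  for (k in 1:40) {
    p0 <- runif(3, -pi, pi)
    o <- optim(p0, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# --- analytic SASA of two overlapping spheres (lens formula) ---------------
oracle_two_sphere_sasa <- function(R1, R2, d) {
  cap <- function(R, Ro, d) {   # buried cap height on sphere R
    if (d >= R + Ro) return(0)
    if (d + R <= Ro) return(2 * R)     # fully engulfed
    h <- R - (d^2 + R^2 - Ro^2) / (2 * d)
    max(0, h)
  }
  c(4 * pi * R1^2 - 2 * pi * R1 * cap(R1, R2, d),
    4 * pi * R2^2 - 2 * pi * R2 * cap(R2, R1, d))
}

# --- closed-form helpers ---------------------------------------------------
born_energy <- function(q, a, eps_out, eps_in = 1) {
  -(KE / 2) * (1 / eps_in - 1 / eps_out) * q^2 / a
}

schlitter_1dof <- function(mass, variance, temperature) {
  cst <- 1.380649e-23 * exp(1)^2 * 1.66053906660e-27 * 1e-20 /
    1.054571817e-34^2
  0.5 * KB * log1p(cst * temperature * mass * variance)
}

# --- fixtures --------------------------------------------------------------
toy_system <- function(n_res = 5, seed = 1) build_toy_dimer(n_res, seed = seed)

# minimal hand-made two-atom force field
two_atom_ff <- function(q = c(1, -1), rmin_half = c(1.9, 1.9),
                        eps = c(0.1, 0.1), radius = c(2, 2)) {
  forcefield(charges = q, rmin_half = rmin_half, epsilon = eps,
             radius = radius, mass = c(12, 12))
}

rigid_transform <- function(xyz, angles = c(0.3, -0.7, 1.1),
                            shift = c(5, -3, 2)) {
  Rx <- matrix(c(1,0,0, 0,cos(angles[1]),-sin(angles[1]),
                 0,sin(angles[1]),cos(angles[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(angles[2]),0,sin(angles[2]), 0,1,0,
                 -sin(angles[2]),0,cos(angles[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(angles[3]),-sin(angles[3]),0,
                 sin(angles[3]),cos(angles[3]),0, 0,0,1), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(Rz %*% Ry %*% Rx), 2, shift, `+`)
}

# hairpin CA trace builder for classifier tests (n = 8 residues)
hairpin_ca <- function(origin = c(0, 0, 0), dx = 1, dy = 5) {
  ca <- matrix(NA_real_, 8, 3)
  for (i in 1:3) ca[i, ] <- origin + c(dx * (i - 1) * 3.8, 0, 0)
  ca[4, ] <- origin + c(dx * 10.3, dy / 2, 0)
  for (i in 5:8) ca[i, ] <- origin + c(dx * (8 - i) * 3.8, dy, 0)
  ca
}

extended_ca <- function(origin = c(0, 0, 0), dir = c(1, 0, 0)) {
  t(sapply(0:7, function(i) origin + i * 3.8 * dir))
}

# place full atoms around externally supplied CA traces
frame_from_ca <- function(top, caA, caB) {
  at <- top$atoms
  xyz <- matrix(NA_real_, nrow(at), 3)
  put <- function(ca, chain) {
    for (i in seq_len(nrow(ca))) {
      idx <- which(at$chain == chain & at$resid == i)
      nm <- at$name[idx]
      base <- ca[i, ]
      off <- list(N = c(-1.2, 0.4, 0), H = c(-1.2, 1.4, 0), CA = c(0, 0, 0),
                  C = c(1.2, -0.4, 0), O = c(1.2, -1.6, 0), SC = c(0, 0, 1.2))
      for (k in seq_along(idx)) xyz[idx[k], ] <<- base + off[[nm[k]]]
    }
  }
  put(caA, top$chains[1]); put(caB, top$chains[2])
  frame(xyz)
}
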