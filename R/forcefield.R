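# Force-field container and its structured-text (JSON/YAML) schema.
#
# Per-atom: charge (e), rmin_half (A), epsilon (kcal/mol), intrinsic radius
# (A, used by both PB dielectric region and GB descreening), mass (amu).
# Bonded: harmonic bonds/angles without the 1/2 factor (Amber convention)
# and cosine dihedrals V_n/2 (1 + cos(n phi - gamma)).

#' Construct a force field
#'
#' @param charges,rmin_half,epsilon,radius,mass numeric per-atom vectors
#'   (length = number of atoms): partial charge (e), half of the
#'   Lennard-Jones minimum distance (A), LJ well depth (kcal/mol),
#'   intrinsic (Born/dielectric) radius (A), mass (amu).
#' @param bonds data frame `i, j, kb, b0` (kcal/mol/A^2, A).
#' @param angles data frame `i, j, k, ktheta, theta0` (kcal/mol/rad^2, rad).
#' @param dihedrals data frame `i, j, k, l, vn2, n, gamma` (kcal/mol, -, rad).
#' @param scee,scnb 1-4 scaling divisors for electrostatics and LJ
#'   (Amber defaults 1.2 and 2.0).
#' @return Object of class `"forcefield"`.
#' @export
forcefield <- function(charges, rmin_half, epsilon, radius, mass,
                       bonds = NULL, angles = NULL, dihedrals = NULL,
                       scee = 1.2, scnb = 2.0) {
  n <- length(charges)
  if (!all(lengths(list(rmin_half, epsilon, radius, mass)) == n))
    stop("per-atom parameter vectors have inconsistent lengths")
  if (any(epsilon < 0)) stop("negative Lennard-Jones epsilon")
  if (any(radius <= 0)) stop("non-positive intrinsic radius")
  if (any(mass <= 0)) stop("non-positive mass")
  empty <- function(cols) as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  bonds <- bonds %||% empty(c("i", "j", "kb", "b0"))
  angles <- angles %||% empty(c("i", "j", "k", "ktheta", "theta0"))
  dihedrals <- dihedrals %||% empty(c("i", "j", "k", "l", "vn2", "n", "gamma"))
  structure(list(charges = as.numeric(charges), rmin_half = as.numeric(rmin_half),
                 epsilon = as.numeric(epsilon), radius = as.numeric(radius),
                 mass = as.numeric(mass), bonds = as.data.frame(bonds),
                 angles = as.data.frame(angles), dihedrals = as.data.frame(dihedrals),
                 scee = scee, scnb = scnb),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("forcefield: ", length(x$charges), " atoms, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals),
      " dihedrals; scee = ", x$scee, ", scnb = ", x$scnb, "\n", sep = "")
  invisible(x)
}

#' Write a force field to a JSON or YAML parameter file
#'
#' The schema is self-describing: `atoms` is a list (in topology order) of
#' `{name, chain, residue_index, charge, rmin_half, epsilon, radius, mass}`;
#' `bonds`/`angles`/`dihedrals` reference atoms by 1-based topology index;
#' `scee`/`scnb` are the 1-4 scaling divisors.
#'
#' @param ff a [forcefield()].
#' @param top the matching [topology()].
#' @param file output path ending in `.json`, `.yaml` or `.yml`.
#' @return `file`, invisibly.
#' @export
write_forcefield <- function(ff, top, file) {
  at <- top$atoms
  rows_as_lists <- function(df)
    unname(lapply(seq_len(nrow(df)), function(r) as.list(df[r, ])))
  obj <- list(
    atoms = lapply(seq_along(ff$charges), function(i) list(
      name = at$name[i], chain = at$chain[i], residue_index = at$resid[i],
      charge = ff$charges[i], rmin_half = ff$rmin_half[i],
      epsilon = ff$epsilon[i], radius = ff$radius[i], mass = ff$mass[i])),
    bonds = rows_as_lists(ff$bonds),
    angles = rows_as_lists(ff$angles),
    dihedrals = rows_as_lists(ff$dihedrals),
    scee = ff$scee, scnb = ff$scnb)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, file)
  }
  invisible(file)
}

#' Read a force field parameter file and validate it against a topology
#'
#' Atoms are matched by `(chain, residue_index, name)`.  Every topology
#' atom must be fully parameterized; missing atoms are reported by name.
#'
#' @param file path to a `.json` / `.yaml` / `.yml` parameter file.
#' @param top the [topology()] the parameters must cover.
#' @return A [forcefield()].
#' @export
read_forcefield <- function(file, top) {
  obj <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = FALSE)
  else yaml::read_yaml(file)
  at <- top$atoms
  n <- nrow(at)
  key <- paste(at$chain, at$resid, at$name)
  got <- vapply(obj$atoms, function(a)
    paste(a$chain, a$residue_index, a$name), character(1))
  pos <- match(key, got)
  if (anyNA(pos)) {
    missing_atoms <- paste0(at$chain[is.na(pos)], "/", at$resid[is.na(pos)],
                            "/", at$name[is.na(pos)])
    stop("force field lacks parameters for atoms: ",
         paste(missing_atoms, collapse = ", "))
  }
  getf <- function(field) {
    v <- vapply(obj$atoms, function(a) {
      x <- a[[field]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))[pos]
    if (anyNA(v))
      stop("atom(s) missing '", field, "': ",
           paste(key[is.na(v)], collapse = ", "))
    v
  }
  df <- function(entries, cols) {
    if (is.null(entries) || !length(entries))
      return(as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols)))
    rows <- lapply(entries, function(e) as.data.frame(e[cols]))
    do.call(rbind, rows)
  }
  forcefield(charges = getf("charge"), rmin_half = getf("rmin_half"),
             epsilon = getf("epsilon"), radius = getf("radius"),
             mass = getf("mass"),
             bonds = df(obj$bonds, c("i", "j", "kb", "b0")),
             angles = df(obj$angles, c("i", "j", "k", "ktheta", "theta0")),
             dihedrals = df(obj$dihedrals, c("i", "j", "k", "l", "vn2", "n", "gamma")),
             scee = obj$scee %||% 1.2, scnb = obj$scnb %||% 2.0)
}

# ---- nonbonded pair table with Amber exclusions ---------------------------

# Pairs at bond-graph distance 1 or 2 (1-2, 1-3) are excluded; distance 3
# (1-4) pairs are scaled by 1/scee (electrostatics) and 1/scnb (LJ).  The
# bond graph is the force field's own bond term list.  Returns integer
# vectors i, j and weights w_ee, w_vdw for all retained i < j pairs;
# callers that loop over frames should hoist this out of the loop.
nonbonded_pairs <- function(ff, n = length(ff$charges)) {
  scee <- ff$scee; scnb <- ff$scnb
  adj <- vector("list", n)
  b <- ff$bonds
  for (r in seq_len(nrow(b))) {
    bi <- b$i[r]; bj <- b$j[r]
    adj[[bi]] <- c(adj[[bi]], bj)
    adj[[bj]] <- c(adj[[bj]], bi)
  }
  # graph distance up to 3 by breadth-first expansion
  dist3 <- vector("list", n)
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    v <- integer(0); w <- integer(0)
    if (length(d1)) { v <- c(v, d1); w <- c(w, rep(1L, length(d1))) }
    if (length(d2)) { v <- c(v, d2); w <- c(w, rep(2L, length(d2))) }
    if (length(d3)) { v <- c(v, d3); w <- c(w, rep(3L, length(d3))) }
    dist3[[i]] <- setNames(w, v)
  }
  ii <- rep(seq_len(n), times = n - seq_len(n))
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  w_ee <- rep(1, length(ii)); w_vdw <- rep(1, length(ii))
  drop <- logical(length(ii))
  for (k in seq_along(ii)) {
    d <- dist3[[ii[k]]][as.character(jj[k])]
    if (!is.na(d)) {
      if (d <= 2L) drop[k] <- TRUE
      else { w_ee[k] <- 1 / scee; w_vdw[k] <- 1 / scnb }
    }
  }
  list(i = ii[!drop], j = jj[!drop], w_ee = w_ee[!drop], w_vdw = w_vdw[!drop])
}
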