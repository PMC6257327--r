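# Central fitting-style entry point: run the full per-frame MMPBSA
# decomposition of a dimer trajectory and return a classed result.

#' MMPBSA decomposition of a dimer trajectory
#'
#' Computes the full per-frame binding-energy matrix (18 components), the
#' trajectory-average decomposition, optionally the Schlitter entropies
#' of complex and monomers, and the stage segmentation of the smoothed,
#' mean-centred dE_MM / dE_sol series.
#'
#' @param traj a [trajectory()] of the dimer complex.
#' @param ff a [forcefield()].
#' @param cfg a [solvation_config()].
#' @param temperature analysis temperature, K.
#' @param smoothing_window odd moving-average window (frames) for the
#'   stage segmentation; default 101 (about 0.4 ns at 4 ps sampling).
#' @param entropy compute Schlitter entropies of complex/A/B and the
#'   -T dS correction (default TRUE).
#' @return Object of class `"mmpbsa"`: list with `energy`
#'   ([energy_matrix()]), `summary` ([trajectory_summary()]), `stages`
#'   ([segment_stages()] result or NULL when the trajectory is too short),
#'   `entropy` (list complex/A/B/correction or NULL), `temperature`,
#'   `smoothing_window`, `call`.
#' @seealso [summary.mmpbsa()], [plot.mmpbsa()]
#' @export
mmpbsa <- function(traj, ff, cfg = solvation_config(), temperature = 305,
                   smoothing_window = 101, entropy = TRUE) {
  em <- energy_matrix(traj, ff, cfg)
  summ <- trajectory_summary(em, temperature)
  stages <- NULL
  if (n_frames(traj) >= 2 * smoothing_window) {
    sm <- function(x) moving_average(normalize_series(x), smoothing_window)
    stages <- segment_stages(sm(em[, "de_mm"]), sm(em[, "de_sol"]),
                             window = smoothing_window)
  }
  ent <- NULL
  if (entropy) {
    s_c <- schlitter_entropy(traj, select_chain(traj$topology, "complex"),
                             temperature)
    s_a <- schlitter_entropy(traj, select_chain(traj$topology, "A"),
                             temperature)
    s_b <- schlitter_entropy(traj, select_chain(traj$topology, "B"),
                             temperature)
    ent <- list(complex = s_c, A = s_a, B = s_b,
                correction = entropy_correction(s_c$minus_t_s, s_a$minus_t_s,
                                                s_b$minus_t_s))
  }
  structure(list(energy = em, summary = summ, stages = stages,
                 entropy = ent, temperature = temperature,
                 smoothing_window = smoothing_window,
                 call = match.call()),
            class = "mmpbsa")
}

#' @export
print.mmpbsa <- function(x, ...) {
  cat("MMPBSA decomposition:", nrow(x$energy), "frames,",
      x$temperature, "K\n\n")
  print(x$summary)
  if (!is.null(x$entropy))
    cat(sprintf("\n-T dS correction: %.3f kcal/mol\n", x$entropy$correction))
  if (!is.null(x$stages) && length(x$stages$boundaries))
    cat("\nStage boundaries at frames:",
        paste(x$stages$boundaries, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname mmpbsa
#' @param object,x an `"mmpbsa"` object.
#' @param ... unused.
summary.mmpbsa <- function(object, ...) object$summary

#' Plot the smoothed, mean-centred binding-energy components
#'
#' Overlays dE_bind, dE_MM and dE_sol (each mean-centred and smoothed)
#' against time, with planted/recovered stage boundaries as dotted lines.
#'
#' @param x an [mmpbsa()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mmpbsa <- function(x, ...) {
  em <- x$energy
  tm <- attr(em, "time") / 1000
  w <- min(x$smoothing_window, nrow(em) - (1 - nrow(em) %% 2))
  if (w %% 2 == 0) w <- w - 1
  sm <- function(col) moving_average(normalize_series(em[, col]), max(1, w))
  y <- cbind(dE_bind = sm("de_bind"), dE_MM = sm("de_mm"), dE_sol = sm("de_sol"))
  graphics::matplot(tm, y, type = "l", lty = 1,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "time (ns)",
                    ylab = "mean-centred energy (kcal/mol)", ...)
  if (!is.null(x$stages))
    graphics::abline(v = tm[x$stages$boundaries], lty = 3, col = "grey40")
  graphics::legend("topright", colnames(y), lty = 1, bty = "n",
                   col = c("black", "firebrick", "steelblue"))
  invisible(x)
}

#' Residuals of the per-frame binding energy around the trajectory mean
#'
#' @param object an [mmpbsa()] object.
#' @param ... unused.
#' @return Mean-centred dE_bind series (kcal/mol).
#' @export
residuals.mmpbsa <- function(object, ...) {
  normalize_series(object$energy[, "de_bind"])
}

#' @export
coef.mmpbsa <- function(object, ...) {
  setNames(object$summary$mean, object$summary$quantity)
}
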