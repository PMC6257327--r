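# Energy time-series utilities: mean-centring, moving-average smoothing,
# stage segmentation at opposing extrema of the MM and solvation
# components, and representative-replica selection.

#' Mean-centre an energy series
#'
#' Subtracts the series mean so several components can share one plot
#' while keeping their variability.
#'
#' @param x numeric series (length >= 1).
#' @return Series with mean zero and unchanged variance.
#' @export
normalize_series <- function(x) {
  if (!length(x)) stop("empty series")
  x - mean(x)
}

#' Centred moving average with shrinking edge windows
#'
#' Interior points average over `window` frames centred on the point;
#' near the edges the window shrinks symmetrically-truncated so the
#' output has the input's length.
#'
#' @param x numeric series.
#' @param window odd window length, `1 <= window <= length(x)`.
#' @return Smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 1 || window > n) stop("window must be in [1, length(x)]")
  h <- (window - 1) / 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# indices of local minima of x over a +/- w neighbourhood (earliest frame
# on plateaus); interior points only.  An extremum must protrude from its
# neighbourhood by at least `prom` (prominence), which suppresses the
# shallow wiggles that smoothed noise always carries.
.local_extrema <- function(x, w, maximum = FALSE, prom = 0) {
  if (maximum) x <- -x
  n <- length(x)
  out <- integer(0)
  if (n < 2 * w + 1) return(out)
  for (i in (w + 1):(n - w)) {
    win <- x[(i - w):(i + w)]
    if (x[i] <= min(win) && which.min(win) == w + 1 &&
        max(win) - x[i] >= prom)
      out <- c(out, i)
  }
  out
}

#' Segment a trajectory into energetic stages
#'
#' A stage boundary is a frame where a local minimum of the (smoothed,
#' mean-centred) molecular-mechanics binding component coincides - within
#' `match_tol` frames - with a local maximum of the solvation component.
#' Extrema are defined over a `+/- window` neighbourhood with the
#' earliest frame winning ties.  Stages are labelled I, II, ... between
#' consecutive boundaries, with the series start and end as implicit
#' outer delimiters.
#'
#' @param de_mm,de_sol equal-length numeric series, already mean-centred
#'   and smoothed (see [normalize_series()], [moving_average()]).
#' @param window extremum neighbourhood half-width, frames.
#' @param match_tol maximum frame offset between a dE_MM minimum and the
#'   matching dE_sol maximum.
#' @param prominence minimum height an extremum must protrude from its
#'   `+/- window` neighbourhood; the default, half the standard deviation
#'   of each series, suppresses the shallow chance extrema that smoothed
#'   noise produces in featureless stretches while passing any real
#'   energetic event.
#' @return Object of class `"stage_boundaries"`: list with `boundaries`
#'   (frame indices), `labels`, and `stages` (data frame with per-stage
#'   frame ranges and mean dE_MM / dE_sol).
#' @export
segment_stages <- function(de_mm, de_sol, window = 101,
                           match_tol = window %/% 2, prominence = NULL) {
  if (length(de_mm) != length(de_sol)) stop("series lengths differ")
  n <- length(de_mm)
  if (n < 2 * window) stop("series shorter than twice the window")
  mins <- .local_extrema(de_mm, window, maximum = FALSE,
                         prom = prominence %||% (0.5 * stats::sd(de_mm)))
  maxs <- .local_extrema(de_sol, window, maximum = TRUE,
                         prom = prominence %||% (0.5 * stats::sd(de_sol)))
  boundaries <- integer(0)
  for (m in mins) {
    if (any(abs(maxs - m) <= match_tol)) boundaries <- c(boundaries, m)
  }
  boundaries <- sort(unique(boundaries))
  edges <- c(1L, boundaries, n)
  stages <- data.frame(
    stage = as.character(utils::as.roman(seq_len(length(edges) - 1L))),
    from = head(edges, -1), to = tail(edges, -1))
  stages$mean_de_mm <- mapply(function(a, b) mean(de_mm[a:b]),
                              stages$from, stages$to)
  stages$mean_de_sol <- mapply(function(a, b) mean(de_sol[a:b]),
                               stages$from, stages$to)
  structure(list(boundaries = boundaries,
                 labels = as.character(utils::as.roman(seq_along(boundaries))),
                 stages = stages),
            class = "stage_boundaries")
}

#' @export
print.stage_boundaries <- function(x, ...) {
  cat("stage boundaries at frames:",
      if (length(x$boundaries)) paste(x$boundaries, collapse = ", ") else "(none)",
      "\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Select the most representative replica
#'
#' Computes, for each replica's energy matrix, the mean per-frame
#' inter-chain interaction energy (electrostatic + van der Waals +
#' solvation change) over the final `tail` ns, and returns the replica
#' with the most favourable (lowest) mean.  Ties go to the lowest index.
#'
#' @param replica_matrices list of [energy_matrix()] objects (each must
#'   carry its `time` attribute).
#' @param tail tail window, ns.
#' @param mode `"favorable"` (default: minimize the interaction energy,
#'   i.e. pick the most negative) or `"maximum"` (literal maximization,
#'   for sensitivity checks).
#' @return Index (1-based) into `replica_matrices`.
#' @export
select_replica <- function(replica_matrices, tail = 2,
                           mode = c("favorable", "maximum")) {
  mode <- match.arg(mode)
  if (!length(replica_matrices)) stop("empty replica set")
  score <- vapply(replica_matrices, function(em) {
    tm <- attr(em, "time")
    if (is.null(tm)) stop("energy matrix lacks a time attribute")
    span <- tm[length(tm)] - tm[1]
    if (tail * 1000 > span + 1e-6)
      stop("tail window (", tail, " ns) exceeds replica span (",
           span / 1000, " ns)")
    keep <- tm > tm[length(tm)] - tail * 1000 + 1e-9
    inter <- (em[keep, "e_ele_C"] - em[keep, "e_ele_A"] - em[keep, "e_ele_B"]) +
             (em[keep, "e_vdw_C"] - em[keep, "e_vdw_A"] - em[keep, "e_vdw_B"]) +
             em[keep, "de_sol"]
    mean(inter)
  }, numeric(1))
  if (mode == "favorable") which.min(score) else which.max(score)
}
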