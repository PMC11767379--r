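# Reflection bookkeeping: indexed amplitudes with a work / free / missing
# partition.  One row per Friedel pair, canonical hemisphere representative.

#' Reflection set
#'
#' @param hkl n x 3 integer matrix of Miller indices (one representative per
#'   Friedel pair; (0,0,0) excluded).
#' @param f_obs Nonnegative observed amplitudes; `NA` for unmeasured
#'   reflections.
#' @param cell A [unit_cell()] (used to compute resolutions).
#' @param sigma Optional amplitude standard deviations.
#' @param status Character vector in `{"work","free","missing"}`; defaults to
#'   `"work"` where `f_obs` is available, `"missing"` otherwise. (Reflections
#'   beyond the run's low-resolution cutoff are additionally treated as
#'   calculated-amplitude-filled at run time, mirroring beam-stop handling.)
#' @return A data.frame of class `reflection_set` with columns
#'   `h,k,l,f_obs,sigma,d,status` and the cell stored as attribute `"cell"`.
#' @export
reflection_set <- function(hkl, f_obs, cell, sigma = NULL, status = NULL) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  n <- nrow(hkl)
  if (length(f_obs) != n) stop("reflection_set: f_obs length mismatch")
  if (any(rowSums(hkl != 0) == 0)) stop("reflection_set: (0,0,0) not allowed")
  if (any(f_obs < 0, na.rm = TRUE)) stop("reflection_set: amplitudes must be >= 0")
  if (is.null(status)) status <- ifelse(is.na(f_obs), "missing", "work")
  if (!all(status %in% c("work", "free", "missing")))
    stop("reflection_set: invalid status label")
  d <- resolution_of(hkl, cell)
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    f_obs = f_obs,
                    sigma = if (is.null(sigma)) NA_real_ else sigma,
                    d = d, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "cell") <- cell
  class(out) <- c("reflection_set", "data.frame")
  out
}

#' Enumerate unique reflections to a resolution limit
#'
#' All Miller indices with `d >= d_min`, one canonical representative per
#' Friedel pair (`h > 0`, or `h = 0, k > 0`, or `h = k = 0, l > 0`).
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @return n x 3 integer matrix.
#' @export
generate_hkl <- function(cell, d_min) {
  smax <- 1 / d_min
  hmax <- ceiling(smax * max(cell$a, cell$b, cell$c))
  rng <- -hmax:hmax
  g <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g <- g[keep, , drop = FALSE]
  Gs <- reciprocal_metric(cell)
  s2 <- rowSums((g %*% Gs) * g)
  g <- g[s2 <= smax^2 + 1e-12, , drop = FALSE]
  ord <- order(rowSums((g %*% Gs) * g), g[, 1], g[, 2], g[, 3])
  unname(g[ord, , drop = FALSE])
}

#' Assign a cross-validation (free) set
#'
#' Uniform random relabelling of a fraction of the measured reflections as
#' `free`; these are excluded from phasing (their calculated amplitudes pass
#' through the amplitude projection untouched) and only monitored via Rfree.
#'
#' @param refl A [reflection_set()].
#' @param fraction Fraction of measured reflections to hold out (default 0.01).
#' @param seed Integer RNG seed; the same seed reproduces the same partition.
#' @return The reflection set with updated `status`.
#' @export
assign_free_set <- function(refl, fraction = 0.01, seed = 1L) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("assign_free_set: fraction must be in (0, 0.5)")
  measured <- which(refl$status != "missing")
  n_free <- round(length(measured) * fraction)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  free_idx <- sample(measured, n_free)
  refl$status[measured] <- "work"
  refl$status[free_idx] <- "free"
  refl
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
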