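# Origin / enantiomer alignment of equivalent density representations.
# Amplitude-only data cannot distinguish maps related by allowed origin
# shifts or density inversion; maps must be brought to a common frame before
# genetic exchange, averaging or comparison.

#' Frame transform
#'
#' A permitted map transformation: fractional translation plus optional
#' density inversion `g(r) -> g(-r)`. Applied as
#' `g_out(x) = g_in(inv * x + shift)` with exact grid-index arithmetic.
#'
#' @param shift Fractional translation (length 3, components in [0,1)).
#' @param inverted Logical inversion flag.
#' @return Object of class `frame_transform`.
#' @export
frame_transform <- function(shift = c(0, 0, 0), inverted = FALSE) {
  shift <- (shift %% 1 + 1) %% 1
  structure(list(shift = shift, inverted = isTRUE(inverted)),
            class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("frame_transform shift=(%.4f, %.4f, %.4f) inverted=%s\n",
              x$shift[1], x$shift[2], x$shift[3], x$inverted))
  invisible(x)
}

#' Invert a frame transform
#' @param t A [frame_transform()].
#' @return The inverse transform (`apply_transform(apply_transform(g, t),
#'   invert_transform(t))` restores `g` bitwise).
#' @export
invert_transform <- function(t) {
  if (t$inverted) t else frame_transform(-t$shift, FALSE)
}

#' Compose frame transforms
#' @param t1,t2 Transforms; the result acts as `t1` after `t2`... i.e.
#'   `apply_transform(g, compose_transforms(t1, t2))` equals
#'   `apply_transform(apply_transform(g, t1), t2)`.
#' @return A [frame_transform()].
#' @export
compose_transforms <- function(t1, t2) {
  # g1(x) = g(s1 + e1 x); g2(x) = g1(s2 + e2 x) = g(s1 + e1 s2 + e1 e2 x)
  e1 <- if (t1$inverted) -1 else 1
  frame_transform(t1$shift + e1 * t2$shift,
                  xor(t1$inverted, t2$inverted))
}

#' Apply a frame transform to a density
#'
#' Exact grid-index permutation (no interpolation). The shift must be
#' commensurate with the grid.
#'
#' @param g A [density_grid()].
#' @param t A [frame_transform()].
#' @return Transformed `density_grid`.
#' @export
apply_transform <- function(g, t) {
  dims <- g$spec$dims
  sidx <- t$shift * dims
  if (max(abs(sidx - round(sidx))) > 1e-6)
    stop("apply_transform: shift incompatible with grid")
  sidx <- as.integer(round(sidx))
  e <- if (t$inverted) -1L else 1L
  m1 <- ((e * (0:(dims[1] - 1)) + sidx[1]) %% dims[1]) + 1L
  m2 <- ((e * (0:(dims[2] - 1)) + sidx[2]) %% dims[2]) + 1L
  m3 <- ((e * (0:(dims[3] - 1)) + sidx[3]) %% dims[3]) + 1L
  density_grid(g$values[m1, m2, m3], g$spec)
}

#' Restore a density to its original frame
#' @param g Transformed density.
#' @param t The transform that produced it.
#' @return The original density.
#' @export
restore_origin <- function(g, t) apply_transform(g, invert_transform(t))

# Candidate shift values for a non-polar axis, restricted to grid-exact ones.
.nonpolar_candidates <- function(n) {
  cand <- c(0, 1/2, 1/4, 3/4, 1/3, 2/3, 1/6, 5/6)
  cand[abs(cand * n - round(cand * n)) < 1e-9]
}

# Does transform (tau, inv) conjugate the operator set onto itself mod 1?
.conjugates_to_group <- function(ops, tau, inv) {
  key <- function(R, t) paste(c(R, round(((t %% 1) + 1) %% 1, 9)), collapse = ",")
  op_keys <- vapply(ops, function(o) key(o$R, o$t), character(1))
  for (o in ops) {
    tnew <- if (inv) tau - as.vector(o$R %*% tau) - o$t
            else     o$t + tau - as.vector(o$R %*% tau)
    if (!(key(o$R, tnew) %in% op_keys)) return(FALSE)
  }
  TRUE
}

#' Allowed origin shifts (and inversions)
#'
#' All frame transforms mapping the space-group operator set onto itself
#' modulo lattice translations, found by brute-force conjugation. Along polar
#' axes candidates are enumerated at grid resolution; along non-polar axes at
#' the crystallographic special fractions compatible with the grid.
#'
#' @param sg A [space_group()].
#' @param spec A `grid_spec`.
#' @return List of [frame_transform()] objects, identity first, non-inverted
#'   before inverted, lexicographic shift order within each block.
#' @export
allowed_origin_shifts <- function(sg, spec) {
  dims <- spec$dims
  cands <- lapply(1:3, function(a) {
    if (sg$polar_axes[a]) (0:(dims[a] - 1)) / dims[a]
    else .nonpolar_candidates(dims[a])
  })
  grid <- expand.grid(s1 = cands[[1]], s2 = cands[[2]], s3 = cands[[3]])
  grid <- grid[order(grid$s1, grid$s2, grid$s3), ]
  out <- list()
  pure_translation <- all(vapply(sg$operators,
                                 function(o) all(o$R == diag(3)), logical(1)))
  for (inv in c(FALSE, TRUE)) {
    for (r in seq_len(nrow(grid))) {
      tau <- as.numeric(grid[r, ])
      ok <- if (pure_translation) TRUE
            else .conjugates_to_group(sg$operators, tau, inv)
      if (ok) out[[length(out) + 1L]] <- frame_transform(tau, inv)
    }
  }
  out
}

# Logical masks over the shift grid of allowed translations, for the FFT
# alignment search: list(plain = 3D logical, inverted = 3D logical).
.allowed_shift_masks <- function(sg, spec) {
  dims <- spec$dims
  plain <- array(FALSE, dims)
  invm <- array(FALSE, dims)
  pure_translation <- all(vapply(sg$operators,
                                 function(o) all(o$R == diag(3)), logical(1)))
  if (pure_translation) {
    plain[] <- TRUE
    invm[] <- TRUE
    return(list(plain = plain, inverted = invm))
  }
  for (tr in allowed_origin_shifts(sg, spec)) {
    idx <- as.integer(round(tr$shift * dims)) %% dims + 1L
    if (tr$inverted) invm[idx[1], idx[2], idx[3]] <- TRUE
    else plain[idx[1], idx[2], idx[3]] <- TRUE
  }
  list(plain = plain, inverted = invm)
}

# Cross-correlation over all cyclic shifts via FFT.
#   plain[s]    = sum_x ref(x) * cand(x + s)
#   inverted[s] = sum_x ref(x) * cand(s - x)
.shift_correlations <- function(ref_vals, cand_vals) {
  A <- stats::fft(ref_vals)
  B <- stats::fft(cand_vals)
  N <- length(ref_vals)
  list(plain = Re(stats::fft(Conj(A) * B, inverse = TRUE)) / N,
       inverted = Re(stats::fft(A * B, inverse = TRUE)) / N)
}

# Pick the best allowed transform from correlation arrays; canonical order
# (non-inverted first, ascending linear shift index) breaks ties, so the
# identity wins among equals.
.best_allowed_transform <- function(corr, masks, dims) {
  best <- -Inf; best_t <- frame_transform()
  for (inv in c(FALSE, TRUE)) {
    cm <- if (inv) corr$inverted else corr$plain
    mk <- if (inv) masks$inverted else masks$plain
    if (!any(mk)) next
    vals <- cm[mk]
    i <- which.max(vals)           # first maximum in index order
    if (vals[i] > best + 1e-9) {
      best <- vals[i]
      lin <- which(mk)[i] - 1L
      s1 <- lin %% dims[1]
      s2 <- (lin %/% dims[1]) %% dims[2]
      s3 <- lin %/% (dims[1] * dims[2])
      best_t <- frame_transform(c(s1, s2, s3) / dims, inv)
    }
  }
  list(transform = best_t, score = best)
}

#' Align a density to a reference
#'
#' Searches all allowed origin shifts and inversions for the transform whose
#' protein mask (Gaussian-weighted density + envelope quantile) best overlaps
#' the reference's protein mask (Jaccard index; equivalent to maximizing the
#' intersection since both masks have fixed point counts). Ties are broken
#' identity-first.
#'
#' @param g Density to align.
#' @param ref Reference density (highest-fitness individual in the GA).
#' @param solvent_fraction Solvent fraction for envelope determination.
#' @param sg A [space_group()].
#' @param sigma Weighting radius for the masks (default 3 A).
#' @param ref_mask Optional precomputed reference mask (logical array).
#' @return List with `aligned` (density_grid), `transform`
#'   ([frame_transform()]), `jaccard` (mask overlap of the winner).
#' @export
align_to_reference <- function(g, ref, solvent_fraction, sg, sigma = 3,
                               ref_mask = NULL) {
  .check_same_spec(g, ref)
  if (is.null(ref_mask))
    ref_mask <- determine_envelope(gaussian_weighted_density(ref, sigma),
                                   solvent_fraction)$protein
  g_mask <- determine_envelope(gaussian_weighted_density(g, sigma),
                               solvent_fraction)$protein
  corr <- .shift_correlations(ref_mask * 1, g_mask * 1)
  masks <- .allowed_shift_masks(sg, g$spec)
  pick <- .best_allowed_transform(corr, masks, g$spec$dims)
  inter <- round(pick$score)
  union <- sum(ref_mask) + sum(g_mask) - inter
  list(aligned = apply_transform(g, pick$transform),
       transform = pick$transform,
       jaccard = inter / union)
}

#' Align by direct density correlation
#'
#' Like [align_to_reference()] but maximizes the real-space Pearson
#' correlation of the density values themselves; used for scoring a
#' reconstruction against a known truth map.
#'
#' @param g Density to align.
#' @param ref Reference density.
#' @param sg A [space_group()].
#' @return List with `aligned`, `transform`, `correlation`.
#' @export
align_by_correlation <- function(g, ref, sg) {
  .check_same_spec(g, ref)
  a <- as.vector(ref$values) - mean(ref$values)
  b <- as.vector(g$values) - mean(g$values)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) stop("align_by_correlation: constant map")
  corr <- .shift_correlations(array(a, g$spec$dims), array(b, g$spec$dims))
  masks <- .allowed_shift_masks(sg, g$spec)
  pick <- .best_allowed_transform(corr, masks, g$spec$dims)
  list(aligned = apply_transform(g, pick$transform),
       transform = pick$transform,
       correlation = pick$score / denom)
}

#' Average aligned densities
#'
#' Pointwise mean of maps already brought to a common frame; averaging
#' independently converged reconstructions cancels their uncorrelated errors.
#'
#' @param densities Nonempty list of `density_grid`s sharing one spec.
#' @return The mean `density_grid`.
#' @export
average_aligned <- function(densities) {
  if (length(densities) == 0) stop("average_aligned: empty list")
  acc <- densities[[1]]$values
  if (length(densities) > 1)
    for (i in 2:length(densities)) {
      .check_same_spec(densities[[i]], densities[[1]])
      acc <- acc + densities[[i]]$values
    }
  density_grid(acc / length(densities), densities[[1]]$spec)
}

#' Real-space Pearson correlation of two maps
#' @param a,b `density_grid`s on the same spec.
#' @return Correlation coefficient.
#' @export
map_correlation <- function(a, b) {
  .check_same_spec(a, b)
  stats::cor(as.vector(a$values), as.vector(b$values))
}
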