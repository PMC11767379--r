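# Self-contained toy crystals: known ground-truth density, amplitude-only
# reflection data with a simulated beam-stop gap, and a reference histogram --
# everything needed to exercise the full pipeline without external data.

#' Toy crystal specification
#'
#' @param cell Unit cell (default 31 A cube, which maps to a 32^3 grid at
#'   3 A resolution with 3x oversampling).
#' @param sg_symbol Space group symbol (default `"P1"`).
#' @param d_min Resolution limit in Angstrom.
#' @param n_blobs Number of Gaussian blobs forming the "protein". The default
#'   emulates a small protein as a cluster of atom-like scatterers.
#' @param blob_width Range of blob standard deviations in Angstrom. Widths
#'   below ~1 A keep the simulated amplitude spectrum significant out to the
#'   resolution limit, as real atomic structures do.
#' @param solvent_fraction Target solvent fraction in [0.3, 0.9].
#' @param noise Multiplicative lognormal amplitude noise sigma (0 = exact).
#' @param beamstop_d Reflections with d above this (Angstrom) are marked
#'   missing, emulating the beam-stop gap in low-angle data.
#' @param free_fraction Fraction of measured reflections held out as free.
#' @param seed RNG seed; the same seed reproduces the same bundle.
#' @return Object of class `toy_crystal_spec`.
#' @export
toy_crystal_spec <- function(cell = unit_cell(31, 31, 31), sg_symbol = "P1",
                             d_min = 3, n_blobs = 150,
                             blob_width = c(0.7, 1.1),
                             solvent_fraction = 0.72, noise = 0,
                             beamstop_d = 25, free_fraction = 0.01,
                             seed = 1L) {
  if (solvent_fraction < 0.3 || solvent_fraction > 0.9)
    stop("toy_crystal_spec: solvent_fraction must be in [0.3, 0.9]")
  if (n_blobs < 1) stop("toy_crystal_spec: need at least one blob")
  structure(list(cell = cell, sg_symbol = sg_symbol, d_min = d_min,
                 n_blobs = n_blobs, blob_width = blob_width,
                 solvent_fraction = solvent_fraction, noise = noise,
                 beamstop_d = beamstop_d, free_fraction = free_fraction,
                 seed = as.integer(seed)),
            class = "toy_crystal_spec")
}

# Sum-of-Gaussians density: blob centers (fractional, 3 x n), widths (A).
.blob_density <- function(spec, centers, widths) {
  dims <- spec$dims
  O <- orthogonalization_matrix(spec$cell)
  i1 <- rep.int(0:(dims[1] - 1), dims[2] * dims[3]) / dims[1]
  i2 <- rep.int(rep(0:(dims[2] - 1), each = dims[1]), dims[3]) / dims[2]
  i3 <- rep(0:(dims[3] - 1), each = dims[1] * dims[2]) / dims[3]
  acc <- numeric(prod(dims))
  for (b in seq_len(ncol(centers))) {
    df <- rbind(i1 - centers[1, b], i2 - centers[2, b], i3 - centers[3, b])
    df <- df - round(df)               # minimal image
    cart <- O %*% df
    r2 <- colSums(cart^2)
    acc <- acc + exp(-r2 / (2 * widths[b]^2))
  }
  array(acc, dims)
}

#' Generate a toy crystal bundle
#'
#' Places random Gaussian blobs inside one contiguous sub-box of the cell
#' (a connected protein region), symmetrizes over the space group, flattens
#' the solvent region to zero (iterating the envelope until stable so the
#' truth exactly satisfies the solvent constraint), normalizes the density
#' to [0, 1], and computes amplitude-only diffraction data with optional
#' multiplicative noise and a beam-stop gap.
#'
#' @param spec A [toy_crystal_spec()].
#' @return List with `truth` (density_grid), `phases` (data.frame h,k,l,
#'   amp, phase of the truth), `refl` ([reflection_set()] with noisy
#'   amplitudes and work/free/missing labels), `ref_hist`
#'   ([reference_histogram()] from the truth protein region), `mask`
#'   (truth envelope_mask), `grid_spec`, `sg`, and the input `spec`.
#' @export
generate_toy_crystal <- function(spec = toy_crystal_spec()) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(spec$seed)
  sg <- space_group(spec$sg_symbol)
  gspec <- build_grid(spec$cell, spec$d_min, oversampling = 3)
  # blob centers inside a contiguous sub-box -> connected protein region
  centers <- rbind(stats::runif(spec$n_blobs, 0.15, 0.70),
                   stats::runif(spec$n_blobs, 0.15, 0.70),
                   stats::runif(spec$n_blobs, 0.15, 0.70))
  widths <- stats::runif(spec$n_blobs, spec$blob_width[1], spec$blob_width[2])
  g0 <- .blob_density(gspec, centers, widths)
  g0 <- symmetrize_density(density_grid(g0, gspec), sg)$values
  # iterate envelope determination + solvent flattening-to-zero until the
  # mask is stable, so the truth is an exact fixed point of its constraints
  sigma_mask <- 3
  vals <- g0
  mask <- NULL
  for (it in 1:20) {
    w <- gaussian_weighted_density(density_grid(vals, gspec), sigma_mask)
    m <- determine_envelope(w, spec$solvent_fraction)
    vals2 <- vals
    vals2[!m$protein] <- 0
    stable <- !is.null(mask) && identical(m$protein, mask$protein)
    mask <- m
    vals <- vals2
    if (stable) break
  }
  if (!stable)
    stop("generate_toy_crystal: infeasible solvent target (envelope did not stabilize)")
  vals <- vals / max(vals)                       # normalized scale, support in [0,1]
  truth <- density_grid(vals, gspec)
  hkl <- generate_hkl(spec$cell, spec$d_min)
  sf <- density_to_structure_factors(truth, hkl)
  f_true <- sf$amp
  n <- length(f_true)
  f_obs <- if (spec$noise > 0) f_true * stats::rlnorm(n, 0, spec$noise) else f_true
  refl <- reflection_set(hkl, f_obs, spec$cell)
  refl$status[refl$d > spec$beamstop_d] <- "missing"
  refl$f_obs[refl$status == "missing"] <- NA_real_
  refl <- assign_free_set(refl, spec$free_fraction, seed = spec$seed + 90001L)
  ref_hist <- reference_histogram_from_density(truth, mask)
  list(truth = truth, phases = sf, refl = refl, ref_hist = ref_hist,
       mask = mask, grid_spec = gspec, sg = sg, spec = spec)
}

#' Reference histogram from a density and mask
#'
#' Sorted protein-region density values (subsampled to at most `max_n`),
#' standing in for the protein density distribution of a solved reference
#' structure at comparable resolution.
#'
#' @param g A [density_grid()].
#' @param mask An envelope mask (protein region must be nonempty).
#' @param max_n Maximum sample size retained (default 1e5).
#' @return A [reference_histogram()].
#' @export
reference_histogram_from_density <- function(g, mask, max_n = 1e5) {
  v <- g$values[mask$protein]
  if (length(v) == 0) stop("reference_histogram_from_density: empty protein region")
  if (length(v) > max_n) {
    # deterministic quantile subsample preserves the distribution
    v <- stats::quantile(v, probs = (seq_len(max_n) - 0.5) / max_n,
                         names = FALSE, type = 7)
  }
  reference_histogram(v)
}
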