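# One iteration of the direct phasing cycle: amplitude projection, Gaussian
# weighted density, envelope determination, histogram matching, HIO solvent
# feedback / solvent flattening, and the progress metrics.

#' Least-squares amplitude scale
#'
#' `lambda = sum(|Fobs||Fcal|) / sum(|Fcal|^2)` over a subset of reflections:
#' the least-squares fit of observed onto calculated amplitudes, recomputed
#' every iteration.
#'
#' @param f_obs,f_cal Nonnegative amplitude vectors (same length).
#' @param subset Indices of the reflections to use (default: all).
#' @return The scale factor lambda (> 0 for non-degenerate input).
#' @export
compute_scale <- function(f_obs, f_cal, subset = seq_along(f_obs)) {
  if (length(subset) == 0) stop("compute_scale: empty subset")
  fo <- f_obs[subset]; fc <- f_cal[subset]
  den <- sum(fc * fc)
  if (den == 0) stop("compute_scale: all calculated amplitudes are zero")
  sum(fo * fc) / den
}

#' Crystallographic R factor
#'
#' `R = sum(||Fobs| - lambda |Fcal||) / sum(|Fobs|)` over a subset.
#'
#' @param f_obs,f_cal Amplitude vectors.
#' @param lambda Scale factor applied to `f_cal`.
#' @param subset Indices to use (default: all).
#' @return Nonnegative R value; 0 iff perfect scaled agreement.
#' @export
r_factor <- function(f_obs, f_cal, lambda = 1, subset = seq_along(f_obs)) {
  if (length(subset) == 0) stop("r_factor: empty subset")
  fo <- f_obs[subset]
  den <- sum(fo)
  if (den == 0) stop("r_factor: sum of observed amplitudes is zero")
  sum(abs(fo - lambda * f_cal[subset])) / den
}

#' Mean phase error
#'
#' Unweighted mean over a subset of `acos(cos(phi_true - phi_cal))`, the
#' wrapped absolute phase difference, in degrees in `[0, 180]`.
#'
#' @param phi_true,phi_cal Phases in degrees.
#' @param subset Indices to use (default: all).
#' @return Mean phase error in degrees.
#' @export
mean_phase_error <- function(phi_true, phi_cal, subset = seq_along(phi_true)) {
  if (length(subset) == 0) stop("mean_phase_error: empty subset")
  dphi <- (phi_true[subset] - phi_cal[subset]) * pi / 180
  mean(acos(pmin(1, pmax(-1, cos(dphi))))) * 180 / pi
}

#' Estimate amplitudes of missing reflections
#'
#' Missing (beam-stop) and low-resolution-replaced reflections get
#' `|Fmiss(h)| = (sum_work |Fobs| / sum_work |Fcal|) * |Fcal(h)|`.
#'
#' @param f_obs Observed amplitudes (only `work_idx` entries are used).
#' @param f_cal Calculated amplitudes for all reflections.
#' @param work_idx Indices of the working set.
#' @param fill_idx Indices of the reflections to estimate.
#' @return Estimated amplitudes for `fill_idx`.
#' @export
fill_missing_amplitudes <- function(f_obs, f_cal, work_idx, fill_idx) {
  den <- sum(f_cal[work_idx])
  if (den == 0) stop("fill_missing_amplitudes: working-set |Fcal| sum is zero")
  num <- sum(f_obs[work_idx])
  if (num <= 0) stop("fill_missing_amplitudes: working-set |Fobs| sum not positive")
  (num / den) * f_cal[fill_idx]
}

#' Sigma0 schedule for the weighted-density radius
#'
#' Linear ramp of the Gaussian averaging radius from `sigma_start` (default
#' 4.0 A) at iteration 0 to `sigma_end` (default 3.0 A) at iteration
#' `ramp_end`, constant afterwards. Larger early radii tolerate the noisy
#' density of early iterations; smaller late radii sharpen the envelope.
#'
#' @param iter Iteration number (>= 0).
#' @param cfg A [phasing_config()] (fields `sigma_start`, `sigma_end`,
#'   `ramp_end`).
#' @return sigma0 in Angstrom.
#' @export
sigma0_schedule <- function(iter, cfg) {
  if (cfg$sigma_end > cfg$sigma_start)
    stop("sigma0_schedule: sigma_end must not exceed sigma_start")
  if (cfg$ramp_end <= 0) return(cfg$sigma_end)
  f <- pmin(pmax(iter, 0) / cfg$ramp_end, 1)
  cfg$sigma_start + f * (cfg$sigma_end - cfg$sigma_start)
}

# FFT of the periodic Gaussian kernel exp(-r^2 / (2 sigma^2)) sampled at
# minimal-image distances; cached per (spec, sigma) in a private environment.
.kernel_cache <- new.env(parent = emptyenv())

.kernel_fft <- function(spec, sigma, r2 = NULL) {
  key <- paste(paste(spec$dims, collapse = "x"), format(sigma, digits = 12))
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (is.null(r2)) r2 <- .min_image_r2(spec)
  K <- exp(-r2 / (2 * sigma * sigma))
  KF <- stats::fft(K, inverse = TRUE)    # unnormalized e^{+} transform, real
  # keep the cache tiny: only the most recent kernel (population iterates in
  # lockstep, so consecutive calls share sigma)
  rm(list = ls(.kernel_cache), envir = .kernel_cache)
  assign(key, KF, envir = .kernel_cache)
  KF
}

#' Gaussian-weighted average density
#'
#' Periodic convolution of the density with the kernel
#' `exp(-r^2 / (2 sigma0^2))` at minimal-image inter-grid distances,
#' implemented by FFT. This local average drives protein/solvent envelope
#' determination.
#'
#' @param grid A [density_grid()].
#' @param sigma0 Averaging radius in Angstrom (> 0).
#' @return A `density_grid` of weighted average values.
#' @export
gaussian_weighted_density <- function(grid, sigma0) {
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("gaussian_weighted_density: sigma0 must be > 0")
  spec <- grid$spec
  KF <- .kernel_fft(spec, sigma0)
  GF <- stats::fft(grid$values, inverse = TRUE) / length(grid$values)
  density_grid(Re(stats::fft(GF * KF)), spec)
}

#' Determine the protein/solvent envelope
#'
#' Grid points whose weighted average density exceeds the
#' `solvent_fraction`-quantile are labelled protein; the protein point count
#' is exactly `round((1 - solvent_fraction) * N)`. Ties at the threshold are
#' broken by stable ascending index order (higher indices fill remaining
#' protein slots).
#'
#' @param w A `density_grid` of weighted average density.
#' @param solvent_fraction Target solvent fraction in (0, 1).
#' @return An object of class `envelope_mask`: list with `protein` (logical
#'   3D array) and `solvent_fraction` (achieved value).
#' @export
determine_envelope <- function(w, solvent_fraction) {
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("determine_envelope: solvent_fraction must be in (0, 1)")
  v <- as.vector(w$values)
  N <- length(v)
  n_prot <- round((1 - solvent_fraction) * N)
  n_solv <- N - n_prot
  prot <- logical(N)
  if (n_solv == 0) {
    prot[] <- TRUE
  } else if (n_prot > 0) {
    thr <- sort(v, partial = n_solv)[n_solv]
    prot <- v > thr
    deficit <- n_prot - sum(prot)
    if (deficit > 0) {
      ties <- which(v == thr)
      if (deficit == length(ties) && deficit == N)
        warning("determine_envelope: degenerate (constant) weighted density")
      prot[ties[seq.int(length(ties) - deficit + 1, length(ties))]] <- TRUE
    }
  }
  structure(list(protein = array(prot, w$spec$dims),
                 solvent_fraction = 1 - sum(prot) / N),
            class = "envelope_mask")
}

# Reference histogram ------------------------------------------------------

#' Reference density histogram
#'
#' A sorted sample of protein-region density values from a reference
#' structure at comparable resolution; its empirical quantile function is the
#' target distribution for histogram matching.
#'
#' @param values Numeric sample of protein-region density values.
#' @return Object of class `reference_histogram` (sorted numeric vector).
#' @export
reference_histogram <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("reference_histogram: need a nonempty finite sample")
  structure(sort(values), class = "reference_histogram")
}

# Quantiles of the reference at probabilities p, by linear interpolation of
# the sorted sample at plotting positions (k - 0.5)/n, clamped at the ends.
.ref_quantile <- function(ref, p) {
  n <- length(ref)
  if (n == 1) return(rep(unclass(ref), length(p)))
  stats::approx(x = (seq_len(n) - 0.5) / n, y = unclass(ref),
                xout = p, rule = 2)$y
}

#' Histogram-match the protein region
#'
#' Rank-transforms protein-region density values so their sorted sequence
#' equals the reference quantiles at plotting positions `(k - 0.5)/n`. The
#' transform is monotone (rank order preserved; ties broken by index order);
#' solvent values are untouched.
#'
#' @param grid A `density_grid` (typically the amplitude-projected density).
#' @param mask An [determine_envelope()] mask.
#' @param ref A [reference_histogram()].
#' @return A `density_grid` with matched protein region.
#' @export
histogram_match <- function(grid, mask, ref) {
  prot <- as.vector(mask$protein)
  m <- sum(prot)
  if (m == 0) stop("histogram_match: empty protein region")
  v <- as.vector(grid$values)
  vals <- v[prot]
  ord <- order(vals)                      # stable: ties keep index order
  target <- .ref_quantile(ref, (seq_len(m) - 0.5) / m)
  matched <- numeric(m)
  matched[ord] <- target
  v[prot] <- matched
  density_grid(array(v, grid$spec$dims), grid$spec)
}

#' Hybrid input-output update
#'
#' Protein points take the modified (histogram-matched) density; solvent
#' points get the negative-feedback update `g_prev - beta * g_proj`, which
#' relaxes the solvent toward constancy while avoiding stagnation.
#'
#' @param g_prev Input density of this iteration (`g_k`).
#' @param g_proj Amplitude-projected density (`g'_k`).
#' @param g_protein_mod Protein-modified density (histogram-matched `g'_k`).
#' @param mask Envelope mask.
#' @param beta Feedback parameter in (0, 1].
#' @return The next density `g_{k+1}`.
#' @export
hio_step <- function(g_prev, g_proj, g_protein_mod, mask, beta) {
  .check_same_spec(g_prev, g_proj)
  .check_same_spec(g_prev, g_protein_mod)
  if (beta <= 0 || beta > 1) stop("hio_step: beta must be in (0, 1]")
  prot <- mask$protein
  out <- g_prev$values - beta * g_proj$values
  out[prot] <- g_protein_mod$values[prot]
  density_grid(out, g_prev$spec)
}

#' Solvent flattening update
#'
#' Solvent points are set to the mean projected density over the solvent
#' region; protein points keep the (optionally histogram-matched) projected
#' density. Used for the final refinement cycles after convergence.
#'
#' @param g_proj Amplitude-projected density.
#' @param mask Envelope mask.
#' @param g_protein_mod Optional protein-modified density (defaults to
#'   `g_proj`).
#' @return Flattened `density_grid`.
#' @export
solvent_flatten_step <- function(g_proj, mask, g_protein_mod = g_proj) {
  prot <- mask$protein
  if (all(prot)) stop("solvent_flatten_step: empty solvent region")
  out <- g_proj$values
  out[!prot] <- mean(out[!prot])
  out[prot] <- g_protein_mod$values[prot]
  density_grid(out, g_proj$spec)
}

# Phasing engine -----------------------------------------------------------
# Precomputes everything reused across iterations: reflection index maps,
# subset masks, min-image distances, the matched-value table. The engine is
# an environment so cached members can be filled lazily.

.make_engine <- function(refl, spec, cfg, ref_hist, sg = NULL,
                         ncs = NULL) {
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$dims <- spec$dims
  e$N <- prod(spec$dims)
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  storage.mode(hkl) <- "integer"
  .check_nyquist(hkl, spec$dims)
  e$ip <- .hkl_linear_index(hkl, spec$dims)
  e$im <- .hkl_linear_index(-hkl, spec$dims)
  if (any(e$ip == e$im))
    stop("reflection coincides with its Friedel mate on this grid")
  lowres <- refl$d > cfg$lowres_cutoff
  e$work <- which(refl$status == "work" & !lowres)
  e$free <- which(refl$status == "free" & !lowres)
  e$fill <- which(refl$status == "missing" | lowres)
  if (length(e$work) == 0) stop("no working reflections below the low-resolution cutoff")
  e$f_obs <- refl$f_obs
  e$r2 <- .min_image_r2(spec)
  e$n_prot <- round((1 - cfg$solvent_fraction) * e$N)
  e$ref <- ref_hist
  e$match_target <- .ref_quantile(ref_hist, (seq_len(e$n_prot) - 0.5) /
                                    max(e$n_prot, 1))
  e$cfg <- cfg
  e$sg <- sg
  e$ncs <- ncs
  if (!is.null(ncs)) e$ncs_pre <- .ncs_precompute(spec, ncs)
  e
}

# One full cycle on a raw value array. Returns list(values, rwork, rfree,
# lambda, sigma0).  mode: "hio" or "flatten".
.engine_cycle <- function(eng, values, iter, mode = "hio") {
  N <- eng$N
  GF <- stats::fft(values, inverse = TRUE) / N
  fc <- Mod(GF[eng$ip])
  fo <- eng$f_obs
  w <- eng$work
  lambda <- compute_scale(fo, fc, w)
  rwork <- r_factor(fo, fc, lambda, w)
  rfree <- if (length(eng$free)) r_factor(fo, fc, lambda, eng$free) else NA_real_
  # replacement amplitudes on the internal (grid) scale
  amp_new <- fc
  amp_new[w] <- fo[w] / lambda
  if (length(eng$fill)) {
    s_fill <- sum(fo[w]) / (lambda * sum(fc[w]))
    amp_new[eng$fill] <- s_fill * fc[eng$fill]
  }
  # free reflections keep their calculated amplitude (excluded from phasing)
  ratio <- ifelse(fc > 0, amp_new / fc, 0)
  znew <- GF[eng$ip] * ratio
  zero_amp <- which(fc == 0 & amp_new > 0)
  if (length(zero_amp)) znew[zero_amp] <- amp_new[zero_amp] # phase 0 fallback
  GF[eng$ip] <- znew
  GF[eng$im] <- Conj(znew)
  g_proj <- Re(stats::fft(array(GF, eng$dims)))
  # weighted average density via the same reciprocal representation
  sigma0 <- if (mode == "flatten") eng$cfg$sigma_end
            else sigma0_schedule(iter, eng$cfg)
  KF <- .kernel_fft(eng$spec, sigma0, eng$r2)
  wavg <- Re(stats::fft(array(GF * KF, eng$dims)))
  # envelope: exactly n_prot protein points, stable tie-break
  n_solv <- N - eng$n_prot
  thr <- sort(wavg, partial = n_solv)[n_solv]
  prot <- wavg > thr
  deficit <- eng$n_prot - sum(prot)
  if (deficit > 0) {
    ties <- which(wavg == thr)
    prot[ties[seq.int(length(ties) - deficit + 1, length(ties))]] <- TRUE
  }
  out <- if (mode == "flatten") {
    o <- g_proj
    o[!prot] <- mean(o[!prot])
    o
  } else {
    values - eng$cfg$beta * g_proj
  }
  out[prot] <- g_proj[prot]
  # optional NCS rotational averaging (after HIO feedback, before matching)
  if (!is.null(eng$ncs))
    out <- .ncs_average_values(out, eng$ncs_pre, region = prot)
  # histogram matching of the protein region
  pv <- out[prot]
  ord <- order(pv)
  matched <- numeric(eng$n_prot)
  matched[ord] <- eng$match_target
  out[prot] <- matched
  list(values = array(out, eng$dims), rwork = rwork, rfree = rfree,
       lambda = lambda, sigma0 = sigma0)
}

#' Amplitude projection
#'
#' Replaces calculated amplitudes with observations on the working set
#' (`|Fobs| / lambda` on the grid's internal scale), fills missing and
#' low-resolution reflections from the working-set amplitude ratio, leaves
#' free reflections untouched, and keeps all calculated phases.
#'
#' @param grid A `density_grid`.
#' @param refl A [reflection_set()].
#' @param cfg A [phasing_config()].
#' @param ref_hist A [reference_histogram()] (needed only to build the shared
#'   engine; not used by the projection itself). May be `NULL`.
#' @return List with `g_proj` (projected density), `lambda`, `rwork`, `rfree`
#'   (R factors computed with this iteration's lambda, before replacement).
#' @export
amplitude_projection <- function(grid, refl, cfg, ref_hist = NULL) {
  eng <- .make_engine(refl, grid$spec, cfg,
                      if (is.null(ref_hist)) reference_histogram(0.5) else ref_hist)
  N <- eng$N
  values <- grid$values
  GF <- stats::fft(values, inverse = TRUE) / N
  fc <- Mod(GF[eng$ip])
  fo <- eng$f_obs
  w <- eng$work
  lambda <- compute_scale(fo, fc, w)
  rwork <- r_factor(fo, fc, lambda, w)
  rfree <- if (length(eng$free)) r_factor(fo, fc, lambda, eng$free) else NA_real_
  amp_new <- fc
  amp_new[w] <- fo[w] / lambda
  if (length(eng$fill)) {
    s_fill <- sum(fo[w]) / (lambda * sum(fc[w]))
    amp_new[eng$fill] <- s_fill * fc[eng$fill]
  }
  ratio <- ifelse(fc > 0, amp_new / fc, 0)
  znew <- GF[eng$ip] * ratio
  zero_amp <- which(fc == 0 & amp_new > 0)
  if (length(zero_amp)) znew[zero_amp] <- amp_new[zero_amp]
  GF[eng$ip] <- znew
  GF[eng$im] <- Conj(znew)
  list(g_proj = density_grid(Re(stats::fft(array(GF, eng$dims))), grid$spec),
       lambda = lambda, rwork = rwork, rfree = rfree)
}

#' Phasing state
#'
#' Container for one reconstruction's evolving density, iteration counter,
#' mode and metrics trace.
#'
#' @param grid Initial `density_grid`.
#' @param refl Reflection set.
#' @param cfg A [phasing_config()].
#' @param ref_hist A [reference_histogram()].
#' @param mode `"hio"` or `"flatten"`.
#' @param ncs Optional [ncs_spec()] enabling per-iteration rotational
#'   averaging.
#' @return Object of class `phasing_state`.
#' @export
phasing_state <- function(grid, refl, cfg, ref_hist, mode = "hio", ncs = NULL) {
  eng <- .make_engine(refl, grid$spec, cfg, ref_hist, ncs = ncs)
  structure(list(values = grid$values, spec = grid$spec, k = 0L, mode = mode,
                 engine = eng,
                 metrics = data.frame(iteration = integer(), rwork = numeric(),
                                      rfree = numeric(), sigma0 = numeric(),
                                      lambda = numeric())),
            class = "phasing_state")
}

#' One direct-phasing cycle
#'
#' Performs amplitude projection, Gaussian-weighted density, envelope
#' determination, (optional NCS averaging,) histogram matching and the HIO or
#' solvent-flattening update; appends one metrics record and increments the
#' iteration counter.
#'
#' @param state A [phasing_state()].
#' @return The updated state.
#' @export
phasing_cycle <- function(state) {
  res <- .engine_cycle(state$engine, state$values, state$k, state$mode)
  state$values <- res$values
  state$metrics <- rbind(state$metrics,
                         data.frame(iteration = state$k, rwork = res$rwork,
                                    rfree = res$rfree, sigma0 = res$sigma0,
                                    lambda = res$lambda))
  state$k <- state$k + 1L
  state
}

#' Extract the current density of a phasing state
#' @param state A [phasing_state()].
#' @return A [density_grid()].
#' @export
state_density <- function(state) density_grid(state$values, state$spec)
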