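# Run configuration: every tunable of the phasing cycle and the genetic
# engine, with the defaults used throughout.

#' Phasing configuration
#'
#' @param solvent_fraction Solvent-fraction estimate in (0,1). Deliberate
#'   underestimation (a few percent below the true value) is recommended so
#'   the envelope fully covers the protein.
#' @param beta HIO feedback parameter in (0, 1] (default 0.7).
#' @param sigma_start,sigma_end Weighted-density radius schedule endpoints in
#'   Angstrom (defaults 4.0 and 3.0).
#' @param ramp_end Iteration at which the sigma ramp ends (default 60% of
#'   `max_iter` when built through [run_config()]).
#' @param lowres_cutoff Reflections with d above this (Angstrom) are replaced
#'   by calculated amplitudes every iteration (default 15).
#' @param free_fraction Free-set fraction (default 0.01).
#' @param max_iter Iteration budget per reconstruction (default 10000).
#' @param flatten_cycles Solvent-flattening cycles after convergence
#'   (default 200).
#' @return List of class `phasing_config`.
#' @export
phasing_config <- function(solvent_fraction = 0.65, beta = 0.7,
                           sigma_start = 4.0, sigma_end = 3.0,
                           ramp_end = NULL, lowres_cutoff = 15,
                           free_fraction = 0.01, max_iter = 10000L,
                           flatten_cycles = 200L) {
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("phasing_config: solvent_fraction must be in (0, 1)")
  if (beta <= 0 || beta > 1) stop("phasing_config: beta must be in (0, 1]")
  if (sigma_end > sigma_start)
    stop("phasing_config: sigma_end must not exceed sigma_start")
  if (is.null(ramp_end)) ramp_end <- as.integer(round(0.6 * max_iter))
  structure(list(solvent_fraction = solvent_fraction, beta = beta,
                 sigma_start = sigma_start, sigma_end = sigma_end,
                 ramp_end = ramp_end, lowres_cutoff = lowres_cutoff,
                 free_fraction = free_fraction,
                 max_iter = as.integer(max_iter),
                 flatten_cycles = as.integer(flatten_cycles)),
            class = "phasing_config")
}

#' Genetic algorithm configuration
#'
#' @param population_size Number of independent reconstructions (default 100).
#' @param ga_interval Iterations between genetic operations (default 100).
#' @param crossover_fraction Fraction of asymmetric-unit points exchanged per
#'   crossover (default 0.50).
#' @param n_segments Number of contiguous crossover segments (default 10).
#' @param mutation_rate Fraction of points replaced per mutation
#'   (default 0.01).
#' @param mutation_range Range of replacement values (default c(0, 1), the
#'   normalized density scale).
#' @param elite_drop_threshold Sliding-window R drop marking an elite
#'   (default 0.02).
#' @param window_recent,window_past,window_gap Sliding window geometry in
#'   iterations (defaults 100/100/100: mean over i-300..i-200 minus mean over
#'   i-100..i).
#' @param elite_use_rfree Require the Rfree windows to drop as well
#'   (default TRUE).
#' @param enabled Disable to run pure independent reconstructions with the
#'   same budget (default TRUE).
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, ga_interval = 100L,
                      crossover_fraction = 0.50, n_segments = 10L,
                      mutation_rate = 0.01, mutation_range = c(0, 1),
                      elite_drop_threshold = 0.02,
                      window_recent = 100L, window_past = 100L,
                      window_gap = 100L, elite_use_rfree = TRUE,
                      enabled = TRUE) {
  if (crossover_fraction <= 0 || crossover_fraction >= 1)
    stop("ga_config: crossover_fraction must be in (0, 1)")
  if (n_segments < 1) stop("ga_config: n_segments must be >= 1")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("ga_config: mutation_rate must be in [0, 1)")
  structure(list(population_size = as.integer(population_size),
                 ga_interval = as.integer(ga_interval),
                 crossover_fraction = crossover_fraction,
                 n_segments = as.integer(n_segments),
                 mutation_rate = mutation_rate,
                 mutation_range = mutation_range,
                 elite_drop_threshold = elite_drop_threshold,
                 window_recent = as.integer(window_recent),
                 window_past = as.integer(window_past),
                 window_gap = as.integer(window_gap),
                 elite_use_rfree = isTRUE(elite_use_rfree),
                 enabled = isTRUE(enabled)),
            class = "ga_config")
}

#' Full run configuration
#'
#' @param phasing A [phasing_config()].
#' @param ga A [ga_config()].
#' @param ncs Optional [ncs_spec()].
#' @param seed Master RNG seed (drives free-set assignment, per-rank initial
#'   densities and the genetic operations; per-rank streams are
#'   `seed + rank`).
#' @param workers Parallel worker count (default 1; results are independent
#'   of the worker count).
#' @return List of class `run_config`.
#' @export
run_config <- function(phasing = phasing_config(), ga = ga_config(),
                       ncs = NULL, seed = 1L, workers = 1L) {
  if (phasing$max_iter > 0 && phasing$max_iter < ga$ga_interval)
    stop("run_config: max_iter must be >= ga_interval")
  structure(list(phasing = phasing, ga = ga, ncs = ncs,
                 seed = as.integer(seed), workers = as.integer(workers)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; every default is overridable. The NCS block
#' accepts `order`, `axis` (3-vector), `point` (fractional 3-vector) and
#' `sigmas`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("phasing", "ga", "ncs", "seed", "workers")
  if (length(setdiff(names(y), known)))
    stop("read_run_config: unknown top-level keys: ",
         paste(setdiff(names(y), known), collapse = ", "))
  ph <- do.call(phasing_config, as.list(y$phasing))
  ga <- do.call(ga_config, as.list(y$ga))
  ncs <- NULL
  if (!is.null(y$ncs))
    ncs <- ncs_spec(order = y$ncs$order,
                    axis_direction = if (is.null(y$ncs$axis)) c(0, 0, 1) else unlist(y$ncs$axis),
                    axis_point = if (is.null(y$ncs$point)) c(0, 0, 0) else unlist(y$ncs$point),
                    core_sigmas = if (is.null(y$ncs$sigmas)) c(15, 5, 3) else unlist(y$ncs$sigmas))
  run_config(ph, ga, ncs,
             seed = if (is.null(y$seed)) 1L else y$seed,
             workers = if (is.null(y$workers)) 1L else y$workers)
}
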