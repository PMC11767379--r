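# The full run: population initialization, per-rank phasing cycles, genetic
# operations every ga_interval iterations, elite-based termination, final
# solvent flattening and density averaging.

# Advance one reconstruction by `n_cycles` cycles. Returns updated values and
# the per-cycle metrics. No RNG is consumed, so results are independent of
# worker scheduling.
.advance <- function(eng, values, iter0, n_cycles, mode = "hio") {
  rw <- numeric(n_cycles); rf <- numeric(n_cycles)
  for (j in seq_len(n_cycles)) {
    res <- .engine_cycle(eng, values, iter0 + j - 1L, mode)
    values <- res$values
    rw[j] <- res$rwork; rf[j] <- res$rfree
  }
  list(values = values, rwork = rw, rfree = rf)
}

.pmap <- function(idx, f, workers) {
  if (workers > 1 && .Platform$OS.type == "unix")
    parallel::mclapply(idx, f, mc.cores = workers)
  else lapply(idx, f)
}

#' Run a single independent reconstruction
#'
#' Initializes a uniform-random density in (0,1), symmetrizes it, and runs
#' the direct phasing cycle for `max_iter` iterations. Deterministic given
#' the seed.
#'
#' @param refl A [reflection_set()] with work/free/missing labels.
#' @param ref_hist A [reference_histogram()].
#' @param cfg A [run_config()].
#' @param sg A [space_group()] (default P1).
#' @param gspec Optional `grid_spec` (default: built from the reflection
#'   set's cell at 3x oversampling).
#' @param seed RNG seed for the initial density.
#' @return List with `trace` (data.frame iteration/rwork/rfree) and `density`
#'   (final [density_grid()]).
#' @export
run_single <- function(refl, ref_hist, cfg, sg = space_group("P1"),
                       gspec = NULL, seed = cfg$seed) {
  if (is.null(gspec))
    gspec <- build_grid(attr(refl, "cell"), min(refl$d), oversampling = 3)
  eng <- .make_engine(refl, gspec, cfg$phasing, ref_hist, sg = sg,
                      ncs = cfg$ncs)
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(seed)
  g <- symmetrize_density(
    density_grid(array(stats::runif(prod(gspec$dims)), gspec$dims), gspec), sg)
  n <- cfg$phasing$max_iter
  if (n == 0)
    return(list(trace = data.frame(iteration = integer(), rwork = numeric(),
                                   rfree = numeric()),
                density = g))
  adv <- .advance(eng, g$values, 0L, n)
  list(trace = data.frame(iteration = seq_len(n) - 1L, rwork = adv$rwork,
                          rfree = adv$rfree),
       density = density_grid(adv$values, gspec))
}

#' Run the full evolutionary reconstruction
#'
#' A population of independent dual-space reconstructions evolves through
#' genetic operations every `ga_interval` iterations: densities are aligned
#' to the highest-fitness reference, selection probabilities are computed
#' with similarity-based fitness sharing, elites are preserved, offspring are
#' produced by multi-segment crossover plus mutation, and every density is
#' returned to its original frame. When all individuals are elite (or the
#' iteration budget is reached) converged reconstructions get
#' `flatten_cycles` cycles of solvent flattening, are aligned and averaged,
#' and the averaged map's phases are emitted.
#'
#' @param refl A [reflection_set()].
#' @param ref_hist A [reference_histogram()].
#' @param cfg A [run_config()].
#' @param sg A [space_group()] (default P1).
#' @param gspec Optional `grid_spec`.
#' @param truth Optional truth [density_grid()]; enables per-member
#'   correlations and the final mean phase error.
#' @param outdir Optional output directory (map, phases, traces, summary).
#' @return A `run_result` list: `densities` (final per-member maps), `elite`,
#'   `elite_iter`, `traces` (list of data.frames), `averaged` (density_grid
#'   or NULL), `avg_phases` (data.frame or NULL), `summary` (list).
#' @export
run_evolutionary <- function(refl, ref_hist, cfg, sg = space_group("P1"),
                             gspec = NULL, truth = NULL, outdir = NULL) {
  if (is.null(gspec))
    gspec <- build_grid(attr(refl, "cell"), min(refl$d), oversampling = 3)
  ph <- cfg$phasing; gac <- cfg$ga
  npop <- gac$population_size
  eng <- .make_engine(refl, gspec, ph, ref_hist, sg = sg, ncs = cfg$ncs)
  asu <- .asu_structure(sg, gspec$dims)
  N <- prod(gspec$dims)
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))

  # per-rank initial densities (stream seed + rank), then a dedicated GA stream
  pop <- vector("list", npop)
  for (i in seq_len(npop)) {
    set.seed(cfg$seed + i)
    v <- array(stats::runif(N), gspec$dims)
    pop[[i]] <- .asu_expand(v[asu$asu_index], asu)
    dim(pop[[i]]) <- gspec$dims
  }
  set.seed(cfg$seed)

  max_iter <- ph$max_iter
  rw_tr <- matrix(NA_real_, max_iter, npop)
  rf_tr <- matrix(NA_real_, max_iter, npop)
  elite <- logical(npop)
  elite_iter <- rep(NA_integer_, npop)
  iter <- 0L

  while (iter < max_iter) {
    block <- min(gac$ga_interval, max_iter - iter)
    adv <- .pmap(seq_len(npop), function(i)
      .advance(eng, pop[[i]], iter, block), cfg$workers)
    for (i in seq_len(npop)) {
      pop[[i]] <- adv[[i]]$values
      rw_tr[(iter + 1):(iter + block), i] <- adv[[i]]$rwork
      rf_tr[(iter + 1):(iter + block), i] <- adv[[i]]$rfree
    }
    iter <- iter + block
    use_rfree <- gac$elite_use_rfree && !anyNA(rf_tr[seq_len(iter), 1])
    for (i in seq_len(npop)) {
      if (!elite[i] &&
          detect_elite(rw_tr[seq_len(iter), i], gac,
                       if (use_rfree) rf_tr[seq_len(iter), i])) {
        elite[i] <- TRUE
        elite_iter[i] <- iter
      }
    }
    if (all(elite) || iter >= max_iter) break
    if (!gac$enabled || npop < 2) next

    # ---- genetic operations (root process, dedicated RNG stream) ----
    rwork_cur <- rw_tr[iter, ]
    ref_idx <- which.min(rwork_cur)      # highest fitness = lowest Rwork
    gref <- density_grid(pop[[ref_idx]], gspec)
    ref_mask <- determine_envelope(
      gaussian_weighted_density(gref, ph$sigma_end), ph$solvent_fraction)$protein
    transforms <- vector("list", npop)
    asu_mat <- matrix(0, length(asu$asu_index), npop)
    for (i in seq_len(npop)) {
      if (i == ref_idx) {
        transforms[[i]] <- frame_transform()
        asu_mat[, i] <- pop[[i]][asu$asu_index]
      } else {
        al <- align_to_reference(density_grid(pop[[i]], gspec), gref,
                                 ph$solvent_fraction, sg,
                                 sigma = ph$sigma_end, ref_mask = ref_mask)
        transforms[[i]] <- al$transform
        asu_mat[, i] <- al$aligned$values[asu$asu_index]
      }
    }
    ev <- evolve_population(asu_mat, rwork_cur, elite, gac)
    for (i in seq_len(npop)) {
      if (elite[i]) next                 # elite preserved bit-identically
      child <- density_grid(array(.asu_expand(ev$asu_mat[, i], asu),
                                  gspec$dims), gspec)
      pop[[i]] <- restore_origin(child, transforms[[i]])$values
    }
  }

  # ---- final solvent flattening for converged reconstructions ----
  conv <- which(elite)
  final_rw <- rw_tr[iter, ]
  if (length(conv) && ph$flatten_cycles > 0) {
    fl <- .pmap(conv, function(i)
      .advance(eng, pop[[i]], iter, ph$flatten_cycles, mode = "flatten"),
      cfg$workers)
    for (k in seq_along(conv)) {
      i <- conv[k]
      pop[[i]] <- fl[[k]]$values
      final_rw[i] <- fl[[k]]$rwork[ph$flatten_cycles]
    }
  }

  densities <- lapply(pop, density_grid, spec = gspec)

  averaged <- NULL; avg_phases <- NULL
  avg_rwork <- NA_real_; avg_rfree <- NA_real_; phase_err <- NA_real_
  if (length(conv)) {
    best <- conv[which.min(final_rw[conv])]
    gbest <- densities[[best]]
    best_mask <- determine_envelope(
      gaussian_weighted_density(gbest, ph$sigma_end), ph$solvent_fraction)$protein
    aligned <- lapply(conv, function(i) {
      if (i == best) return(gbest)
      align_to_reference(densities[[i]], gbest, ph$solvent_fraction, sg,
                         sigma = ph$sigma_end, ref_mask = best_mask)$aligned
    })
    averaged <- average_aligned(aligned)
    pr <- amplitude_projection(averaged, refl, ph, ref_hist)
    avg_rwork <- pr$rwork; avg_rfree <- pr$rfree
    if (!is.null(truth)) {
      al <- align_by_correlation(averaged, truth, sg)
      sf_avg <- density_to_structure_factors(
        al$aligned, as.matrix(refl[, c("h", "k", "l")]))
      sf_true <- density_to_structure_factors(
        truth, as.matrix(refl[, c("h", "k", "l")]))
      lowres <- refl$d > ph$lowres_cutoff
      wk <- which(refl$status == "work" & !lowres)
      phase_err <- mean_phase_error(sf_true$phase, sf_avg$phase, wk)
    }
    avg_phases <- density_to_structure_factors(
      averaged, as.matrix(refl[, c("h", "k", "l")]))
  }

  correlations <- if (!is.null(truth))
    vapply(densities, function(d)
      align_by_correlation(d, truth, sg)$correlation, numeric(1))
  else NULL

  sigma0s <- sigma0_schedule(seq_len(iter) - 1L, ph)
  traces <- lapply(seq_len(npop), function(i)
    data.frame(iteration = seq_len(iter) - 1L, rank = i,
               rwork = rw_tr[seq_len(iter), i],
               rfree = rf_tr[seq_len(iter), i],
               phase_error = NA_real_, sigma0 = sigma0s,
               elite = !is.na(elite_iter[i]) & seq_len(iter) >= elite_iter[i]))

  result <- list(
    densities = densities, elite = elite, elite_iter = elite_iter,
    traces = traces, averaged = averaged, avg_phases = avg_phases,
    summary = list(
      population_size = npop, iterations_run = iter,
      success_count = sum(elite),
      converged = sum(elite) > 0,
      all_elite = all(elite),
      mean_iter_to_elite = if (any(elite)) mean(elite_iter[elite]) else NA_real_,
      final_rwork_avg_map = avg_rwork, final_rfree_avg_map = avg_rfree,
      mean_phase_error = phase_err,
      correlations = correlations))
  class(result) <- "run_result"

  if (!is.null(outdir)) .write_run_outputs(result, refl, gspec, outdir)
  result
}

#' @export
print.run_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("evolutionary phasing run: %d/%d converged in %d iterations\n",
              s$success_count, s$population_size, s$iterations_run))
  if (!is.na(s$mean_iter_to_elite))
    cat(sprintf("  mean iterations to elite: %.0f\n", s$mean_iter_to_elite))
  if (!is.na(s$final_rwork_avg_map))
    cat(sprintf("  averaged map: Rwork=%.4f Rfree=%.4f\n",
                s$final_rwork_avg_map, s$final_rfree_avg_map))
  if (!is.na(s$mean_phase_error))
    cat(sprintf("  mean phase error vs truth: %.1f deg\n", s$mean_phase_error))
  invisible(x)
}

.write_run_outputs <- function(result, refl, gspec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tr <- do.call(rbind, result$traces)
  utils::write.csv(tr, file.path(outdir, "trace.csv"), row.names = FALSE)
  summ <- result$summary
  summ$correlations <- unname(summ$correlations)
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(result$averaged)) {
    write_map_ccp4(result$averaged, file.path(outdir, "averaged.ccp4"))
    write_phases_cif(result$avg_phases, attr(refl, "cell"),
                     file.path(outdir, "averaged_phases.cif"))
  }
  invisible(NULL)
}
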