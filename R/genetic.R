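# Population-level evolution of density reconstructions: adaptive fitness,
# similarity-based fitness sharing, roulette selection, multi-segment
# crossover, mutation, sliding-window elite detection.

#' Population R statistics
#'
#' `r_thres = r_avg + (r_avg - r_min)` adapts the fitness cutoff to the
#' population's current quality.
#'
#' @param rwork Numeric vector of working R factors (length >= 2).
#' @return List with `r_min`, `r_avg`, `r_thres`.
#' @export
population_stats <- function(rwork) {
  if (length(rwork) < 2) stop("population_stats: need at least 2 individuals")
  r_min <- min(rwork); r_avg <- mean(rwork)
  list(r_min = r_min, r_avg = r_avg, r_thres = r_avg + (r_avg - r_min))
}

#' Adaptive fitness
#'
#' `f_i = (r_thres - r_i) / (r_thres - r_min)` for `r_i < r_thres`, else 0.
#' If `r_thres == r_min` (all R equal) the fitness is uniform `1/N`.
#'
#' @param r_eff Effective R values (raw or similarity-modified).
#' @param r_thres,r_min Population statistics.
#' @return Fitness values in `[0, 1]` (or uniform in the degenerate case).
#' @export
ga_fitness <- function(r_eff, r_thres, r_min) {
  if (r_thres < r_min) stop("ga_fitness: r_thres < r_min")
  if (r_thres == r_min) return(rep(1 / length(r_eff), length(r_eff)))
  f <- (r_thres - r_eff) / (r_thres - r_min)
  pmax(f, 0)
}

#' Pairwise density distance matrix
#'
#' Root-mean-square deviation between asymmetric-unit density vectors:
#' `d_ij = sqrt(mean((g_i - g_j)^2))`. Densities must already share a common
#' origin frame.
#'
#' @param asu_mat Matrix with one column per individual (asymmetric-unit
#'   values, origin-aligned).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_density_distance <- function(asu_mat) {
  n <- ncol(asu_mat)
  m <- nrow(asu_mat)
  cp <- crossprod(asu_mat)                       # t(X) %*% X
  sq <- diag(cp)
  d2 <- (outer(sq, sq, "+") - 2 * cp) / m
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' Convergence (similarity) scores
#'
#' `s_i = sum_j exp(-d_ij^2 / (2 sigma^2))` with sigma the standard deviation
#' of the off-diagonal distances. Each `s_i >= 1` because `d_ii = 0`; a fully
#' collapsed population has `s_i = N` (also returned when sigma is 0).
#'
#' @param d_matrix Distance matrix from [pairwise_density_distance()].
#' @return Numeric vector of scores.
#' @export
convergence_scores <- function(d_matrix) {
  n <- nrow(d_matrix)
  off <- d_matrix[row(d_matrix) != col(d_matrix)]
  sigma <- stats::sd(off)
  if (!is.finite(sigma) || sigma == 0) return(rep(n, n))
  rowSums(exp(-d_matrix^2 / (2 * sigma^2)))
}

#' Similarity-modified R
#'
#' `r_mod = r_thres - (r_thres - rwork) / s`: crowded individuals (large `s`)
#' are pushed toward the threshold, lowering their fitness.
#'
#' @param rwork Working R values.
#' @param s Convergence scores (>= 1).
#' @param r_thres Population threshold.
#' @return Modified R values.
#' @export
modified_r <- function(rwork, s, r_thres) {
  if (any(s < 1)) stop("modified_r: convergence scores must be >= 1")
  r_thres - (r_thres - rwork) / s
}

#' Roulette selection probabilities
#'
#' `p_i = f_i / sum(f)`; uniform if all fitness values are zero.
#'
#' @param f Fitness values.
#' @return Probabilities summing to 1.
#' @export
selection_probabilities <- function(f) {
  tot <- sum(f)
  if (tot <= 0) return(rep(1 / length(f), length(f)))
  f / tot
}

#' Selection probabilities with fitness sharing
#'
#' The full diversity-control chain: pairwise distances -> convergence
#' scores -> modified R -> adaptive fitness -> roulette probabilities.
#' In the degenerate case where all raw `rwork` coincide (so
#' `r_thres == r_min` and the plain fitness is 0/0) the sharing-only limit
#' `f_i = 1/s_i` is used, preserving the preference for isolated individuals.
#'
#' @param rwork Working R values (length N).
#' @param asu_mat Origin-aligned asymmetric-unit density matrix (N columns),
#'   or a precomputed distance matrix via `d_matrix`.
#' @param d_matrix Optional precomputed distance matrix.
#' @return List with `p`, `fitness`, `s`, `r_mod`, `stats`, `d_matrix`.
#' @export
shared_selection_probabilities <- function(rwork, asu_mat = NULL,
                                           d_matrix = NULL) {
  if (is.null(d_matrix)) d_matrix <- pairwise_density_distance(asu_mat)
  st <- population_stats(rwork)
  s <- convergence_scores(d_matrix)
  r_mod <- modified_r(rwork, s, st$r_thres)
  f <- if (st$r_thres == st$r_min) 1 / s
       else ga_fitness(r_mod, st$r_thres, st$r_min)
  list(p = selection_probabilities(f), fitness = f, s = s, r_mod = r_mod,
       stats = st, d_matrix = d_matrix)
}

#' Draw a parent by roulette
#'
#' Inverse-CDF roulette draw, distribution-equivalent to an accept-reject
#' selection loop but with deterministic per-draw cost.
#'
#' @param p Selection probabilities.
#' @return A single index.
#' @export
select_parent <- function(p) {
  u <- stats::runif(1) * sum(p)
  findInterval(u, cumsum(p), left.open = TRUE) + 1L
}

#' Sliding-window elite detection
#'
#' Compares the mean R over the past window (iterations `i-300` to `i-200`)
#' with the recent window (`i-100` to `i`); a drop exceeding
#' `elite_drop_threshold` (default 0.02) marks the reconstruction as elite.
#' Traces shorter than 301 samples are never elite. If an Rfree trace is
#' supplied, both traces must show the drop.
#'
#' @param rwork_trace Numeric Rwork history (one value per iteration).
#' @param cfg A [ga_config()] (fields `window_recent`, `window_past`,
#'   `window_gap`, `elite_drop_threshold`).
#' @param rfree_trace Optional Rfree history checked in parallel.
#' @return TRUE if the trace qualifies as elite.
#' @export
detect_elite <- function(rwork_trace, cfg = ga_config(), rfree_trace = NULL) {
  wr <- cfg$window_recent; wp <- cfg$window_past; wg <- cfg$window_gap
  span <- wr + wg + wp
  drop_of <- function(tr) {
    L <- length(tr)
    if (L < span + 1) return(NA_real_)
    mean(tr[(L - span):(L - span + wp)]) - mean(tr[(L - wr):L])
  }
  d <- drop_of(rwork_trace)
  if (is.na(d) || d <= cfg$elite_drop_threshold) return(FALSE)
  if (!is.null(rfree_trace)) {
    df <- drop_of(rfree_trace)
    if (is.na(df) || df <= cfg$elite_drop_threshold) return(FALSE)
  }
  TRUE
}

#' Multi-segment crossover
#'
#' Replaces `n_segments` disjoint contiguous runs of the first parent's
#' asymmetric-unit vector (totalling `crossover_fraction` of its points) with
#' the second parent's values. Segment start positions are uniform random,
#' with rejection resampling to enforce non-overlap.
#'
#' @param a,b Parent asymmetric-unit value vectors (same length).
#' @param cfg A [ga_config()].
#' @return List with `values` (offspring vector) and `segments` (matrix of
#'   start/end indices).
#' @export
crossover <- function(a, b, cfg = ga_config()) {
  n <- length(a)
  if (length(b) != n) stop("crossover: parents differ in length")
  nseg <- cfg$n_segments
  if (cfg$crossover_fraction * n < nseg)
    stop("crossover: crossover_fraction * N smaller than n_segments")
  seg_len <- max(1L, as.integer(round(cfg$crossover_fraction * n / nseg)))
  if (nseg * seg_len > n)
    stop("crossover: segments do not fit the chromosome")
  starts <- integer(0)
  guard <- 0L
  while (length(starts) < nseg) {
    cand <- sample.int(n - seg_len + 1L, 1L)
    if (!any(cand <= starts + seg_len - 1L & cand + seg_len - 1L >= starts)) {
      starts <- c(starts, cand)
    }
    guard <- guard + 1L
    if (guard > 10000L * nseg)
      stop("crossover: could not place non-overlapping segments")
  }
  out <- a
  for (st in starts) out[st:(st + seg_len - 1L)] <- b[st:(st + seg_len - 1L)]
  list(values = out,
       segments = cbind(start = sort(starts), end = sort(starts) + seg_len - 1L))
}

#' Mutation
#'
#' Replaces exactly `floor(mutation_rate * N)` distinct asymmetric-unit points
#' with uniform draws from `mutation_range` (default (0,1), the normalized
#' density scale); all other points are untouched.
#'
#' @param g Asymmetric-unit value vector.
#' @param cfg A [ga_config()].
#' @return Mutated vector.
#' @export
mutate_density <- function(g, cfg = ga_config()) {
  n <- length(g)
  k <- floor(cfg$mutation_rate * n)
  if (k == 0) return(g)
  idx <- sample.int(n, k)
  g[idx] <- stats::runif(k, cfg$mutation_range[1], cfg$mutation_range[2])
  g
}

#' Evolve a population one generation
#'
#' Operates on origin-aligned asymmetric-unit vectors. Elite slots are copied
#' unchanged; every other slot is filled by `mutate(crossover(pa, pb))` with
#' both parents drawn independently by roulette over the similarity-modified
#' fitness. Elites remain selectable as parents.
#'
#' @param asu_mat Aligned ASU matrix (one column per individual).
#' @param rwork Current working R factor per individual.
#' @param elite Logical vector of elite flags.
#' @param cfg A [ga_config()].
#' @return List with `asu_mat` (next generation), `p` (selection
#'   probabilities), `s`, `fitness`, `parents` (2 x N matrix of chosen parent
#'   indices, NA for elite slots).
#' @export
evolve_population <- function(asu_mat, rwork, elite, cfg = ga_config()) {
  n <- ncol(asu_mat)
  sel <- shared_selection_probabilities(rwork, asu_mat)
  out <- asu_mat
  parents <- matrix(NA_integer_, 2, n)
  for (i in seq_len(n)) {
    if (elite[i]) next
    pa <- select_parent(sel$p)
    pb <- select_parent(sel$p)
    child <- crossover(asu_mat[, pa], asu_mat[, pb], cfg)$values
    out[, i] <- mutate_density(child, cfg)
    parents[, i] <- c(pa, pb)
  }
  list(asu_mat = out, p = sel$p, s = sel$s, fitness = sel$fitness,
       parents = parents)
}
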