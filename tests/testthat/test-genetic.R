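# The genetic engine: fitness, diversity control, selection, crossover,
# mutation, elite detection and one-generation evolution.

test_that("population statistics give the adaptive threshold", {
  st <- population_stats(c(0.2, 0.3, 0.4))
  expect_equal(st, list(r_min = 0.2, r_avg = 0.3, r_thres = 0.4))
  st2 <- population_stats(rep(0.37, 5))
  expect_equal(st2$r_thres, 0.37)
  set.seed(1)
  r <- runif(20)
  st3 <- population_stats(r)
  expect_equal(st3$r_thres - st3$r_avg, st3$r_avg - st3$r_min)
  expect_error(population_stats(0.5), "at least 2")
})

test_that("fitness is linear below the threshold and zero above", {
  expect_equal(ga_fitness(0.2, r_thres = 0.4, r_min = 0.2), 1)
  expect_equal(ga_fitness(c(0.4, 0.5), r_thres = 0.4, r_min = 0.2), c(0, 0))
  expect_equal(ga_fitness(c(0.2, 0.3, 0.4), 0.4, 0.2), c(1, 0.5, 0))
  expect_equal(ga_fitness(c(0.1, 0.1, 0.1), 0.1, 0.1), rep(1 / 3, 3))
})

test_that("pairwise density distance is the RMSD metric", {
  m <- cbind(a = rep(0.3, 100), b = rep(0.3, 100), c = rep(0.3, 100) + 0.25)
  d <- pairwise_density_distance(m)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 0.25)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  set.seed(2)
  x <- matrix(runif(300), 100, 3)
  dx <- pairwise_density_distance(x)
  expect_lte(dx[1, 3], dx[1, 2] + dx[2, 3] + 1e-12)
  expect_equal(dx[1, 2], sqrt(mean((x[, 1] - x[, 2])^2)))
})

test_that("convergence scores reward crowding and are at least 1", {
  m <- cbind(rep(0.5, 50), rep(0.5, 50), rep(0.9, 50))
  s <- convergence_scores(pairwise_density_distance(m))
  expect_true(all(s >= 1))
  expect_gt(s[1], s[3])          # the duplicated pair is more crowded
  expect_equal(s[1], s[2])
  # identical population: limit s_i = N
  ident <- matrix(0.4, 50, 4)
  expect_equal(convergence_scores(pairwise_density_distance(ident)), rep(4, 4))
})

test_that("similarity-modified R interpolates toward the threshold", {
  expect_equal(modified_r(0.25, 1, 0.4), 0.25)
  expect_equal(modified_r(0.2, 2, 0.4), 0.3)
  expect_true(all(diff(modified_r(0.2, c(1, 2, 4, 8), 0.4)) > 0))
  expect_error(modified_r(0.2, 0.5, 0.4), ">= 1")
})

test_that("selection probabilities normalize the fitness", {
  expect_equal(selection_probabilities(c(1, 0.5, 0)), c(2 / 3, 1 / 3, 0))
  expect_equal(selection_probabilities(c(0, 2, 0)), c(0, 1, 0))
  expect_equal(selection_probabilities(c(0, 0)), c(0.5, 0.5))
})

test_that("roulette draws follow the probabilities", {
  set.seed(3)
  expect_equal(select_parent(c(1, 0, 0)), 1L)
  p <- c(0.5, 0.3, 0.15, 0.05)
  draws <- replicate(1e5, select_parent(p))
  counts <- tabulate(draws, 4)
  # multinomial check: each count within 4 standard deviations
  for (i in 1:4)
    expect_lt(abs(counts[i] - 1e5 * p[i]), 4 * sqrt(1e5 * p[i] * (1 - p[i])))
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.001)
  # zero-fitness individuals are never selected
  expect_false(any(draws == 4 & p[4] == 0))
  set.seed(99); a <- select_parent(p)
  set.seed(99); b <- select_parent(p)
  expect_identical(a, b)
})

test_that("fitness sharing prefers the distant individual over duplicates", {
  # two identical members and one distant member, all with equal Rwork
  m <- cbind(rep(0.2, 200), rep(0.2, 200), c(rep(0.9, 100), rep(0.1, 100)))
  sel <- shared_selection_probabilities(rep(0.35, 3), m)
  expect_gt(sel$p[3], sel$p[1])
  expect_gt(sel$p[3], sel$p[2])
  expect_equal(sum(sel$p), 1)
  # the duplicates are more crowded than the distant member
  expect_gt(sel$s[1], sel$s[3])
})

test_that("elite detection follows the sliding-window truth table", {
  cfg <- ga_config()
  expect_false(detect_elite(rep(0.5, 301), cfg))                 # constant
  expect_true(detect_elite(c(rep(0.5, 200), rep(0.4, 101)), cfg))  # 0.1 drop
  expect_false(detect_elite(c(rep(0.5, 200), rep(0.49, 101)), cfg)) # 0.01 drop
  expect_false(detect_elite(rep(0.1, 300), cfg))                 # too short
  # with an Rfree trace both windows must drop
  good <- c(rep(0.5, 200), rep(0.4, 101))
  expect_true(detect_elite(good, cfg, rfree_trace = good))
  expect_false(detect_elite(good, cfg, rfree_trace = rep(0.5, 301)))
})

test_that("crossover exchanges the configured fraction in disjoint segments", {
  cfg <- ga_config(crossover_fraction = 0.5, n_segments = 10)
  n <- 1000L
  a <- rep(0, n); b <- rep(1, n)
  set.seed(4)
  cx <- crossover(a, b, cfg)
  expect_equal(sum(cx$values == 1), 500)       # 10 segments x 50 points
  expect_equal(nrow(cx$segments), 10)
  # segments are disjoint and contiguous
  seg <- cx$segments[order(cx$segments[, "start"]), , drop = FALSE]
  expect_true(all(seg[-1, "start"] > seg[-10, "end"]))
  expect_true(all(seg[, "end"] - seg[, "start"] == 49))
  # offspring values come pointwise from a parent, never blended
  set.seed(5)
  a2 <- runif(n); b2 <- runif(n)
  cx2 <- crossover(a2, b2, cfg)
  expect_true(all(cx2$values == a2 | cx2$values == b2))
  # identical parents -> identity
  cx3 <- crossover(a2, a2, cfg)
  expect_identical(cx3$values, a2)
  expect_error(crossover(rep(0, 15), rep(1, 15),
                         ga_config(crossover_fraction = 0.5, n_segments = 10)),
               "n_segments|segments")
})

test_that("mutation changes exactly the configured count within (0,1)", {
  cfg <- ga_config(mutation_rate = 0.01)
  n <- 10000L
  g <- rep(5, n)                      # values outside (0,1) mark changes
  set.seed(6)
  mg <- mutate_density(g, cfg)
  changed <- which(mg != 5)
  expect_equal(length(changed), 100)
  expect_true(all(mg[changed] > 0 & mg[changed] < 1))
  expect_identical(mg[-changed], g[-changed])
  expect_identical(mutate_density(g, ga_config(mutation_rate = 0)), g)
})

test_that("evolution preserves elites, size and determinism", {
  set.seed(7)
  n <- 500L; npop <- 6L
  m <- matrix(runif(n * npop), n, npop)
  rw <- c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45)
  cfg <- ga_config(crossover_fraction = 0.5, n_segments = 5,
                   mutation_rate = 0.01)
  # all elite -> pure preservation
  ev_all <- evolve_population(m, rw, rep(TRUE, npop), cfg)
  expect_identical(ev_all$asu_mat, m)
  # elites bit-identical, size conserved
  elite <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  set.seed(8)
  ev <- evolve_population(m, rw, elite, cfg)
  expect_identical(ev$asu_mat[, 1], m[, 1])
  expect_identical(ev$asu_mat[, 6], m[, 6])
  expect_equal(dim(ev$asu_mat), dim(m))
  set.seed(8)
  ev2 <- evolve_population(m, rw, elite, cfg)
  expect_identical(ev$asu_mat, ev2$asu_mat)
  # selection never picks a zero-fitness member while positives exist
  expect_true(all(ev$fitness[ev$parents[!is.na(ev$parents)]] > 0))
})

test_that("offspring of identical parents differ only at mutation sites", {
  set.seed(9)
  n <- 2000L
  base <- runif(n)
  m <- cbind(base, base, base)
  cfg <- ga_config(crossover_fraction = 0.5, n_segments = 10,
                   mutation_rate = 0.01)
  ev <- evolve_population(m, c(0.3, 0.31, 0.32), rep(FALSE, 3), cfg)
  for (i in 1:3) {
    diffs <- sum(ev$asu_mat[, i] != base)
    expect_equal(diffs, floor(0.01 * n))
  }
})
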