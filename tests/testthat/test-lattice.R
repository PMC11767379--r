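# Unit-cell geometry, grid construction and the Fourier bridge.

test_that("unit cell validates inputs and computes volume", {
  cell <- unit_cell(10, 20, 30)
  expect_equal(cell$volume, 6000)
  mono <- unit_cell(10, 10, 10, beta = 120)
  expect_equal(mono$volume, 1000 * sin(120 * pi / 180))
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, alpha = 200), "angles")
})

test_that("build_grid returns smallest 2,3,5-smooth dims meeting the spacing", {
  spec <- build_grid(unit_cell(30, 30, 30), d_min = 3, oversampling = 3)
  expect_equal(spec$dims, c(30L, 30L, 30L))        # spacing exactly 1 A
  # 25 / (2/3) = 37.5 -> next smooth integer is 40 = 2^3 * 5
  spec2 <- build_grid(unit_cell(25, 25, 25), d_min = 2, oversampling = 3)
  expect_equal(spec2$dims, c(40L, 40L, 40L))
  # halving the oversampling halves dims up to smoothness rounding
  s2 <- build_grid(unit_cell(30, 30, 30), d_min = 3, oversampling = 2)
  s4 <- build_grid(unit_cell(30, 30, 30), d_min = 3, oversampling = 4)
  expect_true(all(s2$dims <= s4$dims))
  expect_true(all(s4$dims <= 2 * s2$dims + 5))
  expect_error(build_grid(unit_cell(10, 10, 10), d_min = -1), "d_min")
})

test_that("resolution follows the reciprocal metric", {
  expect_equal(resolution_of(c(1, 0, 0), unit_cell(100, 50, 25)), 100)
  expect_equal(resolution_of(c(1, 1, 1), unit_cell(10, 10, 10)), 10 / sqrt(3))
  hkl <- rbind(c(1, 2, 3), c(2, 0, 1))
  cell <- unit_cell(37, 22, 15, beta = 105)
  expect_equal(resolution_of(hkl, cell), resolution_of(-hkl, cell))
  expect_error(resolution_of(c(0, 0, 0), cell), "undefined")
})

test_that("FFT structure factors match the direct Fourier sum", {
  set.seed(42)
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    g <- random_grid(n)
    hkl <- matrix(sample(-(n %/% 2 - 1):(n %/% 2 - 1), 9, replace = TRUE), 3)
    sf <- density_to_structure_factors(g, hkl)
    for (r in 1:3) {
      z <- direct_structure_factor(g, hkl[r, ])
      expect_lt(abs(Mod(z) - sf$amp[r]), 1e-10 * (1 + Mod(z)))
    }
  }
})

test_that("a single point density transforms to constant amplitudes", {
  spec <- small_spec(6)
  v <- array(0, c(6, 6, 6)); v[1, 1, 1] <- 2.5
  sf <- density_to_structure_factors(density_grid(v, spec),
                                     rbind(c(1, 0, 0), c(2, 1, 0), c(1, 2, 2)))
  expect_equal(sf$amp, rep(2.5 / 216, 3))
  expect_equal(sf$phase, rep(0, 3))
})

test_that("Friedel symmetry holds exactly for real densities", {
  g <- random_grid(8, seed = 3)
  sf <- density_to_structure_factors(g, rbind(c(1, 2, 3), c(-1, -2, -3)))
  expect_equal(sf$amp[1], sf$amp[2], tolerance = 1e-13)
  expect_equal(sf$phase[1], -sf$phase[2])
})

test_that("the Fourier bridge round-trips band-limited densities", {
  spec <- small_spec(8)
  hkl <- generate_hkl(spec$cell, spec$d_min)
  g0 <- random_grid(8, seed = 5)
  sf0 <- density_to_structure_factors(g0, hkl)
  g <- structure_factors_to_density(sf0, spec, f000 = attr(sf0, "f000"))
  sf <- density_to_structure_factors(g, hkl)
  g2 <- structure_factors_to_density(sf, spec, f000 = attr(sf, "f000"))
  expect_lt(max(abs(g2$values - g$values)), 1e-10 * max(abs(g$values)))
  # zero amplitudes -> constant density at the f000 level
  sfz <- sf; sfz$amp <- 0
  gz <- structure_factors_to_density(sfz, spec, f000 = 1.25)
  expect_equal(as.vector(gz$values), rep(1.25, 512))
  # single cosine mode
  one <- data.frame(h = 1, k = 0, l = 0, amp = 1, phase = 0)
  gc <- structure_factors_to_density(one, spec, f000 = 0)
  expect_equal(as.vector(gc$values[, 1, 1]), 2 * cos(2 * pi * (0:7) / 8))
  expect_error(structure_factors_to_density(
    data.frame(h = c(1, -1), k = 0, l = 0, amp = c(1, 2), phase = 0), spec),
    "Friedel")
})

test_that("index beyond the Nyquist limit is rejected", {
  g <- random_grid(6)
  expect_error(density_to_structure_factors(g, c(3, 0, 0)), "Nyquist")
})

test_that("Parseval consistency between grid and full spectrum", {
  g <- random_grid(10, seed = 8)
  Fall <- stats::fft(g$values, inverse = TRUE) / 1000
  expect_lt(abs(sum(Mod(Fall)^2) - mean(g$values^2)), 1e-8 * mean(g$values^2))
})

test_that("symmetrization is an idempotent projection onto symmetric maps", {
  spec <- small_spec(12, a = 20)
  for (sym in c("P1", "P21212", "P212121", "P42212", "C121")) {
    sg <- space_group(sym)
    g <- random_grid(12, a = 20, seed = 17)
    gs <- symmetrize_density(g, sg)
    v <- as.vector(gs$values)
    for (p in evophase:::.sg_permutations(sg, spec$dims))
      expect_lt(max(abs(v[p] - v)), 1e-10)
    gs2 <- symmetrize_density(gs, sg)
    expect_equal(gs2$values, gs$values, tolerance = 1e-12)
    if (sym == "P1") expect_identical(gs$values, g$values)
  }
})

test_that("space group operators form a closed group with identity", {
  for (sym in supported_space_groups()) {
    ops <- space_group(sym)$operators
    key <- function(R, t) paste(c(R, round(((t %% 1) + 1) %% 1, 9)), collapse = ",")
    keys <- vapply(ops, function(o) key(o$R, o$t), character(1))
    expect_true(key(diag(3), c(0, 0, 0)) %in% keys)
    for (o1 in ops) for (o2 in ops) {
      R <- o1$R %*% o2$R
      t <- as.vector(o1$R %*% o2$t) + o1$t
      expect_true(key(R, t) %in% keys)
      expect_true(abs(det(o1$R)) == 1)
    }
  }
})

test_that("asymmetric unit covers each orbit exactly once", {
  sg <- space_group("P21212")
  dims <- c(12L, 12L, 12L)
  asu <- asu_indices(sg, dims)
  # expanding arbitrary ASU values gives an exactly symmetric map
  set.seed(9)
  vals <- runif(length(asu$asu_index))
  full <- evophase:::.asu_expand(vals, asu)
  for (p in evophase:::.sg_permutations(sg, dims))
    expect_identical(full[p], full)
  # every point maps to a representative that carries its own value
  expect_identical(full[asu$asu_index], vals)
  expect_true(length(asu$asu_index) >= prod(dims) / length(sg$operators))
})
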