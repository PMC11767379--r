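# The direct-phasing cycle: metrics, projection, envelope, histogram
# matching, HIO feedback and solvent flattening.

test_that("amplitude scale is the least-squares fit on the subset", {
  expect_equal(compute_scale(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compute_scale(2 * c(1, 2, 3), c(1, 2, 3)), 2)
  expect_equal(compute_scale(c(3, 1), c(1, 1)), 2)
  expect_equal(compute_scale(c(9, 9, 3, 1), c(9, 9, 1, 1), subset = 3:4), 2)
  expect_error(compute_scale(c(1, 2), c(0, 0)), "zero")
  expect_error(compute_scale(c(1), c(1), subset = integer(0)), "empty")
})

test_that("R factor matches the normalized amplitude residual", {
  expect_equal(r_factor(3 * c(1, 2, 3), c(1, 2, 3), lambda = 3), 0)
  expect_equal(r_factor(c(3, 1), c(2, 2), lambda = 1), 0.5)
  set.seed(1)
  fo <- runif(50, 1, 2); fc <- runif(50, 1, 2)
  expect_equal(r_factor(fo, fc, 1.3), r_factor(7 * fo, 7 * fc, 1.3))
  perm <- sample(50)
  expect_equal(r_factor(fo, fc, 1.3), r_factor(fo[perm], fc[perm], 1.3))
  expect_error(r_factor(c(0, 0), c(1, 1)), "zero")
})

test_that("mean phase error is the wrapped angular mean in [0, 180]", {
  expect_equal(mean_phase_error(c(10, 20, -170), c(10, 20, -170)), 0)
  expect_equal(mean_phase_error(c(0, 90), c(180, -90)), 180)
  expect_equal(mean_phase_error(c(350), c(-10)), 0)       # wrap
  set.seed(2)
  phi_t <- rep(0, 1e5)
  phi_c <- runif(1e5, -180, 180)
  expect_lt(abs(mean_phase_error(phi_t, phi_c) - 90), 0.5)
  perm <- sample(100)
  a <- runif(100, -180, 180); b <- runif(100, -180, 180)
  expect_equal(mean_phase_error(a, b), mean_phase_error(a[perm], b[perm]))
})

test_that("missing amplitudes are filled from the working amplitude ratio", {
  # sum_work fobs = sum_work fcal -> fill equals fcal
  expect_equal(fill_missing_amplitudes(c(2, 3, NA), c(2, 3, 7), 1:2, 3), 7)
  # sums 100 vs 200 and fcal(h0) = 4 -> 2
  fo <- c(60, 40, NA); fc <- c(120, 80, 4)
  expect_equal(fill_missing_amplitudes(fo, fc, 1:2, 3), 2)
  # doubling all fcal leaves the fill ratio to sum_work fobs fixed
  expect_equal(fill_missing_amplitudes(fo, 2 * fc, 1:2, 3), 2)
  expect_error(fill_missing_amplitudes(c(1, NA), c(0, 1), 1, 2), "zero")
})

test_that("sigma0 schedule ramps linearly then stays constant", {
  cfg <- phasing_config(max_iter = 1000, ramp_end = 600)
  expect_equal(sigma0_schedule(0, cfg), 4.0)
  expect_equal(sigma0_schedule(300, cfg), 3.5)
  expect_equal(sigma0_schedule(600, cfg), 3.0)
  expect_equal(sigma0_schedule(999, cfg), 3.0)
  expect_error(phasing_config(sigma_start = 3, sigma_end = 4), "sigma_end")
})

test_that("Gaussian weighted density equals the direct double sum", {
  g <- random_grid(6, a = 6, seed = 11)
  w <- gaussian_weighted_density(g, 1.2)
  expect_lt(max(abs(w$values - direct_weighted_density(g, 1.2))), 1e-8)
  # constant input -> constant output scaled by the kernel sum
  spec <- small_spec(6, a = 6)
  K <- exp(-evophase:::.min_image_r2(spec) / (2 * 1.2^2))
  gc <- density_grid(array(0.7, c(6, 6, 6)), spec)
  wc <- gaussian_weighted_density(gc, 1.2)
  expect_equal(as.vector(wc$values), rep(0.7 * sum(K), 216), tolerance = 1e-10)
  expect_error(gaussian_weighted_density(g, -1), "sigma0")
})

test_that("Gaussian weighting is shift-equivariant", {
  g <- random_grid(8, seed = 12)
  w <- gaussian_weighted_density(g, 1.5)
  shift <- frame_transform(c(1 / 8, 0, 0))
  w_shifted <- gaussian_weighted_density(apply_transform(g, shift), 1.5)
  expect_equal(w_shifted$values, apply_transform(w, shift)$values,
               tolerance = 1e-12)
})

test_that("envelope has the exact protein count with stable tie-break", {
  spec <- small_spec(10)
  set.seed(13)
  w <- density_grid(array(runif(1000), c(10, 10, 10)), spec)
  m <- determine_envelope(w, 0.75)
  expect_equal(sum(m$protein), 250)
  expect_lt(abs(m$solvent_fraction - 0.75), 1 / 1000)
  # strictly increasing flattened values -> protein is the top block
  w2 <- density_grid(array(seq_len(1000) / 1000, c(10, 10, 10)), spec)
  m2 <- determine_envelope(w2, 0.75)
  expect_identical(which(as.vector(m2$protein)), 751:1000)
  # degenerate all-equal input still yields the exact count
  wd <- density_grid(array(1, c(10, 10, 10)), spec)
  md <- suppressWarnings(determine_envelope(wd, 0.6))
  expect_equal(sum(md$protein), 400)
  expect_error(determine_envelope(w, 1.5), "solvent_fraction")
})

test_that("histogram matching is the exact rank transform onto the reference", {
  spec <- small_spec(3, a = 3)
  v <- array(0, c(3, 3, 3))
  v[1:3] <- c(5, 1, 3)
  mask <- structure(list(protein = array(c(rep(TRUE, 3), rep(FALSE, 24)),
                                         c(3, 3, 3)),
                         solvent_fraction = 24 / 27),
                    class = "envelope_mask")
  # fine uniform(0,1) sample -> quantile function is the identity
  ref <- reference_histogram((seq_len(20000) - 0.5) / 20000)
  out <- histogram_match(density_grid(v, spec), mask, ref)
  expect_equal(out$values[1:3], c(2.5, 0.5, 1.5) / 3, tolerance = 1e-4)
  expect_identical(out$values[4:27], v[4:27])  # solvent untouched
  # matching a region to its own histogram leaves values unchanged
  set.seed(14)
  g <- random_grid(8)
  m8 <- determine_envelope(gaussian_weighted_density(g, 2), 0.6)
  own <- reference_histogram(g$values[m8$protein])
  out2 <- histogram_match(g, m8, own)
  expect_equal(out2$values[m8$protein], g$values[m8$protein], tolerance = 1e-12)
  # the output protein histogram equals the reference
  ref3 <- reference_histogram(rnorm(sum(m8$protein)))
  out3 <- histogram_match(g, m8, ref3)
  expect_equal(sort(out3$values[m8$protein]), as.numeric(ref3),
               tolerance = 1e-12)
  expect_error(histogram_match(g, structure(list(protein = array(FALSE, c(8, 8, 8))),
                                            class = "envelope_mask"), ref3),
               "empty")
})

test_that("HIO feedback applies only to the solvent region", {
  spec <- small_spec(4, a = 4)
  prev <- density_grid(array(0.5, c(4, 4, 4)), spec)
  proj <- density_grid(array(0.2, c(4, 4, 4)), spec)
  mod <- density_grid(array(0.9, c(4, 4, 4)), spec)
  prot <- array(FALSE, c(4, 4, 4)); prot[1:32] <- TRUE
  mask <- structure(list(protein = prot, solvent_fraction = 0.5),
                    class = "envelope_mask")
  out <- hio_step(prev, proj, mod, mask, beta = 0.7)
  expect_equal(unique(out$values[prot]), 0.9)
  expect_equal(unique(out$values[!prot]), 0.5 - 0.7 * 0.2)
  # beta -> 0 limit keeps the previous solvent (beta = 0 itself is invalid)
  out_small <- hio_step(prev, proj, mod, mask, beta = 1e-12)
  expect_equal(unique(out_small$values[!prot]), 0.5, tolerance = 1e-9)
  expect_error(hio_step(prev, proj, mod, mask, beta = 1.5), "beta")
})

test_that("solvent flattening zeroes the solvent variance idempotently", {
  spec <- small_spec(4, a = 4)
  set.seed(15)
  g <- density_grid(array(runif(64), c(4, 4, 4)), spec)
  prot <- array(FALSE, c(4, 4, 4)); prot[1:2] <- TRUE
  mask <- structure(list(protein = prot, solvent_fraction = 62 / 64),
                    class = "envelope_mask")
  out <- solvent_flatten_step(g, mask)
  expect_equal(stats::var(out$values[!prot]), 0)
  expect_equal(unique(out$values[!prot]), mean(g$values[!prot]))
  expect_identical(out$values[prot], g$values[prot])
  out2 <- solvent_flatten_step(out, mask)
  expect_equal(out2$values, out$values)
})

test_that("amplitude projection enforces the work amplitudes and spares free ones", {
  bundle <- toy_bundle()
  cfg <- phasing_config(solvent_fraction = 0.72, lowres_cutoff = 15)
  set.seed(16)
  g <- density_grid(array(runif(prod(bundle$grid_spec$dims)),
                          bundle$grid_spec$dims), bundle$grid_spec)
  pr <- amplitude_projection(g, bundle$refl, cfg)
  sf_before <- density_to_structure_factors(g, as.matrix(bundle$refl[, c("h", "k", "l")]))
  sf <- density_to_structure_factors(pr$g_proj, as.matrix(bundle$refl[, c("h", "k", "l")]))
  lowres <- bundle$refl$d > 15
  wk <- which(bundle$refl$status == "work" & !lowres)
  fr <- which(bundle$refl$status == "free" & !lowres)
  expect_lt(max(abs(sf$amp[wk] - bundle$refl$f_obs[wk] / pr$lambda) /
                  (bundle$refl$f_obs[wk] / pr$lambda)), 1e-8)
  expect_equal(sf$amp[fr], sf_before$amp[fr], tolerance = 1e-10)
  expect_equal(sf$phase[wk], sf_before$phase[wk], tolerance = 1e-6)
  # projecting a density that already satisfies the data is a fixed point
  pr2 <- amplitude_projection(bundle$truth, bundle$refl, cfg)
  expect_equal(pr2$lambda, 1, tolerance = 1e-10)
  expect_equal(pr2$rwork, 0, tolerance = 1e-12)
  expect_lt(max(abs(pr2$g_proj$values - bundle$truth$values)), 1e-10)
  # idempotence: applying the projection twice changes nothing
  pr3 <- amplitude_projection(pr$g_proj, bundle$refl, cfg)
  expect_lt(max(abs(pr3$g_proj$values - pr$g_proj$values)), 1e-10)
})

test_that("a full flatten-mode cycle fixes a density satisfying all constraints", {
  bundle <- toy_bundle()
  cfg <- phasing_config(solvent_fraction = 0.72, lowres_cutoff = 15)
  eng <- evophase:::.make_engine(bundle$refl, bundle$grid_spec, cfg,
                                 bundle$ref_hist)
  r <- evophase:::.engine_cycle(eng, bundle$truth$values, 0, "flatten")
  expect_lt(max(abs(r$values - bundle$truth$values)), 1e-8)
  expect_equal(r$rwork, 0, tolerance = 1e-12)
})

test_that("the correct solution is stable over 100 cycles at the final radius", {
  bundle <- toy_bundle()
  # the converged regime: sigma0 at its end value, as after the ramp
  cfg <- phasing_config(solvent_fraction = 0.72, sigma_start = 3,
                        sigma_end = 3, ramp_end = 0, lowres_cutoff = 15,
                        max_iter = 100)
  eng <- evophase:::.make_engine(bundle$refl, bundle$grid_spec, cfg,
                                 bundle$ref_hist)
  v <- bundle$truth$values
  for (i in 1:100) v <- evophase:::.engine_cycle(eng, v, i - 1, "hio")$values
  sf <- density_to_structure_factors(density_grid(v, bundle$grid_spec),
                                     as.matrix(bundle$refl[, c("h", "k", "l")]))
  wk <- which(bundle$refl$status == "work" & bundle$refl$d <= 15)
  expect_lt(mean_phase_error(bundle$phases$phase, sf$phase, wk), 5)
})

test_that("phasing_cycle appends one metrics record per call, deterministically", {
  bundle <- toy_bundle()
  cfg <- phasing_config(solvent_fraction = 0.65, max_iter = 10, ramp_end = 6)
  set.seed(20)
  g <- density_grid(array(runif(prod(bundle$grid_spec$dims)),
                          bundle$grid_spec$dims), bundle$grid_spec)
  st <- phasing_state(g, bundle$refl, cfg, bundle$ref_hist)
  st1 <- phasing_cycle(phasing_cycle(st))
  expect_equal(nrow(st1$metrics), 2)
  expect_equal(st1$k, 2L)
  st2 <- phasing_cycle(phasing_cycle(st))
  expect_identical(st1$values, st2$values)
  expect_identical(st1$metrics, st2$metrics)
})
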