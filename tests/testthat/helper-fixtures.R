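# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# The standard desk-scale toy crystal: P1, 31 A cube -> 32^3 grid, 72%
# solvent, zero amplitude noise, beam-stop gap above 25 A.
toy_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- generate_toy_crystal(toy_crystal_spec(seed = 7))
  .fixture_env$bundle
}

# Small grid spec helper for oracle tests (cubic cell, explicit dims).
small_spec <- function(n, a = 10) {
  structure(list(dims = rep(as.integer(n), 3), cell = unit_cell(a, a, a),
                 d_min = 3, oversampling = 3),
            class = "grid_spec")
}

random_grid <- function(n, a = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- small_spec(n, a)
  density_grid(array(stats::runif(n^3), rep(n, 3)), spec)
}

# Brute-force discrete Fourier sum (the independent oracle for the FFT path).
direct_structure_factor <- function(g, h) {
  dims <- dim(g$values)
  acc <- 0 + 0i
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1))
    acc <- acc + g$values[i + 1, j + 1, k + 1] *
      exp(2i * pi * (h[1] * i / dims[1] + h[2] * j / dims[2] + h[3] * k / dims[3]))
  acc / prod(dims)
}

# Vectorized direct Fourier sum (same oracle, fast enough for many trials).
direct_sf_vec <- function(g, h) {
  dims <- dim(g$values)
  i1 <- rep.int(0:(dims[1] - 1), dims[2] * dims[3])
  i2 <- rep.int(rep(0:(dims[2] - 1), each = dims[1]), dims[3])
  i3 <- rep(0:(dims[3] - 1), each = dims[1] * dims[2])
  ph <- h[1] * i1 / dims[1] + h[2] * i2 / dims[2] + h[3] * i3 / dims[3]
  sum(as.vector(g$values) * exp(2i * pi * ph)) / prod(dims)
}

# Direct O(N^2) double-sum Gaussian-weighted density (oracle for Eq.-1-style
# FFT convolution), using the same minimal-image kernel.
direct_weighted_density <- function(g, sigma) {
  spec <- g$spec
  K <- exp(-evophase:::.min_image_r2(spec) / (2 * sigma^2))
  dims <- spec$dims
  out <- array(0, dims)
  idx <- function(a, n) (a %% n) + 1
  for (i1 in 0:(dims[1] - 1)) for (i2 in 0:(dims[2] - 1)) for (i3 in 0:(dims[3] - 1)) {
    s <- 0
    for (j1 in 0:(dims[1] - 1)) for (j2 in 0:(dims[2] - 1)) for (j3 in 0:(dims[3] - 1))
      s <- s + K[idx(i1 - j1, dims[1]), idx(i2 - j2, dims[2]), idx(i3 - j3, dims[3])] *
        g$values[j1 + 1, j2 + 1, j3 + 1]
    out[i1 + 1, i2 + 1, i3 + 1] <- s
  }
  out
}
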