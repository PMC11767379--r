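# Real-space grid geometry and the Fourier bridge between electron density
# and structure factors.
#
# Conventions (fixed package-wide):
#   * 0-based grid indices i, fractional coordinate x = i / n, periodic wrap.
#   * F(h) = (1/N) sum_j g_j exp(+2 pi i h.x_j), so F(000) is the grid mean;
#     g_j = sum_h F(h) exp(-2 pi i h.x_j).  Parseval: sum|F|^2 = mean(g^2).

.smooth235 <- function(m) {
  # smallest integer >= m whose prime factors are all in {2,3,5}
  n <- max(2L, as.integer(ceiling(m)))
  repeat {
    k <- n
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(n)
    n <- n + 1L
  }
}

#' Build a real-space grid for a cell and resolution
#'
#' Chooses the smallest 2,3,5-smooth grid dimensions so that the spacing along
#' each cell axis is at most `d_min / oversampling`.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @param oversampling Grid oversampling factor relative to `d_min`
#'   (default 3, standard crystallographic practice; must be >= 2).
#' @return An object of class `grid_spec` with fields `dims`, `cell`, `d_min`,
#'   `oversampling`.
#' @examples
#' build_grid(unit_cell(30, 30, 30), d_min = 3)$dims  # 30 30 30
#' @export
build_grid <- function(cell, d_min, oversampling = 3) {
  if (!is.finite(d_min) || d_min <= 0) stop("build_grid: d_min must be > 0")
  if (!is.finite(oversampling) || oversampling < 2)
    stop("build_grid: oversampling must be >= 2")
  target <- d_min / oversampling
  dims <- vapply(c(cell$a, cell$b, cell$c),
                 function(len) .smooth235(len / target), integer(1))
  structure(list(dims = dims, cell = cell, d_min = d_min,
                 oversampling = oversampling),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid %d x %d x %d  (d_min=%.2f A, oversampling=%.1f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$d_min, x$oversampling))
  invisible(x)
}

#' Electron density on a unit-cell grid
#'
#' @param values Numeric 3D array (or vector of length `prod(dims)`), the
#'   density value at each grid point; all values must be finite.
#' @param spec A `grid_spec` from [build_grid()].
#' @return An object of class `density_grid` with fields `values` (3D array)
#'   and `spec`.
#' @export
density_grid <- function(values, spec) {
  dims <- spec$dims
  if (is.null(dim(values))) {
    if (length(values) != prod(dims))
      stop("density_grid: length of values does not match grid dims")
    values <- array(values, dims)
  } else if (!all(dim(values) == dims)) {
    stop("density_grid: array dims do not match grid spec")
  }
  if (!all(is.finite(values))) stop("density_grid: values must be finite")
  structure(list(values = values, spec = spec), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("density_grid %d x %d x %d  mean=%.4g sd=%.4g range=[%.4g, %.4g]\n",
              dim(v)[1], dim(v)[2], dim(v)[3],
              mean(v), stats::sd(v), min(v), max(v)))
  invisible(x)
}

.check_same_spec <- function(a, b, what = "grids") {
  if (!all(a$spec$dims == b$spec$dims))
    stop(what, " have mismatching grid specs")
}

# Linear (1-based) index into the FFT array for Miller indices (n x 3 matrix).
.hkl_linear_index <- function(hkl, dims) {
  h <- hkl[, 1] %% dims[1]
  k <- hkl[, 2] %% dims[2]
  l <- hkl[, 3] %% dims[3]
  1L + h + dims[1] * (k + dims[2] * l)
}

.check_nyquist <- function(hkl, dims) {
  ny <- floor((dims - 1) / 2)
  bad <- abs(hkl[, 1]) > ny[1] | abs(hkl[, 2]) > ny[2] | abs(hkl[, 3]) > ny[3]
  if (any(bad))
    stop("reflection index beyond grid Nyquist limit: (",
         paste(hkl[which(bad)[1], ], collapse = ","), ")")
}

# Full complex structure-factor array of a density (package convention).
.forward_sf <- function(values) {
  stats::fft(values, inverse = TRUE) / length(values)
}

# Density from a full complex structure-factor array.
.inverse_sf <- function(Farr) {
  Re(stats::fft(Farr))
}

#' Structure factors from density
#'
#' Discrete Fourier transform of the grid density, evaluated at the requested
#' Miller indices: `F(h) = (1/N) sum_j g_j exp(+2 pi i h.x_j)`.
#'
#' @param grid A [density_grid()].
#' @param hkl n x 3 integer matrix of Miller indices (all within the grid's
#'   Nyquist limits).
#' @return A data.frame with columns `h,k,l,amp,phase` (phase in degrees in
#'   `[-180, 180)`), with `F(000)` attached as attribute `"f000"`.
#' @export
density_to_structure_factors <- function(grid, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = FALSE)
  hkl <- matrix(as.integer(hkl), ncol = 3)
  dims <- grid$spec$dims
  .check_nyquist(hkl, dims)
  Farr <- .forward_sf(grid$values)
  z <- Farr[.hkl_linear_index(hkl, dims)]
  ph <- (Arg(z) * 180 / pi)
  ph <- ((ph + 180) %% 360) - 180
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    amp = Mod(z), phase = ph)
  attr(out, "f000") <- Re(Farr[1])
  out
}

#' Density from phased structure factors
#'
#' Inverse transform of a set of phased amplitudes onto a grid. The input list
#' carries one reflection per Friedel pair; mates are filled in by conjugate
#' symmetry. If both mates are supplied explicitly they must agree in
#' amplitude (`|F(h)| == |F(-h)|`) and have opposite phases.
#'
#' @param amps data.frame with columns `h,k,l,amp,phase` (degrees).
#' @param spec A `grid_spec`.
#' @param f000 The F(000) term (mean density); default 0.
#' @return A [density_grid()].
#' @export
structure_factors_to_density <- function(amps, spec, f000 = 0) {
  dims <- spec$dims
  hkl <- as.matrix(amps[, c("h", "k", "l")])
  storage.mode(hkl) <- "integer"
  .check_nyquist(hkl, dims)
  Farr <- array(0 + 0i, dims)
  z <- amps$amp * exp(1i * amps$phase * pi / 180)
  ip <- .hkl_linear_index(hkl, dims)
  im <- .hkl_linear_index(-hkl, dims)
  # detect inconsistent explicitly-supplied Friedel mates
  dup <- ip %in% im[ip != im]
  if (any(dup)) {
    key_p <- ip[dup]
    match_m <- match(key_p, im)
    if (any(abs(amps$amp[dup] - amps$amp[match_m]) >
            1e-8 * (1 + amps$amp[dup])))
      stop("inconsistent Friedel mates: |F(h)| != |F(-h)|")
  }
  Farr[ip] <- z
  Farr[im] <- Conj(z)
  Farr[1] <- f000
  density_grid(.inverse_sf(Farr), spec)
}

# Minimal-image squared distance (Angstrom^2) from the origin grid point to
# every grid point; used for real-space kernels on the periodic lattice.
.min_image_r2 <- function(spec) {
  dims <- spec$dims
  O <- orthogonalization_matrix(spec$cell)
  d1 <- (0:(dims[1] - 1)); d1 <- ifelse(d1 > dims[1] / 2, d1 - dims[1], d1) / dims[1]
  d2 <- (0:(dims[2] - 1)); d2 <- ifelse(d2 > dims[2] / 2, d2 - dims[2], d2) / dims[2]
  d3 <- (0:(dims[3] - 1)); d3 <- ifelse(d3 > dims[3] / 2, d3 - dims[3], d3) / dims[3]
  f1 <- rep.int(d1, dims[2] * dims[3])
  f2 <- rep.int(rep(d2, each = dims[1]), dims[3])
  f3 <- rep(d3, each = dims[1] * dims[2])
  cx <- O[1, 1] * f1 + O[1, 2] * f2 + O[1, 3] * f3
  cy <- O[2, 1] * f1 + O[2, 2] * f2 + O[2, 3] * f3
  cz <- O[3, 1] * f1 + O[3, 2] * f2 + O[3, 3] * f3
  array(cx * cx + cy * cy + cz * cz, dims)
}
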