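#' Unit cell
#'
#' Construct a crystallographic unit cell from its six cell constants.
#'
#' @param a,b,c Cell edge lengths in Angstrom, all positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`
#'   and the precomputed cell `volume` (cubic Angstrom).
#' @examples
#' cell <- unit_cell(114.24, 114.164, 60.297)
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit_cell: cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit_cell: cell angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  vol2 <- 1 - sum(ca^2) + 2 * prod(ca)
  if (vol2 <= 0) stop("unit_cell: angles do not define a valid cell (volume <= 0)")
  vol <- a * b * c * sqrt(vol2)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         volume = vol),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard PDB convention: a along x, b in the xy plane.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 matrix `O` such that Cartesian coordinates (Angstrom) are
#'   `O %*% x` for fractional `x`.
#' @export
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Reciprocal metric tensor
#'
#' @param cell A [unit_cell()].
#' @return The 3x3 reciprocal-space metric tensor `G*`; for Miller indices `h`,
#'   `|h*|^2 = t(h) %*% Gstar %*% h` in 1/Angstrom^2.
#' @export
reciprocal_metric <- function(cell) {
  O <- orthogonalization_matrix(cell)
  G <- crossprod(O)          # real-space metric
  solve(G)
}

#' Resolution of reflections
#'
#' d-spacing of Miller indices under the standard reciprocal metric.
#'
#' @param hkl Integer vector of length 3, or an n x 3 matrix of Miller indices.
#' @param cell A [unit_cell()].
#' @return Resolution(s) d in Angstrom.
#' @examples
#' resolution_of(c(1, 1, 1), unit_cell(10, 10, 10))  # 10/sqrt(3)
#' @export
resolution_of <- function(hkl, cell) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, nrow = 1)
  if (ncol(hkl) != 3) stop("resolution_of: hkl must have 3 columns")
  if (any(rowSums(hkl != 0) == 0))
    stop("resolution_of: resolution undefined for (0,0,0)")
  Gs <- reciprocal_metric(cell)
  s2 <- rowSums((hkl %*% Gs) * hkl)
  1 / sqrt(s2)
}
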