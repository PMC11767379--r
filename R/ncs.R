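# Rotational non-crystallographic symmetry: real-space density averaging
# over a known Cn axis, applied every iteration for NCS-bearing targets.

#' NCS specification
#'
#' A known proper rotational symmetry (Cn) inside the asymmetric unit.
#'
#' @param order Rotation order n (>= 2).
#' @param axis_direction Axis direction in the orthogonal Angstrom frame
#'   (normalized internally).
#' @param axis_point A point on the axis, fractional coordinates.
#' @param core_sigmas Three decreasing weighting radii (Angstrom) for the
#'   staged core masks, default c(15, 5, 3).
#' @return Object of class `ncs_spec`.
#' @export
ncs_spec <- function(order, axis_direction = c(0, 0, 1),
                     axis_point = c(0, 0, 0), core_sigmas = c(15, 5, 3)) {
  if (order < 2) stop("ncs_spec: order must be >= 2")
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) stop("ncs_spec: zero axis direction")
  if (length(core_sigmas) != 3 || any(core_sigmas <= 0) ||
      any(diff(core_sigmas) >= 0))
    stop("ncs_spec: core_sigmas must be three decreasing positive radii")
  structure(list(order = as.integer(order),
                 axis_direction = axis_direction / nrm,
                 axis_point = axis_point,
                 core_sigmas = core_sigmas),
            class = "ncs_spec")
}

#' Rotation operators of an NCS axis
#'
#' The n rigid rotations by `2*pi*k/n` about the axis, in the cell's
#' orthogonal frame; `k = 0` is the identity.
#'
#' @param spec An [ncs_spec()].
#' @return List of 3x3 rotation matrices (orthogonal, det +1).
#' @export
build_rotation_operators <- function(spec) {
  u <- spec$axis_direction
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)   # K v = u x v (Rodrigues)
  lapply(0:(spec$order - 1), function(k) {
    th <- 2 * pi * k / spec$order
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  })
}

# Precompute, for each rotation k >= 1, the trilinear interpolation stencil
# (8 corner linear indices + weights) of the rotated position of every grid
# point.  Periodic wrap throughout.
.ncs_precompute <- function(grid_spec, spec) {
  dims <- grid_spec$dims
  O <- orthogonalization_matrix(grid_spec$cell)
  Oi <- solve(O)
  rots <- build_rotation_operators(spec)
  n <- prod(dims)
  i1 <- rep.int(0:(dims[1] - 1), dims[2] * dims[3])
  i2 <- rep.int(rep(0:(dims[2] - 1), each = dims[1]), dims[3])
  i3 <- rep(0:(dims[3] - 1), each = dims[1] * dims[2])
  frac <- rbind(i1 / dims[1], i2 / dims[2], i3 / dims[3])
  p_cart <- O %*% spec$axis_point
  stencils <- vector("list", spec$order - 1L)
  cart <- O %*% frac
  for (k in 2:spec$order) {
    R <- rots[[k]]
    rot <- Oi %*% (R %*% (cart - as.vector(p_cart)) + as.vector(p_cart))
    fi <- rot * dims                      # fractional -> grid units
    f0 <- floor(fi)
    w <- fi - f0                          # trilinear weights, 3 x n
    corner_idx <- function(ox, oy, oz) {
      a <- (as.integer(f0[1, ]) + ox) %% dims[1]
      b <- (as.integer(f0[2, ]) + oy) %% dims[2]
      c_ <- (as.integer(f0[3, ]) + oz) %% dims[3]
      1L + a + dims[1] * (b + dims[2] * c_)
    }
    idx <- matrix(0L, n, 8)
    wgt <- matrix(0, n, 8)
    m <- 1L
    for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
      idx[, m] <- corner_idx(ox, oy, oz)
      wgt[, m] <- (if (ox == 1) w[1, ] else 1 - w[1, ]) *
                  (if (oy == 1) w[2, ] else 1 - w[2, ]) *
                  (if (oz == 1) w[3, ] else 1 - w[3, ])
      m <- m + 1L
    }
    stencils[[k - 1L]] <- list(idx = idx, wgt = wgt)
  }
  stencils
}

# Average raw values over the NCS orbit inside `region` (logical or index).
.ncs_average_values <- function(values, stencils, region = NULL) {
  v <- as.vector(values)
  acc <- v
  for (st in stencils) {
    gathered <- v[st$idx]
    dim(gathered) <- dim(st$idx)
    acc <- acc + rowSums(gathered * st$wgt)
  }
  acc <- acc / (length(stencils) + 1)
  if (is.null(region)) return(array(acc, dim(values)))
  out <- v
  out[region] <- acc[region]
  array(out, dim(values))
}

#' NCS rotational density averaging
#'
#' Within the averaging region, each point's value becomes the mean of the
#' density over its n rotation images (trilinear interpolation with periodic
#' wrap); outside the region the map is unchanged.
#'
#' @param g A [density_grid()].
#' @param spec An [ncs_spec()].
#' @param region Optional [determine_envelope()] mask or logical array
#'   restricting the averaging; default: whole cell.
#' @return Averaged `density_grid`.
#' @export
ncs_average <- function(g, spec, region = NULL) {
  if (inherits(region, "envelope_mask")) region <- region$protein
  st <- .ncs_precompute(g$spec, spec)
  density_grid(.ncs_average_values(g$values, st,
                                   if (is.null(region)) NULL else as.vector(region)),
               g$spec)
}

#' Staged NCS core mask
#'
#' Simplified staged construction of the averaging region: the map is
#' Gaussian-weighted at the stage's radius (`core_sigmas[stage]`), thresholded
#' at the protein quantile; for stages 1 and 2 the mask is additionally
#' intersected with a cylinder of radius `2 * sigma_stage` about the declared
#' axis (stage 1 localizes the NCS center, stage 2 grows the core, stage 3
#' covers the full protein region and reproduces plain envelope
#' determination).
#'
#' @param g A `density_grid` (current modified density).
#' @param spec An [ncs_spec()].
#' @param stage 1, 2 or 3.
#' @param solvent_fraction Solvent fraction for the quantile threshold.
#' @return Logical 3D array.
#' @export
core_mask_from_weighted_density <- function(g, spec, stage, solvent_fraction) {
  stopifnot(stage %in% 1:3)
  sigma <- spec$core_sigmas[stage]
  w <- gaussian_weighted_density(g, sigma)
  mask <- determine_envelope(w, solvent_fraction)$protein
  if (stage == 3) return(mask)
  dims <- g$spec$dims
  O <- orthogonalization_matrix(g$spec$cell)
  i1 <- rep.int(0:(dims[1] - 1), dims[2] * dims[3])
  i2 <- rep.int(rep(0:(dims[2] - 1), each = dims[1]), dims[3])
  i3 <- rep(0:(dims[3] - 1), each = dims[1] * dims[2])
  # minimal-image displacement from the axis point
  df <- rbind(i1 / dims[1], i2 / dims[2], i3 / dims[3]) - spec$axis_point
  df <- df - round(df)
  cart <- O %*% df
  u <- spec$axis_direction
  along <- colSums(cart * u)
  perp2 <- colSums(cart^2) - along^2
  cyl <- perp2 <= (2 * sigma)^2
  mask & array(cyl, dims)
}
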