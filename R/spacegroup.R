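# Space-group symmetry: a documented supported set, stored as explicit
# (rotation, translation) operator lists acting on fractional coordinates
# x' = R x + t.  Centering translations are expanded into the operator list
# so |G| equals the number of general positions in the full cell.

.sg_op <- function(R, t) list(R = matrix(as.integer(R), 3, 3, byrow = TRUE),
                              t = t)

.sg_table <- local({
  I3 <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  tab <- list()
  tab[["P1"]] <- list(.sg_op(I3, c(0, 0, 0)))
  # P21212 (no. 18)
  tab[["P21212"]] <- list(
    .sg_op(I3, c(0, 0, 0)),
    .sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 0)),
    .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1/2, 1/2, 0)),
    .sg_op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1/2, 1/2, 0)))
  # P212121 (no. 19)
  tab[["P212121"]] <- list(
    .sg_op(I3, c(0, 0, 0)),
    .sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(1/2, 0, 1/2)),
    .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1/2, 1/2)),
    .sg_op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1/2, 1/2, 0)))
  # P42212 (no. 94)
  tab[["P42212"]] <- list(
    .sg_op(I3, c(0, 0, 0)),
    .sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 0)),
    .sg_op(c(0, -1, 0, 1, 0, 0, 0, 0, 1), c(1/2, 1/2, 1/2)),
    .sg_op(c(0, 1, 0, -1, 0, 0, 0, 0, 1), c(1/2, 1/2, 1/2)),
    .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1/2, 1/2, 1/2)),
    .sg_op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1/2, 1/2, 1/2)),
    .sg_op(c(0, 1, 0, 1, 0, 0, 0, 0, -1), c(0, 0, 0)),
    .sg_op(c(0, -1, 0, -1, 0, 0, 0, 0, -1), c(0, 0, 0)))
  # C121 (no. 5, unique axis b), centering expanded
  tab[["C121"]] <- list(
    .sg_op(I3, c(0, 0, 0)),
    .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 0, 0)),
    .sg_op(I3, c(1/2, 1/2, 0)),
    .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1/2, 1/2, 0)))
  tab
})

#' Supported space groups
#'
#' @return Character vector of supported Hermann-Mauguin symbols.
#' @export
supported_space_groups <- function() names(.sg_table)

#' Space-group information
#'
#' Symmetry operators and polar-axis flags for a supported space group.
#' Operators act on fractional coordinates as `x' = R x + t`; lattice
#' centering is expanded into the operator list.
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P212121"`. `"C2"` is accepted
#'   as an alias for `"C121"`.
#' @return An object of class `space_group` with fields `hm_symbol`,
#'   `operators` (list of `(R, t)` pairs) and `polar_axes` (logical length 3:
#'   axes along which all rotation parts act as the identity, so the origin
#'   floats continuously).
#' @examples
#' sg <- space_group("P21212")
#' length(sg$operators)
#' @export
space_group <- function(symbol) {
  symbol <- gsub("[[:space:]]", "", symbol)
  if (identical(symbol, "C2")) symbol <- "C121"
  ops <- .sg_table[[symbol]]
  if (is.null(ops))
    stop("space_group: unsupported symbol '", symbol,
         "'; supported: ", paste(names(.sg_table), collapse = ", "))
  polar <- vapply(1:3, function(a) {
    e <- numeric(3); e[a] <- 1
    all(vapply(ops, function(op) all(op$R %*% e == e), logical(1)))
  }, logical(1))
  structure(list(hm_symbol = symbol, operators = ops, polar_axes = polar),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s  (%d operators; polar axes: %s)\n",
              x$hm_symbol, length(x$operators),
              if (any(x$polar_axes)) paste(c("a", "b", "c")[x$polar_axes],
                                           collapse = ",") else "none"))
  invisible(x)
}

# Grid-index permutation realizing one operator on a dims grid: element i of
# the returned vector is the (1-based) linear index of op(x_i).  Errors if the
# operator does not map the grid onto itself.
.op_permutation <- function(op, dims) {
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  tn <- op$t * dims
  if (max(abs(tn - round(tn))) > 1e-9)
    stop("symmetry operator translation incompatible with grid dims")
  i1 <- rep.int(0:(n1 - 1), n2 * n3)
  i2 <- rep.int(rep(0:(n2 - 1), each = n1), n3)
  i3 <- rep(0:(n3 - 1), each = n1 * n2)
  R <- op$R
  # x' = R x + t in fractions;  j_a = sum_b R[a,b] * i_b * n_a / n_b + t_a n_a
  j <- vector("list", 3)
  ii <- list(i1, i2, i3)
  for (a in 1:3) {
    acc <- rep.int(round(tn[a]), n1 * n2 * n3)
    for (b in 1:3) {
      if (R[a, b] != 0) {
        f <- R[a, b] * dims[a] / dims[b]
        if (abs(f - round(f)) > 1e-9)
          stop("grid dims incompatible with axis-mixing symmetry operator")
        acc <- acc + as.integer(round(f)) * ii[[b]]
      }
    }
    j[[a]] <- acc %% dims[a]
  }
  1L + j[[1]] + n1 * (j[[2]] + n2 * j[[3]])
}

# Cached permutations for all operators of sg on a dims grid.
.sg_permutations <- function(sg, dims) {
  lapply(sg$operators, .op_permutation, dims = dims)
}

#' Symmetrize a density over a space group
#'
#' Replaces the density by its mean over all symmetry-operator images, the
#' orthogonal projection onto the subspace of crystallographically symmetric
#' densities. Needed because random starting densities and genetic edits break
#' cell symmetry.
#'
#' @param grid A [density_grid()].
#' @param sg A [space_group()].
#' @return A symmetrized `density_grid`, invariant under every operator.
#' @export
symmetrize_density <- function(grid, sg) {
  v <- as.vector(grid$values)
  perms <- .sg_permutations(sg, grid$spec$dims)
  acc <- numeric(length(v))
  for (p in perms) acc <- acc + v[p]
  density_grid(array(acc / length(perms), grid$spec$dims), grid$spec)
}

# Orbit representatives: rep[i] = min over operators of perm(i).
# asu_index: points that represent their own orbit; rep_map: for every grid
# point, the position of its representative inside asu_index.
.asu_structure <- function(sg, dims) {
  n <- prod(dims)
  perms <- .sg_permutations(sg, dims)
  rep_lin <- seq_len(n)
  for (p in perms) rep_lin <- pmin(rep_lin, p)
  asu <- which(rep_lin == seq_len(n))
  pos <- integer(n)
  pos[asu] <- seq_along(asu)
  list(asu_index = asu, rep_map = pos[rep_lin])
}

#' Asymmetric-unit index subset
#'
#' One representative grid point per symmetry orbit (the minimal linear index
#' of the orbit). These points form the genetic-algorithm chromosome; a full
#' cell is rebuilt by replicating representative values over their orbits.
#'
#' @param sg A [space_group()].
#' @param dims Integer grid dimensions (length 3).
#' @return List with `asu_index` (linear indices of representatives) and
#'   `rep_map` (for each grid point, the position of its representative in
#'   `asu_index`).
#' @export
asu_indices <- function(sg, dims) .asu_structure(sg, dims)

# Expand ASU values to a symmetric full-cell vector.
.asu_expand <- function(asu_values, asu) asu_values[asu$rep_map]
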