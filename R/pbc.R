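# Minimum-image geometry for orthorhombic boxes.

#' Minimum-image displacement
#'
#' Displacement `a - b` under the minimum-image convention of an
#' orthorhombic box; with `box = NULL` the plain difference is returned.
#' Each component of the result has magnitude at most half the box edge.
#'
#' @param a,b Numeric vectors of length 3, or matrices with 3 columns
#'   (rowwise points) in angstrom.
#' @param box Edge lengths (length 3) or `NULL`.
#' @return Displacement vector/matrix, same shape as the inputs.
#' @export
#' @examples
#' min_image_displacement(c(1, 0, 0), c(9, 0, 0), box = c(10, 10, 10))
min_image_displacement <- function(a, b, box = NULL) {
  d <- a - b
  if (is.null(box)) return(d)
  box <- as.numeric(box)
  if (any(box <= 0)) abort("box lengths must be > 0")
  if (is.matrix(d)) {
    d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
  } else {
    d - box * round(d / box)
  }
}

#' Minimum-image distance
#'
#' @inheritParams min_image_displacement
#' @return Euclidean norm(s) of the minimum-image displacement.
#' @export
min_image_distance <- function(a, b, box = NULL) {
  d <- min_image_displacement(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d * d)) else sqrt(sum(d * d))
}

# All minimum-image distances between two point sets (na x 3, nb x 3),
# returned as an na x nb matrix. Desk-scale quadratic evaluation.
pair_distances <- function(pa, pb, box = NULL) {
  na_ <- nrow(pa); nb_ <- nrow(pb)
  dx <- outer(pa[, 1L], pb[, 1L], "-")
  dy <- outer(pa[, 2L], pb[, 2L], "-")
  dz <- outer(pa[, 3L], pb[, 3L], "-")
  if (!is.null(box)) {
    dx <- dx - box[1L] * round(dx / box[1L])
    dy <- dy - box[2L] * round(dy / box[2L])
    dz <- dz - box[3L] * round(dz / box[3L])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Wrap positions into [0, box) per axis.
wrap_positions <- function(x, box) {
  if (is.null(box)) return(x)
  if (is.matrix(x)) {
    x - sweep(floor(sweep(x, 2L, box, "/")), 2L, box, "*")
  } else {
    x - box * floor(x / box)
  }
}

# Angle A-B-C at vertex B, degrees; minimum-image arm vectors when a box
# is given, so the angle is invariant under PBC rewrapping.
vertex_angle <- function(a, b, c_, box = NULL) {
  u <- min_image_displacement(a, b, box)
  v <- min_image_displacement(c_, b, box)
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
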