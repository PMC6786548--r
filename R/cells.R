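#' Crystallographic unit cell
#'
#' Constructs a unit-cell description from the six lattice parameters and a
#' centering flag. Lengths are in nanometres, angles in degrees. The metric
#' tensor must be positive definite (i.e. the cell must have positive volume);
#' degenerate cells are rejected.
#'
#' @param a,b,c Cell edge lengths in nm (all > 0). `b` and `c` default to `a`.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'   `alpha` = angle(b,c), `beta` = angle(a,c), `gamma` = angle(a,b).
#' @param centering Either `"primitive"` or `"body_centered"`.
#' @return An object of class `unit_cell`: a list with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, `centering`.
#' @examples
#' bct <- unit_cell(27.9, 27.9, 33, centering = "body_centered")
#' cell_volume(bct)
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90,
                      centering = c("primitive", "body_centered")) {
  centering <- match.arg(centering)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0))
    stop("cell edge lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                         gamma = gamma, centering = centering),
                    class = "unit_cell")
  v <- cell_volume(cell)
  if (!is.finite(v) || v < 1e-9 * a * b * c)
    stop("degenerate cell: metric tensor is not positive definite")
  cell
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Cell volume from lattice parameters
#'
#' @param cell A [unit_cell()].
#' @return Volume of the (conventional) cell in nm^3.
#' @export
cell_volume <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma))
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(NaN)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Basis matrix of a unit cell
#'
#' Standard crystallographic Cartesian setting: a along x, b in the xy plane.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 matrix whose columns are the a, b, c edge vectors (nm).
#' @export
cell_basis <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma)); sg <- sin(deg2rad(cell$gamma))
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("degenerate cell: no real basis exists")
  cv <- c(cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * sqrt(cz2))
  cbind(av, bv, cv, deparse.level = 0)
}

#' Lattice parameters realised by a basis matrix
#'
#' Inverse of [cell_basis()]: reads off edge lengths and inter-edge angles
#' from three column vectors.
#'
#' @param B 3x3 matrix with the a, b, c vectors as columns.
#' @param centering Centering flag to attach.
#' @return A [unit_cell()].
#' @export
params_from_basis <- function(B, centering = "primitive") {
  len <- sqrt(colSums(B^2))
  ang <- function(u, v) rad2deg(acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))))
  unit_cell(len[1], len[2], len[3],
            alpha = ang(B[, 2], B[, 3]),
            beta  = ang(B[, 1], B[, 3]),
            gamma = ang(B[, 1], B[, 2]),
            centering = centering)
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell (%s)\n", x$centering))
  cat(sprintf("  a = %.3f  b = %.3f  c = %.3f nm\n", x$a, x$b, x$c))
  cat(sprintf("  alpha = %.2f  beta = %.2f  gamma = %.2f deg\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  volume = %.1f nm^3\n", cell_volume(x)))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis Rotation axis (any non-zero 3-vector; normalised internally).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Deterministic orthonormal complement of a unit axis: 3x2 matrix (e1, e2)
# such that (e1, e2, axis) is right-handed.
plane_basis <- function(axis) {
  n <- axis / sqrt(sum(axis^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(ref, n)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  cbind(e1, e2, deparse.level = 0)
}
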