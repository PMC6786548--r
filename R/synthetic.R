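#' Lattice points of a unit cell inside a box
#'
#' Enumerates all lattice translations of `cell` (corner sites, plus body
#' centres for a body-centered cell) that fall inside an axis-aligned box.
#' The box is half-open: a point is kept when `0 <= x < box[i]` on each axis,
#' so a 10x10x10 box of a unit simple-cubic cell holds exactly 1000 points.
#'
#' @param cell A [unit_cell()].
#' @param box Numeric length-3: box extents (nm) along x, y, z.
#' @param orientation 3x3 rotation applied to the cell basis.
#' @param origin Lattice origin (nm), default `c(0, 0, 0)`.
#' @return n x 3 matrix of point coordinates (nm), columns x, y, z.
#' @examples
#' pts <- build_lattice_points(unit_cell(1), box = c(10, 10, 10))
#' nrow(pts) # 1000
#' @export
build_lattice_points <- function(cell, box, orientation = diag(3),
                                 origin = c(0, 0, 0)) {
  stopifnot(length(box) == 3, all(box > 0))
  B <- orientation %*% cell_basis(cell)
  offs <- list(c(0, 0, 0))
  if (cell$centering == "body_centered") offs <- c(offs, list(c(.5, .5, .5)))
  corners <- as.matrix(expand.grid(c(0, box[1]), c(0, box[2]), c(0, box[3])))
  out <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    f <- solve(B, t(corners) - origin) # fractional coords of box corners
    lo <- floor(apply(f, 1, min)) - 2L
    hi <- ceiling(apply(f, 1, max)) + 1L
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    p <- t(B %*% (t(g) + offs[[k]])) + rep(origin, each = nrow(g))
    eps <- 1e-9
    keep <- p[, 1] >= -eps & p[, 1] < box[1] - eps &
            p[, 2] >= -eps & p[, 2] < box[2] - eps &
            p[, 3] >= -eps & p[, 3] < box[3] - eps
    out[[k]] <- p[keep, , drop = FALSE]
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Specification of a cyclic twin
#'
#' Describes an assembly of angular sectors about a common axis. Each sector
#' carries its own unit cell and orientation; by default every sector holds
#' the same cell, rotated about the common axis so that it starts at the
#' sector's opening azimuth (so lattice rows rotate with the sectors, as in a
#' cyclic twin).
#'
#' Wedge angles may sum to less than 360 degrees (the experimental five-fold
#' twin sums to 359). The `closure` policy decides how the deficit is closed:
#' `"append_last"` widens the last sector by the deficit; `"rescale"`
#' multiplies every wedge by 360/sum.
#'
#' @param wedge_angles Sector opening angles in degrees (all > 0, sum <= 360).
#' @param common_axis Twin axis (unit vector; normalised internally).
#' @param cells A [unit_cell()] or list of one cell per sector.
#' @param sector_rotations Optional extra in-sector rotation angles (degrees,
#'   about the common axis) added to each sector's opening azimuth.
#' @param base_orientation 3x3 rotation applied to every sector's cell before
#'   the per-sector azimuthal rotation.
#' @param closure `"append_last"` or `"rescale"`.
#' @return Object of class `twin_spec`.
#' @export
twin_spec <- function(wedge_angles = c(76, 70, 71, 73, 69),
                      common_axis = c(0, 0, 1),
                      cells = unit_cell(27.9, 27.9, 33, centering = "body_centered"),
                      sector_rotations = NULL,
                      base_orientation = diag(3),
                      closure = c("append_last", "rescale")) {
  closure <- match.arg(closure)
  if (any(wedge_angles <= 0)) stop("wedge angles must be positive")
  if (sum(wedge_angles) > 360 + 1e-9) stop("wedge angles sum beyond 360 degrees")
  k <- length(wedge_angles)
  if (k < 2) stop("a twin needs at least 2 sectors")
  if (inherits(cells, "unit_cell")) cells <- rep(list(cells), k)
  if (length(cells) != k) stop("need one cell per sector")
  deficit <- 360 - sum(wedge_angles)
  eff <- wedge_angles
  if (closure == "append_last") eff[k] <- eff[k] + deficit
  else eff <- eff * 360 / sum(eff)
  if (is.null(sector_rotations)) sector_rotations <- rep(0, k)
  structure(list(wedge_angles = wedge_angles, effective_angles = eff,
                 closure_deficit = deficit, closure = closure,
                 common_axis = common_axis / sqrt(sum(common_axis^2)),
                 cells = cells, sector_rotations = sector_rotations,
                 base_orientation = base_orientation),
            class = "twin_spec")
}

#' Build a cyclically twinned point assembly
#'
#' Generates each sector's lattice over the whole box and keeps the points
#' whose azimuth about the common axis (anchored at the box centre) falls in
#' that sector. Every point therefore lies in exactly one sector.
#'
#' @param spec A [twin_spec()].
#' @param box Box extents (nm).
#' @return List with `points` (n x 3 matrix, nm) and `sector` (integer label
#'   per point, 1-based), plus the azimuthal sector start angles as
#'   `sector_starts` (degrees).
#' @export
build_twinned_assembly <- function(spec, box) {
  stopifnot(inherits(spec, "twin_spec"))
  centre <- box / 2
  E <- plane_basis(spec$common_axis)
  starts <- c(0, cumsum(spec$effective_angles))
  pts <- list(); lab <- list()
  for (s in seq_along(spec$effective_angles)) {
    R <- rotation_about(spec$common_axis,
                        starts[s] + spec$sector_rotations[s]) %*%
      spec$base_orientation
    p <- build_lattice_points(spec$cells[[s]], box, orientation = R,
                              origin = centre)
    d <- sweep(p, 2, centre)
    az <- (rad2deg(atan2(d %*% E[, 2], d %*% E[, 1]))) %% 360
    keep <- az >= starts[s] & az < starts[s + 1]
    pts[[s]] <- p[keep, , drop = FALSE]
    lab[[s]] <- rep.int(s, sum(keep))
  }
  points <- do.call(rbind, pts)
  list(points = points, sector = unlist(lab),
       sector_starts = starts[-length(starts)])
}

#' Disorder specification
#'
#' @param jitter_sigma Isotropic Gaussian positional jitter sd (nm, >= 0).
#' @param vacancy_prob Independent deletion probability in [0, 1).
#' @param bend_amplitude Amplitude of the smooth sinusoidal bending field (nm).
#' @param bend_wavelength Wavelength of the bending field (nm).
#' @param bend_axis Displacement direction of the bend (default z, emulating
#'   granule columns bending along the beam axis).
#' @param bend_along Coordinate the bend phase runs along (default x).
#' @param seed Integer seed; all stochastic elements draw from one stream.
#' @return Object of class `disorder_spec`.
#' @export
disorder_spec <- function(jitter_sigma = 0, vacancy_prob = 0,
                          bend_amplitude = 0, bend_wavelength = 200,
                          bend_axis = 3L, bend_along = 1L, seed = 1L) {
  stopifnot(jitter_sigma >= 0, vacancy_prob >= 0, vacancy_prob < 1,
            bend_wavelength > 0)
  structure(list(jitter_sigma = jitter_sigma, vacancy_prob = vacancy_prob,
                 bend_amplitude = bend_amplitude,
                 bend_wavelength = bend_wavelength,
                 bend_axis = as.integer(bend_axis),
                 bend_along = as.integer(bend_along),
                 seed = as.integer(seed)),
            class = "disorder_spec")
}

#' Apply positional disorder to a point set
#'
#' Adds a deterministic sinusoidal bending displacement, isotropic Gaussian
#' jitter, and Bernoulli vacancies, in that order. Reproducible under the
#' spec's seed.
#'
#' @param points n x 3 matrix (nm).
#' @param spec A [disorder_spec()].
#' @return Matrix of surviving, displaced points; attribute `"kept"` holds the
#'   surviving row indices of the input.
#' @export
apply_disorder <- function(points, spec) {
  stopifnot(inherits(spec, "disorder_spec"))
  p <- as.matrix(points)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  if (spec$bend_amplitude != 0) {
    phase <- 2 * pi * p[, spec$bend_along] / spec$bend_wavelength
    p[, spec$bend_axis] <- p[, spec$bend_axis] +
      spec$bend_amplitude * sin(phase)
  }
  if (spec$jitter_sigma > 0)
    p <- p + matrix(stats::rnorm(length(p), 0, spec$jitter_sigma), nrow(p), 3)
  kept <- seq_len(nrow(p))
  if (spec$vacancy_prob > 0) {
    kept <- which(stats::runif(nrow(p)) >= spec$vacancy_prob)
    p <- p[kept, , drop = FALSE]
  }
  attr(p, "kept") <- kept
  p
}
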