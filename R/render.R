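#' Voxel volume container
#'
#' A 3D density grid with a physical voxel size. Data are stored as an R
#' array indexed `[x, y, z]` (1-based, column-major); the physical position
#' of voxel centre `(i, j, k)` is `((i, j, k) - 0.5) * voxel_size + origin`.
#' Contrast convention: protein is high intensity.
#'
#' @param data 3D numeric array.
#' @param voxel_size Voxel edge length in nm (> 0).
#' @param origin Physical position (nm) of the corner of voxel (1,1,1).
#' @return Object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, all(dim(data) >= 1), voxel_size > 0)
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels @ %.3f nm (%.0f x %.0f x %.0f nm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# physical coordinates of voxel centres along one axis
axis_coords <- function(vol, ax) {
  (seq_len(dim(vol$data)[ax]) - 0.5) * vol$voxel_size + vol$origin[ax]
}

#' Render a granule assembly into a voxel volume
#'
#' Each granule becomes a soft-edged sphere: the radial intensity profile is
#' `pnorm((R - r) / edge_softness)`, an error-function falloff whose full
#' width at half maximum equals `granule_diameter`. Optional linker cylinders
#' are drawn between nearest-neighbour pairs whose connecting vector lies
#' (within `linker_angle_tol` degrees) in one of the selected lattice planes;
#' linkers are combined with the granule field by voxelwise maximum so that
#' intensity maxima stay at granule centres. Optional additive Gaussian noise
#' and an optional dual-axis missing-wedge Fourier filter complete the
#' tomogram stand-in.
#'
#' @param points n x 3 matrix of granule centres (nm).
#' @param voxel_size Voxel size in nm (must not exceed the granule radius).
#' @param granule_diameter Sphere FWHM diameter in nm.
#' @param edge_softness Error-function edge width in nm.
#' @param margin Padding around the point extent (nm).
#' @param box Optional explicit box extents (nm); points are shifted by
#'   `margin` regardless.
#' @param linker_planes Optional list of plane normals (lab frame); linkers
#'   are drawn between near-minimal in-plane neighbour pairs.
#' @param linker_radius Cylinder radius (nm).
#' @param linker_intensity Cylinder peak intensity (granule peak is 1).
#' @param linker_angle_tol Max angle (degrees) between a pair vector and the
#'   lattice plane for the pair to receive a linker.
#' @param noise_sigma Additive Gaussian noise sd (intensity units).
#' @param missing_wedge Optional list `list(tilt_range = 60, dual_axis = TRUE)`.
#' @param seed Seed for the noise draw.
#' @return A [volume3d()]; attribute `"centers"` holds the granule centres in
#'   the volume's physical frame.
#' @export
render_volume <- function(points, voxel_size = 1.1, granule_diameter = 20.1,
                          edge_softness = 1.5, margin = granule_diameter,
                          box = NULL, linker_planes = NULL,
                          linker_radius = 3, linker_intensity = 0.8,
                          linker_angle_tol = 10, noise_sigma = 0,
                          missing_wedge = NULL, seed = 1L) {
  p <- as.matrix(points)
  if (nrow(p) < 1) stop("no points to render")
  if (voxel_size > granule_diameter / 2)
    stop("voxel_size exceeds the granule radius: spheres would be unresolvable")
  lo <- apply(p, 2, min) - margin
  p <- sweep(p, 2, lo)
  ext <- if (is.null(box)) apply(p, 2, max) + margin else box
  dims <- pmax(2L, as.integer(ceiling(ext / voxel_size)))
  vol <- array(0, dims)
  R <- granule_diameter / 2
  reach <- R + 4 * edge_softness
  cox <- (seq_len(dims[1]) - 0.5) * voxel_size
  coy <- (seq_len(dims[2]) - 0.5) * voxel_size
  coz <- (seq_len(dims[3]) - 0.5) * voxel_size
  for (g in seq_len(nrow(p))) {
    ix <- which(abs(cox - p[g, 1]) <= reach)
    iy <- which(abs(coy - p[g, 2]) <= reach)
    iz <- which(abs(coz - p[g, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    r2 <- outer(outer((cox[ix] - p[g, 1])^2, (coy[iy] - p[g, 2])^2, "+"),
                (coz[iz] - p[g, 3])^2, "+")
    vol[ix, iy, iz] <- vol[ix, iy, iz] +
      stats::pnorm((R - sqrt(r2)) / edge_softness)
  }
  if (!is.null(linker_planes)) {
    pairs <- linker_pairs(p, linker_planes, linker_angle_tol)
    if (nrow(pairs)) {
      lk <- array(0, dims)
      for (q in seq_len(nrow(pairs))) {
        a <- p[pairs[q, 1], ]; b <- p[pairs[q, 2], ]
        rr <- linker_radius + 4 * edge_softness
        blo <- pmin(a, b) - rr; bhi <- pmax(a, b) + rr
        ix <- which(cox >= blo[1] & cox <= bhi[1])
        iy <- which(coy >= blo[2] & coy <= bhi[2])
        iz <- which(coz >= blo[3] & coz <= bhi[3])
        if (!length(ix) || !length(iy) || !length(iz)) next
        nx <- length(ix); ny <- length(iy); nz <- length(iz)
        X <- array(cox[ix], c(nx, ny, nz))
        Y <- aperm(array(coy[iy], c(ny, nx, nz)), c(2, 1, 3))
        Z <- aperm(array(coz[iz], c(nz, nx, ny)), c(2, 3, 1))
        u <- b - a; L2 <- sum(u^2)
        t0 <- ((X - a[1]) * u[1] + (Y - a[2]) * u[2] + (Z - a[3]) * u[3]) / L2
        t0 <- pmin(pmax(t0, 0), 1)
        d2 <- (X - a[1] - t0 * u[1])^2 + (Y - a[2] - t0 * u[2])^2 +
          (Z - a[3] - t0 * u[3])^2
        lk[ix, iy, iz] <- pmax(lk[ix, iy, iz],
          linker_intensity * stats::pnorm((linker_radius - sqrt(d2)) / edge_softness))
      }
      vol <- pmax(vol, lk)
    }
  }
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sigma), dims)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  out <- volume3d(vol, voxel_size)
  if (!is.null(missing_wedge)) {
    ta <- if (is.null(missing_wedge$tilt_range)) 60 else missing_wedge$tilt_range
    da <- if (is.null(missing_wedge$dual_axis)) TRUE else missing_wedge$dual_axis
    out <- apply_missing_wedge(out, tilt_range = ta, dual_axis = da)
  }
  attr(out, "centers") <- p
  out
}

# nearest-neighbour pairs whose vector lies within tol degrees of any of the
# given planes, restricted to near-minimal in-plane pair length (<= 1.15 min)
linker_pairs <- function(p, normals, tol_deg = 10) {
  n <- nrow(p)
  if (n < 2) return(matrix(integer(), 0, 2))
  D <- as.matrix(stats::dist(p))
  diag(D) <- Inf
  cutoff <- 1.6 * min(D)
  idx <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(integer(), 0, 2))
  v <- p[idx[, 2], , drop = FALSE] - p[idx[, 1], , drop = FALSE]
  len <- sqrt(rowSums(v^2))
  inplane <- rep(FALSE, nrow(idx))
  for (nm in normals) {
    nn <- nm / sqrt(sum(nm^2))
    off <- abs(rad2deg(asin(pmin(1, abs(v %*% nn) / len))))
    inplane <- inplane | (off <= tol_deg)
  }
  if (!any(inplane)) return(matrix(integer(), 0, 2))
  lmin <- min(len[inplane])
  keep <- inplane & len <= 1.15 * lmin
  idx[keep, , drop = FALSE]
}

#' Dual-axis missing-wedge Fourier filter
#'
#' Zeroes the Fourier components inside the missing wedge of a limited-tilt
#' acquisition. For a single tilt axis (y), the missing wedge is the set of
#' spatial frequencies whose (kx, kz) direction lies more than `tilt_range`
#' degrees from the kx axis; the dual-axis mask removes only the intersection
#' of the two single-axis wedges (tilt axes y and x), i.e. the missing
#' pyramid. Energy outside the mask is preserved exactly.
#'
#' @param vol A [volume3d()].
#' @param tilt_range Half tilt range in degrees (default 60).
#' @param dual_axis If `TRUE`, intersect the wedges of both tilt axes.
#' @return Filtered [volume3d()]; attribute `"wedge_mask"` (logical array,
#'   `TRUE` = kept) is attached.
#' @export
apply_missing_wedge <- function(vol, tilt_range = 60, dual_axis = TRUE) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$data)
  fq <- function(n) { k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k / n }
  kx <- fq(d[1]); ky <- fq(d[2]); kz <- fq(d[3])
  KX <- array(abs(kx), d)
  KY <- aperm(array(abs(ky), c(d[2], d[1], d[3])), c(2, 1, 3))
  KZ <- aperm(array(abs(kz), c(d[3], d[1], d[2])), c(2, 3, 1))
  lim <- tan(deg2rad(tilt_range))
  m1 <- KZ <= lim * KX # measured under tilt axis y
  m2 <- KZ <= lim * KY # measured under tilt axis x
  mask <- if (dual_axis) (m1 | m2) else m1
  F <- stats::fft(vol$data)
  F[!mask] <- 0
  out <- vol
  out$data <- Re(stats::fft(F, inverse = TRUE)) / length(F)
  attr(out, "wedge_mask") <- mask
  out
}

#' Sum a slab of a volume into a 2D projection
#'
#' Integrates the density over a slab of the given thickness centred on
#' `anchor` and perpendicular to `normal`, and returns the in-plane image.
#' For an axis-aligned normal the projection is an exact partial sum of
#' voxel planes; for a general normal the slab is resampled by trilinear
#' interpolation on a grid with the volume's voxel size.
#'
#' @param vol A [volume3d()].
#' @param normal Slab normal (3-vector).
#' @param anchor Point on the slab mid-plane (nm). Default: volume centre.
#' @param thickness Slab thickness in nm (default 20, one granule diameter).
#' @return Matrix (image); attributes `"pixel_size"` (nm) and, for axis-
#'   aligned normals, `"axes"` (the two in-plane volume axes).
#' @export
extract_slab_projection <- function(vol, normal = c(0, 0, 1), anchor = NULL,
                                    thickness = 20) {
  stopifnot(inherits(vol, "volume3d"), thickness > 0)
  d <- dim(vol$data)
  ext <- d * vol$voxel_size
  if (is.null(anchor)) anchor <- vol$origin + ext / 2
  n <- normal / sqrt(sum(normal^2))
  ax <- which(abs(abs(n) - 1) < 1e-9)
  if (length(ax) == 1) {
    co <- axis_coords(vol, ax)
    c0 <- anchor[ax]
    keep <- which(co >= c0 - thickness / 2 & co <= c0 + thickness / 2)
    if (!length(keep)) stop("slab lies outside the volume")
    img <- switch(ax,
      apply(vol$data[keep, , , drop = FALSE], c(2, 3), sum),
      apply(vol$data[, keep, , drop = FALSE], c(1, 3), sum),
      apply(vol$data[, , keep, drop = FALSE], c(1, 2), sum))
    attr(img, "pixel_size") <- vol$voxel_size
    attr(img, "axes") <- setdiff(1:3, ax)
    return(img)
  }
  # general normal: resample
  E <- plane_basis(n)
  half_diag <- sqrt(sum(ext^2)) / 2
  s <- seq(-half_diag, half_diag, by = vol$voxel_size)
  tt <- seq(-thickness / 2, thickness / 2, by = vol$voxel_size)
  if (!length(tt)) tt <- 0
  img <- matrix(0, length(s), length(s))
  for (w in tt) {
    P0 <- anchor + w * n
    U <- outer(s, E[, 1])
    for (j in seq_along(s)) {
      pts <- sweep(U, 2, P0 + s[j] * E[, 2], "+")
      img[, j] <- img[, j] + trilinear(vol, pts)
    }
  }
  attr(img, "pixel_size") <- vol$voxel_size
  img
}

# trilinear interpolation of a volume at physical points (m x 3); zero outside
trilinear <- function(vol, pts) {
  d <- dim(vol$data)
  g <- sweep(pts, 2, vol$origin) / vol$voxel_size + 0.5 # voxel-centre coords
  i0 <- floor(g)
  f <- g - i0
  val <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0 + rep(c(dx, dy, dz), each = nrow(pts))
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
          ii[, 3] >= 1 & ii[, 3] <= d[3]
    if (any(ok))
      val[ok] <- val[ok] + w[ok] *
        vol$data[cbind(ii[ok, 1], ii[ok, 2], ii[ok, 3])]
  }
  val
}
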