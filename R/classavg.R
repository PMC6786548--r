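# --- reference-free translational 2D class averaging ---

#' Box particle images out of a slab projection
#'
#' Crops square windows centred on the pick coordinates and normalises each
#' to zero mean / unit variance. Picks too close to the border are skipped
#' with a warning. Duplicate picks yield duplicate images (no
#' deduplication).
#'
#' @param image 2D matrix (e.g. from [extract_slab_projection()]); pixel
#'   size read from the `"pixel_size"` attribute when picks are in nm.
#' @param picks m x 2 matrix of pick centres, in pixels (default) or nm.
#' @param box_px Box side in pixels.
#' @param units `"px"` or `"nm"`.
#' @return Object of class `particle_stack`: `images` (box x box x n
#'   array), `picks`, `box_px`, `pixel_size`.
#' @export
box_particles <- function(image, picks, box_px, units = c("px", "nm")) {
  units <- match.arg(units)
  ps <- attr(image, "pixel_size")
  picks <- as.matrix(picks)
  if (units == "nm") {
    if (is.null(ps)) stop("image has no pixel_size attribute; cannot use nm")
    picks <- picks / ps + 0.5
  }
  half <- floor(box_px / 2)
  d <- dim(image)
  imgs <- list(); kept <- integer()
  for (i in seq_len(nrow(picks))) {
    cx <- round(picks[i, 1]); cy <- round(picks[i, 2])
    x0 <- cx - half; x1 <- x0 + box_px - 1
    y0 <- cy - half; y1 <- y0 + box_px - 1
    if (x0 < 1 || y0 < 1 || x1 > d[1] || y1 > d[2]) {
      warning("pick ", i, " too close to border; skipped")
      next
    }
    w <- image[x0:x1, y0:y1]
    s <- stats::sd(w)
    imgs[[length(imgs) + 1L]] <- if (s > 0) (w - mean(w)) / s else w - mean(w)
    kept <- c(kept, i)
  }
  if (!length(imgs)) stop("no particles could be boxed")
  structure(list(images = array(unlist(imgs), c(box_px, box_px, length(imgs))),
                 picks = picks[kept, , drop = FALSE], box_px = box_px,
                 pixel_size = ps),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("particle_stack: %d particles, box %d px (%.2f nm/px)\n",
              dim(x$images)[3], x$box_px,
              if (is.null(x$pixel_size)) NA else x$pixel_size))
  invisible(x)
}

# cyclic integer shift of a matrix restricted to |shift| <= maxs, by FFT
# cross-correlation; returns list(shift = c(dx, dy), cc = peak value)
best_shift <- function(img, ref, maxs) {
  d <- dim(img)
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(img)),
                      inverse = TRUE)) / length(img)
  sx <- c(0:maxs, (d[1] - maxs):(d[1] - 1))
  sy <- c(0:maxs, (d[2] - maxs):(d[2] - 1))
  sub <- cc[sx + 1, sy + 1]
  ij <- arrayInd(which.max(sub), dim(sub))
  dx <- sx[ij[1]]; dy <- sy[ij[2]]
  if (dx > d[1] / 2) dx <- dx - d[1]
  if (dy > d[2] / 2) dy <- dy - d[2]
  list(shift = c(dx, dy), cc = max(sub))
}

# translate a matrix by integer (dx, dy), zero-filling uncovered borders
shift_image <- function(img, dx, dy) {
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  out[which(okx), which(oky)] <- img[xs[okx], ys[oky]]
  out
}

#' Reference-free translational 2D classification
#'
#' Multivariate-statistics-based reference-free scheme: particles are
#' projected on principal components and split into k initial classes by
#' k-means; each iteration then (1) aligns every particle to its class
#' average by the integer-pixel cross-correlation peak (search range
#' +/- box/4), (2) reassigns it to the best-correlating class, and (3)
#' recomputes the class averages from the shifted particles. Alignment is
#' translational only - no rotation - so angular features of the particles
#' (such as linker directions) are conserved in the averages. An emptied
#' class is reseeded from the worst-fitting particle. Fully reproducible
#' under the seed.
#'
#' @param stack A [box_particles()] stack.
#' @param k Number of classes (default 3).
#' @param iterations Number of alignment iterations (default 8).
#' @param seed Integer seed.
#' @param max_shift Maximum shift in pixels (default box/4).
#' @return Object of class `class_set`: `averages` (list of k normalised
#'   images), `assignment`, `shifts` (n x 2), `cc` (final correlation per
#'   particle), `trace` (assignment matrix, iterations x n), `k`,
#'   `iterations`, `class_size`.
#' @export
classify_particles <- function(stack, k = 3, iterations = 8, seed = 1L,
                               max_shift = NULL) {
  stopifnot(inherits(stack, "particle_stack"))
  imgs <- stack$images
  n <- dim(imgs)[3]
  if (n < k) stop("need at least k particles")
  if (is.null(max_shift)) max_shift <- floor(stack$box_px / 4)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  X <- t(apply(imgs, 3, as.numeric))
  npc <- min(10, n - 1)
  pc <- stats::prcomp(X, rank. = npc)
  assign_now <- if (k == 1) rep(1L, n) else {
    as.integer(stats::kmeans(pc$x, centers = k, nstart = 5,
                             iter.max = 50)$cluster)
  }
  shifts <- matrix(0L, n, 2)
  ccs <- numeric(n)
  trace <- matrix(NA_integer_, iterations, n)
  class_avg <- function(assign, shifts) {
    lapply(seq_len(k), function(j) {
      rows <- which(assign == j)
      if (!length(rows)) return(NULL)
      acc <- matrix(0, dim(imgs)[1], dim(imgs)[2])
      for (r in rows)
        acc <- acc + shift_image(imgs[, , r], shifts[r, 1], shifts[r, 2])
      acc <- acc / length(rows)
      s <- stats::sd(acc)
      if (s > 0) (acc - mean(acc)) / s else acc
    })
  }
  avgs <- class_avg(assign_now, shifts)
  for (it in seq_len(iterations)) {
    for (i in seq_len(n)) {
      best <- NULL
      for (j in seq_len(k)) {
        if (is.null(avgs[[j]])) next
        bs <- best_shift(imgs[, , i], avgs[[j]], max_shift)
        if (is.null(best) || bs$cc > best$cc)
          best <- list(cc = bs$cc, j = j, shift = bs$shift)
      }
      assign_now[i] <- best$j
      shifts[i, ] <- best$shift
      ccs[i] <- best$cc
    }
    # reseed empty classes from the worst-fitting particle
    for (j in seq_len(k)) {
      if (!any(assign_now == j)) {
        worst <- which.min(ccs)
        assign_now[worst] <- j
        shifts[worst, ] <- c(0L, 0L)
      }
    }
    avgs <- class_avg(assign_now, shifts)
    trace[it, ] <- assign_now
  }
  structure(list(averages = avgs, assignment = assign_now, shifts = shifts,
                 cc = ccs, trace = trace, k = k, iterations = iterations,
                 class_size = tabulate(assign_now, k),
                 pixel_size = stack$pixel_size, box_px = stack$box_px),
            class = "class_set")
}

#' @export
print.class_set <- function(x, ...) {
  cat(sprintf("class_set: k = %d, %d iterations, class sizes [%s]\n",
              x$k, x$iterations, paste(x$class_size, collapse = ", ")))
  invisible(x)
}

#' @export
plot.class_set <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$k), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(x$k)) {
    a <- x$averages[[j]]
    graphics::image(a, col = grDevices::gray.colors(64), axes = FALSE,
                    main = sprintf("class %d (n=%d)", j, x$class_size[j]))
  }
  invisible(x)
}

#' Measure linker directions on a class average
#'
#' Computes the mean angular intensity profile on an annulus between the
#' granule edge and half the lattice spacing, and reports profile peaks as
#' linker directions. The principal linker angle is the angle between the
#' two strongest non-antipodal directions; antipodal partners (within
#' `antipode_tol` of 180 degrees) are reported through `opposite_angle`.
#'
#' @param avg Class-average image (matrix); the central granule's intensity
#'   maximum must lie within 2 px of the image centre.
#' @param granule_radius_px Granule radius in pixels (annulus inner edge).
#' @param spacing_px Lattice spacing in pixels (annulus outer edge =
#'   spacing/2).
#' @param prominence Minimum relative peak height above the profile minimum,
#'   as a fraction of the profile range (default 0.35).
#' @param antipode_tol Tolerance (degrees) for calling two directions
#'   antipodal (default 20).
#' @return Object of class `linker_angles`: `directions` (degrees, sorted
#'   by strength), `heights`, `pairwise` (angle matrix), `principal_angle`,
#'   `opposite_angle`.
#' @export
measure_linker_angles <- function(avg, granule_radius_px, spacing_px,
                                  prominence = 0.35, antipode_tol = 20) {
  d <- dim(avg)
  ctr <- (d + 1) / 2
  pk <- arrayInd(which.max(avg), d)
  if (any(abs(pk - ctr) > 2))
    stop("class average has no central granule (maximum off-centre)")
  r0 <- granule_radius_px
  r1 <- spacing_px / 2
  if (r1 <= r0) stop("annulus is empty: spacing/2 must exceed the radius")
  radii <- seq(r0, r1, by = 0.5)
  th <- seq(0, 359, by = 1)
  # lower-quartile over radii: a linker ridge spans the whole annulus while
  # caps of granules in adjacent lattice planes intrude only at its outer
  # edge, so the low quantile keeps ridges and suppresses cap bleed-through
  prof <- vapply(th, function(a) {
    xs <- ctr[1] + radii * cos(deg2rad(a))
    ys <- ctr[2] + radii * sin(deg2rad(a))
    stats::quantile(bilinear(avg, xs, ys), 0.25, names = FALSE)
  }, numeric(1))
  rg <- range(prof)
  # a featureless annulus (isotropic disc) has only pixelisation ripple:
  # require meaningful angular contrast relative to the image's own range
  if (diff(rg) < 0.1 * diff(range(avg))) return(empty_linkers())
  norm <- (prof - rg[1]) / diff(rg)
  nth <- length(th)
  nb_prev <- c(nth, seq_len(nth - 1)); nb_next <- c(2:nth, 1)
  is_peak <- norm >= norm[nb_prev] & norm >= norm[nb_next] &
    norm >= prominence
  if (!any(is_peak)) return(empty_linkers())
  # merge plateau/nearby peaks within 10 degrees, keep the strongest
  cand <- th[is_peak]; h <- norm[is_peak]
  o <- order(-h)
  dirs <- numeric(); hts <- numeric()
  for (i in o) {
    if (!length(dirs) ||
        all(pmin(abs(cand[i] - dirs) %% 360,
                 360 - abs(cand[i] - dirs) %% 360) > 10)) {
      dirs <- c(dirs, cand[i]); hts <- c(hts, h[i])
    }
  }
  pair <- outer(dirs, dirs, function(a, b) {
    x <- abs(a - b) %% 360; pmin(x, 360 - x)
  })
  principal <- NA_real_; opposite <- NA_real_
  if (length(dirs) >= 2) {
    sep <- pair[1, -1]
    anti <- abs(sep - 180) <= antipode_tol
    if (any(anti)) opposite <- sep[anti][1]
    if (any(!anti)) principal <- sep[!anti][1]
  }
  structure(list(directions = dirs, heights = hts, pairwise = pair,
                 principal_angle = principal, opposite_angle = opposite,
                 profile = prof),
            class = "linker_angles")
}

empty_linkers <- function() {
  structure(list(directions = numeric(), heights = numeric(),
                 pairwise = matrix(numeric(), 0, 0),
                 principal_angle = NA_real_, opposite_angle = NA_real_,
                 profile = NULL),
            class = "linker_angles")
}

#' @export
print.linker_angles <- function(x, ...) {
  if (!length(x$directions)) {
    cat("linker_angles: no linker directions detected\n")
    return(invisible(x))
  }
  cat("linker directions (deg):",
      paste(sprintf("%.0f", x$directions), collapse = ", "), "\n")
  cat(sprintf("  principal angle %.1f deg, opposite %.1f deg\n",
              x$principal_angle, x$opposite_angle))
  invisible(x)
}

# bilinear interpolation of a matrix at fractional indices (vectors)
bilinear <- function(img, x, y) {
  d <- dim(img)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
}
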