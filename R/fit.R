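#' Fit a Bravais lattice to a granule point cloud
#'
#' The main estimator of the package: infers the unit cell (parameters,
#' centering, class label) of the crystalline arrangement underlying a set
#' of granule centres. The procedure pools neighbour displacement vectors,
#' clusters them into lattice-translation candidates, selects a primitive
#' basis, reduces it to the shortest translations, and conventionalises it
#' into a classified cell (see [conventionalize_and_classify()]). Point sets
#' whose neighbour vectors cannot be indexed by any lattice (random clouds,
#' 2D sheets) are rejected; hexagonal close-packed stacks - which are not
#' Bravais lattices - are recognised as a layering motif and labelled
#' `HCP_layering`.
#'
#' Granules with incomplete neighbour shells (edge granules, fewer than half
#' the median neighbour count) do not vote in the basis clustering but do
#' receive residuals.
#'
#' @param points n x 3 matrix of granule centres (nm), or a `granule_set`.
#' @param cutoff_factor Neighbour cutoff as multiple of the modal nearest-
#'   neighbour distance (default 1.6).
#' @param cluster_angle_tol,cluster_len_tol Clustering tolerances
#'   (15 degrees, 20%).
#' @param tol_angle,tol_len Symmetry-detection tolerances (1 degree, 2%),
#'   matching the reported experimental uncertainties.
#' @return Object of class `lattice_fit` with components `label`, `cell`,
#'   `centering`, `conv_basis`, `primitive_basis`, `param_sd`, `residuals`,
#'   `n_points`, `modal_nn`, `dev`, `candidates`.
#' @examples
#' pts <- build_lattice_points(unit_cell(27.9, 27.9, 33,
#'                             centering = "body_centered"),
#'                             box = c(170, 170, 170))
#' fit <- fit_lattice(pts)
#' coef(fit)
#' @export
fit_lattice <- function(points, cutoff_factor = 1.6,
                        cluster_angle_tol = 15, cluster_len_tol = 0.2,
                        tol_angle = 1, tol_len = 0.02) {
  if (inherits(points, "granule_set")) points <- points$centers
  p <- as.matrix(points)
  if (nrow(p) < 20)
    warning("fewer than 20 points; lattice inference may be unreliable")
  field <- neighbor_vectors(p, cutoff_factor)
  # edge granules (incomplete shells) are excluded from basis voting
  interior <- field$neighbor_count >= stats::median(field$neighbor_count) / 2
  vote <- field
  keep <- interior[field$idx[, 1]] & interior[field$idx[, 2]]
  vote$idx <- field$idx[keep, , drop = FALSE]
  vote$vec <- field$vec[keep, , drop = FALSE]
  clusters <- cluster_neighbor_vectors(vote, cluster_angle_tol,
                                       cluster_len_tol)
  hcp <- detect_hcp_layering(p, field, clusters)
  basis <- tryCatch(infer_primitive_basis(vote, clusters),
                    error = function(e) e)
  if (inherits(basis, "error")) {
    if (!is.null(hcp)) return(hcp_fit(p, field, hcp))
    stop(basis)
  }
  red <- niggli_reduce(basis)
  cls <- conventionalize_and_classify(red, tol_angle, tol_len)
  res <- lattice_residuals(p, red)
  if (stats::median(res) > 0.15 * field$modal_nn) {
    if (!is.null(hcp)) return(hcp_fit(p, field, hcp))
    cls$label <- "unclassified"
  }
  sds <- param_uncertainty(cls$conv_basis, field)
  structure(list(label = cls$label, cell = cls$cell,
                 centering = cls$centering, conv_basis = cls$conv_basis,
                 primitive_basis = red, param_sd = sds,
                 residuals = res, n_points = nrow(p),
                 modal_nn = field$modal_nn, dev = cls$dev,
                 candidates = cls$candidates,
                 clusters = clusters, call = match.call()),
            class = "lattice_fit")
}

# distance of every point to the nearest lattice site (lattice anchored at
# the point closest to the cloud centroid)
lattice_residuals <- function(p, basis) {
  anchor <- p[which.min(rowSums(sweep(p, 2, colMeans(p))^2)), ]
  f <- solve(basis, t(p) - anchor)
  d <- basis %*% (f - round(f))
  sqrt(colSums(d^2))
}

# sd of realised edge lengths and angles, from raw neighbour vectors matched
# to the conventional cell edges (the experimental +/- values are read as
# this kind of spread)
param_uncertainty <- function(M, field, angle_match = 10, len_match = 0.15) {
  edges <- lapply(1:3, function(i) M[, i])
  match_rows <- function(e) {
    le <- sqrt(sum(e^2))
    lv <- sqrt(rowSums(field$vec^2))
    co <- abs(as.numeric(field$vec %*% e)) / (lv * le)
    which(co >= cos(deg2rad(angle_match)) & abs(lv - le) / le <= len_match)
  }
  rows <- lapply(edges, match_rows)
  len_sd <- vapply(rows, function(r)
    if (length(r) >= 3) stats::sd(sqrt(rowSums(field$vec[r, , drop = FALSE]^2)))
    else NA_real_, numeric(1))
  ang_sd <- matrix(NA_real_, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    # realised angles at granules holding both edge vectors
    gi <- granule_edge_vectors(field, rows[[i]], edges[[i]])
    gj <- granule_edge_vectors(field, rows[[j]], edges[[j]])
    common <- intersect(names(gi), names(gj))
    if (length(common) >= 3) {
      angs <- vapply(common, function(g) {
        u <- gi[[g]]; v <- gj[[g]]
        rad2deg(acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))))
      }, numeric(1))
      ang_sd[i, j] <- ang_sd[j, i] <- stats::sd(angs)
    }
  }
  list(length_sd = len_sd, angle_sd = c(alpha = ang_sd[2, 3],
                                        beta = ang_sd[1, 3],
                                        gamma = ang_sd[1, 2]))
}

# per-granule representative vector near a given edge direction (sign-
# corrected); names are granule indices
granule_edge_vectors <- function(field, rows, e) {
  if (!length(rows)) return(list())
  out <- list()
  for (r in rows) {
    v <- field$vec[r, ]
    s <- if (sum(v * e) >= 0) 1 else -1
    g1 <- as.character(field$idx[r, 1])
    g2 <- as.character(field$idx[r, 2])
    if (is.null(out[[g1]])) out[[g1]] <- s * v
    if (is.null(out[[g2]])) out[[g2]] <- s * v
  }
  out
}

# --- HCP layering detection -------------------------------------------------
# An ABAB close-packed stack is not a Bravais lattice; it is recognised by
# (i) a hexagonal in-plane net (two equal shortest translations at 60
# degrees), (ii) equally spaced layers along the net normal with spacing
# h = c/2, and (iii) a two-layer registry period (layers i and i+2 aligned,
# adjacent layers offset by a non-lattice in-plane shift).
detect_hcp_layering <- function(p, field, clusters, len_tol = 0.05,
                                ang_tol = 4) {
  C <- clusters$centroids
  if (nrow(C) < 2) return(NULL)
  os <- order(clusters$length)[seq_len(min(5, nrow(C)))]
  found <- NULL
  for (ii in seq_len(length(os) - 1)) {
    for (jj in (ii + 1):length(os)) {
      i <- os[ii]; j <- os[jj]
      li <- clusters$length[i]; lj <- clusters$length[j]
      if (abs(li - lj) / mean(c(li, lj)) > len_tol) next
      cosij <- sum(C[i, ] * C[j, ]) / (li * lj)
      afold <- rad2deg(acos(min(1, abs(cosij))))
      if (abs(afold - 60) > ang_tol) next
      found <- c(i, j); break
    }
    if (!is.null(found)) break
  }
  if (is.null(found)) return(NULL)
  u <- C[found[1], ]; v <- C[found[2], ]
  n <- cross3(u, v); n <- n / sqrt(sum(n^2))
  tproj <- as.numeric(p %*% n)
  gaps <- diff(sort(tproj))
  big <- gaps[gaps > 0.2 * field$modal_nn]
  if (length(big) < 3) return(NULL)
  h <- stats::median(big)
  if (stats::sd(big) / h > 0.1) return(NULL)
  layer <- round((tproj - min(tproj)) / h)
  if (max(abs(tproj - min(tproj) - layer * h)) > 0.15 * h) return(NULL)
  # two-layer registry: fractional in-plane offsets repeat with period 2
  E2 <- cbind(u, v)
  G <- solve(crossprod(E2), t(E2)) # 2x3 projector to (u, v) fractional
  fr <- t(G %*% t(p))
  phase <- function(L) {
    f <- fr[layer == L, , drop = FALSE] %% 1
    c(Arg(mean(exp(2i * pi * f[, 1]))), Arg(mean(exp(2i * pi * f[, 2])))) /
      (2 * pi)
  }
  Ls <- sort(unique(layer))
  if (length(Ls) < 4) return(NULL)
  ph <- t(vapply(Ls, phase, numeric(2)))
  circ <- function(a, b) { d <- (a - b) %% 1; pmin(d, 1 - d) }
  same2 <- max(circ(ph[-(1:2), ], ph[seq_len(nrow(ph) - 2), ]))
  adj <- max(circ(ph[-1, ], ph[-nrow(ph), ]))
  if (same2 < 0.1 && adj > 0.2) {
    list(a = mean(c(sqrt(sum(u^2)), sqrt(sum(v^2)))), c = 2 * h, axis = n)
  } else NULL
}

hcp_fit <- function(p, field, hcp) {
  cell <- unit_cell(hcp$a, hcp$a, hcp$c, gamma = 120)
  structure(list(label = "HCP_layering", cell = cell,
                 centering = "primitive",
                 conv_basis = NULL, primitive_basis = NULL,
                 param_sd = list(length_sd = rep(NA_real_, 3),
                                 angle_sd = rep(NA_real_, 3)),
                 residuals = NULL, n_points = nrow(p),
                 modal_nn = field$modal_nn, dev = NA_real_,
                 candidates = "HCP_layering", clusters = NULL,
                 call = sys.call(-1)),
            class = "lattice_fit")
}

# --- S3 methods -------------------------------------------------------------

#' @export
print.lattice_fit <- function(x, ...) {
  cat(sprintf("lattice_fit: %s (%d points)\n", x$label, x$n_points))
  print(x$cell)
  if (!is.null(x$residuals))
    cat(sprintf("  median residual %.3g nm\n", stats::median(x$residuals)))
  invisible(x)
}

#' @export
summary.lattice_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Lattice fit over %d granule centres\n", x$n_points))
  cat(sprintf("  class label : %s\n", x$label))
  cat(sprintf("  centering   : %s\n", x$centering))
  co <- coef(x)
  sd <- x$param_sd
  cat(sprintf("  a = %.2f +/- %.2f  b = %.2f +/- %.2f  c = %.2f +/- %.2f nm\n",
              co["a"], sd$length_sd[1], co["b"], sd$length_sd[2],
              co["c"], sd$length_sd[3]))
  cat(sprintf("  alpha = %.2f  beta = %.2f  gamma = %.2f deg\n",
              co["alpha"], co["beta"], co["gamma"]))
  if (!is.null(x$residuals))
    cat(sprintf("  residuals: median %.3g nm, max %.3g nm\n",
                stats::median(x$residuals), max(x$residuals)))
  if (length(x$candidates) > 1)
    cat("  candidate labels:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.lattice_fit <- function(object, ...) {
  cl <- object$cell
  c(a = cl$a, b = cl$b, c = cl$c,
    alpha = cl$alpha, beta = cl$beta, gamma = cl$gamma)
}

#' @export
residuals.lattice_fit <- function(object, ...) object$residuals

#' Predict nearest lattice sites for new points
#'
#' @param object A `lattice_fit`.
#' @param newdata n x 3 matrix of positions (nm).
#' @param ... Unused.
#' @return Data frame with the snapped lattice site and the residual
#'   distance for each input point.
#' @export
predict.lattice_fit <- function(object, newdata, ...) {
  if (is.null(object$primitive_basis))
    stop("no lattice basis available for this fit")
  p <- as.matrix(newdata)
  B <- object$primitive_basis
  f <- solve(B, t(p))
  site <- t(B %*% round(f))
  res <- sqrt(rowSums((p - site)^2))
  data.frame(x = site[, 1], y = site[, 2], z = site[, 3], residual = res)
}

#' Simulate point sets from a fitted lattice
#'
#' @param object A `lattice_fit`.
#' @param nsim Number of point sets.
#' @param seed Optional seed.
#' @param box Box extents (nm), default 6 cells per side.
#' @param jitter_sigma Gaussian jitter sd (nm); default the fit's median
#'   residual (0 if residuals are unavailable).
#' @param ... Unused.
#' @return List of point matrices.
#' @export
simulate.lattice_fit <- function(object, nsim = 1, seed = NULL,
                                 box = NULL,
                                 jitter_sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cl <- object$cell
  if (is.null(box)) box <- 6 * c(cl$a, cl$b, cl$c)
  if (is.null(jitter_sigma))
    jitter_sigma <- if (is.null(object$residuals)) 0
                    else stats::median(object$residuals)
  lapply(seq_len(nsim), function(i) {
    p <- build_lattice_points(cl, box)
    if (jitter_sigma > 0)
      p <- p + matrix(stats::rnorm(length(p), 0, jitter_sigma), nrow(p), 3)
    p
  })
}

#' Plot a lattice fit
#'
#' Projections of the point cloud on the three coordinate planes, coloured
#' by lattice residual.
#'
#' @param x A `lattice_fit`.
#' @param points The point cloud the fit was computed from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lattice_fit <- function(x, points, ...) {
  p <- as.matrix(points)
  res <- if (is.null(x$residuals)) rep(0, nrow(p)) else x$residuals
  cols <- grDevices::hcl.colors(32, "viridis")[
    1 + round(31 * res / max(res, 1e-9))]
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ax in list(c(1, 2), c(1, 3), c(2, 3))) {
    graphics::plot(p[, ax[1]], p[, ax[2]], col = cols, pch = 16, asp = 1,
                   xlab = c("x", "y", "z")[ax[1]],
                   ylab = c("x", "y", "z")[ax[2]],
                   main = sprintf("%s fit", x$label), ...)
  }
  invisible(x)
}
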