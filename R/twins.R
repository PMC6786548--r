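# --- cyclic twin analysis: domains, boundaries, wedge angles ---

#' Estimate the twin common axis from pooled neighbour vectors
#'
#' In a cyclic twin every domain shares one lattice direction (the rotation
#' axis), while in-plane directions differ between domains. The axis is
#' found as the pooled translation cluster supported by the largest fraction
#' of granules across the whole assembly.
#'
#' @param field A [neighbor_vectors()] result.
#' @param clusters Optional precomputed clustering.
#' @return Unit 3-vector.
#' @export
estimate_common_axis <- function(field, clusters = NULL) {
  if (is.null(clusters)) clusters <- cluster_neighbor_vectors(field)
  C <- clusters$centroids
  score <- numeric(nrow(C))
  for (j in seq_len(nrow(C))) {
    rows <- which(clusters$member == j)
    gr <- unique(c(field$idx[rows, 1], field$idx[rows, 2]))
    score[j] <- length(gr) / field$n_points
  }
  ax <- C[which.max(score), ]
  ax <- ax / sqrt(sum(ax^2))
  if (ax[3] < 0 || (ax[3] == 0 && ax[1] < 0)) ax <- -ax
  ax
}

#' Per-granule lattice row orientation
#'
#' For every granule, the azimuth (about the common axis) of its in-plane
#' neighbour vectors, reduced modulo the in-plane rotational symmetry of the
#' local lattice (90 degrees for a tetragonal net, 180 for triclinic). Only
#' the strongest in-plane direction cluster of each granule votes; granules
#' with fewer than 3 neighbours are marked undetermined (`NA`).
#'
#' @param points n x 3 matrix (nm).
#' @param field Optional precomputed [neighbor_vectors()] (cutoff 1.3
#'   recommended for contact shells).
#' @param axis Common axis; `NULL` = estimate via [estimate_common_axis()].
#' @param symmetry_fold In-plane rotational symmetry order (4 for a square
#'   net, 2 for an oblique net); orientations live in
#'   [0, 360/symmetry_fold).
#' @param inplane_tol Max out-of-plane angle (degrees) for a neighbour
#'   vector to count as in-plane (default 20).
#' @return Object of class `orientation_field`: list with `theta`
#'   (degrees, `NA` = undetermined), `axis`, `fold`, `field`.
#' @export
local_orientation_field <- function(points, field = NULL, axis = NULL,
                                    symmetry_fold = 4, inplane_tol = 20) {
  p <- as.matrix(points)
  if (is.null(field)) field <- neighbor_vectors(p, cutoff_factor = 1.3)
  if (is.null(axis)) axis <- estimate_common_axis(field)
  axis <- axis / sqrt(sum(axis^2))
  E <- plane_basis(axis)
  m <- 360 / symmetry_fold
  v <- field$vec
  lv <- sqrt(rowSums(v^2))
  out_of_plane <- rad2deg(asin(pmin(1, abs(as.numeric(v %*% axis)) / lv)))
  az <- rad2deg(atan2(as.numeric(v %*% E[, 2]), as.numeric(v %*% E[, 1])))
  inpl <- out_of_plane <= inplane_tol
  theta <- rep(NA_real_, nrow(p))
  # per granule: gather in-plane azimuths (both pair directions give the
  # same value mod 180, hence mod m for even folds)
  gi <- c(field$idx[inpl, 1], field$idx[inpl, 2])
  ga <- c(az[inpl], az[inpl] + 180) %% m
  gl <- c(lv[inpl], lv[inpl])
  ord <- order(gi)
  gi <- gi[ord]; ga <- ga[ord]; gl <- gl[ord]
  starts <- c(1, which(diff(gi) > 0) + 1, length(gi) + 1)
  for (s in seq_len(length(starts) - 1)) {
    rows <- starts[s]:(starts[s + 1] - 1)
    g <- gi[rows[1]]
    if (field$neighbor_count[g] < 3) next
    a <- ga[rows]; l <- gl[rows]
    # cluster azimuths mod m with 10-degree tolerance; strongest cluster
    # (most members, then shortest mean length) defines the row direction
    th <- strongest_azimuth(a, l, m)
    theta[g] <- th
  }
  structure(list(theta = theta, axis = axis, fold = symmetry_fold,
                 modulus = m, field = field),
            class = "orientation_field")
}

# Circular clustering of azimuths in [0, m) with fixed tolerance; returns
# the circular mean of the winning cluster. Clusters within one member of
# the largest compete by shortest mean vector length, so that a granule
# missing one neighbour of its densest row (box edge, vacancy) still votes
# for the same row direction as its complete-shell neighbours.
strongest_azimuth <- function(a, l, m, tol = 10) {
  k <- length(a)
  used <- rep(FALSE, k)
  cands <- list()
  circ <- function(x, y) { d <- abs(x - y) %% m; pmin(d, m - d) }
  for (i in seq_len(k)) {
    if (used[i]) next
    memb <- which(circ(a, a[i]) <= tol)
    used[memb] <- TRUE
    cands[[length(cands) + 1L]] <-
      list(n = length(memb), meanlen = mean(l[memb]), rows = memb)
  }
  ns <- vapply(cands, `[[`, numeric(1), "n")
  tied <- which(ns == max(ns))
  best <- cands[[tied[which.min(vapply(cands[tied], `[[`, numeric(1),
                                       "meanlen"))]]]
  z <- mean(exp(2i * pi * a[best$rows] / m))
  (Arg(z) / (2 * pi) * m) %% m
}

#' Segment granules into crystalline domains
#'
#' Graph clustering on the granule contact graph: neighbour pairs whose
#' orientations differ by less than `tolerance_deg` (circularly, modulo the
#' symmetry modulus) are joined; connected components become domains. Small
#' domains (< `min_domain` granules) are absorbed into the adjacent domain
#' they share the most contacts with.
#'
#' @param orientations A [local_orientation_field()] result.
#' @param tolerance_deg Orientation merge tolerance in degrees (default 5).
#' @param min_domain Minimum standalone domain size (default 10; the
#'   effective threshold grows as 4% of the assembly so boundary strips are
#'   always absorbed).
#' @return Integer domain label per granule (labels ordered by decreasing
#'   domain size; undetermined granules inherit the majority label of their
#'   neighbours).
#' @export
segment_domains <- function(orientations, tolerance_deg = 5,
                            min_domain = 10) {
  stopifnot(inherits(orientations, "orientation_field"))
  th <- orientations$theta
  m <- orientations$modulus
  field <- orientations$field
  n <- length(th)
  if (all(is.na(th))) stop("all granules have undetermined orientation")
  # smoothing pass: each granule adopts the circular mean of the densest
  # orientation cluster among itself and its contact neighbours; this keeps
  # single-linkage components from percolating across boundaries through
  # occasional noisy orientations
  i1_ <- field$idx[, 1]; i2_ <- field$idx[, 2]
  adj <- split(c(i2_, i1_), factor(c(i1_, i2_), levels = seq_len(n)))
  th_s <- th
  for (g in seq_len(n)) {
    v <- th[c(g, adj[[g]])]
    v <- v[!is.na(v)]
    if (length(v) >= 2)
      th_s[g] <- strongest_azimuth(v, rep(1, length(v)), m, tol = 6)
  }
  th <- th_s
  # union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  circ <- function(x, y) { d <- abs(x - y) %% m; pmin(d, m - d) }
  i1 <- field$idx[, 1]; i2 <- field$idx[, 2]
  okpair <- !is.na(th[i1]) & !is.na(th[i2]) &
    circ(th[i1], th[i2]) < tolerance_deg
  for (r in which(okpair)) union(i1[r], i2[r])
  lab <- vapply(seq_len(n), find, integer(1))
  # undetermined granules: majority label among contacts
  und <- which(is.na(th))
  for (g in und) {
    nb <- c(i2[i1 == g], i1[i2 == g])
    nb <- nb[!is.na(th[nb])]
    if (length(nb)) lab[g] <- names(which.max(table(lab[nb])))
  }
  lab <- as.integer(factor(lab))
  # absorb small domains into their best-connected neighbour domain; the
  # threshold scales mildly with assembly size so that thin boundary strips
  # of cross-oriented granules never stand as domains of their own
  thr <- max(min_domain, ceiling(0.04 * n))
  repeat {
    sizes <- table(lab)
    small <- as.integer(names(sizes)[sizes < thr])
    if (!length(small)) break
    changed <- FALSE
    for (s in small) {
      memb <- which(lab == s)
      nb <- c(i2[i1 %in% memb], i1[i2 %in% memb])
      nb_lab <- lab[nb]
      nb_lab <- nb_lab[nb_lab != s]
      if (!length(nb_lab)) next
      lab[memb] <- as.integer(names(which.max(table(nb_lab))))
      changed <- TRUE
    }
    if (!changed) break
  }
  # relabel by decreasing size
  o <- order(-table(lab)[as.character(sort(unique(lab)))])
  as.integer(factor(lab, levels = sort(unique(lab))[o]))
}

#' Fit twin boundary planes and the common axis
#'
#' For every adjacent domain pair, fits a plane by total least squares to the
#' midpoints of cross-boundary contact pairs (pairs within 1.3x the modal
#' spacing). The common axis is the direction most nearly contained in all
#' boundary planes (smallest eigenvector of the count-weighted outer-product
#' sum of the boundary normals).
#'
#' @param points n x 3 matrix (nm).
#' @param labels Integer domain label per granule.
#' @param field Optional precomputed contact [neighbor_vectors()].
#' @param min_pairs Minimum cross pairs for a plane fit (default 6).
#' @return List with `boundaries` (list of `domains`, `point`, `normal`,
#'   `n_pairs`, `rms`) and `common_axis`.
#' @export
boundary_planes_and_axis <- function(points, labels, field = NULL,
                                     min_pairs = 6) {
  p <- as.matrix(points)
  if (length(unique(labels)) < 2) stop("need at least 2 domains")
  if (is.null(field)) field <- neighbor_vectors(p, cutoff_factor = 1.3)
  i1 <- field$idx[, 1]; i2 <- field$idx[, 2]
  cross_rows <- which(labels[i1] != labels[i2])
  key <- paste(pmin(labels[i1[cross_rows]], labels[i2[cross_rows]]),
               pmax(labels[i1[cross_rows]], labels[i2[cross_rows]]), sep = "-")
  boundaries <- list()
  for (kk in unique(key)) {
    rows <- cross_rows[key == kk]
    mid <- (p[i1[rows], , drop = FALSE] + p[i2[rows], , drop = FALSE]) / 2
    dom <- as.integer(strsplit(kk, "-")[[1]])
    if (nrow(mid) < min_pairs) {
      boundaries[[length(boundaries) + 1L]] <-
        list(domains = dom, point = colMeans(mid), normal = NULL,
             n_pairs = nrow(mid), rms = NA_real_)
      next
    }
    # total-least-squares plane with trimming of stray midpoints: a twin
    # boundary can only generate midpoints within about half a spacing of
    # the plane, so the trim combines a robust MAD criterion with that
    # physical cap (cross pairs touching a mislabelled granule land farther
    # out and would otherwise thicken the fit)
    keep <- rep(TRUE, nrow(mid))
    for (pass in 1:4) {
      ctr <- colMeans(mid[keep, , drop = FALSE])
      S <- crossprod(sweep(mid[keep, , drop = FALSE], 2, ctr))
      ev <- eigen(S, symmetric = TRUE)
      nrm <- ev$vectors[, 3]
      perp <- as.numeric(sweep(mid, 2, ctr) %*% nrm)
      md <- stats::mad(perp[keep])
      if (!is.finite(md) || md <= 0 || sum(keep) <= 6) break
      lim <- min(3.5 * md, 0.6 * field$modal_nn)
      keep2 <- keep & abs(perp) <= lim
      if (sum(keep2) < 3 || sum(keep2) == sum(keep)) break
      keep <- keep2
    }
    rms <- sqrt(mean(as.numeric(
      sweep(mid[keep, , drop = FALSE], 2, ctr) %*% nrm)^2))
    boundaries[[length(boundaries) + 1L]] <-
      list(domains = dom, point = ctr, normal = nrm,
           n_pairs = nrow(mid), rms = rms,
           midpoints = mid[keep, , drop = FALSE])
  }
  fitted <- Filter(function(b) !is.null(b$normal), boundaries)
  if (length(fitted) < 2)
    return(list(boundaries = boundaries, common_axis = NULL))
  S <- Reduce(`+`, lapply(fitted, function(b)
    b$n_pairs * tcrossprod(b$normal)))
  ax <- eigen(S, symmetric = TRUE)$vectors[, 3]
  if (ax[3] < 0) ax <- -ax
  list(boundaries = boundaries, common_axis = ax)
}

#' Wedge angles between adjacent twin boundaries
#'
#' Boundary half-planes are ordered by azimuth about the common axis (the
#' in-plane trace of each boundary, directed from the axis towards the
#' boundary's midpoint centroid). Wedge angles are the consecutive azimuth
#' gaps; for a cyclic (full-circle) arrangement they sum to 360 degrees by
#' construction and the measured closure deficit is reported as
#' `360 - sum`. An open fan (gap larger than `open_gap` degrees) has an
#' undefined closure deficit and is flagged.
#'
#' @param boundaries Boundary list from [boundary_planes_and_axis()].
#' @param common_axis Unit axis vector.
#' @param anchor Point on the axis; default mean of boundary centroids.
#' @param open_gap Gap (degrees) beyond which the arrangement is treated as
#'   an open fan (default 150).
#' @param points,labels Optional granule centres and domain labels; when
#'   given, each boundary azimuth is refined to the maximum-margin split
#'   between the azimuth distributions of its two domains (radius-weighted
#'   hinge loss, robust to occasional mislabelled granules).
#' @return List with `wedge_angles` (ordered), `azimuths`, `order`
#'   (boundary indices in azimuthal order), `closure_deficit` (`NA` for an
#'   open fan), `cyclic`.
#' @export
wedge_angles <- function(boundaries, common_axis, anchor = NULL,
                         open_gap = 150, points = NULL, labels = NULL,
                         spacing = NULL, field = NULL) {
  fitted <- which(vapply(boundaries, function(b) !is.null(b$normal),
                         logical(1)))
  if (length(fitted) < 1) stop("no fitted boundary planes")
  ax <- common_axis / sqrt(sum(common_axis^2))
  E <- plane_basis(ax)
  # each boundary is a half-plane (ray) radiating from the common axis; its
  # azimuth is estimated from the cross-pair midpoints projected into the
  # plane perpendicular to the axis, with the apex (axis piercing point)
  # refined jointly: direction = radius^2-weighted circular mean (azimuth
  # precision grows with radius), apex = least-squares ray intersection;
  # outliers from occasional mislabelled granules are MAD-trimmed
  mids2 <- lapply(boundaries[fitted], function(b) b$midpoints %*% E)
  dirs <- vector("list", length(fitted))
  ctrs <- vector("list", length(fitted))
  for (bi in seq_along(fitted)) {
    m2 <- mids2[[bi]]
    keep <- rep(TRUE, nrow(m2))
    d <- c(1, 0); ctr <- colMeans(m2)
    # TLS line fit about the midpoint centroid (apex-independent), with
    # MAD trimming of stray midpoints from occasional mislabelled granules
    for (trim in 1:3) {
      ctr <- colMeans(m2[keep, , drop = FALSE])
      rel <- sweep(m2, 2, ctr)
      M <- crossprod(rel[keep, , drop = FALSE])
      d <- eigen(M, symmetric = TRUE)$vectors[, 1]
      lat <- rel[, 1] * (-d[2]) + rel[, 2] * d[1]
      md <- stats::mad(lat[keep])
      if (is.finite(md) && md > 0 && sum(keep) > 6) {
        keep2 <- keep & abs(lat) <= 3.5 * md
        if (sum(keep2) >= 3 && sum(keep2) < sum(keep)) keep <- keep2
        else break
      } else break
    }
    dirs[[bi]] <- d
    ctrs[[bi]] <- ctr
  }
  apex <- if (!is.null(anchor)) as.numeric(rbind(anchor) %*% E) else {
    # least-squares intersection of the boundary lines
    A <- matrix(0, 2, 2); bb <- c(0, 0)
    for (bi in seq_along(fitted)) {
      P <- diag(2) - tcrossprod(dirs[[bi]])
      w <- boundaries[[fitted[bi]]]$n_pairs
      A <- A + w * P
      bb <- bb + w * as.numeric(P %*% ctrs[[bi]])
    }
    tryCatch(as.numeric(solve(A, bb)),
             error = function(e) colMeans(do.call(rbind, ctrs)))
  }
  azs <- vapply(seq_along(fitted), function(bi) {
    d <- dirs[[bi]]
    # direct the ray from the apex towards the midpoint centroid
    if (sum(d * (ctrs[[bi]] - apex)) < 0) d <- -d
    rad2deg(atan2(d[2], d[1])) %% 360
  }, numeric(1))
  if (!is.null(points) && !is.null(labels)) {
    # joint refinement against the labelled granules themselves: (1) each
    # boundary line's offset along its normal is the maximum-margin split of
    # the two domains' projected positions (independent of the apex), (2)
    # the apex is the least-squares intersection of the refined lines, (3)
    # each boundary azimuth is the maximum-margin split of the two domains'
    # azimuths about the refined apex. Granules sitting exactly on a
    # boundary pin the split, so the estimate sharpens with size.
    P2 <- as.matrix(points) %*% E
    spacing <- if (is.null(spacing))
      modal_value(nn_spacing(as.matrix(points))) else spacing
    for (iter in 1:3) {
      offs <- numeric(length(fitted))
      okb <- logical(length(fitted))
      for (bi in seq_along(fitted)) {
        b <- boundaries[[fitted[bi]]]
        d <- dirs[[bi]]
        if (sum(d * (ctrs[[bi]] - apex)) < 0) { d <- -d; dirs[[bi]] <- d }
        nrm2 <- c(-d[2], d[1])
        proj <- as.numeric(P2 %*% nrm2)
        tpar <- as.numeric(sweep(P2, 2, apex) %*% d)
        c0 <- sum(nrm2 * apex)
        near <- abs(proj - c0) < 1.4 * spacing & tpar > -0.25 * spacing
        sA <- labels == b$domains[1] & near
        sB <- labels == b$domains[2] & near
        if (sum(sA) < 4 || sum(sB) < 4) { offs[bi] <- c0; next }
        if (stats::median(proj[sA]) > stats::median(proj[sB])) {
          tmp <- sA; sA <- sB; sB <- tmp
        }
        offs[bi] <- margin_split(proj[sA], proj[sB])
        okb[bi] <- TRUE
      }
      if (sum(okb) >= 2) {
        A <- matrix(0, 2, 2); bb <- c(0, 0)
        for (bi in which(okb)) {
          nrm2 <- c(-dirs[[bi]][2], dirs[[bi]][1])
          w <- boundaries[[fitted[bi]]]$n_pairs
          A <- A + w * tcrossprod(nrm2)
          bb <- bb + w * nrm2 * offs[bi]
        }
        apex <- tryCatch(as.numeric(solve(A, bb)), error = function(e) apex)
      }
      relg <- sweep(P2, 2, apex)
      azg <- rad2deg(atan2(relg[, 2], relg[, 1]))
      rg <- sqrt(rowSums(relg^2))
      for (bi in seq_along(fitted)) {
        b <- boundaries[[fitted[bi]]]
        phi0 <- rad2deg(atan2(dirs[[bi]][2], dirs[[bi]][1]))
        delta <- (azg - phi0 + 180) %% 360 - 180
        sA <- labels == b$domains[1] & abs(delta) < 25
        sB <- labels == b$domains[2] & abs(delta) < 25
        if (sum(sA) < 4 || sum(sB) < 4) next
        if (stats::median(delta[sA]) > stats::median(delta[sB])) {
          dA <- b$domains[2]; dB <- b$domains[1]
        } else {
          dA <- b$domains[1]; dB <- b$domains[2]
        }
        sA <- labels == dA & abs(delta) < 25 & rg > spacing
        sB <- labels == dB & abs(delta) < 25 & rg > spacing
        Pbelow <- P2[sA, , drop = FALSE]
        Pabove <- P2[sB, , drop = FALSE]
        # vacancy pinning: lattice sites of a domain that lie just beyond
        # the boundary are unoccupied, so each domain's unoccupied sites
        # bound the boundary from its far side
        if (!is.null(field)) {
          vacA <- vacancy_sites2d(points, labels, dA, field, E, apex, phi0,
                                  spacing)
          vacB <- vacancy_sites2d(points, labels, dB, field, E, apex, phi0,
                                  spacing)
          Pabove <- rbind(Pabove, vacA)
          Pbelow <- rbind(Pbelow, vacB)
        }
        if (nrow(Pbelow) < 4 || nrow(Pabove) < 4) next
        # scan the boundary angle about the apex; hinge loss in lateral nm
        psis <- seq(-3, 3, by = 0.05)
        hv <- vapply(psis, function(dpsi) {
          phi <- phi0 + dpsi
          nrm <- c(-sin(deg2rad(phi)), cos(deg2rad(phi)))
          c0 <- sum(nrm * apex)
          sum(pmax(0, as.numeric(Pbelow %*% nrm) - c0)) +
            sum(pmax(0, c0 - as.numeric(Pabove %*% nrm)))
        }, numeric(1))
        plateau <- which(hv <= min(hv) + 1e-9)
        phi <- phi0 + mean(range(psis[plateau]))
        dirs[[bi]] <- c(cos(deg2rad(phi)), sin(deg2rad(phi)))
      }
    }
    azs <- vapply(seq_along(fitted), function(bi) {
      d <- dirs[[bi]]
      if (sum(d * (ctrs[[bi]] - apex)) < 0) d <- -d
      rad2deg(atan2(d[2], d[1])) %% 360
    }, numeric(1))
  }
  o <- order(azs, vapply(boundaries[fitted], function(b) b$domains[1],
                         numeric(1)))
  az_sorted <- azs[o]
  if (length(az_sorted) == 1) {
    # single boundary plane: two half-spaces, two wedges of 180 degrees
    return(list(wedge_angles = c(180, 180), azimuths = az_sorted,
                order = fitted[o], closure_deficit = 0, cyclic = TRUE))
  }
  gaps <- diff(c(az_sorted, az_sorted[1] + 360))
  cyclic <- max(gaps) <= open_gap
  list(wedge_angles = as.numeric(gaps), azimuths = az_sorted,
       order = fitted[o],
       closure_deficit = if (cyclic) 360 - sum(gaps) else NA_real_,
       cyclic = cyclic)
}

# in-plane (2D, projected) positions of unoccupied lattice sites of domain
# `d` in the corridor around a boundary: sites predicted by the domain's own
# translation clusters that hold no granule of the domain but lie inside the
# assembly
vacancy_sites2d <- function(points, labels, d, field, E, apex, phi0,
                            spacing, window = 25) {
  P <- as.matrix(points)
  sub <- P[labels == d, , drop = FALSE]
  i1 <- field$idx[, 1]; i2 <- field$idx[, 2]
  inn <- labels[i1] == d & labels[i2] == d
  if (sum(inn) < 10) return(numeric())
  cl <- cluster_neighbor_vectors(list(vec = field$vec[inn, , drop = FALSE]))
  C <- rbind(cl$centroids, -cl$centroids)
  # corridor granules of the domain
  rel <- sweep(P %*% E, 2, apex)
  azg <- rad2deg(atan2(rel[, 2], rel[, 1]))
  delta <- (azg - phi0 + 180) %% 360 - 180
  gsel <- which(labels == d & abs(delta) < window)
  if (!length(gsel)) return(numeric())
  sites <- do.call(rbind, lapply(gsel, function(g)
    sweep(C, 2, P[g, ], "+")))
  # unoccupied by the domain, but interior to the assembly: an interior
  # vacant site keeps a near-full contact shell of granules (of any domain),
  # while sites beyond the assembly surface see only a partial shell
  D_dom <- cdist2(sites, sub)
  D_all <- cdist2(sites, P)
  dmin_dom <- apply(D_dom, 1, min)
  shell <- rowSums(D_all < 1.3 * spacing)
  keep <- dmin_dom > 0.35 * spacing & shell >= 9
  if (!any(keep)) return(matrix(numeric(), 0, 2))
  s2p <- sites[keep, , drop = FALSE] %*% E
  s2 <- sweep(s2p, 2, apex)
  r <- sqrt(rowSums(s2^2))
  azs <- rad2deg(atan2(s2[, 2], s2[, 1]))
  ds <- (azs - phi0 + 180) %% 360 - 180
  s2p[abs(ds) < window & r > 2 * spacing, , drop = FALSE]
}

# squared... no: plain Euclidean distance matrix, chunked for memory
cdist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- matrix(0, nrow(a), nrow(b))
  chunk <- 2000L
  bb2 <- rowSums(b^2)
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(nrow(a), s + chunk - 1L)
    d2 <- outer(rowSums(a[s:e, , drop = FALSE]^2), bb2, "+") -
      2 * a[s:e, , drop = FALSE] %*% t(b)
    out[s:e, ] <- sqrt(pmax(d2, 0))
  }
  out
}

# midpoint of the minimum-hinge interval separating `below` from `above`
# (1D): robust maximum-margin split point
margin_split <- function(below, above) {
  cand <- sort(c(below, above))
  fv <- vapply(cand, function(ph)
    sum(pmax(0, below - ph)) + sum(pmax(0, ph - above)), numeric(1))
  best <- which(fv <= min(fv) + 1e-9)
  mean(range(cand[best]))
}

#' Analyse the twin structure of a granule assembly
#'
#' Full chain: contact-shell neighbour vectors, common-axis estimate,
#' per-granule row orientations, domain segmentation, boundary-plane fits,
#' and wedge angles about the common axis.
#'
#' @param points n x 3 matrix of granule centres (nm), or a `granule_set`.
#' @param symmetry_fold In-plane symmetry order for orientation comparison
#'   (default 4, a square/tetragonal net).
#' @param tolerance_deg Orientation merge tolerance (default 5).
#' @param axis Optional known common axis (skips the estimate).
#' @param min_domain Minimum domain size (default 10).
#' @return Object of class `twin_partition`: `labels`, `boundaries`,
#'   `common_axis`, `wedge_angles`, `closure_deficit`, `cyclic`,
#'   `orientations`, `n_domains`.
#' @examples
#' tw <- build_twinned_assembly(twin_spec(), box = c(400, 400, 70))
#' fitted <- analyze_twins(tw$points)
#' fitted$wedge_angles
#' @export
analyze_twins <- function(points, symmetry_fold = 4, tolerance_deg = 5,
                          axis = NULL, min_domain = 10) {
  if (inherits(points, "granule_set")) points <- points$centers
  p <- as.matrix(points)
  field <- neighbor_vectors(p, cutoff_factor = 1.3)
  if (is.null(axis)) {
    # the shared lattice direction can be longer than the contact shell
    # (e.g. the BCT c axis); estimate the axis on a wider cutoff
    wide <- neighbor_vectors(p, cutoff_factor = 1.6)
    axis_est <- estimate_common_axis(wide)
  } else axis_est <- axis / sqrt(sum(axis^2))
  orient <- local_orientation_field(p, field = field, axis = axis_est,
                                    symmetry_fold = symmetry_fold)
  labels <- segment_domains(orient, tolerance_deg, min_domain)
  bp <- boundary_planes_and_axis(p, labels, field = field,
                                 min_pairs = max(6, round(0.02 * nrow(p))))
  # the pooled-cluster axis (shared lattice direction, averaged over every
  # granule) is far more precise than the boundary-normal eigen-axis; the
  # latter is kept as a diagnostic on the boundary fits
  ax <- if (!is.null(axis)) axis / sqrt(sum(axis^2)) else orient$axis
  wa <- if (!is.null(ax) && length(bp$boundaries))
    wedge_angles(bp$boundaries, ax, points = p, labels = labels,
                 spacing = field$modal_nn, field = field) else NULL
  structure(list(labels = labels, boundaries = bp$boundaries,
                 common_axis = ax,
                 wedge_angles = wa$wedge_angles,
                 boundary_order = wa$order,
                 closure_deficit = wa$closure_deficit,
                 cyclic = isTRUE(wa$cyclic),
                 orientations = orient,
                 n_domains = length(unique(labels))),
            class = "twin_partition")
}

#' @export
print.twin_partition <- function(x, ...) {
  cat(sprintf("twin_partition: %d domains over %d granules\n",
              x$n_domains, length(x$labels)))
  if (!is.null(x$wedge_angles)) {
    cat("  wedge angles:",
        paste(sprintf("%.1f", x$wedge_angles), collapse = ", "), "deg\n")
    cat(sprintf("  closure deficit: %.2f deg (%s)\n",
                x$closure_deficit, if (x$cyclic) "cyclic" else "open fan"))
  }
  if (!is.null(x$common_axis))
    cat(sprintf("  common axis: (%.3f, %.3f, %.3f)\n",
                x$common_axis[1], x$common_axis[2], x$common_axis[3]))
  invisible(x)
}

#' @export
plot.twin_partition <- function(x, points, ...) {
  p <- as.matrix(points)
  E <- if (!is.null(x$common_axis)) plane_basis(x$common_axis)
       else cbind(c(1, 0, 0), c(0, 1, 0))
  u <- p %*% E[, 1]; v <- p %*% E[, 2]
  graphics::plot(u, v, col = x$labels, pch = 16, asp = 1,
                 xlab = "in-plane u (nm)", ylab = "in-plane v (nm)",
                 main = sprintf("%d twin domains", x$n_domains), ...)
  invisible(x)
}
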