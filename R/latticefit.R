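# --- unit-cell inference from a granule point cloud ---
#
# The estimator works entirely in direct space: nearest-neighbour
# displacement vectors are pooled and clustered, the three shortest
# non-coplanar cluster centroids form a primitive basis candidate, the basis
# is reduced to the shortest lattice translations, and a small integer-
# combination search over the reduced basis finds the conventional cell and
# Bravais-class label.

#' Neighbour displacement vectors of a point cloud
#'
#' Collects all displacement vectors between point pairs closer than
#' `cutoff_factor` times the modal nearest-neighbour distance. Every pair
#' contributes the vector and its antipode (v and -v describe the same
#' lattice translation).
#'
#' @param points n x 3 matrix (nm).
#' @param cutoff_factor Cutoff as a multiple of the modal nearest-neighbour
#'   distance (default 1.6).
#' @return Object of class `neighbor_field`: list with `idx` (pair index
#'   matrix), `vec` (pair displacement p_j - p_i), `modal_nn`, `cutoff`,
#'   `n_points`, `neighbor_count` per point.
#' @export
neighbor_vectors <- function(points, cutoff_factor = 1.6) {
  p <- as.matrix(points)
  if (nrow(p) < 2) stop("need at least 2 points")
  nn <- nn_spacing(p)
  modal <- modal_value(nn)
  cutoff <- cutoff_factor * modal
  idx <- pairs_within(p, cutoff)
  if (!nrow(idx)) stop("no neighbour pairs within cutoff")
  vec <- p[idx[, 2], , drop = FALSE] - p[idx[, 1], , drop = FALSE]
  cnt <- tabulate(c(idx[, 1], idx[, 2]), nbins = nrow(p))
  structure(list(idx = idx, vec = vec, modal_nn = modal, cutoff = cutoff,
                 n_points = nrow(p), neighbor_count = cnt, points = p),
            class = "neighbor_field")
}

# mode of a continuous sample: densest 0.25-nm bin, refined by the median of
# values within 10% of the bin centre
modal_value <- function(x, bin = 0.25) {
  br <- seq(min(x) - bin, max(x) + bin, by = bin)
  h <- findInterval(x, br)
  tb <- tabulate(h)
  ctr <- br[which.max(tb)] + bin / 2
  stats::median(x[abs(x - ctr) <= 0.1 * ctr])
}

# all index pairs (i < j) within cutoff, brute force (chunked)
pairs_within <- function(p, cutoff) {
  n <- nrow(p)
  if (n <= 3000) {
    D <- as.matrix(stats::dist(p))
    idx <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
    colnames(idx) <- NULL
    return(idx[, c(1, 2), drop = FALSE])
  }
  out <- list(); oi <- 1L
  chunk <- 800L
  s2 <- rowSums(p^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(s2[s:e], s2, "+") - 2 * p[s:e, , drop = FALSE] %*% t(p)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    hit[, 1] <- hit[, 1] + s - 1L
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    out[[oi]] <- hit; oi <- oi + 1L
  }
  do.call(rbind, out)
}

#' Cluster neighbour vectors into lattice-translation candidates
#'
#' Greedy antipodally-aware clustering: vectors are processed in order of
#' increasing length and joined to a cluster when they lie within
#' `angle_tol` degrees (mod antipode) and within `len_tol` relative length
#' of its running centroid; one refinement pass recomputes centroids and
#' reassigns. Clusters smaller than 5% of the largest are dropped as noise.
#'
#' @param field A [neighbor_vectors()] result.
#' @param angle_tol Angular tolerance in degrees (default 15).
#' @param len_tol Relative length tolerance (default 0.2).
#' @return List with `centroids` (k x 3, one per antipodal translation
#'   class), `count`, `length`, and `member` (per-pair cluster id, 0 =
#'   dropped).
#' @export
cluster_neighbor_vectors <- function(field, angle_tol = 15, len_tol = 0.2) {
  v <- field$vec
  len <- sqrt(rowSums(v^2))
  o <- order(len)
  cent <- matrix(numeric(), 0, 3)
  csum <- matrix(numeric(), 0, 3)
  cnt <- integer()
  assign_pass <- function(cent_fixed = NULL) {
    member <- integer(nrow(v))
    sign_ <- integer(nrow(v))
    for (ii in o) {
      w <- v[ii, ]; lw <- len[ii]
      if (nrow(cent) > 0) {
        cl <- sqrt(rowSums(cent^2))
        dt <- as.numeric(cent %*% w)
        cosang <- abs(dt) / (cl * lw)
        okl <- abs(lw - cl) / cl <= len_tol
        oka <- cosang >= cos(deg2rad(angle_tol))
        cand <- which(okl & oka)
      } else cand <- integer()
      if (length(cand)) {
        j <- cand[which.max(abs(dt[cand]) / (cl[cand] * lw))]
        s <- if (dt[j] >= 0) 1L else -1L
        member[ii] <- j; sign_[ii] <- s
        if (is.null(cent_fixed)) {
          csum[j, ] <<- csum[j, ] + s * w
          cnt[j] <<- cnt[j] + 1L
          cent[j, ] <<- csum[j, ] / cnt[j]
        }
      } else if (is.null(cent_fixed)) {
        cent <<- rbind(cent, w); csum <<- rbind(csum, w)
        cnt <<- c(cnt, 1L)
        member[ii] <- nrow(cent); sign_[ii] <- 1L
      }
    }
    list(member = member, sign = sign_)
  }
  a1 <- assign_pass()
  # refinement pass against frozen centroids
  a2 <- assign_pass(cent_fixed = TRUE)
  member <- a2$member
  keepcl <- which(cnt >= max(3, 0.05 * max(cnt)))
  remap <- integer(length(cnt)); remap[keepcl] <- seq_along(keepcl)
  member <- ifelse(member > 0 & member %in% keepcl, remap[pmax(member, 1)], 0L)
  cent2 <- cent[keepcl, , drop = FALSE]
  # recompute centroids from final membership
  for (j in seq_along(keepcl)) {
    rows <- which(member == j)
    if (length(rows)) {
      s <- sign(v[rows, , drop = FALSE] %*% cent2[j, ])
      s[s == 0] <- 1
      cent2[j, ] <- colMeans(v[rows, , drop = FALSE] * as.numeric(s))
    }
  }
  list(centroids = cent2, count = as.integer(table(factor(member, levels = seq_along(keepcl)))),
       length = sqrt(rowSums(cent2^2)), member = member)
}

#' Infer a primitive lattice basis from clustered neighbour vectors
#'
#' Selects the three shortest pairwise non-coplanar cluster centroids whose
#' determinant exceeds a volume floor, and validates that the candidate basis
#' actually indexes the observed neighbour vectors (at least 60% of pair
#' vectors must map to near-integer combinations); otherwise no 3D lattice is
#' present.
#'
#' @param field A [neighbor_vectors()] result.
#' @param clusters Optional precomputed [cluster_neighbor_vectors()] result.
#' @param angle_floor Minimum pairwise angle (degrees) for basis candidates.
#' @param volume_floor Minimum |det| as a fraction of the modal nearest-
#'   neighbour distance cubed (default 0.1).
#' @return 3x3 matrix with the primitive basis vectors as columns (nm);
#'   attribute `"clusters"` carries the clustering.
#' @export
infer_primitive_basis <- function(field, clusters = NULL, angle_floor = 15,
                                  volume_floor = 0.1) {
  if (is.null(clusters)) clusters <- cluster_neighbor_vectors(field)
  C <- clusters$centroids
  if (nrow(C) < 3) stop("no 3D lattice: fewer than 3 translation clusters")
  o <- order(clusters$length)
  C <- C[o, , drop = FALSE]
  vfloor <- volume_floor * field$modal_nn^3
  k <- nrow(C)
  pick <- NULL
  for (i in 1:(k - 2)) {
    for (j in (i + 1):(k - 1)) {
      cosij <- abs(sum(C[i, ] * C[j, ])) /
        sqrt(sum(C[i, ]^2) * sum(C[j, ]^2))
      if (cosij > cos(deg2rad(angle_floor))) next
      for (l in (j + 1):k) {
        dt <- abs(det(cbind(C[i, ], C[j, ], C[l, ])))
        if (dt > vfloor) { pick <- c(i, j, l); break }
      }
      if (!is.null(pick)) break
    }
    if (!is.null(pick)) break
  }
  if (is.null(pick))
    stop("no 3D lattice: all translation clusters are (near-)coplanar")
  B <- t(C[pick, , drop = FALSE])
  # integer-consistency guard against non-lattice point sets
  f <- solve(B, t(field$vec))
  ok <- colSums(abs(f - round(f)) < 0.25) == 3
  if (mean(ok) < 0.6)
    stop("no 3D lattice: neighbour vectors are not integer combinations ",
         "of any candidate basis (", round(100 * mean(ok)), "% indexed)")
  attr(B, "clusters") <- clusters
  B
}

#' Reduce a lattice basis to the shortest three translations
#'
#' Searches integer combinations (coefficients in [-2, 2]) of the input
#' basis and greedily selects the shortest vector, the shortest non-collinear
#' vector, and the shortest non-coplanar vector. In three dimensions this
#' successive-minima construction always generates the same lattice
#' (the transformation to the input basis is unimodular, which is verified).
#' Columns are returned in increasing length with a consistent sign
#' convention (pairwise inner products all non-negative when the sign parity
#' allows, otherwise all non-positive).
#'
#' @param basis 3x3 matrix, columns = basis vectors.
#' @return Reduced 3x3 basis matrix.
#' @export
niggli_reduce <- function(basis) {
  B <- as.matrix(basis)
  if (abs(det(B)) < 1e-9) stop("singular basis")
  combos <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  combos <- combos[rowSums(abs(combos)) > 0, ]
  V <- combos %*% t(B) # rows are candidate vectors
  len <- sqrt(rowSums(V^2))
  o <- order(len, combos[, 1], combos[, 2], combos[, 3])
  V <- V[o, , drop = FALSE]; len <- len[o]
  v1 <- V[1, ]
  i2 <- which(sapply(seq_len(nrow(V)), function(i) {
    cr <- cross3(v1, V[i, ]); sqrt(sum(cr^2)) > 1e-9 * len[i] * len[1]
  }))[1]
  v2 <- V[i2, ]
  dts <- abs(apply(V, 1, function(w) det(cbind(v1, v2, w))))
  i3 <- which(dts > 1e-9 * len * len[1] * len[i2])[1]
  v3 <- V[i3, ]
  R <- cbind(v1, v2, v3, deparse.level = 0)
  Tm <- solve(B, R)
  if (max(abs(Tm - round(Tm))) > 1e-6 || abs(abs(det(round(Tm))) - 1) > 1e-6)
    stop("internal error: reduction is not unimodular")
  canonical_signs(R[, order(sqrt(colSums(R^2)))])
}

# Flip column signs so pairwise inner products are all >= 0 when the sign
# parity allows (an even number of negative dots), else all <= 0. Flipping
# one column toggles the sign of the two dots it participates in, so the
# parity of the negative count is invariant; dot i involves the two columns
# other than i, hence the column shared by offending dots i and j is 6-i-j.
canonical_signs <- function(B, tol = 1e-9) {
  dots <- function(B) c(sum(B[, 2] * B[, 3]), sum(B[, 1] * B[, 3]),
                        sum(B[, 1] * B[, 2]))
  target_pos <- sum(dots(B) < -tol) %% 2 == 0
  for (it in 1:4) {
    d <- dots(B)
    bad <- if (target_pos) which(d < -tol) else which(d > tol)
    if (length(bad) < 2) break
    col <- 6L - bad[1] - bad[2]
    B[, col] <- -B[, col]
  }
  B
}
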