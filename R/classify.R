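# --- conventional cell search and Bravais-class labelling ---

# deduplicated integer combinations of a basis, pruned by length
combo_vectors <- function(B, max_factor = 2.6) {
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  g <- g[rowSums(abs(g)) > 0, ]
  # keep one of each antipodal pair: first non-zero coefficient positive
  lead <- apply(g, 1, function(r) r[which(r != 0)[1]])
  g <- g[lead > 0, , drop = FALSE]
  W <- g %*% t(B)
  len <- sqrt(rowSums(W^2))
  keep <- len <= max_factor * max(sqrt(colSums(B^2)))
  list(W = W[keep, , drop = FALSE], len = len[keep])
}

cell_angles_abs <- function(M) {
  l <- sqrt(colSums(M^2))
  cosg <- c(sum(M[, 2] * M[, 3]) / (l[2] * l[3]),
            sum(M[, 1] * M[, 3]) / (l[1] * l[3]),
            sum(M[, 1] * M[, 2]) / (l[1] * l[2]))
  list(len = l, cos = cosg, angle_abs = rad2deg(acos(pmin(1, abs(cosg)))),
       nneg = sum(cosg < 0))
}

#' Conventional cell and Bravais-class label from a reduced basis
#'
#' Searches small integer combinations (coefficients in [-2, 2]) of the
#' reduced primitive basis for a conventional cell with at most two lattice
#' points that maximises metric symmetry. Recognised classes, in order of
#' precedence: simple cubic (`cubic_P`), face-centered cubic (`FCC`,
#' recognised by its rhombohedral 60-degree primitive cell), body-centered
#' tetragonal (`BCT`: a = b != c, right angles, and a lattice point at
#' (1/2, 1/2, 1/2) of the doubled cell), and a hexagonal close-packing
#' layering signature (`HCP_layering`). When no symmetric cell passes the
#' tolerances the lattice is reported as `triclinic_P` with a canonical
#' primitive cell: the shortest cell whose three angles are all acute
#' (all obtuse when the lattice admits no acute representative), with edges
#' ordered a >= b >= c. If the best two candidate labels are
#' indistinguishable within tolerance the label is `unclassified` and both
#' candidates are reported.
#'
#' @param reduced 3x3 reduced basis (columns), e.g. from [niggli_reduce()].
#' @param tol_angle Angular tolerance in degrees (default 1).
#' @param tol_len Relative length tolerance (default 0.02).
#' @return List with `label`, `cell` (a [unit_cell()]), `conv_basis`
#'   (columns = conventional cell vectors, lab frame), `dev` (worst
#'   constraint deviation as a fraction of tolerance), and `candidates`.
#' @export
conventionalize_and_classify <- function(reduced, tol_angle = 1,
                                         tol_len = 0.02) {
  B <- as.matrix(reduced)
  Vp <- abs(det(B))
  if (Vp < 1e-9) stop("singular reduced basis")
  cv <- combo_vectors(B)
  W <- cv$W; m <- nrow(W)
  cands <- list()
  for (i in 1:(m - 2)) {
    cri <- W[i, ]
    for (j in (i + 1):(m - 1)) {
      cr <- cross3(cri, W[j, ])
      if (sqrt(sum(cr^2)) < 1e-9) next
      dets <- abs(as.numeric(W[(j + 1):m, , drop = FALSE] %*% cr))
      hit <- which(abs(dets / Vp - 1) < 0.01 | abs(dets / Vp - 2) < 0.01)
      for (h in hit) {
        k <- j + h
        cands[[length(cands) + 1L]] <- c(i, j, k, round(dets[h] / Vp))
      }
    }
  }
  if (!length(cands)) stop("no candidate cells found")
  cands <- do.call(rbind, cands)

  best <- list()
  add_candidate <- function(label, rank, dev, M, cell, centering, npts) {
    best[[length(best) + 1L]] <<- list(label = label, rank = rank, dev = dev,
                                       M = M, cell = cell,
                                       centering = centering, npts = npts)
  }
  for (r in seq_len(nrow(cands))) {
    M <- t(W[cands[r, 1:3], , drop = FALSE])
    npts <- cands[r, 4]
    ca <- cell_angles_abs(M)
    l <- ca$len; aa <- ca$angle_abs
    spread <- (max(l) - min(l)) / mean(l)
    if (npts == 1) {
      # cubic_P
      dev <- max(abs(90 - aa) / tol_angle, spread / tol_len)
      if (dev <= 1)
        add_candidate("cubic_P", 5, dev, M,
                      unit_cell(mean(l)), "primitive", 1)
      # FCC primitive: equal edges, all 60 deg, acute-realisable
      if (ca$nneg %% 2 == 0) {
        dev <- max(abs(60 - aa) / tol_angle, spread / tol_len)
        if (dev <= 1)
          add_candidate("FCC", 4, dev, M,
                        unit_cell(mean(l) * sqrt(2)), "primitive", 1)
      }
      # hexagonal metric: two equal edges at 60/120, third orthogonal
      for (cc in 1:3) {
        ab <- setdiff(1:3, cc)
        devh <- max(abs(l[ab[1]] - l[ab[2]]) / mean(l[ab]) / tol_len,
                    abs(60 - aa[cc]) / tol_angle,      # angle between a and b
                    abs(90 - aa[ab]) / tol_angle)      # c against a and b
        if (devh <= 1) {
          coa <- l[cc] / mean(l[ab])
          if (abs(coa - sqrt(8 / 3)) < 0.08 * sqrt(8 / 3))
            add_candidate("HCP_layering", 2, devh, M,
                          unit_cell(mean(l[ab]), mean(l[ab]), l[cc],
                                    gamma = 120), "primitive", 1)
        }
      }
    } else if (npts == 2) {
      # BCT: right angles, a = b != c, interior point at (1/2,1/2,1/2)
      if (max(abs(90 - aa)) / tol_angle <= 1) {
        for (cc in 1:3) {
          ab <- setdiff(1:3, cc)
          pair_dev <- abs(l[ab[1]] - l[ab[2]]) / mean(l[ab]) / tol_len
          distinct <- abs(l[cc] - mean(l[ab])) / mean(l[ab]) > 2 * tol_len
          if (pair_dev <= 1 && distinct && has_body_center(M, B)) {
            dev <- max(abs(90 - aa) / tol_angle, pair_dev)
            Mo <- M[, c(ab, cc)]
            add_candidate("BCT", 3, dev, Mo,
                          unit_cell(mean(l[ab]), mean(l[ab]), l[cc],
                                    centering = "body_centered"),
                          "body_centered", 2)
            break
          }
        }
      }
    }
  }

  if (length(best)) {
    ranks <- vapply(best, `[[`, numeric(1), "rank")
    devs <- vapply(best, `[[`, numeric(1), "dev")
    o <- order(-ranks, devs)
    top <- best[[o[1]]]
    labs <- unique(vapply(best, `[[`, character(1), "label"))
    ambiguous <- length(labs) > 1 && top$dev > 0.85 &&
      any(devs[vapply(best, `[[`, character(1), "label") != top$label] <= 1)
    if (ambiguous) {
      return(list(label = "unclassified", cell = top$cell,
                  conv_basis = top$M, dev = top$dev,
                  centering = top$centering,
                  candidates = labs))
    }
    return(list(label = top$label, cell = top$cell, conv_basis = top$M,
                dev = top$dev, centering = top$centering,
                candidates = labs))
  }

  # triclinic fallback: canonical shortest all-acute primitive cell
  tri <- cands[cands[, 4] == 1, , drop = FALSE]
  pickM <- NULL; pick_score <- Inf; pick_parity <- NA
  for (r in seq_len(nrow(tri))) {
    M <- t(W[tri[r, 1:3], , drop = FALSE])
    ca <- cell_angles_abs(M)
    if (max(abs(ca$cos)) > cos(deg2rad(5))) next # degenerate-skew guard
    parity_even <- ca$nneg %% 2 == 0
    score <- sum(ca$len^2)
    better <- if (is.na(pick_parity)) TRUE
      else if (parity_even && !pick_parity) TRUE
      else if (parity_even == pick_parity && score < pick_score - 1e-9) TRUE
      else FALSE
    if (better) { pickM <- M; pick_score <- score; pick_parity <- parity_even }
  }
  if (is.null(pickM)) stop("no usable primitive cell found")
  Mc <- canonical_signs(pickM)
  o <- order(-sqrt(colSums(Mc^2)))
  Mc <- Mc[, o]
  cell <- params_from_basis(Mc, "primitive")
  list(label = "triclinic_P", cell = cell, conv_basis = Mc, dev = NA_real_,
       centering = "primitive", candidates = "triclinic_P")
}

# does the conventional cell M of the lattice generated by B contain a
# lattice point at fractional (1/2, 1/2, 1/2)?
has_body_center <- function(M, B) {
  Fm <- solve(M, B) # primitive generators in cell-fractional coords
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  fr <- g %*% t(Fm)
  fr <- fr - floor(fr + 1e-6)
  any(rowSums(abs(fr - 0.5) < 0.05) == 3)
}
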