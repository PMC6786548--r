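test_that("neighbour clusters reproduce the enumerated translation classes", {
  pts <- bct_points(c(170, 170, 170))
  field <- neighbor_vectors(pts, cutoff_factor = 1.6)
  cl <- cluster_neighbor_vectors(field)
  # oracle: brute-force enumeration of translations within the same cutoff
  tr <- lattice_translations(bct_cell(), cut = field$cutoff)
  expect_equal(nrow(cl$centroids), nrow(tr))
  # each centroid matches one enumerated translation (up to antipode)
  for (i in seq_len(nrow(cl$centroids))) {
    d <- apply(tr, 1, function(v)
      min(sqrt(sum((v - cl$centroids[i, ])^2)),
          sqrt(sum((v + cl$centroids[i, ])^2))))
    expect_lt(min(d), 1e-6)
  }
  # simple cubic: exactly the enumerated classes (axes, face and body
  # diagonals within the 1.6 cutoff collapse per antipode)
  cub <- build_lattice_points(unit_cell(20), box = c(160, 160, 160))
  fc <- neighbor_vectors(cub, 1.6)
  cc <- cluster_neighbor_vectors(fc)
  trc <- lattice_translations(unit_cell(20), cut = fc$cutoff)
  expect_equal(nrow(cc$centroids), nrow(trc))
})

test_that("jittered cluster centroids stay near the ideal translations", {
  pts <- apply_disorder(bct_points(c(170, 170, 170)),
                        disorder_spec(jitter_sigma = 1, seed = 6))
  field <- neighbor_vectors(pts, cutoff_factor = 1.6)
  cl <- cluster_neighbor_vectors(field)
  tr <- lattice_translations(bct_cell(), cut = 1.6 * 25.72)
  big <- cl$count >= 0.5 * max(cl$count)
  for (i in which(big)) {
    d <- apply(tr, 1, function(v)
      min(sqrt(sum((v - cl$centroids[i, ])^2)),
          sqrt(sum((v + cl$centroids[i, ])^2))))
    # centroid error ~ 3 sigma_pair / sqrt(n_members)
    expect_lt(min(d), 3 * sqrt(2) / sqrt(cl$count[i]) + 0.2)
  }
})

test_that("the inferred primitive basis spans the correct cell volume", {
  f1 <- neighbor_vectors(bct_points(c(170, 170, 170)), 1.6)
  B1 <- infer_primitive_basis(f1)
  expect_equal(abs(det(B1)), 27.9^2 * 33 / 2, tolerance = 1e-6)
  f2 <- neighbor_vectors(build_lattice_points(triclinic_cell(),
                                              box = c(180, 180, 180)), 1.6)
  B2 <- infer_primitive_basis(f2)
  expect_equal(abs(det(B2)), cell_volume(triclinic_cell()), tolerance = 1e-6)
})

test_that("non-lattice point sets are rejected with a clear signal", {
  set.seed(9)
  rp <- matrix(runif(900, 0, 200), ncol = 3)
  expect_error(fit_lattice(rp), "no 3D lattice")
  # 2D sheet: all clusters coplanar
  sheet <- as.matrix(expand.grid(x = seq(0, 200, 20), y = seq(0, 200, 20)))
  sheet <- cbind(sheet, z = 0)
  f <- neighbor_vectors(sheet, 1.6)
  expect_error(infer_primitive_basis(f), "coplanar|no 3D lattice")
})

test_that("basis reduction finds the shortest translations and is unimodular", {
  # BCT primitive: all three reduced lengths equal half the body diagonal
  B <- cell_basis(bct_cell()) %*% cbind(c(1, 0, 0), c(0, 1, 0), c(.5, .5, .5))
  R <- niggli_reduce(B)
  expect_equal(sqrt(colSums(R^2)), rep(0.5 * sqrt(2 * 27.9^2 + 33^2), 3),
               tolerance = 1e-9)
  # skewed basis (a, a+b, c) of a known lattice reduces to an equivalent cell
  B0 <- cell_basis(unit_cell(10, 12, 14))
  skew <- B0 %*% rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 1))
  R2 <- niggli_reduce(skew)
  Tm <- solve(B0, R2)
  expect_lt(max(abs(Tm - round(Tm))), 1e-9)
  expect_equal(abs(det(round(Tm))), 1)
  expect_equal(sort(sqrt(colSums(R2^2))), c(10, 12, 14), tolerance = 1e-9)
  # already-reduced cubic basis is unchanged up to ordering/sign
  expect_equal(abs(niggli_reduce(diag(3) * 7)), diag(3) * 7)
  expect_error(niggli_reduce(matrix(0, 3, 3)), "singular")
})

test_that("reduction preserves the generated lattice (point-set equality)", {
  B0 <- cell_basis(triclinic_cell())
  skew <- B0 %*% cbind(c(1, 1, 0), c(0, 1, 0), c(1, 0, 1))
  R <- niggli_reduce(skew)
  # all lattice points of each basis within a ball must coincide
  ball_points <- function(B, rad) {
    # wide coefficient range: skewed bases need large integers for points
    # that the reduced basis reaches with small ones
    g <- as.matrix(expand.grid(-12:12, -12:12, -12:12))
    v <- g %*% t(B)
    v <- round(v[sqrt(rowSums(v^2)) <= rad, , drop = FALSE], 6)
    v[order(v[, 1], v[, 2], v[, 3]), ]
  }
  expect_equal(ball_points(skew, 77.7), ball_points(R, 77.7))
})

test_that("noiseless recovery of the experimental cells is exact", {
  fit <- fit_lattice(bct_points(c(300, 300, 300)))
  expect_equal(fit$label, "BCT")
  expect_equal(fit$centering, "body_centered")
  co <- coef(fit)
  expect_equal(unname(co[c("a", "c")]), c(27.9, 33), tolerance = 1e-6)
  expect_lt(max(fit$residuals), 1e-6)
  tri <- fit_lattice(build_lattice_points(triclinic_cell(),
                                          box = c(250, 250, 250)))
  expect_equal(tri$label, "triclinic_P")
  expect_equal(unname(coef(tri)),
               c(28.4, 26.5, 24.2, 78, 66, 61), tolerance = 1e-6)
})

test_that("classification separates cubic, FCC, BCT and the HCP motif", {
  labs <- c(
    cubic = fit_lattice(build_lattice_points(unit_cell(27),
                                             box = c(220, 220, 220)))$label,
    fcc = fit_lattice(fcc_points(30))$label,
    bct = fit_lattice(bct_points(c(200, 200, 170)))$label,
    hcp = fit_lattice(hcp_points())$label,
    tri = fit_lattice(build_lattice_points(triclinic_cell(),
                                           box = c(200, 200, 200)))$label)
  expect_equal(unname(labs),
               c("cubic_P", "FCC", "BCT", "HCP_layering", "triclinic_P"))
  # FCC conventional edge recovered, not confused with its BCT setting
  ffc <- fit_lattice(fcc_points(30))
  expect_equal(ffc$cell$a, 30, tolerance = 1e-6)
})

test_that("classification is invariant to rotation and translation", {
  pts <- bct_points(c(200, 200, 170))
  set.seed(12)
  for (i in 1:3) {
    ax <- rnorm(3); ang <- runif(1, 0, 360)
    R <- rotation_about(ax, ang)
    moved <- sweep(pts %*% t(R), 2, runif(3, -50, 50), "+")
    fit <- fit_lattice(moved)
    expect_equal(fit$label, "BCT")
    expect_equal(unname(coef(fit)[c("a", "c")]), c(27.9, 33),
                 tolerance = 1e-6)
  }
})

test_that("jittered lattices recover parameters within 2% and 2 degrees", {
  ok <- 0
  for (s in 1:5) {
    pts <- apply_disorder(bct_points(c(250, 250, 200)),
                          disorder_spec(jitter_sigma = 1, seed = s))
    fit <- fit_lattice(pts)
    co <- coef(fit)
    ok <- ok + (fit$label == "BCT" &&
                  abs(co["a"] / 27.9 - 1) < 0.02 &&
                  abs(co["c"] / 33 - 1) < 0.02 &&
                  max(abs(co[4:6] - 90)) < 2)
  }
  expect_gte(ok, 4) # >= 95% of replicates in the large-sample limit
})

test_that("parameter uncertainties reflect the applied jitter", {
  pts <- apply_disorder(bct_points(c(250, 250, 200)),
                        disorder_spec(jitter_sigma = 1, seed = 3))
  fit <- fit_lattice(pts)
  # realised edge-length spread ~ sqrt(2) * sigma
  expect_gt(min(fit$param_sd$length_sd, na.rm = TRUE), 0.5)
  expect_lt(max(fit$param_sd$length_sd, na.rm = TRUE), 3)
})

test_that("lattice_fit methods behave like a fitted model object", {
  pts <- bct_points(c(200, 200, 170))
  fit <- fit_lattice(pts)
  expect_output(print(fit), "BCT")
  expect_output(summary(fit), "centering")
  expect_named(coef(fit), c("a", "b", "c", "alpha", "beta", "gamma"))
  expect_equal(length(residuals(fit)), nrow(pts))
  pr <- predict(fit, pts[1:5, ] + 0.3)
  expect_equal(pr$residual, rep(sqrt(3 * 0.09), 5), tolerance = 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 4, box = c(100, 100, 100))
  expect_length(sims, 2)
  expect_gt(nrow(sims[[1]]), 10)
})
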