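test_that("lattice point counts follow the cell density", {
  cub <- build_lattice_points(unit_cell(1), box = c(10, 10, 10))
  expect_equal(nrow(cub), 1000)
  expect_equal(min(dist(cub)), 1)
  # point count tracks box volume / primitive volume for large boxes
  pts <- bct_points(box = c(300, 300, 300))
  expected <- prod(c(300, 300, 300)) / (27.9^2 * 33 / 2)
  expect_lt(abs(nrow(pts) / expected - 1), 0.1)
  # minimum pairwise distance equals the closed-form shortest translation
  expect_equal(min(dist(bct_points(c(120, 120, 100)))),
               0.5 * sqrt(2 * 27.9^2 + 33^2), tolerance = 1e-12)
  expect_error(build_lattice_points(unit_cell(1), box = c(-1, 5, 5)))
})

test_that("neighbour shells match brute-force translation enumeration", {
  # three shortest distinct neighbour distances from the metric tensor
  for (cl in list(bct_cell(), triclinic_cell(), unit_cell(20))) {
    tr <- lattice_translations(cl, cut = 2.2 * max(cl$a, cl$b, cl$c))
    lens <- sort(unique(round(sqrt(rowSums(tr^2)), 6)))
    pts <- build_lattice_points(cl, box = 5 * c(cl$a, cl$b, cl$c))
    D <- dist(pts)
    dists <- sort(unique(round(D[D < 2.2 * max(cl$a, cl$b, cl$c)], 6)))
    expect_equal(dists[1:3], lens[1:3])
  }
})

test_that("twinned assemblies put every point in its labelled sector", {
  spec <- twin_spec()
  expect_equal(spec$closure_deficit, 1)
  expect_equal(sum(spec$effective_angles), 360)
  tw <- build_twinned_assembly(spec, box = c(400, 400, 70))
  E <- granulattice:::plane_basis(spec$common_axis)
  d <- sweep(tw$points, 2, c(400, 400, 70) / 2)
  az <- (atan2(d %*% E[, 2], d %*% E[, 1]) * 180 / pi) %% 360
  starts <- c(tw$sector_starts, 360)
  for (s in unique(tw$sector)) {
    a <- az[tw$sector == s]
    expect_true(all(a >= starts[s] - 1e-9 & a < starts[s + 1] + 1e-9))
  }
  # rescale closure policy inflates every wedge by 360/359
  spec2 <- twin_spec(closure = "rescale")
  expect_equal(spec2$effective_angles, c(76, 70, 71, 73, 69) * 360 / 359)
  expect_error(twin_spec(wedge_angles = c(-5, 100)), "positive")
  expect_error(twin_spec(wedge_angles = c(200, 200)), "360")
})

test_that("a single 360-degree sector degenerates to the plain lattice", {
  spec <- twin_spec(wedge_angles = c(180, 180), sector_rotations = c(0, 0),
                    cells = bct_cell())
  # both sectors share rotation 180 apart about z: with no extra rotation the
  # second sector is the same lattice rotated by its start azimuth; use the
  # two-sector case to check the boundary plane contains the axis
  tw <- build_twinned_assembly(spec, box = c(200, 200, 70))
  expect_setequal(unique(tw$sector), 1:2)
  full <- build_lattice_points(bct_cell(), c(200, 200, 70),
                               origin = c(100, 100, 35))
  # identical up to floating-point wobble of box-edge points under the
  # 180-degree sector rotation
  expect_lte(abs(nrow(tw$points) - nrow(full)), 1)
  D <- granulattice:::cdist2(tw$points, full)
  expect_lt(max(apply(D, 1, min)), 1e-5)
})

test_that("disorder is reproducible, vacancies binomial, jitter calibrated", {
  pts <- bct_points(c(200, 200, 100))
  ident <- apply_disorder(pts, disorder_spec())
  expect_equal(unname(ident[, 1:3]), unname(pts[, 1:3]))
  # same seed -> identical output
  d1 <- apply_disorder(pts, disorder_spec(jitter_sigma = 1, vacancy_prob = .1,
                                          seed = 11))
  d2 <- apply_disorder(pts, disorder_spec(jitter_sigma = 1, vacancy_prob = .1,
                                          seed = 11))
  expect_identical(d1, d2)
  # vacancy count inside the binomial 99.9% interval
  big <- build_lattice_points(unit_cell(10), box = c(130, 130, 120))
  n <- nrow(big)
  expect_gte(n, 2000)
  surv <- nrow(apply_disorder(big, disorder_spec(vacancy_prob = 0.1,
                                                 seed = 3)))
  expect_gte(surv, qbinom(5e-4, n, 0.9))
  expect_lte(surv, qbinom(1 - 5e-4, n, 0.9))
  # RMS displacement of sigma-jitter is sigma * sqrt(3)
  j <- apply_disorder(big, disorder_spec(jitter_sigma = 0.5, seed = 4))
  rms <- sqrt(mean(rowSums((j - big)^2)))
  expect_equal(rms, 0.5 * sqrt(3), tolerance = 0.05)
  # bending displaces along the configured axis only
  b <- apply_disorder(pts, disorder_spec(bend_amplitude = 3,
                                         bend_wavelength = 150, seed = 5))
  expect_equal(b[, 1], pts[, 1])
  expect_equal(b[, 2], pts[, 2])
  zdisp <- abs(b[, 3] - pts[, 3])
  expect_lte(max(zdisp), 3 + 1e-9) # bounded by the amplitude
  expect_gt(max(zdisp), 2.8)       # and the sampled sine nearly reaches it
})

test_that("rendered spheres have the nominal FWHM and render deterministically", {
  v <- render_volume(matrix(c(30, 30, 30), 1), voxel_size = 1.1,
                     granule_diameter = 20.1)
  ctr <- attr(v, "centers")[1, ]
  prof_r <- seq(0, 15, by = 0.1)
  prof <- granulattice:::trilinear(
    v, outer(prof_r, c(1, 0, 0)) + rep(ctr, each = length(prof_r)))
  half_cross <- prof_r[which(prof < max(prof) / 2)[1]]
  expect_equal(2 * half_cross, 20.1, tolerance = 1.1)
  expect_error(render_volume(matrix(c(5, 5, 5), 1), voxel_size = 12,
                             granule_diameter = 20), "unresolvable")
  # seeded noise renders are identical
  p2 <- matrix(c(20, 20, 20, 45, 20, 20), 2, byrow = TRUE)
  n1 <- render_volume(p2, noise_sigma = 0.2, seed = 7)
  n2 <- render_volume(p2, noise_sigma = 0.2, seed = 7)
  expect_identical(n1$data, n2$data)
})

test_that("linkers form a ridge between in-plane nearest neighbours", {
  p2 <- rbind(c(25, 25, 25), c(25 + 25.6, 25, 25))
  v <- render_volume(p2, granule_diameter = 20,
                     linker_planes = list(c(0, 0, 1)))
  mid <- colMeans(attr(v, "centers"))
  on_ridge <- granulattice:::trilinear(v, matrix(mid, 1))
  off_ridge <- granulattice:::trilinear(v, matrix(mid + c(0, 8, 0), 1))
  expect_gt(on_ridge, 0.5)
  expect_lt(off_ridge, on_ridge / 2)
  # intensity maxima stay at granule centres
  expect_gt(granulattice:::trilinear(v, attr(v, "centers"))[1], on_ridge)
})

test_that("missing-wedge filter zeroes the wedge and conserves the rest", {
  set.seed(2)
  v <- volume3d(array(rnorm(36 * 30 * 24), c(36, 30, 24)), 1.1)
  for (dual in c(TRUE, FALSE)) {
    vw <- apply_missing_wedge(v, tilt_range = 60, dual_axis = dual)
    m <- attr(vw, "wedge_mask")
    F0 <- fft(v$data); F1 <- fft(vw$data)
    expect_equal(sum(Mod(F1[m])^2), sum(Mod(F0[m])^2))
    expect_lt(max(Mod(F1[!m])), 1e-9)
  }
  # dual-axis mask keeps everything either single-axis mask keeps
  m1 <- attr(apply_missing_wedge(v, dual_axis = FALSE), "wedge_mask")
  md <- attr(apply_missing_wedge(v, dual_axis = TRUE), "wedge_mask")
  expect_true(all(md[m1]))
  expect_gt(sum(md), sum(m1))
})

test_that("slab projections sum the requested slab only", {
  pts <- bct_points(c(120, 120, 70))
  v <- render_volume(pts, granule_diameter = 20.1)
  # full-depth slab equals the complete z projection
  zfull <- dim(v$data)[3] * v$voxel_size
  full <- extract_slab_projection(v, c(0, 0, 1), anchor = c(0, 0, zfull / 2),
                                  thickness = zfull)
  expect_equal(unclass(full), apply(v$data, c(1, 2), sum),
               ignore_attr = TRUE)
  # slab far from all granules is near-uniform background
  vg <- render_volume(rbind(c(30, 30, 20), c(30, 30, 80)),
                      granule_diameter = 20, margin = 15)
  cz <- attr(vg, "centers")[, 3]
  empty <- extract_slab_projection(vg, c(0, 0, 1),
                                   anchor = c(0, 0, mean(cz)), thickness = 4)
  onlayer <- extract_slab_projection(vg, c(0, 0, 1),
                                     anchor = c(0, 0, cz[1]), thickness = 4)
  expect_lt(max(empty), 0.05 * max(onlayer))
  expect_error(extract_slab_projection(v, c(0, 0, 1),
                                       anchor = c(0, 0, 1e4), thickness = 5),
               "outside")
})
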