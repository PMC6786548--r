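test_that("noiseless renders are detected with unit recall and sub-voxel error", {
  pts <- bct_points(c(120, 120, 100))
  vol <- render_volume(pts, voxel_size = 1.1, granule_diameter = 20.1)
  truth <- attr(vol, "centers")
  g <- detect_granules(vol, expected_diameter = 20.1)
  D <- granulattice:::cdist2(g$centers, truth)
  expect_equal(mean(apply(D, 2, min) < 5), 1) # recall at 5 nm
  expect_equal(mean(apply(D, 1, min) < 5), 1) # precision at 5 nm
  rms <- sqrt(mean(apply(D, 1, min)^2))
  expect_lt(rms, 0.5 * vol$voxel_size)
})

test_that("detection stays reliable under jitter and noise (SNR 3)", {
  pts <- bct_points(c(120, 120, 100))
  pj <- apply_disorder(pts, disorder_spec(jitter_sigma = 1, seed = 2))
  vol <- render_volume(pj, granule_diameter = 20.1, noise_sigma = 1 / 3,
                       seed = 9)
  truth <- attr(vol, "centers")
  g <- detect_granules(vol, 20.1)
  D <- granulattice:::cdist2(g$centers, truth)
  expect_gte(mean(apply(D, 2, min) < 5), 0.98)
})

test_that("close pairs are suppressed and empty volumes yield empty sets", {
  v2 <- render_volume(rbind(c(30, 30, 30), c(30 + 0.6 * 16, 30, 30)),
                      granule_diameter = 20)
  g2 <- detect_granules(v2, 20, min_separation = 16)
  expect_equal(g2$n, 1)
  vu <- volume3d(array(0.5, c(40, 40, 40)), 1.1)
  expect_message(gu <- detect_granules(vu, 20), "no granules")
  expect_equal(gu$n, 0)
  expect_error(detect_granules(vu, 2), "3 voxels")
})

test_that("FWHM diameters reproduce generator values across sizes", {
  for (dia in c(15, 19, 20.1, 25)) {
    v <- render_volume(matrix(c(35, 35, 35), 1), voxel_size = 1.1,
                       granule_diameter = dia, margin = 30)
    m <- measure_diameter(v, attr(v, "centers")[1, ], dia)
    expect_lt(abs(m - dia), 1.1) # bias < 1 voxel
  }
  # hard-edged digital sphere of radius 5 voxels has FWHM 10 voxels
  arr <- array(0, c(31, 31, 31))
  for (i in 1:31) for (j in 1:31) for (k in 1:31)
    if ((i - 16)^2 + (j - 16)^2 + (k - 16)^2 <= 25) arr[i, j, k] <- 1
  vh <- volume3d(arr, 1)
  ctr <- c(15.5, 15.5, 15.5)
  expect_equal(measure_diameter(vh, ctr, 10), 10, tolerance = 1)
  # profile never crossing half maximum is flagged invalid
  flat <- volume3d(array(1, c(40, 40, 40)), 1)
  expect_true(is.na(measure_diameter(flat, c(20, 20, 20), 10)))
})

test_that("nn_spacing equals the brute-force all-pairs oracle", {
  set.seed(8)
  for (n in c(5, 60, 300)) {
    p <- matrix(runif(3 * n, 0, 100), n)
    D <- as.matrix(dist(p)); diag(D) <- Inf
    expect_equal(nn_spacing(p), unname(apply(D, 1, min)))
  }
  expect_equal(nn_spacing(rbind(c(0, 0, 0), c(10, 0, 0))), c(10, 10))
  expect_error(nn_spacing(matrix(1:3, 1)), "at least 2")
  # BCT assembly: all interior spacings equal the half body diagonal
  sp <- nn_spacing(bct_points(c(150, 150, 120)))
  expect_equal(unique(round(sp, 9)), round(0.5 * sqrt(2 * 27.9^2 + 33^2), 9))
})

test_that("triclinic modal spacing equals the shortest cell translation", {
  pts <- build_lattice_points(triclinic_cell(), box = c(180, 180, 180))
  sp <- nn_spacing(pts)
  # brute force over integer combinations |h|,|k|,|l| <= 2
  tr <- lattice_translations(triclinic_cell(), cut = 60, hmax = 2)
  shortest <- min(sqrt(rowSums(tr^2)))
  expect_equal(granulattice:::modal_value(sp), shortest, tolerance = 1e-9)
  expect_equal(shortest, 24.2) # the c edge is the shortest translation
})
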