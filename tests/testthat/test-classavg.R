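make_template <- function(n = 33) {
  img <- disc_image(n, radius = 7)
  img[seq(5, n - 4), (n + 1) / 2 + (-1:1)] <-
    pmax(img[seq(5, n - 4), (n + 1) / 2 + (-1:1)], 0.6)
  img
}

test_that("boxing crops, normalises, skips border picks, keeps duplicates", {
  img <- matrix(rnorm(120 * 100), 120, 100)
  picks <- rbind(c(40, 50), c(40, 50), c(3, 3), c(80, 60))
  expect_warning(st <- box_particles(img, picks, box_px = 21), "border")
  expect_equal(dim(st$images), c(21, 21, 3))
  expect_equal(st$images[, , 1], st$images[, , 2]) # duplicates kept
  for (i in 1:3) {
    expect_equal(mean(st$images[, , i]), 0, tolerance = 1e-12)
    expect_equal(sd(st$images[, , i]), 1, tolerance = 1e-12)
  }
  # pick at the centre of an isolated granule boxes a centred maximum
  v <- render_volume(matrix(c(30, 30, 30), 1), granule_diameter = 20)
  sl <- extract_slab_projection(v, c(0, 0, 1), thickness = 20)
  ctr <- attr(v, "centers")[1, 1:2]
  st2 <- box_particles(sl, rbind(ctr), box_px = 25, units = "nm")
  peak <- arrayInd(which.max(st2$images[, , 1]), c(25, 25))
  expect_lte(max(abs(peak - 13)), 1)
})

test_that("identical particles collapse to the template (k = 1)", {
  tpl <- make_template()
  stack <- structure(list(images = array(rep(tpl, 12), c(33, 33, 12)),
                          picks = matrix(0, 12, 2), box_px = 33,
                          pixel_size = 1),
                     class = "particle_stack")
  cs <- classify_particles(stack, k = 1, iterations = 4, seed = 1)
  avg <- cs$averages[[1]]
  expect_gt(cor(as.numeric(avg), as.numeric(tpl)), 0.999)
  expect_true(all(cs$shifts == 0))
})

test_that("alignment undoes known shifts and preserves content", {
  tpl <- make_template()
  shifts <- rbind(c(0, 0), c(3, -2), c(-4, 1), c(5, 5), c(-2, -3))
  imgs <- vapply(seq_len(nrow(shifts)), function(i)
    granulattice:::shift_image(tpl, shifts[i, 1], shifts[i, 2]),
    matrix(0, 33, 33))
  stack <- structure(list(images = imgs, picks = shifts, box_px = 33,
                          pixel_size = 1),
                     class = "particle_stack")
  cs <- classify_particles(stack, k = 1, iterations = 4, seed = 2)
  expect_gt(cor(as.numeric(cs$averages[[1]]), as.numeric(tpl)), 0.99)
  # the recovered shifts cancel the applied ones (up to a common offset)
  rel <- sweep(cs$shifts, 2, cs$shifts[1, ])
  expect_equal(unname(rel), unname(-shifts))
  # a pure shift preserves total intensity up to border truncation
  sh <- granulattice:::shift_image(tpl, 3, -2)
  expect_lte(sum(sh), sum(tpl))
  expect_gt(sum(sh), 0.8 * sum(tpl))
})

test_that("averaging n noisy copies raises SNR about sqrt(n)", {
  tpl <- make_template()
  tpl <- (tpl - mean(tpl)) / sd(tpl)
  n <- 64
  set.seed(5)
  noise_sd <- sqrt(2) # SNR 0.5 in variance terms
  imgs <- vapply(seq_len(n), function(i)
    tpl + matrix(rnorm(length(tpl), 0, noise_sd), nrow(tpl)),
    matrix(0, 33, 33))
  stack <- structure(list(images = imgs, picks = matrix(0, n, 2),
                          box_px = 33, pixel_size = 1),
                     class = "particle_stack")
  cs <- classify_particles(stack, k = 1, iterations = 3, seed = 3,
                           max_shift = 2)
  r_single <- cor(as.numeric(imgs[, , 1]), as.numeric(tpl))
  r_avg <- cor(as.numeric(cs$averages[[1]]), as.numeric(tpl))
  expect_gt(r_avg, r_single)
  snr <- function(r) r^2 / (1 - r^2)
  gain <- snr(r_avg) / snr(r_single)
  expect_gt(gain, 0.7 * n^0.5) # consistent with sqrt(n) within 30%
})

test_that("two distinct templates are classified apart (k = 2)", {
  t1 <- make_template()
  t2 <- disc_image(33, radius = 7)
  t2[(33 + 1) / 2 + (-1:1), seq(5, 29)] <-
    pmax(t2[(33 + 1) / 2 + (-1:1), seq(5, 29)], 0.6)
  set.seed(6)
  n <- 20
  truth <- rep(1:2, each = n / 2)
  imgs <- vapply(seq_len(n), function(i) {
    base <- if (truth[i] == 1) t1 else t2
    base + matrix(rnorm(length(base), 0, 0.3), nrow(base))
  }, matrix(0, 33, 33))
  stack <- structure(list(images = imgs, picks = matrix(0, n, 2),
                          box_px = 33, pixel_size = 1),
                     class = "particle_stack")
  cs <- classify_particles(stack, k = 2, iterations = 6, seed = 4)
  tab <- table(cs$assignment, truth)
  purity <- sum(apply(tab, 2, max)) / n
  expect_gte(purity, 0.95)
})

test_that("the classification trace is bit-reproducible under a seed", {
  tpl <- make_template()
  set.seed(7)
  imgs <- vapply(1:12, function(i)
    tpl + matrix(rnorm(length(tpl), 0, 0.5), nrow(tpl)),
    matrix(0, 33, 33))
  stack <- structure(list(images = imgs, picks = matrix(0, 12, 2),
                          box_px = 33, pixel_size = 1),
                     class = "particle_stack")
  a <- classify_particles(stack, k = 3, iterations = 8, seed = 11)
  b <- classify_particles(stack, k = 3, iterations = 8, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$averages, b$averages)
  expect_equal(nrow(a$trace), 8)
})

test_that("linker angles are read off class averages correctly", {
  # single ridge at 30 degrees
  la <- measure_linker_angles(ridge_image(30), granule_radius_px = 9,
                              spacing_px = 26)
  expect_equal(la$directions[1], 30, tolerance = 2)
  # isotropic disc: no directions
  expect_length(measure_linker_angles(disc_image(), 9, 26)$directions, 0)
  # off-centre maximum is rejected
  off <- disc_image()
  off[40:45, 40:45] <- 2
  expect_error(measure_linker_angles(off, 9, 26), "off-centre")
  expect_error(measure_linker_angles(disc_image(), 12, 20), "annulus")
})

test_that("square-net slab particles give 90/180-degree linker angles", {
  pts <- bct_points(c(170, 170, 70))
  vol <- render_volume(pts, granule_diameter = 20.1,
                       linker_planes = list(c(0, 0, 1)))
  centers <- attr(vol, "centers")
  zmid <- granulattice:::modal_value(centers[, 3], bin = 2)
  img <- extract_slab_projection(vol, c(0, 0, 1), anchor = c(0, 0, zmid),
                                 thickness = 20)
  layer <- centers[abs(centers[, 3] - zmid) < 5, , drop = FALSE]
  stack <- suppressWarnings(box_particles(img, layer[, 1:2], 45,
                                          units = "nm"))
  cs <- classify_particles(stack, k = 3, iterations = 8, seed = 42)
  avg <- cs$averages[[which.max(cs$class_size)]]
  la <- measure_linker_angles(avg, granule_radius_px = 20.1 / 2 / 1.1,
                              spacing_px = 27.9 / 1.1)
  expect_equal(la$principal_angle, 90, tolerance = 2)
  expect_equal(la$opposite_angle, 180, tolerance = 2)
  # angle conservation: translational alignment of shifted copies of one
  # particle keeps the measured angles
  one <- stack$images[, , 5]
  copies <- vapply(list(c(0, 0), c(3, 1), c(-2, 4), c(1, -3)), function(s)
    granulattice:::shift_image(one, s[1], s[2]), one)
  st2 <- structure(list(images = copies, picks = matrix(0, 4, 2),
                        box_px = 45, pixel_size = 1.1),
                   class = "particle_stack")
  cs2 <- classify_particles(st2, k = 1, iterations = 4, seed = 1)
  la2 <- measure_linker_angles(cs2$averages[[1]], 20.1 / 2 / 1.1,
                               27.9 / 1.1)
  expect_equal(la2$principal_angle, la$principal_angle, tolerance = 2)
})
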