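test_that("single-domain orientations are tight and give one label", {
  pts <- bct_points(c(200, 200, 100))
  orient <- local_orientation_field(pts, axis = c(0, 0, 1))
  th <- orient$theta[!is.na(orient$theta)]
  expect_gt(length(th), 0.9 * nrow(pts))
  spread <- max(abs(((th - th[1] + 45) %% 90) - 45))
  expect_lt(spread, 2)
  labs <- segment_domains(orient)
  expect_equal(length(unique(labs)), 1)
  # degenerate tolerance merges everything regardless of orientation
  tw <- build_twinned_assembly(twin_spec(), box = c(300, 300, 70))
  o2 <- local_orientation_field(tw$points, axis = c(0, 0, 1))
  expect_equal(length(unique(segment_domains(o2, tolerance_deg = 180))), 1)
})

test_that("two domains rotated 73 degrees give a bimodal orientation field", {
  spec <- twin_spec(wedge_angles = c(180, 180),
                    cells = unit_cell(28, 25, 26),
                    sector_rotations = c(0, 73 - 180))
  tw <- build_twinned_assembly(spec, box = c(300, 300, 70))
  # oblique net: compare orientations modulo 180 (fold 2)
  orient <- local_orientation_field(tw$points, axis = c(0, 0, 1),
                                    symmetry_fold = 2)
  th <- orient$theta[!is.na(orient$theta)]
  km <- kmeans(cbind(cos(2 * pi * th / 180), sin(2 * pi * th / 180)), 2,
               nstart = 5)
  mode_angle <- function(z) (Arg(complex(real = z[1], imaginary = z[2])) /
                               (2 * pi) * 180) %% 180
  m1 <- mode_angle(km$centers[1, ]); m2 <- mode_angle(km$centers[2, ])
  gap <- abs(m1 - m2) %% 180
  gap <- min(gap, 180 - gap)
  expect_equal(gap, 73, tolerance = 1.5)
})

test_that("jittered single-domain orientation spread stays below 3 degrees", {
  pts <- apply_disorder(bct_points(c(200, 200, 100)),
                        disorder_spec(jitter_sigma = 1, seed = 7))
  orient <- local_orientation_field(pts, axis = c(0, 0, 1))
  th <- orient$theta[!is.na(orient$theta)]
  z <- mean(exp(1i * 2 * pi * th / 90))
  centre <- (Arg(z) / (2 * pi) * 90) %% 90
  dev <- ((th - centre + 45) %% 90) - 45
  expect_lt(sd(dev), 3)
})

test_that("the five-sector twin is segmented into the generator sectors", {
  tw <- build_twinned_assembly(twin_spec(), box = c(600, 600, 85))
  fit <- analyze_twins(tw$points)
  expect_equal(fit$n_domains, 5)
  tab <- table(fit$labels, tw$sector)
  agreement <- sum(apply(tab, 2, max)) / length(tw$sector)
  expect_gte(agreement, 0.98)
  expect_equal(abs(sum(fit$common_axis * c(0, 0, 1))), 1, tolerance = 1e-3)
})

test_that("wedge angles of the five-fold twin are recovered within 1 degree", {
  tw <- build_twinned_assembly(twin_spec(), box = c(600, 600, 85))
  fit <- analyze_twins(tw$points)
  wedges <- sort(fit$wedge_angles)
  truth <- sort(twin_spec()$effective_angles) # 70 70 71 73 76
  expect_equal(wedges, truth, tolerance = 1)
  expect_equal(sum(fit$wedge_angles) + fit$closure_deficit, 360)
  expect_true(fit$cyclic)
  expect_equal(max(fit$wedge_angles), 76, tolerance = 1)
  expect_gte(min(fit$wedge_angles), 69 - 1)
})

test_that("two half-space domains give one boundary and 180-degree wedges", {
  spec <- twin_spec(wedge_angles = c(180, 180),
                    cells = unit_cell(28, 25, 26),
                    sector_rotations = c(0, 73 - 180))
  tw <- build_twinned_assembly(spec, box = c(300, 300, 70))
  orient <- local_orientation_field(tw$points, axis = c(0, 0, 1),
                                    symmetry_fold = 2)
  labs <- segment_domains(orient)
  expect_equal(length(unique(labs)), 2)
  bp <- boundary_planes_and_axis(tw$points, labs)
  fitted <- Filter(function(b) !is.null(b$normal), bp$boundaries)
  expect_equal(length(fitted), 1)
  # the boundary plane contains the twin axis
  expect_lt(abs(sum(fitted[[1]]$normal * c(0, 0, 1))), 0.05)
  wa <- wedge_angles(bp$boundaries, c(0, 0, 1))
  expect_equal(wa$wedge_angles, c(180, 180))
})

test_that("a regular five-fold twin yields five 72-degree wedges", {
  spec <- twin_spec(wedge_angles = rep(72, 5))
  expect_equal(spec$closure_deficit, 0)
  tw <- build_twinned_assembly(spec, box = c(500, 500, 70))
  fit <- analyze_twins(tw$points)
  expect_equal(fit$n_domains, 5)
  expect_equal(fit$wedge_angles, rep(72, 5), tolerance = 1)
})

test_that("wedge angles are preserved under global rotation", {
  tw <- build_twinned_assembly(twin_spec(), box = c(500, 500, 85))
  base <- sort(analyze_twins(tw$points)$wedge_angles)
  R <- rotation_about(c(1, -2, 3), 63.7)
  rot <- sort(analyze_twins(tw$points %*% t(R))$wedge_angles)
  expect_equal(rot, base, tolerance = 1)
})

test_that("boundary fits are tight on noiseless sectors", {
  tw <- build_twinned_assembly(twin_spec(), box = c(500, 500, 85))
  fit <- analyze_twins(tw$points)
  spacing <- granulattice:::modal_value(nn_spacing(tw$points))
  for (b in fit$boundaries) {
    if (!is.null(b$normal)) expect_lt(b$rms, 0.5 * spacing)
  }
})
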