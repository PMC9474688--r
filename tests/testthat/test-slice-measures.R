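lm_c <- construction_landmarks()
frame_c <- build_femoral_frame(lm_c)

test_that("axial cross-section of a cylinder recovers the analytic circle", {
  res <- 96L
  mesh <- cylinder_mesh(radius = 15, zmin = -40, zmax = 60, res = res)
  cs <- extract_cross_section(mesh, frame_c, lm_c, 10)
  ctr <- colMeans(cs$outer_contour)
  r <- sqrt(rowSums(sweep(cs$outer_contour, 2, ctr)^2))
  sagitta <- 15 * (1 - cos(pi / res))
  expect_lt(max(abs(r - 15)), sagitta + 1e-9)
  expect_gt(stemversion:::polygon_area(cs$outer_contour), 0)  # CCW
  expect_error(extract_cross_section(mesh, frame_c, lm_c, 1000), "plane misses")
})

test_that("cross-section area matches a pixel-count oracle within 1%", {
  fem <- generate_femur(femur_spec(nfa_deg = 30))
  fr <- build_femoral_frame(fem$landmarks)
  cs <- extract_cross_section(fem$mesh, fr, fem$landmarks, 10)
  a_poly <- stemversion:::polygon_area(cs$outer_contour)
  a_pix <- pixel_area(cs$outer_contour, h = 0.1)
  expect_lt(abs(a_poly - a_pix) / a_pix, 0.01)
})

test_that("cortex arcs on a circle are centered on the AP extremes", {
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  cs <- make_section(cbind(14 * cos(phi), 14 * sin(phi)))
  arcs <- classify_cortex_arcs(cs, reference = "ap")
  # ~80 deg of a 180-point circle per +/-40 deg window
  expect_equal(length(arcs$anterior_idx), 80 / 360 * 180, tolerance = 0.05)
  ca <- colMeans(arcs$anterior)
  cp <- colMeans(arcs$posterior)
  expect_gt(ca[2], 12); expect_lt(abs(ca[1]), 0.5)
  expect_lt(cp[2], -12); expect_lt(abs(cp[1]), 0.5)
})

test_that("cortex arcs on an axis-aligned rectangle are exactly the edges", {
  xs <- seq(-20, 20, by = 1)
  top <- cbind(xs, 8); right <- cbind(20, seq(7, -7, by = -1))
  bot <- cbind(rev(xs), -8); left <- cbind(-20, seq(-7, 7, by = 1))
  rect <- rbind(top, right, bot, left)
  cs <- make_section(rect)
  arcs <- classify_cortex_arcs(cs, reference = "ap")
  expect_true(all(arcs$anterior[, 2] == 8))
  expect_true(all(arcs$posterior[, 2] == -8))
  expect_gte(nrow(arcs$anterior), length(xs) - 2)
})

test_that("arc selection on a rotated ellipse matches a dense-sampling oracle", {
  th <- 30 * pi / 180
  t <- seq(0, 2 * pi, length.out = 721)[-721]
  pts <- cbind(18 * cos(t), 9 * sin(t)) %*%
    rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  cs <- make_section(pts)
  arcs <- classify_cortex_arcs(cs, reference = "ap")
  # oracle: filter dense points by the analytic outward normal angle
  nrm <- cbind(9 * cos(t), 18 * sin(t)) %*%
    rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  nang <- atan2(nrm[, 2], nrm[, 1]) * 180 / pi
  keep_a <- abs(((nang - 90 + 180) %% 360) - 180) <= 40
  expect_equal(colMeans(arcs$anterior), colMeans(pts[keep_a, ]), tolerance = 0.05)
  keep_p <- abs(((nang + 90 + 180) %% 360) - 180) <= 40
  expect_equal(colMeans(arcs$posterior), colMeans(pts[keep_p, ]), tolerance = 0.05)
})

test_that("total-least-squares cortex line behaves on exact, symmetric and noisy points", {
  x <- seq(-5, 5, by = 0.5)
  fit <- fit_cortex_line(cbind(x, 2 * x))
  expect_equal(fit$direction, c(1, 2) / sqrt(5), tolerance = 1e-12)
  d <- cbind(x, 2 * x) - rep(fit$point, each = length(x))
  expect_lt(max(abs(d[, 1] * fit$direction[2] - d[, 2] * fit$direction[1])), 1e-9)
  # paired +/- offsets perpendicular to the line leave the fit unchanged
  nrm <- c(-2, 1) / sqrt(5)
  base <- cbind(c(x, x), c(2 * x, 2 * x))
  off <- rbind(matrix(0.4 * nrm, length(x), 2, byrow = TRUE),
               matrix(-0.4 * nrm, length(x), 2, byrow = TRUE))
  fit2 <- fit_cortex_line(base + off)
  expect_equal(fit2$direction, fit$direction, tolerance = 1e-9)
  # seeded noise: direction within 1 degree of truth
  set.seed(5)
  xs <- runif(100, -15, 15)
  fit3 <- fit_cortex_line(cbind(xs, 0.3 * xs + rnorm(100, 0, 0.2)))
  ang <- atan2(fit3$direction[2], fit3$direction[1]) * 180 / pi
  expect_lt(abs(ang - atan2(0.3, 1) * 180 / pi), 1)
  # isotropic points are rejected
  tt <- seq(0, 2 * pi, length.out = 41)[-41]
  expect_error(fit_cortex_line(cbind(cos(tt), sin(tt))), "ill-conditioned")
})

test_that("midcortical line bisects the cortex lines", {
  mk <- function(deg) line2d(c(0, 0), c(cos(deg * pi / 180), sin(deg * pi / 180)))
  b <- midcortical_line(mk(10), mk(-10))
  expect_equal(stemversion:::line_angle_deg(b), 0, tolerance = 1e-12)
  same <- midcortical_line(mk(25), mk(25))
  expect_equal(stemversion:::line_angle_deg(same), 25, tolerance = 1e-12)
  b2 <- midcortical_line(line2d(c(0, 2), c(cos(25 * pi / 180), sin(25 * pi / 180))),
                         line2d(c(0, -2), c(cos(40 * pi / 180), sin(40 * pi / 180))))
  expect_equal(stemversion:::line_angle_deg(b2), 32.5, tolerance = 1e-9)
  expect_equal(b2$point, c(0, 0))
})

test_that("AM-CT recovers generator anteversion and is monotone", {
  f0 <- generate_femur(femur_spec(nfa_deg = 0))
  fr0 <- build_femoral_frame(f0$landmarks)
  expect_lt(abs(am_ct(f0$mesh, fr0, f0$landmarks, 10)$angle_deg), 1e-3)
  f30 <- generate_femur(femur_spec(nfa_deg = 30))
  fr30 <- build_femoral_frame(f30$landmarks)
  expect_lt(abs(am_ct(f30$mesh, fr30, f30$landmarks, 10)$angle_deg - 30), 3)
  f20 <- generate_femur(femur_spec(nfa_deg = 20))
  f40 <- generate_femur(femur_spec(nfa_deg = 40))
  a20 <- am_ct(f20$mesh, build_femoral_frame(f20$landmarks), f20$landmarks, 10)$angle_deg
  a40 <- am_ct(f40$mesh, build_femoral_frame(f40$landmarks), f40$landmarks, 10)$angle_deg
  expect_gt(a40, a20)
  expect_warning(am_ct(f30$mesh, fr30, f30$landmarks, 7), "unconventional")
})

test_that("AM-CT is invariant under uniform scaling and stable under refinement", {
  fem <- generate_femur(femur_spec(nfa_deg = 30))
  fr <- build_femoral_frame(fem$landmarks)
  a0 <- am_ct(fem$mesh, fr, fem$landmarks, 10)$angle_deg
  s <- 1.2
  mesh_s <- mesh_transform(fem$mesh, scale = s)
  lm_s <- stemversion:::landmarks_transform(fem$landmarks, scale = s)
  a_s <- am_ct(mesh_s, build_femoral_frame(lm_s), lm_s, 10)$angle_deg
  expect_equal(a_s, a0, tolerance = 1e-6)
  fem2 <- generate_femur(femur_spec(nfa_deg = 30, mesh_resolution = 144))
  a2 <- am_ct(fem2$mesh, build_femoral_frame(fem2$landmarks), fem2$landmarks, 10)$angle_deg
  expect_lt(abs(a2 - a0), 0.5)
})

test_that("stem anteversion round-trips through psa_from_stem", {
  fem <- generate_femur(femur_spec(nfa_deg = 20))
  fr <- build_femoral_frame(fem$landmarks)
  for (a in c(25, 0, -10)) {
    stem <- generate_stem(stem_spec(stem_anteversion_deg = a), fem)
    expect_equal(psa_from_stem(stem, fr, fem$landmarks)$angle_deg, a,
                 tolerance = 1e-9)
  }
  pca <- posterior_condylar_axis(fem$landmarks)
  stem_pca <- axis3d(c(0, 0, 0), pca$direction)
  expect_equal(psa_from_stem(stem_pca, fr, fem$landmarks)$angle_deg, 0)
})

test_that("image slicing recovers a voxelized cylinder radius within a voxel", {
  mesh <- cylinder_mesh(radius = 15, zmin = -5, zmax = 25, res = 96L, nz = 7L)
  img <- voxelize(mesh, spacing = c(0.5, 0.5, 0.5))
  cs <- slice_from_image(img, frame_c, lm_c, 10)
  ctr <- colMeans(cs$outer_contour)
  r <- sqrt(rowSums(sweep(cs$outer_contour, 2, ctr)^2))
  expect_lt(max(abs(r - 15)), 0.5)
  expect_lt(abs(mean(r) - 15), 0.5)
  img0 <- voxel_image(array(0, dim = c(20, 20, 20)), c(1, 1, 1),
                      lm_c$lesser_trochanter_apex + c(-10, -10, 0))
  expect_error(slice_from_image(img0, frame_c, lm_c, 10), "empty slice")
})

test_that("mesh slicing and image slicing agree on AM-CT within 2 degrees", {
  fem <- generate_femur(femur_spec(nfa_deg = 30))
  fr <- build_femoral_frame(fem$landmarks)
  a_mesh <- am_ct(fem$mesh, fr, fem$landmarks, 10)$angle_deg
  img <- voxelize(fem$mesh, spacing = c(0.98, 0.98, 1.0))
  cs_img <- slice_from_image(img, fr, fem$landmarks, 10)
  a_img <- am_ct(NULL, fr, fem$landmarks, 10, section = cs_img)$angle_deg
  expect_lt(abs(a_img - a_mesh), 2)
})
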