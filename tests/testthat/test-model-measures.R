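test_that("osteotomy plane contains its defining points and the AP direction", {
  fem <- generate_femur(femur_spec(nfa_deg = 25))
  fr <- build_femoral_frame(fem$landmarks)
  for (h in c(5, 10)) {
    pl <- build_osteotomy_plane(fem$mesh, fem$landmarks, fr, h)
    co <- pl$construction
    expect_lt(abs(sum((co$piriformis_center - pl$point) * pl$normal)), 1e-9)
    expect_lt(abs(sum((co$calcar_point - pl$point) * pl$normal)), 1e-9)
    expect_lt(abs(sum(pl$normal * fr$ap_axis)), 1e-9)
    expect_gt(sum(pl$normal * fr$si_axis), 0)
    expect_equal(stemversion:::vnorm(pl$normal), 1, tolerance = 1e-12)
  }
  p5 <- build_osteotomy_plane(fem$mesh, fem$landmarks, fr, 5)
  p10 <- build_osteotomy_plane(fem$mesh, fem$landmarks, fr, 10)
  d <- p10$construction$calcar_point - p5$construction$calcar_point
  expect_equal(sum(d * fr$si_axis), 5, tolerance = 1e-6)
})

test_that("a piriformis center directly proximal to the calcar gives an ML normal", {
  mesh <- cylinder_mesh(radius = 14, zmin = -30, zmax = 40, res = 64L)
  lm <- construction_landmarks()
  fr <- build_femoral_frame(lm)
  cs <- extract_cross_section(mesh, fr, lm, 10)
  i <- which.max(cs$outer_contour[, 1])
  calcar <- cs$plane_point + cs$outer_contour[i, 1] * fr$ml_axis +
    cs$outer_contour[i, 2] * fr$ap_axis
  lm$piriformis_fossa_center <- calcar + 15 * fr$si_axis
  pl <- build_osteotomy_plane(mesh, lm, fr, 10)
  expect_equal(abs(sum(pl$normal * fr$ml_axis)), 1, tolerance = 1e-9)
})

test_that("plane contour of a cut sphere is the analytic circle", {
  res <- 128L
  mesh <- sphere_mesh(radius = 20, center = c(0, 0, 0), res = res)
  pl <- structure(list(point = c(0, 0, 10), normal = c(0, 0, 1),
                       construction = list(height_mm = NA)),
                  class = "osteotomy_plane")
  lm <- construction_landmarks()
  fr <- build_femoral_frame(lm)
  pc <- plane_contour(mesh, pl, fr)
  r <- sqrt(rowSums(sweep(pc$uv, 2, colMeans(pc$uv))^2))
  expect_lt(max(abs(r - sqrt(300))), 0.05)
  expect_true(all(abs((pc$points3d - matrix(pl$point, nrow(pc$points3d), 3,
                                            byrow = TRUE)) %*% pl$normal) < 1e-9))
  pl2 <- structure(list(point = c(0, 0, 30), normal = c(0, 0, 1),
                        construction = list(height_mm = NA)),
                   class = "osteotomy_plane")
  expect_error(plane_contour(mesh, pl2, fr), "does not intersect|only")
})

test_that("osteotomy contour area matches a pixel-count oracle within 1%", {
  fem <- generate_femur(femur_spec(nfa_deg = 20))
  fr <- build_femoral_frame(fem$landmarks)
  pl <- build_osteotomy_plane(fem$mesh, fem$landmarks, fr, 10)
  pc <- plane_contour(fem$mesh, pl, fr)
  a_poly <- stemversion:::polygon_area(pc$uv)
  a_pix <- pixel_area(pc$uv, h = 0.1)
  expect_lt(abs(a_poly - a_pix) / a_pix, 0.01)
})

test_that("circle_fit is exact on circles and calibrated on noisy data", {
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  fit <- circle_fit(cbind(3 + 7 * cos(t), -2 + 7 * sin(t)))
  expect_equal(fit$center, c(3, -2), tolerance = 1e-9)
  expect_equal(fit$radius, 7, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  # three points: the circumscribed circle interpolates exactly
  p3 <- rbind(c(0, 0), c(4, 0), c(1, 3))
  f3 <- circle_fit(p3)
  d <- sqrt(rowSums(sweep(p3, 2, f3$center)^2))
  expect_equal(d, rep(f3$radius, 3), tolerance = 1e-9)
  set.seed(31)
  tt <- runif(200, 0, 2 * pi)
  noisy <- cbind(10 * cos(tt), 10 * sin(tt)) + matrix(rnorm(400, 0, 0.1), 200)
  fn <- circle_fit(noisy)
  expect_lt(abs(fn$radius - 10), 0.05)
  expect_lt(abs(fn$rms - 0.1) / 0.1, 0.3)
  expect_error(circle_fit(cbind(1:8, 2 * (1:8) + 1)), "collinear")
})

test_that("geometric circle fit beats a Monte-Carlo candidate oracle", {
  set.seed(17)
  t <- runif(11, 0, pi)
  pts <- cbind(5 + 8 * cos(t), 1 + 8 * sin(t)) + matrix(rnorm(22, 0, 0.3), 11)
  fit <- circle_fit(pts)
  ssr <- function(c1, c2, r) {
    sum((sqrt((pts[, 1] - c1)^2 + (pts[, 2] - c2)^2) - r)^2)
  }
  best <- fit$rms^2 * nrow(pts)
  cand <- matrix(runif(30000, -1, 1), ncol = 3)
  cand[, 1] <- fit$center[1] + cand[, 1] * 2
  cand[, 2] <- fit$center[2] + cand[, 2] * 2
  cand[, 3] <- pmax(0.1, fit$radius + cand[, 3] * 2)
  mc <- min(vapply(seq_len(nrow(cand)), function(i) {
    ssr(cand[i, 1], cand[i, 2], cand[i, 3])
  }, numeric(1)))
  expect_lte(best, mc + 1e-9)
})

test_that("margin circles respect symmetry on elliptical and circular contours", {
  t <- seq(0, 2 * pi, length.out = 241)[-241]
  ell <- make_contour(cbind(20 * cos(t), 10 * sin(t)))
  mc <- fit_margin_circle(ell, direction = c(1, 0))
  expect_lt(abs(mc$center_uv[2]), 1e-6)   # center on the +u axis
  expect_gt(mc$center_uv[1], 0)
  circ <- make_contour(cbind(3 + 12 * cos(t), -1 + 12 * sin(t)))
  for (m in c("inferior", "superior", "medial")) {
    f <- fit_margin_circle(circ, m)
    expect_equal(f$center_uv, c(3, -1), tolerance = 1e-6)
    expect_equal(f$radius, 12, tolerance = 1e-6)
  }
})

test_that("the inferomedial margin circle passes through the calcar anchor", {
  for (th in c(10, 30)) {
    fem <- generate_femur(femur_spec(nfa_deg = th))
    fr <- build_femoral_frame(fem$landmarks)
    m3 <- am_3d(fem$mesh, fem$landmarks, fr, 10)
    pc <- m3$meta$contour
    ch <- pc$chart
    calcar <- pc$plane_ref$construction$calcar_point
    calcar_uv <- c(sum((calcar - ch$origin) * ch$u),
                   sum((calcar - ch$origin) * ch$v))
    inf <- m3$meta$inferior_circle
    miss <- abs(stemversion:::vnorm(calcar_uv - inf$center_uv) - inf$radius)
    expect_lt(miss, 1)
  }
})

test_that("IMI returns the inferior crossing with the medial tie-break", {
  t <- seq(0, 2 * pi, length.out = 241)[-241]
  circ <- make_contour(cbind(10 * cos(t), 10 * sin(t)))
  # midline along v: the inferior (-v) pole is returned
  down <- imi_point(circ, axis3d(c(0, 0, 0), circ$chart$v),
                    build_femoral_frame(construction_landmarks()))
  expect_equal(down, c(0, 0, -10), tolerance = 1e-6)
  # midline along u: both crossings tie in v; the more medial (+ml = +u) wins
  lr <- imi_point(circ, axis3d(c(0, 0, 0), circ$chart$u),
                  build_femoral_frame(construction_landmarks()))
  expect_equal(lr, c(10, 0, 0), tolerance = 1e-6)
  outside <- axis3d(c(0, 0, 50), circ$chart$u)
  expect_error(imi_point(circ, outside,
                         build_femoral_frame(construction_landmarks())),
               "does not intersect")
  dense <- imi_point(circ, axis3d(c(1.3, 0, 0.4), c(0.2, 0, 0.98)),
                     build_femoral_frame(construction_landmarks()))
  # dense-sampling oracle: resample each edge 20x and take the lowest-v crossing
  fine <- seq(0, 2 * pi, length.out = 4801)[-4801]
  pts <- cbind(10 * cos(fine), 0, 10 * sin(fine))
  ld <- stemversion:::unitize(c(0.2, 0, 0.98))
  a <- c(1.3, 0, 0.4)
  rel <- sweep(pts, 2, a)
  cr <- rel[, 1] * ld[3] - rel[, 3] * ld[1]
  near <- pts[abs(cr) < 0.03 & pts[, 3] < 0, , drop = FALSE]
  expect_lt(stemversion:::vnorm(dense - colMeans(near)), 1)
})

test_that("AM-3D is symmetric at zero, monotone over the DDH range and near truth at 30", {
  f0 <- generate_femur(femur_spec(nfa_deg = 0))
  fr0 <- build_femoral_frame(f0$landmarks)
  expect_lt(abs(am_3d(f0$mesh, f0$landmarks, fr0, 10)$angle_deg), 1e-3)
  expect_lt(abs(am_3d(f0$mesh, f0$landmarks, fr0, 5)$angle_deg), 1e-3)
  sweep_vals <- vapply(seq(10, 50, 10), function(th) {
    fem <- generate_femur(femur_spec(nfa_deg = th))
    fr <- build_femoral_frame(fem$landmarks)
    am_3d(fem$mesh, fem$landmarks, fr, 10)$angle_deg
  }, numeric(1))
  expect_true(all(diff(sweep_vals) > 0))
  expect_lt(abs(sweep_vals[3] - 30), 5)
})

test_that("the T-line measure exceeds the midcortical measure with a posteriorized fossa", {
  fem <- generate_femur(femur_spec(nfa_deg = 20, fossa_posterior_offset = 8))
  fr <- build_femoral_frame(fem$landmarks)
  for (h in c(5, 10)) {
    a_t <- at_3d(fem$mesh, fem$landmarks, fr, h)$angle_deg
    a_m <- am_3d(fem$mesh, fem$landmarks, fr, h)$angle_deg
    expect_gt(a_t, a_m)
  }
  # T-line is the trochanteric-fossa-to-IMI chord measured in the axial plane
  m3 <- am_3d(fem$mesh, fem$landmarks, fr, 10)
  imi <- imi_point(m3$meta$contour, m3$meta$midline, fr)
  d <- imi - fem$landmarks$trochanteric_fossa
  if (sum(d * fr$ml_axis) < 0) d <- -d
  ref <- axial_projected_angle(d, posterior_condylar_axis(fem$landmarks), fr)
  expect_equal(at_3d(fem$mesh, fem$landmarks, fr, 10)$angle_deg, ref,
               tolerance = 1e-9)
})

test_that("3D-model measures are equivariant under rigid motion and bounded across heights", {
  fem <- generate_femur(femur_spec(nfa_deg = 35))
  fr <- build_femoral_frame(fem$landmarks)
  a0 <- am_3d(fem$mesh, fem$landmarks, fr, 10)$angle_deg
  t0 <- at_3d(fem$mesh, fem$landmarks, fr, 10)$angle_deg
  R <- random_rotation(23)
  tr <- c(-15, 8, 42)
  mesh2 <- mesh_transform(fem$mesh, R = R, t = tr)
  lm2 <- stemversion:::landmarks_transform(fem$landmarks, R = R, t = tr)
  fr2 <- build_femoral_frame(lm2)
  expect_equal(am_3d(mesh2, lm2, fr2, 10)$angle_deg, a0, tolerance = 1e-6)
  expect_equal(at_3d(mesh2, lm2, fr2, 10)$angle_deg, t0, tolerance = 1e-6)
  t5 <- at_3d(fem$mesh, fem$landmarks, fr, 5)$angle_deg
  expect_lt(abs(t5 - t0), 10)
})
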