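#' Simulated neck osteotomy plane
#'
#' The plane passes through the center of the piriformis fossa and the calcar
#' point (the most medial point of the axial cross-section at `height_mm`
#' above the lesser-trochanter apex), and contains the frame's AP direction,
#' which makes the simulated cut anterior--posterior symmetric.  The normal
#' is oriented to point proximally (positive SI component; for the degenerate
#' configuration in which the defining points are stacked along SI the normal
#' is along +/-ML and is oriented toward +ML).
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()] in right-side convention.
#' @param frame an anatomical frame.
#' @param height_mm cutting height above the lesser-trochanter apex (mm).
#' @return an object of class `osteotomy_plane` with fields `point`
#'   (piriformis fossa center), `normal` and `construction` (the defining
#'   points and height).
#' @export
build_osteotomy_plane <- function(mesh, landmarks, frame, height_mm) {
  cs <- extract_cross_section(mesh, frame, landmarks, height_mm)
  i <- which.max(cs$outer_contour[, 1])
  calcar <- cs$plane_point +
    cs$outer_contour[i, 1] * frame$ml_axis +
    cs$outer_contour[i, 2] * frame$ap_axis
  pf <- landmarks$piriformis_fossa_center
  d <- pf - calcar
  if (vnorm(d) < 1e-6) stop("piriformis center and calcar point coincide")
  nr <- cross3(frame$ap_axis, d)
  if (vnorm(nr) < 1e-9) stop("degenerate osteotomy plane: defining segment parallel to AP")
  n <- unitize(nr, "osteotomy plane normal")
  s <- sum(n * frame$si_axis)
  if (abs(s) < 1e-12) {
    if (sum(n * frame$ml_axis) < 0) n <- -n
  } else if (s < 0) {
    n <- -n
  }
  structure(list(point = pf, normal = n,
                 construction = list(piriformis_center = pf, calcar_point = calcar,
                                     height_mm = height_mm)),
            class = "osteotomy_plane")
}

#' @export
print.osteotomy_plane <- function(x, ...) {
  cat(sprintf("<osteotomy_plane at %g mm: normal (%.3f, %.3f, %.3f)>\n",
              x$construction$height_mm, x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# Orthonormal in-plane chart for an osteotomy plane:
#   v = unit in-plane projection of +SI (superior positive),
#   u = n x v (perpendicular to v in the plane).
# For AP-containing planes u is +/-AP; angles and margins that need a medial
# direction use the 3D ML coordinate instead of u.
plane_chart <- function(plane, frame) {
  n <- plane$normal
  vr <- frame$si_axis - sum(frame$si_axis * n) * n
  if (vnorm(vr) < 1e-9) {
    vr <- frame$ap_axis - sum(frame$ap_axis * n) * n
  }
  v <- unitize(vr, "in-plane superior direction")
  u <- cross3(n, v)
  list(u = u, v = v, n = n, origin = plane$point, ml = frame$ml_axis)
}

#' Closed contour of a mesh cut by an osteotomy plane
#'
#' Intersects the mesh with the plane and returns the largest closed loop,
#' both as 3D points and in orthonormal in-plane `(u, v)` coordinates with
#' `v` the in-plane projection of the SI axis (superior positive) and `u`
#' perpendicular to it, oriented counter-clockwise in `(u, v)`.
#'
#' @param mesh a [surface_mesh()].
#' @param plane an `osteotomy_plane` from [build_osteotomy_plane()].
#' @param frame an anatomical frame (defines the in-plane chart).
#' @return an object of class `planar_contour` with fields `points3d`, `uv`,
#'   `plane_ref` and `chart`.
#' @export
plane_contour <- function(mesh, plane, frame) {
  loops <- mesh_plane_loops(mesh, plane$point, plane$normal)
  if (length(loops) == 0L) stop("osteotomy plane does not intersect the mesh")
  ch <- plane_chart(plane, frame)
  uv <- lapply(loops, function(L) {
    W <- L - matrix(ch$origin, nrow(L), 3, byrow = TRUE)
    cbind(as.vector(W %*% ch$u), as.vector(W %*% ch$v))
  })
  areas <- vapply(uv, function(p) abs(polygon_area(p)), numeric(1))
  k <- which.max(areas)
  p2 <- uv[[k]]; p3 <- loops[[k]]
  if (nrow(p2) < 16L) {
    stop(sprintf("osteotomy contour has only %d points", nrow(p2)))
  }
  if (polygon_area(p2) < 0) {
    p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
    p3 <- p3[rev(seq_len(nrow(p3))), , drop = FALSE]
  }
  structure(list(points3d = p3, uv = p2, plane_ref = plane, chart = ch),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour: %d points, uv area %.1f mm^2>\n",
              nrow(x$uv), polygon_area(x$uv)))
  invisible(x)
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) fit solved by linear least squares, refined by
#' Gauss--Newton minimization of the geometric (radial) residuals.
#'
#' @param points `n x 2` matrix, `n >= 3`, not collinear.
#' @return a list with `center` (length 2), `radius` and `rms` (root mean
#'   square radial residual).
#' @export
circle_fit <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3L) stop("need at least 3 points to fit a circle")
  x <- p[, 1]; y <- p[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  qrA <- qr(A)
  if (qrA$rank < 3L) stop("no circle: points are collinear")
  sol <- qr.coef(qrA, x^2 + y^2)
  c0 <- sol[1:2]
  r0 <- sqrt(max(sol[3] + sum(c0^2), .Machine$double.eps))
  par <- c(c0, r0)
  for (it in 1:50) {
    dx <- x - par[1]; dy <- y - par[2]
    ri <- sqrt(dx^2 + dy^2)
    ri[ri < 1e-12] <- 1e-12
    res <- ri - par[3]
    J <- cbind(-dx / ri, -dy / ri, -1)
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 3))
    step[is.na(step)] <- 0
    par <- par + step
    if (max(abs(step)) < 1e-12) break
  }
  dx <- x - par[1]; dy <- y - par[2]
  res <- sqrt(dx^2 + dy^2) - par[3]
  list(center = unname(par[1:2]), radius = unname(par[3]),
       rms = sqrt(mean(res^2)))
}

# Extreme-point direction for a named margin of an osteotomy contour.
margin_direction <- function(contour, margin) {
  switch(margin,
    inferior = c(0, -1),
    superior = ,
    lateral  = c(0, 1),
    medial   = {
      # in-plane projection of +ML, expressed in the (u, v) chart
      ch <- contour$chart
      mlv <- ch$ml %||% c(1, 0, 0)
      w <- c(sum(mlv * ch$u), sum(mlv * ch$v))
      if (vnorm(w) < 1e-9) c(0, -1) else w / vnorm(w)
    },
    stop("unknown margin: ", margin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best-fitting margin circle of an osteotomy contour
#'
#' Selects the contiguous run of contour points lying within an angular
#' window (measured about the contour centroid) centered on the extreme point
#' in the margin direction, and fits a circle to it.  Margins: `"inferior"`
#' (-v extreme), `"superior"`/`"lateral"` (+v extreme) and `"medial"` (the
#' extreme of the in-plane projection of the ML axis; on planes containing
#' the AP direction this coincides with the inferior margin).  An explicit
#' `direction` in `(u, v)` coordinates overrides the named margin.
#'
#' @param contour a `planar_contour`.
#' @param margin margin name (see Details).
#' @param window full angular width of the margin arc in degrees.
#' @param min_points minimum number of arc points.
#' @param direction optional explicit length-2 margin direction.
#' @return a list of class `margin_circle` with `center_uv`, `radius`,
#'   `arc_indices` and `rms_residual`.
#' @export
fit_margin_circle <- function(contour, margin = c("medial", "inferior", "superior", "lateral"),
                              window = 60, min_points = 5L, direction = NULL) {
  if (is.null(direction)) {
    margin <- match.arg(margin)
    direction <- margin_direction(contour, margin)
  } else {
    margin <- "custom"
    direction <- unitize(as.numeric(direction), "margin direction")
  }
  p <- contour$uv
  ctr <- polygon_centroid(p)
  rel <- sweep(p, 2, ctr)
  ang <- rad2deg(atan2(rel[, 2], rel[, 1]))
  ext <- which.max(p %*% direction)
  keep <- ang_diff_deg(ang, ang[ext]) <= window / 2
  idx <- contiguous_run(keep, anchor = ext)
  if (length(idx) < min_points) {
    stop(sprintf("margin arc has %d points (< %d)", length(idx), min_points))
  }
  fit <- circle_fit(p[idx, , drop = FALSE])
  structure(list(center_uv = fit$center, radius = fit$radius,
                 arc_indices = idx, rms_residual = fit$rms, margin = margin),
            class = "margin_circle")
}

# Map in-plane (u, v) coordinates back to 3D.
uv_to_3d <- function(contour, uv) {
  ch <- contour$chart
  ch$origin + uv[1] * ch$u + uv[2] * ch$v
}

#' Midcortical-line anteversion on the simulated osteotomy plane (AM-3D)
#'
#' Fits margin circles at the two superior--inferior extremes of the
#' osteotomy contour -- the inferomedial (calcar) margin and the
#' superolateral margin -- and measures the signed axial-plane angle of the
#' 3D line through the two circle centers against the posterior condylar
#' axis.
#'
#' @inheritParams build_osteotomy_plane
#' @param window margin arc angular width, degrees.
#' @return an [anteversion_measure()] with method `"AM-3D"`; the midline and
#'   contour are attached in `meta`.
#' @export
am_3d <- function(mesh, landmarks, frame, height_mm, window = 60) {
  plane <- with_stage("build_osteotomy_plane",
                      build_osteotomy_plane(mesh, landmarks, frame, height_mm))
  pc <- with_stage("plane_contour", plane_contour(mesh, plane, frame))
  # the inferomedial margin direction points from the contour centroid toward
  # the plane's calcar anchor point; the superolateral margin is the opposite
  # end of the cut.  For a symmetric neck these are the -v and +v extremes.
  ch <- pc$chart
  ctr <- polygon_centroid(pc$uv)
  uv_of <- function(p3) c(sum((p3 - ch$origin) * ch$u), sum((p3 - ch$origin) * ch$v))
  d_inf <- uv_of(plane$construction$calcar_point) - ctr
  d_sup <- -d_inf
  inf_c <- with_stage("fit_margin_circle",
                      fit_margin_circle(pc, window = window, direction = d_inf))
  sup_c <- with_stage("fit_margin_circle",
                      fit_margin_circle(pc, window = window, direction = d_sup))
  c1 <- uv_to_3d(pc, sup_c$center_uv)
  c2 <- uv_to_3d(pc, inf_c$center_uv)
  if (vnorm(c1 - c2) < 1) {
    stop("[midline] degenerate midline: margin circle centers within 1 mm")
  }
  d <- c2 - c1
  if (sum(d * frame$ml_axis) < 0) d <- -d
  pca <- posterior_condylar_axis(landmarks)
  ang <- with_stage("axial_projected_angle", axial_projected_angle(d, pca, frame))
  anteversion_measure("AM-3D", height_mm, ang,
                      meta = list(midline = axis3d(c1, c2 - c1), contour = pc,
                                  inferior_circle = inf_c, superior_circle = sup_c))
}

#' Intersection of the midcortical line with the inferior contour margin
#'
#' Intersects the (projected) midline with the contour polygon in `(u, v)`
#' coordinates by segment--line crossing and returns the crossing with the
#' smaller `v` (the inferior margin).  When two crossings tie in `v`, the
#' more medial one (larger 3D ML coordinate) is returned.
#'
#' @param contour a `planar_contour`.
#' @param midline3d an [axis3d()]; its in-plane projection is intersected
#'   with the contour.
#' @param frame an anatomical frame (for the medial tie-break).
#' @return the 3D intersection point.
#' @export
imi_point <- function(contour, midline3d, frame) {
  ch <- contour$chart
  a <- c(sum((midline3d$point - ch$origin) * ch$u),
         sum((midline3d$point - ch$origin) * ch$v))
  d <- c(sum(midline3d$direction * ch$u), sum(midline3d$direction * ch$v))
  if (vnorm(d) < 1e-9) stop("midline is perpendicular to the osteotomy plane")
  d <- d / vnorm(d)
  p <- contour$uv
  n <- nrow(p)
  q1 <- p; q2 <- p[c(2:n, 1L), , drop = FALSE]
  # crossing parameter of each polygon edge with the infinite line a + t d
  cross_line <- (q1[, 1] - a[1]) * d[2] - (q1[, 2] - a[2]) * d[1]
  cross_line2 <- (q2[, 1] - a[1]) * d[2] - (q2[, 2] - a[2]) * d[1]
  hit <- which(cross_line * cross_line2 <= 0 & (cross_line != cross_line2))
  if (length(hit) == 0L) stop("midline does not intersect the contour")
  s <- cross_line[hit] / (cross_line[hit] - cross_line2[hit])
  pts <- q1[hit, , drop = FALSE] + s * (q2[hit, , drop = FALSE] - q1[hit, , drop = FALSE])
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  vmin <- min(pts[, 2])
  cand <- which(pts[, 2] <= vmin + 1e-9)
  if (length(cand) > 1L) {
    ml_coord <- vapply(cand, function(i) {
      sum(uv_to_3d(contour, pts[i, ]) * frame$ml_axis)
    }, numeric(1))
    cand <- cand[which.max(ml_coord)]
  }
  uv_to_3d(contour, pts[cand[1], ])
}

#' T-line anteversion on the simulated osteotomy plane (AT-3D)
#'
#' The T-line connects the trochanteric fossa landmark to the IMI point (the
#' intersection of the osteotomy-plane midcortical line with the inferior
#' contour margin); AT-3D is its signed axial-plane angle against the
#' posterior condylar axis.
#'
#' @inheritParams am_3d
#' @return an [anteversion_measure()] with method `"AT-3D"`.
#' @export
at_3d <- function(mesh, landmarks, frame, height_mm, window = 60) {
  m3 <- am_3d(mesh, landmarks, frame, height_mm, window = window)
  imi <- with_stage("imi_point",
                    imi_point(m3$meta$contour, m3$meta$midline, frame))
  d <- imi - landmarks$trochanteric_fossa
  if (sum(d * frame$ml_axis) < 0) d <- -d
  pca <- posterior_condylar_axis(landmarks)
  ang <- with_stage("axial_projected_angle", axial_projected_angle(d, pca, frame))
  anteversion_measure("AT-3D", height_mm, ang,
                      meta = list(imi = imi, trochanteric_fossa = landmarks$trochanteric_fossa))
}
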