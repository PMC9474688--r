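#' 2D line in axial coordinates
#'
#' @param point length-2 anchor point (mm, axial ML/AP coordinates).
#' @param direction length-2 direction; normalized on construction.
#' @return an object of class `line2d`.
#' @export
line2d <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = unitize(as.numeric(direction), "line direction")),
            class = "line2d")
}

# Angle of a line2d direction in degrees.
line_angle_deg <- function(line) rad2deg(atan2(line$direction[2], line$direction[1]))

new_cross_section <- function(height_mm, outer, frame, plane_point, inner = NULL) {
  outer <- ensure_ccw(outer)
  if (nrow(outer) < 16L) {
    stop(sprintf("cross-section contour has %d points (< 16)", nrow(outer)))
  }
  structure(list(height_mm = height_mm,
                 outer_contour = outer,
                 inner_contour = inner,
                 frame_ref = frame,
                 plane_point = plane_point),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section at %+.1f mm: %d contour points, area %.1f mm^2>\n",
              x$height_mm, nrow(x$outer_contour), polygon_area(x$outer_contour)))
  invisible(x)
}

#' Axial cross-section of a femur mesh
#'
#' Intersects the mesh with the axial plane `height_mm` millimetres proximal
#' to the lesser-trochanter apex (along the frame's SI axis) and returns the
#' largest closed loop in 2D axial coordinates (x = ML, y = AP, both relative
#' to the plane's reference point), oriented counter-clockwise.  Smaller
#' loops (for example a partially attached lesser trochanter) are discarded
#' with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param frame an anatomical frame from [build_femoral_frame()].
#' @param landmarks a [landmark_set()]; supplies the lesser-trochanter apex.
#' @param height_mm proximal offset of the cutting plane in millimetres.
#' @return a `cross_section` object.
#' @export
extract_cross_section <- function(mesh, frame, landmarks, height_mm) {
  p0 <- landmarks$lesser_trochanter_apex + height_mm * frame$si_axis
  loops <- mesh_plane_loops(mesh, p0, frame$si_axis)
  if (length(loops) == 0L) {
    stop(sprintf("plane misses mesh: no intersection at height %.1f mm", height_mm))
  }
  uv <- lapply(loops, function(L) {
    cbind(as.vector((L - matrix(p0, nrow(L), 3, byrow = TRUE)) %*% frame$ml_axis),
          as.vector((L - matrix(p0, nrow(L), 3, byrow = TRUE)) %*% frame$ap_axis))
  })
  areas <- vapply(uv, function(p) abs(polygon_area(p)), numeric(1))
  if (length(loops) > 1L) {
    warning(sprintf("%d intersection loops at height %.1f mm; keeping the largest",
                    length(loops), height_mm))
  }
  new_cross_section(height_mm, uv[[which.max(areas)]], frame, p0)
}

#' Voxel image container
#'
#' A scalar 3D grid with voxel spacing and world origin (coordinates of the
#' center of voxel `[1, 1, 1]`), axes aligned with the world/frame axes.
#'
#' @param data 3D array (numeric or logical).
#' @param spacing length-3 voxel size in millimetres.
#' @param origin length-3 world coordinates of the first voxel center (mm).
#' @return an object of class `voxel_image`.
#' @export
voxel_image <- function(data, spacing, origin) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image: %s voxels, spacing %.2f x %.2f x %.2f mm>\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Axial cross-section from a voxel image
#'
#' Selects the image plane nearest to `height_mm` above the lesser-trochanter
#' apex and extracts the bone boundary as the 0.5-level iso-contour of the
#' binarized slice (marching-squares contouring via
#' [grDevices::contourLines()]), converted to millimetres in the frame's
#' axial coordinates.  The image axes must be aligned with the frame axes
#' (axis 1 along +/-ML, axis 2 along +/-AP, axis 3 along SI).
#'
#' @param image a [voxel_image()].
#' @param frame an anatomical frame.
#' @param landmarks a [landmark_set()].
#' @param height_mm proximal offset of the slice in millimetres.
#' @return a `cross_section` object.
#' @export
slice_from_image <- function(image, frame, landmarks, height_mm) {
  p0 <- landmarks$lesser_trochanter_apex + height_mm * frame$si_axis
  z3 <- (p0 - image$origin)[3] / image$spacing[3] + 1
  k <- as.integer(round(z3))
  if (k < 1L || k > dim(image$data)[3]) {
    stop(sprintf("height %.1f mm maps outside the image grid", height_mm))
  }
  sl <- (image$data[, , k] >= 0.5) * 1
  if (!any(sl > 0)) stop("empty slice: no bone voxels at the requested height")
  xs <- image$origin[1] + (seq_len(dim(sl)[1]) - 1) * image$spacing[1]
  ys <- image$origin[2] + (seq_len(dim(sl)[2]) - 1) * image$spacing[2]
  cl <- grDevices::contourLines(xs, ys, sl, levels = 0.5)
  if (length(cl) == 0L) stop("empty slice: no iso-contour at the requested height")
  zk <- image$origin[3] + (k - 1) * image$spacing[3]
  uv <- lapply(cl, function(cc) {
    n <- length(cc$x)
    if (n > 1 && cc$x[1] == cc$x[n] && cc$y[1] == cc$y[n]) n <- n - 1L
    W <- cbind(cc$x[seq_len(n)], cc$y[seq_len(n)], zk)
    cbind(as.vector((W - matrix(p0, n, 3, byrow = TRUE)) %*% frame$ml_axis),
          as.vector((W - matrix(p0, n, 3, byrow = TRUE)) %*% frame$ap_axis))
  })
  areas <- vapply(uv, function(p) abs(polygon_area(p)), numeric(1))
  new_cross_section(height_mm, uv[[which.max(areas)]], frame, p0)
}

#' Anterior and posterior cortex point runs of a cross-section
#'
#' Splits the outer contour into the anterior and posterior cortical walls:
#' the contiguous runs of contour points whose outward normals lie within
#' `window` degrees of the anterior and posterior window centers.  With
#' `reference = "ap"` the window centers are the +AP and -AP directions; with
#' `reference = "principal"` they are perpendicular to the contour's
#' principal (total-least-squares) axis, which keeps the selected runs on the
#' cortical walls when the section is strongly anteverted.  Near-isotropic
#' sections (principal-axis ratio below 1.05) fall back to the AP reference.
#'
#' @param cs a `cross_section`.
#' @param window half-width of the normal-direction window in degrees.
#' @param reference `"ap"` or `"principal"` (see Details).
#' @param min_points minimum acceptable run length.
#' @return a list with `anterior` and `posterior` point matrices and their
#'   contour `anterior_idx` / `posterior_idx` index vectors.
#' @export
classify_cortex_arcs <- function(cs, window = 40, reference = c("ap", "principal"),
                                 min_points = 5L) {
  reference <- match.arg(reference)
  p <- cs$outer_contour
  vn <- polygon_vertex_normals(p)
  nang <- rad2deg(atan2(vn[, 2], vn[, 1]))
  center_ant <- 90
  if (reference == "principal") {
    pc <- sweep(p, 2, colMeans(p))
    ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
    if (sqrt(ev$values[1] / max(ev$values[2], 1e-300)) >= 1.05) {
      ax <- ev$vectors[, 1]
      if (ax[1] < 0) ax <- -ax
      center_ant <- rad2deg(atan2(ax[2], ax[1])) + 90
    }
  }
  pick <- function(center) {
    keep <- ang_diff_deg(nang, center) <= window
    u <- c(cos(deg2rad(center)), sin(deg2rad(center)))
    anchor <- which.max(p %*% u)
    idx <- contiguous_run(keep, anchor = if (keep[anchor]) anchor else NULL)
    idx
  }
  ai <- pick(center_ant)
  pi_ <- pick(center_ant - 180)
  if (length(ai) < min_points || length(pi_) < min_points) {
    stop(sprintf("fewer than %d qualifying cortex points (anterior %d, posterior %d)",
                 min_points, length(ai), length(pi_)))
  }
  list(anterior = p[ai, , drop = FALSE], posterior = p[pi_, , drop = FALSE],
       anterior_idx = ai, posterior_idx = pi_)
}

#' Total-least-squares cortex line
#'
#' Fits a line to 2D cortex points by the principal direction of the centered
#' point cloud (orthogonal-distance regression), anchored at the centroid.
#' The direction is oriented with a non-negative ML component.
#'
#' @param points `n x 2` matrix of axial points (mm), `n >= 5`.
#' @return a [line2d()].
#' @export
fit_cortex_line <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("need at least 5 points to fit a cortex line")
  ctr <- colMeans(points)
  pc <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  if (sqrt(ev$values[1] / max(ev$values[2], 1e-300)) < 1.05) {
    stop("ill-conditioned fit: cortex points are isotropic")
  }
  d <- ev$vectors[, 1]
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  line2d(ctr, d)
}

#' Midcortical line
#'
#' The angular bisector of the anterior and posterior cortex lines: the two
#' directions are co-oriented and summed, and the anchor is the midpoint of
#' the two anchors.  For parallel inputs this is the parallel mid-line.
#'
#' @param anterior,posterior [line2d()] objects.
#' @return a [line2d()].
#' @export
midcortical_line <- function(anterior, posterior) {
  da <- anterior$direction
  dp <- posterior$direction
  if (sum(da * dp) < 0) dp <- -dp
  d <- da + dp
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  line2d((anterior$point + posterior$point) / 2, d)
}

#' Anteversion measurement result
#'
#' @param method one of `"AM-CT"`, `"AM-3D"`, `"AT-3D"`, `"PSA"`.
#' @param height_mm slice/osteotomy height in millimetres, or `NA` for PSA.
#' @param angle_deg signed anteversion in degrees, in `(-180, 180]`.
#' @param meta optional named list of provenance details.
#' @return an object of class `anteversion_measure`.
#' @export
anteversion_measure <- function(method, height_mm, angle_deg, meta = list()) {
  method <- match.arg(method, c("AM-CT", "AM-3D", "AT-3D", "PSA"))
  if (method == "PSA") height_mm <- NA_real_
  if (!is.finite(angle_deg) || angle_deg <= -180 || angle_deg > 180) {
    stop("angle_deg must be finite and in (-180, 180]")
  }
  structure(list(method = method, height_mm = height_mm,
                 angle_deg = angle_deg, meta = meta),
            class = "anteversion_measure")
}

#' @export
print.anteversion_measure <- function(x, ...) {
  h <- if (is.na(x$height_mm)) "" else sprintf(" @ %g mm", x$height_mm)
  cat(sprintf("%s%s: %.1f deg\n", x$method, h, x$angle_deg))
  invisible(x)
}

#' @export
format.anteversion_measure <- function(x, ...) {
  sprintf("%s(height=%s) = %.3f deg", x$method,
          ifelse(is.na(x$height_mm), "n/a", format(x$height_mm)), x$angle_deg)
}

# Wrap a measurement stage so failures are labeled with the stage name.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Midcortical-line anteversion on an axial CT-style section (AM-CT)
#'
#' Composition of [extract_cross_section()], [classify_cortex_arcs()],
#' [fit_cortex_line()] (anterior and posterior), [midcortical_line()] and
#' [axial_projected_angle()] against the posterior condylar axis.
#'
#' @param mesh a [surface_mesh()] in right-side convention.
#' @param frame an anatomical frame.
#' @param landmarks a [landmark_set()].
#' @param height_mm section height above the lesser-trochanter apex; 5 and
#'   10 mm are the conventional levels (other values allowed with a warning).
#' @param window cortex normal window half-width, degrees.
#' @param reference cortex window reference, see [classify_cortex_arcs()].
#' @param section optionally, a precomputed `cross_section` (e.g. from
#'   [slice_from_image()]); when supplied `mesh` may be `NULL`.
#' @return an [anteversion_measure()] with method `"AM-CT"`.
#' @export
am_ct <- function(mesh, frame, landmarks, height_mm,
                  window = 40, reference = "principal", section = NULL) {
  if (!height_mm %in% c(5, 10)) {
    warning(sprintf("unconventional AM-CT height %.1f mm (expected 5 or 10)", height_mm))
  }
  cs <- if (is.null(section)) {
    with_stage("extract_cross_section",
               extract_cross_section(mesh, frame, landmarks, height_mm))
  } else section
  arcs <- with_stage("classify_cortex_arcs",
                     classify_cortex_arcs(cs, window = window, reference = reference))
  la <- with_stage("fit_cortex_line", fit_cortex_line(arcs$anterior))
  lp <- with_stage("fit_cortex_line", fit_cortex_line(arcs$posterior))
  mid <- with_stage("midcortical_line", midcortical_line(la, lp))
  pca <- with_stage("posterior_condylar_axis", posterior_condylar_axis(landmarks))
  dir3 <- mid$direction[1] * frame$ml_axis + mid$direction[2] * frame$ap_axis
  ang <- with_stage("axial_projected_angle", axial_projected_angle(dir3, pca, frame))
  anteversion_measure("AM-CT", height_mm, ang,
                      meta = list(n_contour = nrow(cs$outer_contour),
                                  n_anterior = nrow(arcs$anterior),
                                  n_posterior = nrow(arcs$posterior)))
}

#' Postoperative stem anteversion (PSA)
#'
#' The signed axial-plane angle between the implanted stem's neck axis and
#' the posterior condylar axis.
#'
#' @param stem_neck_axis an [axis3d()] for the stem neck.
#' @param frame an anatomical frame.
#' @param landmarks a [landmark_set()] (supplies the posterior condyles).
#' @return an [anteversion_measure()] with method `"PSA"`.
#' @export
psa_from_stem <- function(stem_neck_axis, frame, landmarks) {
  pca <- posterior_condylar_axis(landmarks)
  ang <- axial_projected_angle(stem_neck_axis$direction, pca, frame)
  anteversion_measure("PSA", NA_real_, ang)
}
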