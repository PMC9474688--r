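#' Oriented 3D axis
#'
#' A line through `point` with unit `direction`.
#'
#' @param point length-3 numeric point (mm).
#' @param direction length-3 numeric direction; normalized on construction.
#' @return an object of class `axis3d`.
#' @export
axis3d <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = unitize(as.numeric(direction), "axis direction")),
            class = "axis3d")
}

#' @export
print.axis3d <- function(x, ...) {
  cat(sprintf("<axis3d: point (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)>\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Femoral anatomical coordinate frame
#'
#' Builds the right-handed femoral frame from canonicalized (right-side
#' convention) landmarks:
#' * SI: unit vector from the epicondyle midpoint to the femoral head center
#'   (superior positive);
#' * ML: component of the lateral-to-medial posterior condyle vector
#'   orthogonal to SI (medial positive);
#' * AP: `ML x SI` (anterior positive).
#'
#' The origin is the femoral head center.  All anteversion angles are
#' measured in this frame's axial plane (the plane spanned by ML and AP).
#'
#' @param landmarks a [landmark_set()] in right-side convention (see
#'   [canonicalize_side()]).
#' @return an object of class `anatomical_frame` with fields `origin`,
#'   `si_axis`, `ap_axis`, `ml_axis` and `side`.
#' @export
build_femoral_frame <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set")) stop("landmarks must be a landmark_set")
  epimid <- (landmarks$epicondyle_medial + landmarks$epicondyle_lateral) / 2
  si <- unitize(landmarks$head_center - epimid, "SI axis")
  cond <- landmarks$post_condyle_medial - landmarks$post_condyle_lateral
  cond_u <- unitize(cond, "condylar line")
  if (rad2deg(acos(min(1, abs(sum(cond_u * si))))) < 0.5) {
    stop("degenerate frame: condylar line is parallel to the SI axis")
  }
  ml <- unitize(cond - sum(cond * si) * si, "ML axis")
  ap <- cross3(ml, si)
  structure(list(origin = landmarks$head_center,
                 si_axis = si, ap_axis = ap, ml_axis = ml,
                 side = landmarks$side),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame (%s side)>\n", x$side))
  cat(sprintf("  origin %8.2f %8.2f %8.2f\n", x$origin[1], x$origin[2], x$origin[3]))
  for (nm in c("si_axis", "ap_axis", "ml_axis")) {
    cat(sprintf("  %-7s %8.4f %8.4f %8.4f\n", sub("_axis", "", nm),
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

#' Posterior condylar axis (PCA)
#'
#' The axis through the two posterior condyle landmarks, oriented from the
#' lateral to the medial condyle.  All anteversion angles are measured
#' against this axis.
#'
#' @param landmarks a [landmark_set()].
#' @return an [axis3d()] anchored at the lateral condyle.
#' @export
posterior_condylar_axis <- function(landmarks) {
  d <- landmarks$post_condyle_medial - landmarks$post_condyle_lateral
  if (vnorm(d) < 1e-9) stop("posterior condyle landmarks coincide")
  axis3d(landmarks$post_condyle_lateral, d)
}

# Project a 3D vector into the frame's axial plane coordinates (ML, AP).
axial_coords <- function(v, frame) {
  c(sum(v * frame$ml_axis), sum(v * frame$ap_axis))
}

#' Signed axial-plane angle between a direction and a reference axis
#'
#' Both vectors are projected onto the frame's axial plane (the plane
#' perpendicular to SI) and the signed angle from the projected reference to
#' the projected direction is returned in degrees, computed as the
#' two-argument arctangent in the frame's axial (ML, AP) coordinates.  With
#' the right-side convention this makes anteversion -- the medial end of a
#' line tipped anteriorly -- positive, and retroversion negative.  Range
#' `(-180, 180]`.
#'
#' @param direction length-3 vector to measure.
#' @param reference an [axis3d()] (typically the posterior condylar axis) or
#'   a length-3 vector.
#' @param frame an [build_femoral_frame()] result.
#' @return signed angle in degrees.
#' @export
axial_projected_angle <- function(direction, reference, frame) {
  ref <- if (inherits(reference, "axis3d")) reference$direction else as.numeric(reference)
  d2 <- axial_coords(as.numeric(direction), frame)
  r2 <- axial_coords(ref, frame)
  if (vnorm(d2) <= 1e-6) {
    stop("degenerate projection: `direction` is parallel to the SI axis")
  }
  if (vnorm(r2) <= 1e-6) {
    stop("degenerate projection: `reference` is parallel to the SI axis")
  }
  ang <- rad2deg(atan2(r2[1] * d2[2] - r2[2] * d2[1], sum(r2 * d2)))
  if (ang <= -180) ang <- ang + 360
  ang
}
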