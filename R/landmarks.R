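LANDMARK_NAMES <- c("head_center", "lesser_trochanter_apex",
                    "piriformis_fossa_center", "trochanteric_fossa",
                    "post_condyle_medial", "post_condyle_lateral",
                    "epicondyle_medial", "epicondyle_lateral")

#' Named anatomical landmark set
#'
#' Bundles the eight named proximal/distal femoral landmarks (3D points in
#' millimetres) used to build the anatomical frame and the measurement
#' references, together with the side of the hip.
#'
#' @param ... named length-3 numeric vectors, one per landmark; alternatively
#'   a single named list.  Required names: `head_center`,
#'   `lesser_trochanter_apex`, `piriformis_fossa_center`,
#'   `trochanteric_fossa`, `post_condyle_medial`, `post_condyle_lateral`,
#'   `epicondyle_medial`, `epicondyle_lateral`.
#' @param side `"left"` or `"right"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(..., side) {
  pts <- list(...)
  if (length(pts) == 1L && is.list(pts[[1]]) && is.null(names(pts)[1])) {
    pts <- pts[[1]]
  }
  missing <- setdiff(LANDMARK_NAMES, names(pts))
  if (length(missing)) {
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  }
  pts <- lapply(pts[LANDMARK_NAMES], function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p))) {
      stop("each landmark must be a finite length-3 point")
    }
    p
  })
  if (missing(side) || !side %in% c("left", "right")) {
    stop("side must be \"left\" or \"right\"")
  }
  epimid <- (pts$epicondyle_medial + pts$epicondyle_lateral) / 2
  if (vnorm(pts$head_center - epimid) <= 1) {
    stop("head_center coincides with the epicondyle midpoint")
  }
  if (vnorm(pts$post_condyle_medial - pts$post_condyle_lateral) < 1e-9) {
    stop("posterior condyle landmarks coincide")
  }
  structure(c(pts, list(side = side)), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %s femur>\n", x$side))
  for (nm in LANDMARK_NAMES) {
    cat(sprintf("  %-24s %8.2f %8.2f %8.2f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

#' Read landmarks from JSON
#'
#' The file is a JSON object mapping each landmark name to an `[x, y, z]`
#' array in millimetres, plus a `"side"` entry.
#'
#' @param path path to a JSON landmark file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  side <- obj$side
  if (is.null(side)) stop("landmark file lacks a side tag")
  obj$side <- NULL
  landmark_set(lapply(obj, as.numeric), side = side)
}

#' Write landmarks to JSON
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- c(lapply(unclass(landmarks)[LANDMARK_NAMES], as.numeric),
           list(side = landmarks$side))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Apply x -> scale * R x + t to every landmark point.
landmarks_transform <- function(landmarks, R = diag(3), t = c(0, 0, 0), scale = 1) {
  pts <- lapply(unclass(landmarks)[LANDMARK_NAMES], function(p) {
    as.numeric(scale * (R %*% p) + t)
  })
  landmark_set(pts, side = landmarks$side)
}

# Reflect every landmark through the plane (point, normal).
landmarks_mirror <- function(landmarks, point, normal, new_side = landmarks$side) {
  n <- unitize(normal, "mirror normal")
  pts <- lapply(unclass(landmarks)[LANDMARK_NAMES], function(p) {
    p - 2 * sum((p - point) * n) * n
  })
  landmark_set(pts, side = new_side)
}

#' Canonicalize a hip to the right-side convention
#'
#' Left hips are mirrored through their own sagittal plane (the plane through
#' the femoral head center perpendicular to the condylar medial direction) so
#' that every downstream measurement can use a single right-side sign
#' convention: anteversion positive, retroversion negative.  Right hips are
#' returned unchanged.
#'
#' @param landmarks a [landmark_set()].
#' @param mesh optional [surface_mesh()] mirrored with the landmarks.
#' @return a list with elements `landmarks` and `mesh` (the latter `NULL`
#'   when no mesh was supplied).
#' @export
canonicalize_side <- function(landmarks, mesh = NULL) {
  if (!inherits(landmarks, "landmark_set")) stop("landmarks must be a landmark_set")
  if (identical(landmarks$side, "right")) {
    return(list(landmarks = landmarks, mesh = mesh))
  }
  epimid <- (landmarks$epicondyle_medial + landmarks$epicondyle_lateral) / 2
  si <- unitize(landmarks$head_center - epimid, "superior-inferior axis")
  mlr <- landmarks$post_condyle_medial - landmarks$post_condyle_lateral
  ml <- unitize(mlr - sum(mlr * si) * si, "medial-lateral axis")
  o <- landmarks$head_center
  lm2 <- landmarks_mirror(landmarks, o, ml, new_side = "right")
  mesh2 <- if (!is.null(mesh)) mesh_mirror(mesh, o, ml) else NULL
  list(landmarks = lm2, mesh = mesh2)
}
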