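#' Triangulated surface mesh
#'
#' Minimal container for a triangulated surface: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of 1-based vertex
#' indices per triangle.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Rigid (plus uniform scale) transform of a mesh
#'
#' Applies `x -> scale * R x + t` to every vertex.
#'
#' @param mesh a [surface_mesh()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @param scale uniform scale factor.
#' @return the transformed `surface_mesh`.
#' @export
mesh_transform <- function(mesh, R = diag(3), t = c(0, 0, 0), scale = 1) {
  v <- scale * (mesh$vertices %*% t(R))
  v <- sweep(v, 2, -t)    # add t
  surface_mesh(v, mesh$faces)
}

#' Reflect a mesh through a plane
#'
#' Mirrors every vertex through the plane with unit `normal` passing through
#' `point`, and flips triangle winding so outward orientation is preserved.
#'
#' @param mesh a [surface_mesh()].
#' @param point a point on the mirror plane (mm).
#' @param normal plane normal.
#' @return the mirrored `surface_mesh`.
#' @export
mesh_mirror <- function(mesh, point, normal) {
  n <- unitize(normal, "mirror normal")
  d <- (mesh$vertices %*% n) - sum(point * n)
  v <- mesh$vertices - 2 * (d %*% t(n))
  surface_mesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE])
}

# Edge occurrence counts; a watertight manifold has every edge in 2 faces.
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  key <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
  k <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  all(tabulate(match(k, unique(k))) == 2L)
}

#' Intersect a mesh with a plane
#'
#' Computes the closed polyline loops in which the plane with the given
#' `point` and `normal` cuts the triangulated surface.  Intersection points
#' are computed by linear interpolation along mesh edges and chained into
#' ordered loops via shared-edge adjacency.
#'
#' @param mesh a [surface_mesh()].
#' @param point a point on the plane (mm).
#' @param normal plane normal (need not be unit length).
#' @return a list of loops; each loop is a matrix of ordered 3D points (the
#'   first point is not repeated at the end).  Empty list when the plane
#'   misses the mesh.
#' @export
mesh_plane_loops <- function(mesh, point, normal) {
  n <- unitize(normal, "plane normal")
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector(v %*% n) - sum(point * n)
  # nudge on-plane vertices (relative tolerance, so rigid motions of a mesh
  # with an exactly coplanar vertex ring behave identically) so every
  # crossing is a clean sign change
  tol <- 1e-9 * max(abs(d), 1)
  d[abs(d) < tol] <- tol
  pos <- d > 0
  s <- pos[f[, 1]] + pos[f[, 2]] + pos[f[, 3]]
  cross_face <- which(s == 1L | s == 2L)
  if (length(cross_face) == 0L) return(list())

  nv <- nrow(v)
  seg_face <- integer(0); seg_key <- numeric(0)
  seg_pts <- matrix(0, 0, 3)
  for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
    i <- f[cross_face, e[1]]
    j <- f[cross_face, e[2]]
    hit <- pos[i] != pos[j]
    if (!any(hit)) next
    ii <- i[hit]; jj <- j[hit]
    t <- d[ii] / (d[ii] - d[jj])
    p <- v[ii, , drop = FALSE] + t * (v[jj, , drop = FALSE] - v[ii, , drop = FALSE])
    seg_face <- c(seg_face, cross_face[hit])
    seg_key <- c(seg_key, pmin(ii, jj) * (nv + 1) + pmax(ii, jj))
    seg_pts <- rbind(seg_pts, p)
  }
  ord <- order(seg_face)
  seg_face <- seg_face[ord]; seg_key <- seg_key[ord]
  seg_pts <- seg_pts[ord, , drop = FALSE]
  if (length(seg_face) %% 2L != 0L || any(seg_face[c(TRUE, FALSE)] != seg_face[c(FALSE, TRUE)])) {
    stop("open or non-manifold intersection: a cut triangle lacks two crossing edges")
  }
  nseg <- length(seg_face) / 2L
  K <- cbind(seg_key[c(TRUE, FALSE)], seg_key[c(FALSE, TRUE)])
  P1 <- seg_pts[c(TRUE, FALSE), , drop = FALSE]
  P2 <- seg_pts[c(FALSE, TRUE), , drop = FALSE]

  # adjacency: each edge key should appear in exactly two segments
  keys <- unique(as.vector(K))
  kidx <- matrix(match(as.vector(K), keys), ncol = 2)
  occ <- vector("list", length(keys))
  for (s_i in seq_len(nseg)) {
    occ[[kidx[s_i, 1]]] <- c(occ[[kidx[s_i, 1]]], s_i)
    occ[[kidx[s_i, 2]]] <- c(occ[[kidx[s_i, 2]]], s_i)
  }
  if (any(lengths(occ) != 2L)) {
    stop("open or non-manifold intersection: boundary edge crossed by the plane")
  }

  used <- rep(FALSE, nseg)
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    pts <- list()
    cur <- s0
    k_cur <- kidx[s0, 1]
    repeat {
      used[cur] <- TRUE
      if (kidx[cur, 1] == k_cur) {
        pts[[length(pts) + 1L]] <- P1[cur, ]
        k_next <- kidx[cur, 2]
      } else {
        pts[[length(pts) + 1L]] <- P2[cur, ]
        k_next <- kidx[cur, 1]
      }
      cand <- occ[[k_next]]
      nxt <- cand[cand != cur]
      if (length(nxt) != 1L) stop("intersection chaining failed")
      if (used[nxt]) break
      cur <- nxt
      k_cur <- k_next
    }
    loop <- do.call(rbind, pts)
    # drop near-coincident consecutive points (plane through a vertex ring)
    m <- nrow(loop)
    if (m > 1L) {
      nxt <- loop[c(2:m, 1L), , drop = FALSE]
      keep <- rowSums((nxt - loop)^2) > 1e-16
      loop <- loop[keep, , drop = FALSE]
    }
    if (nrow(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Axis-aligned bounds of a mesh
#' @param mesh a [surface_mesh()].
#' @return 2x3 matrix with rows min/max.
#' @export
mesh_bounds <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}
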