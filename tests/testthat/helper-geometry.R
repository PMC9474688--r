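# Shared fixtures: analytic meshes and canonical landmark sets, built in code.

cylinder_mesh <- function(radius = 15, zmin = -40, zmax = 40, res = 64L,
                          nz = 17L) {
  phi <- seq(0, 2 * pi, length.out = res + 1L)[-(res + 1L)]
  zs <- seq(zmin, zmax, length.out = nz)
  verts <- do.call(rbind, lapply(zs, function(z) {
    cbind(radius * cos(phi), radius * sin(phi), z)
  }))
  verts <- rbind(verts, c(0, 0, zmin), c(0, 0, zmax))
  i_bot <- nz * res + 1L; i_top <- nz * res + 2L
  jn <- c(2:res, 1L)
  faces <- list()
  for (i in seq_len(nz - 1L)) {
    a <- (i - 1L) * res + seq_len(res)
    b <- (i - 1L) * res + jn
    cc <- i * res + seq_len(res)
    d <- i * res + jn
    faces[[i]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  faces[[nz]] <- cbind(i_bot, jn, seq_len(res))
  at <- (nz - 1L) * res + seq_len(res)
  faces[[nz + 1L]] <- cbind(at, (nz - 1L) * res + jn, i_top)
  surface_mesh(verts, do.call(rbind, faces))
}

sphere_mesh <- function(radius = 20, center = c(0, 0, 0), res = 96L) {
  nlat <- res %/% 2L
  phi <- seq(0, 2 * pi, length.out = res + 1L)[-(res + 1L)]
  lat <- seq(-pi / 2, pi / 2, length.out = nlat + 1L)
  lat <- lat[-c(1L, nlat + 1L)]
  verts <- do.call(rbind, lapply(lat, function(th) {
    cbind(radius * cos(th) * cos(phi), radius * cos(th) * sin(phi),
          radius * sin(th))
  }))
  nb <- length(lat)
  verts <- rbind(verts, c(0, 0, -radius), c(0, 0, radius))
  verts <- sweep(verts, 2, -center)
  i_bot <- nb * res + 1L; i_top <- nb * res + 2L
  jn <- c(2:res, 1L)
  faces <- list()
  for (i in seq_len(nb - 1L)) {
    a <- (i - 1L) * res + seq_len(res)
    b <- (i - 1L) * res + jn
    cc <- i * res + seq_len(res)
    d <- i * res + jn
    faces[[i]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  faces[[nb]] <- cbind(i_bot, jn, seq_len(res))
  at <- (nb - 1L) * res + seq_len(res)
  faces[[nb + 1L]] <- cbind(at, (nb - 1L) * res + jn, i_top)
  surface_mesh(verts, do.call(rbind, faces))
}

# Canonical aligned landmark set: SI = +y, condylar line along +z (medial at
# +z), so the frame axes are si = (0,1,0), ml = (0,0,1), ap = (-1,0,0).
aligned_landmarks <- function() {
  landmark_set(
    head_center = c(0, 400, 0),
    lesser_trochanter_apex = c(5, 360, 5),
    piriformis_fossa_center = c(-8, 385, 2),
    trochanteric_fossa = c(-10, 382, 4),
    post_condyle_medial = c(-15, 5, 25),
    post_condyle_lateral = c(-15, 5, -25),
    epicondyle_medial = c(0, 0, 40),
    epicondyle_lateral = c(0, 0, -40),
    side = "right")
}

# Landmarks whose frame equals the generator's construction frame
# (ml = +x, ap = -y, si = +z).
construction_landmarks <- function() {
  landmark_set(
    head_center = c(0, 0, 50),
    lesser_trochanter_apex = c(10, 10, 0),
    piriformis_fossa_center = c(-10, 8, 20),
    trochanteric_fossa = c(-12, 10, 22),
    post_condyle_medial = c(25, 15, -330),
    post_condyle_lateral = c(-25, 15, -330),
    epicondyle_medial = c(40, 0, -330),
    epicondyle_lateral = c(-40, 0, -330),
    side = "right")
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rotation_about(ax, stats::runif(1, 10, 170))
}

# Build a cross_section directly from a 2D loop (for arc/line unit tests).
make_section <- function(points2d, height = 10) {
  lm <- construction_landmarks()
  frame <- build_femoral_frame(lm)
  stemversion:::new_cross_section(height, as.matrix(points2d), frame,
                                  lm$lesser_trochanter_apex + height * frame$si_axis)
}

# Minimal planar_contour in an identity chart (u, v in the world xz plane).
make_contour <- function(uv, ml = c(1, 0, 0)) {
  ch <- list(u = c(1, 0, 0), v = c(0, 0, 1), n = c(0, -1, 0),
             origin = c(0, 0, 0), ml = ml)
  uv <- stemversion:::ensure_ccw(as.matrix(uv))
  p3 <- t(apply(uv, 1, function(q) ch$origin + q[1] * ch$u + q[2] * ch$v))
  structure(list(points3d = p3, uv = uv, plane_ref = NULL, chart = ch),
            class = "planar_contour")
}

# 2D pixel-count area oracle for a polygon.
pixel_area <- function(poly, h = 0.1) {
  bb <- rbind(apply(poly, 2, min) - 2 * h, apply(poly, 2, max) + 2 * h)
  xs <- seq(bb[1, 1], bb[2, 1], by = h)
  ys <- seq(bb[1, 2], bb[2, 2], by = h)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  sum(stemversion:::points_in_polygon(px, py, poly)) * h * h
}
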