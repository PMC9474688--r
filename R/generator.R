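# Constructive parametric proximal-femur generator with exact ground truth.
#
# The bone is modelled as a stack of analytic horizontal sections in a
# canonical right-femur construction frame (x = medial, y = posterior,
# z = superior; so the anatomical frame built from the emitted landmarks is
# ml = +x, ap = -y, si = +z):
#   * distal shaft: circle of radius `shaft_radius`;
#   * calcar zone (from 5 mm below to 14 mm above the lesser-trochanter
#     apex): a fixed ellipse elongated along the neck azimuth -- sections in
#     this zone are z-invariant so the 5 and 10 mm measurement levels see
#     identical geometry;
#   * neck: the horizontal sections of an elliptical cylinder tilted by the
#     neck-shaft angle and rotated about SI by the native anteversion;
#   * head: a sphere centred on the neck axis.
# Landmarks are emitted analytically from the construction, so ground truth
# is exact rather than annotated.

#' Parametric femur specification
#'
#' @param nfa_deg native femoral (neck) anteversion, degrees; ground truth.
#' @param neck_shaft_angle_deg neck-shaft angle in the coronal sense
#'   (default 130; the neck axis is elevated `neck_shaft_angle_deg - 90`
#'   degrees out of the axial plane).
#' @param head_radius femoral head radius, mm.
#' @param neck_radii length-2 semi-axes of the neck cross-section, mm: first
#'   the AP-ish semi-axis, second the semi-axis in the neck's superoinferior
#'   plane (controls the axial elongation of the neck-base sections).
#' @param shaft_radius distal shaft radius, mm.
#' @param cortical_thickness nominal cortical wall thickness, mm (metadata;
#'   the generator models the periosteal surface).
#' @param lt_height_offset z position of the lesser-trochanter apex in the
#'   construction frame, mm.
#' @param fossa_posterior_offset posteriorization of the trochanteric fossa
#'   along the bone surface, mm (emulates the DDH-like posterior fossa).
#' @param condylar_torsion_deg rotation of the posterior condylar axis about
#'   SI, degrees, in the anteversion-positive sense.  The emitted neck
#'   azimuth is `nfa_deg + condylar_torsion_deg` so the anteversion measured
#'   against the PCA remains `nfa_deg`.
#' @param side `"right"` or `"left"` (left femurs are the exact sagittal
#'   mirror of the right construction).
#' @param mesh_resolution number of azimuthal segments (>= 16).
#' @param seed retained for interface symmetry; the construction is fully
#'   deterministic.
#' @return an object of class `femur_spec`.
#' @export
femur_spec <- function(nfa_deg = 30, neck_shaft_angle_deg = 130,
                       head_radius = 22, neck_radii = c(13, 13),
                       shaft_radius = 14, cortical_thickness = 5,
                       lt_height_offset = 0, fossa_posterior_offset = 6,
                       condylar_torsion_deg = 0, side = "right",
                       mesh_resolution = 72, seed = 1L) {
  if (!is.finite(nfa_deg) || nfa_deg < -30 || nfa_deg > 80) {
    stop("nfa_deg must lie in [-30, 80]")
  }
  if (any(c(head_radius, neck_radii, shaft_radius, cortical_thickness) <= 0)) {
    stop("radii and thicknesses must be positive")
  }
  if (mesh_resolution < 16L) stop("mesh_resolution must be >= 16 segments")
  if (!side %in% c("left", "right")) stop("side must be \"left\" or \"right\"")
  if (neck_shaft_angle_deg <= 95 || neck_shaft_angle_deg >= 175) {
    stop("neck_shaft_angle_deg must lie in (95, 175)")
  }
  structure(list(nfa_deg = nfa_deg,
                 neck_shaft_angle_deg = neck_shaft_angle_deg,
                 head_radius = head_radius,
                 neck_radii = as.numeric(neck_radii),
                 shaft_radius = shaft_radius,
                 cortical_thickness = cortical_thickness,
                 lt_height_offset = lt_height_offset,
                 fossa_posterior_offset = fossa_posterior_offset,
                 condylar_torsion_deg = condylar_torsion_deg,
                 side = side, mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "femur_spec")
}

# Derived construction constants.
femur_geometry <- function(spec) {
  z_lt <- spec$lt_height_offset
  elev <- deg2rad(spec$neck_shaft_angle_deg - 90)
  rot <- deg2rad(spec$nfa_deg + spec$condylar_torsion_deg)
  az <- c(cos(rot), -sin(rot))          # neck azimuth (anterior = -y)
  a1 <- spec$neck_radii[2] / sin(elev)  # axial semi-major of the tilted neck
  b1 <- spec$neck_radii[1]
  z_nb <- z_lt + 14                     # neck-base level (top of calcar zone)
  L <- 52                               # neck-axis length to the head centre
  hz <- z_nb + L * sin(elev)
  hxy <- L * cos(elev) * az
  list(z_lt = z_lt, elev = elev, rot = rot, az = az, a1 = a1, b1 = b1,
       rs = spec$shaft_radius, z_nb = z_nb, head_z = hz, head_xy = hxy,
       rh = spec$head_radius, z_bot = z_lt - 45, z_top = hz + spec$head_radius,
       neck_axis_dir = c(cos(elev) * az, sin(elev)),
       neck_axis_point = c(0, 0, z_nb))
}

# Analytic horizontal section parts at height z: list of ellipses
# (center, a, b, rot) in the construction frame.
femur_section_parts <- function(g, z) {
  parts <- list()
  if (z <= g$z_nb) {
    blend_lo <- g$z_lt - 15; blend_hi <- g$z_lt - 5
    if (z >= blend_hi) {
      parts[[1]] <- list(center = c(0, 0), a = g$a1, b = g$b1, rot = g$rot)
    } else if (z >= blend_lo) {
      w <- (z - blend_lo) / (blend_hi - blend_lo)
      parts[[1]] <- list(center = c(0, 0),
                         a = g$rs + w * (g$a1 - g$rs),
                         b = g$rs + w * (g$b1 - g$rs), rot = g$rot)
    } else {
      parts[[1]] <- list(center = c(0, 0), a = g$rs, b = g$rs, rot = 0)
    }
  } else if (z <= g$head_z) {
    q <- (z - g$z_nb) / tan(g$elev) * g$az
    parts[[1]] <- list(center = q, a = g$a1, b = g$b1, rot = g$rot)
  }
  dzh <- z - g$head_z
  if (abs(dzh) < g$rh) {
    parts[[length(parts) + 1L]] <- list(center = g$head_xy,
                                        a = sqrt(g$rh^2 - dzh^2),
                                        b = sqrt(g$rh^2 - dzh^2), rot = 0)
  }
  parts
}

# Reference (star-shape) centre of the section at height z.
femur_section_center <- function(g, z) {
  if (z <= g$z_nb) c(0, 0)
  else if (z <= g$head_z) (z - g$z_nb) / tan(g$elev) * g$az
  else g$head_xy
}

# Radial extent from c0 along unit directions (cos(phi), sin(phi)) to the
# union boundary of the section parts.
femur_section_radius <- function(g, z, phi, c0 = femur_section_center(g, z)) {
  parts <- femur_section_parts(g, z)
  if (length(parts) == 0L) return(rep(0, length(phi)))
  ux <- cos(phi); uy <- sin(phi)
  r <- rep(0, length(phi))
  for (p in parts) {
    cr <- cos(p$rot); sr <- sin(p$rot)
    wx <- c0[1] - p$center[1]; wy <- c0[2] - p$center[2]
    # rotate by -rot into the ellipse frame (azimuth rotation is -rot in xy)
    w1 <- (cr * wx - sr * wy) / p$a
    w2 <- (sr * wx + cr * wy) / p$b
    v1 <- (cr * ux - sr * uy) / p$a
    v2 <- (sr * ux + cr * uy) / p$b
    A <- v1^2 + v2^2
    B <- w1 * v1 + w2 * v2
    C <- w1^2 + w2^2 - 1
    disc <- B^2 - A * C
    ok <- disc >= 0
    t <- rep(0, length(phi))
    t[ok] <- (-B[ok] + sqrt(disc[ok])) / A[ok]
    t[t < 0] <- 0
    r <- pmax(r, t)
  }
  r
}

# Point on the generated surface at height z and polar angle phi (degrees,
# measured about the section centre in the construction xy plane).
femur_surface_point <- function(g, z, phi_deg) {
  c0 <- femur_section_center(g, z)
  phi <- deg2rad(phi_deg)
  r <- femur_section_radius(g, z, phi, c0)
  c(c0 + r * c(cos(phi), sin(phi)), z)
}

#' Generate a parametric proximal-femur mesh with landmarks and ground truth
#'
#' Builds a closed triangulated surface by sweeping the analytic horizontal
#' sections described in the package vignette, and emits the landmark set
#' and ground truth analytically from the construction.  Deterministic for a
#' given spec.
#'
#' @param spec a [femur_spec()].
#' @return a list of class `virtual_femur` with elements `mesh`
#'   ([surface_mesh()]), `landmarks` ([landmark_set()]), `truth` (list with
#'   `nfa_deg`, the neck [axis3d()] and the derived construction geometry)
#'   and `spec`.
#' @export
generate_femur <- function(spec) {
  if (!inherits(spec, "femur_spec")) stop("spec must be a femur_spec")
  g <- femur_geometry(spec)
  res <- spec$mesh_resolution
  phi <- seq(0, 2 * pi, length.out = res + 1L)[-(res + 1L)]

  zs <- sort(unique(c(seq(g$z_bot, g$z_top - 0.75, by = 1.25),
                      g$z_lt - 15, g$z_lt - 5, g$z_nb,
                      g$head_z - g$rh + 0.25, g$head_z, g$z_top - 0.75)))
  zs <- zs[zs >= g$z_bot & zs <= g$z_top - 0.5]
  nz <- length(zs)

  verts <- matrix(0, nz * res + 2L, 3L)
  for (i in seq_len(nz)) {
    c0 <- femur_section_center(g, zs[i])
    r <- femur_section_radius(g, zs[i], phi, c0)
    rows <- ((i - 1L) * res + 1L):(i * res)
    verts[rows, 1] <- c0[1] + r * cos(phi)
    verts[rows, 2] <- c0[2] + r * sin(phi)
    verts[rows, 3] <- zs[i]
  }
  i_bot <- nz * res + 1L
  i_top <- nz * res + 2L
  verts[i_bot, ] <- c(femur_section_center(g, zs[1]), zs[1])
  verts[i_top, ] <- c(g$head_xy, g$z_top)

  jn <- c(2:res, 1L)
  odd <- seq_len(res) %% 2L == 1L
  faces <- vector("list", nz + 1L)
  for (i in seq_len(nz - 1L)) {
    a <- (i - 1L) * res + seq_len(res)
    b <- (i - 1L) * res + jn
    cc <- i * res + seq_len(res)
    d <- i * res + jn
    # alternate the quad diagonal by column parity so the triangulation is
    # mirror-symmetric (keeps symmetric bones exactly symmetric as meshes)
    faces[[i]] <- rbind(cbind(a[odd], b[odd], d[odd]),
                        cbind(a[odd], d[odd], cc[odd]),
                        cbind(a[!odd], b[!odd], cc[!odd]),
                        cbind(b[!odd], d[!odd], cc[!odd]))
  }
  a1r <- seq_len(res); b1r <- jn
  faces[[nz]] <- cbind(i_bot, b1r, a1r)
  at <- (nz - 1L) * res + seq_len(res); bt <- (nz - 1L) * res + jn
  faces[[nz + 1L]] <- cbind(at, bt, i_top)
  mesh <- surface_mesh(verts, do.call(rbind, faces))

  rot_deg <- rad2deg(g$rot)
  # polar angle of the section's lateral extreme (support point in -x);
  # the piriformis fossa sits posterior of it along the surface so the
  # osteotomy plane tracks the neck at any anteversion
  tl <- atan2(-g$b1 * sin(g$rot), -g$a1 * cos(g$rot))
  lat_pt <- c(g$a1 * cos(tl) * cos(g$rot) + g$b1 * sin(tl) * sin(g$rot),
              -g$a1 * cos(tl) * sin(g$rot) + g$b1 * sin(tl) * cos(g$rot))
  phi_lat <- rad2deg(atan2(lat_pt[2], lat_pt[1]))
  r_lat <- vnorm(lat_pt)
  pf_phi <- phi_lat - rad2deg(8 / r_lat)
  tf_phi0 <- phi_lat - rad2deg(4 / r_lat)
  r_tf <- femur_section_radius(g, g$z_lt + 22, deg2rad(tf_phi0))
  dphi <- rad2deg(spec$fossa_posterior_offset / max(r_tf, 1))
  epimid <- c(g$head_xy, g$z_lt - 380)
  Rt <- rotation_about(c(0, 0, 1), -spec$condylar_torsion_deg)
  off <- function(v) as.numeric(Rt %*% v)
  landmarks <- landmark_set(
    head_center = c(g$head_xy, g$head_z),
    lesser_trochanter_apex = femur_surface_point(g, g$z_lt, 45 - rot_deg),
    piriformis_fossa_center = femur_surface_point(g, g$z_lt + 20, pf_phi),
    trochanteric_fossa = femur_surface_point(g, g$z_lt + 22, tf_phi0 - dphi),
    post_condyle_medial = epimid + off(c(25, 15, -5)),
    post_condyle_lateral = epimid + off(c(-25, 15, -5)),
    epicondyle_medial = epimid + off(c(40, 0, 0)),
    epicondyle_lateral = epimid + off(c(-40, 0, 0)),
    side = "right")

  truth <- list(nfa_deg = spec$nfa_deg,
                neck_axis = axis3d(g$neck_axis_point, g$neck_axis_dir),
                geometry = g)

  if (spec$side == "left") {
    o <- landmarks$head_center
    m <- c(1, 0, 0)
    mesh <- mesh_mirror(mesh, o, m)
    landmarks <- landmarks_mirror(landmarks, o, m, new_side = "left")
    na <- truth$neck_axis
    truth$neck_axis <- axis3d(
      na$point - 2 * sum((na$point - o) * m) * m,
      na$direction - 2 * sum(na$direction * m) * m)
  }

  structure(list(mesh = mesh, landmarks = landmarks, truth = truth, spec = spec),
            class = "virtual_femur")
}

#' @export
print.virtual_femur <- function(x, ...) {
  cat(sprintf("<virtual_femur: %s side, anteversion %.1f deg, %d vertices>\n",
              x$spec$side, x$spec$nfa_deg, nrow(x$mesh$vertices)))
  invisible(x)
}

#' Implanted-stem specification
#'
#' @param stem_anteversion_deg ground-truth stem anteversion, degrees,
#'   measured from the posterior condylar axis in the axial plane.
#' @param neck_length stem neck length, mm (metadata).
#' @param neck_inclination_deg elevation of the stem neck axis out of the
#'   axial plane, degrees (90 is degenerate: the axis is parallel to SI).
#' @return an object of class `stem_spec`.
#' @export
stem_spec <- function(stem_anteversion_deg = 25, neck_length = 35,
                      neck_inclination_deg = 40) {
  if (!is.finite(stem_anteversion_deg) ||
      stem_anteversion_deg <= -180 || stem_anteversion_deg > 180) {
    stop("stem_anteversion_deg must be finite and in (-180, 180]")
  }
  structure(list(stem_anteversion_deg = stem_anteversion_deg,
                 neck_length = neck_length,
                 neck_inclination_deg = neck_inclination_deg),
            class = "stem_spec")
}

#' Generate an implanted-stem neck axis with known anteversion
#'
#' The axis is anchored at the femur's neck-base canal centre and directed
#' with the requested inclination out of the axial plane and the requested
#' anteversion azimuth measured from the posterior condylar axis, so that
#' [psa_from_stem()] recovers `stem_anteversion_deg` exactly.
#'
#' @param spec a [stem_spec()].
#' @param femur a `virtual_femur` from [generate_femur()].
#' @return an [axis3d()] in the femur's own coordinates.
#' @export
generate_stem <- function(spec, femur) {
  if (!inherits(spec, "stem_spec")) stop("spec must be a stem_spec")
  cs <- canonicalize_side(femur$landmarks)
  lm <- cs$landmarks
  frame <- build_femoral_frame(lm)
  pca <- posterior_condylar_axis(lm)
  p2 <- axial_coords(pca$direction, frame)
  p2 <- p2 / vnorm(p2)
  al <- deg2rad(spec$stem_anteversion_deg)
  d2 <- c(cos(al) * p2[1] - sin(al) * p2[2],
          cos(al) * p2[2] + sin(al) * p2[1])
  incl <- deg2rad(spec$neck_inclination_deg)
  dir <- cos(incl) * (d2[1] * frame$ml_axis + d2[2] * frame$ap_axis) +
    sin(incl) * frame$si_axis
  anchor <- femur$truth$neck_axis$point
  if (femur$landmarks$side == "left") {
    o <- femur$landmarks$head_center
    epimid <- (femur$landmarks$epicondyle_medial + femur$landmarks$epicondyle_lateral) / 2
    si <- unitize(femur$landmarks$head_center - epimid)
    mlr <- femur$landmarks$post_condyle_medial - femur$landmarks$post_condyle_lateral
    m <- unitize(mlr - sum(mlr * si) * si)
    dir <- dir - 2 * sum(dir * m) * m
  }
  axis3d(anchor, dir)
}

#' Voxelize a closed mesh into a binary occupancy grid
#'
#' Inside/outside is evaluated per voxel centre by even--odd counting against
#' the mesh's planar cross-section at each grid layer; the grid covers the
#' mesh bounds padded by two voxels.
#'
#' @param mesh a closed [surface_mesh()], axes aligned with the grid.
#' @param spacing voxel size, mm (default emulates a 0.98 mm in-plane / 1 mm
#'   slice CT protocol).
#' @return a [voxel_image()] with logical occupancy data.
#' @export
voxelize <- function(mesh, spacing = c(0.98, 0.98, 1.0)) {
  if (!mesh_is_closed(mesh)) stop("open mesh: voxelization requires a watertight surface")
  b <- mesh_bounds(mesh)
  origin <- b[1, ] - 2 * spacing
  n <- ceiling((b[2, ] - origin) / spacing) + 2L
  xs <- origin[1] + (seq_len(n[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * spacing[2]
  grid <- array(FALSE, dim = n)
  px <- rep(xs, times = n[2])
  py <- rep(ys, each = n[1])
  for (k in seq_len(n[3])) {
    zk <- origin[3] + (k - 1) * spacing[3]
    loops <- tryCatch(mesh_plane_loops(mesh, c(0, 0, zk), c(0, 0, 1)),
                      error = function(e) list())
    if (length(loops) == 0L) next
    inside <- rep(FALSE, length(px))
    for (L in loops) {
      poly <- L[, 1:2, drop = FALSE]
      bb <- rbind(apply(poly, 2, min), apply(poly, 2, max))
      sel <- px >= bb[1, 1] & px <= bb[2, 1] & py >= bb[1, 2] & py <= bb[2, 2]
      if (!any(sel)) next
      inside[sel] <- xor(inside[sel],
                         points_in_polygon(px[sel], py[sel], poly))
    }
    grid[, , k] <- matrix(inside, n[1], n[2])
  }
  voxel_image(grid, spacing, origin)
}

#' Virtual cohort specification
#'
#' @param n number of hips.
#' @param psa_mean,psa_sd cohort stem-anteversion moments, degrees.
#' @param methods per-method calibration table (columns `method`,
#'   `height_mm`, `angle_mean`, `angle_sd`, `r`); defaults to the shipped
#'   reference calibration (see [table2_defaults()]).
#' @param mode `"geometric"` (parametric bones, measured end-to-end) or
#'   `"statistical"` (bivariate-normal angle draws).
#' @param seed RNG seed.
#' @param stem_noise_sd geometric mode: SD of the stem-minus-native
#'   anteversion deviation, degrees.
#' @param nfa_range geometric mode: truncation bounds for native anteversion,
#'   degrees.
#' @param jitter_sd geometric mode: relative SD of per-subject size jitter.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 28, psa_mean = NULL, psa_sd = NULL, methods = NULL,
                        mode = c("statistical", "geometric"), seed = 1L,
                        stem_noise_sd = 5, nfa_range = c(-10, 70),
                        jitter_sd = 0.03) {
  mode <- match.arg(mode)
  def <- table2_defaults()
  if (is.null(psa_mean)) psa_mean <- def$psa_mean
  if (is.null(psa_sd)) psa_sd <- def$psa_sd
  if (is.null(methods)) methods <- def$methods
  if (n < 3L) stop("cohort needs n >= 3")
  if (psa_sd <= 0 || any(methods$angle_sd <= 0)) stop("SDs must be positive")
  if (any(abs(methods$r) > 1)) {
    stop("non-positive-definite implied covariance: |r| must be <= 1")
  }
  structure(list(n = as.integer(n), psa_mean = psa_mean, psa_sd = psa_sd,
                 methods = methods, mode = mode, seed = as.integer(seed),
                 stem_noise_sd = stem_noise_sd, nfa_range = nfa_range,
                 jitter_sd = jitter_sd),
            class = "cohort_spec")
}

#' Shipped reference calibration for the statistical cohort generator
#'
#' Reads the per-method angle means/SDs and correlations with PSA that ship
#' with the package (`extdata/table2_reference.csv`).
#'
#' @return a list with `psa_mean`, `psa_sd` and the `methods` data frame.
#' @export
table2_defaults <- function() {
  path <- system.file("extdata", "table2_reference.csv", package = "stemversion",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  psa <- tab[tab$method == "PSA", ]
  list(psa_mean = psa$angle_mean, psa_sd = psa$angle_sd,
       methods = tab[tab$method != "PSA", ])
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

sample_crowe <- function(n) {
  sample(c("I", "II", "III", "IV"), n, replace = TRUE,
         prob = c(17, 3, 3, 5) / 28)
}

#' Generate a geometric virtual cohort
#'
#' Draws native anteversion from a truncated normal with the cohort's PSA
#' moments, jitters the size parameters per subject, sets the implanted stem
#' anteversion to the native anteversion plus normal noise, and returns fully
#' constructed virtual subjects (mesh, landmarks, stem axis, ground truth).
#'
#' @param cohort a [cohort_spec()] with `mode = "geometric"`.
#' @param mesh_resolution azimuthal mesh resolution passed to the femur
#'   generator.
#' @return a list of `virtual_subject` objects.
#' @export
generate_geometric_cohort <- function(cohort, mesh_resolution = 72L) {
  if (!inherits(cohort, "cohort_spec")) stop("cohort must be a cohort_spec")
  if (cohort$mode != "geometric") stop("cohort mode must be \"geometric\"")
  set.seed(cohort$seed)
  nfa <- rtruncnorm1(cohort$n, cohort$psa_mean, cohort$psa_sd,
                     cohort$nfa_range[1], cohort$nfa_range[2])
  sides <- sample(c("right", "left"), cohort$n, replace = TRUE)
  crowe <- sample_crowe(cohort$n)
  lapply(seq_len(cohort$n), function(i) {
    jit <- function(x) x * (1 + stats::rnorm(1, 0, cohort$jitter_sd))
    fs <- femur_spec(nfa_deg = nfa[i],
                     head_radius = jit(22),
                     neck_radii = c(jit(13), jit(13)),
                     shaft_radius = jit(14),
                     fossa_posterior_offset = max(0.5, stats::rnorm(1, 6, 1.5)),
                     side = sides[i], mesh_resolution = mesh_resolution)
    fem <- generate_femur(fs)
    ss <- stem_spec(stem_anteversion_deg =
                      nfa[i] + stats::rnorm(1, 0, cohort$stem_noise_sd))
    stem <- generate_stem(ss, fem)
    structure(list(hip_id = sprintf("hip%03d", i),
                   crowe_type = crowe[i],
                   femur_spec = fs, stem_spec = ss,
                   mesh = fem$mesh, landmarks = fem$landmarks,
                   stem_neck_axis = stem,
                   truth = list(nfa_deg = nfa[i],
                                psa_deg = ss$stem_anteversion_deg)),
              class = "virtual_subject")
  })
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf("<virtual_subject %s: %s side, NFA %.1f deg, stem %.1f deg>\n",
              x$hip_id, x$landmarks$side, x$truth$nfa_deg, x$truth$psa_deg))
  invisible(x)
}

#' Generate a statistical virtual cohort
#'
#' Draws one PSA value per hip from `N(psa_mean, psa_sd^2)` and, for each
#' method cell, an angle from the bivariate normal implied by the cell's
#' mean, SD and target correlation with PSA (conditional-normal
#' construction); with `r = 1` and equal SDs the method equals PSA plus a
#' constant, exactly.
#'
#' @param cohort a [cohort_spec()] with `mode = "statistical"`.
#' @return a cohort data frame (one row per hip, canonical columns).
#' @export
generate_statistical_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort_spec")) stop("cohort must be a cohort_spec")
  if (cohort$mode != "statistical") stop("cohort mode must be \"statistical\"")
  set.seed(cohort$seed)
  n <- cohort$n
  psa <- stats::rnorm(n, cohort$psa_mean, cohort$psa_sd)
  rec <- data.frame(hip_id = sprintf("hip%03d", seq_len(n)),
                    side = sample(c("right", "left"), n, replace = TRUE),
                    crowe_type = sample_crowe(n),
                    psa_deg = psa, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort$methods))) {
    m <- cohort$methods[i, ]
    col <- METHOD_COLUMNS$column[METHOD_COLUMNS$method == m$method &
                                   METHOD_COLUMNS$height_mm == m$height_mm]
    z <- psa - cohort$psa_mean
    rec[[col]] <- m$angle_mean + m$r * (m$angle_sd / cohort$psa_sd) * z +
      sqrt(max(0, 1 - m$r^2)) * m$angle_sd * stats::rnorm(n)
  }
  rec$truth_nfa_deg <- NA_real_
  rec
}

#' Measure one virtual subject end-to-end
#'
#' Canonicalizes the side, builds the anatomical frame and computes AM-CT,
#' AM-3D and AT-3D at the requested heights plus PSA, returning one cohort
#' row.
#'
#' @param subject a `virtual_subject`.
#' @param heights measurement heights in millimetres.
#' @return a one-row cohort data frame.
#' @export
measure_subject <- function(subject, heights = c(5, 10)) {
  cs <- canonicalize_side(subject$landmarks, subject$mesh)
  lm <- cs$landmarks; mesh <- cs$mesh
  stem <- subject$stem_neck_axis
  if (subject$landmarks$side == "left") {
    o <- subject$landmarks$head_center
    epimid <- (subject$landmarks$epicondyle_medial +
                 subject$landmarks$epicondyle_lateral) / 2
    si <- unitize(subject$landmarks$head_center - epimid)
    mlr <- subject$landmarks$post_condyle_medial -
      subject$landmarks$post_condyle_lateral
    m <- unitize(mlr - sum(mlr * si) * si)
    stem <- axis3d(stem$point - 2 * sum((stem$point - o) * m) * m,
                   stem$direction - 2 * sum(stem$direction * m) * m)
  }
  frame <- build_femoral_frame(lm)
  row <- data.frame(hip_id = subject$hip_id, side = subject$landmarks$side,
                    crowe_type = subject$crowe_type,
                    psa_deg = psa_from_stem(stem, frame, lm)$angle_deg,
                    stringsAsFactors = FALSE)
  safe <- function(expr) {
    tryCatch(expr$angle_deg, error = function(e) {
      warning(sprintf("%s: measurement failed (%s)", subject$hip_id,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }
  for (h in heights) {
    row[[sprintf("am_ct_%g", h)]] <- safe(am_ct(mesh, frame, lm, h))
    row[[sprintf("am_3d_%g", h)]] <- safe(am_3d(mesh, lm, frame, h))
    row[[sprintf("at_3d_%g", h)]] <- safe(at_3d(mesh, lm, frame, h))
  }
  row$truth_nfa_deg <- subject$truth$nfa_deg
  row
}

#' Measure a list of virtual subjects
#'
#' @param subjects list of `virtual_subject` objects.
#' @param heights measurement heights in millimetres.
#' @return a cohort data frame, one row per subject.
#' @export
measure_cohort <- function(subjects, heights = c(5, 10)) {
  do.call(rbind, lapply(subjects, measure_subject, heights = heights))
}
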