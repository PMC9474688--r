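# Internal geometry helpers shared across modules.

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x, what = "vector") {
  n <- vnorm(x)
  if (!is.finite(n) || n < 1e-12) {
    stop(sprintf("cannot normalize degenerate %s (norm %.3g)", what, n),
         call. = FALSE)
  }
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the (not necessarily unit)
#' `axis`, right-hand rule.
#'
#' @param axis length-3 numeric axis of rotation.
#' @param angle_deg rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- unitize(axis, "rotation axis")
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Signed polygon area, shoelace; positive for counter-clockwise loops.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Reorder a closed loop (first point not repeated) to counter-clockwise.
ensure_ccw <- function(p) {
  if (polygon_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Area centroid of a simple polygon (shoelace moments).
polygon_centroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

# Outward unit vertex normals of a CCW simple polygon (mean of edge normals).
polygon_vertex_normals <- function(p) {
  n <- nrow(p)
  e <- p[c(2:n, 1L), , drop = FALSE] - p
  en <- cbind(e[, 2], -e[, 1])           # outward for CCW orientation
  len <- sqrt(rowSums(en^2))
  len[len < 1e-300] <- 1
  en <- en / len
  vn <- en + en[c(n, 1:(n - 1)), , drop = FALSE]
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-300] <- 1
  vn / len
}

# Smallest absolute angular difference in degrees.
ang_diff_deg <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

# Indices of the contiguous run of TRUE values (on a closed loop) that
# contains `anchor`; falls back to the longest run when anchor fails.
contiguous_run <- function(keep, anchor = NULL) {
  n <- length(keep)
  if (!any(keep)) return(integer(0))
  if (all(keep)) return(seq_len(n))
  r <- rle(c(keep, keep))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(which(r$values & starts <= n), function(k) {
    ((starts[k]:(ends[k])) - 1L) %% n + 1L
  })
  runs <- runs[!duplicated(lapply(runs, sort))]
  # a run that wraps past index n subsumes its truncated prefix; drop subsets
  sets <- lapply(runs, sort)
  subset_of_other <- vapply(seq_along(sets), function(i) {
    any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[i]]) < length(sets[[j]]) && all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  runs <- runs[!subset_of_other]
  if (!is.null(anchor)) {
    hit <- vapply(runs, function(ix) anchor %in% ix, logical(1))
    if (any(hit)) {
      runs <- runs[hit]
      return(runs[[which.max(lengths(runs))]])
    }
  }
  runs[[which.max(lengths(runs))]]
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}
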