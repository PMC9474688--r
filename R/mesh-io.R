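# STL / PLY mesh input and output.  Units are millimetres throughout.

#' Read a surface mesh from STL (ASCII or binary)
#'
#' Binary versus ASCII is detected from the file size implied by the binary
#' triangle count.  Duplicate vertices shared by neighbouring triangles are
#' merged so the result is an indexed, manifold-capable mesh.
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(ntri) == 1L && !is.na(ntri) && size == 84 + 50 * as.numeric(ntri)) {
    tri <- matrix(0, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
      invisible(readBin(con, "raw", 2L))
    }
    return(stl_index(tri))
  }
  close(con)
  on.exit()
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("not a valid ASCII STL file: ", path)
  }
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }))
  stl_index(nums)
}

# Merge duplicated triangle-soup vertices into an indexed mesh.
stl_index <- function(tri) {
  key <- apply(tri, 1, function(p) paste(sprintf("%.9g", p), collapse = "_"))
  idx <- match(key, key[!duplicated(key)])
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a surface mesh to STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write the 50-byte-per-triangle binary layout instead of
#'   ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len < 1e-300] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con,
               size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    lines <- character(0)
    out <- file(path, "w")
    on.exit(close(out))
    writeLines("solid mesh", out)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop",
        "  endfacet"), out)
    }
    writeLines("endsolid mesh", out)
  }
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' Supports the common `element vertex` / `element face` layout with float
#' vertex properties and a leading list-count face property.
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || trimws(txt[1]) != "ply") stop("not a PLY file: ", path)
  if (!grepl("ascii", txt[2])) stop("only ASCII PLY is supported")
  endh <- match("end_header", trimws(txt))
  hdr <- txt[seq_len(endh)]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  body <- txt[(endh + 1L):length(txt)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  surface_mesh(verts, faces)
}

#' Write an ASCII PLY mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
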