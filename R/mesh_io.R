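#' Read and write surface meshes (STL / PLY)
#'
#' Minimal readers and writers for the two interchange formats used throughout
#' the pipeline. STL is written binary (the de-facto clinical export format);
#' both binary and ASCII STL are read. PLY is read/written in ASCII form and
#' carries optional per-vertex RGB colours (used for the false-colour deviation
#' export).
#'
#' STL stores a triangle soup; on read, coincident vertices are merged exactly
#' (bitwise-equal coordinates) so that region/landmark indices remain usable.
#'
#' @param mesh a [tri_mesh()].
#' @param path file path.
#' @return `read_*` return a [tri_mesh()]; writers return `path` invisibly.
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_stl <- function(mesh, path) {
  stopifnot_mesh(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  nrm <- mesh_face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # 12 floats + uint16 per facet
  block <- matrix(0, 12L, nf)
  block[1:3, ] <- t(nrm)
  block[4:6, ] <- t(v[f[, 1L], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2L], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3L], , drop = FALSE])
  for (i in seq_len(nf)) {
    writeBin(block[, i], con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  head <- head[head != as.raw(0)]
  ascii <- all(head < as.raw(128))
  txt <- if (ascii) rawToChar(head) else ""
  if (ascii && grepl("^\\s*solid", txt) && grepl("facet", txt)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n = nf * 50L)
  # unpack 50-byte records: 12 little-endian floats then 2 attribute bytes
  idx <- rep(seq_len(nf) - 1L, each = 48L) * 50L +
    rep(seq_len(48L), times = nf)
  floats <- readBin(rec[idx], "double", n = nf * 12L, size = 4L,
                    endian = "little")
  m <- matrix(floats, nrow = 12L)
  tris <- rbind(t(m[4:6, , drop = FALSE]), t(m[7:9, , drop = FALSE]),
                t(m[10:12, , drop = FALSE]))
  ord <- as.vector(t(matrix(seq_len(3L * nf), nrow = nf)))
  soup_to_mesh(tris[ord, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  soup_to_mesh(do.call(rbind, nums))
}

# triangle soup (3 rows per face, in order) -> merged tri_mesh
soup_to_mesh <- function(tris) {
  key <- paste(tris[, 1L], tris[, 2L], tris[, 3L])
  uid <- !duplicated(key)
  verts <- tris[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  tri_mesh(verts, matrix(idx, ncol = 3L, byrow = TRUE))
}

#' @rdname mesh_io
#' @param colors optional n x 3 integer matrix of per-vertex RGB in 0..255.
#' @export
write_ply <- function(mesh, path, colors = NULL) {
  stopifnot_mesh(mesh)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           "comment maxillomorph surface export",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(colors)) {
    stopifnot(nrow(colors) == nv, ncol(colors) == 3L)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vtxt <- if (is.null(colors)) {
    sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L], mesh$vertices[, 2L],
            mesh$vertices[, 3L])
  } else {
    sprintf("%.9g %.9g %.9g %d %d %d", mesh$vertices[, 1L],
            mesh$vertices[, 2L], mesh$vertices[, 3L],
            as.integer(colors[, 1L]), as.integer(colors[, 2L]),
            as.integer(colors[, 3L]))
  }
  ftxt <- sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                  mesh$faces[, 3L] - 1L)
  writeLines(c(hdr, vtxt, ftxt), path)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file (no end_header)")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1L]))
  vlines <- lines[(end + 1L):(end + nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                              function(x) as.numeric(x[1:3])))
  flines <- lines[(end + nv + 1L):(end + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                              function(x) as.integer(x[2:4]) + 1L))
  tri_mesh(vm, fm)
}

#' Landmark sets and region labels on disk
#'
#' Landmarks are stored as JSON objects mapping a landmark name (`A`, `IOr`,
#' `IOl`, and `J`/`O`/`M`/`X` suffixed `_left` / `_right`) to an `[x, y, z]`
#' position in mm. Region labels map a region id (`R1_left`, ..., `R4_right`)
#' to a 0-based list of face indices of the reference mesh.
#'
#' @param landmarks named list of length-3 numeric vectors.
#' @param path file path.
#' @name landmark_io
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmarks <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}

#' @rdname landmark_io
#' @param regions named list of 1-based integer face-index vectors.
#' @export
write_region_labels <- function(regions, path) {
  jsonlite::write_json(lapply(regions, function(i) as.integer(i) - 1L), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_region_labels <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE),
         function(i) as.integer(i) + 1L)
}
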