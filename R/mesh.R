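#' Triangle surface mesh
#'
#' Lightweight container for an open or closed triangle surface in millimetre
#' coordinates, used for the reference skull, patient/phantom skulls and all
#' derived surfaces. Faces are 1-based vertex index triples; the winding order
#' defines the outward normal (right-hand rule).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @export
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)))
#' mesh_areas(m)
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "tri_mesh")) stop("expected a tri_mesh")
  if (nrow(mesh$faces) < 1L) stop("mesh has no faces")
  invisible(mesh)
}

#' Per-face areas, centroids and normals
#'
#' @param mesh a [tri_mesh()].
#' @return `mesh_areas`: numeric vector of face areas (mm^2).
#' @export
mesh_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

#' @rdname mesh_areas
#' @return `mesh_centroids`: m x 3 matrix of face centroids (mm).
#' @export
mesh_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

#' @rdname mesh_areas
#' @return `mesh_face_normals`: m x 3 matrix of unit outward face normals.
#' @export
mesh_face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr * cr))
  len[len == 0] <- 1
  cr / len
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Area-weighted vertex normals
#'
#' Vertex normals as the normalized area-weighted sum of incident face normals
#' (the standard discrete approximation of the smooth surface normal).
#'
#' @param mesh a [tri_mesh()].
#' @return n x 3 matrix of unit vertex normals (zero rows for isolated
#'   vertices).
#' @export
mesh_vertex_normals <- function(mesh) {
  cr <- face_cross(mesh) # length 2*area, direction = face normal
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    n[, 1L] <- n[, 1L] + unname(tapply_add(cr[, 1L], idx, nrow(n)))
    n[, 2L] <- n[, 2L] + unname(tapply_add(cr[, 2L], idx, nrow(n)))
    n[, 3L] <- n[, 3L] + unname(tapply_add(cr[, 3L], idx, nrow(n)))
  }
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, group = index)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle closest-point queries (not vertex-only) against all
#' faces of `mesh`, accelerated by a centroid-radius bound.
#'
#' @param points numeric matrix, q x 3 query points (mm).
#' @param mesh a [tri_mesh()].
#' @return list with `point` (q x 3 closest surface points), `dist` (unsigned
#'   distances, mm) and `face` (1-based face index hit).
#' @export
mesh_closest_point <- function(points, mesh) {
  stopifnot_mesh(mesh)
  points <- rbind(points)
  storage.mode(points) <- "double"
  cpp_closest_on_mesh(points, mesh$vertices, mesh$faces)
}

#' Icosphere mesh
#'
#' Geodesic sphere by repeated subdivision of an icosahedron with projection
#' onto the sphere; used as the analytic oracle geometry for the deviation
#' module and as a generic test surface.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 subdivision passes (0 = icosahedron).
#' @param center length-3 numeric, sphere centre (mm).
#' @return a [tri_mesh()] with outward-oriented faces.
#' @export
mesh_sphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      hit <- mids[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m * m))
      newv[[length(newv) + 1L]] <<- m
      idx <- nv + length(newv)
      mids[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c3 <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c3, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2L, center, `+`)
  tri_mesh(v, f)
}

# Connected components over faces (faces sharing a vertex are connected).
# Returns an integer component id per face.
face_components <- function(mesh) {
  nf <- nrow(mesh$faces)
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nf)) {
    a <- find(mesh$faces[i, 1L])
    b <- find(mesh$faces[i, 2L])
    c3 <- find(mesh$faces[i, 3L])
    parent[b] <- a
    parent[c3] <- a
  }
  roots <- vapply(mesh$faces[, 1L], find, integer(1))
  match(roots, unique(roots))
}

# Face adjacency over shared edges, as a list of integer neighbour vectors.
face_edge_adjacency <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- c(ek(f[, 1L], f[, 2L]), ek(f[, 2L], f[, 3L]), ek(f[, 3L], f[, 1L]))
  fid <- rep.int(seq_len(nf), 3L)
  sp <- split(fid, edges)
  adj <- vector("list", nf)
  for (grp in sp) {
    if (length(grp) < 2L) next
    for (i in grp) adj[[i]] <- c(adj[[i]], setdiff(grp, i))
  }
  lapply(adj, unique)
}

#' Extract a sub-mesh from a face subset
#'
#' @param mesh a [tri_mesh()].
#' @param face_idx integer vector of 1-based face indices to keep.
#' @param drop_vertices drop unreferenced vertices and reindex faces.
#' @return a [tri_mesh()].
#' @export
mesh_subset <- function(mesh, face_idx, drop_vertices = TRUE) {
  stopifnot_mesh(mesh)
  f <- mesh$faces[face_idx, , drop = FALSE]
  if (!drop_vertices) return(tri_mesh(mesh$vertices, f))
  keep <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  tri_mesh(mesh$vertices[keep, , drop = FALSE],
           matrix(remap[f], ncol = 3L))
}
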