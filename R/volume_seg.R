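#' CT-like scalar volume in Hounsfield units
#'
#' @param voxels 3D numeric array of Hounsfield units.
#' @param spacing numeric length 3, mm per axis (> 0).
#' @param origin numeric length 3, mm position of the first voxel centre.
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop("voxels must be a non-empty 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)), class = "hu_volume")
}

#' Read a NIfTI volume as Hounsfield units
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return an [hu_volume()] (spacing from the NIfTI pixdim).
#' @export
read_hu_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  hu_volume(img[, , , drop = TRUE], spacing = RNifti::pixdim(img)[1:3])
}

#' Bone thresholding of a Hounsfield volume
#'
#' Virtual dissection of soft tissue by windowing the Hounsfield scale: a voxel
#' belongs to bone exactly when `hu_min <= HU <= hu_max` (inclusive bounds).
#' The defaults, 226 to 48,060 HU, are the standard bone window used for
#' skull model extraction; per-case fine tuning (as done interactively in
#' clinical segmentation suites) is out of scope — the bounds are plain
#' parameters.
#'
#' @param volume an [hu_volume()].
#' @param hu_min,hu_max window bounds in HU, `hu_min <= hu_max`.
#' @return a logical 3D array of class `binary_mask` with `spacing` and
#'   `origin` attributes of the source volume.
#' @export
threshold_bone <- function(volume, hu_min = 226, hu_max = 48060) {
  if (!inherits(volume, "hu_volume")) stop("volume must be an hu_volume()")
  if (hu_min > hu_max) stop("hu_min must not exceed hu_max")
  mask <- volume$voxels >= hu_min & volume$voxels <= hu_max
  structure(mask, spacing = volume$spacing, origin = volume$origin,
            class = "binary_mask")
}

#' Iso-surface extraction from a binary mask
#'
#' Extracts the 0.5 iso-surface of the mask by marching tetrahedra (each
#' boundary voxel cell is split into six tetrahedra; crossing edges are cut at
#' their midpoint and triangulated), yielding a triangle surface in mm with
#' outward-oriented normals. Voxel centres are mapped to
#' `origin + (index - 1) * spacing`.
#'
#' @param mask a [threshold_bone()] result (or any logical 3D array).
#' @param spacing mm per axis; taken from the mask attributes when present.
#' @param origin mm; likewise.
#' @return a [tri_mesh()].
#' @export
extract_surface <- function(mask, spacing = NULL, origin = NULL) {
  m <- mask
  if (is.null(spacing)) spacing <- attr(mask, "spacing")
  if (is.null(origin)) origin <- attr(mask, "origin")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  m <- array(as.logical(m), dim = dim(m))
  if (!any(m)) stop("mask is empty; no surface to extract")
  if (all(m)) stop("mask is full; no iso-surface crosses the volume")
  dims <- dim(m)
  v <- array(as.numeric(m), dim = dims)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  # boundary cells: cells whose 8 corners are neither all inside nor all out
  s <- v[1:(nx - 1), 1:(ny - 1), 1:(nz - 1)] + v[2:nx, 1:(ny - 1), 1:(nz - 1)] +
    v[1:(nx - 1), 2:ny, 1:(nz - 1)] + v[2:nx, 2:ny, 1:(nz - 1)] +
    v[1:(nx - 1), 1:(ny - 1), 2:nz] + v[2:nx, 1:(ny - 1), 2:nz] +
    v[1:(nx - 1), 2:ny, 2:nz] + v[2:nx, 2:ny, 2:nz]
  cells <- which(s > 0 & s < 8, arr.ind = TRUE)
  if (nrow(cells) == 0L) stop("mask has no inside/outside boundary")
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
                c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))
  iso <- 0.5
  tris <- vector("list", 4096L)
  ntri <- 0L
  push <- function(p1, p2, p3, inside_c, outside_c) {
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    if (sum(n * (outside_c - inside_c)) < 0) {
      tmp <- p2; p2 <- p3; p3 <- tmp
    }
    ntri <<- ntri + 1L
    if (ntri > length(tris)) length(tris) <<- 2L * ntri
    tris[[ntri]] <<- rbind(p1, p2, p3)
  }
  # canonical edge cut: order endpoints by global voxel id for bitwise-stable
  # vertex positions across neighbouring tetrahedra
  cut <- function(ga, gb, pa, pb, va, vb) {
    if (ga > gb) {
      t <- (iso - vb) / (va - vb)
      pb + t * (pa - pb)
    } else {
      t <- (iso - va) / (vb - va)
      pa + t * (pb - pa)
    }
  }
  for (ci in seq_len(nrow(cells))) {
    base <- cells[ci, ]
    cidx <- sweep(corner_off, 2L, as.integer(base), `+`) # 8 x 3 voxel indices
    gid <- (cidx[, 3L] - 1L) * nx * ny + (cidx[, 2L] - 1L) * nx + cidx[, 1L]
    vals <- v[gid]
    pos <- sweep(sweep(cidx - 1L, 2L, spacing, `*`), 2L, origin, `+`)
    for (ti in 1:6) {
      tv <- tets[ti, ]
      tvals <- vals[tv]
      inside <- tvals > iso
      ni <- sum(inside)
      if (ni == 0L || ni == 4L) next
      pin <- pos[tv[inside], , drop = FALSE]
      pout <- pos[tv[!inside], , drop = FALSE]
      gin <- gid[tv[inside]]
      gout <- gid[tv[!inside]]
      vin <- tvals[inside]
      vout <- tvals[!inside]
      cin <- colMeans(pin)
      cout <- colMeans(pout)
      if (ni == 1L) {
        push(cut(gin[1], gout[1], pin[1, ], pout[1, ], vin[1], vout[1]),
             cut(gin[1], gout[2], pin[1, ], pout[2, ], vin[1], vout[2]),
             cut(gin[1], gout[3], pin[1, ], pout[3, ], vin[1], vout[3]),
             cin, cout)
      } else if (ni == 3L) {
        push(cut(gin[1], gout[1], pin[1, ], pout[1, ], vin[1], vout[1]),
             cut(gin[2], gout[1], pin[2, ], pout[1, ], vin[2], vout[1]),
             cut(gin[3], gout[1], pin[3, ], pout[1, ], vin[3], vout[1]),
             cin, cout)
      } else {
        q1 <- cut(gin[1], gout[1], pin[1, ], pout[1, ], vin[1], vout[1])
        q2 <- cut(gin[1], gout[2], pin[1, ], pout[2, ], vin[1], vout[2])
        q3 <- cut(gin[2], gout[2], pin[2, ], pout[2, ], vin[2], vout[2])
        q4 <- cut(gin[2], gout[1], pin[2, ], pout[1, ], vin[2], vout[1])
        push(q1, q2, q3, cin, cout)
        push(q1, q3, q4, cin, cout)
      }
    }
  }
  soup <- do.call(rbind, tris[seq_len(ntri)])
  soup_to_mesh(soup)
}

#' Automated mesh cleaning
#'
#' The automated subset of model optimization: removes degenerate (zero-area)
#' faces, keeps only the largest connected component (by surface area), and
#' drops unreferenced vertices. Idempotent; manual artifact repair is out of
#' scope.
#'
#' @param mesh a [tri_mesh()].
#' @return a cleaned [tri_mesh()].
#' @export
clean_mesh <- function(mesh) {
  stopifnot_mesh(mesh)
  areas <- mesh_areas(mesh)
  keep <- which(areas > 0)
  m1 <- tri_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
  comp <- face_components(m1)
  if (max(comp) > 1L) {
    carea <- rowsum(mesh_areas(m1), comp)
    main <- as.integer(rownames(carea))[which.max(carea[, 1L])]
    m1 <- tri_mesh(m1$vertices, m1$faces[comp == main, , drop = FALSE])
  }
  mesh_subset(m1, seq_len(nrow(m1$faces)), drop_vertices = TRUE)
}
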