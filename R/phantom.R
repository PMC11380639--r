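#' Phantom cohort specification
#'
#' Parameters of the synthetic skull-phantom generator. The generator emulates
#' the study situation — a fixed reference skull plus a cohort of subject
#' skulls — with known ground truth: each subject differs from the reference by
#' sex-conditioned region-wise surface offsets along the outward normal,
#' per-vertex isotropic noise, a contiguous missing-surface patch in the
#' alveolar region (R4), landmark digitization jitter, and a random rigid
#' misalignment.
#'
#' Region offsets are specified in the deviation sign convention: *negative*
#' values displace the surface outward/anteriorly (so an injected offset equals
#' the expected region `Dmean` directly). Defaults place a -1.5 mm outward sex
#' effect in the paranasal (R1) and zygomatic (R3) regions of males, mirroring
#' the qualitative cohort finding that males sit in the negative (anterior)
#' value clusters of those regions; magnitudes are free parameters, since no
#' quantitative per-region effect size is established.
#'
#' @param seed integer RNG seed; identical spec + seed reproduces the cohort
#'   bit-identically.
#' @param n_subjects number of subjects (>= 1).
#' @param region_offset_mean list with elements `male` and `female`, each a
#'   length-4 numeric of mean signed offsets (mm) for R1..R4.
#' @param region_offset_sd between-subject SD of the drawn offsets, mm (>= 0).
#' @param noise_sd per-vertex isotropic Gaussian noise SD, mm (>= 0).
#' @param dropout_fraction fraction in `[0, 1]` of each side's R4 area removed
#'   as one contiguous patch (emulating edentulous / invalid areas).
#' @param misalignment named numeric `c(translation_mm=, rotation_deg=)`:
#'   half-widths of the uniform random rigid perturbation.
#' @param sex_ratio fraction of males; male count is `round(n * sex_ratio)`.
#' @param age_range numeric length 2, years; ages drawn uniformly.
#' @param landmark_jitter_sd SD of isotropic landmark digitization jitter, mm.
#' @param age_slope_mm_per_year optional linear link from age to an additional
#'   uniform R4 offset (default 0: age is not linked to geometry).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         n_subjects = 50L,
                         region_offset_mean = list(
                           male = c(-1.5, 0, -1.5, 0),
                           female = c(0, 0, 0, 0)),
                         region_offset_sd = 0.5,
                         noise_sd = 0.3,
                         dropout_fraction = 0.15,
                         misalignment = c(translation_mm = 5, rotation_deg = 5),
                         sex_ratio = 0.68,
                         age_range = c(20, 89),
                         landmark_jitter_sd = 1.5,
                         age_slope_mm_per_year = 0) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (dropout_fraction < 0 || dropout_fraction > 1) {
    stop("dropout_fraction must be in [0, 1]")
  }
  if (region_offset_sd < 0 || noise_sd < 0 || landmark_jitter_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  stopifnot(length(region_offset_mean$male) == 4L,
            length(region_offset_mean$female) == 4L)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 region_offset_mean = region_offset_mean,
                 region_offset_sd = region_offset_sd, noise_sd = noise_sd,
                 dropout_fraction = dropout_fraction,
                 misalignment = misalignment, sex_ratio = sex_ratio,
                 age_range = age_range,
                 landmark_jitter_sd = landmark_jitter_sd,
                 age_slope_mm_per_year = age_slope_mm_per_year),
            class = "phantom_spec")
}

# run code under a fixed seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

subject_seed <- function(spec, subject_index) {
  (spec$seed %% 100000L) * 20011L + subject_index * 7L
}

# phantom surface height field: central ellipsoidal dome blended into exactly
# planar lateral (zygomatic) wings for |x| >= .wing_x0, so that landmarks
# constructed on the wing (J, O, M) lie on the triangulated surface exactly
.wing_x0 <- 30
phantom_height <- function(x, z) {
  dome <- 35 * sqrt(pmax(0, 1 - (x / 60)^2 - (z / 55)^2))
  c0 <- 35 * sqrt(1 - (.wing_x0 / 60)^2)
  c1 <- -35 * (.wing_x0 / 3600) / sqrt(1 - (.wing_x0 / 60)^2)
  plane <- c0 + c1 * (abs(x) - .wing_x0) - 0.15 * z
  u <- pmin(1, pmax(0, (abs(x) - 24) / (.wing_x0 - 24)))
  w <- u * u * (3 - 2 * u) # smoothstep
  (1 - w) * dome + w * plane
}

phantom_region_boxes <- function() {
  # (|x| min, |x| max, z min, z max); gaps >= 3 mm keep regions disjoint with
  # unlabeled faces in between (labels are a strict subset of all faces)
  list(R1 = c(6, 15, -6, 10),    # paranasal
       R2 = c(18, 28, -6, 10),   # facial maxillary sinus wall
       R3 = c(32, 45, 6, 24),    # zygomatic bone
       R4 = c(4, 28, -32, -12))  # alveolar process
}

#' Generate the reference skull phantom
#'
#' Builds a smooth parametric midface-like open surface (ellipsoidal dome
#' blended into planar zygomatic wings), with per-side face-label sets for the
#' four reconstructive regions of interest (R1 paranasal, R2 facial maxillary
#' sinus wall, R3 zygomatic bone, R4 alveolar process), an orbital-rim
#' polyline per side, and the full landmark set (A, IOr, IOl and per-side J,
#' O, M, X) placed on the surface. Axes: +X = subject's right, +Y = anterior,
#' +Z = superior; all units mm. Normals point anteriorly (outward).
#'
#' The phantom is deliberately parametric rather than anatomically realistic:
#' the validation strategy is recovery of known deformations, not shape
#' realism.
#'
#' @param resolution `"coarse"`, `"medium"`, `"fine"`, or a numeric grid
#'   spacing in mm. Must yield at least 500 faces.
#' @return a list of class `reference_phantom`: `mesh` ([tri_mesh()]),
#'   `regions` (named list `R1_right` ... `R4_left` of face indices),
#'   `landmarks` (named list of points), `rims` (per side: point matrix with
#'   vertex indices as attribute `vertex_index`).
#' @export
make_reference_phantom <- function(resolution = "coarse") {
  spacing <- if (is.character(resolution)) {
    switch(match.arg(resolution, c("coarse", "medium", "fine")),
           coarse = 2, medium = 1.5, fine = 1)
  } else {
    as.numeric(resolution)
  }
  # the surface extends well beyond the labeled regions: registration matches
  # the whole surface (as whole skulls are superimposed in practice), so the
  # regions of interest must stay a small fraction of the matched area
  xs <- seq(-72, 72, by = spacing)
  zs <- seq(-56, 44, by = spacing)
  nx <- length(xs)
  nz <- length(zs)
  nfaces <- 2L * (nx - 1L) * (nz - 1L)
  if (nfaces < 500L) {
    stop(sprintf(
      "resolution too coarse: %d faces < 500 minimum; use a spacing <= 4 mm",
      nfaces))
  }
  g <- expand.grid(x = xs, z = zs) # x varies fastest
  verts <- cbind(g$x, phantom_height(g$x, g$z), g$z)
  vid <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nx - 1L)
  v00 <- vid(i, j); v10 <- vid(i + 1L, j)
  v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
  faces <- rbind(cbind(v00, v11, v10), cbind(v00, v01, v11))
  # interleave so the two triangles of a quad are adjacent in index order
  ord <- as.vector(rbind(seq_len(length(v00)),
                         seq_len(length(v00)) + length(v00)))
  faces <- faces[ord, , drop = FALSE]
  mesh <- tri_mesh(verts, faces)

  cent <- mesh_centroids(mesh)
  boxes <- phantom_region_boxes()
  regions <- list()
  for (rn in names(boxes)) {
    b <- boxes[[rn]]
    for (side in c("right", "left")) {
      sx <- if (side == "right") cent[, 1L] else -cent[, 1L]
      inb <- sx >= b[1L] & sx <= b[2L] & cent[, 3L] >= b[3L] & cent[, 3L] <= b[4L]
      regions[[paste0(rn, "_", side)]] <- which(inb)
    }
  }

  nearest_vertex <- function(x0, z0) {
    which.min((verts[, 1L] - x0)^2 + (verts[, 3L] - z0)^2)
  }
  rim_z <- zs[which.min(abs(zs - 28))]
  rims <- list()
  for (side in c("right", "left")) {
    sgn <- if (side == "right") 1 else -1
    rim_x <- xs[xs * sgn >= .wing_x0 & xs * sgn <= 47]
    rim_x <- rim_x[order(abs(rim_x))] # medial to lateral
    idx <- vapply(rim_x, function(x0) nearest_vertex(x0, rim_z), integer(1))
    pts <- verts[idx, , drop = FALSE]
    attr(pts, "vertex_index") <- idx
    rims[[side]] <- pts
  }

  landmarks <- list(
    A = verts[nearest_vertex(0, -14), ],
    IOr = verts[nearest_vertex(24, 26), ],
    IOl = verts[nearest_vertex(-24, 26), ],
    X_right = verts[nearest_vertex(20, -14), ],
    X_left = verts[nearest_vertex(-20, -14), ])
  for (side in c("right", "left")) {
    J <- as.numeric(locate_J(mesh, regions[[paste0("R3_", side)]]))
    O <- as.numeric(locate_O(rims[[side]], J))
    landmarks[[paste0("J_", side)]] <- J
    landmarks[[paste0("O_", side)]] <- O
    landmarks[[paste0("M_", side)]] <- (J + O) / 2
  }

  structure(list(mesh = mesh, regions = regions, landmarks = landmarks,
                 rims = rims, spacing = spacing,
                 adjacency = face_edge_adjacency(mesh)),
            class = "reference_phantom")
}

#' Synthesize one phantom subject
#'
#' Derives a subject skull from the reference by applying, in order: (i) a
#' per-region surface offset along the reference vertex normals, drawn from
#' the sex-conditioned offset distribution (negative = outward, matching the
#' deviation sign convention); (ii) per-vertex isotropic Gaussian noise;
#' (iii) one contiguous face-dropout patch per side in R4 covering about
#' `dropout_fraction` of that side's R4 area; (iv) isotropic jitter on the
#' anatomical landmarks; and (v) a random rigid misalignment applied to mesh
#' and landmarks alike. All draws are recorded in the returned ground truth.
#'
#' @param reference a [make_reference_phantom()] result.
#' @param spec a [phantom_spec()].
#' @param subject_index integer in `1..spec$n_subjects`.
#' @return list of class `phantom_subject`: `mesh`, `landmarks`, `regions`
#'   (face labels remapped to subject face indexing), `rims`, and `truth`
#'   (class `phantom_truth`: `subject_id`, `sex`, `age`, `per_region_offset`,
#'   `dropout_area` mm^2, `removed_faces` in reference indexing,
#'   `applied_transform`, `euler_deg`, `translation_mm`).
#' @export
synthesize_subject <- function(reference, spec, subject_index) {
  if (!inherits(reference, "reference_phantom")) {
    stop("reference must come from make_reference_phantom()")
  }
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec()")
  if (subject_index < 1L || subject_index > spec$n_subjects) {
    stop("subject_index must be in 1..n_subjects")
  }
  demo <- cohort_demographics(spec)
  sex <- demo$sex[subject_index]
  age <- demo$age[subject_index]

  local_seed(subject_seed(spec, subject_index), {
    mu <- spec$region_offset_mean[[sex]]
    offsets <- stats::rnorm(4L, mean = mu, sd = spec$region_offset_sd)
    offsets[4L] <- offsets[4L] + spec$age_slope_mm_per_year * (age - mean(spec$age_range))
    verts <- reference$mesh$vertices
    vn <- mesh_vertex_normals(reference$mesh)
    for (r in 1:4) {
      vids <- unique(as.vector(reference$mesh$faces[
        c(reference$regions[[paste0("R", r, "_right")]],
          reference$regions[[paste0("R", r, "_left")]]), , drop = FALSE]))
      # negative offset = outward displacement (deviation sign convention)
      verts[vids, ] <- verts[vids, ] - offsets[r] * vn[vids, , drop = FALSE]
    }
    if (spec$noise_sd > 0) {
      verts <- verts + matrix(stats::rnorm(length(verts), sd = spec$noise_sd),
                              ncol = 3L)
    }
    areas <- mesh_areas(reference$mesh)
    removed <- integer(0)
    if (spec$dropout_fraction > 0) {
      adj <- reference$adjacency
      if (is.null(adj)) adj <- face_edge_adjacency(reference$mesh)
      for (side in c("right", "left")) {
        r4 <- reference$regions[[paste0("R4_", side)]]
        target <- spec$dropout_fraction * sum(areas[r4])
        seed_face <- r4[sample.int(length(r4), 1L)]
        removed <- c(removed, grow_patch(seed_face, r4, adj, areas, target))
      }
    }
    keep <- setdiff(seq_len(nrow(reference$mesh$faces)), removed)
    subj_mesh <- tri_mesh(verts, reference$mesh$faces[keep, , drop = FALSE])
    regions <- lapply(reference$regions, function(idx) {
      m <- match(setdiff(idx, removed), keep)
      m[!is.na(m)]
    })

    lm <- reference$landmarks
    if (spec$landmark_jitter_sd > 0) {
      jit <- function(p) p + stats::rnorm(3L, sd = spec$landmark_jitter_sd)
      for (nm in c("A", "IOr", "IOl", "X_right", "X_left",
                   "J_right", "J_left", "O_right", "O_left")) {
        lm[[nm]] <- jit(lm[[nm]])
      }
      for (side in c("right", "left")) {
        lm[[paste0("M_", side)]] <-
          (lm[[paste0("J_", side)]] + lm[[paste0("O_", side)]]) / 2
      }
    }
    ang <- stats::runif(3L, -spec$misalignment[["rotation_deg"]],
                        spec$misalignment[["rotation_deg"]])
    tr <- stats::runif(3L, -spec$misalignment[["translation_mm"]],
                       spec$misalignment[["translation_mm"]])
    transform <- rigid_transform(euler_rotation(ang[1L], ang[2L], ang[3L]), tr)
    subj_mesh <- apply_transform(subj_mesh, transform)
    lm <- apply_transform(lm, transform)
    rims <- lapply(reference$rims, function(p) {
      out <- apply_transform(unclass(p[, , drop = FALSE]), transform)
      attr(out, "vertex_index") <- attr(p, "vertex_index")
      out
    })

    truth <- structure(list(
      subject_id = subject_index, sex = sex, age = age,
      per_region_offset = offsets,
      dropout_area = sum(areas[removed]),
      removed_faces = removed,
      applied_transform = transform,
      euler_deg = ang, translation_mm = tr), class = "phantom_truth")
    structure(list(mesh = subj_mesh, landmarks = lm, regions = regions,
                   rims = rims, truth = truth), class = "phantom_subject")
  })
}

# contiguous patch of faces inside `allowed`, grown breadth-first from
# seed_face until the accumulated area reaches `target`
grow_patch <- function(seed_face, allowed, adj, areas, target) {
  if (target <= 0) return(integer(0))
  allowed_set <- rep(FALSE, length(adj))
  allowed_set[allowed] <- TRUE
  patch <- integer(0)
  acc <- 0
  queue <- seed_face
  seen <- rep(FALSE, length(adj))
  seen[seed_face] <- TRUE
  while (length(queue) > 0L && acc < target) {
    f <- queue[1L]
    queue <- queue[-1L]
    patch <- c(patch, f)
    acc <- acc + areas[f]
    nb <- adj[[f]]
    nb <- nb[allowed_set[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  patch
}

cohort_demographics <- function(spec) {
  local_seed(spec$seed, {
    n <- spec$n_subjects
    n_male <- round(n * spec$sex_ratio)
    sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    age <- stats::runif(n, spec$age_range[1L], spec$age_range[2L])
    list(sex = sex, age = age)
  })
}

#' Synthesize a full phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @param reference optionally a pre-built [make_reference_phantom()]; built at
#'   `resolution` otherwise.
#' @param resolution passed to [make_reference_phantom()] when `reference` is
#'   not supplied.
#' @return list of class `phantom_cohort`: `reference`, `subjects` (list of
#'   [synthesize_subject()] results) and `truth` (CSV-serializable
#'   `data.frame`: `subject_id, sex, age, offset_R1..offset_R4, dropout_area,
#'   tx, ty, tz, rx, ry, rz`).
#' @export
synthesize_cohort <- function(spec, reference = NULL, resolution = "coarse") {
  if (is.null(reference)) reference <- make_reference_phantom(resolution)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    synthesize_subject(reference, spec, i)
  })
  truth <- do.call(rbind, lapply(subjects, function(s) {
    tr <- s$truth
    data.frame(subject_id = tr$subject_id, sex = tr$sex, age = tr$age,
               offset_R1 = tr$per_region_offset[1L],
               offset_R2 = tr$per_region_offset[2L],
               offset_R3 = tr$per_region_offset[3L],
               offset_R4 = tr$per_region_offset[4L],
               dropout_area = tr$dropout_area,
               tx = tr$translation_mm[1L], ty = tr$translation_mm[2L],
               tz = tr$translation_mm[3L],
               rx = tr$euler_deg[1L], ry = tr$euler_deg[2L],
               rz = tr$euler_deg[3L])
  }))
  structure(list(reference = reference, subjects = subjects, truth = truth),
            class = "phantom_cohort")
}
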