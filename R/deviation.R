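#' Sample a reference region for surface comparison
#'
#' Discretizes a marked region of the reference mesh into one sample per face:
#' the face centroid, the unit outward face normal, and the face area as the
#' sample's area weight. The area weights sum to the region area, so that
#' area-weighted statistics of the deviation field turn into surface integrals
#' (ID, IAD in mm^3; AVD in mm^2).
#'
#' @param reference a [tri_mesh()].
#' @param region_faces integer vector of 1-based face indices of the region.
#' @return an object of class `region_samples`: list with `points` (k x 3),
#'   `normals` (k x 3, unit), `area_weights` (mm^2) and `faces`.
#' @export
sample_region <- function(reference, region_faces) {
  stopifnot_mesh(reference)
  region_faces <- as.integer(region_faces)
  if (length(region_faces) < 1L) stop("region is empty")
  if (min(region_faces) < 1L || max(region_faces) > nrow(reference$faces)) {
    stop("region face indices out of range")
  }
  sub <- tri_mesh(reference$vertices,
                  reference$faces[region_faces, , drop = FALSE])
  structure(list(points = mesh_centroids(sub),
                 normals = mesh_face_normals(sub),
                 area_weights = mesh_areas(sub),
                 faces = region_faces),
            class = "region_samples")
}

#' Signed surface deviation of a subject against a reference region
#'
#' For each region sample, measures the distance from the sample point to the
#' registered subject surface and signs it by the reference outward normal:
#' a subject surface lying outside / in front of the reference gives a
#' *negative* deviation, one lying inside / behind gives a *positive* one
#' (blue vs. red in the conventional false-colour rendering). Samples whose
#' unsigned distance exceeds the validity `window` are marked invalid and carry
#' no distance (grey areas: no comparison possible there).
#'
#' Two correspondence rules are available:
#' \describe{
#'   \item{`"closest"`}{exact closest point on the subject surface; the sign is
#'     the sign of `-(q - p) . n`. Default.}
#'   \item{`"normal"`}{normal projection: the subject surface is intersected
#'     along the sample's normal line (both directions) and the intersection
#'     with the smallest absolute offset within the window is taken. A sample
#'     over missing subject surface finds no intersection and is invalid, which
#'     makes this rule the right one for detecting absent (e.g. edentulous)
#'     areas.}
#' }
#'
#' @param samples a [sample_region()] result.
#' @param subject a [tri_mesh()] already registered to the reference frame.
#' @param window validity window in mm (default 5.0, i.e. -5 mm anterior to
#'   +5 mm posterior, a total corridor of 1 cm).
#' @param method `"closest"` or `"normal"`.
#' @return an object of class `deviation_field`: list with `d` (signed mm, NA
#'   where invalid), `valid` (logical), `area_weights`, `window`, `method`.
#' @export
signed_deviation <- function(samples, subject, window = 5.0,
                             method = c("closest", "normal")) {
  if (!inherits(samples, "region_samples")) {
    stop("samples must come from sample_region()")
  }
  method <- match.arg(method)
  stopifnot_mesh(subject)
  if (method == "closest") {
    cp <- mesh_closest_point(samples$points, subject)
    vec <- cp$point - samples$points
    outward <- rowSums(vec * samples$normals)
    d <- -sign(outward) * cp$dist
    d[outward == 0] <- cp$dist[outward == 0] # degenerate: on-surface, d = 0
    valid <- cp$dist <= window
  } else {
    hit <- cpp_line_mesh(samples$points, samples$normals,
                         subject$vertices, subject$faces, window)
    # t > 0: intersection along the outward normal => subject outside => negative
    d <- -hit$t
    valid <- !is.na(hit$t)
  }
  d[!valid] <- NA_real_
  structure(list(d = d, valid = valid, area_weights = samples$area_weights,
                 window = window, method = method),
            class = "deviation_field")
}

#' Seven-parameter summary of a region deviation field
#'
#' Summarizes the valid samples of a deviation field into the seven standard
#' surface-comparison parameters. With valid signed distances `d_i` and area
#' weights `a_i`:
#' \itemize{
#'   \item `Dmax = max d_i`, `Dmin = min d_i` (mm)
#'   \item `Dmean = sum(a_i d_i) / sum(a_i)` (area-weighted mean, mm)
#'   \item `DSD = sqrt(sum(a_i (d_i - Dmean)^2) / sum(a_i))` (mm)
#'   \item `AVD = sum(a_i)` (area of valid distance, mm^2)
#'   \item `ID = sum(a_i d_i)` (integrated distance, mm^3)
#'   \item `IAD = sum(a_i |d_i|)` (integrated absolute distance, mm^3)
#' }
#' The identity `ID = Dmean * AVD` holds exactly by construction. A field with
#' no valid samples yields the designated empty summary: `AVD = 0`, all
#' distance parameters `NA` (a fully invalid, grey region).
#'
#' @param field a [signed_deviation()] result.
#' @return a one-row `data.frame` with columns `Dmax`, `Dmin`, `Dmean`, `DSD`,
#'   `AVD`, `ID`, `IAD`.
#' @export
summarize_region <- function(field) {
  if (!inherits(field, "deviation_field")) {
    stop("field must come from signed_deviation()")
  }
  v <- field$valid
  if (!any(v)) {
    return(data.frame(Dmax = NA_real_, Dmin = NA_real_, Dmean = NA_real_,
                      DSD = NA_real_, AVD = 0, ID = NA_real_, IAD = NA_real_))
  }
  d <- field$d[v]
  a <- field$area_weights[v]
  avd <- sum(a)
  dmean <- sum(a * d) / avd
  data.frame(Dmax = max(d), Dmin = min(d), Dmean = dmean,
             DSD = sqrt(sum(a * (d - dmean)^2) / avd),
             AVD = avd, ID = dmean * avd, IAD = sum(a * abs(d)))
}

#' False-colour classification of a deviation field
#'
#' Maps each sample to the conventional inspection colours: `grey` for invalid
#' samples, `green` where `|d| < green_band`, `blue` for deviations at or below
#' `-green_band` (subject in front of the reference) and `red` at or above
#' `+green_band` (subject behind). The returned intensity ramps linearly from 0
#' at the green-band edge to 1 at the validity-window edge (green and grey
#' samples have intensity 0).
#'
#' @param field a [signed_deviation()] result.
#' @param green_band half-width of the green band in mm (default 1.0).
#' @return a `data.frame` with columns `color` (factor: blue/green/red/grey)
#'   and `intensity` in `[0, 1]`.
#' @export
false_color <- function(field, green_band = 1.0) {
  if (!inherits(field, "deviation_field")) {
    stop("field must come from signed_deviation()")
  }
  color <- rep("grey", length(field$d))
  intensity <- rep(0, length(field$d))
  v <- field$valid
  d <- field$d
  color[v & abs(d) < green_band] <- "green"
  color[v & d <= -green_band] <- "blue"
  color[v & d >= green_band] <- "red"
  ramp <- v & abs(d) >= green_band
  span <- max(field$window - green_band, .Machine$double.eps)
  intensity[ramp] <- pmin(1, (abs(d[ramp]) - green_band) / span)
  data.frame(color = factor(color, levels = c("blue", "green", "red", "grey")),
             intensity = intensity)
}

#' Export a false-colour region mesh as PLY
#'
#' Writes the region sub-mesh with per-vertex RGB derived from the per-sample
#' (per-face) false colours; vertex colour is the mean of incident face
#' colours. Blue/red saturate with intensity, green is the neutral in-band
#' colour and grey marks invalid faces.
#'
#' @param reference a [tri_mesh()].
#' @param region_faces face indices of the region.
#' @param field matching [signed_deviation()] result.
#' @param path output `.ply` path.
#' @param green_band passed to [false_color()].
#' @return `path`, invisibly.
#' @export
export_colored_ply <- function(reference, region_faces, field, path,
                               green_band = 1.0) {
  fc <- false_color(field, green_band = green_band)
  base <- list(blue = c(0, 60, 255), green = c(0, 200, 60),
               red = c(255, 40, 30), grey = c(150, 150, 150))
  face_rgb <- t(vapply(seq_along(fc$color), function(i) {
    col <- as.character(fc$color[i])
    w <- if (col %in% c("blue", "red")) 0.35 + 0.65 * fc$intensity[i] else 1
    base[[col]] * w + c(255, 255, 255) * (1 - w) * 0.2
  }, numeric(3)))
  sub <- mesh_subset(reference, region_faces, drop_vertices = TRUE)
  vert_rgb <- matrix(0, nrow(sub$vertices), 3L)
  cnt <- numeric(nrow(sub$vertices))
  for (k in 1:3) {
    idx <- sub$faces[, k]
    for (j in 1:3) {
      vert_rgb[, j] <- vert_rgb[, j] + tapply_add(face_rgb[, j], idx, nrow(vert_rgb))
    }
    cnt <- cnt + tapply_add(rep(1, nrow(sub$faces)), idx, length(cnt))
  }
  cnt[cnt == 0] <- 1
  write_ply(sub, path, colors = round(vert_rgb / cnt))
}
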