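#' Locate the J point (caudal-lateral zygoma)
#'
#' The J point is the most caudal and most lateral point of the zygomatic
#' bone. "Most caudal and lateral" is operationalized as the region vertex
#' maximizing the score `w_c * (-z') + w_l * |x|'`, where `z'` and `|x|'` are
#' standardized to the mesh bounding box so the two criteria are commensurate.
#' Ties are broken by the lowest vertex index.
#'
#' @param mesh a [tri_mesh()].
#' @param zygoma_faces face indices of the zygomatic region (one side).
#' @param weights length-2 numeric `(w_c, w_l)`, caudal and lateral weights.
#' @return the winning vertex position (length-3 numeric, mm), with the vertex
#'   index as attribute `vertex_index`.
#' @export
locate_J <- function(mesh, zygoma_faces, weights = c(1, 1)) {
  stopifnot_mesh(mesh)
  if (length(zygoma_faces) < 1L) stop("zygoma region is empty")
  vids <- sort(unique(as.vector(mesh$faces[zygoma_faces, , drop = FALSE])))
  v <- mesh$vertices
  rngx <- range(abs(v[, 1L]))
  rngz <- range(v[, 3L])
  sx <- (abs(v[vids, 1L]) - rngx[1L]) / max(diff(rngx), .Machine$double.eps)
  sz <- (v[vids, 3L] - rngz[1L]) / max(diff(rngz), .Machine$double.eps)
  score <- weights[1L] * (-sz) + weights[2L] * sx
  win <- vids[which.max(score)] # which.max takes the first (lowest index) tie
  structure(v[win, ], vertex_index = win)
}

#' Locate the O point (orbital-rim foot point)
#'
#' The point on the orbital-rim polyline (vertices and segment interiors)
#' closest to J — the foot of the shortest connecting line from J to the rim.
#' When two segments are exactly equidistant the point on the earlier segment
#' is returned.
#'
#' @param rim_polyline k x 3 matrix of ordered rim points (k >= 2), mm.
#' @param J length-3 numeric, the J point.
#' @return closest point on the polyline (length-3 numeric), with attribute
#'   `segment` (index of the segment it lies on).
#' @export
locate_O <- function(rim_polyline, J) {
  p <- rbind(rim_polyline)
  if (nrow(p) < 2L) stop("rim polyline needs at least 2 vertices")
  J <- as.numeric(J)
  best <- NULL
  best_d2 <- Inf
  best_seg <- NA_integer_
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]
    b <- p[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab * ab)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((J - a) * ab) / len2))
    q <- a + t * ab
    d2 <- sum((J - q)^2)
    if (d2 < best_d2 - 1e-12 * max(1, d2)) { # strict: earlier segment wins ties
      best_d2 <- d2
      best <- q
      best_seg <- i
    }
  }
  structure(best, segment = best_seg)
}

#' Construct the reconstruction landmark set
#'
#' Builds the per-side planning landmarks on a (registered) mesh: `J` from the
#' zygomatic region via [locate_J()], `O` as its orbital-rim foot point via
#' [locate_O()], `M` as the midpoint of `J O`; the `A` point and the premolar
#' apices `X` are annotations passed through (the apex position cannot be
#' derived from surface geometry alone — on real data it is digitized, on
#' phantoms the generator provides it).
#'
#' @param mesh a [tri_mesh()].
#' @param region_labels named list of face-index vectors including `R3_right`
#'   and `R3_left` (zygomatic bone).
#' @param rim_polylines list with `right` and `left` rim point matrices.
#' @param annotations named list providing `A` and `X_right`, `X_left` (and
#'   optionally `IOr`, `IOl`, passed through when present).
#' @param weights passed to [locate_J()].
#' @return named list of landmarks: `A`, (`IOr`, `IOl`,) and `J`/`O`/`M`/`X`
#'   suffixed `_right` / `_left`.
#' @export
construct_landmarks <- function(mesh, region_labels, rim_polylines,
                                annotations, weights = c(1, 1)) {
  if (is.null(annotations$A)) stop("annotation 'A' (A-point) is missing")
  out <- list(A = as.numeric(annotations$A))
  for (nm in c("IOr", "IOl")) {
    if (!is.null(annotations[[nm]])) out[[nm]] <- as.numeric(annotations[[nm]])
  }
  for (side in c("right", "left")) {
    xnm <- paste0("X_", side)
    if (is.null(annotations[[xnm]])) {
      stop("premolar apex annotation missing for side: ", side)
    }
    zf <- region_labels[[paste0("R3_", side)]]
    if (is.null(zf) || length(zf) < 1L) {
      stop("zygoma region (R3) missing for side: ", side)
    }
    rim <- rim_polylines[[side]]
    if (is.null(rim)) stop("orbital rim polyline missing for side: ", side)
    J <- locate_J(mesh, zf, weights = weights)
    O <- locate_O(rim, J)
    out[[paste0("J_", side)]] <- as.numeric(J)
    out[[paste0("O_", side)]] <- as.numeric(O)
    out[[paste0("M_", side)]] <- (as.numeric(J) + as.numeric(O)) / 2
    out[[xnm]] <- as.numeric(annotations[[xnm]])
  }
  out
}

#' Three-point angle
#'
#' Angle at vertex `V` between the legs `V P` and `V Q`, in degrees, in
#' `(0, 180]`.
#'
#' @param P,V,Q length-3 numeric points; `P != V`, `Q != V`.
#' @return angle in degrees.
#' @export
three_point_angle <- function(P, V, Q) {
  u <- as.numeric(P) - as.numeric(V)
  w <- as.numeric(Q) - as.numeric(V)
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) stop("angle legs must have nonzero length")
  ca <- sum(u * w) / (nu * nw)
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Measure the two reconstruction segments of one side
#'
#' Segment lengths `AX = ||A - X||` (anterior segment, A-point to premolar
#' apex) and `MX = ||M - X||` (posterior segment, apex to zygoma midpoint),
#' and the three-point angle between them with its vertex at the shared
#' endpoint `X`.
#'
#' @param landmarks a landmark set (see [construct_landmarks()]).
#' @param side `"left"` or `"right"`.
#' @param subject_id optional id carried into the result.
#' @return one-row `data.frame`: `subject_id`, `side`, `length_AX_mm`,
#'   `length_MX_mm`, `angle_deg`.
#' @export
measure_segments <- function(landmarks, side = c("left", "right"),
                             subject_id = NA) {
  side <- match.arg(side)
  A <- landmarks$A
  M <- landmarks[[paste0("M_", side)]]
  X <- landmarks[[paste0("X_", side)]]
  for (nm in c("A", "M", "X")) {
    p <- list(A = A, M = M, X = X)[[nm]]
    if (is.null(p) || any(!is.finite(p))) {
      stop("landmark '", nm, "' missing or non-finite for side: ", side)
    }
  }
  data.frame(subject_id = subject_id, side = side,
             length_AX_mm = sqrt(sum((as.numeric(A) - as.numeric(X))^2)),
             length_MX_mm = sqrt(sum((as.numeric(M) - as.numeric(X))^2)),
             angle_deg = three_point_angle(A, X, M))
}

#' Pool side measurements into the cutting-guide template
#'
#' Side-wise and pooled descriptive statistics of the segment measurements.
#' Left and right are scalar, side-symmetric quantities, so pooling simply
#' concatenates the two sides (doubling the sample); for equal side counts the
#' pooled mean equals the unweighted mean of the side means. SDs are sample
#' SDs (n - 1).
#'
#' @param measurements `data.frame` with columns `side`, `length_AX_mm`,
#'   `length_MX_mm`, `angle_deg` (rows = one side of one subject), e.g. rbound
#'   [measure_segments()] results.
#' @return a `data.frame` of class `cutting_guide_template` with one row per
#'   (`cell` in left/right/pooled) and columns `n`, `mean_*`, `sd_*` for the
#'   three quantities.
#' @export
pool_sides <- function(measurements) {
  m <- as.data.frame(measurements)
  need <- c("side", "length_AX_mm", "length_MX_mm", "angle_deg")
  if (!all(need %in% names(m))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(m) < 1L) stop("no measurements to pool")
  for (s in c("left", "right")) {
    if (!any(m$side == s)) stop("no measurements for side: ", s)
  }
  cell_stats <- function(d, cell) {
    data.frame(cell = cell, n = nrow(d),
               mean_length_AX_mm = mean(d$length_AX_mm),
               sd_length_AX_mm = stats::sd(d$length_AX_mm),
               mean_length_MX_mm = mean(d$length_MX_mm),
               sd_length_MX_mm = stats::sd(d$length_MX_mm),
               mean_angle_deg = mean(d$angle_deg),
               sd_angle_deg = stats::sd(d$angle_deg))
  }
  out <- rbind(cell_stats(m[m$side == "left", ], "left"),
               cell_stats(m[m$side == "right", ], "right"),
               cell_stats(m, "pooled"))
  class(out) <- c("cutting_guide_template", class(out))
  out
}
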