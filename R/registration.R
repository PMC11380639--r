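#' Local best-fit refinement (radius-trimmed iterative closest point)
#'
#' Refines an initial rigid alignment of a moving mesh onto a fixed mesh by
#' iterative closest point with a fixed correspondence radius: at every
#' iteration only moving samples whose closest point on the fixed surface lies
#' within `radius` participate in the least-squares update. This mirrors the
#' "local best fit" refinement used in industrial inspection software, whose
#' single published parameter is the 4.0 mm matching radius.
#'
#' Samples are the moving-mesh face centroids (all faces), weighted by face
#' area; correspondences are exact point-to-triangle closest points on the
#' fixed mesh and are re-trimmed at every iteration. Iterations stop when the
#' RMS residual over the current correspondence set changes by less than `tol`
#' or after `max_iter` iterations. The RMS over each iteration's correspondence
#' set is non-increasing across the Kabsch update by construction.
#'
#' @param moving,fixed [tri_mesh()] surfaces; `moving` is aligned onto `fixed`.
#' @param init a [rigid_transform()] initial alignment (e.g. from
#'   [kabsch_align()] on the three anatomical points).
#' @param radius correspondence radius in mm (default 4.0).
#' @param tol convergence tolerance on the RMS change, mm (default 1e-6).
#' @param max_iter maximum number of iterations (default 100).
#' @return a [rigid_transform()] mapping `moving` onto `fixed` (composed with
#'   `init`), with attributes `rms` (final RMS, mm), `n_matched` (samples in
#'   the final correspondence set), `iterations`, and `rms_trace` (per-iteration
#'   RMS after each update).
#' @export
local_best_fit <- function(moving, fixed, init = rigid_transform(),
                           radius = 4.0, tol = 1e-6, max_iter = 100L) {
  stopifnot_mesh(moving)
  stopifnot_mesh(fixed)
  if (!inherits(init, "rigid_transform")) stop("init must be a rigid_transform")
  samples <- mesh_centroids(moving)
  w <- mesh_areas(moving)
  current <- init
  cur <- apply_transform(samples, current)
  cp <- mesh_closest_point(cur, fixed)
  sel <- cp$dist <= radius
  if (!any(sel)) {
    stop(sprintf(
      "no correspondences within %.3g mm at the initial alignment; ",
      radius),
      "gross misalignment - check the 3-point landmark alignment")
  }
  rms <- sqrt(sum(w[sel] * cp$dist[sel]^2) / sum(w[sel]))
  trace_before <- numeric(0)
  trace_after <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # least-squares update on the current trimmed correspondence set
    upd <- kabsch_align(cur[sel, , drop = FALSE],
                        cp$point[sel, , drop = FALSE], weights = w[sel])
    candidate <- transform_compose(upd, current)
    new_pos <- apply_transform(samples, candidate)
    res <- new_pos[sel, , drop = FALSE] - cp$point[sel, , drop = FALSE]
    rms_after <- sqrt(sum(w[sel] * rowSums(res^2)) / sum(w[sel]))
    trace_before <- c(trace_before, rms)
    trace_after <- c(trace_after, rms_after)
    current <- candidate
    cur <- new_pos
    converged <- abs(rms - rms_after) < tol
    # re-trim for the next iteration
    cp <- mesh_closest_point(cur, fixed)
    sel <- cp$dist <= radius
    if (!any(sel)) {
      rms <- rms_after
      break
    }
    rms <- sqrt(sum(w[sel] * cp$dist[sel]^2) / sum(w[sel]))
    if (converged || iter >= max_iter) break
  }
  structure(current,
            rms = rms, n_matched = sum(sel), iterations = iter,
            rms_trace = trace_after, rms_trace_before = trace_before,
            class = class(current))
}

#' Three-point anatomical alignment
#'
#' Convenience wrapper: rigid alignment from a subject's `A`, `IOr`, `IOl`
#' landmarks onto the reference's, by [kabsch_align()]. This is the initial
#' alignment step before [local_best_fit()].
#'
#' @param subject_landmarks,reference_landmarks named lists containing `A`,
#'   `IOr` and `IOl` (length-3 numerics, mm).
#' @return a [rigid_transform()] mapping subject coordinates into the
#'   reference frame.
#' @export
three_point_alignment <- function(subject_landmarks, reference_landmarks) {
  need <- c("A", "IOr", "IOl")
  for (nm in need) {
    if (is.null(subject_landmarks[[nm]]) || is.null(reference_landmarks[[nm]]))
      stop("landmark '", nm, "' missing from one of the landmark sets")
  }
  s <- do.call(rbind, subject_landmarks[need])
  d <- do.call(rbind, reference_landmarks[need])
  kabsch_align(s, d)
}

#' Register a subject mesh to the reference
#'
#' Full registration: three-point landmark (Kabsch) alignment on `A`, `IOr`,
#' `IOl`, optionally refined by radius-trimmed ICP ([local_best_fit()]).
#'
#' @param subject,reference [tri_mesh()] surfaces.
#' @param subject_landmarks,reference_landmarks landmark sets containing at
#'   least `A`, `IOr`, `IOl`.
#' @param radius ICP correspondence radius, mm.
#' @param refine run the ICP refinement after the landmark alignment.
#' @param ... passed to [local_best_fit()].
#' @return a [rigid_transform()] mapping the subject into the reference frame.
#' @export
register_subject <- function(subject, reference, subject_landmarks,
                             reference_landmarks, radius = 4.0,
                             refine = TRUE, ...) {
  init <- three_point_alignment(subject_landmarks, reference_landmarks)
  if (!refine) return(init)
  local_best_fit(subject, reference, init = init, radius = radius, ...)
}
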