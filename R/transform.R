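#' Rigid transforms
#'
#' A rigid (proper orthogonal) transform `x -> R x + t` in mm. Reflections and
#' scaling are never produced: `R` is orthonormal with `det(R) = +1`.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("rotation must be 3x3 and translation length 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be proper (det +1, no reflection)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1L], x$translation[2L], x$translation[3L]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x a `rigid_transform`.
#' @export
transform_inverse <- function(x) {
  rigid_transform(t(x$rotation), -as.vector(t(x$rotation) %*% x$translation))
}

#' @rdname rigid_transform
#' @param first,second transforms; the composition applies `first`, then
#'   `second`.
#' @export
transform_compose <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.vector(second$rotation %*% first$translation) +
                    second$translation)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3 x 3 rotation matrix.
#' @return the rotation angle in degrees (geodesic distance from identity).
#' @export
rotation_angle_deg <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Euler-angle rotation (XYZ intrinsic order)
#'
#' @param rx,ry,rz rotations about x, y, z in degrees, applied in that order.
#' @return 3 x 3 rotation matrix `Rz %*% Ry %*% Rx`.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  a <- rx * pi / 180; b <- ry * pi / 180; c3 <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c3), -sin(c3), 0), c(sin(c3), cos(c3), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform
#'
#' Meshes, point matrices, single points and named landmark lists all transform
#' by the same map `x -> R x + t`.
#'
#' @param x a [tri_mesh()], a q x 3 matrix, a length-3 numeric, or a named list
#'   of length-3 numerics (a landmark set).
#' @param transform a [rigid_transform()].
#' @return the same kind of object, transformed.
#' @export
apply_transform <- function(x, transform) {
  if (!inherits(transform, "rigid_transform")) stop("expected a rigid_transform")
  R <- transform$rotation
  t <- transform$translation
  tp <- function(m) sweep(m %*% t(R), 2L, t, `+`)
  if (inherits(x, "tri_mesh")) {
    tri_mesh(tp(x$vertices), x$faces)
  } else if (is.matrix(x)) {
    tp(x)
  } else if (is.numeric(x) && length(x) == 3L) {
    as.vector(R %*% x) + t
  } else if (is.list(x)) {
    lapply(x, function(p) as.vector(R %*% as.numeric(p)) + t)
  } else {
    stop("cannot transform object of class ", paste(class(x), collapse = "/"))
  }
}

#' Least-squares rigid alignment of paired points (Kabsch)
#'
#' Finds the rigid transform (rotation + translation, no scaling, no
#' reflection) minimizing the weighted sum of squared distances
#' `sum w_i || R s_i + t - d_i ||^2` between corresponding source and target
#' points. Used both for the initial 3-point anatomical alignment (A-point,
#' IOr, IOl) and inside the trimmed-ICP refinement.
#'
#' @param source_points,target_points n x 3 matrices of corresponding points,
#'   n >= 3, not collinear.
#' @param weights optional positive weights, length n.
#' @return a [rigid_transform()] mapping source onto target.
#' @export
kabsch_align <- function(source_points, target_points, weights = NULL) {
  s <- rbind(source_points)
  d <- rbind(target_points)
  if (nrow(s) != nrow(d)) stop("point lists must have equal length")
  if (nrow(s) < 3L) stop("at least 3 point pairs are required")
  if (is.null(weights)) weights <- rep(1, nrow(s))
  w <- weights / sum(weights)
  cs <- colSums(s * w)
  cd <- colSums(d * w)
  s0 <- sweep(s, 2L, cs)
  d0 <- sweep(d, 2L, cd)
  if (collinear_points(s0) || collinear_points(d0)) {
    stop("points are collinear; a unique rigid alignment does not exist")
  }
  H <- t(s0 * w) %*% d0
  sv <- svd(H)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  rigid_transform(R, cd - as.vector(R %*% cs))
}

collinear_points <- function(p0) {
  # smallest principal extent ~ 0 in two directions <=> collinear;
  # equivalently the largest pairwise triangle area is ~ 0
  if (nrow(p0) == 3L) {
    a <- p0[2L, ] - p0[1L, ]
    b <- p0[3L, ] - p0[1L, ]
    cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
            a[3L] * b[1L] - a[1L] * b[3L],
            a[1L] * b[2L] - a[2L] * b[1L])
    return(0.5 * sqrt(sum(cr^2)) <= 1e-6)
  }
  ev <- svd(p0, nu = 0, nv = 0)$d
  ev[2L] < 1e-8 * max(ev[1L], 1e-12)
}

#' Serialize rigid transforms as JSON
#'
#' Stored as `{"R": [[...],[...],[...]], "t": [tx, ty, tz]}` with the rotation
#' in row-major order and translation in mm.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(R = transform$rotation, t = transform$translation),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(as.matrix(obj$R), as.numeric(obj$t))
}
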