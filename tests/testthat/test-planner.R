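test_that("J point maximizes the caudal-lateral score (brute-force oracle)", {
  # three-vertex region with distinct caudal/lateral trade-offs
  v <- rbind(c(0, 0, 0), c(10, 0, -5), c(2, 0, -5), c(0, 0, 10))
  m <- tri_mesh(v, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  J <- locate_J(m, c(1L, 2L), weights = c(1, 1))
  # brute force over all region vertices with the same standardization
  vids <- sort(unique(as.vector(m$faces)))
  sx <- (abs(v[vids, 1]) - min(abs(v[, 1]))) / diff(range(abs(v[, 1])))
  sz <- (v[vids, 3] - min(v[, 3])) / diff(range(v[, 3]))
  best <- vids[which.max(-sz + sx)]
  expect_equal(as.numeric(J), v[best, ])
  expect_equal(attr(J, "vertex_index"), best)
  # vertex (10, 0, -5): caudal AND most lateral wins
  expect_equal(as.numeric(J), c(10, 0, -5))
})

test_that("J tie-breaking picks the lowest vertex index", {
  v <- rbind(c(5, 0, -5), c(-5, 0, -5), c(0, 0, 5)) # 1 and 2 tie on score
  m <- tri_mesh(v, rbind(c(1L, 2L, 3L)))
  J <- locate_J(m, 1L)
  expect_equal(attr(J, "vertex_index"), 1L)
  # single-vertex region degenerates to that vertex
  m2 <- tri_mesh(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
                 rbind(c(1L, 2L, 3L)))
  expect_error(locate_J(m2, integer(0)), "empty")
})

test_that("O point is the analytic foot point on the rim", {
  rim <- rbind(c(0, 0, 0), c(10, 0, 0)) # straight rim along X
  O <- locate_O(rim, c(3, 4, 0))
  expect_equal(as.numeric(O), c(3, 0, 0), tolerance = 1e-12)
  # J on the polyline: O = J
  expect_equal(as.numeric(locate_O(rim, c(5, 0, 0))), c(5, 0, 0))
  # beyond the end: clamped to the end vertex
  expect_equal(as.numeric(locate_O(rim, c(15, 2, 0))), c(10, 0, 0))
  # equidistant to two segments: the earlier one wins
  rim2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0))
  O2 <- locate_O(rim2, c(2, 0, 0) + c(1, 1, 0) * 0) # on the shared vertex
  expect_equal(attr(O2, "segment"), 1L)
  expect_error(locate_O(rim[1, , drop = FALSE], c(0, 0, 0)), "2 vertices")
})

test_that("constructed landmarks satisfy the midpoint invariant and pass-through", {
  ref <- ref_phantom()
  lm <- construct_landmarks(ref$mesh, ref$regions, ref$rims,
                            annotations = ref$landmarks)
  for (side in c("right", "left")) {
    expect_equal(lm[[paste0("M_", side)]],
                 (lm[[paste0("J_", side)]] + lm[[paste0("O_", side)]]) / 2,
                 tolerance = 1e-12)
  }
  expect_equal(lm$A, ref$landmarks$A)
  expect_equal(lm$X_left, ref$landmarks$X_left)
  # missing premolar apex names the side
  bad <- ref$landmarks
  bad$X_left <- NULL
  expect_error(construct_landmarks(ref$mesh, ref$regions, ref$rims, bad),
               "left")
})

test_that("landmarks of a rigidly moved mesh are the moved landmarks", {
  ref <- ref_phantom()
  tr <- rigid_transform(euler_rotation(4, -3, 7), c(3, -2, 5))
  moved <- apply_transform(ref$mesh, tr)
  moved_rims <- lapply(ref$rims, function(p) apply_transform(p[, , drop = FALSE], tr))
  lm <- construct_landmarks(moved, ref$regions, moved_rims,
                            annotations = apply_transform(ref$landmarks, tr))
  expect_equal(lm[c("A", "J_right", "O_right", "M_right", "X_right")],
               apply_transform(ref$landmarks, tr)[
                 c("A", "J_right", "O_right", "M_right", "X_right")],
               tolerance = 1e-6)
})

test_that("three-point angle matches analytic triples", {
  O <- c(0, 0, 0)
  expect_equal(three_point_angle(c(1, 0, 0), O, c(0, 1, 0)), 90)
  expect_equal(three_point_angle(c(1, 0, 0), O, c(-2, 0, 0)), 180)
  expect_equal(three_point_angle(c(1, 0, 0), O, c(1, 1, 0)), 45,
               tolerance = 1e-12)
  # symmetry in the outer points
  set.seed(3)
  for (i in 1:10) {
    p <- stats::rnorm(3); q <- stats::rnorm(3); v <- stats::rnorm(3)
    expect_equal(three_point_angle(p, v, q), three_point_angle(q, v, p),
                 tolerance = 1e-12)
  }
  expect_error(three_point_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "nonzero")
})

test_that("segment measurement equals direct vector arithmetic", {
  lm <- list(A = c(0, 0, 0), M_left = c(3, 4, 12), X_left = c(3, 4, 0))
  m <- measure_segments(lm, "left", subject_id = 9)
  expect_equal(m$length_AX_mm, 5) # 3-4-5 triangle
  expect_equal(m$length_MX_mm, 12)
  expect_equal(m$angle_deg,
               three_point_angle(lm$A, lm$X_left, lm$M_left))
  expect_equal(m$subject_id, 9)
  # collinear with X between A and M: 180 degrees
  lm2 <- list(A = c(0, 0, 0), M_right = c(2, 0, 0), X_right = c(1, 0, 0))
  expect_equal(measure_segments(lm2, "right")$angle_deg, 180)
  expect_error(measure_segments(list(A = c(0, 0, 0)), "left"), "missing")
})

test_that("lengths and angles are invariant under rigid transforms", {
  ref <- ref_phantom()
  set.seed(11)
  base <- rbind(measure_segments(ref$landmarks, "left"),
                measure_segments(ref$landmarks, "right"))
  for (i in 1:10) {
    tr <- random_rigid()
    lm <- apply_transform(ref$landmarks, tr)
    moved <- rbind(measure_segments(lm, "left"), measure_segments(lm, "right"))
    expect_equal(moved$length_AX_mm, base$length_AX_mm, tolerance = 1e-9)
    expect_equal(moved$length_MX_mm, base$length_MX_mm, tolerance = 1e-9)
    expect_equal(moved$angle_deg, base$angle_deg, tolerance = 1e-9)
  }
})

test_that("side pooling reproduces hand-computed means", {
  m <- data.frame(side = c("left", "left", "right", "right"),
                  length_AX_mm = c(1, 3, 5, 7),
                  length_MX_mm = c(2, 2, 4, 4),
                  angle_deg = c(100, 110, 120, 130))
  tp <- pool_sides(m)
  pooled <- tp[tp$cell == "pooled", ]
  expect_equal(pooled$mean_length_AX_mm, 4)
  expect_equal(pooled$n, 4L)
  expect_equal(tp$n[tp$cell == "left"], 2L)
  # equal-n identity: pooled mean = mean of side means
  expect_equal(pooled$mean_angle_deg,
               mean(c(tp$mean_angle_deg[tp$cell == "left"],
                      tp$mean_angle_deg[tp$cell == "right"])))
  # degenerate: one identical measurement per side
  m2 <- data.frame(side = c("left", "right"), length_AX_mm = 10,
                   length_MX_mm = 10, angle_deg = 10)
  tp2 <- pool_sides(m2)
  expect_equal(tp2$mean_length_AX_mm[tp2$cell == "pooled"], 10)
  expect_equal(tp2$sd_length_AX_mm[tp2$cell == "pooled"], 0)
  expect_error(pool_sides(m[m$side == "left", ]), "right")
})
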