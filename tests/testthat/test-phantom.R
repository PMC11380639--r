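test_that("reference phantom has disjoint region labels covering a strict subset", {
  ref <- ref_phantom()
  expect_length(ref$regions, 8L)
  all_idx <- unlist(ref$regions, use.names = FALSE)
  expect_equal(anyDuplicated(all_idx), 0L) # pairwise disjoint
  expect_lt(length(all_idx), nrow(ref$mesh$faces)) # strict subset
  expect_true(all(vapply(ref$regions, length, integer(1)) > 0L))
})

test_that("every reference landmark lies on the phantom surface", {
  ref <- ref_phantom()
  pts <- do.call(rbind, ref$landmarks)
  cp <- mesh_closest_point(pts, ref$mesh)
  expect_lt(max(cp$dist), 1e-6)
  # normals are outward: anterior (+Y) on average
  expect_gt(mean(mesh_face_normals(ref$mesh)[, 2]), 0.5)
})

test_that("phantom construction is deterministic and resolution-validated", {
  a <- make_reference_phantom("coarse")
  b <- make_reference_phantom("coarse")
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$regions, b$regions)
  expect_error(make_reference_phantom(8), "500")
})

test_that("an all-zero spec reproduces the reference up to the recorded transform", {
  ref <- ref_phantom()
  spec <- null_spec(seed = 5, n = 1, misalign = c(translation_mm = 0,
                                                  rotation_deg = 0))
  s <- synthesize_subject(ref, spec, 1)
  expect_equal(s$mesh$vertices, ref$mesh$vertices, tolerance = 1e-12)
  expect_identical(s$mesh$faces, ref$mesh$faces)
  expect_equal(s$landmarks, ref$landmarks, tolerance = 1e-12)
})

test_that("region offsets displace vertices along the normal by the drawn amount", {
  ref <- ref_phantom()
  spec <- phantom_spec(seed = 3, n_subjects = 1,
                       region_offset_mean = list(male = c(-2, 0, 0, 0),
                                                 female = c(-2, 0, 0, 0)),
                       region_offset_sd = 0, noise_sd = 0,
                       dropout_fraction = 0, landmark_jitter_sd = 0,
                       misalignment = c(translation_mm = 0, rotation_deg = 0))
  s <- synthesize_subject(ref, spec, 1)
  vn <- mesh_vertex_normals(ref$mesh)
  delta <- s$mesh$vertices - ref$mesh$vertices
  r1_vids <- unique(as.vector(ref$mesh$faces[
    c(ref$regions$R1_right, ref$regions$R1_left), ]))
  # signed normal displacement in the deviation convention (outward = negative)
  disp <- -rowSums(delta[r1_vids, ] * vn[r1_vids, ])
  expect_equal(mean(disp), -2, tolerance = 1e-6)
  expect_lt(max(abs(disp + 2)), 1e-6)
  # other regions untouched
  untouched <- setdiff(seq_len(nrow(ref$mesh$vertices)), r1_vids)
  expect_lt(max(abs(delta[untouched, ])), 1e-12)
})

test_that("R4 dropout removes a contiguous patch of about the requested area", {
  ref <- ref_phantom()
  spec <- phantom_spec(seed = 9, n_subjects = 1, dropout_fraction = 0.3,
                       region_offset_mean = list(male = c(0, 0, 0, 0),
                                                 female = c(0, 0, 0, 0)),
                       region_offset_sd = 0, noise_sd = 0,
                       landmark_jitter_sd = 0)
  s <- synthesize_subject(ref, spec, 1)
  areas <- mesh_areas(ref$mesh)
  r4 <- c(ref$regions$R4_right, ref$regions$R4_left)
  removed <- s$truth$removed_faces
  expect_true(all(removed %in% r4))
  frac <- sum(areas[removed]) / sum(areas[r4])
  expect_equal(frac, 0.3, tolerance = 0.05)
  expect_equal(s$truth$dropout_area, sum(areas[removed]))
  expect_equal(nrow(s$mesh$faces), nrow(ref$mesh$faces) - length(removed))
})

test_that("subject landmarks are the rigidly transformed reference landmarks", {
  ref <- ref_phantom()
  spec <- null_spec(seed = 13, n = 2)
  s <- synthesize_subject(ref, spec, 2)
  expect_equal(s$landmarks,
               apply_transform(ref$landmarks, s$truth$applied_transform),
               tolerance = 1e-9)
  # recorded rotation is proper orthonormal
  R <- s$truth$applied_transform$rotation
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
  expect_equal(det(R), 1, tolerance = 1e-8)
})

test_that("cohorts honour the sex ratio and are bit-identical under a seed", {
  spec <- phantom_spec(seed = 17, n_subjects = 50, sex_ratio = 0.68,
                       noise_sd = 0, dropout_fraction = 0,
                       landmark_jitter_sd = 0)
  ref <- ref_phantom()
  demo1 <- maxillomorph:::cohort_demographics(spec)
  expect_equal(sum(demo1$sex == "male"), 34L)
  expect_equal(sum(demo1$sex == "female"), 16L)
  expect_true(all(demo1$age >= 20 & demo1$age <= 89))

  small <- phantom_spec(seed = 23, n_subjects = 2, noise_sd = 0.2)
  c1 <- synthesize_cohort(small, reference = ref)
  c2 <- synthesize_cohort(small, reference = ref)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$subjects[[2]]$mesh$vertices,
                   c2$subjects[[2]]$mesh$vertices)
  expect_equal(nrow(c1$truth), 2L)
  one <- synthesize_cohort(phantom_spec(seed = 1, n_subjects = 1),
                           reference = ref)
  expect_equal(nrow(one$truth), 1L)
})

test_that("phantom spec rejects invalid parameters", {
  expect_error(phantom_spec(n_subjects = 0), "n_subjects")
  expect_error(phantom_spec(dropout_fraction = 1.2), "dropout_fraction")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
})
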