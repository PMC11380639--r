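test_that("region sampling produces one area-weighted sample per face", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  s1 <- sample_region(m, 1L)
  expect_equal(nrow(s1$points), 1L)
  expect_equal(s1$area_weights, 0.5)
  expect_equal(abs(s1$normals[1, 3]), 1)
  s2 <- sample_region(m, c(1L, 2L))
  expect_equal(sum(s2$area_weights), 1.0, tolerance = 1e-12)
  expect_error(sample_region(m, integer(0)), "empty")

  sheet <- square_sheet(n = 7, size = 10) # planar square, area 100
  ss <- sample_region(sheet, seq_len(nrow(sheet$faces)))
  expect_equal(sum(ss$area_weights), 100, tolerance = 1e-6)
})

test_that("zero deviation for an identical subject", {
  ref <- ref_phantom()
  smp <- sample_region(ref$mesh, ref$regions$R2_right)
  for (method in c("closest", "normal")) {
    fld <- signed_deviation(smp, ref$mesh, method = method)
    expect_true(all(fld$valid))
    expect_lt(max(abs(fld$d)), 1e-9)
    sm <- summarize_region(fld)
    expect_equal(sm$Dmean, 0, tolerance = 1e-9)
    expect_equal(sm$ID, 0, tolerance = 1e-9)
    expect_equal(sm$IAD, 0, tolerance = 1e-9)
    expect_equal(sm$AVD, sum(smp$area_weights), tolerance = 1e-9)
  }
})

test_that("concentric spheres give the analytic signed deviation", {
  refs <- mesh_sphere(30, 5)
  subj <- mesh_sphere(32, 5)
  smp <- sample_region(refs, seq_len(nrow(refs$faces)))
  for (method in c("closest", "normal")) {
    fld <- signed_deviation(smp, subj, window = 5, method = method)
    expect_true(all(fld$valid))
    # subject outside the reference => negative, magnitude 2 mm
    expect_lt(max(abs(fld$d + 2)), 0.02)
    sm <- summarize_region(fld)
    expect_equal(sm$ID, sm$Dmean * sm$AVD, tolerance = 1e-12)
    expect_equal(sm$IAD, abs(sm$ID), tolerance = 1e-12)
    expect_lt(sm$DSD, 0.02)
    S <- sum(smp$area_weights)
    expect_equal(sm$ID, -2 * S, tolerance = 0.02 * S)
  }
})

test_that("deviations beyond the window are invalid, not clipped", {
  refs <- mesh_sphere(30, 3)
  far <- mesh_sphere(36, 3) # 6 mm > 5 mm window
  smp <- sample_region(refs, seq_len(nrow(refs$faces)))
  fld <- signed_deviation(smp, far, window = 5)
  expect_false(any(fld$valid))
  expect_true(all(is.na(fld$d)))
  sm <- summarize_region(fld)
  expect_equal(sm$AVD, 0)
  expect_true(is.na(sm$Dmean))
})

test_that("summary respects hand-computed weighted identities", {
  fld <- structure(list(d = c(-1, 1), valid = c(TRUE, TRUE),
                        area_weights = c(3, 3), window = 5,
                        method = "closest"), class = "deviation_field")
  sm <- summarize_region(fld)
  expect_equal(sm$Dmean, 0)
  expect_equal(sm$ID, 0)
  expect_equal(sm$IAD, 6) # 2 * a with a = 3
  expect_equal(sm$Dmax, 1)
  expect_equal(sm$Dmin, -1)
  expect_equal(sm$DSD, 1)
  # unequal weights: Dmean pulled toward the larger-area sample
  fld2 <- structure(list(d = c(-1, 1), valid = c(TRUE, TRUE),
                         area_weights = c(3, 1), window = 5,
                         method = "closest"), class = "deviation_field")
  sm2 <- summarize_region(fld2)
  expect_equal(sm2$Dmean, -0.5)
  expect_equal(sm2$ID, sm2$Dmean * sm2$AVD, tolerance = 1e-12)
  expect_gte(sm2$IAD, abs(sm2$ID))
})

test_that("translation along the normal shifts Dmean by the same amount, sign flipped", {
  sheet <- square_sheet(n = 8, size = 20) # normals +Z
  smp <- sample_region(sheet, seq_len(nrow(sheet$faces)))
  up <- apply_transform(sheet, rigid_transform(diag(3), c(0, 0, 1)))
  for (method in c("closest", "normal")) {
    fld <- signed_deviation(smp, up, method = method)
    expect_equal(summarize_region(fld)$Dmean, -1, tolerance = 1e-9)
  }
  down <- apply_transform(sheet, rigid_transform(diag(3), c(0, 0, -1)))
  expect_equal(summarize_region(signed_deviation(smp, down))$Dmean, 1,
               tolerance = 1e-9)
})

test_that("phantom offsets are recovered as Dmean with matching sign", {
  ref <- ref_phantom()
  spec <- phantom_spec(seed = 4, n_subjects = 1,
                       region_offset_mean = list(male = c(-2, 0, 1, 0),
                                                 female = c(-2, 0, 1, 0)),
                       region_offset_sd = 0, noise_sd = 0,
                       dropout_fraction = 0, landmark_jitter_sd = 0,
                       misalignment = c(translation_mm = 0, rotation_deg = 0))
  s <- synthesize_subject(ref, spec, 1)
  for (rg in c("R1_right", "R3_left", "R2_right")) {
    smp <- sample_region(ref$mesh, ref$regions[[rg]])
    fld <- signed_deviation(smp, s$mesh, method = "normal")
    expected <- c(R1_right = -2, R3_left = 1, R2_right = 0)[[rg]]
    expect_equal(summarize_region(fld)$Dmean, expected, tolerance = 0.02)
  }
})

test_that("R4 dropout reduces the valid area by about the removed fraction", {
  ref <- ref_phantom()
  spec <- phantom_spec(seed = 8, n_subjects = 1, dropout_fraction = 0.3,
                       region_offset_mean = list(male = c(0, 0, 0, 0),
                                                 female = c(0, 0, 0, 0)),
                       region_offset_sd = 0, noise_sd = 0,
                       landmark_jitter_sd = 0,
                       misalignment = c(translation_mm = 0, rotation_deg = 0))
  s <- synthesize_subject(ref, spec, 1)
  for (side in c("right", "left")) {
    rg <- paste0("R4_", side)
    smp <- sample_region(ref$mesh, ref$regions[[rg]])
    fld <- signed_deviation(smp, s$mesh, method = "normal")
    frac <- summarize_region(fld)$AVD / sum(smp$area_weights)
    expect_equal(frac, 0.7, tolerance = 0.05)
  }
})

test_that("false colours follow the sign and band semantics", {
  fld <- structure(list(d = c(0, -0.5, 0.99, -3.2, 1.0, 4.9, NA),
                        valid = c(rep(TRUE, 6), FALSE),
                        area_weights = rep(1, 7), window = 5,
                        method = "closest"), class = "deviation_field")
  fc <- false_color(fld, green_band = 1)
  expect_equal(as.character(fc$color),
               c("green", "green", "green", "blue", "red", "red", "grey"))
  expect_equal(fc$intensity[1:3], c(0, 0, 0))
  expect_equal(fc$intensity[4], (3.2 - 1) / 4, tolerance = 1e-12)
  expect_equal(fc$intensity[5], 0, tolerance = 1e-12)
  expect_equal(fc$intensity[6], 3.9 / 4, tolerance = 1e-12)
  expect_equal(fc$intensity[7], 0)
})

test_that("false-colour PLY export writes vertex colours", {
  ref <- ref_phantom()
  smp <- sample_region(ref$mesh, ref$regions$R1_right)
  fld <- signed_deviation(smp, ref$mesh)
  p <- tempfile(fileext = ".ply")
  export_colored_ply(ref$mesh, ref$regions$R1_right, fld, p)
  lines <- readLines(p)
  expect_true(any(grepl("property uchar red", lines)))
  m <- read_ply(p)
  expect_equal(nrow(m$faces), length(ref$regions$R1_right))
})
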