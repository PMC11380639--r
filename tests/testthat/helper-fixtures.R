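# Shared fixtures, built once per test run.

# coarse reference phantom (most tests share it; construction is deterministic)
ref_phantom <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- make_reference_phantom("coarse")
    ref
  }
})

# a spec with every deformation switched off: subjects differ from the
# reference by a rigid transform only
null_spec <- function(seed = 1L, n = 2L, misalign = c(translation_mm = 5,
                                                      rotation_deg = 5)) {
  phantom_spec(seed = seed, n_subjects = n,
               region_offset_mean = list(male = c(0, 0, 0, 0),
                                         female = c(0, 0, 0, 0)),
               region_offset_sd = 0, noise_sd = 0, dropout_fraction = 0,
               landmark_jitter_sd = 0, misalignment = misalign)
}

random_rigid <- function() {
  rigid_transform(euler_rotation(stats::runif(1, -180, 180),
                                 stats::runif(1, -90, 90),
                                 stats::runif(1, -180, 180)),
                  stats::runif(3, -30, 30))
}

# small axis-aligned square sheet in the XY plane (z = 0), outward normal +Z
square_sheet <- function(n = 10, size = 10) {
  xs <- seq(0, size, length.out = n + 1)
  g <- expand.grid(x = xs, y = xs)
  verts <- cbind(g$x, g$y, 0)
  vid <- function(i, j) (j - 1L) * (n + 1L) + i
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  faces <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                 cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  tri_mesh(verts, faces)
}
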