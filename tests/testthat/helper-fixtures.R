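# Shared fixtures, built in code at test time.

# reduced scan geometry used throughout the suite: 4 mm lateral field at
# 20 um/px, 3.2 mm depth at 16 um/px, cropped to 120 rows
small_scan <- function(n_alines = 200L) {
  scan_config(lateral_fov = 4, n_alines = n_alines, depth_pixels = 200L,
              depth_crop = 120L, depth_fov = 3.2)
}

small_source <- function() source_spectrum(n_samples = 512L)

# toy linearly separable image set: bright-left vs bright-right
toy_separable <- function(n = 20L, px = 32L, seed = 3L) {
  set.seed(seed)
  imgs <- lapply(seq_len(n), function(i) {
    m <- matrix(runif(px * px, 0, 60), px, px)
    half <- seq_len(px %/% 2L)
    if (i %% 2L == 0L) m[, half] <- m[, half] + 120 else m[, -half] <- m[, -half] + 120
    m
  })
  list(images = imgs,
       labels = ifelse(seq_len(n) %% 2L == 0L, "male", "female"))
}

# a small imaged cohort shared by preprocessing/evaluation tests
tiny_dataset <- function(n_chicks = 6L, frames = 5L, keep = 4L,
                         ambiguous_rate = 0, seed = 42L,
                         speckle = 0.05) {
  simulate_cohort(
    cohort_spec(n_chicks = n_chicks, frames_per_chick = frames,
                keep_per_chick = keep, ambiguous_rate = ambiguous_rate,
                seed = seed),
    phantom_params(speckle_scale = speckle),
    small_source(), small_scan())
}
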