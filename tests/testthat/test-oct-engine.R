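test_that("interferograms follow the forward model", {
  src <- small_source()
  # no sample arm: spectrum equals the source envelope exactly, and the
  # reconstruction is dark away from zero depth
  ig0 <- simulate_interferogram(numeric(150), src, depth_pitch = 16)
  expect_equal(ig0$intensities, ig0$background)
  env0 <- reconstruct_aline(ig0, depth_pixels = 150)
  expect_lt(max(env0), 1e-9)

  prof <- numeric(150); prof[40] <- 0.8
  ig <- simulate_interferogram(prof, src, depth_pitch = 16)
  expect_true(all(ig$intensities >= 0))
  expect_error(simulate_interferogram(numeric(0), src), "empty")
  expect_error(simulate_interferogram(c(0.5, 2), src), "\\[0,1\\]")
  expect_equal(source_spectrum()$center_wavelength, 840)
})

test_that("a single reflector produces the analytic fringe frequency", {
  src <- small_source()
  for (bin in c(25L, 60L, 110L)) {
    prof <- numeric(150); prof[bin] <- 1
    ig <- simulate_interferogram(prof, src, depth_pitch = 16)
    # oracle: direct O(n^2) DFT of the background-subtracted spectrum
    mags <- brute_dft_mag(ig$intensities - ig$background)
    expect_equal(which.max(mags[2:151]), bin)
    # implementation agrees with the brute-force sum at every kept bin
    env <- reconstruct_aline(ig, depth_pixels = 150)
    expect_equal(env, mags[2:151], tolerance = 1e-8)
  }
})

test_that("constant spectra reconstruct to zero away from DC", {
  env <- reconstruct_aline(rep(7, 512), depth_pixels = 200)
  expect_true(all(env < 1e-9))
})

test_that("reconstruction rejects mismatched background lengths", {
  expect_error(reconstruct_aline(runif(64), background = runif(32)),
               "does not match")
})

test_that("axial resolution matches the coherence-length prediction", {
  ar <- axial_resolution()
  expect_equal(ar$theory_um, 2 * log(2) / pi * 0.84^2 / 0.031, tolerance = 1e-12)
  expect_lt(abs(ar$fwhm_um - ar$theory_um) / ar$theory_um, 0.2)
  # the configured default bandwidth was chosen to land near 10 um
  expect_lt(abs(ar$fwhm_um - 10) / 10, 0.2)
})

test_that("normalization scales the maximum to exactly one", {
  g <- matrix(5, 4, 4)
  expect_true(all(normalize_bscan(g) == 1))
  set.seed(1)
  x <- matrix(runif(200, 0.01, 7), 10, 20)
  expect_equal(normalize_bscan(x), x / max(x))
  expect_identical(max(normalize_bscan(x)), 1)
  # idempotence
  expect_identical(normalize_bscan(normalize_bscan(x)), normalize_bscan(x))
  expect_error(normalize_bscan(matrix(0, 3, 3)), "positive")
})

test_that("log compression maps the dynamic range onto [0,255] monotonely", {
  expect_identical(log_compress_u8(1), 255L)
  expect_identical(log_compress_u8(10^(-50 / 20)), 0L)
  expect_identical(log_compress_u8(0), 0L)
  # half the dynamic range in dB -> mid grey (direct affine-in-dB oracle)
  expect_lte(abs(log_compress_u8(10^(-25 / 20)) - 128L), 1L)
  # monotone on sorted inputs
  set.seed(2)
  x <- sort(runif(500))
  expect_true(all(diff(log_compress_u8(x)) >= 0L))
  expect_error(log_compress_u8(0.5, floor_db = 10), "negative")
  expect_error(log_compress_u8(1.5), "\\[0,1\\]")
})

test_that("B-scans have the configured cropped geometry", {
  cfg <- small_scan()
  ph <- make_phantom("male", seed = 4)
  map <- rasterize_phantom(ph, cfg$depth_pixels, cfg$n_alines,
                           cfg$depth_pitch, cfg$lateral_pitch)
  bs <- scan_bscan(map, source = small_source(), config = cfg,
                   speckle_scale = 0.1, seed = 1, chick_id = 1,
                   frame_index = 2, label = "male")
  expect_equal(dim(bs$pixels), c(120L, 200L))
  expect_true(all(bs$pixels >= 0L & bs$pixels <= 255L))
  expect_error(scan_bscan(map[["values"]][, 1:50], source = small_source(),
                          config = cfg), "lateral")
})

test_that("isolated reflectors land on their ground-truth pixel", {
  cfg <- small_scan(n_alines = 64L)
  sim <- oct_simulator(small_source(), cfg)
  set.seed(7)
  for (trial in 1:5) {
    row <- sample(10:110, 1); col <- sample(2:63, 1)
    R <- matrix(0, cfg$depth_pixels, cfg$n_alines)
    R[row, col] <- 1
    bs <- scan_bscan(R, sim = sim, noise_floor = 0)
    peak <- which(bs$pixels == max(bs$pixels), arr.ind = TRUE)[1, ]
    expect_lte(abs(peak["row"] - row), 1)
    expect_equal(unname(peak["col"]), col)
  }
})

test_that("empty scenes reject normalization or stay near-black with noise", {
  cfg <- small_scan(n_alines = 32L)
  R <- matrix(0, cfg$depth_pixels, cfg$n_alines)
  expect_error(scan_bscan(R, source = small_source(), config = cfg,
                          noise_floor = 0), "positive")
  bs <- scan_bscan(R, source = small_source(), config = cfg,
                   noise_floor = 1e-3, seed = 3)
  expect_true(all(bs$pixels >= 0L & bs$pixels <= 255L))
  # noise-only image: no lateral structure, so neighbouring A-lines are
  # uncorrelated (a tissue scene correlates strongly)
  r <- cor(as.vector(bs$pixels[, -1]), as.vector(bs$pixels[, -ncol(bs$pixels)]))
  expect_lt(abs(r), 0.15)
})
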