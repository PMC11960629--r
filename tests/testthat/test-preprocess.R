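test_that("enhancement is identity on flat or disabled input", {
  flat <- matrix(120, 30, 40)
  expect_equal(enhance_image(flat), flat)
  off <- preprocess_config(denoise = "none", contrast = "none",
                           sharpen = "none")
  set.seed(1)
  img <- matrix(sample(0:255, 1200, TRUE), 30, 40)
  expect_identical(enhance_image(img, off), img)
  expect_error(enhance_image(img, preprocess_config(denoise = "wavelet")),
               "unknown denoise")
})

test_that("median denoising pulls salt-and-pepper images toward the clean one", {
  clean <- matrix(0, 60, 80)
  clean[25:35, ] <- 200  # a bright band, as a tissue surface
  set.seed(4)
  corrupt <- clean
  hits <- sample(length(clean), 300)
  corrupt[hits] <- ifelse(runif(300) < 0.5, 0, 255)
  cfg <- preprocess_config(contrast = "none", sharpen = "none")
  denoised <- enhance_image(corrupt, cfg)
  expect_lt(mean(abs(denoised - clean)), mean(abs(corrupt - clean)))
})

test_that("median filter agrees with an independent implementation", {
  set.seed(9)
  img <- matrix(runif(30 * 20, 0, 255), 30, 20)
  ours <- enhance_image(img, preprocess_config(contrast = "none",
                                               sharpen = "none"))
  # oracle: EBImage median filter on the interior (border conventions differ)
  # EBImage quantizes internally, so agreement is to ~1e-3 relative
  ref <- EBImage::medianFilter(t(img) / 255, size = 1) * 255
  expect_equal(ours[2:29, 2:19], t(ref)[2:29, 2:19], tolerance = 1e-3)
})

test_that("quality selection keeps the top-scoring frames deterministically", {
  expect_equal(quality_select(c(3, 1, 2, 5), keep = 2), c(1L, 4L))
  expect_equal(quality_select(rep(1, 4), keep = 4), 1:4)      # keep-all
  expect_equal(quality_select(c(2, 2, 2), keep = 2), c(1L, 2L))  # tie by index
  expect_error(quality_select(1:3, keep = 4), "exceeds")
  # blank frames score zero and drop first
  structured <- matrix(0, 40, 40); structured[15:20, ] <- 180
  blank <- matrix(0, 40, 40)
  expect_gt(quality_score(structured), quality_score(blank))
  keep <- quality_select(list(structured, blank, structured), keep = 2)
  expect_equal(keep, c(1L, 3L))
})

test_that("augmentation building blocks behave as involutions/identities", {
  set.seed(2)
  img <- matrix(runif(40 * 30, 0, 255), 40, 30)
  cfg <- preprocess_config(brightness_target = NA)
  expect_identical(augment_image(img, config = cfg, angle = 0, flip = FALSE)[[1]],
                   img)
  expect_identical(flip_horizontal(flip_horizontal(img)), img)
  expect_error(augment_image(img, config = cfg, angle = 40), "exceeds")
  # rotation preserves shape and is deterministic
  a <- augment_image(img, config = cfg, seed = 5)
  b <- augment_image(img, config = cfg, seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a[[1]]), dim(img))
})

test_that("brightness normalization hits the configured target mean", {
  set.seed(6)
  img <- matrix(runif(500, 20, 80), 20, 25)
  out <- normalize_brightness(img, target_mean = 100)
  expect_equal(mean(out), 100, tolerance = 1e-8)
  cfg <- preprocess_config(brightness_target = 90)
  aug <- augment_image(img, config = cfg, seed = 1)[[1]]
  expect_equal(mean(aug), 90, tolerance = 2)  # clipping can shift slightly
})

test_that("area resize follows the width x height convention", {
  img <- matrix(runif(600 * 1000), 600, 1000)
  out <- resize_image(img, 75, 64)
  expect_equal(dim(out), c(64L, 75L))
  # resize to own size is exact identity
  small <- matrix(runif(50 * 40), 40, 50)
  expect_equal(resize_image(small, 50, 40), small)
  expect_error(resize_image(small, 0, 10), "positive")
})

test_that("integer downscales equal explicit block means", {
  set.seed(8)
  cb <- (outer(1:64, 1:48, "+") %% 2) * 255 + matrix(runif(64 * 48), 64, 48)
  ours <- resize_image(cb, 24, 32)   # 2x in both axes
  oracle <- block_mean_downscale(cb, 2, 2)
  expect_equal(ours, oracle, tolerance = 1e-9)
  # global mean is conserved by area weighting
  expect_equal(mean(ours), mean(cb), tolerance = 1e-9)
})

test_that("image-level splits reproduce the 960/240 design", {
  manifest <- data.frame(
    chick_id = rep(1:30, each = 40),
    frame_index = rep(1:40, 30),
    label = rep(c("male", "female"), each = 600))
  m <- split_dataset(manifest, 0.8, mode = "by_image", seed = 1)
  expect_equal(sum(m$split == "train"), 960L)
  expect_equal(sum(m$split == "test"), 240L)
  # stratified: each label contributes 80 %
  expect_equal(sum(m$split == "train" & m$label == "male"), 480L)
  expect_error(split_dataset(manifest, 1.0), "strictly inside")
  expect_error(split_dataset(manifest, 0), "strictly inside")
})

test_that("chick-level splits are leakage-free", {
  manifest <- data.frame(
    chick_id = rep(1:30, each = 40),
    frame_index = rep(1:40, 30),
    label = rep(c("male", "female"), each = 600))
  m <- split_dataset(manifest, 0.8, mode = "by_chick", seed = 3)
  tr_chicks <- unique(m$chick_id[m$split == "train"])
  te_chicks <- unique(m$chick_id[m$split == "test"])
  expect_length(tr_chicks, 24L)
  expect_length(te_chicks, 6L)
  expect_length(intersect(tr_chicks, te_chicks), 0L)
  # deterministic under seed
  expect_identical(m, split_dataset(manifest, 0.8, "by_chick", seed = 3))
})

test_that("uneven strata still split to the exact overall fraction", {
  set.seed(11)
  manifest <- data.frame(
    chick_id = rep(1:30, each = 40),
    frame_index = rep(1:40, 30),
    label = sample(c("male", "female", "ambiguous"), 1200, TRUE,
                   prob = c(0.47, 0.48, 0.05)))
  m <- split_dataset(manifest, 0.8, mode = "by_image", seed = 2)
  expect_equal(sum(m$split == "train"), 960L)
})

test_that("manifests round-trip through CSV", {
  manifest <- data.frame(path = c("a.png", "b.png"), chick_id = 1:2,
                         frame_index = c(3L, 4L), label = c("male", "female"),
                         quality = c(1.5, 2.25), split = c("train", "test"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(manifest, path)
  expect_equal(readLines(path)[1],
               "path,chick_id,frame_index,label,quality,split")
  back <- read_manifest(path)
  expect_equal(back, manifest)
})

test_that("written B-scans follow the naming pattern and re-read exactly", {
  dir <- withr::local_tempdir()
  pix <- matrix(as.integer(round(runif(120 * 80, 0, 255))), 120, 80)
  p <- write_bscan_png(pix, dir, chick_id = 7, frame_index = 12)
  expect_match(basename(p), "^chick007_frame012\\.png$")
  expect_equal(read_gray_image(p), pix, tolerance = 1e-9,
               ignore_attr = TRUE)
})
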