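#' Preprocessing configuration
#'
#' Method tags and strengths for image preparation. The recognized tags:
#' denoise `"median"` (3x3 median filter) or `"none"`; contrast
#' `"stretch"` (linear percentile stretch) or `"none"`; sharpen
#' `"unsharp"` (unsharp masking) or `"none"`.
#'
#' @param target_width,target_height network input size in pixels
#'   (printed width x height order; defaults 75 x 64).
#' @param rotation_range augmentation rotation bound in degrees (±).
#' @param flip allow horizontal flips during augmentation.
#' @param denoise,contrast,sharpen method tags, see above.
#' @param sharpen_strength unsharp-mask gain.
#' @param stretch_quantiles lower/upper percentile for contrast stretch.
#' @param brightness_target,brightness_sd target per-image mean/sd for
#'   brightness-contrast normalization during augmentation (`NA` = off).
#' @return list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(target_width = 75L, target_height = 64L,
                              rotation_range = 15, flip = TRUE,
                              denoise = "median", contrast = "stretch",
                              sharpen = "unsharp", sharpen_strength = 0.5,
                              stretch_quantiles = c(0.01, 0.99),
                              brightness_target = 100, brightness_sd = NA) {
  if (target_width <= 0 || target_height <= 0)
    stopf("target dimensions must be positive")
  if (rotation_range < 0) stopf("rotation_range must be >= 0")
  structure(list(target_width = as.integer(target_width),
                 target_height = as.integer(target_height),
                 rotation_range = rotation_range, flip = flip,
                 denoise = denoise, contrast = contrast, sharpen = sharpen,
                 sharpen_strength = sharpen_strength,
                 stretch_quantiles = stretch_quantiles,
                 brightness_target = brightness_target,
                 brightness_sd = brightness_sd),
            class = "preprocess_config")
}

#' Enhance a B-scan image
#'
#' Noise reduction, contrast enhancement and sharpening, in that order,
#' according to the method tags in `config`. All steps are no-ops on a
#' flat image, and disabled steps are identity.
#'
#' @param img 8-bit single-channel image (numeric matrix, values 0–255).
#' @param config a [preprocess_config()].
#' @return numeric matrix, same shape, values in \[0, 255\].
#' @export
enhance_image <- function(img, config = preprocess_config()) {
  if (!is_u8_image(img)) stopf("expected a single-channel image in [0,255]")
  out <- img
  out <- switch(config$denoise,
    median = median3_filter(out),
    none = out,
    stopf("unknown denoise method '%s'", config$denoise))
  out <- switch(config$contrast,
    stretch = {
      q <- quantile(out, config$stretch_quantiles, names = FALSE)
      if (diff(q) < 1e-9) out
      else pmin(pmax((out - q[1L]) / diff(q), 0), 1) * 255
    },
    none = out,
    stopf("unknown contrast method '%s'", config$contrast))
  out <- switch(config$sharpen,
    unsharp = pmin(pmax(out + config$sharpen_strength *
                          (out - gauss_blur(out, 1.0)), 0), 255),
    none = out,
    stopf("unknown sharpen method '%s'", config$sharpen))
  out
}

#' Image quality score
#'
#' Mean gradient magnitude (absolute central differences, both axes)
#' within the tissue band — the rows whose mean intensity exceeds a small
#' threshold. Blank images score 0.
#'
#' @param img 8-bit image matrix.
#' @param band_threshold minimum row-mean intensity for a row to count as
#'   tissue.
#' @return scalar score (>= 0).
#' @export
quality_score <- function(img, band_threshold = 2) {
  rows <- which(rowMeans(img) > band_threshold)
  if (length(rows) < 2L) return(0)
  # contiguous span of the tissue band, padded so its edges count
  rows <- max(1L, min(rows) - 1L):min(nrow(img), max(rows) + 1L)
  sub <- img[rows, , drop = FALSE]
  gx <- abs(sub[, -1L, drop = FALSE] - sub[, -ncol(sub), drop = FALSE])
  gy <- abs(sub[-1L, , drop = FALSE] - sub[-nrow(sub), , drop = FALSE])
  (mean(gx) + mean(gy)) / 2
}

#' Quality-based frame selection
#'
#' Emulates the manual retention of the clearest frames: per chick, frames
#' are ranked by quality score (descending) and the top `keep` are
#' retained; ties are broken by frame index (ascending), so selection is
#' deterministic.
#'
#' @param scores numeric quality scores, one per frame, or a list of
#'   images (scored with [quality_score()]).
#' @param keep number of frames to retain.
#' @param frame_index frame indices used for tie-breaking (defaults to
#'   position).
#' @return integer indices of the retained frames, in frame order.
#' @examples
#' quality_select(c(3, 1, 2, 5), keep = 2)  # frames 1 and 4
#' @export
quality_select <- function(scores, keep, frame_index = seq_along(scores)) {
  if (is.list(scores)) scores <- vapply(scores, quality_score, numeric(1))
  if (keep > length(scores))
    stopf("keep (%d) exceeds available frames (%d)", keep, length(scores))
  ord <- order(-scores, frame_index)
  sort(ord[seq_len(keep)])
}

#' Rotate an image about its centre
#'
#' @param img image matrix.
#' @param angle degrees, counter-clockwise; bilinear interpolation,
#'   zero fill, output shape preserved.
#' @return rotated matrix.
#' @export
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  rotate_bilinear(img, angle)
}

#' Horizontal flip
#' @param img image matrix.
#' @return matrix with lateral axis reversed.
#' @export
flip_horizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Brightness/contrast normalization
#'
#' Shifts (and optionally rescales) an image so its mean matches
#' `target_mean` (and sd matches `target_sd` when given), then clips to
#' \[0, 255\].
#'
#' @param img 8-bit image matrix.
#' @param target_mean target per-image mean.
#' @param target_sd target per-image sd (`NA` = leave contrast alone).
#' @return adjusted matrix.
#' @export
normalize_brightness <- function(img, target_mean = 100, target_sd = NA) {
  out <- img
  if (!is.na(target_sd)) {
    s <- stats::sd(out)
    if (s > 1e-9) out <- (out - mean(out)) * (target_sd / s) + mean(out)
  }
  pmin(pmax(out + (target_mean - mean(out)), 0), 255)
}

#' Augment a training image
#'
#' Label-preserving augmentation: random rotation within
#' `±rotation_range` degrees, optional random horizontal flip, and
#' brightness normalization toward the configured target. Output shape
#' equals input shape.
#'
#' @param img 8-bit image matrix.
#' @param n number of augmented copies.
#' @param config a [preprocess_config()].
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param angle,flip override the random draws with fixed values (used for
#'   the deterministic building blocks; `angle` beyond the configured
#'   range is rejected).
#' @return list of `n` augmented matrices.
#' @export
augment_image <- function(img, n = 1L, config = preprocess_config(),
                          seed = NULL, angle = NULL, flip = NULL) {
  if (!is.null(angle) && abs(angle) > config$rotation_range)
    stopf("rotation %g exceeds the configured bound %g",
          angle, config$rotation_range)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- if (is.null(angle)) runif(1, -config$rotation_range,
                                     config$rotation_range) else angle
      f <- if (is.null(flip)) config$flip && runif(1) < 0.5 else flip
      out <- rotate_image(img, a)
      if (f) out <- flip_horizontal(out)
      if (!is.na(config$brightness_target))
        out <- normalize_brightness(out, config$brightness_target,
                                    config$brightness_sd)
      out
    })
  })
}

#' Resize an image by area averaging
#'
#' Exact area-weighted resampling: each output pixel is the mean of the
#' input region it covers, with fractional pixels weighted by overlap.
#' For integer downscale factors this is block averaging, which preserves
#' the energy of small bright structures (the cones) far better than
#' nearest-neighbour sampling at the 13x reduction from 1000 x 600 to
#' 75 x 64. Resizing to the input's own size is exactly the identity.
#'
#' @param img image matrix (`height x width`).
#' @param target_width,target_height output size in pixels.
#' @return numeric matrix `target_height x target_width`.
#' @examples
#' dim(resize_image(matrix(0, 600, 1000), 75, 64))  # 64 75
#' @export
resize_image <- function(img, target_width, target_height) {
  if (target_width <= 0 || target_height <= 0)
    stopf("target size must be positive")
  A <- overlap_weights(nrow(img), as.integer(target_height))
  B <- overlap_weights(ncol(img), as.integer(target_width))
  A %*% img %*% t(B)
}

# out x in row-stochastic matrix of interval overlaps for 1-D area resampling
overlap_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * scale
    hi <- j * scale
    i0 <- floor(lo) + 1
    i1 <- min(ceiling(hi), n_in)
    for (i in i0:i1)
      W[j, i] <- max(0, min(hi, i) - max(lo, i - 1))
    W[j, ] <- W[j, ] / sum(W[j, ])
  }
  W
}

#' Assign train/test splits to a manifest
#'
#' Two modes. `"by_image"` stratifies by frame label, so an 80/20 split of
#' the 1200-image design yields 960/240. `"by_chick"` assigns whole chicks
#' (stratified by sex) to one side, guaranteeing that no chick contributes
#' frames to both sides — the leakage-safe default (30 chicks at 0.8 give
#' 24 train / 6 test chicks).
#'
#' @param manifest data frame with columns `chick_id`, `frame_index`,
#'   `label` (and optionally more).
#' @param train_fraction fraction of images (or chicks) in the training
#'   split; strictly inside (0, 1).
#' @param mode `"by_chick"` (default) or `"by_image"`.
#' @param seed RNG seed.
#' @return the manifest with a `split` column (`"train"`/`"test"`).
#' @export
split_dataset <- function(manifest, train_fraction = 0.8,
                          mode = c("by_chick", "by_image"), seed = 1L) {
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be strictly inside (0,1), got %g",
          train_fraction)
  if (length(unique(manifest$chick_id)) < 2L)
    stopf("need at least 2 chicks to split")
  manifest$split <- NA_character_
  with_seed(seed, {
    if (mode == "by_image") {
      strata <- split(seq_len(nrow(manifest)), manifest$label)
      quota <- quota_allocate(lengths(strata), train_fraction)
      for (s in seq_along(strata)) {
        idx <- strata[[s]]
        tr <- idx[sample.int(length(idx), quota[s])]
        manifest$split[tr] <- "train"
        manifest$split[setdiff(idx, tr)] <- "test"
      }
    } else {
      # stratify chicks by their (majority) sex label
      chick_sex <- vapply(split(as.character(manifest$label), manifest$chick_id),
                          function(l) names(sort(table(l[l != "ambiguous"]),
                                                 decreasing = TRUE))[1L],
                          character(1))
      ids <- as.integer(names(chick_sex))
      strata <- split(ids, chick_sex)
      quota <- quota_allocate(lengths(strata), train_fraction)
      train_ids <- integer(0)
      for (s in seq_along(strata)) {
        grp <- strata[[s]]
        train_ids <- c(train_ids, grp[sample.int(length(grp), quota[s])])
      }
      manifest$split <- ifelse(manifest$chick_id %in% train_ids,
                               "train", "test")
    }
  })
  manifest
}

# largest-remainder allocation: per-stratum train counts that sum exactly
# to round(total * fraction), so an 80/20 split of 1200 is always 960/240
quota_allocate <- function(n_per_stratum, fraction) {
  exact <- n_per_stratum * fraction
  base <- floor(exact)
  extra <- round(sum(n_per_stratum) * fraction) - sum(base)
  if (extra > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Write / read a dataset manifest
#'
#' CSV with header `path,chick_id,frame_index,label,quality,split`.
#'
#' @param manifest data frame with (at least) those columns.
#' @param path CSV file path.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("path", "chick_id", "frame_index", "label", "quality", "split")
  missing <- setdiff(cols, names(manifest))
  for (m in missing) manifest[[m]] <- NA
  write.csv(manifest[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a B-scan as an 8-bit grayscale PNG
#'
#' Files follow the pattern `chick{ID}_frame{N}.png`.
#'
#' @param bscan a `"bscan"` object or 8-bit matrix.
#' @param dir output directory.
#' @param chick_id,frame_index used for the filename when `bscan` is a
#'   plain matrix.
#' @return the written file path.
#' @export
write_bscan_png <- function(bscan, dir, chick_id = NULL, frame_index = NULL) {
  if (inherits(bscan, "bscan")) {
    pix <- bscan$pixels
    if (is.null(chick_id)) chick_id <- bscan$chick_id
    if (is.null(frame_index)) frame_index <- bscan$frame_index
  } else pix <- bscan
  path <- file.path(dir, sprintf("chick%03d_frame%03d.png",
                                 as.integer(chick_id),
                                 as.integer(frame_index)))
  png::writePNG(pix / 255, path)
  path
}

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' @param path image file.
#' @return numeric matrix with values in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * 255
}
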