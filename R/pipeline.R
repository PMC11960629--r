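#' Simulate an imaged cohort
#'
#' Generates the phantom cohort, rasterizes each frame and scans it through
#' the OCT forward model, yielding 8-bit B-scans with a manifest. With an
#' output directory, images are written as `chick{ID}_frame{N}.png` with a
#' `manifest.csv` sidecar.
#'
#' @param spec a [cohort_spec()].
#' @param params [phantom_params()] for the flock.
#' @param source a [source_spectrum()].
#' @param config a [scan_config()]; cohorts are typically scanned at
#'   reduced resolution (the retained-image counts do not depend on it).
#' @param speckle_scale multiplicative speckle magnitude (`NULL` uses the
#'   phantom parameter).
#' @param enhance apply [enhance_image()] to each frame.
#' @param pre a [preprocess_config()] used when `enhance = TRUE`.
#' @param out_dir optional directory for PNGs and the manifest.
#' @param progress print progress every 250 frames.
#' @return list of class `"oct_dataset"`: `images` (list of 8-bit
#'   matrices), `manifest` (data frame with `path`, `chick_id`,
#'   `frame_index`, `label`, `quality`), `spec`, `config`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), params = phantom_params(),
                            source = source_spectrum(),
                            config = scan_config(), speckle_scale = NULL,
                            enhance = FALSE, pre = preprocess_config(),
                            out_dir = NULL, progress = FALSE) {
  cohort <- make_cohort(spec, params)
  sim <- oct_simulator(source, config)
  n <- length(cohort$frames)
  noise_seeds <- derive_seeds(spec$seed + 1L, n)
  if (is.null(speckle_scale)) speckle_scale <- params$speckle_scale

  images <- vector("list", n)
  quality <- numeric(n)
  for (i in seq_len(n)) {
    ph <- cohort$frames[[i]]
    map <- rasterize_phantom(ph, depth_rows = config$depth_pixels,
                             n_lateral = config$n_alines,
                             depth_pitch = config$depth_pitch,
                             lateral_pitch = config$lateral_pitch)
    bs <- scan_bscan(map, sim = sim, speckle_scale = speckle_scale,
                     seed = noise_seeds[i],
                     chick_id = cohort$manifest$chick_id[i],
                     frame_index = cohort$manifest$frame_index[i],
                     label = cohort$manifest$label[i])
    img <- bs$pixels
    if (enhance) img <- enhance_image(img, pre)
    images[[i]] <- img
    quality[i] <- quality_score(img)
    if (progress && i %% 250L == 0L)
      message(sprintf("  scanned %d / %d frames", i, n))
  }
  manifest <- cohort$manifest
  manifest$quality <- quality
  manifest$path <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(out_dir, mode = 2L) != 0L)
      stopf("output directory '%s' is not writable", out_dir)
    for (i in seq_len(n))
      manifest$path[i] <- write_bscan_png(images[[i]], out_dir,
                                          manifest$chick_id[i],
                                          manifest$frame_index[i])
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  structure(list(images = images, manifest = manifest, spec = spec,
                 config = config), class = "oct_dataset")
}

#' @export
print.oct_dataset <- function(x, ...) {
  cat(sprintf("OCT dataset: %d images (%d x %d px), %d chicks\n",
              length(x$images), nrow(x$images[[1L]]), ncol(x$images[[1L]]),
              length(unique(x$manifest$chick_id))))
  invisible(x)
}

#' Retain the best frames per chick
#'
#' Applies [quality_select()] chick-wise, emulating the manual retention
#' of the clearest frames (e.g. 40 of 50).
#'
#' @param dataset an `"oct_dataset"`.
#' @param keep frames retained per chick (defaults to the cohort spec).
#' @return the filtered `"oct_dataset"`.
#' @export
select_frames <- function(dataset, keep = NULL) {
  if (is.null(keep)) keep <- dataset$spec$keep_per_chick
  m <- dataset$manifest
  keep_idx <- unlist(lapply(split(seq_len(nrow(m)), m$chick_id), function(idx)
    idx[quality_select(m$quality[idx], keep, m$frame_index[idx])]))
  keep_idx <- sort(keep_idx)
  dataset$images <- dataset$images[keep_idx]
  dataset$manifest <- m[keep_idx, , drop = FALSE]
  rownames(dataset$manifest) <- NULL
  dataset
}

#' Run the full pipeline
#'
#' simulate -> select -> split -> resize -> train -> evaluate. Randomness
#' at every stage derives from `seed`, so a rerun with the same
#' configuration reproduces the same manifest and metrics.
#'
#' @param spec,params,source,config cohort and scanner configuration; the
#'   defaults scan at reduced resolution suitable for a desk-scale run.
#' @param size network input size, `"WxH"` (default `"75x64"`).
#' @param split_mode `"by_chick"` (leakage-safe default) or `"by_image"`.
#' @param train_fraction train share of the split.
#' @param train_cfg a [train_config()].
#' @param tau confidence threshold for `"not_detect"`.
#' @param augment_n extra augmented copies per training image
#'   (augmentation is applied to the training split only, after the
#'   split; 0 disables).
#' @param pre a [preprocess_config()].
#' @param enhance apply image enhancement before training.
#' @param seed master seed.
#' @param out_dir optional output directory: images, manifest, metrics
#'   JSON/CSV, learning-curve CSV and a run record are written there.
#' @param progress report stage progress.
#' @return list of class `"oct_run"`: `dataset`, `model`, `cm`
#'   (confusion matrix), `metrics`, `history`, `counts`, `timings`,
#'   `config_snapshot`.
#' @export
run_pipeline <- function(spec = cohort_spec(),
                         params = phantom_params(),
                         source = source_spectrum(n_samples = 512L),
                         config = scan_config(n_alines = 200L,
                                              depth_pixels = 200L,
                                              depth_crop = 120L),
                         size = "75x64",
                         split_mode = c("by_chick", "by_image"),
                         train_fraction = 0.8,
                         train_cfg = train_config(),
                         tau = 0.6, augment_n = 0L,
                         pre = preprocess_config(), enhance = FALSE,
                         seed = 1L, out_dir = NULL, progress = FALSE) {
  split_mode <- match.arg(split_mode)
  wh <- parse_size(size)
  seeds <- derive_seeds(seed, 4L)
  spec$seed <- seeds[1L]
  timings <- c()
  tick <- function(nm, expr) {
    t0 <- proc.time()[3L]
    r <- force(expr)
    timings[nm] <<- proc.time()[3L] - t0
    r
  }

  if (progress) message("stage: simulate")
  dataset <- tick("simulate",
    simulate_cohort(spec, params, source, config, enhance = enhance,
                    pre = pre, out_dir = out_dir, progress = progress))
  dataset <- tick("select", select_frames(dataset))
  dataset$manifest <- tick("split",
    split_dataset(dataset$manifest, train_fraction, mode = split_mode,
                  seed = seeds[2L]))

  if (progress) message("stage: resize/train")
  small <- lapply(dataset$images, resize_image,
                  target_width = wh["width"], target_height = wh["height"])
  m <- dataset$manifest
  tr <- which(m$split == "train" & m$label %in% SEX_LEVELS)
  te <- which(m$split == "test")
  train_imgs <- small[tr]
  train_labs <- m$label[tr]
  if (augment_n > 0L) {
    aug_seeds <- derive_seeds(seeds[3L], length(tr))
    for (i in seq_along(tr)) {
      extra <- augment_image(small[[tr[i]]], n = augment_n, config = pre,
                             seed = aug_seeds[i])
      train_imgs <- c(train_imgs, extra)
      train_labs <- c(train_labs, rep(m$label[tr[i]], augment_n))
    }
  }
  cfg <- train_cfg; cfg$seed <- seeds[4L]
  model <- tick("train", cnn_fit(train_imgs, train_labs, config = cfg))

  if (progress) message("stage: evaluate")
  pred <- tick("evaluate", predict(model, small[te], tau = tau))
  cm <- confusion_matrix3(pred, m$label[te])
  metrics <- classification_metrics(cm)

  counts <- c(frames = length(dataset$images) %/% 1L,
              train = length(tr), test = length(te))
  snapshot <- list(spec = unclass(spec), size = size,
                   split_mode = split_mode,
                   train_fraction = train_fraction,
                   train_config = unclass(cfg), tau = tau,
                   augment_n = augment_n, seed = seed,
                   version = as.character(utils::packageVersion("octsex")))
  run <- structure(list(dataset = dataset, model = model, cm = cm,
                        metrics = metrics, history = model$history,
                        counts = counts, timings = timings,
                        config_snapshot = snapshot), class = "oct_run")
  if (!is.null(out_dir)) {
    write_manifest(dataset$manifest, file.path(out_dir, "manifest.csv"))
    write_metrics(metrics, file.path(out_dir, "metrics.json"))
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    learning_curves(model, file.path(out_dir, "history.csv"))
    record <- c(snapshot,
                list(counts = as.list(counts),
                     timings = as.list(round(timings, 2)),
                     confusion_matrix = unclass(cm),
                     accuracy = metrics$accuracy))
    tmp <- file.path(out_dir, ".run_record.tmp")
    jsonlite::write_json(record, tmp, auto_unbox = TRUE, digits = NA)
    file.rename(tmp, file.path(out_dir, "run_record.json"))
  }
  run
}

#' @export
print.oct_run <- function(x, ...) {
  cat(sprintf("pipeline run: %d frames (%d train / %d test), accuracy %.3f\n",
              x$counts["frames"], x$counts["train"], x$counts["test"],
              x$metrics$accuracy))
  print(x$cm)
  invisible(x)
}
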