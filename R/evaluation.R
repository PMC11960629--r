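#' Three-category confusion matrix
#'
#' Rows are true classes, columns predicted classes, over
#' `c("female", "male", "not_detect")`. Frames whose anatomy is occluded
#' (`"ambiguous"` in manifests) belong to the true `"not_detect"` class.
#'
#' @param predicted,truth equal-length label vectors; `"ambiguous"` is
#'   accepted as a synonym for `"not_detect"`.
#' @return 3 x 3 integer matrix of class `"confusion_matrix3"` with
#'   dimnames `truth` x `predicted`.
#' @examples
#' confusion_matrix3(c("male", "female"), c("male", "male"))
#' @export
confusion_matrix3 <- function(predicted, truth) {
  canon <- function(v) {
    v <- as.character(v)
    v[v == "ambiguous"] <- "not_detect"
    bad <- setdiff(unique(v), EVAL_LEVELS)
    if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
    factor(v, levels = EVAL_LEVELS)
  }
  predicted <- canon(predicted); truth <- canon(truth)
  if (length(predicted) != length(truth))
    stopf("predicted and truth lengths differ")
  cm <- table(truth = truth, predicted = predicted)
  structure(unclass(cm), class = "confusion_matrix3")
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  cat("confusion matrix (rows = truth, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision (`TP / column sum`), recall (`TP / row sum`) and F1
#' (harmonic mean; 0 where undefined), plus macro averages (unweighted
#' mean over classes with nonzero support), support-weighted averages, and
#' overall accuracy (`trace / total`). When every evaluated sample's true
#' class is among the averaged classes, weighted recall equals accuracy.
#'
#' @param cm a [confusion_matrix3()] or any square count matrix with
#'   matching row/column classes.
#' @return list of class `"metrics_report"`: `per_class` (data frame),
#'   `macro`, `weighted` (named vectors: precision, recall, f1),
#'   `accuracy`, `support`.
#' @examples
#' m <- classification_metrics(confusion_matrix3(
#'   c("male", "male", "female"), c("male", "female", "female")))
#' m$accuracy
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stopf("cm must be square")
  total <- sum(cm)
  if (total <= 0) stopf("empty confusion matrix")
  tp <- diag(cm)
  colsum <- colSums(cm); rowsum <- rowSums(cm)
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  recall <- ifelse(rowsum > 0, tp / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- rowsum
  has <- support > 0
  macro <- c(precision = mean(precision[has]), recall = mean(recall[has]),
             f1 = mean(f1[has]))
  wts <- support[has] / sum(support[has])
  weighted <- c(precision = sum(precision[has] * wts),
                recall = sum(recall[has] * wts),
                f1 = sum(f1[has] * wts))
  structure(list(
    per_class = data.frame(class = rownames(cm) %||% paste0("c", seq_len(nrow(cm))),
                           precision = precision, recall = recall, f1 = f1,
                           support = support, row.names = NULL),
    macro = macro, weighted = weighted,
    accuracy = sum(tp) / total, support = support),
    class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat("per-class metrics:\n")
  print(x$per_class, digits = 4)
  cat(sprintf("macro    : P %.4f  R %.4f  F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("weighted : P %.4f  R %.4f  F1 %.4f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  cat(sprintf("accuracy : %.4f\n", x$accuracy))
  invisible(x)
}

#' Export a metrics report
#'
#' @param report a `"metrics_report"`.
#' @param path file path; `.csv` writes the per-class table plus summary
#'   rows, `.json` the full structure.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    pc <- report$per_class
    summ <- data.frame(class = c("macro", "weighted"),
                       precision = c(report$macro["precision"],
                                     report$weighted["precision"]),
                       recall = c(report$macro["recall"],
                                  report$weighted["recall"]),
                       f1 = c(report$macro["f1"], report$weighted["f1"]),
                       support = c(NA, sum(report$support)))
    write.csv(rbind(pc, summ), path, row.names = FALSE)
  }
  invisible(path)
}

#' Learning-curve table
#'
#' Per-epoch loss and accuracy for training and validation, as a data
#' frame (optionally written to CSV). Plot with [plot.oct_cnn()].
#'
#' @param model a fitted `"oct_cnn"` (or its `history` data frame).
#' @param path optional CSV output path.
#' @return the history data frame (columns `epoch`, `train_loss`,
#'   `val_loss`, `train_acc`, `val_acc`).
#' @export
learning_curves <- function(model, path = NULL) {
  h <- if (inherits(model, "oct_cnn")) model$history else model
  if (is.null(h) || nrow(h) == 0L) stopf("empty training history")
  if (!is.null(path)) write.csv(h, path, row.names = FALSE)
  h
}

#' Image-size ablation
#'
#' Re-trains and evaluates the classifier at a sweep of input sizes
#' (printed width x height). For each size the images are area-resized, a
#' fresh seed-controlled model is trained on the train split and evaluated
#' on the test split, optionally averaged over several seeds; a size too
#' small for the three pooling stages is recorded as a per-row error and
#' the sweep continues.
#'
#' @param images list of 8-bit image matrices, parallel to `manifest`.
#' @param manifest data frame with `label` and `split` columns.
#' @param sizes character vector of `"WxH"` sizes. The default sweep
#'   mirrors the study's table; the full-resolution 1000x600 row is
#'   supported but omitted from the default because its dense layer has
#'   ~3e8 parameters.
#' @param config a [train_config()].
#' @param seeds one model seed per replicate; rows report the mean over
#'   replicates.
#' @param tau confidence threshold for the `"not_detect"` rule.
#' @return data frame of class `"ablation_result"`: one row per size with
#'   macro/weighted precision, recall, F1, accuracy, and seconds.
#' @export
size_ablation <- function(images, manifest,
                          sizes = c("224x224", "128x128", "128x64",
                                    "64x64", "75x64"),
                          config = train_config(), seeds = c(1L, 2L, 3L),
                          tau = 0.6) {
  rows <- lapply(sizes, function(sz) {
    t0 <- proc.time()[3L]
    res <- tryCatch({
      wh <- parse_size(sz)
      reps <- lapply(seeds, function(sd) {
        cfg <- config; cfg$seed <- as.integer(sd)
        evaluate_split(images, manifest, wh, cfg, tau)
      })
      agg <- function(f) mean(vapply(reps, f, numeric(1)))
      data.frame(size = sz,
                 precision_macro = agg(function(r) r$metrics$macro["precision"]),
                 precision_weighted = agg(function(r) r$metrics$weighted["precision"]),
                 recall_macro = agg(function(r) r$metrics$macro["recall"]),
                 recall_weighted = agg(function(r) r$metrics$weighted["recall"]),
                 f1_macro = agg(function(r) r$metrics$macro["f1"]),
                 f1_weighted = agg(function(r) r$metrics$weighted["f1"]),
                 accuracy = agg(function(r) r$metrics$accuracy),
                 seconds = unname(proc.time()[3L] - t0), error = NA_character_)
    }, error = function(e)
      data.frame(size = sz, precision_macro = NA, precision_weighted = NA,
                 recall_macro = NA, recall_weighted = NA, f1_macro = NA,
                 f1_weighted = NA, accuracy = NA,
                 seconds = unname(proc.time()[3L] - t0),
                 error = conditionMessage(e)))
    res
  })
  structure(do.call(rbind, rows), class = c("ablation_result", "data.frame"))
}

# resize images to wh, train on the train split, evaluate on the test split
evaluate_split <- function(images, manifest, wh, config, tau) {
  stopifnot(nrow(manifest) == length(images), "split" %in% names(manifest))
  small <- lapply(images, resize_image, target_width = wh["width"],
                  target_height = wh["height"])
  tr <- which(manifest$split == "train" & manifest$label %in% SEX_LEVELS)
  te <- which(manifest$split == "test")
  if (!length(tr)) stopf("empty training split")
  model <- cnn_fit(small[tr], manifest$label[tr], config = config)
  pred <- predict(model, small[te], tau = tau)
  cm <- confusion_matrix3(pred, manifest$label[te])
  list(model = model, cm = cm, metrics = classification_metrics(cm))
}
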