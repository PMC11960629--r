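#' Feature-map dimensions of the CNN
#'
#' The network applies three conv("same")/maxpool(2x2, stride 2) blocks
#' with 32, 64 and 128 filters, so each pooling floor-halves both spatial
#' axes and the flattened feature length is
#' `floor(h/8) * floor(w/8)`-ish by repeated halving times 128. For the
#' default 75 x 64 (width x height) input the pooled sizes are 37 x 32,
#' 18 x 16 and 9 x 8, and the flatten length is 9 * 8 * 128 = 9216.
#'
#' @param input_height,input_width network input size in pixels (rows,
#'   columns).
#' @return list: `pooled` (3 x 2 matrix of `(height, width)` after each
#'   block), `flatten` (feature count).
#' @examples
#' cnn_feature_dims(64, 75)$flatten  # 9216
#' @export
cnn_feature_dims <- function(input_height, input_width) {
  h <- as.integer(input_height); w <- as.integer(input_width)
  if (h < 8L || w < 8L)
    stopf("input %dx%d is too small for three pooling stages", h, w)
  dims <- matrix(0L, 3L, 2L, dimnames = list(NULL, c("height", "width")))
  for (i in 1:3) { h <- h %/% 2L; w <- w %/% 2L; dims[i, ] <- c(h, w) }
  list(pooled = dims, flatten = h * w * 128L)
}

# He-initialized weights for the fixed architecture
cnn_init_weights <- function(input_height, input_width, seed = 1L) {
  fd <- cnn_feature_dims(input_height, input_width)
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  with_seed(seed, list(
    W1 = he(9L, 32L), b1 = numeric(32L),
    W2 = he(288L, 64L), b2 = numeric(64L),
    W3 = he(576L, 128L), b3 = numeric(128L),
    W4 = he(fd$flatten, 256L), b4 = numeric(256L),
    W5 = he(256L, 2L), b5 = numeric(2L)))
}

#' Training configuration
#'
#' Defaults follow the training regime: Adam with learning rate 1e-4,
#' batch size 128, up to 1000 epochs with early stopping after 50 epochs
#' without validation-loss improvement. A learning rate of 0 freezes the
#' weights (useful for exercising the stopping rule in isolation).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (consecutive epochs without
#'   validation-loss improvement); must be below `max_epochs`.
#' @param val_fraction fraction of the training data held out for
#'   validation (never the test split).
#' @param conv_dropout,fc_dropout dropout rates after the conv stack and
#'   the dense layer.
#' @param seed RNG seed for weight init, shuffling and dropout.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         max_epochs = 1000L, patience = 50L,
                         val_fraction = 0.1, conv_dropout = 0.25,
                         fc_dropout = 0.5, seed = 1L) {
  if (learning_rate < 0) stopf("learning_rate must be >= 0")
  if (batch_size < 1L || max_epochs < 1L) stopf("batch/epochs must be positive")
  if (patience < 1L || patience >= max_epochs)
    stopf("patience must be in [1, max_epochs)")
  if (conv_dropout < 0 || conv_dropout >= 1 || fc_dropout < 0 || fc_dropout >= 1)
    stopf("dropout rates must be in [0,1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 conv_dropout = conv_dropout, fc_dropout = fc_dropout,
                 seed = as.integer(seed)), class = "train_config")
}

# epoch at which the patience rule halts, given per-epoch validation
# losses; NA if no stop occurs within the sequence
stop_epoch_for <- function(val_losses, patience) {
  best <- Inf; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) { best <- val_losses[e]; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

# coerce a list of matrices or an h x w x n array to a cube array in [0,1]
as_input_array <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1L]])
    arr <- array(0, c(d[1L], d[2L], length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]
    x <- arr
  }
  if (length(dim(x)) != 3L) stop("x must be an h x w x n array or list of matrices")
  if (max(x) > 1) x <- x / 255
  x
}

#' Fit the chick-sexing CNN
#'
#' Trains the compact convolutional network — three conv(3x3, "same",
#' ReLU)/maxpool(2x2) blocks with 32/64/128 filters, 25 % dropout, a
#' 256-unit dense layer with 50 % dropout, and a 2-way softmax — with
#' minibatch Adam and categorical cross-entropy. A stratified fraction of
#' the training images is held out for validation; training stops at
#' `max_epochs` or when validation loss has not improved for `patience`
#' consecutive epochs, and the weights with the best validation loss are
#' retained.
#'
#' @param x training images: an `h x w x n` array or list of matrices,
#'   grayscale, either 0–255 or already scaled to \[0, 1\].
#' @param y labels: factor or character in `c("female", "male")`
#'   (class index 0 = female, 1 = male).
#' @param config a [train_config()].
#' @param val_x,val_y optional explicit validation set; when omitted,
#'   `val_fraction` of `(x, y)` is held out, stratified by label.
#' @param verbose print one line per epoch.
#' @return an object of class `"oct_cnn"`: `weights`, `input_dim`
#'   (`c(height, width)`), `levels`, `history` (data frame with per-epoch
#'   `train_loss`, `val_loss`, `train_acc`, `val_acc`), `stopped_epoch`,
#'   `best_epoch`, `config`. Methods: [predict.oct_cnn()],
#'   [print.oct_cnn()], [summary.oct_cnn()], [plot.oct_cnn()],
#'   [coef.oct_cnn()].
#' @export
cnn_fit <- function(x, y, config = train_config(), val_x = NULL,
                    val_y = NULL, verbose = FALSE) {
  x <- as_input_array(x)
  y <- as.character(y)
  if (!all(y %in% SEX_LEVELS))
    stopf("training labels must be binary (female/male); exclude ambiguous frames")
  if (dim(x)[3L] != length(y)) stopf("x and y lengths differ")
  if (dim(x)[3L] < 1L) stopf("empty training set")
  yi <- as.integer(y == "male")  # 0 = female, 1 = male
  h <- dim(x)[1L]; w <- dim(x)[2L]
  fd <- cnn_feature_dims(h, w)

  seeds <- derive_seeds(config$seed, 3L)
  # validation hold-out (stratified by label), never the test split
  if (is.null(val_x) && config$val_fraction > 0) {
    vi <- with_seed(seeds[2L], {
      unlist(lapply(split(seq_along(yi), yi), function(idx)
        idx[sample.int(length(idx),
                       max(1L, round(length(idx) * config$val_fraction)))]))
    })
    val_x <- x[, , vi, drop = FALSE]
    val_yi <- yi[vi]
    x <- x[, , -vi, drop = FALSE]
    yi <- yi[-vi]
  } else if (!is.null(val_x)) {
    val_x <- as_input_array(val_x)
    val_yi <- as.integer(as.character(val_y) == "male")
  } else {
    val_x <- x; val_yi <- yi  # degenerate: validate on train
  }
  n <- dim(x)[3L]
  if (n < 1L) stopf("empty training split after validation hold-out")

  wts <- cnn_init_weights(h, w, seed = seeds[1L])
  adam_m <- lapply(wts, function(p) p * 0)
  adam_v <- lapply(wts, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L

  hist <- vector("list", config$max_epochs)
  best_loss <- Inf; best_wts <- wts; best_epoch <- 0L; wait <- 0L
  stopped <- config$max_epochs

  with_seed(seeds[3L], {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tl <- 0; ta <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        g <- cnn_grad_batch(x[, , idx, drop = FALSE], yi[idx], wts,
                            config$conv_dropout, config$fc_dropout)
        tl <- tl + g$loss * length(idx); ta <- ta + g$acc * length(idx)
        nb <- nb + length(idx)
        if (config$learning_rate > 0) {
          step <- step + 1L
          for (nm in names(wts)) {
            gr <- g$grads[[nm]]
            adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr
            adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr^2
            mhat <- adam_m[[nm]] / (1 - b1^step)
            vhat <- adam_v[[nm]] / (1 - b2^step)
            wts[[nm]] <- wts[[nm]] - config$learning_rate *
              mhat / (sqrt(vhat) + eps)
          }
        }
      }
      vp <- cnn_forward_batch(val_x, wts)
      vl <- -mean(log(pmax(vp[cbind(seq_along(val_yi), val_yi + 1L)], 1e-12)))
      va <- mean((vp[, 2L] > vp[, 1L]) == (val_yi == 1L))
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / nb,
                                  val_loss = vl, train_acc = ta / nb,
                                  val_acc = va)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f | val loss %.4f  acc %.3f",
                        epoch, tl / nb, ta / nb, vl, va))
      if (vl < best_loss) {
        best_loss <- vl; best_wts <- wts; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stopped <- epoch; break }
      }
    }
  })

  structure(list(weights = best_wts, input_dim = c(height = h, width = w),
                 levels = SEX_LEVELS, feature_dims = fd,
                 history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 stopped_epoch = stopped, best_epoch = best_epoch,
                 config = config, call = match.call()),
            class = "oct_cnn")
}

#' Predict sex from B-scan images
#'
#' Runs the network (dropout inert) and applies the confidence rule: a
#' frame is labelled `"not_detect"` when the winning softmax probability
#' falls below `tau`, otherwise the argmax class. With `tau <= 0.5` the
#' `"not_detect"` label is unreachable for a two-way softmax.
#'
#' @param object a fitted [cnn_fit()] model.
#' @param x images (`h x w x n` array, list of matrices, or a single
#'   matrix) matching the model's input size.
#' @param tau confidence threshold in \[0, 1\] (default 0.6).
#' @param type `"label"` (default) or `"prob"`.
#' @param ... unused.
#' @return for `"prob"`, an `n x 2` matrix with columns `female`, `male`;
#'   for `"label"`, a character vector over
#'   `c("female", "male", "not_detect")`.
#' @export
predict.oct_cnn <- function(object, x, tau = 0.6, type = c("label", "prob"),
                            ...) {
  type <- match.arg(type)
  if (is.matrix(x)) x <- list(x)
  x <- as_input_array(x)
  if (dim(x)[1L] != object$input_dim["height"] ||
      dim(x)[2L] != object$input_dim["width"])
    stopf("input is %dx%d but the model expects %dx%d (height x width)",
          dim(x)[1L], dim(x)[2L],
          object$input_dim["height"], object$input_dim["width"])
  p <- cnn_forward_batch(x, object$weights)
  colnames(p) <- SEX_LEVELS
  if (type == "prob") return(p)
  label_from_probs(p, tau)
}

#' Confidence-thresholded label rule
#'
#' Maps class probabilities to a label: `"not_detect"` when the winning
#' probability is below `tau`, otherwise the argmax class. This is the
#' package's operationalization of the third evaluation outcome; for a
#' two-way softmax the winning probability is always at least 0.5, so
#' `tau <= 0.5` makes `"not_detect"` unreachable.
#'
#' @param probs `n x 2` probability matrix (columns female, male) or a
#'   length-2 vector.
#' @param tau confidence threshold.
#' @return character labels over `c("female", "male", "not_detect")`.
#' @examples
#' label_from_probs(c(0.5, 0.5), tau = 0.6)  # "not_detect"
#' @export
label_from_probs <- function(probs, tau = 0.6) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  lab <- SEX_LEVELS[max.col(probs, ties.method = "first")]
  lab[apply(probs, 1L, max) < tau] <- "not_detect"
  lab
}

#' @export
print.oct_cnn <- function(x, ...) {
  fd <- x$feature_dims
  cat(sprintf("chick-sexing CNN (input %d x %d px, %d features after conv stack)\n",
              x$input_dim["width"], x$input_dim["height"], fd$flatten))
  cat(sprintf("trained %d epoch(s); best validation loss %.4f at epoch %d\n",
              x$stopped_epoch,
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.oct_cnn <- function(object, ...) {
  fd <- object$feature_dims
  n_par <- sum(vapply(object$weights, length, numeric(1)))
  cat("Compact CNN for OCT chick sexing\n")
  cat(sprintf("  input: %d x %d grayscale (width x height)\n",
              object$input_dim["width"], object$input_dim["height"]))
  for (i in 1:3)
    cat(sprintf("  conv%d 3x3 'same' + ReLU + maxpool 2x2 -> %d x %d x %d\n",
                i, fd$pooled[i, "width"], fd$pooled[i, "height"],
                c(32L, 64L, 128L)[i]))
  cat(sprintf("  flatten -> %d; dense 256 + ReLU; softmax 2\n", fd$flatten))
  cat(sprintf("  parameters: %s\n", format(n_par, big.mark = ",")))
  h <- object$history
  cat(sprintf("  epochs run: %d (best %d); final val acc %.3f\n",
              object$stopped_epoch, object$best_epoch,
              h$val_acc[nrow(h)]))
  invisible(object)
}

#' @export
coef.oct_cnn <- function(object, ...) object$weights

#' Plot learning curves
#'
#' Two panels: accuracy and loss per epoch for the training and
#' validation sets.
#'
#' @param x a fitted `"oct_cnn"`.
#' @param ... passed to [plot()].
#' @export
plot.oct_cnn <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", main = "model accuracy", ...)
  lines(h$epoch, h$val_acc, lty = 2)
  legend("bottomright", c("train", "validation"), lty = 1:2, bty = "n")
  plot(h$epoch, h$train_loss, type = "l",
       ylim = range(c(h$train_loss, h$val_loss)),
       xlab = "epoch", ylab = "loss", main = "model loss", ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' Weights go to an RDS file; a JSON sidecar records the architecture,
#' training configuration, class indexing and training summary.
#'
#' @param model a fitted `"oct_cnn"`.
#' @param path base path (without extension).
#' @return `save_oct_cnn`: the base path, invisibly. `load_oct_cnn`: the
#'   restored model.
#' @export
save_oct_cnn <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  side <- list(input_dim = as.list(model$input_dim),
               flatten = model$feature_dims$flatten,
               levels = model$levels, class_index = list(female = 0, male = 1),
               config = unclass(model$config),
               stopped_epoch = model$stopped_epoch,
               best_epoch = model$best_epoch)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_oct_cnn
#' @export
load_oct_cnn <- function(path) readRDS(paste0(path, ".rds"))
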