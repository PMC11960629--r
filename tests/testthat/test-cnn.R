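test_that("feature dimensions follow floor-halving through the conv stack", {
  fd <- cnn_feature_dims(64, 75)   # 75 x 64 input in width x height terms
  expect_equal(unname(fd$pooled[, "height"]), c(32L, 16L, 8L))
  expect_equal(unname(fd$pooled[, "width"]), c(37L, 18L, 9L))
  expect_equal(fd$flatten, 9216L)
  expect_equal(cnn_feature_dims(64, 64)$flatten, 8192L)
  expect_equal(cnn_feature_dims(8, 8)$flatten, 128L)
  expect_error(cnn_feature_dims(7, 64), "too small")

  # property: flatten = thrice-floor-halved dims x 128, arithmetic oracle
  set.seed(5)
  for (i in 1:25) {
    h <- sample(8:200, 1); w <- sample(8:200, 1)
    half3 <- function(v) v %/% 2L %/% 2L %/% 2L
    expect_equal(cnn_feature_dims(h, w)$flatten, half3(h) * half3(w) * 128L)
  }
})

test_that("weight shapes match the architecture", {
  w <- octsex:::cnn_init_weights(64, 75, seed = 1)
  expect_equal(dim(w$W1), c(9L, 32L))
  expect_equal(dim(w$W2), c(288L, 64L))
  expect_equal(dim(w$W3), c(576L, 128L))
  expect_equal(dim(w$W4), c(9216L, 256L))
  expect_equal(dim(w$W5), c(256L, 2L))
  expect_identical(octsex:::cnn_init_weights(64, 75, seed = 1), w)
})

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  H <- 9L; W <- 10L; N <- 2L
  X <- array(runif(H * W * N), c(H, W, N))
  y <- c(0L, 1L)
  wts <- octsex:::cnn_init_weights(H, W, seed = 2)
  g <- octsex:::cnn_grad_batch(X, y, wts, 0, 0)
  lossfn <- function(w) {
    p <- octsex:::cnn_forward_batch(X, w)
    -mean(log(p[cbind(1:N, y + 1L)]))
  }
  eps <- 1e-6
  for (nm in names(wts)) {
    idx <- sample(length(wts[[nm]]), min(5L, length(wts[[nm]])))
    for (i in idx) {
      wp <- wts; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- wts; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("softmax outputs normalize and inference is deterministic", {
  set.seed(3)
  X <- array(runif(16 * 16 * 10), c(16, 16, 10))
  w <- octsex:::cnn_init_weights(16L, 16L, seed = 4)
  p1 <- octsex:::cnn_forward_batch(X, w)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-6))
  # dropout is inert at inference: two passes are identical
  p2 <- octsex:::cnn_forward_batch(X, w)
  expect_identical(p1, p2)
})

test_that("the confidence rule yields the three-way label", {
  expect_equal(label_from_probs(c(1, 0), tau = 0.6), "female")
  expect_equal(label_from_probs(c(0, 1), tau = 0.6), "male")
  expect_equal(label_from_probs(c(0.5, 0.5), tau = 0.6), "not_detect")
  expect_equal(label_from_probs(rbind(c(0.41, 0.59), c(0.79, 0.21)), 0.6),
               c("not_detect", "female"))
  # tau <= 0.5 makes not_detect unreachable for a 2-way softmax
  set.seed(6)
  p1 <- runif(200); probs <- cbind(p1, 1 - p1)
  expect_false("not_detect" %in% label_from_probs(probs, tau = 0.5))
})

test_that("training configuration validates and echoes the regime defaults", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$max_epochs, 1000L)
  expect_equal(cfg$patience, 50L)
  expect_error(train_config(patience = 1000, max_epochs = 1000), "patience")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(fc_dropout = 1), "dropout")
})

test_that("early stopping halts one epoch after the patience window", {
  expect_equal(octsex:::stop_epoch_for(rep(1.7, 50), patience = 3L), 4L)
  expect_equal(octsex:::stop_epoch_for(rep(1.7, 50), patience = 5L), 6L)
  expect_true(is.na(octsex:::stop_epoch_for(seq(2, 1, length.out = 30), 5L)))
  # an improvement resets the counter
  expect_equal(octsex:::stop_epoch_for(c(3, 2.5, 2.6, 2.7, 2.4, 2.4, 2.4), 2L), 4L)

  # end to end: frozen weights give a constant validation loss
  toy <- toy_separable(n = 12, px = 16)
  fit <- cnn_fit(toy$images, toy$labels,
                 train_config(learning_rate = 0, batch_size = 6,
                              max_epochs = 30, patience = 3,
                              val_fraction = 0.25, seed = 1))
  expect_equal(fit$stopped_epoch, 4L)
  expect_equal(nrow(fit$history), 4L)
  expect_equal(length(unique(fit$history$val_loss)), 1L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("a separable image set is learned to full training accuracy", {
  toy <- toy_separable(n = 20, px = 32)
  fit <- cnn_fit(toy$images, toy$labels,
                 train_config(learning_rate = 1e-3, batch_size = 10,
                              max_epochs = 60, patience = 25,
                              val_fraction = 0.2, seed = 1))
  expect_lt(fit$stopped_epoch, 200L)
  expect_equal(max(fit$history$train_acc), 1)
  pr <- predict(fit, toy$images, type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  lab <- predict(fit, toy$images[[1]])
  expect_true(lab %in% c("female", "male", "not_detect"))
})

test_that("fit rejects bad inputs and mismatched prediction shapes", {
  toy <- toy_separable(n = 8, px = 16)
  expect_error(cnn_fit(toy$images, rep("ambiguous", 8)), "binary")
  expect_error(cnn_fit(toy$images, toy$labels[1:4]), "differ")
  fit <- cnn_fit(toy$images, toy$labels,
                 train_config(learning_rate = 0, max_epochs = 5, patience = 2,
                              batch_size = 4, val_fraction = 0.25, seed = 1))
  expect_error(predict(fit, matrix(0, 8, 8)), "expects")
})

test_that("models survive a save/load round trip with a JSON sidecar", {
  toy <- toy_separable(n = 8, px = 16)
  fit <- cnn_fit(toy$images, toy$labels,
                 train_config(learning_rate = 0, max_epochs = 5, patience = 2,
                              batch_size = 4, val_fraction = 0.25, seed = 1))
  base <- file.path(withr::local_tempdir(), "model")
  save_oct_cnn(fit, base)
  back <- load_oct_cnn(base)
  expect_identical(coef(back), coef(fit))
  side <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(side$class_index$female, 0L)
  expect_equal(side$class_index$male, 1L)
  expect_equal(side$flatten, fit$feature_dims$flatten)
})
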