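# Independent oracles used across the suite. These deliberately use naive
# algorithms (loops, flood fill, direct DFT sums) so they share no code
# with the package implementation they check.

# 4-connected component count of a logical matrix, by BFS flood fill
flood_fill_components <- function(mask) {
  if (!any(mask)) return(0L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (j0 in seq_len(ncol(mask))) for (i0 in seq_len(nrow(mask))) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    comp <- comp + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- comp
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        i <- p[1L] + d[1L]; j <- p[2L] + d[2L]
        if (i >= 1L && j >= 1L && i <= nrow(mask) && j <= ncol(mask) &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- comp
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  comp
}

# direct O(n^2) DFT magnitude at every bin (no FFT)
brute_dft_mag <- function(x) {
  n <- length(x)
  j <- seq_len(n) - 1
  vapply(seq_len(n) - 1, function(m)
    Mod(sum(x * exp(-2i * pi * j * m / n))), numeric(1))
}

# metrics from raw label pairs by explicit per-class counting loops
brute_metrics <- function(cm) {
  k <- nrow(cm)
  precision <- recall <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    precision[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (precision[c] + recall[c] > 0)
      2 * precision[c] * recall[c] / (precision[c] + recall[c]) else 0
  }
  support <- rowSums(cm)
  has <- support > 0
  list(precision = precision, recall = recall, f1 = f1,
       macro = c(mean(precision[has]), mean(recall[has]), mean(f1[has])),
       weighted = c(sum(precision[has] * support[has]) / sum(support[has]),
                    sum(recall[has] * support[has]) / sum(support[has]),
                    sum(f1[has] * support[has]) / sum(support[has])),
       accuracy = sum(diag(cm)) / sum(cm))
}

# explicit block-mean downscale for integer factors
block_mean_downscale <- function(img, fy, fx) {
  h <- nrow(img) %/% fy; w <- ncol(img) %/% fx
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- mean(img[((i - 1) * fy + 1):(i * fy),
                          ((j - 1) * fx + 1):(j * fx)])
  out
}
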