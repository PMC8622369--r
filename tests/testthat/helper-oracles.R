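# Independent brute-force oracles used to cross-check the implementation.

# pairwise AUC: wins + half ties over all positive-negative pairs
bf_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# trapezoidal integration of the empirical ROC curve
trapezoid_auc <- function(pos, neg) {
  th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# sort-and-assign aligned ranks, written independently of base rank():
# walk the sorted aligned values, give tie groups the average of the
# positions they span
bf_aligned_ranks <- function(values, higher_is_better = TRUE) {
  a <- values - rowMeans(values)
  v <- as.vector(if (higher_is_better) -a else a)
  ord <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  matrix(r, nrow(values), ncol(values))
}

# straight-from-formula omnibus statistic (independent code path)
bf_far_statistic <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks); kn <- k * n
  Rj <- colSums(ranks); Ri <- rowSums(ranks)
  num <- sum(Rj^2) - (k * n^2 / 4) * (kn + 1)^2
  den <- kn * (kn + 1) * (2 * kn + 1) / 6 - sum(Ri^2) / k
  (k - 1) * num / den
}

# elementwise mean cross-entropy, loop form
bf_cross_entropy <- function(probs, labels) {
  tot <- 0
  for (i in seq_len(nrow(probs)))
    tot <- tot - log(max(probs[i, labels[i]], 1e-12))
  tot / nrow(probs)
}

random_metric_table <- function(n = 4, k = 3, ties = FALSE, seed = 1) {
  set.seed(seed)
  v <- matrix(round(runif(n * k, 50, 100), if (ties) 0 else 3), n, k)
  metric_table(v, paste0("b", seq_len(n)), paste0("t", seq_len(k)))
}

tiny_spec <- function(...) {
  synthetic_spec(n_classes = 3, samples_per_class = 8, height = 16,
                 width = 16, signal_amplitude = 0.5, noise_sigma = 0.1,
                 clutter_amplitude = 0.1, seed = 42, ...)
}
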