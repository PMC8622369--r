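#' Friedman aligned ranks
#'
#' Aligns every observation by subtracting its block mean, then ranks all
#' `k*n` aligned values jointly — rank 1 is best (the largest aligned
#' value when higher is better), ties receive the average of the ranks
#' they span. Joint ranking across blocks makes the procedure more
#' sensitive than the plain Friedman test when the number of blocks is
#' small.
#'
#' @param table a [metric_table()] with `n >= 2` blocks.
#' @return An object of class `aligned_ranks` with elements
#'   `aligned_values` and `ranks` (both `n x k`), `avg_rank` (per
#'   treatment), `n`, `k` and the treatment labels.
#' @export
aligned_ranks <- function(table) {
  stopifnot(inherits(table, "metric_table"))
  x <- table$values
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("need at least 2 blocks", call. = FALSE)
  if (k < 2L) stop("need at least 2 treatments", call. = FALSE)
  aligned <- x - rowMeans(x)
  v <- if (table$higher_is_better) -aligned else aligned
  ranks <- matrix(rank(v, ties.method = "average"), n, k,
                  dimnames = dimnames(x))
  structure(list(aligned_values = aligned, ranks = ranks,
                 avg_rank = colMeans(ranks), n = n, k = k,
                 treatment_labels = table$treatment_labels),
            class = "aligned_ranks")
}

#' @export
print.aligned_ranks <- function(x, ...) {
  cat(sprintf("<aligned_ranks> n = %d blocks, k = %d treatments\n", x$n, x$k))
  print(round(x$avg_rank, 4))
  invisible(x)
}

#' Aligned-ranks omnibus test
#'
#' Tests the hypothesis that all treatments perform equally, using the
#' chi-square-referenced statistic
#' \deqn{T = (k-1)\,\frac{\sum_j \hat R_{\cdot j}^2 - (kn^2/4)(kn+1)^2}
#'   {kn(kn+1)(2kn+1)/6 - \sum_i \hat R_{i\cdot}^2 / k}}
#' with \eqn{\hat R_{\cdot j}} the treatment rank totals and
#' \eqn{\hat R_{i\cdot}} the block rank totals, referred to chi-square
#' with `k - 1` degrees of freedom. With a degenerate denominator (every
#' block fully tied) the statistic is undefined and reported as `NA`.
#'
#' @param ar an [aligned_ranks()] result (or a [metric_table()], which is
#'   ranked first).
#' @return A list with `statistic`, `df`, `p_value` and, when degenerate,
#'   an explanatory `note`.
#' @export
far_omnibus <- function(ar) {
  if (inherits(ar, "metric_table")) ar <- aligned_ranks(ar)
  stopifnot(inherits(ar, "aligned_ranks"))
  n <- ar$n; k <- ar$k
  kn <- k * n
  treat_tot <- colSums(ar$ranks)
  block_tot <- rowSums(ar$ranks)
  num <- sum(treat_tot^2) - (k * n^2 / 4) * (kn + 1)^2
  den <- kn * (kn + 1) * (2 * kn + 1) / 6 - sum(block_tot^2) / k
  if (abs(den) < sqrt(.Machine$double.eps)) {
    return(list(statistic = NA_real_, df = k - 1L, p_value = NA_real_,
                note = paste("degenerate denominator: every block is fully",
                             "tied, the statistic is undefined")))
  }
  T_stat <- (k - 1) * num / den
  list(statistic = T_stat, df = k - 1L,
       p_value = stats::pchisq(T_stat, df = k - 1L, lower.tail = FALSE))
}

#' Finner post-hoc comparison against the best treatment
#'
#' The treatment with the lowest average aligned rank is taken as control;
#' every other treatment `j` is compared to it through
#' `z_j = (Rbar_j - Rbar_control) / sqrt(k(kn+1)/6)` and the raw
#' two-sided normal p-value `2(1 - Phi(z_j))`. Raw p-values are then
#' adjusted by the Finner step-down procedure: sort ascending and take
#' `adj_p_(i) = max_{j <= i} [1 - (1 - p_(j))^(m/j)]` with `m = k - 1`
#' comparisons; a hypothesis is rejected when its adjusted p falls below
#' `alpha`. Both raw and adjusted p-values are reported.
#'
#' @param ar an [aligned_ranks()] result (or a [metric_table()]).
#' @param alpha significance level (default 0.05).
#' @return An object of class `posthoc_report`: the control label and a
#'   data frame with one row per non-control treatment (rank difference,
#'   z, raw and adjusted p, rejection flag), in ascending raw-p order.
#' @export
finner_posthoc <- function(ar, alpha = 0.05) {
  if (inherits(ar, "metric_table")) ar <- aligned_ranks(ar)
  stopifnot(inherits(ar, "aligned_ranks"))
  k <- ar$k; n <- ar$n
  avg <- ar$avg_rank
  ctrl <- which(avg == min(avg))
  if (length(ctrl) > 1L) {
    warning("tie for the best average rank; control chosen lexicographically")
    ctrl <- ctrl[order(ar$treatment_labels[ctrl])][1L]
  }
  se <- sqrt(k * (k * n + 1) / 6)
  others <- setdiff(seq_len(k), ctrl)
  diff <- avg[others] - avg[ctrl]
  z <- diff / se
  raw_p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  ord <- order(raw_p)
  m <- k - 1L
  adj_sorted <- 1 - (1 - raw_p[ord])^(m / seq_along(ord))
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  adj_p <- numeric(length(raw_p))
  adj_p[ord] <- adj_sorted
  comparisons <- data.frame(
    treatment = ar$treatment_labels[others],
    rank_diff = unname(diff), z = unname(z),
    p_raw = unname(raw_p), p_finner = unname(adj_p),
    rejected = unname(adj_p < alpha),
    stringsAsFactors = FALSE)
  comparisons <- comparisons[order(comparisons$p_raw), ]
  rownames(comparisons) <- NULL
  structure(list(control = ar$treatment_labels[ctrl],
                 avg_rank = avg, comparisons = comparisons,
                 alpha = alpha, se = se),
            class = "posthoc_report")
}

#' @export
print.posthoc_report <- function(x, ...) {
  cat(sprintf("<posthoc_report> control: %s (alpha = %g)\n", x$control,
              x$alpha))
  df <- x$comparisons
  df$p_raw <- signif(df$p_raw, 4)
  df$p_finner <- signif(df$p_finner, 4)
  print(df)
  invisible(x)
}

#' Full aligned-ranks comparison of treatments
#'
#' Convenience wrapper running [aligned_ranks()], [far_omnibus()] and
#' [finner_posthoc()] on one metric table — the complete nonparametric
#' multiple-comparison report (average rankings, omnibus statistic and
#' p-value, pairwise raw/Finner-adjusted p-values and decisions).
#'
#' @param table a [metric_table()].
#' @param alpha significance level for the post-hoc decisions.
#' @return An object of class `far_report`.
#' @export
far_compare <- function(table, alpha = 0.05) {
  ar <- aligned_ranks(table)
  omnibus <- far_omnibus(ar)
  posthoc <- finner_posthoc(ar, alpha)
  structure(list(metric_name = table$metric_name, ranking = ar,
                 omnibus = omnibus, posthoc = posthoc, alpha = alpha),
            class = "far_report")
}

#' @export
print.far_report <- function(x, ...) {
  cat(sprintf("Aligned-ranks comparison on %s (n = %d blocks, k = %d)\n",
              x$metric_name, x$ranking$n, x$ranking$k))
  cat(sprintf("Omnibus T = %.4f on %d df, p = %.6g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  avg <- sort(x$ranking$avg_rank)
  for (nm in names(avg)) cat(sprintf("  %-12s %.4f\n", nm, avg[nm]))
  print(x$posthoc)
  invisible(x)
}

far_report_to_list <- function(report) {
  list(metric = report$metric_name,
       avg_rank = as.list(report$ranking$avg_rank),
       omnibus = report$omnibus[c("statistic", "df", "p_value")],
       control = report$posthoc$control,
       comparisons = report$posthoc$comparisons,
       alpha = report$alpha)
}
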