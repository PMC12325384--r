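#' Pre/post change in decoding accuracy
#'
#' Post-session mean accuracy minus pre-session mean accuracy, in percentage
#' points, for two decoding results with matching task, band, feature kind and
#' cross-validation scheme.
#'
#' @param pre,post `decoding_result` objects for the same animal and analysis.
#' @return Numeric delta in percentage points (post - pre).
#' @export
accuracy_delta <- function(pre, post) {
  stopifnot(inherits(pre, "decoding_result"), inherits(post, "decoding_result"))
  same <- identical(pre$task$labels, post$task$labels) &&
    identical(pre$band, post$band) && identical(pre$kind, post$kind) &&
    identical(pre$scheme, post$scheme)
  if (!same) stop("pre and post results differ in task, band, kind or scheme")
  post$mean_acc - pre$mean_acc
}

#' Exact two-sided Wilcoxon signed-rank test against zero
#'
#' Paired signed-rank test of whether the median of `deltas` is zero. Zeros
#' are dropped before ranking (Wilcoxon's original treatment); tied absolute
#' values receive midranks. The two-sided p-value is computed from the exact
#' permutation distribution of the positive-rank sum over all 2^n sign
#' assignments of the observed rank multiset (evaluated by convolution, so
#' ties are handled exactly):
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param deltas Numeric vector of paired differences. All-zero input leaves
#'   the test undefined and raises an error. Fewer than 5 non-zero values
#'   make the smallest attainable two-sided p larger than 0.05; a warning is
#'   emitted.
#' @return List with `statistic` (W, the positive-rank sum), `p_value`
#'   (two-sided, exact), `n` (non-zero pairs used) and `n_dropped`.
#' @export
wilcoxon_signed_rank <- function(deltas) {
  if (length(deltas) == 0) stop("no deltas supplied")
  nz <- deltas[deltas != 0]
  n_dropped <- length(deltas) - length(nz)
  n <- length(nz)
  if (n == 0) stop("all deltas are zero: signed-rank test undefined")
  if (n < 5) warning("fewer than 5 non-zero pairs: test cannot reach p < 0.05")
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  # exact null distribution of W over all 2^n sign assignments, on a grid of
  # doubled ranks so midranks (x.5) become integers
  r2 <- round(2 * r)
  total <- sum(r2)
  dist <- numeric(total + 1)   # index s+1 = probability mass at doubled-sum s
  dist[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), dist[seq_len(total + 1 - v)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * W)
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  p <- min(1, 2 * min(p_le, p_ge))
  list(statistic = W, p_value = p, n = n, n_dropped = n_dropped)
}

#' Summarize a cohort of pre/post decoding accuracies
#'
#' Builds the machine-readable analogue of a per-layer, per-band comparison
#' grid: for every combination of `layer`, `band`, `kind` and `task`, the
#' per-animal accuracy change (post - pre, percentage points), its median, and
#' the exact two-sided signed-rank p-value against zero. Cells with fewer than
#' `min_n` animals report deltas but no p-value. No multiple-comparison
#' correction is applied by default (per-cell p-values are reported as-is);
#' set `p_adjust = "BH"` for a Benjamini-Hochberg-adjusted column.
#'
#' @param accs Data frame with columns `layer`, `band`, `kind`, `task`,
#'   `animal`, `pre_acc`, `post_acc` (one row per animal per cell).
#' @param alpha Significance level for the `signif` flag (default 0.05).
#' @param min_n Minimum animals for testing (default 5).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A `comparison_grid` data frame: one row per cell with
#'   `median_delta`, `p_value`, `signif`, `stars` (`*` p < 0.05, `**`
#'   p < 0.01), `n`, and a list-column `deltas`.
#' @export
summarize_comparison <- function(accs, alpha = 0.05, min_n = 5,
                                 p_adjust = "none") {
  need <- c("layer", "band", "kind", "task", "animal", "pre_acc", "post_acc")
  miss <- setdiff(need, names(accs))
  if (length(miss)) stop("`accs` lacks column(s): ", paste(miss, collapse = ", "))
  key <- interaction(accs$layer, accs$band, accs$kind, accs$task, drop = TRUE)
  cells <- lapply(split(accs, key), function(d) {
    delta <- d$post_acc - d$pre_acc
    p <- NA_real_
    if (length(delta) >= min_n && any(delta != 0)) {
      p <- wilcoxon_signed_rank(delta)$p_value
    }
    data.frame(layer = d$layer[1], band = d$band[1], kind = d$kind[1],
               task = d$task[1], n = length(delta),
               median_delta = stats::median(delta), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  if (p_adjust != "none") {
    out$p_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out$signif <- !is.na(out$p_value) & out$p_value < alpha
  out$stars <- ifelse(is.na(out$p_value), "",
                      ifelse(out$p_value < 0.01, "**",
                             ifelse(out$p_value < alpha, "*", "")))
  out$deltas <- unname(lapply(split(accs, key),
                              function(d) d$post_acc - d$pre_acc))
  class(out) <- c("comparison_grid", "data.frame")
  out
}

#' Heatmap of a comparison grid
#'
#' Median accuracy changes as a band-by-layer heatmap (red = improvement,
#' blue = impairment), one panel per feature kind and task. Requires ggplot2.
#'
#' @param grid A `comparison_grid` from [summarize_comparison()].
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
plot_comparison <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_comparison requires ggplot2")
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$layer, y = .data$band,
                                     fill = .data$median_delta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0,
                                  name = "median Δaccuracy (pp)") +
    ggplot2::facet_grid(kind ~ task) +
    ggplot2::theme_minimal()
}
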