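#' Counting accuracy against ground truth
#'
#' Absolute relative counting error in percent:
#' `|auto - truth| / truth * 100`.
#'
#' @param auto_count automatic count.
#' @param truth_count ground-truth count, `> 0`.
#' @return Percent error, `>= 0`.
#' @export
counting_accuracy <- function(auto_count, truth_count) {
  if (any(truth_count <= 0)) stop("truth count must be > 0", call. = FALSE)
  abs(auto_count - truth_count) / truth_count * 100
}

#' Summarize counting accuracy over validation regions
#'
#' @param auto_counts,truth_counts integer vectors, one entry per region.
#' @return An `accuracy_summary`: per-region percent errors, their mean and
#'   SD, the signed mean bias, the number of regions and of cells.
#' @export
accuracy_summary <- function(auto_counts, truth_counts) {
  if (length(auto_counts) != length(truth_counts)) {
    stop("count vectors differ in length", call. = FALSE)
  }
  err <- counting_accuracy(auto_counts, truth_counts)
  structure(list(per_region_error = err,
                 mean_error = mean(err),
                 sd_error = stats::sd(err),
                 mean_signed_bias =
                   mean((auto_counts - truth_counts) / truth_counts * 100),
                 n_regions = length(err),
                 n_cells_total = sum(truth_counts)),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("<accuracy_summary> %.2f%% +/- %.2f%% over %d regions (%d cells)\n",
              x$mean_error, x$sd_error, x$n_regions, x$n_cells_total))
  invisible(x)
}

#' Per-axis centroid deviation of detected seeds
#'
#' Seeds are matched to ground-truth centroids by greedy nearest-neighbor
#' pairing (repeatedly taking the globally closest unmatched pair) within
#' `match_radius` pixels; the mean absolute deviation per axis is reported
#' over the matched pairs, along with the unmatched counts.  Symmetric under
#' exchanging seeds and truth.
#'
#' @param seeds a [seed_set].
#' @param truth a [ground_truth].
#' @param match_radius matching radius in pixels, `> 0` (default 5).
#' @return `list(mean_abs_dev = c(z =, y =, x =), n_matched,
#'   n_unmatched_seeds, n_unmatched_truth)`.
#' @export
centroid_deviation <- function(seeds, truth, match_radius = 5) {
  if (match_radius <= 0) stop("match_radius must be > 0", call. = FALSE)
  s <- as.matrix(seeds$seeds[, c("z", "y", "x")])
  t <- as.matrix(truth$centroids[, c("z", "y", "x")])
  if (nrow(s) == 0L || nrow(t) == 0L) {
    stop("nothing to compare", call. = FALSE)
  }
  dm <- outer(seq_len(nrow(s)), seq_len(nrow(t)), function(i, j) {
    sqrt((s[i, 1] - t[j, 1])^2 + (s[i, 2] - t[j, 2])^2 +
           (s[i, 3] - t[j, 3])^2)
  })
  pairs <- list()
  repeat {
    m <- which.min(dm)
    if (length(m) == 0L || dm[m] > match_radius) break
    i <- (m - 1) %% nrow(dm) + 1
    j <- (m - 1) %/% nrow(dm) + 1
    pairs[[length(pairs) + 1L]] <- c(i, j)
    dm[i, ] <- Inf
    dm[, j] <- Inf
    if (all(!is.finite(dm))) break
  }
  if (length(pairs) == 0L) stop("nothing to compare", call. = FALSE)
  pm <- do.call(rbind, pairs)
  dev <- abs(s[pm[, 1], , drop = FALSE] - t[pm[, 2], , drop = FALSE])
  list(mean_abs_dev = c(z = mean(dev[, 1]), y = mean(dev[, 2]),
                        x = mean(dev[, 3])),
       n_matched = nrow(pm),
       n_unmatched_seeds = nrow(s) - nrow(pm),
       n_unmatched_truth = nrow(t) - nrow(pm))
}

significance_stars <- function(p) {
  if (p < 0.0005) "****"
  else if (p < 0.005) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Two-tailed equal-variance Student's t-test
#'
#' Classic pooled-variance two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-sided p-value; significance stars follow
#' the convention `*` p < 0.05, `**` p < 0.01, `***` p < 0.005,
#' `****` p < 0.0005.
#'
#' @param group_a,group_b numeric measurement vectors, each of length
#'   `>= 2`.
#' @return A `group_comparison`: the groups, `t_statistic`, `df`, `p_value`
#'   and `stars`.
#' @export
ttest_equal_var <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (sp2 <= 0) stop("degenerate variance", call. = FALSE)
  t <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- as.integer(na + nb - 2L)
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(group_a = group_a, group_b = group_b,
                 t_statistic = t, df = df, p_value = p,
                 stars = significance_stars(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.4f (df = %d), p = %.4g %s\n",
              x$t_statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Box-plot summary of pooled measurements
#'
#' Mean, median, quartiles (linear interpolation, i.e. `stats::quantile`
#' type 7 -- chosen over Tukey hinges for determinism across sample sizes),
#' the total range, and the individual points lying beyond 1.5 times the
#' interquartile range from the quartiles.
#'
#' @param values numeric vector, `n >= 1`.
#' @return `list(n, mean, median, q1, q3, iqr, range, outliers)`.
#' @export
summarize_boxplot <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(n = length(values),
       mean = mean(values),
       median = q[2],
       q1 = q[1],
       q3 = q[3],
       iqr = iqr,
       range = range(values),
       outliers = values[values < lo | values > hi])
}
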