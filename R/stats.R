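# Cohort-level comparison of the five GN metrics: Friedman omnibus over
# within-exam ranks, pairwise Wilcoxon signed-rank with Holm adjustment,
# Pearson correlation with strength labels, and a linkage-preserving paired
# permutation test at the single-exam level.

metric_columns <- function(table) {
  known <- intersect(gn_metric_names(), names(table))
  cols <- if (length(known) >= 2) known else names(table)[vapply(table, is.numeric, TRUE)]
  cols <- setdiff(cols, c("n_slices_used", "n_slices"))
  if (length(cols) < 2) stop("need >= 2 metric columns", call. = FALSE)
  cols
}

#' Friedman omnibus test across GN metrics
#'
#' Chi-square Friedman test on within-exam ranks (average ranks for ties)
#' of an exams-by-metrics table.
#'
#' @param table Data frame or matrix, rows = exams, columns = metrics
#'   (non-metric columns such as `exam_id` are ignored).
#' @return A list: `statistic`, `p_value`, `df`, `n_exams`, `n_metrics`.
#' @export
friedman_omnibus <- function(table) {
  cols <- metric_columns(as.data.frame(table))
  m <- as.matrix(as.data.frame(table)[cols])
  if (nrow(m) < 3) stop("need >= 3 exams", call. = FALSE)
  if (anyNA(m)) {
    stop("missing cells; exclude incomplete exams (rows) before the Friedman test",
         call. = FALSE)
  }
  ft <- friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # every exam fully tied across metrics: no rank signal at all
    stat <- 0
    p <- 1
  }
  list(statistic = stat, p_value = p,
       df = unname(ft$parameter), n_exams = nrow(m), n_metrics = ncol(m))
}

# one paired Wilcoxon signed-rank test; zeros discarded, exact for small n
wilcoxon_pair <- function(x, y, exact_max_n = 25) {
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, n = 0, method = "degenerate", degenerate = TRUE))
  }
  exact <- n <= exact_max_n && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  list(p = wt$p.value, n = n,
       method = if (exact) "exact" else "normal approximation",
       degenerate = FALSE)
}

#' Pairwise Wilcoxon signed-rank tests with Holm adjustment
#'
#' Tests every metric pair two-sided, discarding zero differences
#' (classic signed-rank); exact null for n <= 25 untied differences,
#' normal approximation with continuity correction otherwise. Raw p
#' values are Holm step-down adjusted.
#'
#' @param table Exams-by-metrics data frame or matrix.
#' @param alpha Family-wise significance level for the flags.
#' @return A tibble: `metric_a`, `metric_b`, `n`, `p_raw`, `p_holm`,
#'   `significant`, `method`, `degenerate`.
#' @export
pairwise_wilcoxon_holm <- function(table, alpha = 0.05) {
  df <- as.data.frame(table)
  cols <- metric_columns(df)
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    w <- wilcoxon_pair(df[[pr[1]]], df[[pr[2]]])
    tibble::tibble(metric_a = pr[1], metric_b = pr[2], n = w$n,
                   p_raw = w$p, method = w$method, degenerate = w$degenerate)
  })
  res$p_holm <- p.adjust(res$p_raw, method = "holm")
  res$significant <- res$p_holm < alpha
  res[c("metric_a", "metric_b", "n", "p_raw", "p_holm", "significant",
        "method", "degenerate")]
}

#' Pearson correlation matrix with strength labels
#'
#' Pearson r for every metric pair, each labelled by the conventional
#' strength bins: very strong (r >= 0.8), strong (0.6 <= r < 0.8),
#' moderate (0.4 <= r < 0.6), weak (0.2 <= r < 0.4), very weak/none
#' (r < 0.2). Zero-variance columns yield undefined correlations.
#'
#' @param table Exams-by-metrics data frame or matrix.
#' @return A list of class `"gn_correlation"`: `r` (symmetric matrix,
#'   unit diagonal) and `labels`, a tibble of off-diagonal pairs with
#'   `r` and `strength`.
#' @export
pearson_matrix_with_strength <- function(table) {
  df <- as.data.frame(table)
  cols <- metric_columns(df)
  m <- as.matrix(df[cols])
  if (nrow(m) < 3) stop("need >= 3 exams", call. = FALSE)
  zero_var <- apply(m, 2, function(v) stats::var(v) == 0)
  r <- suppressWarnings(cor(m, method = "pearson"))
  r[zero_var, ] <- NA; r[, zero_var] <- NA
  diag(r) <- ifelse(zero_var, NA, 1)
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  labels <- purrr::map_dfr(pairs, function(pr) {
    rv <- r[pr[1], pr[2]]
    tibble::tibble(metric_a = pr[1], metric_b = pr[2], r = rv,
                   strength = correlation_strength(rv))
  })
  structure(list(r = r, labels = labels), class = "gn_correlation")
}

#' @rdname pearson_matrix_with_strength
#' @param r Correlation value(s).
#' @export
correlation_strength <- function(r) {
  dplyr::case_when(
    is.na(r) ~ "undefined",
    r >= 0.8 ~ "very strong",
    r >= 0.6 ~ "strong",
    r >= 0.4 ~ "moderate",
    r >= 0.2 ~ "weak",
    TRUE ~ "very weak/none")
}

# all 2^k signed sums of v, via meet-in-the-middle for larger k
signed_sums <- function(v) {
  s <- 0
  for (x in v) s <- c(s + x, s - x)
  s
}

#' Linkage-preserving paired permutation test for one exam
#'
#' Treats an exam as a matched set of slice-level measurements from two
#' metrics. The observed statistic is |mean(A - B)| over slices; the null
#' is generated by independently flipping the sign of each per-slice
#' difference (swapping the metric labels within a slice), which preserves
#' the slice-to-slice structure. Exhaustive enumeration up to 20 slices,
#' Monte-Carlo with the add-one estimator above.
#'
#' @param slice_values_a,slice_values_b Equal-length numeric vectors of
#'   slice-aligned values from one exam.
#' @param n_perm Monte-Carlo permutation count (used only above 20
#'   slices).
#' @param seed Seed for the Monte-Carlo draw.
#' @return A list: `p_value`, `observed` (HU), `n_slices`, `method`.
#' @examples
#' paired_permutation_exam(c(2, 3), c(1, 2))$p_value  # 0.5
#' @export
paired_permutation_exam <- function(slice_values_a, slice_values_b,
                                    n_perm = 10000, seed = 1L) {
  stopifnot(length(slice_values_a) == length(slice_values_b),
            length(slice_values_a) >= 1, n_perm >= 1)
  d <- slice_values_a - slice_values_b
  n <- length(d)
  obs <- abs(mean(d))
  if (all(d == 0)) {
    return(list(p_value = 1, observed = 0, n_slices = n, method = "degenerate"))
  }
  tol <- 1e-12 * max(1, obs)
  if (n <= 20) {
    half <- n %/% 2
    sa <- signed_sums(d[seq_len(half)])
    sb <- signed_sums(d[-seq_len(half)])
    null_means <- abs(outer(sa, sb, "+")) / n
    p <- mean(null_means >= obs - tol)
    method <- "exhaustive"
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null_means <- abs(signs %*% d) / n
    p <- (1 + sum(null_means >= obs - tol)) / (1 + n_perm)
    method <- "monte-carlo"
  }
  list(p_value = p, observed = obs, n_slices = n, method = method)
}

#' Compare GN metrics across a cohort
#'
#' Runs the full two-tier comparison: Friedman omnibus and pairwise
#' Wilcoxon + Holm across metrics, the Pearson correlation matrix with
#' strength labels, and (when slice-level records are supplied) the
#' per-exam linkage-preserving permutation tests among the three
#' soft-tissue metrics.
#'
#' @param cohort Exams-by-metrics data frame (e.g. rows of
#'   [compute_exam_gn()] pivoted wide with [gn_cohort_table()]).
#' @param slice_values Optional long tibble of slice-level records with
#'   columns `exam_id`, `slice`, `metric`, `value`.
#' @param alpha Significance level.
#' @param n_perm,seed Permutation settings, see
#'   [paired_permutation_exam()].
#' @return An object of class `"gn_comparison"`; see [tidy()] and
#'   [glance()] methods.
#' @export
gn_compare <- function(cohort, slice_values = NULL, alpha = 0.05,
                       n_perm = 10000, seed = 1L) {
  cohort <- as.data.frame(cohort)
  fr <- friedman_omnibus(cohort)
  pw <- pairwise_wilcoxon_holm(cohort, alpha = alpha)
  pc <- pearson_matrix_with_strength(cohort)
  perm <- NULL
  if (!is.null(slice_values)) {
    tissue <- intersect(c("Duke_tissue_mode", "Wisconsin_tissue_mean",
                          "Wisconsin_tissue_mode"), unique(slice_values$metric))
    pairs <- utils::combn(tissue, 2, simplify = FALSE)
    wide <- tidyr::pivot_wider(
      slice_values[c("exam_id", "slice", "metric", "value")],
      names_from = "metric", values_from = "value")
    perm <- purrr::map_dfr(split(wide, wide$exam_id), function(ex) {
      purrr::map_dfr(pairs, function(pr) {
        keep <- !is.na(ex[[pr[1]]]) & !is.na(ex[[pr[2]]])
        pp <- paired_permutation_exam(ex[[pr[1]]][keep], ex[[pr[2]]][keep],
                                      n_perm = n_perm, seed = seed)
        tibble::tibble(exam_id = ex$exam_id[1], metric_a = pr[1],
                       metric_b = pr[2], p_value = pp$p_value,
                       observed = pp$observed, n_slices = pp$n_slices,
                       method = pp$method)
      })
    })
  }
  structure(list(friedman = fr, pairwise = pw, pearson = pc,
                 permutation = perm, alpha = alpha,
                 n_exams = fr$n_exams, n_metrics = fr$n_metrics),
            class = "gn_comparison")
}

#' Pivot per-exam metric rows into an exams-by-metrics table
#'
#' @param exam_results Long tibble with `exam_id`, `metric`, `exam_gn`
#'   (rows of [compute_exam_gn()] across exams).
#' @return Wide tibble: one row per exam, one column per metric.
#' @export
gn_cohort_table <- function(exam_results) {
  tidyr::pivot_wider(exam_results[c("exam_id", "metric", "exam_gn")],
                     names_from = "metric", values_from = "exam_gn")
}

#' @export
print.gn_comparison <- function(x, ...) {
  cat(sprintf("<gn_comparison> %d exams x %d metrics\n", x$n_exams, x$n_metrics))
  cat(sprintf("  Friedman chi-sq = %.4g (df %d), p = %.3g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  cat(sprintf("  %d/%d metric pairs significant at alpha = %g (Holm)\n",
              sum(x$pairwise$significant), nrow(x$pairwise), x$alpha))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation tests: %d exam-pair rows, %d with p < %g\n",
                nrow(x$permutation), sum(x$permutation$p_value < x$alpha),
                x$alpha))
  }
  invisible(x)
}

#' Tidy a GN metric comparison
#'
#' One row per metric pair: Pearson r and strength label joined with the
#' Wilcoxon raw and Holm-adjusted p values.
#'
#' @param x A `gn_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gn_comparison <- function(x, ...) {
  dplyr::left_join(x$pairwise, x$pearson$labels,
                   by = c("metric_a", "metric_b"))
}

#' @rdname tidy.gn_comparison
#' @export
glance.gn_comparison <- function(x, ...) {
  tibble::tibble(n_exams = x$n_exams, n_metrics = x$n_metrics,
                 friedman_statistic = x$friedman$statistic,
                 friedman_df = x$friedman$df,
                 friedman_p = x$friedman$p_value,
                 n_pairs = nrow(x$pairwise),
                 n_significant = sum(x$pairwise$significant),
                 alpha = x$alpha)
}
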