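test_that("Friedman omnibus matches the textbook formula on fixed tables", {
  # every exam ranks the metrics 1 < 2 < 3: rank sums (3, 6, 9), Q = 6
  m <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3, byrow = TRUE)
  expect_equal(friedman_omnibus(m)$statistic, 6.0)
  set.seed(77)
  for (i in 1:10) {
    tbl <- matrix(rnorm(10 * 5, mean = 15, sd = 3), 10, 5,
                  dimnames = list(NULL, paste0("m", 1:5)))
    got <- friedman_omnibus(tbl)
    expect_lt(abs(got$statistic - friedman_oracle(tbl)), 1e-8)
    expect_lt(abs(got$p_value -
                    stats::pchisq(friedman_oracle(tbl), 4, lower.tail = FALSE)),
              1e-8)
  }
})

test_that("identical metric columns give a null Friedman result", {
  v <- c(4, 9, 2, 7)
  m <- cbind(a = v, b = v, c = v)
  r <- friedman_omnibus(m)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("Friedman rejects degenerate tables", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[2, 3] <- NA
  expect_error(friedman_omnibus(m), "missing cells|exclude")
  expect_error(friedman_omnibus(m[1:2, ]), ">= 3 exams")
})

test_that("pairwise Wilcoxon matches exact enumeration and the normal formula", {
  # n = 6 all-positive differences: two-sided exact p = 2/2^6
  x <- 1:6 + c(0.5, 1, 1.5, 2, 2.5, 3)
  y <- as.numeric(1:6)
  w <- ctgn:::wilcoxon_pair(x, y)
  expect_equal(w$p, 0.03125)
  expect_equal(w$method, "exact")

  set.seed(5)
  for (i in 1:5) {
    d <- rnorm(9)
    w <- ctgn:::wilcoxon_pair(d + 0.4, rep(0, 9))
    expect_lt(abs(w$p - wilcoxon_exact_oracle(d + 0.4)), 1e-8)
  }

  # large-n path: normal approximation with continuity correction
  set.seed(6)
  d <- rnorm(40, mean = 0.3)
  w <- ctgn:::wilcoxon_pair(d, rep(0, 40))
  p_oracle <- wilcoxon_normal_oracle(d)
  expect_lt(abs(w$p - p_oracle), 1e-8)
  expect_equal(w$method, "normal approximation")
})

test_that("degenerate pairs report p = 1 and Holm dominance holds", {
  tbl <- tibble::tibble(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                        c = c(2, 3, 4.5, 5))
  r <- pairwise_wilcoxon_holm(tbl)
  ab <- r[r$metric_a == "a" & r$metric_b == "b", ]
  expect_equal(ab$p_raw, 1)
  expect_true(ab$degenerate)
  expect_true(all(r$p_holm >= r$p_raw))
  expect_true(all(r$p_raw >= 0 & r$p_holm <= 1))
})

test_that("significance sets shrink as alpha decreases", {
  set.seed(31)
  tbl <- tibble::tibble(a = rnorm(15, 10), b = rnorm(15, 11), c = rnorm(15, 13))
  r1 <- pairwise_wilcoxon_holm(tbl, alpha = 0.05)
  r2 <- pairwise_wilcoxon_holm(tbl, alpha = 0.01)
  expect_true(all(which(r2$significant) %in% which(r1$significant)))
})

test_that("Pearson matrix is symmetric with unit diagonal and binned labels", {
  set.seed(41)
  base <- rnorm(30, 20, 4)
  tbl <- tibble::tibble(a = base, b = base * 1.1 + rnorm(30, 0, 0.5),
                        c = rnorm(30, 20, 4))
  pm <- pearson_matrix_with_strength(tbl)
  expect_equal(pm$r, t(pm$r))
  expect_equal(unname(diag(pm$r)), rep(1, 3))
  ab <- pm$labels[pm$labels$metric_a == "a" & pm$labels$metric_b == "b", ]
  expect_equal(ab$strength, "very strong")
  # self-correlation is exactly 1
  self <- pearson_matrix_with_strength(tibble::tibble(a = base, b = base))
  expect_equal(self$r["a", "b"], 1)
  expect_equal(self$labels$strength, "very strong")
})

test_that("correlation strength follows the conventional r bins", {
  expect_equal(correlation_strength(c(0.85, 0.7, 0.55, 0.3, 0.1, NA)),
               c("very strong", "strong", "moderate", "weak",
                 "very weak/none", "undefined"))
  expect_equal(correlation_strength(c(0.8, 0.6, 0.4, 0.2)),
               c("very strong", "strong", "moderate", "weak"))
})

test_that("zero-variance columns yield undefined correlations", {
  tbl <- tibble::tibble(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  pm <- pearson_matrix_with_strength(tbl)
  expect_true(is.na(pm$r["a", "b"]))
  expect_equal(pm$labels$strength, "undefined")
})

test_that("paired permutation test matches exhaustive enumeration", {
  expect_equal(paired_permutation_exam(c(1, 1), c(0, 0))$p_value, 0.5)
  p12 <- paired_permutation_exam(rep(1, 12), rep(0, 12))
  expect_equal(p12$p_value, 2 / 4096)
  expect_equal(p12$method, "exhaustive")
  expect_equal(paired_permutation_exam(c(3, 3), c(3, 3))$p_value, 1)
})

test_that("Monte-Carlo permutation p agrees with enumeration and is seeded", {
  set.seed(3)
  a <- rnorm(12, 10, 1); b <- a - 0.4 + rnorm(12, 0, 0.6)
  exact <- paired_permutation_exam(a, b)$p_value
  # force the Monte-Carlo path by replicating beyond the enumeration limit
  a2 <- c(a, a); b2 <- c(b, b)
  mc1 <- paired_permutation_exam(a2, b2, n_perm = 50000, seed = 42)
  mc2 <- paired_permutation_exam(a2, b2, n_perm = 50000, seed = 42)
  expect_identical(mc1$p_value, mc2$p_value)
  expect_equal(mc1$method, "monte-carlo")
  exact24 <- {
    d <- a2 - b2
    s <- 0
    for (x in d[1:12]) s <- c(s + x, s - x)
    s2 <- 0
    for (x in d[13:24]) s2 <- c(s2 + x, s2 - x)
    mean(abs(outer(s, s2, "+")) / 24 >= abs(mean(d)) - 1e-12)
  }
  expect_lt(abs(mc1$p_value - exact24), 0.01)
})

test_that("gn_compare assembles both tiers and its tidiers are consistent", {
  set.seed(55)
  n <- 12
  cohort <- tibble::tibble(
    exam_id = sprintf("e%02d", 1:n),
    Duke_tissue_mode = rnorm(n, 14, 2))
  cohort$Wisconsin_tissue_mean <- cohort$Duke_tissue_mode + 2  # constant shift
  cohort$Wisconsin_tissue_mode <- rnorm(n, 15, 2)
  slice_values <- tidyr::expand_grid(exam_id = cohort$exam_id, slice = 1:8) |>
    dplyr::mutate(Duke_tissue_mode = rnorm(dplyr::n(), 14, 1)) |>
    dplyr::mutate(Wisconsin_tissue_mean = Duke_tissue_mode + 2 + rnorm(dplyr::n(), 0, 0.2)) |>
    tidyr::pivot_longer(c("Duke_tissue_mode", "Wisconsin_tissue_mean"),
                        names_to = "metric", values_to = "value")
  cmp <- gn_compare(cohort, slice_values = slice_values, seed = 7)
  expect_s3_class(cmp, "gn_comparison")
  td <- tidy(cmp)
  expect_equal(nrow(td), 3)  # C(3,2) metric pairs
  expect_true(all(c("p_raw", "p_holm", "r", "strength") %in% names(td)))
  shift <- td[td$metric_a == "Duke_tissue_mode" &
                td$metric_b == "Wisconsin_tissue_mean", ]
  expect_lt(shift$p_holm, 0.05)        # constant +2 shift is significant
  expect_equal(shift$r, 1)             # and perfectly correlated
  gl <- glance(cmp)
  expect_equal(gl$n_exams, n)
  expect_lt(gl$friedman_p, 0.05)
  expect_equal(nrow(cmp$permutation), n)  # one tissue pair per exam
  expect_true(all(cmp$permutation$p_value <= 1))
})
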