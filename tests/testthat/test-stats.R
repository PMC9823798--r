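test_that("perfect antimonotone pairs give rho = -1", {
  x <- c(1, 4, 9, 16, 25)
  r <- spearman_test(x, rev(seq_along(x)))
  expect_equal(r$statistic, -1)
})

test_that("rho matches the rank-formula oracle", {
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  r <- spearman_test(x, y)
  expect_equal(r$statistic, 0.8)
  expect_equal(r$statistic, rho_ranks(x, y))
})

test_that("small-sample Spearman p equals full permutation enumeration", {
  set.seed(5)
  for (n in c(5, 6, 7)) {
    x <- sample(100, n); y <- sample(100, n)
    r <- spearman_test(x, y)
    en <- spearman_enum(x, y)
    expect_equal(r$statistic, en$rho, tolerance = 1e-12)
    expect_equal(r$p_value, en$p, tolerance = 1e-9)
  }
})

test_that("degenerate Spearman inputs are flagged, not guessed", {
  expect_warning(r <- spearman_test(c(1, 1, 1, 1), c(1, 2, 3, 4)), "zero variance")
  expect_true(is.na(r$statistic))
  expect_true(is.na(spearman_test(1:2, 2:1)$statistic))  # n gate
})

test_that("rank-sum test matches exact enumeration on small groups", {
  set.seed(9)
  cases <- list(list(a = c(1, 5, 9), b = c(2, 3, 12)),
                list(a = sample(50, 4), b = sample(50, 4) + 60),
                list(a = c(7, 1, 3), b = c(2, 9, 4, 6)))
  for (cs in cases) {
    r <- ranksum_test(cs$a, cs$b)
    en <- ranksum_enum(cs$a, cs$b)
    expect_equal(r$statistic, en$statistic)
    expect_equal(r$p_value, en$p, tolerance = 1e-9)
  }
})

test_that("identical groups give p = 1 and extreme separation the minimal p", {
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # all 20 assignments of 3-vs-3 ranks: two-sided floor is 2/20
  expect_equal(ranksum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_error(ranksum_test(numeric(0), 1:3), "empty")
})

test_that("Kruskal-Wallis H matches the rank formula", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_test(g)
  expect_equal(r$statistic, kruskal_H(g), tolerance = 1e-12)
  expect_equal(r$statistic, 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 21)
  expect_equal(r$p_value, pchisq(r$statistic, 2, lower.tail = FALSE))
  # tie-corrected instance
  g2 <- list(c(1, 1, 3), c(2, 2), c(5, 4, 4))
  expect_equal(kruskal_test(g2)$statistic, kruskal_H(g2), tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis agrees with the asymptotic rank sum", {
  set.seed(2)
  a <- rnorm(12); b <- rnorm(12) + 0.8
  p_kw <- kruskal_test(list(a, b))$p_value
  w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_lt(abs(p_kw - w) / w, 0.1)
})

test_that("empty groups are dropped with a warning, too few is fatal", {
  expect_warning(r <- kruskal_test(list(1:3, numeric(0), 4:6)), "dropped")
  expect_equal(r$n, 6L)
  expect_error(suppressWarnings(kruskal_test(list(1:3, numeric(0)))),
               "at least two")
})

test_that("the analysis emits exactly the planned comparisons", {
  plan <- default_comparison_plan()
  set.seed(3)
  mk <- function(f, cmp) {
    base <- runif(8, 20, 100)
    data.frame(subject_id = sprintf("S%02d", 1:8), feature = f,
               comparison = cmp, baseline_median = base,
               post_median = base * 0.8, delta = -base * 0.2,
               n_epochs_baseline = 4, n_epochs_post = 4)
  }
  st <- rbind(do.call(rbind, lapply(plan$reeg, function(d) mk("rEEG", d))),
              do.call(rbind, lapply(plan$asi, function(d) mk("ASI", d))))
  clin <- data.frame(subject_id = sprintf("S%02d", 1:8),
                     gestational_age_days = seq(200, 290, length.out = 8),
                     fentanyl = rep(c(0, 1), 4),
                     diagnosis_group = rep(0:3, 2))
  out <- run_cohort_analyses(st, clin, plan)
  # 10 delta~baseline + 10 pre~post + 2 features x 3 clinical tests
  expect_equal(nrow(out$stats), 26)
  expect_equal(sum(out$stats$family == "delta_vs_baseline"), 10)
  expect_equal(sum(out$stats$family == "clinical_factors"), 6)
  expect_true(all(out$stats$family_size[out$stats$family == "delta_vs_baseline"] == 10))
  # deterministic monotone construction: every planned rho is -1
  rhos <- out$stats$statistic[out$stats$family == "delta_vs_baseline"]
  expect_true(all(rhos == -1))
  expect_equal(nrow(out$scatter), 8 * 10)
})

test_that("too few subjects yields not-computed results, never silence", {
  st <- data.frame(subject_id = "S01", feature = "rEEG", comparison = "P3-P4",
                   baseline_median = 50, post_median = 40, delta = -10,
                   n_epochs_baseline = 4, n_epochs_post = 4)
  out <- run_cohort_analyses(st, NULL)
  expect_equal(nrow(out$stats), 20)      # all planned rows present
  expect_true(all(is.na(out$stats$statistic)))
  expect_null(out$scatter)
})
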