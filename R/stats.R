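#' Spearman rank correlation
#'
#' Two-sided Spearman correlation with average ranks for ties; the p-value
#' is exact (permutation distribution) for small untied samples and
#' asymptotic otherwise, as provided by [stats::cor.test()]. Missing pairs
#' are dropped listwise.
#'
#' @param x,y Paired numeric vectors.
#' @param comparison Label carried into the result.
#' @return A `stat_result` data frame row: `test`, `comparison`,
#'   `statistic` (rho), `p_value`, `n`.
#' @export
spearman_test <- function(x, y, comparison = "") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(stat_row("spearman", comparison, NA, NA, n))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; Spearman correlation undefined")
    return(stat_row("spearman", comparison, NA, NA, n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  stat_row("spearman", comparison, unname(ct$estimate), ct$p.value, n)
}

#' Wilcoxon rank sum test
#'
#' Two-sided two-sample rank test; exact for small untied samples, normal
#' approximation with tie correction otherwise ([stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors (`NA` dropped).
#' @param comparison Label carried into the result.
#' @return A `stat_result` row with the rank-sum `W` statistic.
#' @export
ranksum_test <- function(group_a, group_b, comparison = "") {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b)) stop("empty group in rank sum test")
  wt <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
  stat_row("wilcoxon_ranksum", comparison, unname(wt$statistic), wt$p.value,
           length(a) + length(b))
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic with a chi-square p-value on `k - 1` degrees of
#' freedom ([stats::kruskal.test()]). Empty groups are dropped with a
#' warning; fewer than two remaining groups is an error.
#'
#' @param groups List of numeric vectors.
#' @param comparison Label carried into the result.
#' @return A `stat_result` row.
#' @export
kruskal_test <- function(groups, comparison = "") {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  empty <- vapply(groups, function(g) length(g) == 0, logical(1))
  if (any(empty)) {
    warning(sprintf("%d empty group(s) dropped from Kruskal-Wallis", sum(empty)))
    groups <- groups[!empty]
  }
  if (length(groups) < 2) stop("Kruskal-Wallis needs at least two non-empty groups")
  kt <- kruskal.test(groups)
  stat_row("kruskal_wallis", comparison, unname(kt$statistic), kt$p.value,
           sum(lengths(groups)))
}

stat_row <- function(test, comparison, statistic, p, n) {
  structure(data.frame(test = test, comparison = comparison,
                       statistic = as.numeric(statistic),
                       p_value = as.numeric(p), n = as.integer(n)),
            class = c("stat_result", "data.frame"))
}

#' The a-priori comparison plan
#'
#' Multiple comparisons are minimised up front to the physiologically
#' interpretable set: rEEG (global activity level) on the biparietal P3-P4
#' derivation, the frontal F3-F4 derivation and the four referential
#' channels; ASI on the interhemispheric, the two intrahemispheric, and the
#' frontal pairings. No multiple-testing correction is applied (the family
#' size is recorded so users can apply one).
#'
#' @return List of class `comparison_plan` with `reeg` and `asi` comparison
#'   labels and the `primary` comparison per feature used for the
#'   clinical-factor analyses.
#' @export
default_comparison_plan <- function() {
  structure(list(
    reeg = c("P3-P4", "F3-F4", "F3", "F4", "P3", "P4"),
    asi = names(asi_pairs()),
    primary = c(rEEG = "P3-P4", ASI = "interhemispheric")),
    class = "comparison_plan")
}

#' Run the planned cohort analyses
#'
#' Emits exactly the planned comparisons and nothing else:
#' \itemize{
#'   \item delta versus baseline (Spearman) for every planned rEEG
#'     derivation and ASI pairing -- the context-sensitivity question: does
#'     a higher pre-drug level predict a larger drug-induced reduction;
#'   \item pre versus post drug (Wilcoxon rank sum) per planned comparison;
#'   \item gestational age versus baseline (Spearman), fentanyl versus
#'     baseline (rank sum) and diagnosis group versus baseline
#'     (Kruskal-Wallis) on each feature's primary comparison.
#' }
#' Comparisons with insufficient subjects are reported as not computed
#' (`NA` statistic), never silently skipped.
#'
#' @param short_table Short-term result table (rows from
#'   [short_term_result()] across subjects, features, comparisons).
#' @param clinical Clinical covariate table (`subject_id`,
#'   `gestational_age_days`, `fentanyl`, `diagnosis_group`); may be `NULL`
#'   to skip the clinical-factor block.
#' @param plan A [default_comparison_plan()].
#' @param min_n Minimum subjects with non-missing results per comparison.
#' @return List with `stats` (the `stat_result` table, with a `family`
#'   column and `family_size`), and `scatter` (per-comparison
#'   baseline-versus-delta points for display).
#' @export
run_cohort_analyses <- function(short_table, clinical = NULL,
                                plan = default_comparison_plan(),
                                min_n = 5) {
  rows <- list(); scat <- list()
  planned <- rbind(
    data.frame(feature = "rEEG", comparison = plan$reeg),
    data.frame(feature = "ASI", comparison = plan$asi))

  for (i in seq_len(nrow(planned))) {
    f <- planned$feature[i]; cmp <- planned$comparison[i]
    tab <- short_table[short_table$feature == f &
                         short_table$comparison == cmp, , drop = FALSE]
    tab <- tab[!is.na(tab$delta) & !is.na(tab$baseline_median), , drop = FALSE]
    label <- sprintf("%s %s delta~baseline", f, cmp)
    if (nrow(tab) >= min_n) {
      r <- spearman_test(tab$baseline_median, tab$delta, label)
      scat[[label]] <- data.frame(feature = f, comparison = cmp,
                                  subject_id = tab$subject_id,
                                  baseline = tab$baseline_median,
                                  delta = tab$delta)
      r2 <- ranksum_test(tab$baseline_median, tab$post_median,
                         sprintf("%s %s pre~post", f, cmp))
    } else {
      r <- stat_row("spearman", label, NA, NA, nrow(tab))
      r2 <- stat_row("wilcoxon_ranksum", sprintf("%s %s pre~post", f, cmp),
                     NA, NA, nrow(tab))
    }
    r$family <- "delta_vs_baseline"; r2$family <- "pre_vs_post"
    rows[[length(rows) + 1]] <- r
    rows[[length(rows) + 1]] <- r2
  }

  if (!is.null(clinical)) {
    for (f in names(plan$primary)) {
      cmp <- plan$primary[[f]]
      tab <- short_table[short_table$feature == f &
                           short_table$comparison == cmp, , drop = FALSE]
      m <- merge(tab, clinical, by = "subject_id")
      m <- m[!is.na(m$baseline_median), , drop = FALSE]
      mk <- function(res) { res$family <- "clinical_factors"; res }
      if (nrow(m) >= min_n) {
        rows[[length(rows) + 1]] <- mk(spearman_test(
          m$gestational_age_days, m$baseline_median,
          sprintf("%s %s GA~baseline", f, cmp)))
        g0 <- m$baseline_median[m$fentanyl == 0]
        g1 <- m$baseline_median[m$fentanyl == 1]
        rows[[length(rows) + 1]] <- mk(if (length(g0) >= 2 && length(g1) >= 2)
          ranksum_test(g0, g1, sprintf("%s %s fentanyl~baseline", f, cmp))
          else stat_row("wilcoxon_ranksum",
                        sprintf("%s %s fentanyl~baseline", f, cmp), NA, NA,
                        nrow(m)))
        gl <- split(m$baseline_median, m$diagnosis_group)
        gl <- gl[lengths(gl) > 0]
        rows[[length(rows) + 1]] <- mk(if (length(gl) >= 2)
          suppressWarnings(kruskal_test(gl,
            sprintf("%s %s diagnosis~baseline", f, cmp)))
          else stat_row("kruskal_wallis",
                        sprintf("%s %s diagnosis~baseline", f, cmp), NA, NA,
                        nrow(m)))
      } else {
        for (tst in c("spearman", "wilcoxon_ranksum", "kruskal_wallis"))
          rows[[length(rows) + 1]] <- mk(stat_row(tst,
            sprintf("%s %s clinical (not computed)", f, cmp), NA, NA, nrow(m)))
      }
    }
  }

  stats <- do.call(rbind, rows)
  stats$family_size <- ave(seq_len(nrow(stats)), stats$family, FUN = length)
  list(stats = stats,
       scatter = if (length(scat)) do.call(rbind, scat) else NULL)
}
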