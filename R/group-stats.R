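#' Group summaries and significance tests on subject-level values
#'
#' Computes per-group n, mean and SEM (sample sd / sqrt(n)) and the percent
#' change of every group versus the reference, then applies the requested
#' omnibus or two-group test at the subject level: Welch's unpaired t-test,
#' Mann-Whitney (Wilcoxon rank sum), one-way ANOVA or Kruskal-Wallis.
#' Routine test machinery is delegated to `stats`. Post-hoc comparisons are
#' off by default; `"tukey"` (after ANOVA) and `"pairwise_wilcox"`
#' (Holm-corrected pairwise rank sums, after Kruskal-Wallis) are available.
#'
#' Both percent conventions are reported: `pct_change_vs_ref`
#' (`(ref - mean) / ref * 100`, positive = reduction) and `pct_of_ref`
#' (`mean / ref * 100`).
#'
#' @param data tibble of subject-level values.
#' @param value,group columns (tidy-eval) holding the measurement and the
#'   group label.
#' @param reference_group reference level for percent change; default the
#'   first group in factor/appearance order.
#' @param test `"welch_t"`, `"mann_whitney"`, `"anova"` or
#'   `"kruskal_wallis"`. The two-sample tests require exactly 2 groups.
#' @param posthoc `"none"` (default), `"tukey"`, `"pairwise_wilcox"`.
#' @return A `synq_group_stats`: list with `groups` tibble, `test` list
#'   (`name, statistic, p_value`), optional `posthoc` tibble. `tidy()`
#'   returns the group table, `glance()` the test.
#' @export
group_stats <- function(data, value, group, reference_group = NULL,
                        test = c("welch_t", "mann_whitney", "anova",
                                 "kruskal_wallis"),
                        posthoc = c("none", "tukey", "pairwise_wilcox")) {
  test <- match.arg(test)
  posthoc <- match.arg(posthoc)
  v <- rlang::eval_tidy(enquo(value), data)
  g <- as.factor(rlang::eval_tidy(enquo(group), data))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  ns <- table(g)
  if (any(ns < 2L)) {
    abort(sprintf("every group needs n >= 2 (got %s).",
                  paste(sprintf("%s: %d", names(ns), ns), collapse = ", ")))
  }
  reference_group <- reference_group %||% levels(g)[1]
  if (!reference_group %in% levels(g)) {
    abort(sprintf("reference group '%s' not present.", reference_group))
  }
  groups <- tibble(group = levels(g)) |>
    dplyr::mutate(
      n = unname(as.integer(ns[.data$group])),
      mean = vapply(.data$group, function(k) mean(v[g == k]), numeric(1),
                    USE.NAMES = FALSE),
      sem = vapply(.data$group, function(k) {
        sd(v[g == k]) / sqrt(sum(g == k))
      }, numeric(1), USE.NAMES = FALSE))
  ref_mean <- groups$mean[groups$group == reference_group]
  groups$pct_change_vs_ref <- percent_change(ref_mean, groups$mean)
  groups$pct_of_ref <- groups$mean / ref_mean * 100

  two <- test %in% c("welch_t", "mann_whitney")
  if (two && nlevels(g) != 2L) {
    abort(sprintf("%s requires exactly 2 groups.", test))
  }
  ht <- switch(test,
    welch_t = t.test(v ~ g, var.equal = FALSE),
    mann_whitney = wilcox.test(v ~ g, exact = FALSE),
    anova = {
      a <- stats::anova(aov(v ~ g))
      list(statistic = a$`F value`[1], p.value = a$`Pr(>F)`[1])
    },
    kruskal_wallis = kruskal.test(v ~ g))
  test_res <- list(name = test,
                   statistic = unname(ht$statistic),
                   p_value = unname(ht$p.value))
  ph <- NULL
  if (posthoc == "tukey") {
    tk <- TukeyHSD(aov(v ~ g))$g
    ph <- tibble(comparison = rownames(tk), diff = tk[, "diff"],
                 p_adj = tk[, "p adj"])
  } else if (posthoc == "pairwise_wilcox") {
    pw <- pairwise.wilcox.test(v, g, p.adjust.method = "holm",
                               exact = FALSE)$p.value
    ph <- tibble(comparison = paste(rep(rownames(pw), ncol(pw)),
                                    rep(colnames(pw), each = nrow(pw)),
                                    sep = "-"),
                 p_adj = as.vector(pw))
    ph <- ph[stats::complete.cases(ph), ]
  }
  structure(list(groups = groups, test = test_res, posthoc = ph,
                 reference_group = reference_group),
            class = "synq_group_stats")
}

#' @export
print.synq_group_stats <- function(x, ...) {
  cat(sprintf("<synq_group_stats> %s: statistic %.4g, p = %.4g (ref: %s)\n",
              x$test$name, x$test$statistic, x$test$p_value,
              x$reference_group))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.synq_group_stats <- function(x, ...) x$groups

#' @export
glance.synq_group_stats <- function(x, ...) {
  tibble(test = x$test$name, statistic = x$test$statistic,
         p.value = x$test$p_value, n_groups = nrow(x$groups),
         reference_group = x$reference_group)
}
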