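#' Paired group comparison with a normality gate
#'
#' Compares paired vectors of percent-correct scores at the group level.
#' The paired differences are first screened with a Shapiro-Wilk test; when
#' they are compatible with normality (gate p >= `gate_alpha`) a two-tailed
#' paired t-test is used, otherwise the Wilcoxon signed-rank test (with
#' zero differences dropped, per the signed-rank convention; the count is
#' recorded). All-zero differences are a degenerate case returned with
#' p = 1.
#'
#' @param pre,post Equal-length paired vectors of scores (% correct).
#' @param gate_alpha Level of the normality gate (default 0.05).
#' @return A list of class `group_comparison`: `n`, `pre_mean`, `post_mean`,
#'   `difference` (post - pre), `test_used` (`"paired-t"` or `"wilcoxon"`),
#'   `statistic`, `p_value`, `normality_p`, `zeros_dropped`.
#' @export
paired_group_test <- function(pre, post, gate_alpha = 0.05) {
  if (length(pre) != length(post))
    stop("`pre` and `post` must be paired vectors of equal length",
         call. = FALSE)
  keep <- stats::complete.cases(pre, post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  d <- post - pre
  out <- list(n = n, pre_mean = mean(pre), post_mean = mean(post),
              difference = mean(post) - mean(pre))
  if (all(d == 0)) {
    out <- c(out, list(test_used = "paired-t", statistic = 0, p_value = 1,
                       normality_p = NA_real_, zeros_dropped = n))
    return(structure(out, class = "group_comparison"))
  }
  normality_p <- tryCatch(stats::shapiro.test(d)$p.value,
                          error = function(e) 0)
  if (normality_p >= gate_alpha) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    out <- c(out, list(test_used = "paired-t",
                       statistic = unname(tt$statistic),
                       p_value = tt$p.value))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    out <- c(out, list(test_used = "wilcoxon",
                       statistic = unname(wt$statistic),
                       p_value = wt$p.value))
  }
  out$normality_p <- normality_p
  out$zeros_dropped <- sum(d == 0)
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s, n = %d: %.2f%% -> %.2f%% (diff %+.2f), stat = %.3f, p = %.3g>\n",
              x$test_used, x$n, x$pre_mean, x$post_mean, x$difference,
              x$statistic, x$p_value))
  invisible(x)
}

#' Nested-subset group analysis
#'
#' Runs the group-level pre/post comparison for the nonimplanted ear (or
#' any condition) over an ordered cascade of increasingly strict inclusion
#' criteria, for both postoperative aggregation conventions. Each row
#' reports the surviving N, the pre and post means, their difference and
#' the gated test's p-value — the layout of a standard
#' subjects-by-stringency outcome table.
#'
#' @param x A `bimodal_cohort`.
#' @param subsets Named list of [filter_criteria()] in cascade order
#'   (default [filter_presets()]).
#' @param condition Condition analysed (default `"nonimplanted"`).
#' @param methods Aggregation methods to run.
#' @param registry Test registry.
#' @param gate_alpha Normality-gate level passed to [paired_group_test()].
#' @return data.frame of class `nested_subset_table` with columns `subset`,
#'   `method`, `n`, `pre_mean`, `post_mean`, `difference`, `test_used`,
#'   `statistic`, `p_value`. Subsets with fewer than 3 comparable subjects
#'   yield a row of NAs. The per-subset exclusion logs are attached as the
#'   `"exclusions"` attribute.
#' @export
nested_subset_analysis <- function(x, subsets = filter_presets(),
                                   condition = "nonimplanted",
                                   methods = c("average", "latest"),
                                   registry = default_test_registry(),
                                   gate_alpha = 0.05) {
  rows <- list()
  logs <- list()
  for (label in names(subsets)) {
    flt <- apply_filters(x, subsets[[label]])
    logs[[label]] <- flt$exclusions
    for (mm in methods) {
      sids <- comparable_subjects(flt$cohort, condition, registry)
      if (length(sids) < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          subset = label, method = mm, n = length(sids), pre_mean = NA_real_,
          post_mean = NA_real_, difference = NA_real_,
          test_used = NA_character_, statistic = NA_real_, p_value = NA_real_)
        next
      }
      pre <- vapply(sids, function(sid)
        100 * preop_score(flt$cohort, sid, condition, registry)$p, numeric(1))
      post <- vapply(sids, function(sid)
        100 * aggregate_post(flt$cohort, sid, condition, mm, registry)$p,
        numeric(1))
      g <- paired_group_test(pre, post, gate_alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = label, method = mm, n = g$n, pre_mean = g$pre_mean,
        post_mean = g$post_mean, difference = g$difference,
        test_used = g$test_used, statistic = g$statistic,
        p_value = g$p_value)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "exclusions") <- logs
  class(out) <- c("nested_subset_table", "data.frame")
  out
}
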