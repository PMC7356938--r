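#' Classify one subject's pre/post change in one condition
#'
#' Builds the preoperative score observation and the aggregated
#' postoperative observation for the requested condition, runs the
#' critical-difference comparison, and maps the outcome to a verdict:
#' `"higher"` or `"lower"` when the change is significant, `"no_change"`
#' otherwise. A subject whose preoperative score is missing or flagged
#' could-not-test, or who has no usable postoperative datapoint (e.g. after
#' filtering), is `"not_testable"` — could-not-test scores are never coded
#' as 0%.
#'
#' @param x A `bimodal_cohort` (typically the filtered cohort).
#' @param subject_id Subject identifier.
#' @param condition One of `"implanted"`, `"nonimplanted"`, `"bilateral"`.
#' @param method Postoperative aggregation, `"average"` or `"latest"`.
#' @param registry Test registry.
#' @param cfg A [crit_diff_config()].
#' @return A list of class `subject_verdict` with `subject_id`, `condition`,
#'   `method`, `status` (`"classified"` or `"not_testable"`), `verdict`,
#'   and (when classified) `pre`, `post` and the `crit_diff_result`.
#' @export
classify_subject <- function(x, subject_id, condition = "nonimplanted",
                             method = c("average", "latest"),
                             registry = default_test_registry(),
                             cfg = crit_diff_config()) {
  method <- match.arg(method)
  out <- tryCatch({
    pre <- preop_score(x, subject_id, condition, registry)
    post <- aggregate_post(x, subject_id, condition, method, registry)
    res <- compare_scores(pre, post, cfg)
    verdict <- if (!res$significant) "no_change" else res$direction
    list(status = "classified", verdict = verdict, pre = pre, post = post,
         result = res)
  }, bimodalshift_not_testable = function(e) {
    list(status = "not_testable", verdict = "not_testable", pre = NULL,
         post = NULL, result = NULL)
  })
  structure(c(list(subject_id = subject_id, condition = condition,
                   method = method), out),
            class = "subject_verdict")
}

#' @export
print.subject_verdict <- function(x, ...) {
  if (x$status == "not_testable") {
    cat(sprintf("<%s / %s / %s: not testable>\n", x$subject_id, x$condition,
                x$method))
  } else {
    cat(sprintf("<%s / %s / %s: %.1f%% -> %.1f%%, z = %.2f, %s>\n",
                x$subject_id, x$condition, x$method, 100 * x$pre$p,
                100 * x$post$p, x$result$z, x$verdict))
  }
  invisible(x)
}

#' Classify every subject in a cohort
#'
#' Applies [classify_subject()] across subjects, conditions and
#' aggregation methods, returning a per-subject table (suitable for a
#' pre-vs-post scatterplot export) and a count summary. Verdict counts per
#' condition and method always sum to the cohort size.
#'
#' @param x A `bimodal_cohort`.
#' @param conditions Conditions to classify.
#' @param methods Aggregation methods to run.
#' @param registry Test registry.
#' @param cfg A [crit_diff_config()].
#' @return An object of class `classification_summary`: list with
#'   `per_subject` (data.frame `subject_id`, `condition`, `method`,
#'   `pre_pct`, `pre_n`, `post_pct`, `post_n`, `z`, `verdict`) and
#'   `summary` (counts of higher/lower/no_change/not_testable).
#' @export
classify_cohort <- function(x, conditions = score_conditions(),
                            methods = c("average", "latest"),
                            registry = default_test_registry(),
                            cfg = crit_diff_config()) {
  rows <- list()
  for (cc in conditions) for (mm in methods) {
    for (sid in x$subjects$subject_id) {
      v <- classify_subject(x, sid, cc, mm, registry, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cc, method = mm,
        pre_pct = if (is.null(v$pre)) NA_real_ else 100 * v$pre$p,
        pre_n = if (is.null(v$pre)) NA_integer_ else v$pre$n,
        post_pct = if (is.null(v$post)) NA_real_ else 100 * v$post$p,
        post_n = if (is.null(v$post)) NA_integer_ else v$post$n,
        z = if (is.null(v$result)) NA_real_ else v$result$z,
        verdict = v$verdict
      )
    }
  }
  per_subject <- do.call(rbind, rows)
  lvl <- c("higher", "lower", "no_change", "not_testable")
  summary <- do.call(rbind, lapply(conditions, function(cc) {
    do.call(rbind, lapply(methods, function(mm) {
      sel <- per_subject$condition == cc & per_subject$method == mm
      counts <- table(factor(per_subject$verdict[sel], levels = lvl))
      data.frame(condition = cc, method = mm,
                 higher = as.integer(counts[["higher"]]),
                 lower = as.integer(counts[["lower"]]),
                 no_change = as.integer(counts[["no_change"]]),
                 not_testable = as.integer(counts[["not_testable"]]),
                 n = as.integer(sum(counts)))
    }))
  }))
  structure(list(per_subject = per_subject, summary = summary),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("<per-subject classification>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Expected number of false-positive individual changes
#'
#' With a two-tailed test at level `alpha` applied independently to each of
#' `n_subjects` subjects, `alpha / 2 * n_subjects` subjects are expected to
#' be flagged in each direction by chance alone; the result is rounded to
#' the nearest integer (halves up). For 132 subjects at alpha 0.05 this is
#' 3 per direction.
#'
#' @param n_subjects Number of subjects tested (>= 0).
#' @param two_tailed_alpha Two-tailed significance level in (0, 1).
#' @return Non-negative integer.
#' @examples
#' expected_false_positives(132, 0.05) # 3
#' @export
expected_false_positives <- function(n_subjects, two_tailed_alpha = 0.05) {
  if (!is.numeric(n_subjects) || n_subjects < 0 || n_subjects != round(n_subjects))
    stop("`n_subjects` must be a non-negative integer", call. = FALSE)
  if (!is.numeric(two_tailed_alpha) || two_tailed_alpha <= 0 ||
      two_tailed_alpha >= 1)
    stop("`two_tailed_alpha` must lie in (0, 1)", call. = FALSE)
  as.integer(floor(two_tailed_alpha / 2 * n_subjects + 0.5))
}
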