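#' Inclusion-filter criteria
#'
#' Declarative rules for which postoperative evaluation sessions enter an
#' analysis of the nonimplanted (hearing-aid) ear:
#' * a hearing-aid verification requirement — sessions whose verification
#'   route is `"unknown"` are dropped when `require_ha_verified` is set;
#' * a cap on the change in unaided pure-tone average relative to the
#'   preoperative PTA, so that progressive hearing loss cannot masquerade
#'   as a speech-perception change. The baseline 25 dB rule is applied to
#'   the absolute difference; the stricter 20/10/5 dB rules apply to
#'   *increases* only (a threshold that improves is not grounds for
#'   exclusion there).
#'
#' @param require_ha_verified Drop sessions without evidence of correct
#'   hearing-aid function.
#' @param max_pta_change_db Cap in dB (default 25).
#' @param absolute If `TRUE` the cap applies to `|post PTA - pre PTA|`; if
#'   `FALSE` to the increase `post - pre` only.
#' @param pta_frequencies Frequencies (Hz) entering the PTA.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(require_ha_verified = FALSE,
                            max_pta_change_db = 25,
                            absolute = TRUE,
                            pta_frequencies = c(500, 1000, 2000)) {
  stopifnot(is.numeric(max_pta_change_db), max_pta_change_db >= 0)
  structure(list(require_ha_verified = isTRUE(require_ha_verified),
                 max_pta_change_db = as.numeric(max_pta_change_db),
                 absolute = isTRUE(absolute),
                 pta_frequencies = pta_frequencies),
            class = "filter_criteria")
}

#' Preset filter cascade
#'
#' The ordered subsets used for the nested group analysis: all subjects
#' (baseline 25 dB absolute PTA rule only), hearing aid verified, then PTA
#' increases capped at 20, 10 and 5 dB. Tightening down the list can only
#' shrink the surviving cohort.
#'
#' @param pta_frequencies Frequencies (Hz) entering the PTA.
#' @return Named list of [filter_criteria()] in cascade order.
#' @export
filter_presets <- function(pta_frequencies = c(500, 1000, 2000)) {
  list(
    "All subjects" = filter_criteria(FALSE, 25, TRUE, pta_frequencies),
    "HA working"   = filter_criteria(TRUE, 25, TRUE, pta_frequencies),
    "<=20 PTA"     = filter_criteria(TRUE, 20, FALSE, pta_frequencies),
    "<=10 PTA"     = filter_criteria(TRUE, 10, FALSE, pta_frequencies),
    "<=5 PTA"      = filter_criteria(TRUE, 5, FALSE, pta_frequencies)
  )
}

#' Apply inclusion filters to a cohort
#'
#' Evaluates the criteria per postoperative session (datapoint-level
#' exclusion): a session is removed when verification is required but
#' absent, or when its nonimplanted-ear PTA moved beyond the cap relative
#' to that subject's preoperative PTA. Preoperative sessions are always
#' kept. Subjects left without any postoperative session simply drop out of
#' downstream comparisons. Every removal is recorded in the exclusion log
#' with its reason.
#'
#' @param x A `bimodal_cohort`.
#' @param criteria A [filter_criteria()].
#' @return List with `cohort` (the filtered `bimodal_cohort`) and
#'   `exclusions` (data.frame `subject_id`, `session_id`, `reason`).
#' @export
apply_filters <- function(x, criteria = filter_criteria()) {
  stopifnot(inherits(x, "bimodal_cohort"), inherits(criteria, "filter_criteria"))
  ses <- x$sessions
  pre_rows <- ses[ses$phase == "pre", , drop = FALSE]
  pre_pta <- vapply(unique(pre_rows$subject_id), function(sid) {
    session_pta(pre_rows[pre_rows$subject_id == sid, , drop = FALSE][1L, ],
                criteria$pta_frequencies)
  }, numeric(1))

  drop <- logical(nrow(ses))
  reason <- character(nrow(ses))
  for (i in seq_len(nrow(ses))) {
    if (ses$phase[i] != "post") next
    if (criteria$require_ha_verified &&
        (is.na(ses$ha_verification[i]) || ses$ha_verification[i] == "unknown")) {
      drop[i] <- TRUE
      reason[i] <- "hearing aid function not verified"
      next
    }
    base <- pre_pta[[ses$subject_id[i]]]
    if (is.null(base) || is.na(base))
      stop("no preoperative PTA for subject ", ses$subject_id[i], call. = FALSE)
    delta <- session_pta(ses[i, , drop = FALSE], criteria$pta_frequencies) - base
    change <- if (criteria$absolute) abs(delta) else delta
    if (change > criteria$max_pta_change_db) {
      drop[i] <- TRUE
      reason[i] <- sprintf("PTA %s %.1f dB exceeds %.0f dB cap",
                           if (criteria$absolute) "change" else "increase",
                           delta, criteria$max_pta_change_db)
    }
  }
  exclusions <- data.frame(subject_id = ses$subject_id[drop],
                           session_id = ses$session_id[drop],
                           reason = reason[drop])
  filtered <- cohort(x$subjects, ses[!drop, , drop = FALSE], validate = FALSE)
  list(cohort = filtered, exclusions = exclusions)
}

# Subjects that still have a usable pre score and at least one usable post
# datapoint for a condition (the denominator of any pre/post comparison).
comparable_subjects <- function(x, condition = "nonimplanted",
                                registry = default_test_registry()) {
  ok <- vapply(x$subjects$subject_id, function(sid) {
    tryCatch({
      preop_score(x, sid, condition, registry)
      nrow(usable_scores(x$sessions, sid, condition, "post")) > 0L
    }, bimodalshift_not_testable = function(e) FALSE)
  }, logical(1))
  x$subjects$subject_id[ok]
}
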