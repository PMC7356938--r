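#' Speech-test registry
#'
#' Maps each test identifier to its scoring unit, items per list, and (for
#' sentence keyword tests) a conservative effective item-count override.
#' Keyword scores within a sentence are not statistically independent, so
#' sentence tests with 100+ keywords per list are treated as if they carried
#' far fewer independent items; the conventional conservative choice is an
#' effective N of 40.
#'
#' @param extra Optional data.frame of additional rows with the same columns
#'   (`test_id`, `scoring_unit`, `items_per_list`, `effective_n_override`).
#' @return data.frame registry.
#' @export
default_test_registry <- function(extra = NULL) {
  reg <- data.frame(
    test_id = c("word_w50", "word_w25", "cnc_w50", "sent_kw_cuny",
                "sent_kw_tam", "sent_kw_azbio"),
    scoring_unit = c("words", "words", "words", "keywords", "keywords",
                     "keywords"),
    items_per_list = c(50L, 25L, 50L, 102L, 120L, 142L),
    effective_n_override = c(NA_integer_, NA_integer_, NA_integer_, 40L,
                             40L, 40L)
  )
  if (!is.null(extra)) reg <- rbind(reg, extra[names(reg)])
  reg
}

#' Effective number of independent scored items
#'
#' Word tests contribute `n_lists * items_per_list` independent items;
#' sentence keyword tests use the registry's conservative override (40)
#' regardless of the nominal keyword count or number of lists.
#'
#' @param test_id Registered test identifier.
#' @param n_lists Number of lists averaged into the score (positive
#'   integer).
#' @param registry Registry data.frame (see [default_test_registry()]).
#' @return Positive integer effective N.
#' @examples
#' effective_n("word_w50", 1) # 50
#' effective_n("sent_kw_cuny", 3) # 40
#' @export
effective_n <- function(test_id, n_lists = 1L, registry = default_test_registry()) {
  i <- match(test_id, registry$test_id)
  if (is.na(i)) stop("unregistered test id: ", test_id, call. = FALSE)
  if (is.na(n_lists) || n_lists < 1 || n_lists != round(n_lists))
    stop("`n_lists` must be a positive integer", call. = FALSE)
  ov <- registry$effective_n_override[i]
  if (!is.na(ov)) return(as.integer(ov))
  as.integer(n_lists * registry$items_per_list[i])
}

# Classed signal for "this subject/condition cannot enter a comparison".
not_testable <- function(message) {
  stop(structure(class = c("bimodalshift_not_testable", "error", "condition"),
                 list(message = message, call = NULL)))
}

# Usable score rows for one subject x condition: a numeric percent and no
# could-not-test flag.
usable_scores <- function(sessions, subject_id, condition, phase) {
  pct <- paste0(condition, "_pct")
  cnt <- paste0(condition, "_cnt")
  rows <- sessions[sessions$subject_id == subject_id &
                   sessions$phase == phase, , drop = FALSE]
  if (!nrow(rows) || !pct %in% names(rows)) return(rows[0, , drop = FALSE])
  keep <- !is.na(rows[[pct]])
  if (cnt %in% names(rows)) keep <- keep & !(rows[[cnt]] %in% TRUE)
  rows[keep, , drop = FALSE]
}

#' Aggregate postoperative scores for one subject and condition
#'
#' Two aggregation conventions are supported: `"latest"` takes the
#' chronologically last usable postoperative score with its own effective N;
#' `"average"` takes the unweighted mean of the session proportions with an
#' effective N equal to the sum of the per-session effective Ns (so the
#' average of three 50-word lists is treated as a 150-item score). Ties in
#' `months_since_surgery` for "latest" are broken by file order (last row
#' wins) with a warning.
#'
#' @param x A `bimodal_cohort` (typically after [apply_filters()]).
#' @param subject_id Subject identifier.
#' @param condition One of `"implanted"`, `"nonimplanted"`, `"bilateral"`.
#' @param method `"average"` or `"latest"`.
#' @param registry Test registry.
#' @return A [score_observation()].
#' @export
aggregate_post <- function(x, subject_id, condition = "nonimplanted",
                           method = c("average", "latest"),
                           registry = default_test_registry()) {
  method <- match.arg(method)
  stopifnot(condition %in% score_conditions())
  rows <- usable_scores(x$sessions, subject_id, condition, "post")
  if (!nrow(rows))
    not_testable(sprintf("subject %s has no usable postoperative %s-ear score",
                         subject_id, condition))
  pct <- rows[[paste0(condition, "_pct")]]
  n_eff <- vapply(seq_len(nrow(rows)), function(i) {
    effective_n(rows[[paste0(condition, "_test_id")]][i],
                rows[[paste0(condition, "_n_lists")]][i], registry)
  }, integer(1))
  if (method == "latest") {
    mx <- max(rows$months_since_surgery)
    at <- which(rows$months_since_surgery == mx)
    if (length(at) > 1L)
      warning(sprintf("subject %s: tie at %g months for latest %s score; using file order",
                      subject_id, mx, condition), call. = FALSE)
    i <- at[length(at)]
    return(score_observation(pct[i] / 100, n_eff[i]))
  }
  score_observation(mean(pct) / 100, sum(n_eff))
}

# Preoperative score observation, or a not_testable signal when the score
# is absent or flagged could-not-test.
preop_score <- function(x, subject_id, condition,
                        registry = default_test_registry()) {
  rows <- usable_scores(x$sessions, subject_id, condition, "pre")
  if (!nrow(rows))
    not_testable(sprintf("subject %s has no usable preoperative %s-ear score",
                         subject_id, condition))
  if (nrow(rows) > 1L) rows <- rows[1L, , drop = FALSE]
  n_eff <- effective_n(rows[[paste0(condition, "_test_id")]][1L],
                       rows[[paste0(condition, "_n_lists")]][1L], registry)
  score_observation(rows[[paste0(condition, "_pct")]][1L] / 100, n_eff)
}
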