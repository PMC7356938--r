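#' Pearson correlation as an association result
#'
#' Product-moment correlation with a two-tailed p-value from the t
#' distribution on n - 2 degrees of freedom, returned as one tidy row.
#'
#' @param x,y Paired numeric vectors (incomplete pairs dropped).
#' @param x_label,y_label Labels recorded in the result.
#' @return One-row data.frame: `x_label`, `y_label`, `control_label`, `r`,
#'   `p_value`, `n`.
#' @export
pearson_assoc <- function(x, y, x_label = deparse1(substitute(x)),
                          y_label = deparse1(substitute(y))) {
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(x_label = x_label, y_label = y_label,
             control_label = NA_character_,
             r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single control variable:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-tailed p-value from the t distribution on n - 3 degrees of
#' freedom. Equivalent to correlating the residuals of least-squares
#' projections of `x` and `y` on the control.
#'
#' @param x,y,control Paired numeric vectors (incomplete triples dropped).
#' @param x_label,y_label,control_label Labels recorded in the result.
#' @return One-row data.frame: `x_label`, `y_label`, `control_label`, `r`,
#'   `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, control,
                                x_label = deparse1(substitute(x)),
                                y_label = deparse1(substitute(y)),
                                control_label = deparse1(substitute(control))) {
  keep <- stats::complete.cases(x, y, control)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  z <- as.numeric(control[keep])
  n <- length(x)
  if (n < 4) stop("at least 4 complete triples are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("partial correlation undefined: the control is collinear with an input",
         call. = FALSE)
  pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pr <- max(-1, min(1, pr))
  df <- n - 3
  p <- if (abs(pr) >= 1) 0 else {
    tval <- pr * sqrt(df / (1 - pr^2))
    2 * stats::pt(-abs(tval), df)
  }
  data.frame(x_label = x_label, y_label = y_label,
             control_label = control_label, r = pr, p_value = p, n = n)
}

#' Per-subject change variables for the association analysis
#'
#' Builds, per subject, the quantities the association screen correlates:
#' the nonimplanted-ear score change (post - pre, percentage points), the
#' change in unaided PTA of that ear (dB), the average postoperative
#' implanted-ear score (%), the postoperative nonimplanted-ear score (%),
#' and the implanted-ear advantage (implanted minus nonimplanted
#' postoperative score, percentage points). Only datapoints with evidence
#' of correct hearing-aid function are used: the hearing-aid-verified
#' filter is applied before any variable is computed, and the exclusion
#' log is attached to the result.
#'
#' @param x A `bimodal_cohort`.
#' @param method Postoperative aggregation for the nonimplanted-ear change
#'   (`"average"` or `"latest"`); the implanted-ear score is always the
#'   postoperative average.
#' @param registry Test registry.
#' @param pta_frequencies Frequencies (Hz) for the PTA.
#' @return data.frame (one row per subject with complete constituents):
#'   `subject_id`, `ha_pre_pct`, `ha_post_pct`, `ha_change`, `pta_pre`,
#'   `pta_post`, `pta_change`, `ci_post_pct`, `advantage`. Omitted subjects
#'   are listed in the `"omitted"` attribute, filter removals in
#'   `"exclusions"`.
#' @export
build_change_variables <- function(x, method = c("average", "latest"),
                                   registry = default_test_registry(),
                                   pta_frequencies = c(500, 1000, 2000)) {
  method <- match.arg(method)
  flt <- apply_filters(x, filter_criteria(require_ha_verified = TRUE,
                                          max_pta_change_db = 25,
                                          absolute = TRUE,
                                          pta_frequencies = pta_frequencies))
  ch <- flt$cohort
  rows <- list(); omitted <- list()
  for (sid in ch$subjects$subject_id) {
    row <- tryCatch({
      ha_pre <- preop_score(ch, sid, "nonimplanted", registry)
      ha_post <- aggregate_post(ch, sid, "nonimplanted", method, registry)
      ci_post <- aggregate_post(ch, sid, "implanted", "average", registry)
      pre_ses <- ch$sessions[ch$sessions$subject_id == sid &
                             ch$sessions$phase == "pre", , drop = FALSE]
      post_ses <- ch$sessions[ch$sessions$subject_id == sid &
                              ch$sessions$phase == "post", , drop = FALSE]
      pta_pre <- session_pta(pre_ses[1L, ], pta_frequencies)
      post_ptas <- vapply(seq_len(nrow(post_ses)), function(i)
        session_pta(post_ses[i, , drop = FALSE], pta_frequencies), numeric(1))
      pta_post <- if (method == "latest")
        post_ptas[which.max(post_ses$months_since_surgery)]
      else mean(post_ptas)
      data.frame(subject_id = sid,
                 ha_pre_pct = 100 * ha_pre$p,
                 ha_post_pct = 100 * ha_post$p,
                 ha_change = 100 * (ha_post$p - ha_pre$p),
                 pta_pre = pta_pre, pta_post = pta_post,
                 pta_change = pta_post - pta_pre,
                 ci_post_pct = 100 * ci_post$p,
                 advantage = 100 * (ci_post$p - ha_post$p))
    }, bimodalshift_not_testable = function(e) {
      omitted[[length(omitted) + 1L]] <<- data.frame(subject_id = sid,
                                                     reason = conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character())
  attr(out, "omitted") <- if (length(omitted)) do.call(rbind, omitted) else
    data.frame(subject_id = character(), reason = character())
  attr(out, "exclusions") <- flt$exclusions
  out
}

#' Association screen for the nonimplanted-ear score change
#'
#' Correlates the nonimplanted-ear score change with the three variables of
#' interest — PTA change in the same ear, the implanted-ear advantage, and
#' the average postoperative implanted-ear score — and recomputes the
#' advantage correlation after partialling out the postoperative
#' hearing-aid score. Sign convention: change = post - pre, so a drop is
#' negative.
#'
#' @param x A `bimodal_cohort`, or a change-variable table from
#'   [build_change_variables()].
#' @param method Aggregation method when `x` is a cohort.
#' @param registry Test registry.
#' @return data.frame of association rows (`x_label`, `y_label`,
#'   `control_label`, `r`, `p_value`, `n`).
#' @export
association_analysis <- function(x, method = "average",
                                 registry = default_test_registry()) {
  cv <- if (inherits(x, "bimodal_cohort"))
    build_change_variables(x, method, registry) else x
  rbind(
    pearson_assoc(cv$pta_change, cv$ha_change, "pta_change", "ha_change"),
    pearson_assoc(cv$advantage, cv$ha_change, "advantage", "ha_change"),
    pearson_assoc(cv$ci_post_pct, cv$ha_change, "ci_post_pct", "ha_change"),
    partial_correlation(cv$advantage, cv$ha_change, cv$ha_post_pct,
                        "advantage", "ha_change", "ha_post_pct")
  )
}

#' Demographic correlation screen
#'
#' Correlates the nonimplanted-ear score change with each preoperative
#' demographic variable. Binary variables are coded 0/1 (point-biserial):
#' gender female = 1, implanted side right = 1, round-window approach = 1,
#' preoperative hearing-aid use in the implanted ear TRUE = 1. Variables
#' that are entirely missing or constant are skipped and logged. The
#' preoperative unaided PTA of the nonimplanted ear is included from the
#' change-variable table.
#'
#' @param x A `bimodal_cohort`.
#' @param method Aggregation for the score change.
#' @param registry Test registry.
#' @return data.frame of association rows; skipped variables are recorded
#'   in the `"skipped"` attribute.
#' @export
demographic_screen <- function(x, method = "average",
                               registry = default_test_registry()) {
  cv <- build_change_variables(x, method, registry)
  sub <- x$subjects[match(cv$subject_id, x$subjects$subject_id), , drop = FALSE]
  code01 <- function(v, one) as.numeric(v == one)
  vars <- list(
    age_at_implant = sub$age_at_implant,
    age_at_moderate_loss = sub$age_at_moderate_loss,
    age_at_profound_loss = sub$age_at_profound_loss,
    preop_pta_nonimplanted = cv$pta_pre,
    education_years = sub$education_years,
    gender_female = code01(sub$gender, "female"),
    implanted_side_right = code01(sub$implanted_side, "right"),
    approach_round_window = code01(sub$surgical_approach, "round_window"),
    preop_ha_in_implanted_ear = as.numeric(sub$preop_ha_in_implanted_ear)
  )
  rows <- list(); skipped <- list()
  for (nm in names(vars)) {
    v <- vars[[nm]]
    res <- tryCatch(pearson_assoc(v, cv$ha_change, nm, "ha_change"),
                    error = function(e) {
                      skipped[[length(skipped) + 1L]] <<-
                        data.frame(variable = nm, reason = conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_label = character())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(variable = character(), reason = character())
  out
}
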