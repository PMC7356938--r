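#' Longitudinal bimodal cohort
#'
#' Container for a longitudinal speech-audiometry cohort: one `subjects`
#' table (demographics and device metadata, one row per subject) and one
#' `sessions` table (one row per evaluation session, holding the phase,
#' time since surgery, unaided audiometric thresholds for the nonimplanted
#' ear, the hearing-aid verification route, and percent-correct speech
#' scores for the three listening conditions).
#'
#' Audiogram thresholds live in wide columns named `thr_<freq>hz` (dB HL).
#' Each condition `implanted`, `nonimplanted`, `bilateral` contributes four
#' session columns: `<cond>_test_id`, `<cond>_pct` (percent correct, 0-100),
#' `<cond>_cnt` (logical "could not test" flag) and `<cond>_n_lists`.
#'
#' @param subjects data.frame of subject-level fields (see
#'   [cohort_column_dictionary()]).
#' @param sessions data.frame of session-level fields.
#' @param validate If `TRUE` (default), run [validate_cohort()] and stop on
#'   any issue.
#' @return An object of class `bimodal_cohort`.
#' @export
cohort <- function(subjects, sessions, validate = TRUE) {
  obj <- structure(list(subjects = as.data.frame(subjects),
                        sessions = as.data.frame(sessions)),
                   class = "bimodal_cohort")
  if (validate) {
    issues <- validate_cohort(obj)
    if (nrow(issues)) {
      msg <- paste(sprintf("row %s, %s [%s]: %s", issues$row, issues$field,
                           issues$table, issues$problem), collapse = "\n  ")
      stop("cohort validation failed:\n  ", msg, call. = FALSE)
    }
  }
  obj
}

#' @export
print.bimodal_cohort <- function(x, ...) {
  n_pre <- sum(x$sessions$phase == "pre")
  n_post <- sum(x$sessions$phase == "post")
  cat(sprintf("<bimodal cohort: %d subjects, %d sessions (%d pre, %d post)>\n",
              nrow(x$subjects), nrow(x$sessions), n_pre, n_post))
  invisible(x)
}

score_conditions <- function() c("implanted", "nonimplanted", "bilateral")

ha_verification_levels <- function() {
  c("in_ear", "aided_unaided_thresholds", "aided_unaided_speech",
    "clinician_report", "unknown")
}

#' Column dictionary for the cohort CSV schemas
#'
#' Machine-readable description of the two delimited-text schemas the
#' readers and writers use: one entry per column with the table it belongs
#' to, its type, units and allowed values.
#'
#' @return A data.frame with columns `table`, `column`, `type`, `units`,
#'   `allowed`, `required`.
#' @export
cohort_column_dictionary <- function() {
  sub_cols <- data.frame(
    table = "subjects",
    column = c("subject_id", "site_id", "gender", "age_at_implant",
               "age_at_moderate_loss", "age_at_profound_loss", "etiology",
               "device_brand", "electrode", "processor", "implanted_side",
               "surgical_approach", "preop_ha_in_implanted_ear",
               "education_years"),
    type = c("character", "character", "character", "numeric", "numeric",
             "numeric", "character", "character", "character", "character",
             "character", "character", "logical", "numeric"),
    units = c("", "", "", "years", "years", "years", "", "", "", "", "", "",
              "", "years"),
    allowed = c("", "", "male|female", ">=0", ">=0 or NA", ">=0 or NA", "",
                "", "", "", "left|right", "cochleostomy|round_window",
                "TRUE|FALSE", ">=0 or NA"),
    required = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  base_cols <- data.frame(
    table = "sessions",
    column = c("subject_id", "session_id", "phase", "months_since_surgery",
               "ha_verification"),
    type = c("character", "character", "character", "numeric", "character"),
    units = c("", "", "", "months", ""),
    allowed = c("", "", "pre|post", ">=0 (0 for pre)",
                paste(ha_verification_levels(), collapse = "|")),
    required = TRUE
  )
  thr_cols <- data.frame(
    table = "sessions",
    column = paste0("thr_", c(250, 500, 1000, 2000, 4000), "hz"),
    type = "numeric", units = "dB HL", allowed = "[-10, 130] or NA",
    required = FALSE
  )
  cond_cols <- do.call(rbind, lapply(score_conditions(), function(cc) {
    data.frame(
      table = "sessions",
      column = paste0(cc, c("_test_id", "_pct", "_cnt", "_n_lists")),
      type = c("character", "numeric", "logical", "integer"),
      units = c("", "% correct", "", "lists"),
      allowed = c("registered test id", "[0, 100] or NA", "TRUE|FALSE",
                  ">=1"),
      required = FALSE
    )
  }))
  rbind(sub_cols, base_cols, thr_cols, cond_cols)
}

#' Validate a cohort against the schema
#'
#' Checks mandatory columns, value ranges, duplicate keys, the
#' pre-phase/time consistency rule, and the exclusive percent-correct /
#' could-not-test contract. Issues are collected, not thrown, so a caller
#' can report all of them at once with row numbers.
#'
#' @param x A `bimodal_cohort` (or a list with `subjects` and `sessions`).
#' @return data.frame with columns `table`, `row`, `field`, `problem`; zero
#'   rows when the cohort is valid.
#' @export
validate_cohort <- function(x) {
  issues <- list()
  note <- function(table, row, field, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      table = table, row = row, field = field, problem = problem)
  }
  sub <- x$subjects; ses <- x$sessions

  dict <- cohort_column_dictionary()
  for (tb in c("subjects", "sessions")) {
    df <- if (tb == "subjects") sub else ses
    need <- dict$column[dict$table == tb & dict$required]
    for (col in setdiff(need, names(df)))
      note(tb, NA_integer_, col, "mandatory column missing")
  }
  if (length(issues)) return(do.call(rbind, issues))

  if (anyDuplicated(sub$subject_id))
    for (i in which(duplicated(sub$subject_id)))
      note("subjects", i, "subject_id", "duplicate subject id")
  bad_age <- which(!is.na(sub$age_at_implant) & sub$age_at_implant < 0)
  for (i in bad_age) note("subjects", i, "age_at_implant", "negative age")
  if (all(c("age_at_moderate_loss", "age_at_profound_loss") %in% names(sub))) {
    bad <- which(!is.na(sub$age_at_moderate_loss) &
                 !is.na(sub$age_at_profound_loss) &
                 sub$age_at_moderate_loss > sub$age_at_profound_loss)
    for (i in bad)
      note("subjects", i, "age_at_moderate_loss",
           "moderate-loss age exceeds profound-loss age")
  }

  key <- paste(ses$subject_id, ses$session_id)
  for (i in which(duplicated(key)))
    note("sessions", i, "session_id", "duplicate (subject, session) key")
  for (i in which(!ses$subject_id %in% sub$subject_id))
    note("sessions", i, "subject_id", "unknown subject id")
  for (i in which(!ses$phase %in% c("pre", "post")))
    note("sessions", i, "phase", "phase must be 'pre' or 'post'")
  for (i in which(ses$phase == "pre" & ses$months_since_surgery != 0))
    note("sessions", i, "months_since_surgery",
         "pre-phase session must have months_since_surgery = 0")
  for (i in which(!is.na(ses$months_since_surgery) &
                  ses$months_since_surgery < 0))
    note("sessions", i, "months_since_surgery", "negative time")
  for (i in which(!ses$ha_verification %in% ha_verification_levels()))
    note("sessions", i, "ha_verification", "unknown verification route")

  for (col in grep("^thr_[0-9]+hz$", names(ses), value = TRUE)) {
    v <- ses[[col]]
    for (i in which(!is.na(v) & (v < -10 | v > 130)))
      note("sessions", i, col, "threshold outside [-10, 130] dB HL")
  }
  for (cc in score_conditions()) {
    pct <- ses[[paste0(cc, "_pct")]]
    cnt <- ses[[paste0(cc, "_cnt")]]
    nl <- ses[[paste0(cc, "_n_lists")]]
    if (!is.null(pct))
      for (i in which(!is.na(pct) & (pct < 0 | pct > 100)))
        note("sessions", i, paste0(cc, "_pct"),
             "percent correct outside [0, 100]")
    if (!is.null(pct) && !is.null(cnt))
      for (i in which(!is.na(pct) & !is.na(cnt) & cnt))
        note("sessions", i, paste0(cc, "_cnt"),
             "both a score and a could-not-test flag are present")
    if (!is.null(nl))
      for (i in which(!is.na(nl) & (nl < 1 | nl != round(nl))))
        note("sessions", i, paste0(cc, "_n_lists"),
             "number of lists must be a positive integer")
  }

  if (!length(issues))
    return(data.frame(table = character(), row = integer(),
                      field = character(), problem = character()))
  do.call(rbind, issues)
}

#' Read a cohort from its two CSV files
#'
#' @param subjects_path,sessions_path Paths to the subjects and sessions
#'   CSV files (schemas per [cohort_column_dictionary()]).
#' @param validate Stop with a collected report when the files violate the
#'   schema (default `TRUE`).
#' @return A `bimodal_cohort`.
#' @export
read_cohort <- function(subjects_path, sessions_path, validate = TRUE) {
  sub <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  ses <- utils::read.csv(sessions_path, stringsAsFactors = FALSE)
  # all-NA logical columns come back as logical already; coerce flags anyway
  for (col in intersect(c("preop_ha_in_implanted_ear"), names(sub)))
    sub[[col]] <- as.logical(sub[[col]])
  for (col in intersect(paste0(score_conditions(), "_cnt"), names(ses)))
    ses[[col]] <- as.logical(ses[[col]])
  cohort(sub, ses, validate = validate)
}

#' Write a cohort to its two CSV files
#'
#' Writing then reading reproduces the cohort (up to numeric print
#' precision).
#'
#' @param x A `bimodal_cohort`.
#' @param subjects_path,sessions_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(x, subjects_path, sessions_path) {
  stopifnot(inherits(x, "bimodal_cohort"))
  utils::write.csv(x$subjects, subjects_path, row.names = FALSE, na = "")
  utils::write.csv(x$sessions, sessions_path, row.names = FALSE, na = "")
  invisible(c(subjects = subjects_path, sessions = sessions_path))
}

#' Pure-tone average
#'
#' Arithmetic mean of unaided audiometric thresholds at the requested
#' frequencies. All requested frequencies must be present: a missing
#' threshold raises an error rather than being silently imputed.
#'
#' @param audiogram Named numeric vector of thresholds (dB HL), names being
#'   frequencies in Hz (e.g. `c("500" = 60, "1000" = 70, "2000" = 80)`).
#' @param frequencies Frequencies (Hz) entering the average; the default
#'   500/1000/2000 Hz three-frequency PTA is the common clinical convention.
#' @return PTA in dB HL.
#' @examples
#' pure_tone_average(c("500" = 60, "1000" = 70, "2000" = 80)) # 70
#' @export
pure_tone_average <- function(audiogram, frequencies = c(500, 1000, 2000)) {
  want <- as.character(frequencies)
  missing <- want[!want %in% names(audiogram) | is.na(audiogram[want])]
  if (length(missing))
    stop("missing threshold at ", paste(missing, collapse = ", "), " Hz",
         call. = FALSE)
  mean(as.numeric(audiogram[want]))
}

# PTA of one sessions-table row from its wide thr_<freq>hz columns.
session_pta <- function(row, frequencies = c(500, 1000, 2000)) {
  cols <- paste0("thr_", frequencies, "hz")
  absent <- cols[!cols %in% names(row)]
  if (length(absent))
    stop("audiogram columns missing: ", paste(absent, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(row[1L, cols])
  names(v) <- as.character(frequencies)
  pure_tone_average(v, frequencies)
}
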