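# Fixtures are built in code: a minimal hand-written cohort exercising the
# aggregation, filtering and classification paths, and a brute-force
# enumeration oracle written independently of the package's vectorised
# implementation.

tiny_subjects <- function() {
  data.frame(
    subject_id = c("A", "B"),
    site_id = c("site_1", "site_2"),
    gender = c("male", "female"),
    age_at_implant = c(60, 55),
    age_at_moderate_loss = c(30, NA),
    age_at_profound_loss = c(50, NA),
    etiology = c("unknown", "genetic"),
    device_brand = c("Cochlear", "Med-El"),
    electrode = c("perimodiolar", "standard"),
    processor = c("gen2", "gen1"),
    implanted_side = c("left", "right"),
    surgical_approach = c("cochleostomy", "round_window"),
    preop_ha_in_implanted_ear = c(TRUE, FALSE),
    education_years = c(16, 12)
  )
}

# Subject A: pre at 44%, three post word_w50 sessions at 40/50/60%,
# stable audiogram. Subject B: pre implanted-ear score "could not test",
# one post session with a 12 dB PTA increase, verification unknown.
tiny_sessions <- function() {
  thr <- function(pta) {
    data.frame(thr_250hz = pta - 15, thr_500hz = pta - 5, thr_1000hz = pta,
               thr_2000hz = pta + 5, thr_4000hz = pta + 15)
  }
  base <- function(sid, ses, phase, months, verif, pta) {
    cbind(data.frame(subject_id = sid, session_id = ses, phase = phase,
                     months_since_surgery = months, ha_verification = verif),
          thr(pta))
  }
  scores <- function(df, ni_pct, ci_pct = 20, bi_pct = 50, ci_cnt = FALSE,
                     test = "word_w50", n_lists = 1L) {
    df$implanted_test_id <- test
    df$implanted_pct <- if (ci_cnt) NA_real_ else ci_pct
    df$implanted_cnt <- ci_cnt
    df$implanted_n_lists <- n_lists
    df$nonimplanted_test_id <- test
    df$nonimplanted_pct <- ni_pct
    df$nonimplanted_cnt <- FALSE
    df$nonimplanted_n_lists <- n_lists
    df$bilateral_test_id <- test
    df$bilateral_pct <- bi_pct
    df$bilateral_cnt <- FALSE
    df$bilateral_n_lists <- n_lists
    df
  }
  rbind(
    scores(base("A", "E0", "pre", 0, "aided_unaided_thresholds", 70), 44),
    scores(base("A", "E1", "post", 1, "aided_unaided_thresholds", 70), 40,
           ci_pct = 70, bi_pct = 72),
    scores(base("A", "E2", "post", 12, "aided_unaided_thresholds", 70), 50,
           ci_pct = 74, bi_pct = 78),
    scores(base("A", "E3", "post", 24, "aided_unaided_thresholds", 70), 60,
           ci_pct = 80, bi_pct = 84),
    scores(base("B", "E0", "pre", 0, "unknown", 65), 30, ci_cnt = TRUE),
    scores(base("B", "E1", "post", 6, "unknown", 77), 24, ci_pct = 66,
           bi_pct = 70)
  )
}

tiny_cohort <- function() cohort(tiny_subjects(), tiny_sessions())

# Independent brute-force oracle: explicit loops and choose()-based
# binomial probabilities, no shared code with exact_abs_diff_z().
brute_force_z <- function(p1, n1, p2, n2) {
  m <- 0; m2 <- 0
  for (k1 in 0:n1) {
    for (k2 in 0:n2) {
      w <- choose(n1, k1) * p1^k1 * (1 - p1)^(n1 - k1) *
        choose(n2, k2) * p2^k2 * (1 - p2)^(n2 - k2)
      d <- abs(k1 / n1 - k2 / n2)
      m <- m + w * d
      m2 <- m2 + w * d^2
    }
  }
  v <- m2 - m^2
  if (v <= 0) {
    if (m == 0) return(0)
    return(Inf)
  }
  m / sqrt(v)
}
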