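test_that("a minimal cohort validates and summarises", {
  co <- tiny_cohort()
  expect_s3_class(co, "bimodal_cohort")
  expect_equal(nrow(validate_cohort(co)), 0)
  expect_equal(sum(co$sessions$phase == "pre"), 2)
  expect_equal(sum(co$sessions$phase == "post"), 4)
})

test_that("validation collects out-of-range and inconsistent rows", {
  ses <- tiny_sessions()
  ses$nonimplanted_pct[2] <- 101
  ses$months_since_surgery[1] <- 3   # pre phase must be at time zero
  ses$thr_500hz[3] <- 200
  issues <- validate_cohort(list(subjects = tiny_subjects(), sessions = ses))
  expect_true(any(issues$row == 2 & issues$field == "nonimplanted_pct"))
  expect_true(any(issues$row == 1 & issues$field == "months_since_surgery"))
  expect_true(any(issues$row == 3 & issues$field == "thr_500hz"))
  expect_error(cohort(tiny_subjects(), ses), "validation failed")
})

test_that("duplicate keys and missing mandatory columns are reported", {
  ses <- tiny_sessions()
  ses$session_id[2] <- "E0"
  issues <- validate_cohort(list(subjects = tiny_subjects(), sessions = ses))
  expect_true(any(issues$problem == "duplicate (subject, session) key"))
  ses2 <- tiny_sessions()
  ses2$phase <- NULL
  issues2 <- validate_cohort(list(subjects = tiny_subjects(), sessions = ses2))
  expect_true(any(issues2$field == "phase" &
                  issues2$problem == "mandatory column missing"))
})

test_that("cohorts round-trip through their CSV files", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "subjects.csv"); ep <- file.path(dir, "sessions.csv")
  co <- tiny_cohort()
  write_cohort(co, sp, ep)
  back <- read_cohort(sp, ep)
  expect_equal(back$subjects, co$subjects)
  expect_equal(back$sessions, co$sessions)

  syn <- generate_cohort(sim_config(n_subjects = 12, seed = 7))
  write_cohort(syn, sp, ep)
  back2 <- read_cohort(sp, ep)
  expect_equal(back2$subjects, syn$subjects, tolerance = 1e-12)
  expect_equal(back2$sessions, syn$sessions, tolerance = 1e-12)
})

test_that("pure-tone average is the mean at requested frequencies only", {
  expect_equal(pure_tone_average(c("500" = 60, "1000" = 70, "2000" = 80)), 70)
  expect_equal(pure_tone_average(c("500" = 55, "1000" = 55, "2000" = 55)), 55)
  expect_error(pure_tone_average(c("500" = 60, "2000" = 80)), "1000")
  expect_equal(pure_tone_average(c("250" = 30, "500" = 60, "1000" = 70,
                                   "2000" = 80, "4000" = 95),
                                 c(500, 1000, 2000, 4000)), 76.25)
})

test_that("effective N follows the word-count rule with a sentence override", {
  expect_equal(effective_n("word_w50", 1), 50L)
  expect_equal(effective_n("word_w25", 2), 50L)
  expect_equal(effective_n("sent_kw_cuny", 1), 40L)
  expect_equal(effective_n("sent_kw_cuny", 3), 40L)
  expect_equal(effective_n("sent_kw_tam", 1), 40L)
  expect_error(effective_n("no_such_test", 1), "unregistered")
})

test_that("postoperative aggregation follows the average and latest rules", {
  co <- tiny_cohort()
  avg <- aggregate_post(co, "A", "nonimplanted", "average")
  expect_equal(avg$p, 0.50)       # mean of 40, 50, 60%
  expect_equal(avg$n, 150L)       # three 50-word lists pooled
  lat <- aggregate_post(co, "A", "nonimplanted", "latest")
  expect_equal(lat$p, 0.60)       # month-24 session
  expect_equal(lat$n, 50L)
  one <- aggregate_post(co, "B", "nonimplanted", "latest")
  expect_equal(one$p, 0.24)
  # average of identical scores equals that score
  ses <- tiny_sessions()
  ses$nonimplanted_pct[ses$subject_id == "A" & ses$phase == "post"] <- 34
  co2 <- cohort(tiny_subjects(), ses)
  expect_equal(aggregate_post(co2, "A", "nonimplanted", "average")$p, 0.34)
})

test_that("latest-score ties are broken by file order with a warning", {
  ses <- tiny_sessions()
  ses$months_since_surgery[ses$subject_id == "A" & ses$phase == "post"] <-
    c(1, 24, 24)
  co <- cohort(tiny_subjects(), ses)
  expect_warning(lat <- aggregate_post(co, "A", "nonimplanted", "latest"),
                 "tie")
  expect_equal(lat$p, 0.60)  # last row wins
})

test_that("a subject with no usable postoperative score is not testable", {
  ses <- tiny_sessions()
  ses$nonimplanted_pct[ses$subject_id == "B" & ses$phase == "post"] <- NA
  co <- cohort(tiny_subjects(), ses)
  expect_error(aggregate_post(co, "B", "nonimplanted", "average"),
               class = "bimodalshift_not_testable")
})

test_that("filters drop unverified sessions and apply the PTA boundary", {
  co <- tiny_cohort()
  # subject B: verification unknown, 12 dB PTA increase
  verif <- apply_filters(co, filter_criteria(require_ha_verified = TRUE))
  expect_true("B" %in% verif$exclusions$subject_id)
  expect_match(verif$exclusions$reason[1], "not verified")

  at20 <- apply_filters(co, filter_criteria(FALSE, 20, absolute = FALSE))
  expect_false("B" %in% at20$exclusions$subject_id)  # 12 <= 20: kept
  at10 <- apply_filters(co, filter_criteria(FALSE, 10, absolute = FALSE))
  expect_true("B" %in% at10$exclusions$subject_id)   # 12 > 10: dropped

  # an exact-boundary change is kept (strictly-greater rule)
  at12 <- apply_filters(co, filter_criteria(FALSE, 12, absolute = FALSE))
  expect_equal(nrow(at12$exclusions), 0)
})

test_that("the absolute baseline rule also drops large PTA improvements", {
  ses <- tiny_sessions()
  sel <- ses$subject_id == "B" & ses$phase == "post"
  for (cc in grep("^thr_", names(ses), value = TRUE))
    ses[sel, cc] <- ses[sel, cc] - 42   # 30 dB improvement vs pre
  co <- cohort(tiny_subjects(), ses)
  abs25 <- apply_filters(co, filter_criteria(FALSE, 25, absolute = TRUE))
  expect_true("B" %in% abs25$exclusions$subject_id)
  inc25 <- apply_filters(co, filter_criteria(FALSE, 25, absolute = FALSE))
  expect_equal(nrow(inc25$exclusions), 0)
})

test_that("tightening the cascade never increases the surviving count", {
  co <- generate_cohort(sim_config(n_subjects = 60, seed = 21))
  ns <- vapply(filter_presets(), function(crit) {
    flt <- apply_filters(co, crit)
    length(comparable_subjects(flt$cohort, "nonimplanted"))
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
})
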