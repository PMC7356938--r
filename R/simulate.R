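#' Configuration for the synthetic cohort generator
#'
#' Full parameterization of the synthetic multicenter cohort. Defaults
#' emulate a 132-subject bimodal cochlear-implant cohort: 1-11
#' postoperative sessions averaging about 2.5, mean follow-up around 37
#' months, preoperative hearing-aid-ear scores averaging about 44%, a mean
#' nonimplanted-ear PTA progression of roughly 2.5 dB with a heavy right
#' tail (so a few subjects exceed a 20 dB increase), preoperative
#' could-not-test rates of 29/132 (implanted ear) and 41/132 (bilateral),
#' and a hearing-aid verification mix of 81/132 threshold-verified, 41/132
#' clinician-report and 10/132 unknown.
#'
#' The nonimplanted-ear decline model is linear in the implanted-ear
#' advantage, in percentage points:
#' `change_i = beta0 + beta1 * advantage_i + eps_i`, `eps ~ N(0, sd)`,
#' where `advantage_i` is the subject's true postoperative implanted-ear
#' score minus their preoperative hearing-aid-ear score (x100). The default
#' `beta1 < 0` makes larger advantages produce larger drops, yielding a
#' mean change of roughly -7.5 points over the default advantage
#' distribution.
#'
#' @param n_subjects Number of subjects.
#' @param seed Optional integer seed for full reproducibility.
#' @param session_lambda Postoperative session count is
#'   `1 + Poisson(session_lambda)` truncated at `max_sessions`; the default
#'   1.5 gives a mean close to 2.5.
#' @param max_sessions Upper truncation for the session count.
#' @param followup_shape,followup_mean_months Gamma law for the last
#'   follow-up time (months), truncated to
#'   `[followup_min_months, followup_max_months]`.
#' @param followup_min_months,followup_max_months Truncation bounds.
#' @param preop_ha_score_mean,preop_ha_score_sd Truncated-normal law on
#'   `[0, 1]` for the true preoperative nonimplanted-ear proportion.
#' @param preop_ci_score_mean,preop_ci_score_sd Same for the ear to be
#'   implanted (low).
#' @param postop_ci_score_mean,postop_ci_score_sd Same for the true
#'   postoperative implanted-ear proportion (high).
#' @param bilateral_bonus Additive bonus (proportion) of the bilateral
#'   condition over the better single ear.
#' @param decline_beta0 Intercept of the decline model (percentage points).
#' @param decline_beta_advantage Slope per percentage point of
#'   implanted-ear advantage.
#' @param decline_sd SD of the decline residual (percentage points).
#' @param pta_progression_prob Probability a subject has any PTA
#'   progression (zero-inflation).
#' @param pta_progression_mean_db Mean of the exponential progression law
#'   (dB at the last follow-up), given progression occurs.
#' @param preop_pta_mean,preop_pta_sd Truncated-normal law (dB HL, on
#'   `[25, 110]`) for the preoperative nonimplanted-ear PTA.
#' @param p_cnt_implanted,p_cnt_bilateral Probabilities that the
#'   preoperative implanted-ear / bilateral score is "could not test".
#' @param verification_probs Named probabilities over the hearing-aid
#'   verification routes (must sum to 1).
#' @param test_mix Named probabilities over registered test ids (per
#'   subject; must sum to 1).
#' @param n_lists_probs Named probabilities over list counts per session.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 132L,
                       seed = NULL,
                       session_lambda = 1.5,
                       max_sessions = 11L,
                       followup_shape = 1.6,
                       followup_mean_months = 37,
                       followup_min_months = 1,
                       followup_max_months = 132,
                       preop_ha_score_mean = 0.44,
                       preop_ha_score_sd = 0.20,
                       preop_ci_score_mean = 0.08,
                       preop_ci_score_sd = 0.10,
                       postop_ci_score_mean = 0.65,
                       postop_ci_score_sd = 0.18,
                       bilateral_bonus = 0.05,
                       decline_beta0 = -2.5,
                       decline_beta_advantage = -0.18,
                       decline_sd = 8,
                       pta_progression_prob = 0.5,
                       pta_progression_mean_db = 5.5,
                       preop_pta_mean = 72,
                       preop_pta_sd = 12,
                       p_cnt_implanted = 29 / 132,
                       p_cnt_bilateral = 41 / 132,
                       verification_probs = c(aided_unaided_thresholds = 81 / 132,
                                              clinician_report = 41 / 132,
                                              unknown = 10 / 132),
                       test_mix = c(word_w50 = 0.60, word_w25 = 0.15,
                                    sent_kw_cuny = 0.25),
                       n_lists_probs = c("1" = 0.8, "2" = 0.2)) {
  cfg <- as.list(environment())
  probs <- c(p_cnt_implanted, p_cnt_bilateral, pta_progression_prob,
             verification_probs, test_mix, n_lists_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(verification_probs) - 1) > 1e-8)
    stop("`verification_probs` must sum to 1", call. = FALSE)
  if (abs(sum(test_mix) - 1) > 1e-8)
    stop("`test_mix` must sum to 1", call. = FALSE)
  if (abs(sum(n_lists_probs) - 1) > 1e-8)
    stop("`n_lists_probs` must sum to 1", call. = FALSE)
  sds <- c(preop_ha_score_sd, preop_ci_score_sd, postop_ci_score_sd,
           decline_sd, preop_pta_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative",
                         call. = FALSE)
  if (n_subjects < 1 || session_lambda < 0 || followup_shape <= 0 ||
      followup_mean_months <= 0 || pta_progression_mean_db < 0)
    stop("infeasible simulation configuration", call. = FALSE)
  if (!all(names(verification_probs) %in% ha_verification_levels()))
    stop("unknown verification route in `verification_probs`", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Null simulation preset
#'
#' A cohort with no true change in the nonimplanted ear and no PTA
#' progression: the decline model's intercept, slope and residual SD are
#' all zero, so any pre/post differences are pure binomial measurement
#' noise. Used for calibration checks.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  sim_config(decline_beta0 = 0, decline_beta_advantage = 0, decline_sd = 0,
             pta_progression_prob = 0, ...)
}

#' Study-scale simulation preset
#'
#' The default [sim_config()] under its documented, study-scale marginal
#' targets: 132 subjects, mean 2.5 sessions, 37-month mean follow-up, 44%
#' mean preoperative hearing-aid-ear score, ~2.5 dB mean PTA progression,
#' 29/132 and 41/132 preoperative could-not-test rates, and the
#' 81/41/10 verification mix.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_like_config <- function(...) sim_config(...)

# Truncated-normal draws by inverse-CDF; exact for any bounds.
rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(upper, pmax(lower, rep(mean, n))))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic bimodal cohort
#'
#' Draws per-subject true scores and the nonimplanted-ear decline from the
#' configured laws, then generates observed percent-correct scores as
#' binomial draws at each session's effective item count divided by that
#' count — i.e. the measurement noise is exactly the noise model the
#' critical-difference procedure assumes. Audiograms shift over time
#' according to the PTA-progression law (a subject's total progression is
#' reached at the last follow-up and accrues proportionally to time).
#' Could-not-test flags and the verification mix are applied at the stated
#' rates. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `bimodal_cohort`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  registry <- default_test_registry()

  etiologies <- c("unknown", "genetic", "noise", "otosclerosis", "menieres",
                  "meningitis", "progressive", "ssnhl", "other")
  eti_probs <- c(52, 19, 14, 13, 4, 4, 4, 4, 18) / 132
  brands <- c("AB", "Med-El", "Cochlear", "Neurelec")
  brand_probs <- c(21, 25, 76, 10) / 132

  age_implant <- rtnorm(n, 56.8, 16, 15, 89)
  age_profound <- pmax(0, age_implant - stats::rexp(n, 1 / 8))
  age_moderate <- pmax(0, age_profound - stats::rexp(n, 1 / 15))
  age_moderate[stats::runif(n) < 0.10] <- NA
  age_profound[stats::runif(n) < 0.10] <- NA

  subjects <- data.frame(
    subject_id = ids,
    site_id = sample(paste0("site_", 1:8), n, replace = TRUE,
                     prob = c(0.40, rep(0.60 / 7, 7))),
    gender = sample(c("male", "female"), n, replace = TRUE,
                    prob = c(68, 64) / 132),
    age_at_implant = age_implant,
    age_at_moderate_loss = age_moderate,
    age_at_profound_loss = age_profound,
    etiology = sample(etiologies, n, replace = TRUE, prob = eti_probs),
    device_brand = sample(brands, n, replace = TRUE, prob = brand_probs),
    electrode = sample(c("standard", "perimodiolar", "lateral_wall"), n,
                       replace = TRUE),
    processor = sample(c("gen1", "gen2", "gen3"), n, replace = TRUE),
    implanted_side = sample(c("left", "right"), n, replace = TRUE),
    surgical_approach = sample(c("cochleostomy", "round_window"), n,
                               replace = TRUE, prob = c(0.6, 0.4)),
    preop_ha_in_implanted_ear = stats::runif(n) < 0.35,
    education_years = rtnorm(n, 14, 3, 6, 22)
  )

  verification <- sample(names(cfg$verification_probs), n, replace = TRUE,
                         prob = cfg$verification_probs)
  test_id <- sample(names(cfg$test_mix), n, replace = TRUE,
                    prob = cfg$test_mix)

  # true (latent) proportions
  ha_pre <- rtnorm(n, cfg$preop_ha_score_mean, cfg$preop_ha_score_sd, 0, 1)
  ci_pre <- rtnorm(n, cfg$preop_ci_score_mean, cfg$preop_ci_score_sd, 0, 1)
  ci_post <- rtnorm(n, cfg$postop_ci_score_mean, cfg$postop_ci_score_sd, 0, 1)
  advantage <- 100 * (ci_post - ha_pre)
  change <- cfg$decline_beta0 + cfg$decline_beta_advantage * advantage +
    stats::rnorm(n, 0, cfg$decline_sd)
  ha_post <- pmin(1, pmax(0, ha_pre + change / 100))
  bil_pre <- pmin(1, pmax(ha_pre, ci_pre) + cfg$bilateral_bonus)
  bil_post <- pmin(1, pmax(ha_post, ci_post) + cfg$bilateral_bonus)

  # audiograms: offsets give a gently sloping loss around the PTA
  freqs <- c(250, 500, 1000, 2000, 4000)
  offsets <- c(-15, -5, 0, 5, 15)
  pta_pre <- rtnorm(n, cfg$preop_pta_mean, cfg$preop_pta_sd, 25, 110)
  progression <- ifelse(stats::runif(n) < cfg$pta_progression_prob,
                        stats::rexp(n, 1 / max(cfg$pta_progression_mean_db,
                                               1e-12)),
                        0)
  if (cfg$pta_progression_mean_db == 0) progression[] <- 0

  n_post <- pmin(1L + stats::rpois(n, cfg$session_lambda),
                 as.integer(cfg$max_sessions))
  followup <- pmin(pmax(stats::rgamma(n, shape = cfg$followup_shape,
                                      scale = cfg$followup_mean_months /
                                        cfg$followup_shape),
                        cfg$followup_min_months),
                   cfg$followup_max_months)

  cnt_ci <- stats::runif(n) < cfg$p_cnt_implanted
  cnt_bil <- stats::runif(n) < cfg$p_cnt_bilateral

  session_rows <- vector("list", n)
  for (i in seq_len(n)) {
    months <- if (n_post[i] == 1L) followup[i] else
      c(sort(stats::runif(n_post[i] - 1L, 0.5, followup[i] * 0.98)),
        followup[i])
    months <- round(months, 2)
    phases <- c("pre", rep("post", n_post[i]))
    all_months <- c(0, months)
    k <- length(phases)

    thr <- matrix(NA_real_, k, length(freqs))
    for (s in seq_len(k)) {
      shift <- if (phases[s] == "pre") 0 else
        progression[i] * all_months[s] / followup[i]
      thr[s, ] <- pmin(130, pmax(-10, pta_pre[i] + offsets + shift))
    }
    colnames(thr) <- paste0("thr_", freqs, "hz")

    draw_pct <- function(p, n_lists) {
      ne <- effective_n(test_id[i], n_lists, registry)
      100 * stats::rbinom(1L, ne, p) / ne
    }
    nl <- as.integer(sample(names(cfg$n_lists_probs), k, replace = TRUE,
                            prob = cfg$n_lists_probs))
    truth <- list(
      implanted = c(ci_pre[i], rep(ci_post[i], n_post[i])),
      nonimplanted = c(ha_pre[i], rep(ha_post[i], n_post[i])),
      bilateral = c(bil_pre[i], rep(bil_post[i], n_post[i]))
    )
    df <- data.frame(subject_id = ids[i],
                     session_id = sprintf("E%02d", seq_len(k) - 1L),
                     phase = phases, months_since_surgery = all_months,
                     ha_verification = verification[i])
    df <- cbind(df, as.data.frame(thr))
    for (cc in score_conditions()) {
      pct <- vapply(seq_len(k), function(s) draw_pct(truth[[cc]][s], nl[s]),
                    numeric(1))
      cnt <- rep(FALSE, k)
      if (cc == "implanted" && cnt_ci[i]) cnt[1L] <- TRUE
      if (cc == "bilateral" && cnt_bil[i]) cnt[1L] <- TRUE
      pct[cnt] <- NA_real_
      df[[paste0(cc, "_test_id")]] <- test_id[i]
      df[[paste0(cc, "_pct")]] <- pct
      df[[paste0(cc, "_cnt")]] <- cnt
      df[[paste0(cc, "_n_lists")]] <- nl
    }
    session_rows[[i]] <- df
  }
  sessions <- do.call(rbind, session_rows)
  rownames(sessions) <- NULL
  cohort(subjects, sessions, validate = FALSE)
}
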