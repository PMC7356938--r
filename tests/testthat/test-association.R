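test_that("pearson association matches closed-form and handles edges", {
  expect_equal(pearson_assoc(1:10, 1:10)$r, 1)
  expect_equal(pearson_assoc(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(1)
  x <- rnorm(15); y <- 0.4 * x + rnorm(15)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_assoc(x, y)
  expect_equal(res$r, r_manual, tolerance = 1e-12)
  tval <- r_manual * sqrt((15 - 2) / (1 - r_manual^2))
  expect_equal(res$p_value, 2 * pt(-abs(tval), 13), tolerance = 1e-12)
  expect_error(pearson_assoc(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_assoc(1:2, 1:2), "at least 3")
})

test_that("pearson is invariant to affine rescaling", {
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- pearson_assoc(x, y)$r
  expect_equal(pearson_assoc(3 * x - 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_assoc(x, -2 * y + 100)$r, -r0, tolerance = 1e-12)
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    oracle <- cor(rx, ry)
    res <- partial_correlation(x, y, z)
    expect_equal(res$r, oracle, tolerance = 1e-10)
    # and the p-value uses n - 3 degrees of freedom
    tval <- oracle * sqrt((n - 3) / (1 - oracle^2))
    expect_equal(res$p_value, 2 * pt(-abs(tval), n - 3), tolerance = 1e-10)
  }
})

test_that("an uncorrelated control leaves the correlation almost unchanged", {
  set.seed(4)
  n <- 2000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  plain <- pearson_assoc(x, y)$r
  partial <- partial_correlation(x, y, z)$r
  expect_equal(partial, plain, tolerance = 0.05)
})

test_that("a collinear control is refused", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  expect_error(partial_correlation(x, y, y), "collinear")
  expect_error(partial_correlation(x, y, 2 * x + 1), "collinear")
  expect_error(partial_correlation(x[1:3], y[1:3], rnorm(3)), "at least 4")
})

test_that("change variables are built on the verified subset only", {
  co <- generate_cohort(sim_config(n_subjects = 50, seed = 9))
  cv <- build_change_variables(co)
  expect_true(all(c("ha_change", "pta_change", "ci_post_pct", "advantage",
                    "ha_post_pct") %in% names(cv)))
  expect_equal(cv$ha_change, cv$ha_post_pct - cv$ha_pre_pct, tolerance = 1e-9)
  expect_equal(cv$advantage, cv$ci_post_pct - cv$ha_post_pct,
               tolerance = 1e-9)
  # no subject whose sessions were all unverified can appear
  unverified <- co$sessions$subject_id[co$sessions$ha_verification == "unknown"]
  expect_false(any(cv$subject_id %in% unverified))
  excl <- attr(cv, "exclusions")
  expect_true(all(unique(unverified) %in% excl$subject_id))
})

test_that("an advantage-linked decline is recovered with the built-in sign", {
  co <- generate_cohort(sim_config(n_subjects = 132, seed = 12,
                                   decline_beta0 = 0,
                                   decline_beta_advantage = -0.25,
                                   decline_sd = 5))
  res <- association_analysis(co)
  adv <- res[res$x_label == "advantage" & is.na(res$control_label), ]
  expect_lt(adv$r, -0.2)   # larger advantage, larger drop
  expect_lt(adv$p_value, 0.01)
})

test_that("the demographic screen detects an injected linear effect", {
  co <- generate_cohort(null_config(n_subjects = 120, seed = 13))
  # inject an age-dependent decline into the postoperative scores
  age <- co$subjects$age_at_implant[match(co$sessions$subject_id,
                                          co$subjects$subject_id)]
  post <- co$sessions$phase == "post"
  co$sessions$nonimplanted_pct[post] <- pmin(100, pmax(0,
    co$sessions$nonimplanted_pct[post] - 0.5 * (age[post] - 40)))
  scr <- demographic_screen(co)
  agerow <- scr[scr$x_label == "age_at_implant", ]
  expect_lt(agerow$r, -0.3)      # older subjects decline more by construction
  expect_lt(agerow$p_value, 0.01)
  expect_true(all(abs(scr$r) <= 1))
  # a constant binary variable is skipped, not fatal
  co$subjects$implanted_side <- "left"
  scr2 <- demographic_screen(co)
  expect_false("implanted_side_right" %in% scr2$x_label)
  expect_true("implanted_side_right" %in% attr(scr2, "skipped")$variable)
})
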