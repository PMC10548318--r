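# Mixed models, GAMM smooths, adherence logistic regression, BH-FDR,
# and the recovery-report machinery.

test_that("BH q-values match the hand-rolled step-up on examples and
          random vectors", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust("a"), "numeric")
  set.seed(3)
  for (r in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- fdr_adjust(p)
    expect_equal(q, bf_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("an intercept-only balanced fit recovers the grand mean", {
  set.seed(4)
  d <- data.frame(user_id = rep(sprintf("u%02d", 1:10), each = 10),
                  y = rnorm(100, 3, 1))
  fit <- fit_linear_mixed(d, model_spec("y", group = "user"))
  expect_lt(abs(fit$terms$estimate[1] - mean(d$y)), 1e-6)
  expect_true(fit$converged)
})

test_that("specs referencing absent or degenerate columns fail by name", {
  co <- simulate_cohort(sim_config(n_users = 20, seed = 5))
  ft <- build_feature_table(co$sessions, co$users)
  expect_error(
    fit_linear_mixed(ft, model_spec("outcome_mood",
                                    predictors = "not_a_column")),
    "not_a_column")
  ft$flat <- 1
  expect_error(
    fit_linear_mixed(ft, model_spec("outcome_mood", predictors = "flat")),
    "flat")
  ft$dup <- ft$session_count_raw
  expect_error(
    fit_linear_mixed(ft, model_spec(
      "outcome_mood", predictors = c("session_count_raw", "dup"))),
    "dup")
})

test_that("complete separation is flagged, not fatal", {
  d <- data.frame(adherent = rep(c(TRUE, FALSE), each = 25),
                  x = c(rnorm(25, 10), rnorm(25, -10)))
  fit <- fit_adherence_logit(
    d, model_spec("adherent", predictors = "x", family = "binomial"))
  expect_true(fit$separation)
  expect_s3_class(fit$terms, "tbl_df")
})

test_that("the adherence model recovers an injected odds ratio of 2", {
  ad <- simulate_adherence_cohort(2000, or_days_4_7 = 2, seed = 11)
  fit <- fit_adherence_logit(
    ad, model_spec("adherent",
                   predictors = c("days_per_week_f", "length_f",
                                  "time_of_day_f", "age_z"),
                   family = "binomial"))
  or <- fit$terms$odds_ratio[fit$terms$term == "days_per_week_f4-7"]
  expect_gt(or, 1.6)
  expect_lt(or, 2.5)
  expect_false(fit$separation)
})

test_that("BH keeps the global-null rejection rate near its nominal level", {
  clean <- vapply(1:100, function(r) {
    ad <- simulate_adherence_cohort(400, seed = 6000 + r,
                                    null_model = TRUE)
    fit <- fit_adherence_logit(
      ad, model_spec("adherent",
                     predictors = c("days_per_week_f", "length_f",
                                    "time_of_day_f", "age_z"),
                     family = "binomial"))
    q <- fit$terms$q_value[fit$terms$term != "(Intercept)"]
    all(q >= 0.05)
  }, logical(1))
  # nominal no-rejection rate is 1 - alpha = 0.95; allow Monte Carlo error
  expect_gte(mean(clean), 0.90)
})

test_that("linear and smooth fits agree when the truth is linear", {
  cfg <- sim_config(n_users = 150, mean_sessions_per_user = 20,
                    session_effect = 0.015, seed = 7)
  co <- simulate_cohort(cfg)
  ft <- build_feature_table(co$sessions, co$users)
  lin <- fit_linear_mixed(
    ft, model_spec("outcome_mood", predictors = "session_count_raw",
                   covariates = "baseline_mood", group = "user"))
  sm <- fit_nonlinear_mixed(
    ft, model_spec("outcome_mood", covariates = "baseline_mood",
                   smooths = list(list(var = "session_count_raw"))),
    cutoff_quantile = 1)
  beta <- lin$terms$estimate[lin$terms$term == "session_count_raw"]
  g <- sm$smooths
  lin_curve <- beta * g$x
  offset <- mean(g$fit - lin_curve)  # smooths are centered
  dev <- abs(g$fit - (lin_curve + offset))
  expect_true(all(dev <= 1.96 * g$se + 0.02))
})

test_that("zero-noise zero-effect data produce a flat smooth", {
  cfg <- sim_config(n_users = 30, mean_sessions_per_user = 15,
                    session_effect = 0, noise_sd = 0, baseline_sd = 0,
                    seed = 8)
  co <- simulate_cohort(cfg)
  ft <- build_feature_table(co$sessions, co$users)
  sm <- fit_nonlinear_mixed(
    ft, model_spec("outcome_mood",
                   smooths = list(list(var = "session_count_raw"))),
    include_user_re = FALSE, cutoff_quantile = 1)
  expect_lt(max(abs(sm$smooths$fit)), 1e-6)
})

test_that("dropping sparse by-levels warns and keeps supported levels", {
  co <- simulate_cohort(sim_config(n_users = 100, seed = 9))
  ft <- build_feature_table(co$sessions, co$users)
  # make one level artificially rare
  ft$days_per_week_f[ft$days_per_week_f == "4-7"][-(1:5)] <- NA
  ft <- ft[!is.na(ft$days_per_week_f), ]
  expect_warning(
    fit_nonlinear_mixed(
      ft, model_spec("outcome_mood",
                     smooths = list(list(var = "session_count_raw",
                                         by = "days_per_week_f"))),
      include_user_re = FALSE, min_level_n = 30),
    "insufficient support")
})

test_that("an irrelevant covariate shifts the dose estimate by less than
          its standard error", {
  co <- simulate_cohort(sim_config(n_users = 300, session_effect = 0.01,
                                   seed = 10))
  ft <- build_feature_table(co$sessions, co$users)
  set.seed(99)
  ft$junk <- rnorm(nrow(ft))
  base <- fit_linear_mixed(
    ft, model_spec("outcome_mood", predictors = "session_count_raw",
                   covariates = "baseline_mood", group = "user"))
  plus <- fit_linear_mixed(
    ft, model_spec("outcome_mood", predictors = "session_count_raw",
                   covariates = c("baseline_mood", "junk"), group = "user"))
  b0 <- base$terms[base$terms$term == "session_count_raw", ]
  b1 <- plus$terms[plus$terms$term == "session_count_raw", ]
  expect_lt(abs(b1$estimate - b0$estimate), b0$se)
})

test_that("continent-nested intercepts fit and report both variance
          components", {
  co <- simulate_cohort(sim_config(n_users = 120, seed = 12))
  ft <- build_feature_table(co$sessions, co$users)
  fit <- fit_linear_mixed(
    ft, model_spec("outcome_mood", predictors = "session_count_raw",
                   covariates = "baseline_mood", group = "continent_user"))
  expect_gte(nrow(fit$ranef_var), 2)
  expect_true(all(fit$terms$conf_low <= fit$terms$estimate &
                    fit$terms$estimate <= fit$terms$conf_high))
  expect_true(all(fit$terms$q_value >= fit$terms$p_value - 1e-12))
})

test_that("under a null dose effect the CI covers zero at its nominal
          rate", {
  spec <- model_spec("outcome_mood", predictors = "session_count_raw",
                     covariates = "baseline_mood", group = "user")
  covered <- vapply(1:100, function(r) {
    cfg <- sim_config(n_users = 500, mean_sessions_per_user = 10,
                      session_effect = 0, seed = 40000 + r)
    co <- simulate_cohort(cfg)
    ft <- build_feature_table(co$sessions, co$users)
    fit <- fit_linear_mixed(ft, spec)
    row <- fit$terms[fit$terms$term == "session_count_raw", ]
    row$conf_low <= 0 && 0 <= row$conf_high
  }, logical(1))
  # nominal 95%; the bound leaves room for Monte Carlo error
  expect_gte(mean(covered), 0.90)
})

test_that("recovery reports summarize coverage, bias, and RMSE", {
  truths <- c(theta = 2)
  perfect <- tibble::tibble(parameter = "theta", estimate = 2,
                            conf_low = 1.5, conf_high = 2.5)[rep(1, 25), ]
  rep1 <- recovery_report(truths, perfect)
  expect_equal(rep1$coverage, 1)
  expect_equal(rep1$bias, 0)

  offset <- perfect
  offset$estimate <- 2.3
  rep2 <- recovery_report(truths, offset)
  expect_equal(rep2$bias, 0.3)
  expect_equal(rep2$rmse, 0.3)

  expect_error(recovery_report(truths, perfect[1:5, ]), "replicates")
  expect_error(recovery_report(truths,
                               dplyr::mutate(perfect, parameter = "other")),
               "other")
})
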