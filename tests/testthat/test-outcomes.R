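# Equanimity (rolling mood SD), resilience (sessions to recovery), and
# adherence labelling.

test_that("rolling SD uses the sample (n-1) formula", {
  eq <- equanimity_series(c(3, 3, 3, 3, 4))
  expect_true(all(is.na(eq$raw_sd[1:4])))
  expect_equal(eq$raw_sd[5], sd(c(3, 3, 3, 3, 4)))
  expect_equal(eq$raw_sd[5], 0.4472136, tolerance = 1e-6)
  expect_error(equanimity_series(c(3, 3, 3), window = 1), "window")
  # oracle equivalence on random streams
  for (r in 1:50) {
    m <- sample(1:5, sample(3:30, 1), replace = TRUE)
    expect_equal(equanimity_series(m)$raw_sd, bf_roll_sd(m))
  }
})

test_that("normalization maps minimum SD to 5 and maximum to 1", {
  set.seed(1)
  m <- sample(1:5, 200, replace = TRUE)
  eq <- equanimity_series(m)
  def <- !is.na(eq$raw_sd)
  expect_equal(eq$equanimity[def][which.min(eq$raw_sd[def])], 5)
  expect_equal(eq$equanimity[def][which.max(eq$raw_sd[def])], 1)
  expect_true(all(eq$equanimity[def] >= 1 & eq$equanimity[def] <= 5))
  # strictly decreasing in the window SD
  o <- order(eq$raw_sd[def])
  expect_true(all(diff(eq$equanimity[def][o]) <= 0))
})

test_that("a perfectly stable user sits at the scale maximum", {
  s <- dplyr::bind_rows(
    stream_from_days(0:9, rep(3, 10), user = "steady"),
    stream_from_days(0:9, c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5), user = "labile")
  )
  eq <- equanimity_table(s, scope = "global")
  steady <- eq$equanimity[eq$user_id == "steady"]
  expect_true(all(steady[!is.na(steady)] == 5))
})

test_that("halving latent noise raises group mean equanimity", {
  mk <- function(noise, seed, prefix) {
    cfg <- sim_config(n_users = 200, mean_sessions_per_user = 15,
                      noise_sd = noise, seed = seed)
    co <- simulate_cohort(cfg)
    co$sessions$user_id <- paste0(prefix, co$sessions$user_id)
    co$sessions
  }
  pooled <- dplyr::bind_rows(mk(1, 11, "ctrl_"), mk(0.5, 12, "calm_"))
  eq <- equanimity_table(pooled, scope = "global")
  per_user <- eq %>%
    filter(!is.na(equanimity)) %>%
    group_by(user_id) %>%
    summarise(eqm = mean(equanimity), .groups = "drop") %>%
    mutate(group = ifelse(grepl("^calm_", user_id), "calm", "ctrl"))
  tt <- t.test(eqm ~ group, data = per_user)
  expect_gt(mean(per_user$eqm[per_user$group == "calm"]),
            mean(per_user$eqm[per_user$group == "ctrl"]))
  expect_lt(tt$p.value, 0.01)
})

test_that("a drop below the trailing-week mean opens one event and the
          counter runs to recovery", {
  s <- stream_from_days(0:5, c(4, 4, 4, 3, 3, 4))
  ev <- resilience_events(s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$reference_mood, 4)
  expect_equal(ev$drop_pos, 4)
  expect_equal(ev$sessions_to_recovery, 2)
  expect_false(ev$censored)
})

test_that("an open event at end-of-stream is censored", {
  s <- stream_from_days(0:3, c(4, 4, 4, 3))
  ev <- resilience_events(s)
  expect_equal(nrow(ev), 1)
  expect_true(ev$censored)
  expect_true(is.na(ev$sessions_to_recovery))
})

test_that("an injected dip creates one event with counter equal to the dip
          duration", {
  moods <- rep(4, 30)
  moods[10:12] <- 3  # three-session dip
  ev <- resilience_events(stream_from_days(0:29, moods))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$drop_pos, 10)
  expect_equal(ev$sessions_to_recovery, 3)
  expect_false(ev$censored)
})

test_that("resilience events match the brute-force scanner on random
          streams", {
  for (r in 1:150) {
    s <- random_stream(sample(3:40, 1), seed = 400 + r)
    got <- resilience_events(s)
    days <- as.integer(as.Date(s$timestamp, tz = "UTC"))
    want <- bf_resilience(days, s$mood)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$drop_pos, want$drop_pos)
      expect_equal(got$reference_mood, want$reference_mood)
      expect_equal(got$sessions_to_recovery, want$sessions_to_recovery)
      expect_equal(got$censored, want$censored)
    }
  }
})

test_that("non-censored recovery counters satisfy the event invariants", {
  co <- simulate_cohort(sim_config(n_users = 60, seed = 13))
  ev <- resilience_events(co$sessions)
  done <- ev[!ev$censored, ]
  expect_true(all(done$sessions_to_recovery >= 1))
  # at the drop, mood sits at least 1 point below the frozen reference
  moods <- co$sessions %>%
    group_by(user_id) %>%
    mutate(.pos = dplyr::row_number()) %>%
    ungroup()
  j <- dplyr::left_join(ev, moods, by = c("user_id", drop_pos = ".pos"))
  expect_true(all(j$mood <= j$reference_mood - 1))
})

test_that("adherence eligibility, labels, and the threshold contract", {
  s <- dplyr::bind_rows(
    stream_from_days(0:28, rep(3, 29), user = "u29"),
    stream_from_days(0:29, rep(3, 30), user = "u30"),
    stream_from_days(0:148, rep(3, 149), user = "u149"),
    stream_from_days(0:149, rep(3, 150), user = "u150")
  )
  ad <- adherence_dataset(s, users_for(s), first_n = 30, threshold = 150)
  expect_false("u29" %in% ad$user_id)
  expect_equal(attr(ad, "n_excluded"), 1)
  lab <- setNames(ad$adherent, ad$user_id)
  expect_false(lab[["u30"]])
  expect_false(lab[["u149"]])
  expect_true(lab[["u150"]])
  expect_error(adherence_dataset(s, users_for(s), first_n = 30,
                                 threshold = 30), "threshold")
})

test_that("a cohort of uniform long streams has adherer fraction 1", {
  s <- dplyr::bind_rows(lapply(1:5, function(u)
    stream_from_days(0:199, rep(3, 200), user = paste0("u", u))))
  ad <- adherence_dataset(s, users_for(s), first_n = 30, threshold = 150)
  expect_equal(attr(ad, "adherer_fraction"), 1)
})

test_that("adherence features use only the first N sessions", {
  # identical first 30 sessions, wildly different later behaviour
  early <- stream_from_days(0:29, rep(3, 30), user = "a")
  late_active <- dplyr::bind_rows(
    early,
    stream_from_days(30:199, rep(5, 170), user = "a"))
  late_active_b <- late_active
  late_active_b$user_id <- "b"
  just_early <- early
  just_early$user_id <- "b"
  combined <- dplyr::bind_rows(late_active, just_early)
  d1 <- adherence_dataset(combined, users_for(combined), first_n = 30,
                          threshold = 150)
  feat_cols <- c("baseline_mood", "mean_days_per_week", "ratio_at_n",
                 "mean_length", "n_types", "dominant_time_of_day")
  expect_equal(as.list(d1[d1$user_id == "a", feat_cols]),
               as.list(d1[d1$user_id == "b", feat_cols]))
  expect_true(d1$adherent[d1$user_id == "a"])
  expect_false(d1$adherent[d1$user_id == "b"])
})
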