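# Synthetic EMA session-stream generator.
#
# Mood is generated from a latent-Gaussian process thresholded at fixed
# global cutpoints: latent = baseline + session_effect * (index - 1) +
# consistency_effect * trailing days/week + nonlinear_profile(index) + noise,
# and the ordinal check-in is 1 + (number of cutpoints below the latent
# value). Churn is an absorbing per-session dropout, so per-user session
# counts are geometric with mean 1/churn_hazard (up to the cap).

# category lists used for content labels; marginals approximate the
# observed composition of a large digital-meditation user base
.continents <- c(
  "Africa", "Asia", "Australia and Oceania", "Europe",
  "North America", "South America"
)
.continent_p <- c(0.015, 0.038, 0.094, 0.219, 0.601, 0.033)

.practice_types <- c(
  "Alternative", "Body scan", "Breathing meditation", "Compassion meditation",
  "Contemplation", "Guided imagery", "Loving-kindness (metta)", "MBCT or MBSR",
  "Mindfulness meditation", "Positive affirmations", "Relaxation meditation",
  "Vipassana"
)
.practice_type_p <- c(0.524, 0.039, 0.065, 0.018, 0.027, 0.094, 0.008, 0.006,
                      0.148, 0.046, 0.013, 0.012)

.worldviews <- c("Buddhism", "Christianity", "Hinduism", "Islam", "Judaism",
                 "Modernism", "Niches", "Other", "Taoism")
.worldview_p <- c(0.070, 0.008, 0.001, 0.001, 0.001, 0.239, 0.114, 0.565,
                  0.001)

.orientations <- c("Niches", "Positivity based", "Problem focused",
                   "Techniques")
.orientation_p <- c(0.256, 0.301, 0.319, 0.124)

.attribution_tags <- c("Exercise", "Family", "Finances", "Food or diet",
                       "Friends", "Health", "Relationships", "Sleep",
                       "Spirituality", "Study", "Travel", "Work")

.reason_names <- c("anxiety", "stress", "sadness", "wellbeing")
.reason_p <- c(0.684, 0.653, 0.367, 0.632)

.experience_names <- c("none", "apps", "web_course", "local_class",
                       "mentoring", "retreats")
.experience_p <- c(0.195, 0.700, 0.236, 0.280, 0.143, 0.140)

# content labels removed before analysis (children / sleep meditations)
.excluded_types <- c("Sleep meditation", "Children's meditation")

#' Configuration for the synthetic session-stream generator
#'
#' Collects and validates every parameter of the latent-threshold mood
#' simulator. All randomness downstream flows from `seed`: the user table,
#' the session table, and any auxiliary cohort use fixed offsets of this
#' root seed, so each stage is reproducible in isolation.
#'
#' @param n_users number of users to simulate (>= 1).
#' @param mean_sessions_per_user target mean sessions per user; sets the
#'   churn hazard to `1 / mean_sessions_per_user` unless `churn_hazard`
#'   is given explicitly.
#' @param session_effect latent-mood units gained per completed session
#'   (the true linear dose-response slope).
#' @param consistency_effect latent-mood units per extra distinct day
#'   meditated in the trailing 7 days (inclusive of the current day).
#' @param nonlinear_profile optional tabulated dose-response: a data frame
#'   with columns `session_index` and `offset` (latent units). Values
#'   between tabulated points are linearly interpolated; beyond the table
#'   the last offset is carried forward (plateau). See
#'   [saturating_profile()].
#' @param noise_sd within-user latent noise SD (>= 0).
#' @param baseline_sd SD of the per-user baseline latent mood.
#' @param churn_hazard per-session probability of permanent dropout in
#'   `[0, 1]`; overrides `mean_sessions_per_user` when supplied. A hazard
#'   of 0 means users always reach `max_sessions`.
#' @param max_sessions cap on sessions per user (`Inf` allowed).
#' @param gap_prob success probability of the geometric inter-session gap
#'   distribution on `1..gap_max` days. The default (0.28, max 14) puts
#'   about 90% of gaps at 7 days or less.
#' @param gap_max largest possible inter-session gap in days.
#' @param returning_users if `TRUE`, a fraction of gaps is drawn uniformly
#'   from 8-30 days to create many multi-practice-period streams.
#' @param ordinal_cutpoints four strictly ascending latent thresholds
#'   mapping latent mood to the 1-5 ordinal scale.
#' @param age_mean,age_sd parameters of the (untruncated) normal age
#'   distribution; ages are sampled truncated to `>= 18` years.
#' @param p_focus named probabilities for the attentional-focus label,
#'   in the order interoceptive, exteroceptive, other.
#' @param include_excluded_content if `TRUE`, a fraction `p_excluded` of
#'   sessions is labelled as sleep or children content so that the
#'   content filter has something to remove.
#' @param p_excluded probability a session carries excluded content when
#'   `include_excluded_content` is `TRUE`.
#' @param seed integer root seed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_users = 100,
                       mean_sessions_per_user = 20,
                       session_effect = 0,
                       consistency_effect = 0,
                       nonlinear_profile = NULL,
                       noise_sd = 1,
                       baseline_sd = 0.5,
                       churn_hazard = NULL,
                       max_sessions = 300,
                       gap_prob = 0.28,
                       gap_max = 14,
                       returning_users = FALSE,
                       ordinal_cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                       age_mean = 37.5,
                       age_sd = 12.6,
                       p_focus = c(interoceptive = 0.45,
                                   exteroceptive = 0.35,
                                   other = 0.20),
                       include_excluded_content = FALSE,
                       p_excluded = 0.05,
                       seed = 1L) {
  if (!is.numeric(n_users) || length(n_users) != 1 || n_users < 1)
    abort_config("n_users", "must be a count >= 1")
  if (!is.numeric(mean_sessions_per_user) || mean_sessions_per_user < 1)
    abort_config("mean_sessions_per_user", "must be a count >= 1")
  if (is.null(churn_hazard)) churn_hazard <- 1 / mean_sessions_per_user
  if (!is.numeric(churn_hazard) || churn_hazard < 0 || churn_hazard > 1)
    abort_config("churn_hazard", "must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_config("noise_sd", "must be >= 0")
  if (!is.numeric(baseline_sd) || baseline_sd < 0)
    abort_config("baseline_sd", "must be >= 0")
  if (!is.numeric(max_sessions) || max_sessions < 1)
    abort_config("max_sessions", "must be a count >= 1 (Inf allowed)")
  if (!is.numeric(gap_prob) || gap_prob <= 0 || gap_prob >= 1)
    abort_config("gap_prob", "must lie in (0, 1)")
  if (!is.numeric(gap_max) || gap_max < 1)
    abort_config("gap_max", "must be >= 1")
  if (length(ordinal_cutpoints) != 4 ||
      any(diff(ordinal_cutpoints) <= 0))
    abort_config("ordinal_cutpoints",
                 "must be 4 strictly ascending thresholds")
  if (!is.null(nonlinear_profile)) {
    if (!is.data.frame(nonlinear_profile) ||
        !all(c("session_index", "offset") %in% names(nonlinear_profile)))
      abort_config("nonlinear_profile",
                   "must have columns session_index and offset")
  }
  if (length(p_focus) != 3 || any(p_focus < 0) || sum(p_focus) <= 0)
    abort_config("p_focus", "must be 3 non-negative probabilities")
  if (!is.numeric(p_excluded) || p_excluded < 0 || p_excluded > 1)
    abort_config("p_excluded", "must lie in [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort_config("seed", "must be a single integer")

  structure(
    list(
      n_users = as.integer(n_users),
      mean_sessions_per_user = mean_sessions_per_user,
      session_effect = session_effect,
      consistency_effect = consistency_effect,
      nonlinear_profile = nonlinear_profile,
      noise_sd = noise_sd,
      baseline_sd = baseline_sd,
      churn_hazard = churn_hazard,
      max_sessions = max_sessions,
      gap_prob = gap_prob,
      gap_max = gap_max,
      returning_users = isTRUE(returning_users),
      ordinal_cutpoints = as.numeric(ordinal_cutpoints),
      age_mean = age_mean,
      age_sd = age_sd,
      p_focus = p_focus / sum(p_focus),
      include_excluded_content = isTRUE(include_excluded_content),
      p_excluded = p_excluded,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  users: %d  churn hazard: %.4g  cap: %s\n",
              x$n_users, x$churn_hazard, format(x$max_sessions)))
  cat(sprintf("  session effect: %g  consistency effect: %g  noise SD: %g\n",
              x$session_effect, x$consistency_effect, x$noise_sd))
  cat(sprintf("  cutpoints: %s  seed: %d\n",
              paste(x$ordinal_cutpoints, collapse = ", "), x$seed))
  invisible(x)
}

#' Tabulated saturating dose-response profile
#'
#' Builds a `nonlinear_profile` table for [sim_config()]: a fast early
#' rise that plateaus, `offset(i) = amplitude * (1 - exp(-(i - 1) / rate))`.
#'
#' @param n_sessions number of session indices to tabulate.
#' @param amplitude plateau height in latent-mood units.
#' @param rate e-folding scale in sessions; smaller means faster early gains.
#' @return a data frame with columns `session_index` and `offset`.
#' @export
saturating_profile <- function(n_sessions = 300, amplitude = 0.8, rate = 20) {
  idx <- seq_len(n_sessions)
  data.frame(session_index = idx,
             offset = amplitude * (1 - exp(-(idx - 1) / rate)))
}

# interpolator for a tabulated profile; plateau beyond the table
.profile_fun <- function(profile) {
  if (is.null(profile)) return(function(i) rep(0, length(i)))
  f <- stats::approxfun(profile$session_index, profile$offset, rule = 2)
  function(i) f(i)
}

# distinct calendar days with >= 1 session in the trailing `window`-day
# window inclusive of the current day (days: sorted integer day numbers,
# one user); the count at i is #unique days in (d_i - window, d_i]
.days_per_week <- function(days, window = 7) {
  ud <- unique(days)
  findInterval(days, ud) - findInterval(days - window, ud)
}

# ordinal mood = 1 + number of cutpoints strictly below the latent value
.latent_to_mood <- function(latent, cutpoints) {
  1L + as.integer(rowSums(outer(latent, cutpoints, ">")))
}

#' Simulate the user (onboarding) table
#'
#' Draws `n_users` user profiles: continent of use, age (normal, truncated
#' to 18+ by inverse-CDF sampling), reasons for meditating, previous
#' experience indicators, and the per-user baseline latent mood.
#'
#' @param config a [sim_config()].
#' @return a tibble with one row per user.
#' @export
simulate_users <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_users
  set.seed(config$seed)

  lo <- pnorm(18, config$age_mean, config$age_sd)
  age <- qnorm(runif(n, lo, 1), config$age_mean, config$age_sd)

  reasons <- vapply(.reason_p, function(p) runif(n) < p, logical(n))
  if (n == 1) reasons <- matrix(reasons, nrow = 1)
  colnames(reasons) <- paste0("reason_", .reason_names)

  experience <- vapply(.experience_p, function(p) runif(n) < p, logical(n))
  if (n == 1) experience <- matrix(experience, nrow = 1)
  colnames(experience) <- paste0("exp_", .experience_names)

  out <- tibble(
    user_id = sprintf("u%05d", seq_len(n)),
    continent = sample(.continents, n, replace = TRUE, prob = .continent_p),
    age = round(age, 1),
    baseline_latent = rnorm(n, 0, config$baseline_sd)
  )
  bind_cols(out, as_tibble(reasons), as_tibble(experience))
}

# gaps in days between consecutive sessions: geometric on 1..gap_max
.sample_gaps <- function(k, config) {
  if (k == 0) return(integer(0))
  # truncated geometric via inverse CDF on the renormalized support
  pmax_tail <- 1 - (1 - config$gap_prob)^config$gap_max
  u <- runif(k) * pmax_tail
  g <- ceiling(log1p(-u) / log(1 - config$gap_prob))
  g <- pmin(pmax(g, 1L), config$gap_max)
  if (config$returning_users) {
    long <- runif(k) < 0.15
    g[long] <- sample(8:30, sum(long), replace = TRUE)
  }
  as.integer(g)
}

#' Simulate session streams with ground-truth latent mood
#'
#' For each user, draws a geometric number of sessions (absorbing churn,
#' capped at `max_sessions`), inter-session gaps from the configured gap
#' distribution, and a latent mood trajectory
#' `baseline + session_effect * (i - 1) + consistency_effect * days/week +
#' nonlinear_profile(i) + noise`, thresholded at the ordinal cutpoints.
#'
#' @param users tibble from [simulate_users()].
#' @param config the same [sim_config()].
#' @return a tibble of session records, one row per session, with the
#'   ground-truth latent table attached as `attr(, "truth")` (keyed by
#'   `user_id` and `session_index`, joining the session table 1:1).
#' @export
simulate_sessions <- function(users, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(users) == 0) stop("`users` must be nonempty", call. = FALSE)
  set.seed(config$seed + 1L)

  prof <- .profile_fun(config$nonlinear_profile)
  n_u <- nrow(users)

  # session counts: geometric (mean 1/h) under absorbing churn, capped
  n_sess <- if (config$churn_hazard == 0) {
    rep(config$max_sessions, n_u)
  } else {
    pmin(1L + rgeom(n_u, config$churn_hazard), config$max_sessions)
  }
  if (any(!is.finite(n_sess)))
    abort_config("max_sessions", "must be finite when churn_hazard is 0")
  n_sess <- as.integer(n_sess)

  start_day <- as.integer(round(runif(n_u, 0, 365)))
  origin <- as.Date("2021-05-18")

  N <- sum(n_sess)
  uid <- rep.int(seq_len(n_u), n_sess)
  pos <- sequence(n_sess)

  # inter-session gaps in days (0 at each user's first session)
  gaps <- .sample_gaps(N, config)
  gaps[pos == 1L] <- 0L
  cg <- cumsum(gaps)
  first_idx <- which(pos == 1L)
  days <- start_day[uid] + (cg - rep.int(cg[first_idx], n_sess))

  # gaps are >= 1 day, so within-user days are distinct and sorted
  dpw <- unlist(lapply(split(days, uid), .days_per_week),
                use.names = FALSE)

  latent_sys <- users$baseline_latent[uid] +
    config$session_effect * (pos - 1) +
    config$consistency_effect * dpw +
    prof(pos)
  latent <- latent_sys + rnorm(N, 0, config$noise_sd)
  mood <- .latent_to_mood(latent, config$ordinal_cutpoints)

  tod <- sample(c("morning", "day", "night"), N, replace = TRUE,
                prob = c(0.4, 0.3, 0.3))
  hour <- ifelse(tod == "morning", 5, ifelse(tod == "day", 11, 18)) +
    runif(N, 0, 6)

  len <- round(rnorm(N, 11.5, 4.1))
  long <- runif(N) < 0.02
  len[long] <- sample(31:90, sum(long), replace = TRUE)
  len <- pmax(len, 1)

  ptype <- sample(.practice_types, N, replace = TRUE,
                  prob = .practice_type_p)
  if (config$include_excluded_content) {
    excl <- runif(N) < config$p_excluded
    ptype[excl] <- sample(.excluded_types, sum(excl), replace = TRUE)
  }

  n_attr <- sample(0:2, N, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  tag1 <- sample(.attribution_tags, N, replace = TRUE)
  tag2 <- sample(.attribution_tags, N, replace = TRUE)
  while (any(fix <- n_attr == 2 & tag1 == tag2))
    tag2[fix] <- sample(.attribution_tags, sum(fix), replace = TRUE)
  attributions <- ifelse(n_attr == 0, "",
                         ifelse(n_attr == 1, tag1,
                                paste(tag1, tag2, sep = ";")))

  sessions <- tibble(
    user_id = users$user_id[uid],
    session_index = pos,
    timestamp = as.POSIXct(origin, tz = "UTC") +
      days * 86400 + round(hour * 3600),
    mood = mood,
    length_min = len,
    practice_type = ptype,
    worldview = sample(.worldviews, N, replace = TRUE, prob = .worldview_p),
    orientation = sample(.orientations, N, replace = TRUE,
                         prob = .orientation_p),
    focus = sample(names(config$p_focus), N, replace = TRUE,
                   prob = config$p_focus),
    rating_score = round(pmin(pmax(rnorm(N, 4.72, 0.12), 1), 5), 2),
    rating_count = round(rlnorm(N, 10.5, 1)),
    play_count = round(rlnorm(N, 13.5, 1)),
    attributions = attributions,
    time_of_day = tod
  )
  truth <- tibble(
    user_id = users$user_id[uid],
    session_index = pos,
    latent_systematic = latent_sys,
    latent = latent,
    profile_offset = prof(pos),
    days_per_week = dpw,
    mood = mood
  )
  attr(sessions, "truth") <- truth
  sessions
}

#' Simulate a full cohort (users, sessions, ground truth)
#'
#' @param config a [sim_config()].
#' @return a list of class `medema_cohort` with elements `users`,
#'   `sessions`, `truth`, and `config`.
#' @export
simulate_cohort <- function(config) {
  users <- simulate_users(config)
  sessions <- simulate_sessions(users, config)
  structure(
    list(users = users, sessions = sessions,
         truth = attr(sessions, "truth"), config = config),
    class = "medema_cohort"
  )
}

#' @export
print.medema_cohort <- function(x, ...) {
  cat(sprintf("<medema_cohort> %d users, %d sessions (seed %d)\n",
              nrow(x$users), nrow(x$sessions), x$config$seed))
  invisible(x)
}

#' Expected ordinal mood under the latent-threshold model
#'
#' Closed-form population mean of the 1-5 mood check-in when the latent
#' systematic offset is `offset`, marginalizing over the Gaussian baseline
#' and noise: `E = 1 + sum_k Phi((offset - c_k) / s)` with
#' `s = sqrt(noise_sd^2 + baseline_sd^2)`.
#'
#' @param offset latent systematic offset(s), in latent-mood units.
#' @param config a [sim_config()] supplying cutpoints and SDs.
#' @return expected mood, same length as `offset`.
#' @export
expected_mood <- function(offset, config) {
  s <- sqrt(config$noise_sd^2 + config$baseline_sd^2)
  vapply(offset, function(m) {
    1 + sum(pnorm((m - config$ordinal_cutpoints) / s))
  }, numeric(1))
}

#' Derivative of expected mood with respect to the latent offset
#'
#' The local slope of the ordinal link: a latent dose-response slope
#' `b` appears on the observed 1-5 scale as approximately
#' `b * mood_link_slope(offset, config)`.
#'
#' @inheritParams expected_mood
#' @return link derivative, same length as `offset`.
#' @export
mood_link_slope <- function(offset, config) {
  s <- sqrt(config$noise_sd^2 + config$baseline_sd^2)
  vapply(offset, function(m) {
    sum(dnorm((m - config$ordinal_cutpoints) / s)) / s
  }, numeric(1))
}

#' Simulate a user-level adherence cohort with a known odds ratio
#'
#' Draws first-30-session habit features at the user level and a binary
#' long-term adherence label from a logistic model with configurable
#' log-odds effects. Used for parameter-recovery studies of the adherence
#' logistic regression without simulating full 150-session streams.
#'
#' @param n_users cohort size.
#' @param or_days_4_7 true odds ratio for practicing 4-7 days/week
#'   relative to 1 day/week.
#' @param base_rate marginal adherence probability at the reference level.
#' @param seed integer seed.
#' @param null_model if `TRUE`, all non-intercept effects are zeroed so
#'   the label is independent of every feature (for false-positive-rate
#'   checks).
#' @return a tibble with factor habit features, covariates, a logical
#'   `adherent` label, and the true coefficient vector in
#'   `attr(, "truth")` (log-odds scale).
#' @export
simulate_adherence_cohort <- function(n_users = 2000, or_days_4_7 = 2,
                                      base_rate = 0.12, seed = 1L,
                                      null_model = FALSE) {
  if (n_users < 1) abort_config("n_users", "must be a count >= 1")
  set.seed(seed)
  dpw <- factor(sample(c("1", "2", "3", "4-7"), n_users, replace = TRUE,
                       prob = c(0.35, 0.30, 0.20, 0.15)),
                levels = c("1", "2", "3", "4-7"))
  len <- factor(sample(c("5-10", "11-20", "21-30"), n_users, replace = TRUE,
                       prob = c(0.45, 0.40, 0.15)),
                levels = c("5-10", "11-20", "21-30"))
  tod <- factor(sample(c("night", "morning", "day"), n_users, replace = TRUE,
                       prob = c(0.35, 0.40, 0.25)),
                levels = c("night", "morning", "day"))
  age_z <- rnorm(n_users)

  beta <- c(
    `(Intercept)` = qlogis(base_rate),
    `days_per_week_f2` = 0.15,
    `days_per_week_f3` = 0.30,
    `days_per_week_f4-7` = log(or_days_4_7),
    `length_f11-20` = 0.10,
    `length_f21-30` = 0.05,
    `time_of_day_fmorning` = 0.25,
    `time_of_day_fday` = 0.05,
    `age_z` = 0.10
  )
  if (null_model) beta[-1] <- 0
  X <- model.matrix(~ days_per_week_f + length_f + time_of_day_f + age_z,
                    data.frame(days_per_week_f = dpw, length_f = len,
                               time_of_day_f = tod, age_z = age_z))
  eta <- drop(X %*% beta[colnames(X)])
  out <- tibble(
    user_id = sprintf("a%05d", seq_len(n_users)),
    days_per_week_f = dpw,
    length_f = len,
    time_of_day_f = tod,
    age_z = age_z,
    adherent = runif(n_users) < plogis(eta)
  )
  attr(out, "truth") <- beta
  out
}
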