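suppressPackageStartupMessages(library(dplyr))

# Independent brute-force oracles: deliberately naive recomputations
# (linear scans, O(n^2) loops, textbook formulas) used to cross-check the
# package's vectorized implementations.

# period ids by scanning each gap against the threshold
bf_period_ids <- function(days, gap_days = 7) {
  pid <- integer(length(days))
  cur <- 1L
  for (i in seq_along(days)) {
    if (i > 1 && days[i] - days[i - 1] > gap_days) cur <- cur + 1L
    pid[i] <- cur
  }
  pid
}

# habit features recomputed from scratch at every index (O(n^2))
bf_habits <- function(days, focus, ptype, week_window = 7) {
  n <- length(days)
  res <- data.frame(session_count = integer(n),
                    days_since_last = rep(NA_real_, n),
                    days_per_week = integer(n),
                    ratio = rep(NA_real_, n),
                    n_types = integer(n))
  for (i in seq_len(n)) {
    res$session_count[i] <- i
    if (i > 1) res$days_since_last[i] <- days[i] - days[i - 1]
    win <- days[1:i]
    res$days_per_week[i] <-
      length(unique(win[win >= days[i] - (week_window - 1)]))
    ce <- sum(focus[1:i] == "exteroceptive")
    ci <- sum(focus[1:i] == "interoceptive")
    if (ci > 0) res$ratio[i] <- ce / ci
    res$n_types[i] <- length(unique(ptype[1:i]))
  }
  res
}

# rolling sample SD by direct sd() on every window
bf_roll_sd <- function(m, w = 5) {
  n <- length(m)
  out <- rep(NA_real_, n)
  if (n >= w) for (i in w:n) out[i] <- sd(m[(i - w + 1):i])
  out
}

# resilience scanner recomputing the trailing-week mean at every index
bf_resilience <- function(days, moods, drop = 1, week = 7) {
  n <- length(moods)
  events <- list()
  active <- FALSE
  ref <- NA_real_; dp <- NA_integer_; cnt <- 0L
  for (i in seq_len(n)) {
    if (active) {
      cnt <- cnt + 1L
      if (moods[i] >= ref) {
        events[[length(events) + 1]] <-
          data.frame(drop_pos = dp, reference_mood = ref,
                     sessions_to_recovery = cnt, censored = FALSE)
        active <- FALSE
      }
    } else {
      w <- c()
      if (i > 1) for (j in 1:(i - 1))
        if (days[i] - days[j] <= week) w <- c(w, moods[j])
      if (length(w) > 0 && moods[i] <= mean(w) - drop) {
        active <- TRUE; ref <- mean(w); dp <- i; cnt <- 0L
      }
    }
  }
  if (active)
    events[[length(events) + 1]] <-
      data.frame(drop_pos = dp, reference_mood = ref,
                 sessions_to_recovery = NA_integer_, censored = TRUE)
  if (length(events) == 0)
    data.frame(drop_pos = integer(0), reference_mood = numeric(0),
               sessions_to_recovery = integer(0), censored = logical(0))
  else do.call(rbind, events)
}

# hand-rolled Benjamini-Hochberg step-up
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# expected ordinal mood under the latent-threshold model by numerical
# integration over the baseline distribution (independent of the
# package's closed form)
oracle_expected_mood <- function(offset, cutpoints, noise_sd, baseline_sd) {
  vapply(offset, function(m) {
    1 + sum(vapply(cutpoints, function(ck) {
      stats::integrate(function(b) {
        pnorm((m + b - ck) / noise_sd) * dnorm(b, 0, baseline_sd)
      }, -Inf, Inf)$value
    }, numeric(1)))
  }, numeric(1))
}

oracle_link_slope <- function(offset, cutpoints, noise_sd, baseline_sd,
                              h = 1e-4) {
  (oracle_expected_mood(offset + h, cutpoints, noise_sd, baseline_sd) -
     oracle_expected_mood(offset - h, cutpoints, noise_sd, baseline_sd)) /
    (2 * h)
}

# ---- stream builders ----

# random single-user stream (gap 0 allowed: several sessions per day)
random_stream <- function(n, seed, user = "u1") {
  set.seed(seed)
  gaps <- sample(0:10, n - 1, replace = TRUE,
                 prob = c(0.15, rep(0.085, 10)))
  days <- cumsum(c(sample(0:30, 1), gaps))
  tibble::tibble(
    user_id = user,
    timestamp = as.POSIXct("2021-06-01", tz = "UTC") +
      days * 86400 + seq_len(n),
    mood = sample(1:5, n, replace = TRUE),
    length_min = sample(5:30, n, replace = TRUE),
    practice_type = sample(c("a", "b", "c", "d"), n, replace = TRUE),
    worldview = "Other",
    orientation = "Techniques",
    focus = sample(c("interoceptive", "exteroceptive", "other"), n,
                   replace = TRUE),
    rating_score = 4.7,
    rating_count = 10,
    play_count = 100,
    attributions = "",
    time_of_day = sample(c("morning", "day", "night"), n, replace = TRUE)
  )
}

# fixed stream from explicit day numbers and moods (daily resolution)
stream_from_days <- function(days, moods, user = "u1",
                             practice_type = "Mindfulness meditation",
                             length_min = 10) {
  n <- length(days)
  tibble::tibble(
    user_id = user,
    timestamp = as.POSIXct("2021-06-01", tz = "UTC") +
      days * 86400 + seq_len(n),
    mood = moods,
    length_min = rep_len(length_min, n),
    practice_type = rep_len(practice_type, n),
    worldview = "Other",
    orientation = "Techniques",
    focus = "interoceptive",
    rating_score = 4.7,
    rating_count = 10,
    play_count = 100,
    attributions = "",
    time_of_day = "morning"
  )
}

# minimal user covariate table for hand-built streams
users_for <- function(sessions) {
  ids <- unique(sessions$user_id)
  tibble::tibble(
    user_id = ids,
    continent = "Europe",
    age = 35,
    baseline_latent = 0,
    reason_anxiety = TRUE, reason_stress = FALSE,
    reason_sadness = FALSE, reason_wellbeing = TRUE,
    exp_none = FALSE, exp_apps = TRUE, exp_web_course = FALSE,
    exp_local_class = FALSE, exp_mentoring = FALSE, exp_retreats = FALSE
  )
}
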