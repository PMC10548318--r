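# Engineered outcomes: equanimity (sign-flipped, rescaled rolling mood
# SD), resilience (sessions to recovery after a 1-point mood drop below
# the trailing-week average), and the long-term adherence label.

#' Rolling-SD equanimity series for one mood stream
#'
#' Equanimity is operationalized as mood stability: the rolling
#' `window`-session sample SD of the 1-5 mood check-ins, sign-flipped
#' (so less variability means more equanimity) and min-max rescaled onto
#' `[1, 5]`. The value at index i is defined once `window` observations
#' end at i. By default the rescaling range is this series' own defined
#' raw SDs; pass `corpus_range` to normalize against a pooled corpus (see
#' [equanimity_table()], which normalizes globally across users so the
#' scale is comparable between them).
#'
#' @param moods integer vector of mood check-ins in 1-5.
#' @param window rolling window in sessions (>= 2, default 5: a typical
#'   practice-period length).
#' @param corpus_range optional `c(min, max)` of raw SDs to rescale
#'   against.
#' @return a tibble with `index`, `raw_sd` (sample SD, n-1 denominator),
#'   and `equanimity` on `[1, 5]`; the first `window - 1` rows are NA.
#'   Zero variability maps to the scale maximum 5. If every defined raw
#'   SD is identical the normalization is degenerate and all values map
#'   to 5.
#' @export
equanimity_series <- function(moods, window = 5, corpus_range = NULL) {
  if (!is.numeric(window) || window < 2)
    abort_config("window", "must be >= 2")
  raw <- .roll_sd(moods, window)
  rng <- corpus_range %||% suppressWarnings(range(raw, na.rm = TRUE))
  tibble(index = seq_along(moods), raw_sd = raw,
         equanimity = .equanimity_rescale(raw, rng))
}

# trailing-window sample SD (n-1 denominator) via cumulative sums;
# moods are small integers so the shortcut formula is numerically safe
.roll_sd <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  i <- w:n
  s <- c1[i + 1] - c1[i - w + 1]
  s2 <- c2[i + 1] - c2[i - w + 1]
  out[i] <- sqrt(pmax((s2 - s^2 / w) / (w - 1), 0))
  out
}

# sign flip + min-max onto [1, 5]; degenerate range maps to 5
.equanimity_rescale <- function(raw, rng) {
  if (!all(is.finite(rng)) || diff(rng) == 0)
    return(ifelse(is.na(raw), NA_real_, 5))
  1 + 4 * (rng[2] - raw) / (rng[2] - rng[1])
}

#' Per-session equanimity across a cohort
#'
#' Computes the rolling-SD equanimity for every user and rescales on the
#' pooled corpus of defined raw SDs (`scope = "global"`, the default, so
#' values are comparable across users) or within each user
#' (`scope = "user"`).
#'
#' @param sessions session tibble with `user_id` and `mood`, sorted by
#'   timestamp within user.
#' @param window rolling window in sessions.
#' @param scope normalization scope, `"global"` or `"user"`.
#' @return the session tibble with `raw_sd` and `equanimity` columns.
#' @export
equanimity_table <- function(sessions, window = 5,
                             scope = c("global", "user")) {
  scope <- match.arg(scope)
  if (!is.numeric(window) || window < 2)
    abort_config("window", "must be >= 2")
  out <- sessions %>%
    group_by(.data$user_id) %>%
    mutate(raw_sd = .roll_sd(.data$mood, window)) %>%
    ungroup()
  if (scope == "global") {
    rng <- suppressWarnings(range(out$raw_sd, na.rm = TRUE))
    out$equanimity <- .equanimity_rescale(out$raw_sd, rng)
  } else {
    out <- out %>%
      group_by(.data$user_id) %>%
      mutate(equanimity =
               .equanimity_rescale(.data$raw_sd,
                                   suppressWarnings(
                                     range(.data$raw_sd, na.rm = TRUE)))) %>%
      ungroup()
  }
  out
}

#' Detect mood-recovery (resilience) events
#'
#' Scans each user's stream for sessions whose mood sits at least `drop`
#' points below the user's trailing-week mean mood (sessions within the
#' previous `week` calendar days, the current check-in excluded so a drop
#' cannot dilute its own reference). When such a drop occurs, the
#' reference is frozen and a counter runs over subsequent sessions until
#' the first whose mood returns to or above the reference. Events still
#' open at end-of-stream are marked censored (these users may have
#' churned, so their recovery time is unknown and they are excluded from
#' analysis). While an event is active no new event is opened, and a
#' deeper drop does not reset the counter; the recovering session itself
#' is not considered as a new drop.
#'
#' @param sessions session tibble with `user_id`, `timestamp`, `mood`,
#'   sorted by timestamp within user.
#' @param drop mood-point drop defining an event (default 1).
#' @param week trailing reference window in days (default 7).
#' @param freeze_reference if `FALSE`, the recovery target is recomputed
#'   as the trailing-week mean at every session during recovery instead
#'   of being frozen at drop time.
#' @return a tibble of events: `user_id`, `drop_pos` (within-user session
#'   position), `reference_mood`, `sessions_to_recovery` (NA when
#'   censored), `censored`.
#' @export
resilience_events <- function(sessions, drop = 1, week = 7,
                              freeze_reference = TRUE) {
  if (!is.numeric(drop) || drop <= 0) abort_config("drop", "must be > 0")
  if (!is.numeric(week) || week < 1) abort_config("week", "must be >= 1")
  .check_sorted(sessions)
  sessions %>%
    group_by(.data$user_id) %>%
    group_modify(function(df, key) {
      days <- .session_day(df$timestamp)
      moods <- df$mood
      n <- length(moods)
      events <- list()
      active <- FALSE
      ref <- NA_real_; drop_pos <- NA_integer_; count <- 0L
      trailing_mean <- function(i) {
        w <- which(days >= days[i] - week & seq_len(n) < i)
        if (length(w) == 0) NA_real_ else mean(moods[w])
      }
      for (i in seq_len(n)) {
        if (active) {
          count <- count + 1L
          target <- if (freeze_reference) ref else {
            tm <- trailing_mean(i)
            if (is.na(tm)) ref else tm
          }
          if (moods[i] >= target) {
            events[[length(events) + 1]] <-
              tibble(drop_pos = drop_pos, reference_mood = ref,
                     sessions_to_recovery = count, censored = FALSE)
            active <- FALSE
          }
        } else {
          tm <- trailing_mean(i)
          if (!is.na(tm) && moods[i] <= tm - drop) {
            active <- TRUE; ref <- tm; drop_pos <- i; count <- 0L
          }
        }
      }
      if (active)
        events[[length(events) + 1]] <-
          tibble(drop_pos = drop_pos, reference_mood = ref,
                 sessions_to_recovery = NA_integer_, censored = TRUE)
      if (length(events) == 0) {
        tibble(drop_pos = integer(0), reference_mood = numeric(0),
               sessions_to_recovery = integer(0), censored = logical(0))
      } else bind_rows(events)
    }) %>%
    ungroup()
}

#' Build the adherence dataset
#'
#' One row per user who completed at least `first_n` sessions: habit
#' features aggregated over the first `first_n` sessions only (no
#' leakage from later behaviour) and a binary label marking whether the
#' user's full stream reached `threshold` sessions. Features: dominant
#' time of day (modal; earliest of night/morning/day on ties), mean
#' days/week and mean days-since-last factorized into the adherence
#' level sets, the exteroceptive:interoceptive ratio at session
#' `first_n`, mean session length binned, distinct practice types
#' binned, the first session's mood as baseline, and the onboarding
#' covariates.
#'
#' @param sessions session tibble, sorted by timestamp within user.
#' @param users user covariate tibble.
#' @param first_n number of early sessions the features may use.
#' @param threshold session count defining long-term adherence; must
#'   exceed `first_n`.
#' @return a tibble with one row per eligible user and the empirical
#'   adherer fraction in `attr(, "adherer_fraction")`; the number of
#'   excluded (sub-`first_n`) users is in `attr(, "n_excluded")`.
#' @export
adherence_dataset <- function(sessions, users, first_n = 30,
                              threshold = 150) {
  if (!is.numeric(first_n) || first_n < 1)
    abort_config("first_n", "must be >= 1")
  if (!is.numeric(threshold) || threshold <= first_n)
    abort_config("threshold", "must exceed first_n")
  .check_sorted(sessions)

  totals <- sessions %>% count(.data$user_id, name = "n_total")
  eligible <- totals %>% filter(.data$n_total >= first_n)
  n_excluded <- nrow(totals) - nrow(eligible)

  early <- sessions %>%
    semi_join(eligible, by = "user_id") %>%
    group_by(.data$user_id) %>%
    slice_head(n = first_n) %>%
    ungroup() %>%
    compute_habit_features()

  feats <- early %>%
    group_by(.data$user_id) %>%
    summarise(
      baseline_mood = first(.data$mood),
      mean_days_per_week = mean(.data$days_per_week),
      mean_days_since_last = mean(.data$days_since_last, na.rm = TRUE),
      ratio_at_n = last(.data$extero_intero_ratio),
      mean_length = mean(.data$length_min),
      n_types = last(.data$n_practice_types),
      dominant_time_of_day = names(which.max(table(
        factor(.data$time_of_day, c("night", "morning", "day"))))),
      .groups = "drop"
    ) %>%
    mutate(
      days_per_week_f = days_per_week_level(round(.data$mean_days_per_week)),
      days_since_last_f = days_since_last_level(
        round(.data$mean_days_since_last), adherence = TRUE),
      length_f = length_level(.data$mean_length),
      n_types_f = n_types_level(.data$n_types),
      ratio_f = ratio_level(.data$ratio_at_n),
      time_of_day_f = factor(.data$dominant_time_of_day,
                             c("night", "morning", "day"))
    ) %>%
    left_join(eligible, by = "user_id") %>%
    mutate(adherent = .data$n_total >= threshold) %>%
    left_join(users, by = "user_id")

  attr(feats, "adherer_fraction") <-
    if (nrow(feats)) mean(feats$adherent) else NA_real_
  attr(feats, "n_excluded") <- n_excluded
  feats
}
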