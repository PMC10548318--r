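# Session-stream feature engineering: practice-period segmentation,
# forward-shifted outcomes, cumulative habit features, box-plot trimming
# and harmonization to coarse bins.

# calendar day number (UTC) of each session
.session_day <- function(timestamp) {
  as.integer(as.Date(timestamp, tz = "UTC"))
}

.check_sorted <- function(sessions) {
  bad <- sessions %>%
    group_by(.data$user_id) %>%
    summarise(ok = !is.unsorted(.data$timestamp, strictly = FALSE),
              .groups = "drop")
  if (any(!bad$ok))
    stop("sessions must be sorted by timestamp within user (unsorted: ",
         paste(bad$user_id[!bad$ok], collapse = ", "), ")", call. = FALSE)
  invisible(sessions)
}

#' Remove children-related and sleep meditations
#'
#' Content filter applied before all feature computation: sessions whose
#' practice-type (content) label matches any of `patterns`
#' (case-insensitive) are dropped. Sleep meditations are removed because
#' the user may have fallen asleep mid-track; children's content because
#' the account holder may not have completed the session. Mood
#' attributions are deliberately not consulted: attributing one's mood
#' to sleep is a covariate, not excluded content.
#'
#' @param sessions session tibble.
#' @param patterns character patterns matched against `practice_type`.
#' @return the filtered tibble; the number of removed rows is attached
#'   as `attr(, "n_removed")`.
#' @export
filter_excluded_content <- function(sessions,
                                    patterns = c("sleep", "child")) {
  pat <- paste(patterns, collapse = "|")
  hit <- grepl(pat, sessions$practice_type, ignore.case = TRUE)
  out <- sessions[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Segment a session stream into practice periods
#'
#' A practice period is a maximal run of a user's sessions in which no
#' two consecutive sessions are more than `gap_days` calendar days apart.
#' A gap of exactly `gap_days` stays within the period; a longer gap
#' starts a new one. Gaps are measured as calendar-day differences of the
#' session timestamps, not 24-hour blocks.
#'
#' @param sessions session tibble (one or many users), sorted by
#'   timestamp within user.
#' @param gap_days period-breaking gap threshold in days (default 7).
#' @return a tibble with one row per practice period: `user_id`,
#'   `period_index`, `n_sessions`, `first_pos` / `last_pos` (within-user
#'   session positions), `session_positions` (list column),
#'   `baseline_mood` (first session's mood in the period), and
#'   `days_since_previous_period` (NA for a user's first period).
#' @export
segment_practice_periods <- function(sessions, gap_days = 7) {
  if (!is.numeric(gap_days) || gap_days < 1)
    abort_config("gap_days", "must be >= 1")
  .check_sorted(sessions)
  sessions %>%
    group_by(.data$user_id) %>%
    group_modify(function(df, key) {
      days <- .session_day(df$timestamp)
      pid <- cumsum(c(TRUE, diff(days) > gap_days))
      pos <- seq_along(days)
      first_pos <- tapply(pos, pid, min)
      last_pos <- tapply(pos, pid, max)
      gap_before <- c(NA_integer_,
                      days[first_pos[-1]] - days[last_pos[-length(last_pos)]])
      tibble(
        period_index = seq_along(first_pos),
        n_sessions = as.integer(tapply(pos, pid, length)),
        first_pos = as.integer(first_pos),
        last_pos = as.integer(last_pos),
        session_positions = unname(split(pos, pid)),
        baseline_mood = df$mood[first_pos],
        days_since_previous_period = as.numeric(gap_before)
      )
    }) %>%
    ungroup()
}

#' Forward-shift mood outcomes within practice periods
#'
#' Within each practice period of k sessions, builds k - 1 rows pairing
#' the predictors of session j with the mood of session j + 1, so each
#' session predicts the following check-in. The period's first mood is
#' removed from the outcomes and carried as the period's baseline
#' covariate.
#'
#' @inheritParams segment_practice_periods
#' @return a tibble with `user_id`, `period_index`, `predictor_pos`,
#'   `outcome_pos` (within-user session positions), `outcome_mood`,
#'   `baseline_mood`, and `days_between_periods`.
#' @export
shift_outcomes <- function(sessions, gap_days = 7) {
  if (!is.numeric(gap_days) || gap_days < 1)
    abort_config("gap_days", "must be >= 1")
  .check_sorted(sessions)
  df <- sessions %>%
    group_by(.data$user_id) %>%
    mutate(
      .pos = row_number(),
      .day = .session_day(.data$timestamp),
      .pid = cumsum(c(TRUE, diff(.data$.day) > gap_days)),
      .next_pid = lead(.data$.pid),
      .next_mood = lead(.data$mood)
    ) %>%
    ungroup()
  periods <- df %>%
    group_by(.data$user_id, .data$.pid) %>%
    summarise(baseline_mood = first(.data$mood),
              .first_day = first(.data$.day),
              .last_day = last(.data$.day),
              .groups = "drop_last") %>%
    mutate(days_between_periods =
             as.numeric(.data$.first_day - lag(.data$.last_day))) %>%
    ungroup() %>%
    select("user_id", ".pid", "baseline_mood", "days_between_periods")
  df %>%
    filter(!is.na(.data$.next_pid) & .data$.pid == .data$.next_pid) %>%
    left_join(periods, by = c("user_id", ".pid")) %>%
    transmute(
      user_id = .data$user_id,
      period_index = .data$.pid,
      predictor_pos = .data$.pos,
      outcome_pos = .data$.pos + 1L,
      outcome_mood = .data$.next_mood,
      baseline_mood = .data$baseline_mood,
      days_between_periods = .data$days_between_periods
    )
}

#' Cumulative habit features per session
#'
#' Adds, per user and in stream order: the cumulative session count;
#' days since the previous session (calendar days, NA for the first);
#' distinct days meditated in the trailing 7-day window inclusive of the
#' current day; the cumulative exteroceptive-to-interoceptive session
#' ratio (NA while no interoceptive session has been completed); and the
#' running count of distinct practice types.
#'
#' @param sessions session tibble, sorted by timestamp within user.
#' @param week_window trailing window in days for `days_per_week`.
#' @return the input tibble with columns `session_count`,
#'   `days_since_last`, `days_per_week`, `extero_intero_ratio`, and
#'   `n_practice_types` appended.
#' @export
compute_habit_features <- function(sessions, week_window = 7) {
  if (!is.numeric(week_window) || week_window < 1)
    abort_config("week_window", "must be >= 1")
  .check_sorted(sessions)
  sessions %>%
    group_by(.data$user_id) %>%
    mutate(
      .day = .session_day(.data$timestamp),
      session_count = row_number(),
      days_since_last = c(NA_real_, diff(.data$.day)),
      days_per_week = .days_per_week(.data$.day, week_window),
      .cum_ext = cumsum(.data$focus == "exteroceptive"),
      .cum_int = cumsum(.data$focus == "interoceptive"),
      extero_intero_ratio = ifelse(.data$.cum_int == 0, NA_real_,
                                   .data$.cum_ext / .data$.cum_int),
      n_practice_types = cumsum(!duplicated(.data$practice_type))
    ) %>%
    ungroup() %>%
    select(-".day", -".cum_ext", -".cum_int")
}

#' Box-plot (Tukey fence) outlier mask
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]`. Quartiles use
#' `stats::quantile` with the given `type` (default 7, the R default);
#' the convention is configurable because fence positions depend on it.
#'
#' @param values numeric vector (nonempty; NAs are kept, i.e. not trimmed).
#' @param k fence multiplier (1.5 = standard box-plot whiskers).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return a logical keep-mask the same length as `values`.
#' @export
trim_outliers <- function(values, k = 1.5, type = 7) {
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                type = type)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  keep | is.na(values)
}

#' Harmonize values to the nearest multiple of a bin width
#'
#' Rounds each value to the nearest multiple of `width`; exact half-way
#' ties round away from zero (so 12.5 with width 5 gives 15).
#'
#' @param values numeric vector.
#' @param width positive bin width (default 5, i.e. nearest 5 minutes or
#'   5 sessions).
#' @return the binned vector.
#' @export
harmonize <- function(values, width = 5) {
  if (!is.numeric(width) || width <= 0)
    abort_config("width", "must be > 0")
  sign(values) * floor(abs(values) / width + 0.5) * width
}

# --- factorized habit levels used by the nonlinear and adherence models ---

#' Factorize habit features into the analysis level sets
#'
#' Groupings used to stratify the nonlinear dose-response smooths and the
#' adherence model: days/week into 1 / 2 / 3 / 4-7; days since last
#' session into 1 / 2 / 3-7 (or 1 / 2 / 3-4 / 5-7 for adherence); session
#' length into 5-10 / 11-20 / 21-30 minutes; distinct practice types into
#' 1-4 / 5-8 / 9-12; and the exteroceptive:interoceptive ratio into
#' integer levels 0:1 through 9:1. Values outside a level set map to NA.
#'
#' @param x numeric vector to factorize.
#' @name habit_levels
NULL

#' @rdname habit_levels
#' @export
days_per_week_level <- function(x) {
  lv <- ifelse(is.na(x), NA, ifelse(x <= 1, "1", ifelse(x == 2, "2",
          ifelse(x == 3, "3", "4-7"))))
  lv[!is.na(x) & x > 7] <- NA
  factor(lv, levels = c("1", "2", "3", "4-7"))
}

#' @rdname habit_levels
#' @param adherence use the finer adherence grouping for days since last.
#' @export
days_since_last_level <- function(x, adherence = FALSE) {
  if (adherence) {
    lv <- ifelse(is.na(x), NA, ifelse(x <= 1, "1", ifelse(x == 2, "2",
            ifelse(x <= 4, "3-4", ifelse(x <= 7, "5-7", NA)))))
    factor(lv, levels = c("1", "2", "3-4", "5-7"))
  } else {
    lv <- ifelse(is.na(x), NA, ifelse(x <= 1, "1", ifelse(x == 2, "2",
            ifelse(x <= 7, "3-7", NA))))
    factor(lv, levels = c("1", "2", "3-7"))
  }
}

#' @rdname habit_levels
#' @export
length_level <- function(x) {
  lv <- ifelse(is.na(x), NA, ifelse(x >= 5 & x <= 10, "5-10",
          ifelse(x > 10 & x <= 20, "11-20",
            ifelse(x > 20 & x <= 30, "21-30", NA))))
  factor(lv, levels = c("5-10", "11-20", "21-30"))
}

#' @rdname habit_levels
#' @export
n_types_level <- function(x) {
  lv <- ifelse(is.na(x), NA, ifelse(x <= 4, "1-4",
          ifelse(x <= 8, "5-8", ifelse(x <= 12, "9-12", NA))))
  factor(lv, levels = c("1-4", "5-8", "9-12"))
}

#' @rdname habit_levels
#' @export
ratio_level <- function(x) {
  r <- round(x)
  r[!is.na(r) & (r < 0 | r > 9)] <- NA
  factor(ifelse(is.na(r), NA, paste0(r, ":1")),
         levels = paste0(0:9, ":1"))
}

#' Build the model-ready feature table
#'
#' Runs the full feature-engineering chain on a session stream: content
#' filtering (sleep / children sessions), cumulative habit features,
#' practice-period segmentation, forward-shifted outcomes, box-plot
#' trimming of cumulative session counts and session lengths, and
#' harmonization of counts and lengths to `bin_width`-unit bins. One row
#' per within-period transition: predictors from session j, outcome mood
#' from session j + 1.
#'
#' @param sessions session tibble (see [simulate_sessions()] for the
#'   schema).
#' @param users user covariate tibble with `user_id`, `continent`, `age`,
#'   `reason_*`, and `exp_*` columns.
#' @param gap_days practice-period gap threshold (days).
#' @param week_window trailing window for days/week (days).
#' @param bin_width harmonization width (minutes and sessions).
#' @param content_filter apply the sleep/children filter first.
#' @param trim apply box-plot trimming to cumulative session count and
#'   session length.
#' @return a tibble of feature rows with the attrition log (rows entering
#'   and leaving every filter) attached as `attr(, "attrition")`.
#' @export
build_feature_table <- function(sessions, users, gap_days = 7,
                                week_window = 7, bin_width = 5,
                                content_filter = TRUE, trim = TRUE) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble(stage = stage, rows_in = n_in,
                                      rows_out = n_out)
  }

  n0 <- nrow(sessions)
  if (content_filter) {
    sessions <- filter_excluded_content(sessions)
    note("content_filter", n0, nrow(sessions))
  }

  feats <- compute_habit_features(sessions, week_window)
  feats <- feats %>%
    group_by(.data$user_id) %>%
    mutate(.pos = row_number()) %>%
    ungroup()

  shifted <- shift_outcomes(sessions, gap_days)
  note("shift_outcomes", nrow(sessions), nrow(shifted))

  pred_cols <- feats %>%
    select("user_id", ".pos", "session_count", "days_since_last",
           "days_per_week", "extero_intero_ratio", "n_practice_types",
           "length_min", "practice_type", "worldview", "orientation",
           "focus", "time_of_day", "rating_score", "rating_count",
           "play_count", "attributions")
  rows <- shifted %>%
    left_join(pred_cols, by = c(user_id = "user_id",
                                predictor_pos = ".pos")) %>%
    left_join(users, by = "user_id")

  if (trim && nrow(rows) > 0) {
    keep <- trim_outliers(rows$session_count) &
      trim_outliers(rows$length_min)
    n_in <- nrow(rows)
    rows <- rows[keep, , drop = FALSE]
    note("boxplot_trim", n_in, nrow(rows))
  }

  # attribution indicator columns from the predictor session's tags
  for (tag in .attribution_tags) {
    col <- paste0("attr_", gsub("[^a-z]+", "_", tolower(tag)))
    rows[[col]] <- grepl(tag, rows$attributions, fixed = TRUE)
  }

  rows <- rows %>%
    mutate(
      session_count_raw = .data$session_count,
      session_count = harmonize(.data$session_count, bin_width),
      length_harmonized = harmonize(.data$length_min, bin_width),
      ratio_missing = is.na(.data$extero_intero_ratio),
      extero_intero_ratio_filled =
        ifelse(is.na(.data$extero_intero_ratio), 0,
               .data$extero_intero_ratio),
      rating_count_log10 = log10(1 + .data$rating_count),
      play_count_log10 = log10(1 + .data$play_count),
      days_per_week_f = days_per_week_level(.data$days_per_week),
      days_since_last_f = days_since_last_level(.data$days_since_last),
      length_f = length_level(.data$length_min),
      n_types_f = n_types_level(.data$n_practice_types),
      ratio_f = ratio_level(.data$extero_intero_ratio)
    ) %>%
    select(-"attributions")

  attr(rows, "attrition") <- bind_rows(log)
  rows
}
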