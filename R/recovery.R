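# Parameter-recovery diagnostics: coverage, bias, RMSE of replicate
# fits against the simulation's injected truth.

#' Summarize parameter recovery across seeded replicates
#'
#' For each injected true parameter, computes the mean estimate, bias,
#' RMSE, and the fraction of replicate 95% CIs covering the truth.
#'
#' @param truths named numeric vector of true parameter values.
#' @param replicates tibble with one row per replicate and parameter:
#'   columns `parameter`, `estimate`, `conf_low`, `conf_high`.
#' @param min_replicates smallest replicate count per parameter for a
#'   meaningful coverage estimate (default 20).
#' @return a tibble of class `recovery_report`: `parameter`, `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `coverage`, `n_replicates`.
#' @export
recovery_report <- function(truths, replicates, min_replicates = 20) {
  stopifnot(is.numeric(truths), !is.null(names(truths)))
  need <- c("parameter", "estimate", "conf_low", "conf_high")
  missing_cols <- setdiff(need, names(replicates))
  if (length(missing_cols))
    stop("replicates lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(replicates$parameter), names(truths))
  if (length(unknown))
    stop("no truth supplied for parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  out <- replicates %>%
    group_by(.data$parameter) %>%
    summarise(
      n_replicates = n(),
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - truths[.data$parameter[1]]),
      rmse = sqrt(mean((.data$estimate - truths[.data$parameter[1]])^2)),
      coverage = mean(.data$conf_low <= truths[.data$parameter[1]] &
                        .data$conf_high >= truths[.data$parameter[1]]),
      .groups = "drop"
    ) %>%
    mutate(truth = unname(truths[.data$parameter]), .after = "parameter")
  if (any(out$n_replicates < min_replicates))
    stop("coverage needs >= ", min_replicates,
         " seeded replicates per parameter", call. = FALSE)
  class(out) <- c("recovery_report", class(out))
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  NextMethod()
  invisible(x)
}
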