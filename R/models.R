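# Model layer: hierarchical linear mixed models (lme4), penalized
# thin-plate spline GAMMs (mgcv), adherence logistic regression, and
# Benjamini-Hochberg FDR adjustment. All intervals are Wald 95% CIs.

#' Specify a model over the feature table
#'
#' A light container naming the outcome, the predictor and covariate
#' columns, the grouping structure for random intercepts, optional smooth
#' terms, and the family. Columns are validated against the data at fit
#' time; a term that names a missing column raises an error naming it.
#'
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param covariates character vector of adjustment column names.
#' @param group random-intercept structure: `"user"` (intercept per
#'   user), `"continent_user"` (users nested within continent), or
#'   `"none"`.
#' @param smooths optional list of smooth terms, each a list with `var`
#'   (numeric column) and optionally `by` (stratifying factor column).
#' @param family `"gaussian"` or `"binomial"`.
#' @param missing_ratio how linear models handle the undefined
#'   exteroceptive:interoceptive ratio (no interoceptive sessions yet):
#'   `"indicator"` keeps the rows, replacing the ratio with its
#'   zero-filled version plus a missingness indicator; `"complete"`
#'   drops them.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome, predictors = character(),
                       covariates = character(),
                       group = c("user", "continent_user", "none"),
                       smooths = NULL,
                       family = c("gaussian", "binomial"),
                       missing_ratio = c("indicator", "complete")) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  structure(
    list(outcome = outcome, predictors = predictors,
         covariates = covariates, group = match.arg(group),
         smooths = smooths, family = match.arg(family),
         missing_ratio = match.arg(missing_ratio)),
    class = "model_spec"
  )
}

# expand terms, applying the missing-ratio policy; check columns exist
.spec_terms <- function(spec, data) {
  terms <- c(spec$predictors, spec$covariates)
  if (spec$missing_ratio == "indicator" &&
      "extero_intero_ratio" %in% terms &&
      all(c("extero_intero_ratio_filled", "ratio_missing") %in% names(data))) {
    terms <- setdiff(terms, "extero_intero_ratio")
    terms <- c(terms, "extero_intero_ratio_filled", "ratio_missing")
  }
  need <- unique(c(spec$outcome, terms,
                   vapply(spec$smooths, function(s)
                     c(s$var, s$by %||% s$var)[1], character(1)),
                   unlist(lapply(spec$smooths, function(s) s$by))))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("spec references columns not in the data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  terms
}

# error on zero-variance or aliased fixed-effect columns
.check_design <- function(formula_fixed, data) {
  mm <- model.matrix(formula_fixed, data)
  keep <- colnames(mm) != "(Intercept)"
  if (any(keep)) {
    v <- apply(mm[, keep, drop = FALSE], 2, function(x) diff(range(x)))
    if (any(v == 0))
      stop("zero-variance design column(s): ",
           paste(colnames(mm)[keep][v == 0], collapse = ", "),
           call. = FALSE)
  }
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(mm)
}

# Wald coefficient table with BH q-values
.wald_table <- function(est, se) {
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    conf_low = unname(est - qnorm(0.975) * se),
    conf_high = unname(est + qnorm(0.975) * se),
    statistic = unname(z), p_value = unname(p),
    q_value = fdr_adjust(unname(p))
  )
}

#' Fit a hierarchical linear mixed-effects model
#'
#' Gaussian mixed model with random intercepts per user, optionally
#' nested within continent (`group = "continent_user"` fits
#' `(1 | continent / user_id)`), via [lme4::lmer()] with REML. Fixed
#' effects get Wald 95% CIs, normal-approximation p-values, and BH FDR
#' q-values over the model's coefficient table.
#'
#' @param data feature table (see [build_feature_table()]).
#' @param spec a gaussian [model_spec()].
#' @return an object of class `medema_fit` with elements `terms`
#'   (coefficient tibble), `ranef_var`, `sigma`, `n_obs`, `n_users`,
#'   `converged`, `messages`, and the underlying `model`.
#' @export
fit_linear_mixed <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian")
    stop("fit_linear_mixed requires a gaussian spec", call. = FALSE)
  terms <- .spec_terms(spec, data)
  if (length(unique(data$user_id)) < 2)
    stop("need >= 2 users to fit random intercepts", call. = FALSE)
  if (spec$missing_ratio == "complete" &&
      "extero_intero_ratio" %in% terms)
    data <- data[!is.na(data$extero_intero_ratio), , drop = FALSE]

  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fixed <- as.formula(paste(spec$outcome, "~", rhs))
  used <- stats::complete.cases(
    data[, unique(c(spec$outcome, terms)), drop = FALSE])
  data <- data[used, , drop = FALSE]
  .check_design(fixed, data)

  re <- switch(spec$group,
               user = "(1 | user_id)",
               continent_user = "(1 | continent / user_id)",
               none = stop("fit_linear_mixed needs a grouping; use lm ",
                           "for a fixed-effects-only model", call. = FALSE))
  form <- as.formula(paste(spec$outcome, "~", rhs, "+", re))

  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- length(conv_msgs) == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      terms = .wald_table(est, se),
      ranef_var = tibble(group = vc$grp, variance = vc$vcov),
      sigma = stats::sigma(fit),
      n_obs = nrow(data),
      n_users = length(unique(data$user_id)),
      converged = converged,
      messages = c(msgs, conv_msgs),
      family = "gaussian", kind = "linear_mixed",
      spec = spec, model = fit
    ),
    class = "medema_fit"
  )
}

#' Fit a generalized additive mixed model with thin-plate splines
#'
#' Penalized thin-plate regression spline smooths of a numeric exposure
#' (typically the cumulative session count), optionally stratified by a
#' habit-level factor (`by`), with parametric covariate adjustment and a
#' user-level random intercept (`s(user, bs = "re")`). Smoothing
#' penalties are selected automatically by (f)REML. Each by-level's
#' session axis is truncated at the `cutoff_quantile` of its own support
#' so smooths are not extrapolated into sparse tails, and levels with
#' fewer than `min_level_n` rows are dropped with a warning.
#'
#' @param data feature table.
#' @param spec a [model_spec()] with at least one entry in `smooths`.
#' @param k basis dimension for each thin-plate smooth.
#' @param include_user_re include the per-user random intercept.
#' @param cutoff_quantile per-level support cutoff on the smooth axis
#'   (1 disables truncation).
#' @param min_level_n minimum rows required to keep a by-level.
#' @param grid_n evaluation-grid resolution for the exported smooths.
#' @return a `medema_fit` with parametric `terms`, a `smooths` tibble
#'   (term, level, x, fit, se, pointwise 95% CI), and `smooth_tests`
#'   (per-smooth EDF and p-value).
#' @export
fit_nonlinear_mixed <- function(data, spec, k = 20, include_user_re = TRUE,
                                cutoff_quantile = 0.99, min_level_n = 50,
                                grid_n = 100) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$smooths) || !length(spec$smooths))
    stop("spec has no smooth terms", call. = FALSE)
  terms <- .spec_terms(spec, data)

  data <- as.data.frame(data)
  data$user_f <- factor(data$user_id)

  smooth_bits <- character()
  for (s in spec$smooths) {
    if (!is.null(s$by)) {
      byv <- data[[s$by]]
      if (!is.factor(byv)) byv <- factor(byv)
      # drop unsupported levels, truncate each level's axis tail
      counts <- table(byv)
      low <- names(counts)[counts < min_level_n]
      if (length(low)) {
        warning("dropping level(s) of ", s$by,
                " with insufficient support: ",
                paste(low, collapse = ", "), call. = FALSE)
        data <- data[!(byv %in% low) & !is.na(byv), , drop = FALSE]
      } else {
        data <- data[!is.na(byv), , drop = FALSE]
      }
      data[[s$by]] <- droplevels(factor(data[[s$by]]))
      if (cutoff_quantile < 1) {
        cuts <- tapply(data[[s$var]], data[[s$by]], quantile,
                       probs = cutoff_quantile, na.rm = TRUE)
        data <- data[data[[s$var]] <=
                       unname(cuts[as.character(data[[s$by]])]), ,
                     drop = FALSE]
      }
      smooth_bits <- c(smooth_bits,
                       sprintf("s(%s, by = %s, bs = 'tp', k = %d)",
                               s$var, s$by, k),
                       s$by)
    } else {
      if (cutoff_quantile < 1) {
        cut <- quantile(data[[s$var]], cutoff_quantile, na.rm = TRUE)
        data <- data[!is.na(data[[s$var]]) & data[[s$var]] <= cut, ,
                     drop = FALSE]
      }
      smooth_bits <- c(smooth_bits,
                       sprintf("s(%s, bs = 'tp', k = %d)", s$var, k))
    }
  }
  if (include_user_re)
    smooth_bits <- c(smooth_bits, "s(user_f, bs = 're')")

  # degenerate input: a constant outcome has an exact flat fit that the
  # REML machinery cannot represent (zero residual variance)
  y <- data[[spec$outcome]]
  if (length(unique(na.omit(y))) == 1)
    return(.flat_gamm_result(data, spec, na.omit(y)[1], grid_n))

  rhs <- paste(c(if (length(terms)) terms else "1", smooth_bits),
               collapse = " + ")
  form <- as.formula(paste(spec$outcome, "~", rhs))

  big <- nrow(data) > 10000
  fit <- if (big) {
    mgcv::bam(form, data = data, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(form, data = data, method = "REML")
  }
  sm <- summary(fit)

  # parametric terms
  est <- sm$p.coeff
  se <- sm$se[seq_along(est)]
  names(se) <- names(est)
  term_tab <- .wald_table(est, se)

  # smooth-term tests (excluding the random-effect smooth)
  st <- as.data.frame(sm$s.table)
  st$term <- rownames(sm$s.table)
  smooth_tests <- as_tibble(st[!grepl("user_f", st$term),
                               c("term", "edf", "p-value")])
  names(smooth_tests) <- c("term", "edf", "p_value")

  # evaluation grids for plotting / recovery
  grids <- list()
  ref_row <- data[1, , drop = FALSE]
  for (s in spec$smooths) {
    if (!is.null(s$by)) {
      for (lev in levels(data[[s$by]])) {
        sub <- data[data[[s$by]] == lev, s$var]
        if (!length(sub)) next
        grids[[length(grids) + 1]] <-
          .smooth_grid(fit, ref_row, s$var, lev, s$by,
                       seq(min(sub), max(sub), length.out = grid_n))
      }
    } else {
      grids[[length(grids) + 1]] <-
        .smooth_grid(fit, ref_row, s$var, NA_character_, NULL,
                     seq(min(data[[s$var]], na.rm = TRUE),
                         max(data[[s$var]], na.rm = TRUE),
                         length.out = grid_n))
    }
  }

  structure(
    list(
      terms = term_tab,
      smooths = bind_rows(grids),
      smooth_tests = smooth_tests,
      n_obs = nrow(data),
      n_users = length(unique(data$user_id)),
      converged = fit$converged %||% TRUE,
      family = "gaussian", kind = "nonlinear_mixed",
      spec = spec, model = fit
    ),
    class = "medema_fit"
  )
}

# exact result for a constant outcome: intercept = the constant, every
# smooth identically zero with zero pointwise uncertainty
.flat_gamm_result <- function(data, spec, const, grid_n) {
  grids <- lapply(spec$smooths, function(s) {
    xs <- seq(min(data[[s$var]], na.rm = TRUE),
              max(data[[s$var]], na.rm = TRUE), length.out = grid_n)
    tibble(term = sprintf("s(%s)", s$var), level = NA_character_,
           x = xs, fit = 0, se = 0, conf_low = 0, conf_high = 0)
  })
  structure(
    list(
      terms = tibble(term = "(Intercept)", estimate = const, se = 0,
                     conf_low = const, conf_high = const,
                     statistic = Inf, p_value = 0, q_value = 0),
      smooths = bind_rows(grids),
      smooth_tests = tibble(term = vapply(spec$smooths, function(s)
        sprintf("s(%s)", s$var), character(1)), edf = 0,
        p_value = NA_real_),
      n_obs = nrow(data),
      n_users = length(unique(data$user_id)),
      converged = TRUE,
      family = "gaussian", kind = "nonlinear_mixed",
      spec = spec, model = NULL
    ),
    class = "medema_fit"
  )
}

# evaluate one smooth term on a grid, holding everything else at a
# reference row (type = "terms" isolates the smooth's contribution)
.smooth_grid <- function(fit, ref_row, var, level, by, xs) {
  nd <- ref_row[rep(1, length(xs)), , drop = FALSE]
  nd[[var]] <- xs
  if (!is.null(by)) nd[[by]] <- factor(level, levels = levels(ref_row[[by]]))
  label <- if (is.null(by)) sprintf("s(%s)", var)
           else sprintf("s(%s):%s%s", var, by, level)
  pr <- predict(fit, newdata = nd, type = "terms", se.fit = TRUE)
  cols <- colnames(pr$fit)
  col <- if (label %in% cols) label else grep(sprintf("s\\(%s\\)", var),
                                              cols, value = TRUE)[1]
  tibble(
    term = sprintf("s(%s)", var),
    level = level,
    x = xs,
    fit = pr$fit[, col],
    se = pr$se.fit[, col],
    conf_low = pr$fit[, col] - qnorm(0.975) * pr$se.fit[, col],
    conf_high = pr$fit[, col] + qnorm(0.975) * pr$se.fit[, col]
  )
}

#' Fit the adherence logistic regression
#'
#' Logistic regression of the long-term adherence label on first-N-session
#' habit features and covariates, reporting odds ratios with Wald 95% CIs,
#' p-values, and BH FDR q-values. Factor reference levels are the first
#' level of each factor (the level sets of [habit_levels]). Complete
#' separation is flagged on the result, not raised as an error.
#'
#' @param data adherence dataset (see [adherence_dataset()] or
#'   [simulate_adherence_cohort()]).
#' @param spec a binomial [model_spec()] whose outcome is the logical
#'   label column.
#' @return a `medema_fit`; `terms` carries log-odds estimates plus
#'   `odds_ratio`, `or_low`, `or_high` columns.
#' @export
fit_adherence_logit <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "binomial")
    stop("fit_adherence_logit requires a binomial spec", call. = FALSE)
  terms <- .spec_terms(spec, data)
  y <- data[[spec$outcome]]
  if (length(unique(na.omit(y))) < 2)
    stop("adherence label must contain both classes", call. = FALSE)

  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- as.formula(paste(spec$outcome, "~", rhs))
  used <- stats::complete.cases(
    data[, unique(c(spec$outcome, terms)), drop = FALSE])
  data <- data[used, , drop = FALSE]
  .check_design(form, data)

  msgs <- character()
  fit <- withCallingHandlers(
    stats::glm(form, data = data, family = stats::binomial()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separation <- any(grepl("fitted probabilities numerically 0 or 1",
                          msgs)) || any(abs(coef(fit)) > 15)

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tab <- .wald_table(est, se)
  tab$odds_ratio <- exp(tab$estimate)
  tab$or_low <- exp(tab$conf_low)
  tab$or_high <- exp(tab$conf_high)

  structure(
    list(
      terms = tab,
      n_obs = nrow(data),
      n_users = nrow(data),
      converged = fit$converged,
      separation = separation,
      messages = msgs,
      family = "binomial", kind = "adherence_logit",
      spec = spec, model = fit
    ),
    class = "medema_fit"
  )
}

#' @export
print.medema_fit <- function(x, ...) {
  cat(sprintf("<medema_fit: %s> %d rows, %d users%s\n",
              x$kind, x$n_obs, x$n_users,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (isTRUE(x$separation)) cat("  [possible complete separation]\n")
  print(x$terms, n = 10)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values for a vector of p-values: order-preserving,
#' capped at 1, with `q >= p` elementwise.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NAs allowed
#'   and propagated).
#' @return the q-values, same length and order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop("`pvalues` must be numeric", call. = FALSE)
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}
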