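#' Backward stepwise AIC selection of mediators in the outcome model
#'
#' Secondary-analysis variable selection: starting from the outcome model
#' containing the exposure, all candidate mediators and all confounders,
#' repeatedly evaluates every single-mediator deletion, removes the one
#' giving the largest AIC decrease, and stops when no deletion decreases the
#' AIC. Only mediators are eligible for removal; the exposure, confounders
#' and intercept are forced terms. AIC is computed under the independence
#' Gaussian likelihood of the ordinary linear model (\code{stats::lm} +
#' \code{stats::AIC}), the convention of standard stepwise tooling; the full
#' step trace makes the convention auditable. Ties in AIC are broken by
#' removing the mediator listed earliest in \code{mediators}, so selection is
#' deterministic.
#'
#' @param data analysis-ready data frame (processed mediators).
#' @param outcome outcome column name.
#' @param mediators candidate mediator names, in a fixed order.
#' @param forced regressors never removed (exposure and confounders).
#' @param exposure exposure name, always part of \code{forced}.
#' @return object of class \code{"selection_trace"}: \code{steps} (data
#'   frame: step, removed, aic_before, aic_after), \code{retained},
#'   \code{initial_aic}, \code{final_aic}, \code{outcome}.
#' @export
backward_stepwise_aic <- function(data, outcome, mediators,
                                  forced = c("apoe2", "age_enroll", "sex",
                                             "education", "bmi", "lipid_med",
                                             "generation"),
                                  exposure = "apoe2") {
  forced <- union(exposure, forced)
  current <- mediators
  fit_aic <- function(meds) {
    f <- med_formula(outcome, c(forced, meds))
    m <- stats::lm(f, data)
    if (any(is.na(stats::coef(m))))
      stop("outcome model is not estimable (aliased coefficients)")
    stats::AIC(m)
  }
  aic_cur <- fit_aic(current)
  initial_aic <- aic_cur
  steps <- data.frame(step = integer(), removed = character(),
                      aic_before = numeric(), aic_after = numeric(),
                      stringsAsFactors = FALSE)
  step_no <- 0L
  while (length(current)) {
    cand_aic <- vapply(seq_along(current), function(i)
      fit_aic(current[-i]), numeric(1))
    best <- which.min(cand_aic)          # first minimum = earliest mediator
    if (cand_aic[best] >= aic_cur) break
    step_no <- step_no + 1L
    steps <- rbind(steps, data.frame(
      step = step_no, removed = current[best],
      aic_before = aic_cur, aic_after = cand_aic[best],
      stringsAsFactors = FALSE))
    aic_cur <- cand_aic[best]
    current <- current[-best]
  }
  structure(list(steps = steps, retained = current,
                 initial_aic = initial_aic, final_aic = aic_cur,
                 outcome = outcome, candidates = mediators),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, digits = 2, ...) {
  cat("Backward stepwise AIC selection for", x$outcome, "\n")
  cat("  candidates:", length(x$candidates),
      " retained:", length(x$retained), "\n")
  cat("  AIC:", format(x$initial_aic, digits = 8), "->",
      format(x$final_aic, digits = 8), "in", nrow(x$steps), "step(s)\n")
  if (nrow(x$steps))
    print(format(x$steps, digits = digits), row.names = FALSE)
  if (length(x$retained))
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection trace as CSV
#'
#' @param trace a \code{selection_trace}.
#' @param path output path.
#' @return the steps table, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.csv(trace$steps, path, row.names = FALSE)
  invisible(trace$steps)
}

#' Secondary mediation analysis after mediator selection
#'
#' Runs \code{\link{backward_stepwise_aic}} on the outcome model, then
#' re-runs the full mediation analysis (\code{\link{medgee}}) using only the
#' retained mediators. Selection is performed once, on the full analysis
#' sample; the bootstrap keeps the retained set fixed across replicates. An
#' empty retained set is legal: the decomposition then reduces to direct =
#' total, combined indirect = 0, mediated proportion = 0.
#'
#' @inheritParams medgee
#' @return list with \code{trace} (the \code{selection_trace}) and
#'   \code{fit} (a \code{medgee} on the retained set).
#' @export
medgee_secondary <- function(data, outcome, mediators, exposure = "apoe2",
                             confounders = c("age_enroll", "sex", "education",
                                             "bmi", "lipid_med", "generation"),
                             cluster = "family_id",
                             engine = c("gee", "ols"),
                             total_threshold = 0.1) {
  engine <- match.arg(engine)
  trace <- backward_stepwise_aic(data, outcome, mediators,
                                 forced = c(exposure, confounders),
                                 exposure = exposure)
  # an empty retained set is legal: the fit degenerates to direct = total
  fit <- medgee(data, outcome = outcome, mediators = trace$retained,
                exposure = exposure, confounders = confounders,
                cluster = cluster, engine = engine,
                total_threshold = total_threshold)
  list(trace = trace, fit = fit)
}
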