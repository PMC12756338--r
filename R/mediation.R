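bq <- function(x) sprintf("`%s`", x)   # backtick names like "CE 18:3"

med_formula <- function(response, rhs) {
  stats::as.formula(paste(bq(response), "~", paste(bq(rhs), collapse = " + ")),
                    env = baseenv())
}

#' Multiple-mediator causal mediation analysis in clustered data
#'
#' The central fitting function. For one continuous outcome it fits, on the
#' same analysis sample, (i) one marginal linear mediator regression per
#' mediator (mediator ~ exposure + confounders) and (ii) one outcome
#' regression (outcome ~ exposure + all mediators + confounders), both by
#' Gaussian GEE with an exchangeable working correlation over clusters
#' (\code{\link{gee_gaussian}}), and combines them by the
#' product-of-coefficients method: the indirect effect through mediator k is
#' \eqn{\delta_k = \alpha_k \beta_k} (exposure coefficient of mediator model
#' k times mediator-k coefficient of the outcome model), the direct effect
#' \eqn{\theta} is the exposure coefficient of the outcome model, the
#' combined indirect effect is \eqn{\Delta = \sum_k \delta_k}, the total
#' effect is \eqn{\tau = \theta + \Delta}, and the mediated proportion is
#' \eqn{\Delta / \tau}. A negative indirect effect is protective (the pathway
#' reduces the outcome time); a positive one is deleterious. No
#' exposure-mediator interaction terms are included.
#'
#' Confidence intervals come from a family bootstrap; see
#' \code{\link{boot_medgee}} and \code{\link{confint.medgee}}.
#'
#' @param data analysis-ready data frame: exposure coded 0/1, mediators
#'   already log-transformed and standardized (see
#'   \code{\link{preprocess_mediators}}), complete cases.
#' @param outcome outcome column name (e.g. \code{"think_time"}).
#' @param mediators mediator column names.
#' @param exposure exposure column name (0 = reference group).
#' @param confounders confounder column names adjusted for in both model
#'   sets.
#' @param cluster cluster (family) id column name.
#' @param engine \code{"gee"} (exchangeable working correlation, default) or
#'   \code{"ols"} (independence working correlation; point estimates equal
#'   ordinary least squares, standard errors remain cluster-robust).
#' @param total_threshold absolute total effect (seconds) below which the
#'   mediated proportion is flagged numerically unstable.
#' @return an object of class \code{"medgee"}: the decomposition
#'   (\code{effects}), per-mediator indirect effects (\code{indirect}), the
#'   fitted \code{gee_fit} objects, and the data/variable bookkeeping used by
#'   the bootstrap.
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 80, n_mediators = 3, seed = 2))
#' d <- preprocess_mediators(sim$cohort, sim$truth$mediators)
#' fit <- medgee(d, outcome = "think_time", mediators = sim$truth$mediators)
#' fit
#' @export
medgee <- function(data, outcome, mediators, exposure = "apoe2",
                   confounders = c("age_enroll", "sex", "education", "bmi",
                                   "lipid_med", "generation"),
                   cluster = "family_id",
                   engine = c("gee", "ols"),
                   total_threshold = 0.1) {
  engine <- match.arg(engine)
  vars <- c(outcome, mediators, exposure, confounders, cluster)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  corstr <- if (engine == "gee") "exchangeable" else "independence"

  mediator_fits <- lapply(mediators, function(m)
    gee_gaussian(med_formula(m, c(exposure, confounders)), data,
                 cluster = cluster, corstr = corstr))
  names(mediator_fits) <- mediators
  outcome_fit <- gee_gaussian(
    med_formula(outcome, c(exposure, mediators, confounders)), data,
    cluster = cluster, corstr = corstr)

  not_conv <- !vapply(c(mediator_fits, list(outcome_fit)),
                      function(f) f$converged, logical(1))
  if (any(not_conv)) stop("GEE did not converge for ",
                          sum(not_conv), " model(s)")

  dec <- decompose_effects(mediator_fits, outcome_fit, exposure = exposure,
                           mediators = mediators,
                           total_threshold = total_threshold)
  dec$outcome <- outcome
  structure(c(dec, list(
    mediator_fits = mediator_fits, outcome_fit = outcome_fit,
    data = data, exposure = exposure, mediators = mediators,
    confounders = confounders, cluster = cluster, engine = engine,
    total_threshold = total_threshold, call = match.call())),
    class = "medgee")
}

#' Product-method effect decomposition from fitted models
#'
#' Combines a list of mediator-model fits and one outcome-model fit into
#' direct, per-mediator indirect, combined indirect and total effects and the
#' mediated proportion. Pure arithmetic on coefficients; the identities
#' total = direct + combined and combined = sum of per-mediator indirects
#' hold exactly by construction.
#'
#' @param mediator_fits named list of \code{gee_fit}s, one per mediator, each
#'   containing the exposure coefficient.
#' @param outcome_fit \code{gee_fit} containing the exposure and all mediator
#'   coefficients.
#' @param exposure exposure coefficient name.
#' @param mediators mediator names; must match \code{names(mediator_fits)}
#'   and appear in the outcome fit.
#' @param total_threshold instability threshold for the mediated proportion.
#' @return list: \code{direct}, \code{indirect} (named), \code{alpha},
#'   \code{beta} (the components), \code{combined_indirect}, \code{total},
#'   \code{prop_mediated}, \code{unstable_total}.
#' @export
decompose_effects <- function(mediator_fits, outcome_fit, exposure,
                              mediators = names(mediator_fits),
                              total_threshold = 0.1) {
  if (!setequal(mediators, names(mediator_fits)))
    stop("mediator_fits must contain exactly one fit per mediator")
  oc <- stats::coef(outcome_fit)
  miss <- setdiff(mediators, names(oc))
  if (length(miss))
    stop("outcome model lacks mediator coefficient(s): ",
         paste(miss, collapse = ", "))
  if (!exposure %in% names(oc))
    stop("outcome model lacks the exposure coefficient '", exposure, "'")
  alpha <- vapply(mediators, function(m) {
    cm <- stats::coef(mediator_fits[[m]])
    if (!exposure %in% names(cm))
      stop("mediator model '", m, "' lacks the exposure coefficient")
    cm[[exposure]]
  }, numeric(1))
  beta <- oc[mediators]
  names(beta) <- mediators
  indirect <- alpha * beta
  direct <- oc[[exposure]]
  combined <- sum(indirect)
  total <- direct + combined
  list(direct = direct, indirect = indirect, alpha = alpha, beta = beta,
       combined_indirect = combined, total = total,
       prop_mediated = if (total != 0) combined / total else NA_real_,
       unstable_total = abs(total) < total_threshold)
}

#' Difference-method estimate of the combined indirect effect
#'
#' Independent check on the product method: fits the outcome model without
#' and with the mediators by ordinary least squares (\code{stats::lm}) on the
#' same sample and returns the drop in the exposure coefficient. For linear
#' models with no exposure-mediator interaction this equals the
#' product-method combined indirect effect exactly when the mediator models
#' are also least squares on the same sample; with the exchangeable-GEE
#' engine the two agree only approximately.
#'
#' @inheritParams medgee
#' @return the difference of the exposure coefficients (without - with
#'   mediators).
#' @export
difference_method <- function(data, outcome, mediators, exposure = "apoe2",
                              confounders = c("age_enroll", "sex", "education",
                                              "bmi", "lipid_med",
                                              "generation")) {
  f_without <- med_formula(outcome, c(exposure, confounders))
  f_with <- med_formula(outcome, c(exposure, mediators, confounders))
  c_without <- stats::coef(stats::lm(f_without, data))[[exposure]]
  c_with <- stats::coef(stats::lm(f_with, data))[[exposure]]
  c_without - c_with
}

#' @export
print.medgee <- function(x, digits = 3, ...) {
  cat("Causal mediation analysis (", x$engine, " engine): ",
      x$outcome, "\n", sep = "")
  cat("  ", length(x$mediators), " mediators, ",
      x$outcome_fit$n_obs, " participants in ",
      x$outcome_fit$n_clusters, " families\n", sep = "")
  eff <- c(`Direct effect` = x$direct,
           `Combined indirect effect` = x$combined_indirect,
           `Total effect` = x$total)
  for (i in seq_along(eff))
    cat(sprintf("  %-26s %8.*f s\n", names(eff)[i], digits, eff[i]))
  cat(sprintf("  %-26s %7s%%%s\n", "Mediated proportion",
              format_percent(x$prop_mediated),
              if (isTRUE(x$unstable_total)) "  [unstable: |total| small]"
              else ""))
  invisible(x)
}

format_percent <- function(p) {
  if (is.na(p)) return("NA")
  sprintf("%.0f", 100 * p)
}

#' @export
coef.medgee <- function(object, ...) {
  c(direct = object$direct,
    stats::setNames(object$indirect, paste0("indirect_", object$mediators)),
    combined_indirect = object$combined_indirect, total = object$total,
    prop_mediated = object$prop_mediated)
}

#' @export
summary.medgee <- function(object, ...) {
  ind <- data.frame(mediator = object$mediators,
                    alpha = object$alpha, beta = object$beta,
                    indirect = object$indirect, row.names = NULL)
  structure(list(outcome = object$outcome, engine = object$engine,
                 effects = coef(object), indirect_table = ind,
                 outcome_fit = summary(object$outcome_fit),
                 unstable_total = object$unstable_total),
            class = "summary.medgee")
}

#' @export
print.summary.medgee <- function(x, digits = 3, ...) {
  cat("Mediation decomposition for", x$outcome, "(engine:", x$engine, ")\n\n")
  cat("Per-mediator indirect effects (alpha = exposure->mediator,",
      "beta = mediator->outcome):\n")
  print(format(x$indirect_table, digits = digits), row.names = FALSE)
  cat("\nDirect ", format(x$effects[["direct"]], digits = digits),
      ", combined indirect ",
      format(x$effects[["combined_indirect"]], digits = digits),
      ", total ", format(x$effects[["total"]], digits = digits),
      ", mediated proportion ",
      format_percent(x$effects[["prop_mediated"]]), "%\n", sep = "")
  invisible(x)
}

#' Forest-style plot of per-mediator indirect effects
#'
#' Base-graphics dot plot of the indirect effect of the exposure through each
#' mediator, with bootstrap percentile intervals when a \code{medgee_boot}
#' result is supplied. Negative values are protective pathways (they reduce
#' the outcome time).
#'
#' @param x a \code{medgee} fit.
#' @param boot optional \code{\link{boot_medgee}} result for intervals.
#' @param ... passed to \code{plot}.
#' @export
plot.medgee <- function(x, boot = NULL, ...) {
  k <- length(x$mediators)
  ord <- order(x$indirect)
  est <- x$indirect[ord]
  lab <- x$mediators[ord]
  xlim <- range(0, est)
  lo <- hi <- NULL
  if (!is.null(boot)) {
    ci <- boot$ci
    rows <- match(paste0("indirect_", lab), ci$quantity)
    lo <- ci$ci_low[rows]; hi <- ci$ci_high[rows]
    xlim <- range(0, lo, hi)
  }
  op <- graphics::par(mar = c(4, 9, 2, 1)); on.exit(graphics::par(op))
  plot(est, seq_len(k), yaxt = "n", ylab = "",
       xlab = "indirect effect (s)", xlim = xlim,
       pch = 19, main = x$outcome, ...)
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  if (!is.null(lo))
    graphics::segments(lo, seq_len(k), hi, seq_len(k))
  invisible(x)
}
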