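#' Efron percentile confidence interval
#'
#' Empirical quantiles at (1-level)/2 and 1-(1-level)/2 of a vector of
#' bootstrap replicate estimates, using the linear-interpolation quantile
#' definition (\code{stats::quantile} type 7). The convention is fixed and
#' documented because quantile definitions differ across software.
#'
#' @param values numeric vector of replicate estimates (non-empty; NAs from
#'   failed replicates are removed).
#' @param level confidence level in (0,1).
#' @return numeric vector \code{c(lower, upper)}.
#' @examples
#' percentile_ci(1:100, 0.95)  # c(3.475, 97.525)
#' @export
percentile_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing replicate values")
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)")
  a <- (1 - level) / 2
  unname(stats::quantile(values, c(a, 1 - a), type = 7))
}

#' Family (cluster) bootstrap for the mediation decomposition
#'
#' Resamples clusters (families) with replacement -- the same number of
#' families as observed -- concatenates their members, re-runs the entire
#' estimation (all mediator regressions, the outcome regression, and the
#' product-method decomposition) on each replicate, and forms Efron
#' percentile confidence intervals for every reported quantity: the direct
#' effect, each per-mediator indirect effect, the combined indirect effect,
#' the total effect, and the mediated proportion. Resampled copies of a
#' family are treated as distinct clusters. A quantity is flagged significant
#' when its interval excludes zero; the mediated proportion, a ratio with
#' possibly wide and sign-crossing intervals, carries no significance flag.
#'
#' Mediator standardization is not redone inside replicates by default: the
#' transform is treated as fixed from the original analysis sample
#' (\code{restandardize = TRUE} re-z-scores the mediator columns within each
#' replicate). Replicates in which any model fails to converge are dropped
#' and counted; more than \code{max_fail_frac} failures is an error.
#'
#' @param fit a \code{\link{medgee}} fit.
#' @param reps number of bootstrap replicates (study convention: 1500).
#' @param level confidence level.
#' @param seed integer seed; replicate resampling draws are generated
#'   up-front from this seed so results are reproducible and independent of
#'   evaluation order.
#' @param resample_unit \code{"family"} (default) or \code{"individual"};
#'   individual resampling ignores the family structure and is provided for
#'   sensitivity checks only.
#' @param restandardize re-standardize mediator columns within each
#'   replicate.
#' @param max_fail_frac maximum tolerated fraction of failed replicates.
#' @return object of class \code{"medgee_boot"}: \code{estimates} (point
#'   estimates), \code{replicates} (reps x quantities matrix), \code{ci}
#'   (data frame: quantity, estimate, ci_low, ci_high, significant),
#'   \code{n_failed}, \code{reps}, \code{level}, \code{seed}.
#' @export
boot_medgee <- function(fit, reps = 1500L, level = 0.95, seed = 1L,
                        resample_unit = c("family", "individual"),
                        restandardize = FALSE, max_fail_frac = 0.01) {
  stopifnot(inherits(fit, "medgee"))
  resample_unit <- match.arg(resample_unit)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1")
  data <- fit$data
  cl_vals <- as.character(data[[fit$cluster]])
  data[[fit$cluster]] <- cl_vals
  fams <- unique(cl_vals)
  if (length(fams) < 2L) stop("need at least 2 families to bootstrap")
  idx_by_fam <- split(seq_len(nrow(data)), factor(cl_vals, levels = fams))

  point <- coef(fit)
  qnames <- names(point)

  set.seed(as.integer(seed))
  draws <- if (resample_unit == "family") {
    matrix(sample.int(length(fams), length(fams) * reps, replace = TRUE),
           nrow = reps)
  } else {
    matrix(sample.int(nrow(data), nrow(data) * reps, replace = TRUE),
           nrow = reps)
  }

  # Design matrices are built once on the original sample; each replicate
  # re-runs the identical estimation (gee_core per mediator model, gee_core
  # for the outcome model, product-method arithmetic) on resampled rows.
  corstr <- if (fit$engine == "gee") "exchangeable" else "independence"
  unquote <- function(x) gsub("^`|`$", "", x)
  Xm <- stats::model.matrix(
    med_formula("..boot_lhs", c(fit$exposure, fit$confounders))[-2], data)
  Xo <- stats::model.matrix(
    med_formula("..boot_lhs",
                c(fit$exposure, fit$mediators, fit$confounders))[-2], data)
  colnames(Xm) <- unquote(colnames(Xm))
  colnames(Xo) <- unquote(colnames(Xo))
  M <- as.matrix(data[, fit$mediators, drop = FALSE])
  y <- data[[fit$outcome]]
  k <- length(fit$mediators)

  one_rep <- function(b) {
    if (resample_unit == "family") {
      picked <- draws[b, ]
      rows <- unlist(idx_by_fam[picked], use.names = FALSE)
      # distinct cluster ids for repeated families
      id <- rep(seq_along(picked), lengths(idx_by_fam[picked]))
    } else {
      rows <- draws[b, ]
      id <- seq_along(rows)
    }
    Xm_b <- Xm[rows, , drop = FALSE]
    Xo_b <- Xo[rows, , drop = FALSE]
    M_b <- M[rows, , drop = FALSE]
    if (restandardize && k > 0) {
      M_b <- scale(M_b)
      Xo_b[, fit$mediators] <- M_b
    }
    alpha <- numeric(k)
    for (j in seq_len(k)) {
      mf <- gee_core(Xm_b, M_b[, j], id, corstr = corstr, sandwich = FALSE)
      if (!mf$converged) stop("mediator model did not converge")
      alpha[j] <- mf$coefficients[[fit$exposure]]
    }
    of <- gee_core(Xo_b, y[rows], id, corstr = corstr, sandwich = FALSE)
    if (!of$converged) stop("outcome model did not converge")
    theta <- of$coefficients[[fit$exposure]]
    beta <- of$coefficients[fit$mediators]
    indirect <- alpha * beta
    combined <- sum(indirect)
    total <- theta + combined
    c(theta, indirect, combined, total,
      if (total != 0) combined / total else NA_real_)
  }

  reps_mat <- matrix(NA_real_, reps, length(qnames),
                     dimnames = list(NULL, qnames))
  n_failed <- 0L
  for (b in seq_len(reps)) {
    val <- tryCatch(one_rep(b), error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1L else reps_mat[b, ] <- val
  }
  if (n_failed > max_fail_frac * reps)
    stop(n_failed, " of ", reps, " bootstrap replicates failed (> ",
         100 * max_fail_frac, "% tolerated)")

  ci <- t(apply(reps_mat, 2, percentile_ci, level = level))
  tab <- data.frame(quantity = qnames, estimate = unname(point),
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    significant = ci[, 1] > 0 | ci[, 2] < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$significant[tab$quantity == "prop_mediated"] <- NA
  structure(list(estimates = point, replicates = reps_mat, ci = tab,
                 n_failed = n_failed, reps = reps, level = level,
                 seed = seed, resample_unit = resample_unit,
                 outcome = fit$outcome),
            class = "medgee_boot")
}

#' @export
print.medgee_boot <- function(x, digits = 3, ...) {
  cat("Family bootstrap (", x$reps, " replicates, ",
      round(100 * x$level), "% percentile CIs) for ", x$outcome, "\n",
      sep = "")
  if (x$n_failed > 0)
    cat("  ", x$n_failed, " replicate(s) failed and were excluded\n", sep = "")
  main <- x$ci[x$ci$quantity %in%
                 c("direct", "combined_indirect", "total", "prop_mediated"), ]
  print(format(main, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Bootstrap percentile confidence intervals for a mediation fit
#'
#' Runs (or reuses) the family bootstrap and returns the percentile interval
#' for every decomposition quantity.
#'
#' @param object a \code{medgee} fit.
#' @param parm quantities to keep (default all).
#' @param level confidence level.
#' @param boot optional precomputed \code{\link{boot_medgee}} result.
#' @param ... passed to \code{\link{boot_medgee}} (e.g. \code{reps},
#'   \code{seed}).
#' @return matrix with columns \code{lower}, \code{upper}.
#' @export
confint.medgee <- function(object, parm, level = 0.95, boot = NULL, ...) {
  if (is.null(boot)) boot <- boot_medgee(object, level = level, ...)
  ci <- boot$ci
  m <- as.matrix(ci[, c("ci_low", "ci_high")])
  dimnames(m) <- list(ci$quantity,
                      paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                             " %"))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}
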