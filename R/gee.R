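#' Marginal linear model by GEE with exchangeable working correlation
#'
#' Fits a Gaussian identity-link marginal model by generalized estimating
#' equations, with an exchangeable (compound-symmetric) working correlation
#' within clusters and cluster-robust (sandwich) standard errors. This is the
#' estimation engine used for both the mediator regressions and the outcome
#' regressions of the mediation analysis: point estimates account for the
#' working correlation, while inference relies on the robust variance, so the
#' standard errors are valid even if the exchangeable structure is wrong.
#'
#' The working correlation parameter is re-estimated at every iteration by the
#' usual moment estimator over all within-cluster pairs of Pearson residuals,
#' and the scale (residual variance) uses the bias-corrected denominator
#' \eqn{n - p}. Coefficients are updated by iteratively reweighted estimating
#' equations until the largest absolute coefficient change falls below
#' \code{tol}. With every cluster of size one the working correlation is
#' irrelevant and the fit coincides with ordinary least squares.
#'
#' @param formula model formula (identity link, Gaussian working variance).
#' @param data a data frame containing all model variables and the cluster id.
#' @param cluster cluster (family) identifier: a one-sided formula such as
#'   \code{~ family_id}, a column name, or a vector of length \code{nrow(data)}.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param maxit maximum number of iterations.
#' @param corstr working correlation: \code{"exchangeable"} (default) or
#'   \code{"independence"}.
#' @return An object of class \code{"gee_fit"}: coefficients, robust
#'   (sandwich) standard errors and variance matrix, estimated working
#'   correlation \code{rho}, scale estimate, cluster counts, convergence
#'   information, and the usual model components for \code{predict} and
#'   \code{residuals}.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 60, n_mediators = 2,
#'                                      seed = 1))$cohort
#' fit <- gee_gaussian(think_time ~ apoe2 + age_enroll + sex, cohort,
#'                     cluster = ~family_id)
#' summary(fit)
#' @export
gee_gaussian <- function(formula, data, cluster, tol = 1e-8, maxit = 100L,
                         corstr = c("exchangeable", "independence")) {
  corstr <- match.arg(corstr)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- resolve_cluster(cluster, data)
  if (length(id) != length(y))
    stop("cluster identifier must have one entry per row of 'data'")
  id <- factor(id, levels = unique(id))

  core <- gee_core(X, y, id, tol = tol, maxit = maxit, corstr = corstr,
                   sandwich = TRUE)
  # drop the backticks model.matrix adds around non-syntactic column names
  # (e.g. "CE 18:3") so coefficients are addressable by the plain name
  unquote <- function(x) gsub("^`|`$", "", x)
  names(core$coefficients) <- unquote(names(core$coefficients))
  names(core$robust.se) <- unquote(names(core$robust.se))
  dimnames(core$vcov) <- lapply(dimnames(core$vcov), unquote)
  structure(c(core, list(
    formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf), call = cl
  )), class = "gee_fit")
}

# Estimation core on a prebuilt design matrix. Used directly by the
# bootstrap, which refits the same models on resampled rows thousands of
# times; the formula interface above is a thin wrapper. `id` may be a factor
# or an integer/character group vector.
gee_core <- function(X, y, id, tol = 1e-8, maxit = 100L,
                     corstr = "exchangeable", sandwich = TRUE) {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient; drop collinear regressors")
  if (!is.factor(id)) id <- factor(id, levels = unique(id))
  K <- nlevels(id)
  if (K < 2L) stop("need at least 2 clusters for cluster-robust estimation")
  csize <- tabulate(id)
  max_n <- max(csize)
  n_pairs <- sum(csize * (csize - 1)) / 2

  # the exchangeable inverse ((1-rho)I + rho J)^{-1} = (I - c J)/(1-rho)
  # with c = rho/(1+(n_i-1)rho) lets every crossproduct be formed from
  # rowsum() cluster totals, with no per-cluster loop.
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  Xs <- rowsum(X, id)                    # K x p cluster column sums
  ys <- rowsum(y, id)

  beta <- solve(XtX, Xty)                # OLS start (exact when rho = 0)
  rho <- 0
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    r <- as.vector(y - X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable" && n_pairs > 0) {
      e <- r / sqrt(phi)
      S <- rowsum(e, id)
      Q <- rowsum(e^2, id)
      denom <- n_pairs - p
      if (denom <= 0) denom <- n_pairs
      rho <- sum(S^2 - Q) / 2 / denom
      lo <- -1 / (max_n - 1) + 1e-6
      rho <- min(max(rho, if (max_n > 1L) lo else 0), 1 - 1e-6)
    } else rho <- 0
    cw <- rho / (1 + (csize - 1) * rho)  # per-cluster off-diagonal weight
    A <- XtX - crossprod(Xs, Xs * cw)
    b <- Xty - crossprod(Xs, ys * cw)
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }

  coefs <- as.vector(beta)
  names(coefs) <- colnames(X)
  out <- list(coefficients = coefs, rho = rho, n_obs = n, n_clusters = K,
              cluster_sizes = csize, converged = converged,
              iterations = iter, corstr = corstr)
  r <- as.vector(y - X %*% beta)
  phi <- sum(r^2) / (n - p)
  out$scale <- phi
  out$fitted.values <- as.vector(X %*% beta)
  out$residuals <- r
  if (sandwich) {
    cw <- rho / (1 + (csize - 1) * rho)
    A <- XtX - crossprod(Xs, Xs * cw)
    bread_inv <- solve(A / (phi * (1 - rho)))
    # cluster score contributions g_i = X_i' V_i^{-1} r_i, vectorized
    Xr <- rowsum(X * r, id)
    rs <- rowsum(r, id)
    G <- (Xr - Xs * (cw * as.vector(rs))) / (phi * (1 - rho))
    vcov_rob <- bread_inv %*% crossprod(G) %*% bread_inv
    se <- sqrt(diag(vcov_rob))
    names(se) <- colnames(X)
    dimnames(vcov_rob) <- list(colnames(X), colnames(X))
    out$robust.se <- se
    out$vcov <- vcov_rob
  }
  out
}

resolve_cluster <- function(cluster, data) {
  if (inherits(cluster, "formula")) {
    v <- all.vars(cluster)
    if (length(v) != 1L) stop("cluster formula must name exactly one variable")
    if (!v %in% names(data)) stop("cluster variable '", v, "' not found in data")
    data[[v]]
  } else if (is.character(cluster) && length(cluster) == 1L &&
             cluster %in% names(data)) {
    data[[cluster]]
  } else cluster
}

#' Two-sided Wald p-value for a GEE coefficient
#'
#' Normal-reference p-value computed from the coefficient estimate and its
#' cluster-robust standard error.
#'
#' @param fit a \code{gee_fit}.
#' @param coefficient coefficient name.
#' @return two-sided p-value.
#' @export
wald_pvalue <- function(fit, coefficient) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!coefficient %in% names(fit$coefficients))
    stop("unknown coefficient: ", coefficient)
  z <- fit$coefficients[[coefficient]] / fit$robust.se[[coefficient]]
  2 * stats::pnorm(-abs(z))
}

#' @export
print.gee_fit <- function(x, digits = 4, ...) {
  cat("Gaussian GEE (", x$corstr, " working correlation)\n", sep = "")
  cat("  ", x$n_obs, " observations in ", x$n_clusters, " clusters",
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  working correlation rho =", format(x$rho, digits = digits),
      " scale =", format(x$scale, digits = digits), "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  z <- object$coefficients / object$robust.se
  tab <- cbind(Estimate = object$coefficients,
               `Robust SE` = object$robust.se,
               z = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, rho = object$rho, scale = object$scale,
                 n_obs = object$n_obs, n_clusters = object$n_clusters,
                 converged = object$converged, iterations = object$iterations,
                 corstr = object$corstr, call = object$call),
            class = "summary.gee_fit")
}

#' @export
print.summary.gee_fit <- function(x, digits = 4, ...) {
  cat("Gaussian GEE, ", x$corstr, " working correlation\n", sep = "")
  cat(x$n_obs, "observations,", x$n_clusters, "clusters;",
      "rho =", format(x$rho, digits = digits),
      "; scale =", format(x$scale, digits = digits), "\n")
  if (!x$converged) cat("WARNING: did not converge in", x$iterations,
                        "iterations\n")
  stats::printCoefmat(x$coefficients, digits = digits, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
residuals.gee_fit <- function(object, ...) object$residuals

#' @export
fitted.gee_fit <- function(object, ...) object$fitted.values

#' @export
predict.gee_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  as.vector(X %*% object$coefficients)
}

#' Export a coefficient table
#'
#' Writes term, estimate, robust SE and Wald p-value of a fitted GEE model to
#' CSV, the machine-readable shape of supplementary regression tables.
#'
#' @param fit a \code{gee_fit}.
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_gee_summary <- function(fit, path) {
  s <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(s), estimate = s[, "Estimate"],
                    robust_se = s[, "Robust SE"], p = s[, "Pr(>|z|)"],
                    row.names = NULL)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
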