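# shared fixtures: all synthetic, built in code at test time

# small analysis-ready cohort (processed mediators) plus its truth
small_sim <- function(n_families = 80, k = 3, seed = 1, ...) {
  cfg <- sim_config(n_families = n_families, n_mediators = k, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  d <- preprocess_mediators(sim$cohort, sim$truth$mediators)
  list(data = d, truth = sim$truth, mediators = sim$truth$mediators,
       cohort = sim$cohort, config = cfg)
}

# formula builder for syntactic column names
med_f <- function(data, response, rhs) {
  stats::as.formula(paste(response, "~",
                          if (length(rhs)) paste(rhs, collapse = " + ")
                          else "1"))
}

# a gee_fit shell carrying fixed coefficients, for exercising the
# decomposition arithmetic on known inputs
pseudo_fit <- function(coefs) {
  structure(list(coefficients = coefs,
                 robust.se = rep(1, length(coefs)),
                 converged = TRUE),
            class = "gee_fit")
}

# decomposition from plain numbers: direct effect plus named per-mediator
# (alpha, beta) pairs routed through the real decompose_effects()
decompose_from_numbers <- function(direct, alpha, beta, exposure = "apoe2") {
  stopifnot(length(alpha) == length(beta))
  meds <- names(alpha)
  mfits <- lapply(meds, function(m)
    pseudo_fit(stats::setNames(c(0, alpha[[m]]), c("(Intercept)", exposure))))
  names(mfits) <- meds
  ofit <- pseudo_fit(c(`(Intercept)` = 0,
                       stats::setNames(direct, exposure), beta))
  decompose_effects(mfits, ofit, exposure = exposure, mediators = meds)
}
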