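test_that("singleton-cluster GEE equals ordinary least squares", {
  set.seed(31)
  n <- 150
  d <- data.frame(y = rnorm(n), x = rnorm(n), z = rbinom(n, 1, 0.5),
                  id = seq_len(n))
  fit <- gee_gaussian(y ~ x + z, d, cluster = ~id)
  ols <- stats::lm(y ~ x + z, d)
  expect_lt(max(abs(coef(fit) - coef(ols))), 1e-8)
  expect_identical(fit$rho, 0)
  expect_true(fit$converged)
})

test_that("balanced-cluster intercept-only fit equals the grand mean", {
  sim <- simulate_cohort(sim_config(n_families = 120,
                                    family_size_range = c(4L, 4L),
                                    n_mediators = 1, seed = 32))
  fit <- gee_gaussian(think_time ~ 1, sim$cohort, cluster = ~family_id)
  expect_lt(abs(coef(fit)[[1]] - mean(sim$cohort$think_time)), 1e-8)
})

test_that("the moment estimator recovers the working correlation and the
           coefficients recover the truth", {
  sim <- simulate_cohort(sim_config(n_families = 500,
                                    family_size_range = c(4L, 4L),
                                    n_mediators = 1, rho_family = 0.5,
                                    seed = 33))
  d <- preprocess_mediators(sim$cohort, "lipid_01")
  fit <- gee_gaussian(
    think_time ~ apoe2 + lipid_01 + age_enroll + sex + education + bmi +
      lipid_med + generation, d, cluster = ~family_id)
  expect_lt(abs(fit$rho - 0.5), 0.05)
  expect_true(fit$rho > -1 / 3 && fit$rho < 1)
  expect_true(all(fit$robust.se > 0))
  # exposure (direct) and mediator (standardized-scale beta) coefficients
  expect_lt(abs(coef(fit)[["apoe2"]] - sim$truth$think$direct),
            4 * fit$robust.se[["apoe2"]])
  expect_lt(abs(coef(fit)[["lipid_01"]] - sim$truth$think$beta_std[[1]]),
            4 * fit$robust.se[["lipid_01"]])
})

test_that("exchangeable and independence fits agree when rho is zero", {
  sim <- simulate_cohort(sim_config(n_families = 400, n_mediators = 1,
                                    rho_family = 0, seed = 34))
  d <- preprocess_mediators(sim$cohort, "lipid_01")
  f <- think_time ~ apoe2 + lipid_01 + age_enroll + sex
  ex <- gee_gaussian(f, d, cluster = ~family_id, corstr = "exchangeable")
  ind <- gee_gaussian(f, d, cluster = ~family_id, corstr = "independence")
  expect_lt(abs(ex$rho), 0.05)
  slopes <- setdiff(names(coef(ex)), "(Intercept)")
  expect_lt(max(abs(coef(ex)[slopes] - coef(ind)[slopes])), 0.02)
  expect_lt(abs(coef(ex)[["(Intercept)"]] - coef(ind)[["(Intercept)"]]), 0.1)
})

test_that("fits are invariant to row order and cluster relabeling", {
  sim <- small_sim(n_families = 60, k = 2, seed = 35)
  f <- think_time ~ apoe2 + lipid_01 + lipid_02 + age_enroll
  base <- gee_gaussian(f, sim$data, cluster = ~family_id)
  set.seed(1)
  perm <- sample(nrow(sim$data))
  shuffled <- sim$data[perm, ]
  relabeled <- shuffled
  relabeled$family_id <- paste0("zz_", relabeled$family_id)
  for (d2 in list(shuffled, relabeled)) {
    alt <- gee_gaussian(f, d2, cluster = ~family_id)
    expect_lt(max(abs(coef(alt) - coef(base))), 1e-10)
    expect_lt(max(abs(alt$robust.se - base$robust.se)), 1e-10)
  }
})

test_that("agrees with an independent compound-symmetry estimator", {
  skip_if_not_installed("nlme")
  sim <- small_sim(n_families = 300, k = 1, seed = 36)
  f <- think_time ~ apoe2 + lipid_01 + age_enroll
  gee <- gee_gaussian(f, sim$data, cluster = ~family_id)
  gls <- nlme::gls(f, data = sim$data,
                   correlation = nlme::corCompSymm(form = ~1 | family_id))
  expect_lt(max(abs(coef(gee) - coef(gls))), 0.02)
})

test_that("Wald p-values follow the normal reference", {
  fit <- pseudo_fit(c(a = 0, b = 1.96))
  fit$robust.se <- c(a = 2.3, b = 1)
  expect_identical(wald_pvalue(fit, "a"), 1)
  expect_equal(wald_pvalue(fit, "b"), 0.05, tolerance = 1e-3)
  expect_error(wald_pvalue(fit, "nope"), "unknown coefficient")
})

test_that("Wald test holds its size under the null", {
  # x has no effect on y; clustered noise; 400 refits
  reject <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    set.seed(4000 + i)
    K <- 80
    fam <- rep(seq_len(K), each = 3)
    d <- data.frame(id = fam,
                    x = rnorm(K * 3),
                    y = rnorm(K)[fam] + rnorm(K * 3))
    fit <- gee_gaussian(y ~ x, d, cluster = ~id)
    if (wald_pvalue(fit, "x") < 0.05) reject <- reject + 1L
  }
  expect_gt(reject / n_rep, 0.02)
  expect_lt(reject / n_rep, 0.09)
})

test_that("robust intervals for the exposure cover the truth at ~95%", {
  covered <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    sim <- simulate_cohort(sim_config(n_families = 100, n_mediators = 1,
                                      seed = 5000 + i))
    d <- preprocess_mediators(sim$cohort, "lipid_01")
    fit <- gee_gaussian(think_time ~ apoe2 + lipid_01 + age_enroll + sex +
                          education + bmi + lipid_med + generation,
                        d, cluster = ~family_id)
    est <- coef(fit)[["apoe2"]]
    se <- fit$robust.se[["apoe2"]]
    truth <- sim$truth$think$direct
    if (est - 1.96 * se <= truth && truth <= est + 1.96 * se)
      covered <- covered + 1L
  }
  expect_gt(covered / n_rep, 0.90)
  expect_lt(covered / n_rep, 0.99)
})

test_that("degenerate designs are rejected with clear errors", {
  sim <- small_sim(n_families = 10, k = 1, seed = 37)
  d <- sim$data
  d$dup <- d$age_enroll
  expect_error(gee_gaussian(think_time ~ age_enroll + dup, d, ~family_id),
               "rank deficient")
  d1 <- d
  d1$one <- "F1"
  expect_error(gee_gaussian(think_time ~ age_enroll, d1, ~one), "clusters")
  expect_error(gee_gaussian(think_time ~ age_enroll, d, ~nonexistent),
               "not found")
})

test_that("fit summaries export term, estimate, robust SE and p-value", {
  sim <- small_sim(n_families = 40, k = 1, seed = 38)
  fit <- gee_gaussian(think_time ~ apoe2 + lipid_01, sim$data, ~family_id)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_gee_summary(fit, path)
  back <- utils::read.csv(path)
  expect_identical(back$term, c("(Intercept)", "apoe2", "lipid_01"))
  expect_equal(back$estimate, unname(coef(fit)))
  expect_equal(back$p[2], wald_pvalue(fit, "apoe2"), tolerance = 1e-6)
})
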