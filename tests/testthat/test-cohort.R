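test_that("allele calling reproduces the SNP haplotype table", {
  # the five resolvable unordered genotype pairs
  expect_identical(call_apoe_alleles("T/T", "T/T"), c("e2", "e2"))
  expect_identical(call_apoe_alleles("C/T", "T/T"), c("e2", "e3"))
  expect_identical(call_apoe_alleles("C/C", "T/T"), c("e3", "e3"))
  expect_identical(call_apoe_alleles("C/C", "C/T"), c("e3", "e4"))
  expect_identical(call_apoe_alleles("C/C", "C/C"), c("e4", "e4"))
  # double heterozygote: phase-ambiguous diplotype
  expect_error(call_apoe_alleles("C/T", "C/T"),
               class = "clustmed_ambiguous_haplotype")
  # pairs forcing the undefined (rs7412=T, rs429358=C) haplotype
  for (g in list(c("T/T", "C/T"), c("C/T", "C/C"), c("T/T", "C/C")))
    expect_error(call_apoe_alleles(g[1], g[2]),
                 class = "clustmed_undefined_haplotype")
  # allele order within an unphased genotype must not matter
  expect_identical(call_apoe_alleles("T/C", "T/T"),
                   call_apoe_alleles("C/T", "T/T"))
})

test_that("genotype strings are parsed leniently but validated", {
  expect_identical(call_apoe_alleles("t/t", "TT"), c("e2", "e2"))
  expect_identical(call_apoe_alleles("C|C", "T|T"), c("e3", "e3"))
  expect_error(call_apoe_alleles("A/T", "T/T"), "biallelic")
  expect_error(call_apoe_alleles("T", "T/T"), "biallelic")
})

test_that("group assignment follows the genotype-group rules", {
  expect_identical(assign_apoe_group(c("e2", "e3")), "APOE2")
  expect_identical(assign_apoe_group(c("e2", "e2")), "APOE2")
  expect_identical(assign_apoe_group(c("e3", "e3")), "APOE3")
  expect_identical(assign_apoe_group(c("e3", "e4")), "EXCLUDED")
  expect_identical(assign_apoe_group(c("e2", "e4")), "EXCLUDED")
  expect_identical(assign_apoe_group(c("e4", "e4")), "EXCLUDED")
  expect_error(assign_apoe_group(c("e1", "e3")))
})

test_that("cohort-level group derivation handles missing and invalid calls", {
  g <- derive_apoe_groups(c("T/T", "C/C", "C/T", NA, "C/C"),
                          c("T/T", "C/C", "C/T", "T/T", "T/T"),
                          on_invalid = "na")
  expect_identical(g, c("APOE2", "EXCLUDED", NA, NA, "APOE3"))
  expect_error(derive_apoe_groups("C/T", "C/T", on_invalid = "error"),
               class = "clustmed_ambiguous_haplotype")
})

test_that("mediator preprocessing is the z-score of the natural log", {
  d <- data.frame(m = c(exp(1), exp(3)))
  out <- preprocess_mediators(d, "m")
  # logs {1, 3}: mean 2, sample SD sqrt(2), z = (x - 2)/sqrt(2)
  expect_equal(out$m, c(-1, 1) / sqrt(2))
  sc <- attr(out, "mediator_scaling")
  expect_equal(sc$log_mean, 2)
  expect_equal(sc$log_sd, sqrt(2))
})

test_that("processed mediators have mean 0 and SD 1; transform is scale and
           base invariant", {
  sim <- small_sim(n_families = 40, k = 3, seed = 21)
  for (m in sim$mediators) {
    expect_lt(abs(mean(sim$data[[m]])), 1e-8)
    expect_lt(abs(stats::sd(sim$data[[m]]) - 1), 1e-8)
  }
  # multiplying a raw column by a constant leaves the z-scored log unchanged
  resc <- sim$cohort
  resc$lipid_01 <- resc$lipid_01 * 37.5
  out <- preprocess_mediators(resc, sim$mediators)
  expect_equal(out$lipid_01, sim$data$lipid_01, tolerance = 1e-12)
  # z-scoring removes the log base: log10 gives the same processed values
  z_ln <- sim$data$lipid_02
  l10 <- log10(sim$cohort$lipid_02)
  z_10 <- (l10 - mean(l10)) / stats::sd(l10)
  expect_equal(z_10, z_ln, tolerance = 1e-12)
})

test_that("preprocessing rejects nonpositive and constant mediators", {
  expect_error(preprocess_mediators(data.frame(m = c(1, 0, 2)), "m"),
               "strictly positive")
  expect_error(preprocess_mediators(data.frame(m = c(1, -2, 2)), "m"),
               "strictly positive")
  expect_error(preprocess_mediators(data.frame(m = rep(5, 4)), "m"),
               "zero variance")
  expect_error(preprocess_mediators(data.frame(m = 1:3), "absent"),
               "not found")
})

test_that("analysis sample drops excluded genotypes and incomplete rows", {
  cohort <- data.frame(
    participant_id = paste0("P", 1:5),
    family_id = c("F1", "F1", "F2", "F2", "F3"),
    rs7412 = c("C/C", "C/C", "C/C", "T/T", "C/T"),
    rs429358 = c("T/T", "C/T", "T/T", "T/T", "T/T"),
    age_enroll = c(60, 61, 62, 63, 64), sex = c(0, 1, 0, 1, 0),
    education = c(12, 14, 16, 12, 13),
    bmi = c(25, 26, NA, 28, 29),
    lipid_med = c(0, 0, 1, 1, 0), birth_year = c(1930, 1940, 1938, 1941, 1929),
    m1 = c(1.2, 3.1, 2.2, 0.9, 1.4),
    think_time = c(20, 21, 22, 23, 24), ink_time = c(10, 11, 12, 13, 14),
    stringsAsFactors = FALSE)
  out <- build_analysis_sample(cohort, mediators = "m1")
  expect_identical(nrow(out), 3L)          # e4 carrier and missing BMI gone
  expect_identical(attr(out, "drop_log"), list(genotype = 1L, missing = 1L))
  expect_identical(out$total_time, out$think_time + out$ink_time)
  expect_identical(out$generation, as.integer(out$birth_year > 1935))
  expect_identical(out$apoe2, c(0L, 1L, 1L))
})

test_that("complete synthetic cohorts pass through with zero drops", {
  sim <- simulate_cohort(sim_config(n_families = 30, n_mediators = 2,
                                    seed = 22))
  out <- build_analysis_sample(sim$cohort, mediators = sim$truth$mediators)
  expect_identical(nrow(out), nrow(sim$cohort))
  expect_identical(attr(out, "drop_log"), list(genotype = 0L, missing = 0L))
})

test_that("an all-dropped cohort is an error", {
  cohort <- data.frame(family_id = "F1", apoe_group = "EXCLUDED",
                       age_enroll = 60, sex = 0, education = 12, bmi = 25,
                       lipid_med = 0, generation = 1, m1 = 2,
                       think_time = 20, ink_time = 10)
  expect_error(build_analysis_sample(cohort, mediators = "m1"), "empty")
})

test_that("standardization statistics come from the analysis sample", {
  # the excluded row carries an extreme mediator value; processing before
  # versus after exclusion must disagree
  sim <- simulate_cohort(sim_config(n_families = 30, n_mediators = 1,
                                    seed = 23))
  cohort <- sim$cohort
  cohort$apoe_group <- ifelse(cohort$apoe2 == 1, "APOE2", "APOE3")
  cohort$apoe_group[1] <- "EXCLUDED"
  cohort$lipid_01[1] <- cohort$lipid_01[1] * 1e6
  after <- preprocess_mediators(
    build_analysis_sample(cohort, mediators = "lipid_01"), "lipid_01")
  before <- preprocess_mediators(cohort, "lipid_01")
  before <- build_analysis_sample(before, mediators = "lipid_01")
  expect_gt(max(abs(after$lipid_01 - before$lipid_01)), 0.01)
  expect_lt(abs(mean(after$lipid_01)), 1e-8)   # stats from the analysis rows
  expect_gt(abs(mean(before$lipid_01)), 0.01)  # stats contaminated
})
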