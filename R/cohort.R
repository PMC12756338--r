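#' Read a cohort table from CSV
#'
#' Reads a per-participant cohort table with a documented header:
#' \code{participant_id}, \code{family_id}, either SNP genotype columns
#' (\code{rs7412}, \code{rs429358}, e.g. \code{"T/T"}) or a precomputed
#' \code{apoe_group}, confounders (\code{age_enroll}, \code{sex},
#' \code{education}, \code{bmi}, \code{lipid_med}, and \code{birth_year} or
#' \code{generation}), outcomes (\code{think_time}, \code{ink_time},
#' optionally \code{total_time}), and mediator columns by name (column names
#' with spaces such as \code{"CE 18:3"} are preserved). Empty cells are
#' treated as missing.
#'
#' @param path CSV file path.
#' @return a data frame; \code{family_id} and \code{participant_id} as
#'   character.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                       stringsAsFactors = FALSE)
  if (!"family_id" %in% names(x))
    stop("cohort file must contain a 'family_id' column")
  x$family_id <- as.character(x$family_id)
  if ("participant_id" %in% names(x))
    x$participant_id <- as.character(x$participant_id)
  x
}

parse_genotype <- function(g, snp, valid) {
  al <- strsplit(gsub("\\s", "", toupper(g)), "[/|]")[[1]]
  if (length(al) == 1L && nchar(al) == 2L)
    al <- strsplit(al, "")[[1]]
  if (length(al) != 2L || !all(al %in% valid))
    stop(snp, " genotype '", g, "' is not a biallelic call from {",
         paste(valid, collapse = ","), "}")
  al
}

#' Call APOE alleles from rs7412 and rs429358 genotypes
#'
#' The three APOE alleles are haplotypes of rs7412 and rs429358:
#' e2 = (rs7412=T, rs429358=T), e3 = (C, T), e4 = (C, C). The combination
#' (rs7412=T, rs429358=C) does not define an allele here. Given unphased
#' biallelic genotypes at the two SNPs, the diplotype is resolved by assigning
#' each T at rs7412 to an e2 haplotype and each C at rs429358 to an e4
#' haplotype; remaining haplotypes are e3. Two cases cannot be resolved and
#' raise errors rather than guessing:
#' \itemize{
#'   \item both SNPs heterozygous (T/C and T/C): the phase is ambiguous
#'     (e2/e4 versus the undefined pairing), condition class
#'     \code{"clustmed_ambiguous_haplotype"};
#'   \item more T alleles at rs7412 than non-C alleles at rs429358 can absorb:
#'     an undefined (T, C) haplotype is forced, condition class
#'     \code{"clustmed_undefined_haplotype"}.
#' }
#' Both classes inherit from \code{"clustmed_haplotype_error"}.
#'
#' @param rs7412 genotype string, alleles in \{C, T\} (e.g. \code{"C/T"}).
#' @param rs429358 genotype string, alleles in \{T, C\}.
#' @return character vector of two alleles from \{"e2","e3","e4"\}.
#' @examples
#' call_apoe_alleles("T/T", "T/T")  # c("e2","e2")
#' call_apoe_alleles("C/C", "T/T")  # c("e3","e3")
#' @export
call_apoe_alleles <- function(rs7412, rs429358) {
  a1 <- parse_genotype(rs7412, "rs7412", c("C", "T"))
  a2 <- parse_genotype(rs429358, "rs429358", c("C", "T"))
  n_t <- sum(a1 == "T")        # e2 haplotypes required
  n_c <- sum(a2 == "C")        # e4 haplotypes required
  if (n_t == 1L && n_c == 1L)
    stop(errorCondition(
      paste0("ambiguous haplotype: rs7412=", rs7412, ", rs429358=", rs429358,
             " is heterozygous at both SNPs; the diplotype cannot be",
             " resolved without phase"),
      class = c("clustmed_ambiguous_haplotype", "clustmed_haplotype_error",
                "error", "condition")))
  if (n_t + n_c > 2L)
    stop(errorCondition(
      paste0("undefined haplotype: rs7412=", rs7412, ", rs429358=", rs429358,
             " forces the combination rs7412=T with rs429358=C, which",
             " defines no APOE allele"),
      class = c("clustmed_undefined_haplotype", "clustmed_haplotype_error",
                "error", "condition")))
  sort(c(rep("e2", n_t), rep("e4", n_c), rep("e3", 2L - n_t - n_c)))
}

#' Assign the APOE genotype group from an allele pair
#'
#' e3e3 is the APOE3 reference group; e2e2 and e2e3 form the APOE2 group;
#' any pair containing an e4 allele (including e2e4) is EXCLUDED from the
#' analysis.
#'
#' @param alleles character vector of two alleles from \{"e2","e3","e4"\}.
#' @return one of \code{"APOE2"}, \code{"APOE3"}, \code{"EXCLUDED"}.
#' @export
assign_apoe_group <- function(alleles) {
  if (length(alleles) != 2L || !all(alleles %in% c("e2", "e3", "e4")))
    stop("alleles must be two values from {e2, e3, e4}")
  if ("e4" %in% alleles) return("EXCLUDED")
  if ("e2" %in% alleles) return("APOE2")
  "APOE3"
}

#' Derive APOE genotype groups for a whole cohort
#'
#' Vectorized wrapper around \code{\link{call_apoe_alleles}} and
#' \code{\link{assign_apoe_group}}.
#'
#' @param rs7412,rs429358 genotype string vectors.
#' @param on_invalid \code{"error"} to propagate haplotype errors,
#'   \code{"na"} to return \code{NA} for unresolvable rows (they are then
#'   dropped, with a logged reason, by \code{\link{build_analysis_sample}}).
#' @return character vector of groups.
#' @export
derive_apoe_groups <- function(rs7412, rs429358,
                               on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  mapply(function(g1, g2) {
    if (is.na(g1) || is.na(g2)) return(NA_character_)
    res <- tryCatch(assign_apoe_group(call_apoe_alleles(g1, g2)),
                    clustmed_haplotype_error = function(e)
                      if (on_invalid == "na") NA_character_ else stop(e))
    res
  }, rs7412, rs429358, USE.NAMES = FALSE)
}

#' Log-transform and standardize mediator columns
#'
#' Replaces each named mediator column by the z-score of its natural log,
#' using the sample mean and the n-1 sample SD of the log. Standardization
#' makes the log base irrelevant to downstream estimates; the transformation
#' constants are recorded in the \code{"mediator_scaling"} attribute for
#' reporting. Intended to be applied to the analysis sample, i.e. after
#' exclusions (see \code{\link{build_analysis_sample}}).
#'
#' @param cohort cohort data frame.
#' @param mediator_names character vector of mediator columns (strictly
#'   positive raw abundances).
#' @return the cohort with processed mediator columns and a
#'   \code{"mediator_scaling"} attribute (data frame: mediator, log_mean,
#'   log_sd).
#' @export
preprocess_mediators <- function(cohort, mediator_names) {
  missing_cols <- setdiff(mediator_names, names(cohort))
  if (length(missing_cols))
    stop("mediator columns not found: ", paste(missing_cols, collapse = ", "))
  scaling <- data.frame(mediator = mediator_names,
                        log_mean = NA_real_, log_sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(mediator_names)) {
    m <- mediator_names[i]
    v <- cohort[[m]]
    if (any(!is.finite(v)) || any(v <= 0))
      stop("mediator '", m, "' must be strictly positive and finite")
    lv <- log(v)
    s <- stats::sd(lv)
    if (!is.finite(s) || s == 0)
      stop("mediator '", m, "' has zero variance on the log scale")
    scaling$log_mean[i] <- mean(lv)
    scaling$log_sd[i] <- s
    cohort[[m]] <- (lv - mean(lv)) / s
  }
  attr(cohort, "mediator_scaling") <- scaling
  cohort
}

#' Build the complete-case analysis sample
#'
#' Applies the study's exclusion and completeness rules: derives
#' \code{apoe_group} from the SNPs when absent (unresolvable haplotypes
#' become missing), derives \code{generation} from \code{birth_year > 1935}
#' when absent, recodes the exposure as \code{apoe2} (1 = APOE2, 0 = APOE3
#' reference), drops EXCLUDED (e4-carrier) and unresolved genotypes, drops
#' rows with any missing exposure, confounder, mediator or outcome
#' (complete-case), and recomputes \code{total_time = think_time + ink_time}.
#' Counts of rows dropped per reason are attached as the \code{"drop_log"}
#' attribute.
#'
#' @param cohort cohort data frame (see \code{\link{read_cohort}}).
#' @param mediators mediator column names.
#' @param confounders confounder column names.
#' @param outcomes outcome columns; \code{total_time} is always recomputed
#'   from think and ink when both are present.
#' @return the analysis sample with attribute \code{"drop_log"} =
#'   \code{list(genotype = , missing = )}.
#' @export
build_analysis_sample <- function(cohort, mediators,
                                  confounders = c("age_enroll", "sex",
                                                  "education", "bmi",
                                                  "lipid_med", "generation"),
                                  outcomes = c("think_time", "ink_time")) {
  if (!"apoe_group" %in% names(cohort)) {
    if (all(c("rs7412", "rs429358") %in% names(cohort))) {
      cohort$apoe_group <- derive_apoe_groups(cohort$rs7412, cohort$rs429358,
                                              on_invalid = "na")
    } else if ("apoe2" %in% names(cohort)) {
      # exposure already coded 0 = APOE3 reference, 1 = APOE2
      cohort$apoe_group <- ifelse(is.na(cohort$apoe2), NA_character_,
                                  ifelse(cohort$apoe2 == 1, "APOE2", "APOE3"))
    } else {
      stop("cohort needs 'apoe_group', 'apoe2', or both 'rs7412' and 'rs429358'")
    }
  }
  if ("generation" %in% confounders && !"generation" %in% names(cohort)) {
    if (!"birth_year" %in% names(cohort))
      stop("cohort needs either 'generation' or 'birth_year'")
    cohort$generation <- as.integer(cohort$birth_year > 1935)
  }
  if (!"apoe2" %in% names(cohort))
    cohort$apoe2 <- ifelse(cohort$apoe_group == "APOE2", 1L,
                           ifelse(cohort$apoe_group == "APOE3", 0L, NA_integer_))

  n0 <- nrow(cohort)
  keep_geno <- !is.na(cohort$apoe_group) & cohort$apoe_group != "EXCLUDED"
  dropped_geno <- sum(!keep_geno)
  cohort <- cohort[keep_geno, , drop = FALSE]

  needed <- unique(c("family_id", "apoe2", confounders, mediators, outcomes))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("analysis columns not found: ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(cohort[, needed, drop = FALSE])
  dropped_missing <- sum(!complete)
  cohort <- cohort[complete, , drop = FALSE]
  if (nrow(cohort) == 0L)
    stop("analysis sample is empty after exclusions (", n0, " rows dropped)")

  if (all(c("think_time", "ink_time") %in% names(cohort)))
    cohort$total_time <- cohort$think_time + cohort$ink_time
  rownames(cohort) <- NULL
  attr(cohort, "drop_log") <- list(genotype = dropped_geno,
                                   missing = dropped_missing)
  cohort
}
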