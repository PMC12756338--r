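#' Analysis run configuration
#'
#' Collects and validates everything one end-to-end analysis needs. The
#' three modes mirror the study design: \code{"primary"} uses all mediators;
#' \code{"secondary"} first applies backward stepwise AIC selection of
#' mediators in each outcome model and reruns the mediation analysis on the
#' retained set (which may differ across outcomes); \code{"sensitivity"}
#' drops the variables in \code{sensitivity_drop} (default: lipid-lowering
#' medication use) from the confounders of both the mediator and the outcome
#' models.
#'
#' @param input path to a cohort CSV (see \code{\link{read_cohort}}) or a
#'   cohort data frame.
#' @param mediators mediator column names.
#' @param confounders confounder column names.
#' @param outcomes outcome column names.
#' @param mode analysis mode.
#' @param reps bootstrap replicates (study convention 1500).
#' @param level CI level.
#' @param seed integer master seed for the bootstrap.
#' @param engine estimation engine, see \code{\link{medgee}}.
#' @param sensitivity_drop confounders removed in sensitivity mode.
#' @param resample_unit bootstrap resampling unit.
#' @return validated list of class \code{"run_config"}.
#' @export
run_config <- function(input, mediators,
                       confounders = c("age_enroll", "sex", "education",
                                       "bmi", "lipid_med", "generation"),
                       outcomes = c("total_time", "think_time", "ink_time"),
                       mode = c("primary", "secondary", "sensitivity"),
                       reps = 1500L, level = 0.95, seed = 1L,
                       engine = c("gee", "ols"),
                       sensitivity_drop = "lipid_med",
                       resample_unit = c("family", "individual")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  resample_unit <- match.arg(resample_unit)
  if (reps < 1L) stop("reps must be >= 1")
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)")
  structure(list(input = input, mediators = mediators,
                 confounders = confounders, outcomes = outcomes, mode = mode,
                 reps = as.integer(reps), level = level,
                 seed = as.integer(seed), engine = engine,
                 sensitivity_drop = sensitivity_drop,
                 resample_unit = resample_unit),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file; keys as in \code{\link{run_config}}.
#' @param ... overrides.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  args <- utils::modifyList(raw, list(...))
  do.call(run_config, args)
}

#' Run the full mediation analysis end to end
#'
#' Executes read -> genotype/exclusion -> preprocessing -> mediator and
#' outcome regressions -> product-method decomposition -> family bootstrap
#' for every outcome, honouring the analysis mode, and (when \code{out_dir}
#' is given) writes \code{effects.csv} (one row per outcome and quantity with
#' percentile CI and significance flag), \code{indirect_effects.csv} (one row
#' per outcome and mediator), \code{selection_trace.csv} in secondary mode,
#' \code{summary.json}, and \code{run.log}. The decomposition identities
#' (total = direct + combined indirect; mediated proportion x total =
#' combined indirect) are machine-checked on every run before anything is
#' written.
#'
#' @param config a \code{\link{run_config}} (or path to one, YAML/JSON).
#' @param out_dir optional output directory, created if needed.
#' @return (invisibly) a list of class \code{"clustmed_run"}: per-outcome
#'   \code{fit} (\code{medgee}), \code{boot} (\code{medgee_boot}), and
#'   \code{trace} (secondary mode), plus the drop log and config.
#' @export
run_clustmed <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("clustmed run: mode=%s engine=%s reps=%d seed=%d (R %s, clustmed %s)",
      config$mode, config$engine, config$reps, config$seed,
      getRversion(),
      tryCatch(as.character(utils::packageVersion("clustmed")),
               error = function(e) "dev"))

  confounders <- config$confounders
  if (config$mode == "sensitivity") {
    confounders <- setdiff(confounders, config$sensitivity_drop)
    say("sensitivity mode: dropping %s from mediator and outcome models",
        paste(config$sensitivity_drop, collapse = ", "))
  }

  cohort <- if (is.character(config$input)) read_cohort(config$input)
            else config$input
  say("read %d rows", nrow(cohort))
  sample_ <- build_analysis_sample(cohort, mediators = config$mediators,
                                   confounders = confounders)
  dl <- attr(sample_, "drop_log")
  say("analysis sample: %d rows (dropped: genotype=%d, missing=%d)",
      nrow(sample_), dl$genotype, dl$missing)
  sample_ <- preprocess_mediators(sample_, config$mediators)
  say("preprocessed %d mediators (log + z-score on the analysis sample)",
      length(config$mediators))

  results <- list()
  for (i in seq_along(config$outcomes)) {
    oc <- config$outcomes[i]
    if (config$mode == "secondary") {
      sec <- medgee_secondary(sample_, outcome = oc,
                              mediators = config$mediators,
                              confounders = confounders,
                              engine = config$engine)
      fit <- sec$fit
      trace <- sec$trace
      say("%s: retained %d/%d mediators after backward AIC", oc,
          length(trace$retained), length(config$mediators))
    } else {
      fit <- medgee(sample_, outcome = oc, mediators = config$mediators,
                    confounders = confounders, engine = config$engine)
      trace <- NULL
    }
    check_identities(fit)
    boot <- boot_medgee(fit, reps = config$reps, level = config$level,
                        seed = config$seed + i,
                        resample_unit = config$resample_unit)
    say("%s: direct %.3f, combined indirect %.3f, total %.3f, PM %s%% (%d/%d replicates ok)",
        oc, fit$direct, fit$combined_indirect, fit$total,
        format_percent(fit$prop_mediated), boot$reps - boot$n_failed,
        boot$reps)
    results[[oc]] <- list(fit = fit, boot = boot, trace = trace)
  }

  run <- structure(list(results = results, config = config,
                        drop_log = dl, log = log_lines),
                   class = "clustmed_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  invisible(run)
}

check_identities <- function(fit, tol = 1e-10) {
  stopifnot(abs(fit$total - (fit$direct + fit$combined_indirect)) < tol,
            abs(fit$combined_indirect - sum(fit$indirect)) < tol)
  if (!is.na(fit$prop_mediated) && fit$total != 0)
    stopifnot(abs(fit$prop_mediated * fit$total - fit$combined_indirect) <
                tol * max(1, abs(fit$total)))
  invisible(TRUE)
}

effects_table <- function(run) {
  do.call(rbind, lapply(names(run$results), function(oc) {
    ci <- run$results[[oc]]$boot$ci
    main <- ci[ci$quantity %in% c("direct", "combined_indirect", "total",
                                  "prop_mediated"), ]
    cbind(outcome = oc, main, row.names = NULL)
  }))
}

indirect_table <- function(run) {
  do.call(rbind, lapply(names(run$results), function(oc) {
    r <- run$results[[oc]]
    if (!length(r$fit$mediators)) return(NULL)
    ci <- r$boot$ci
    rows <- match(paste0("indirect_", r$fit$mediators), ci$quantity)
    data.frame(outcome = oc, mediator = r$fit$mediators,
               estimate = ci$estimate[rows], ci_low = ci$ci_low[rows],
               ci_high = ci$ci_high[rows],
               significant = ci$significant[rows],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(effects_table(run), file.path(out_dir, "effects.csv"),
                   row.names = FALSE)
  utils::write.csv(indirect_table(run),
                   file.path(out_dir, "indirect_effects.csv"),
                   row.names = FALSE)
  if (run$config$mode == "secondary") {
    traces <- do.call(rbind, lapply(names(run$results), function(oc) {
      st <- run$results[[oc]]$trace$steps
      if (nrow(st)) cbind(outcome = oc, st, row.names = NULL) else NULL
    }))
    if (is.null(traces))
      traces <- data.frame(outcome = character(), step = integer(),
                           removed = character(), aic_before = numeric(),
                           aic_after = numeric())
    utils::write.csv(traces, file.path(out_dir, "selection_trace.csv"),
                     row.names = FALSE)
  }
  summary_list <- list(
    config = run$config[c("mode", "engine", "reps", "level", "seed",
                          "mediators", "confounders", "outcomes",
                          "resample_unit")],
    drop_log = run$drop_log,
    outcomes = lapply(run$results, function(r) {
      out <- list(direct = r$fit$direct,
                  combined_indirect = r$fit$combined_indirect,
                  total = r$fit$total,
                  prop_mediated = r$fit$prop_mediated,
                  prop_mediated_pct = round(100 * r$fit$prop_mediated),
                  unstable_total = r$fit$unstable_total,
                  indirect = as.list(r$fit$indirect),
                  n_failed_replicates = r$boot$n_failed)
      if (!is.null(r$trace)) out$retained <- r$trace$retained
      out
    }))
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.clustmed_run <- function(x, ...) {
  cat("clustmed run (mode:", x$config$mode, ", engine:", x$config$engine,
      ",", x$config$reps, "bootstrap reps)\n\n")
  tab <- effects_table(x)
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}
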