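#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the synthetic-cohort
#' generator (or input paths for externally supplied tables), sampler
#' settings, and analysis toggles. Unknown keys are rejected.
#'
#' @param ... Overrides for the defaults listed below.
#' @return Object of class `gng_pipeline_config`.
#' @details Keys: `seed`; `gen` (a [generation_config()] or `NULL` when
#'   reading from files); `trials_path`, `cohort_path` (used when `gen` is
#'   `NULL`); `chains`, `iter`, `warmup`, `thin` (sampler); `group_fit`
#'   (fit group-specific means), `covariates_in_fit` (include the four
#'   survey scores as covariates on group means), `include_interaction`
#'   (quit model).
#' @export
pipeline_config <- function(...) {
  defaults <- list(seed = 1L, gen = generation_config(),
                   trials_path = NULL, cohort_path = NULL,
                   chains = 2L, iter = 600L, warmup = 300L, thin = 16L,
                   group_fit = TRUE, covariates_in_fit = FALSE,
                   include_interaction = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) stop("unknown config key(s): ",
                                 paste(unknown, collapse = ", "),
                                 call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "gng_pipeline_config")
}

.config_snapshot <- function(config) {
  x <- unclass(config)
  x$gen <- if (is.null(x$gen)) NULL else {
    g <- unclass(x$gen)
    g$design <- unclass(g$design)
    g
  }
  x
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest) -> QC exclusions -> hierarchical fit ->
#' behavioral congruency statistics -> group-level session-change inference
#' -> logistic moderation model. All report tables, a diagnostics JSON and
#' a config snapshot are written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "gng_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }

  if (!is.null(config$gen)) {
    say("stage simulate: generating %d + %d subjects",
        config$gen$n_quit, config$gen$n_nonquit)
    dat <- generate_cohort(config$gen)
    trials <- dat$trials; cohort <- dat$cohort
    utils::write.csv(dat$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    say("stage ingest: reading %s", config$trials_path)
    trials <- read_trials(config$trials_path)
    cohort <- read_cohort(config$cohort_path)
    dat <- NULL
  }
  write_trials(trials, file.path(out_dir, "trials.csv"))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  qc <- apply_exclusions(cohort, trials)
  say("stage qc: retained %d of %d subjects", nrow(qc$retained),
      nrow(cohort))
  utils::write.csv(qc$excluded, file.path(out_dir, "exclusion_log.csv"),
                   row.names = FALSE)
  keep <- trials$subject %in% qc$retained$subject
  trials <- trials[keep, ]

  acc <- condition_accuracy(trials)
  utils::write.csv(acc, file.path(out_dir, "condition_accuracy.csv"),
                   row.names = FALSE)
  contrasts <- do.call(rbind, lapply(sort(unique(trials$session)),
                                     function(s) {
                                       congruency_contrasts(acc, s)
                                     }))
  utils::write.csv(contrasts, file.path(out_dir,
                                        "congruency_contrasts.csv"),
                   row.names = FALSE)
  say("stage behavior: %d contrasts", nrow(contrasts))

  groups <- NULL
  if (config$group_fit && "quit" %in% names(qc$retained)) {
    groups <- stats::setNames(ifelse(qc$retained$quit == 1L, "quit",
                                     "nonquit"), qc$retained$subject)
  }
  covs <- NULL
  if (config$covariates_in_fit) {
    covs <- qc$retained[c("subject", "bis", "ktsnd", "cws", "ybocs")]
  }
  model <- build_model(trials, groups = groups, covariates = covs)
  say("stage fit: %d chains x %d iter (%d warmup), thin %d",
      config$chains, config$iter, config$warmup, config$thin)
  fit <- fit_hierarchical(model, chains = config$chains,
                          iter = config$iter, warmup = config$warmup,
                          thin = config$thin, seed = config$seed)
  say("stage fit: max split R-hat %.3f", fit$diagnostics$max_rhat)
  utils::write.csv(posterior_summary(fit),
                   file.path(out_dir, "posterior_summary.csv"),
                   row.names = FALSE)

  change <- credible_group_change(fit)
  utils::write.csv(change, file.path(out_dir, "group_change.csv"),
                   row.names = FALSE)

  means <- subject_parameter_means(fit)
  write_parameters(means, file.path(out_dir, "subject_parameters.csv"))

  quit_tab <- NULL
  if ("quit" %in% names(qc$retained) &&
      length(unique(qc$retained$quit)) == 2L &&
      nrow(qc$retained) >= 20L) {
    pi_est <- means$ses1_pi_rew[match(qc$retained$subject, means$subject)]
    qm <- fit_quit_model(qc$retained, pi_est,
                         include_interaction = config$include_interaction)
    quit_tab <- qm$table
    utils::write.csv(quit_tab, file.path(out_dir, "quit_model.csv"),
                     row.names = FALSE)
    say("stage quit model: %d terms", nrow(quit_tab))
  } else {
    say("stage quit model: skipped (insufficient cohort)")
  }

  diag <- list(max_rhat = fit$diagnostics$max_rhat,
               n_subjects = model$packed$n_sub,
               n_excluded = nrow(qc$excluded),
               chains = config$chains, iter = config$iter,
               warmup = config$warmup, thin = config$thin,
               seed = config$seed)
  jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.config_snapshot(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(data = dat, qc = qc, accuracy = acc,
                 contrasts = contrasts, fit = fit, change = change,
                 quit_model = quit_tab))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()]; an optional `gen` mapping is
#' passed to [generation_config()]. Unknown keys are rejected by the
#' respective constructors.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$gen)) {
    raw$gen <- do.call(generation_config, raw$gen)
  }
  do.call(pipeline_config, raw)
}
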