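#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the study conditions the analysis assumes: per-subject
#' unconstrained session-1 parameters drawn from group-level normals whose
#' means give learning rate ~0.2, outcome sensitivities ~4, a modest go
#' bias, positive Pavlovian biases (so congruent conditions are learned
#' better, at roughly 0.6-0.8 accuracy) and ~15% lapse noise; a positive
#' reward-domain Pavlovian-bias shift at session 2 for quitters only; and a
#' quit-outcome logistic model whose coefficients default to the reported
#' moderation structure (participation helps, the participation x bias
#' interaction hurts).
#'
#' @param n_quit,n_nonquit Group sizes.
#' @param eta1_mean,eta1_sd Length-7 group mean / SD of unconstrained
#'   session-1 parameters (order of [param_names()]).
#' @param delta_mean_quit,delta_mean_nonquit Length-7 group means of the
#'   unconstrained session deltas.
#' @param delta_sd Length-7 SDs of the deltas.
#' @param quit_coefs Named coefficients of the quit-outcome logistic model
#'   on standardized components.
#' @param outcome_mode `"group"`: quit status is the preassigned group
#'   label (the logistic linear predictor is still recorded);
#'   `"logistic"`: quit ~ Bernoulli(plogis(linear predictor)) and the
#'   realized outcome selects the delta group.
#' @param design A [task_design()].
#' @param simulate_behavior If `FALSE`, skip trial simulation (covariates,
#'   parameters and outcomes only) -- useful for studies of the quit model
#'   alone.
#' @param seed Integer seed; generation is reproducible from config + seed.
#' @return Object of class `gng_genconfig`.
#' @export
generation_config <- function(
    n_quit = 20L, n_nonquit = 30L,
    eta1_mean = c(qnorm(0.2), log(4), log(4), 0.2, 0.6, 0.5, qnorm(0.15)),
    eta1_sd = c(0.4, 0.3, 0.3, 0.4, 0.5, 0.5, 0.4),
    delta_mean_quit = c(0, 0, 0, 0, 0.8, 0, 0),
    delta_mean_nonquit = rep(0, 7),
    delta_sd = rep(0.3, 7),
    quit_coefs = c(intercept = -1.775, duration = 0.214, sex_male = 0.050,
                   bis = 0.869, ktsnd = -0.109, cws = -1.073, ybocs = 0.366,
                   participation = 1.127, pi_rew = -0.067,
                   interaction = -0.845),
    outcome_mode = c("group", "logistic"),
    design = task_design(), simulate_behavior = TRUE, seed = 1L) {
  stopifnot(n_quit >= 1L, n_nonquit >= 1L,
            length(eta1_mean) == 7L, length(eta1_sd) == 7L,
            all(eta1_sd > 0), all(delta_sd > 0),
            length(delta_mean_quit) == 7L,
            length(delta_mean_nonquit) == 7L, length(delta_sd) == 7L)
  req <- c("intercept", "duration", "sex_male", "bis", "ktsnd", "cws",
           "ybocs", "participation", "pi_rew", "interaction")
  if (!all(req %in% names(quit_coefs))) {
    stop("quit_coefs must name: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_quit = as.integer(n_quit),
                 n_nonquit = as.integer(n_nonquit),
                 eta1_mean = eta1_mean, eta1_sd = eta1_sd,
                 delta_mean_quit = delta_mean_quit,
                 delta_mean_nonquit = delta_mean_nonquit,
                 delta_sd = delta_sd, quit_coefs = quit_coefs,
                 outcome_mode = match.arg(outcome_mode),
                 design = design,
                 simulate_behavior = isTRUE(simulate_behavior),
                 seed = as.integer(seed)),
            class = "gng_genconfig")
}

#' Generate a ground-truth synthetic cohort
#'
#' Draws subject parameters from the configured group-level normals,
#' simulates both sessions of go/no-go behavior through the generative
#' model, draws covariates, participation rates and quit outcomes, and
#' assigns CO readings consistent with quit status (quitters below 5 ppm).
#'
#' @param config A [generation_config()].
#' @return List: `trials` (long trial table, both sessions), `cohort`
#'   (one row per subject: covariates, participation, survey days, CO,
#'   smoking flag, quit outcome), `truth` (generating `eta1_*`, `d_*`,
#'   natural `ses1_*`/`ses2_*` parameters, linear predictor), and the
#'   `config` itself.
#' @export
generate_cohort <- function(config = generation_config()) {
  stopifnot(inherits(config, "gng_genconfig"))
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_quit + cfg$n_nonquit
  subjects <- sprintf("s%03d", seq_len(n))
  group_label <- rep(c("quit", "nonquit"), c(cfg$n_quit, cfg$n_nonquit))

  eta1 <- sapply(seq_len(7), function(k) {
    rnorm(n, cfg$eta1_mean[k], cfg$eta1_sd[k])
  })
  colnames(eta1) <- .par_names

  # covariates and participation
  duration <- pmax(rnorm(n, 7, 3), 0.5)
  sex <- ifelse(runif(n) < 0.86, "male", "female")
  bis <- rnorm(n); ktsnd <- rnorm(n); cws <- rnorm(n); ybocs <- rnorm(n)
  participation <- stats::rbeta(n, 6, 2)

  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  pi_rew_true <- eta1[, "pi_rew"]
  qc <- cfg$quit_coefs
  lp <- qc[["intercept"]] + qc[["duration"]] * zs(duration) +
    qc[["sex_male"]] * (sex == "male") + qc[["bis"]] * zs(bis) +
    qc[["ktsnd"]] * zs(ktsnd) + qc[["cws"]] * zs(cws) +
    qc[["ybocs"]] * zs(ybocs) +
    qc[["participation"]] * zs(participation) +
    qc[["pi_rew"]] * zs(pi_rew_true) +
    qc[["interaction"]] * zs(participation) * zs(pi_rew_true)

  if (cfg$outcome_mode == "logistic") {
    quit <- rbinom(n, 1L, plogis(lp))
    group_label <- ifelse(quit == 1L, "quit", "nonquit")
  } else {
    quit <- as.integer(group_label == "quit")
  }

  delta <- t(vapply(seq_len(n), function(i) {
    mu <- if (group_label[i] == "quit") cfg$delta_mean_quit
          else cfg$delta_mean_nonquit
    rnorm(7, mu, cfg$delta_sd)
  }, numeric(7)))
  colnames(delta) <- .delta_names

  trials <- NULL
  if (cfg$simulate_behavior) {
    trials <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      th1 <- transform_params(eta1[i, ])
      th2 <- session2_parameters(eta1[i, ], delta[i, ])
      trials[[2L * i - 1L]] <- simulate_session(th1, cfg$design,
                                                subject = subjects[i],
                                                session = 1L)
      trials[[2L * i]] <- simulate_session(th2, cfg$design,
                                           subject = subjects[i],
                                           session = 2L)
    }
    trials <- do.call(rbind, trials)
  }

  co_ppm <- ifelse(quit == 1L, runif(n, 0, 5), runif(n, 5, 30))
  cohort <- data.frame(
    subject = subjects, group = group_label, quit = quit,
    sex = sex, duration = duration, bis = bis, ktsnd = ktsnd, cws = cws,
    ybocs = ybocs, participation = participation, survey_days = 36L,
    co_ppm = co_ppm, smoked_last_week = quit == 0L,
    stringsAsFactors = FALSE)

  th1 <- t(apply(eta1, 1, transform_params))
  th2 <- t(vapply(seq_len(n), function(i) {
    session2_parameters(eta1[i, ], delta[i, ])
  }, numeric(7)))
  truth <- data.frame(subject = subjects, group = group_label, quit = quit,
                      lp = as.numeric(lp), stringsAsFactors = FALSE)
  truth[paste0("eta1_", .par_names)] <- eta1
  truth[.delta_names] <- delta
  truth[paste0("ses1_", .par_names)] <- th1
  truth[paste0("ses2_", .par_names)] <- th2

  list(trials = trials, cohort = cohort, truth = truth, config = cfg)
}

#' Parameter-recovery report
#'
#' Compares generating subject-level parameters with their posterior means
#' and the generating group-level deltas with the fitted group change.
#'
#' @param cohort_data Output of [generate_cohort()].
#' @param fit A `gng_fit` estimated on the generated trials.
#' @return List: `subject` (per unconstrained parameter: correlation,
#'   bias, RMSE, 95% central-interval coverage), `group_delta` (per group
#'   and delta parameter: generating mean, posterior median, sign
#'   recovered, credible flag).
#' @export
recovery_report <- function(cohort_data, fit) {
  truth <- cohort_data$truth
  eta_draws <- subject_eta_draws(fit)
  subs <- dimnames(eta_draws)[[2]]
  rows <- match(subs, truth$subject)
  if (anyNA(rows)) stop("fitted subjects missing from ground truth",
                        call. = FALSE)
  pn <- param_names(deltas = TRUE)
  truth_mat <- as.matrix(truth[rows, c(paste0("eta1_", .par_names),
                                       .delta_names)])
  subject <- do.call(rbind, lapply(seq_along(pn), function(k) {
    est <- colMeans(eta_draws[, , k])
    lo <- apply(eta_draws[, , k], 2, quantile, 0.025)
    hi <- apply(eta_draws[, , k], 2, quantile, 0.975)
    tr <- truth_mat[, k]
    data.frame(parameter = pn[k], correlation = cor(tr, est),
               bias = mean(est - tr), rmse = sqrt(mean((est - tr)^2)),
               coverage95 = mean(tr >= lo & tr <= hi), row.names = NULL)
  }))
  gc <- credible_group_change(fit)
  gen_mean <- function(g, p) {
    mu <- if (g == "quit") cohort_data$config$delta_mean_quit
          else cohort_data$config$delta_mean_nonquit
    mu[match(p, .delta_names)]
  }
  gc$generating_mean <- mapply(gen_mean, gc$group, gc$parameter)
  gc$sign_recovered <- ifelse(
    gc$generating_mean == 0, !gc$credible,
    sign(gc$median) == sign(gc$generating_mean))
  list(subject = subject, group_delta = gc)
}
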