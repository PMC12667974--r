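#' CO-verified abstinence classification
#'
#' Abstinent iff exhaled carbon monoxide is strictly below the threshold
#' (default 5 ppm) and no smoking was reported over the last week.
#'
#' @param co_ppm Exhaled CO in ppm (non-negative).
#' @param smoked_last_week Logical: any self-reported smoking in the last
#'   week.
#' @param threshold CO cutoff in ppm (default 5; strict `<`).
#' @return Logical vector.
#' @export
classify_abstinence <- function(co_ppm, smoked_last_week, threshold = 5) {
  if (any(co_ppm < 0)) stop("CO ppm must be non-negative", call. = FALSE)
  (co_ppm < threshold) & !smoked_last_week
}

.exclusion_reasons <- c("data_issue", "low_concentration",
                        "excessive_presses", "nonconvergence",
                        "incomplete_survey")

#' Apply cohort quality-control exclusions
#'
#' Subjects are excluded, with one reason code each (the first matching, in
#' a fixed priority order), for: a raised data-issue flag; a raised
#' low-concentration flag; go responses on more than `go_rate_threshold` of
#' trials in either session; any parameter split R-hat above
#' `rhat_threshold`; or fewer than `min_survey_days` completed survey days.
#'
#' @param cohort Data frame with a `subject` column, `survey_days`, and
#'   optional logical columns `flag_data_issue`, `flag_low_concentration`.
#' @param trials Optional long trial table used for the button-press filter.
#' @param rhat Optional named numeric vector of per-subject maximum R-hat.
#' @param go_rate_threshold Exclusion threshold on the per-session go rate
#'   (default 0.9, strict `>`).
#' @param rhat_threshold Convergence bound (default 1.1, strict `>`).
#' @param min_survey_days Minimum completed survey days (default 7).
#' @return List: `retained` (cohort subset), `excluded` (data frame
#'   `subject`, `reason`).
#' @export
apply_exclusions <- function(cohort, trials = NULL, rhat = NULL,
                             go_rate_threshold = 0.9, rhat_threshold = 1.1,
                             min_survey_days = 7) {
  stopifnot(is.data.frame(cohort), "subject" %in% names(cohort))
  if (!is.null(trials)) {
    orphan <- setdiff(unique(trials$subject), cohort$subject)
    if (length(orphan) > 0L) {
      stop("subject(s) in trials but not in cohort: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  reason <- rep(NA_character_, nrow(cohort))
  flag <- function(col) {
    if (col %in% names(cohort)) isTRUE_vec(cohort[[col]]) else
      rep(FALSE, nrow(cohort))
  }
  hit <- function(cond, code) {
    reason[is.na(reason) & cond] <<- code
  }
  hit(flag("flag_data_issue"), "data_issue")
  hit(flag("flag_low_concentration"), "low_concentration")
  if (!is.null(trials)) {
    go_rate <- tapply(trials$response == "go",
                      paste(trials$subject, trials$session, sep = "\r"),
                      mean)
    keys <- strsplit(names(go_rate), "\r", fixed = TRUE)
    subj_over <- unique(vapply(keys, `[[`, "", 1L)[go_rate >
                                                     go_rate_threshold])
    hit(cohort$subject %in% subj_over, "excessive_presses")
  }
  if (!is.null(rhat)) {
    over <- names(rhat)[rhat > rhat_threshold]
    hit(cohort$subject %in% over, "nonconvergence")
  }
  if ("survey_days" %in% names(cohort)) {
    hit(cohort$survey_days < min_survey_days, "incomplete_survey")
  }
  excluded <- data.frame(subject = cohort$subject[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(retained = cohort[is.na(reason), , drop = FALSE], excluded = excluded)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

.quit_terms <- c("(Intercept)", "smoking_duration", "sex_male", "BIS",
                 "KTSND", "CWS", "YBOCS", "participation_rate", "pi_rew",
                 "participation_rate:pi_rew")

#' Logistic moderation model of cessation success
#'
#' Maximum-likelihood logistic regression of quit outcome on smoking
#' duration, sex, four baseline survey scores (BIS, KTSND, CWS, YBOCS),
#' clinic participation rate, the reward-domain Pavlovian bias, and
#' (optionally) the participation x Pavlovian-bias interaction. All
#' continuous predictors are z-scored before entry; the interaction is the
#' product of the standardized components.
#'
#' @param cohort Data frame with columns `quit` (0/1), `duration`, `sex`
#'   (`"male"`/`"female"`), `bis`, `ktsnd`, `cws`, `ybocs`,
#'   `participation`.
#' @param pi_rew Numeric vector of subject-level reward Pavlovian bias
#'   estimates, aligned with `cohort` rows.
#' @param include_interaction Include the participation x pi_rew term
#'   (default TRUE).
#' @return Object of class `gng_quit_model`: `table` (term, estimate, se,
#'   z, p), the underlying `glm` fit, and the standardization constants.
#' @export
fit_quit_model <- function(cohort, pi_rew, include_interaction = TRUE) {
  stopifnot(is.data.frame(cohort), nrow(cohort) == length(pi_rew))
  if (nrow(cohort) < 20L) stop("need at least 20 retained subjects",
                               call. = FALSE)
  if (length(unique(cohort$quit)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  zs <- function(x) as.numeric(scale(x))
  dat <- data.frame(
    quit = as.integer(cohort$quit),
    smoking_duration = zs(cohort$duration),
    sex_male = as.integer(cohort$sex == "male"),
    BIS = zs(cohort$bis), KTSND = zs(cohort$ktsnd), CWS = zs(cohort$cws),
    YBOCS = zs(cohort$ybocs),
    participation_rate = zs(cohort$participation),
    pi_rew = zs(pi_rew))
  form <- quit ~ smoking_duration + sex_male + BIS + KTSND + CWS + YBOCS +
    participation_rate + pi_rew
  if (include_interaction) {
    form <- stats::update.formula(form, . ~ . + participation_rate:pi_rew)
  }
  fit <- glm(form, family = binomial(), data = dat)
  if (any(abs(coef(fit)) > 15) || !fit$converged) {
    warning("possible quasi-separation: extreme coefficients or ",
            "non-convergence (max |coef| = ",
            format(max(abs(coef(fit))), digits = 3), ")")
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zval <- est / se
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), z = unname(zval),
                    p = unname(2 * pnorm(-abs(zval))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit,
                 include_interaction = include_interaction,
                 scale_info = list(
                   participation = c(mean(cohort$participation),
                                     sd(cohort$participation)),
                   pi_rew = c(mean(pi_rew), sd(pi_rew)))),
            class = "gng_quit_model")
}

#' @export
print.gng_quit_model <- function(x, ...) {
  cat("logistic model of cessation success (n =",
      length(x$fit$y), ")\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Simple slopes of clinic participation across Pavlovian bias
#'
#' For a model with the interaction term, the effect of participation at a
#' given (standardized) Pavlovian bias is
#' `beta_participation + beta_interaction * pi`; the SE follows from the
#' delta method (linear combination of coefficients).
#'
#' @param result A [fit_quit_model()] result with the interaction included.
#' @param pi_grid Standardized Pavlovian-bias values at which to evaluate
#'   the slope (default -2..2).
#' @return Data frame: `pi_rew`, `slope`, `se`.
#' @export
moderation_profile <- function(result, pi_grid = seq(-2, 2, by = 0.5)) {
  stopifnot(inherits(result, "gng_quit_model"))
  if (!result$include_interaction) {
    stop("model was fitted without the interaction term", call. = FALSE)
  }
  V <- vcov(result$fit)
  bp <- coef(result$fit)[["participation_rate"]]
  bi <- coef(result$fit)[["participation_rate:pi_rew"]]
  vp <- V["participation_rate", "participation_rate"]
  vi <- V["participation_rate:pi_rew", "participation_rate:pi_rew"]
  cpi <- V["participation_rate", "participation_rate:pi_rew"]
  data.frame(pi_rew = pi_grid,
             slope = bp + bi * pi_grid,
             se = sqrt(vp + pi_grid^2 * vi + 2 * pi_grid * cpi))
}

#' Credible session-change assessment of group-level delta parameters
#'
#' For each group and each session-delta parameter, summarizes the
#' posterior of the group-level mean: median, 95% HDI, direction, and a
#' credibility flag (95% HDI excludes 0).
#'
#' @param fit A `gng_fit` estimated with group-specific means (or a single
#'   group).
#' @param params Delta parameters to assess (default all seven).
#' @return Data frame: group, parameter, median, hdi95_lo, hdi95_hi,
#'   p_gt0, credible, direction.
#' @export
credible_group_change <- function(fit, params = paste0("d_", .par_names)) {
  stopifnot(inherits(fit, "gng_fit"))
  groups <- fit$model$groups
  rows <- list()
  for (g in groups) {
    for (p in params) {
      lab <- if (length(groups) == 1L) paste0("mu.", p)
             else paste0("mu[", g, "].", p)
      x <- as.numeric(fit$draws[, , lab])
      s <- summarize_draws(x)
      credible <- s[["hdi95_lo"]] > 0 || s[["hdi95_hi"]] < 0
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, median = s[["median"]],
        hdi95_lo = s[["hdi95_lo"]], hdi95_hi = s[["hdi95_hi"]],
        p_gt0 = s[["p_gt0"]], credible = credible,
        direction = if (s[["median"]] > 0) "increase" else "decrease",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
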