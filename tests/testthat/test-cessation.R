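test_that("abstinence requires CO under 5 ppm and no reported smoking", {
  expect_true(classify_abstinence(4.9, FALSE))
  expect_false(classify_abstinence(5.0, FALSE))   # strict threshold
  expect_false(classify_abstinence(3.0, TRUE))
  expect_equal(classify_abstinence(c(1, 6, 2), c(FALSE, FALSE, TRUE)),
               c(TRUE, FALSE, FALSE))
  expect_error(classify_abstinence(-1, FALSE), "non-negative")
})

make_qc_cohort <- function() {
  data.frame(subject = paste0("s", 1:6),
             survey_days = c(30L, 30L, 6L, 30L, 30L, 30L),
             flag_data_issue = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
             stringsAsFactors = FALSE)
}

make_qc_trials <- function() {
  one <- function(subj, go_rate) {
    n <- 180L
    data.frame(subject = subj, session = 1L, trial = seq_len(n) - 1L,
               condition = rep(gng_conditions(), each = 45L),
               response = ifelse(seq_len(n) <= round(go_rate * n), "go",
                                 "nogo"),
               outcome = 0L, stringsAsFactors = FALSE)
  }
  rbind(one("s1", 0.5), one("s2", 0.95), one("s3", 0.5), one("s4", 0.5),
        one("s5", 0.5), one("s6", 0.5))
}

test_that("exclusion filters apply the documented reasons in order", {
  cohort <- make_qc_cohort()
  trials <- make_qc_trials()
  rh <- c(s5 = 1.25, s1 = 1.05)
  res <- apply_exclusions(cohort, trials, rhat = rh)
  expect_setequal(res$retained$subject, c("s1", "s6"))
  got <- setNames(res$excluded$reason, res$excluded$subject)
  expect_equal(got[["s2"]], "excessive_presses")
  expect_equal(got[["s3"]], "incomplete_survey")
  expect_equal(got[["s4"]], "data_issue")
  expect_equal(got[["s5"]], "nonconvergence")
  # retained + excluded partitions the cohort
  expect_setequal(c(res$retained$subject, res$excluded$subject),
                  cohort$subject)
  # idempotent on the retained set
  res2 <- apply_exclusions(res$retained,
                           trials[trials$subject %in%
                                    res$retained$subject, ],
                           rhat = rh)
  expect_equal(nrow(res2$excluded), 0L)
  expect_equal(res2$retained$subject, res$retained$subject)
})

test_that("trials for unknown subjects are rejected", {
  cohort <- make_qc_cohort()
  trials <- make_qc_trials()
  trials$subject[1] <- "ghost"
  expect_error(apply_exclusions(cohort, trials), "ghost")
})

test_that("the quit model reports the full published term list", {
  dat <- generate_cohort(generation_config(n_quit = 30, n_nonquit = 30,
                                           simulate_behavior = FALSE,
                                           seed = 42))
  qm <- fit_quit_model(dat$cohort, dat$truth$eta1_pi_rew)
  expect_equal(qm$table$term,
               c("(Intercept)", "smoking_duration", "sex_male", "BIS",
                 "KTSND", "CWS", "YBOCS", "participation_rate", "pi_rew",
                 "participation_rate:pi_rew"))
  qm0 <- fit_quit_model(dat$cohort, dat$truth$eta1_pi_rew,
                        include_interaction = FALSE)
  expect_false("participation_rate:pi_rew" %in% qm0$table$term)
  expect_error(fit_quit_model(dat$cohort[1:10, ],
                              dat$truth$eta1_pi_rew[1:10]), "20")
})

test_that("a null outcome yields uniformly unremarkable coefficients", {
  set.seed(99)
  n <- 500
  cohort <- data.frame(subject = paste0("s", 1:n), quit = rbinom(n, 1, 0.4),
                       duration = rnorm(n, 7, 3),
                       sex = sample(c("male", "female"), n, TRUE),
                       bis = rnorm(n), ktsnd = rnorm(n), cws = rnorm(n),
                       ybocs = rnorm(n), participation = runif(n))
  qm <- fit_quit_model(cohort, rnorm(n))
  expect_lt(max(abs(qm$table$z[-1])), 4)
  expect_lt(mean(qm$table$p[-1] < 0.05), 0.35)
})

test_that("standardization makes the fit scale-invariant", {
  dat <- generate_cohort(generation_config(n_quit = 40, n_nonquit = 60,
                                           outcome_mode = "logistic",
                                           simulate_behavior = FALSE,
                                           seed = 7))
  co <- dat$cohort
  qm1 <- fit_quit_model(co, dat$truth$eta1_pi_rew)
  co2 <- co; co2$cws <- co2$cws * 2; co2$duration <- co2$duration * 10
  qm2 <- fit_quit_model(co2, dat$truth$eta1_pi_rew)
  expect_equal(qm1$table$z, qm2$table$z, tolerance = 1e-8)
})

test_that("simple slopes follow the interaction and match the bootstrap", {
  cfg <- generation_config(n_quit = 200, n_nonquit = 300,
                           outcome_mode = "logistic",
                           simulate_behavior = FALSE, seed = 13)
  dat <- generate_cohort(cfg)
  qm <- fit_quit_model(dat$cohort, dat$truth$eta1_pi_rew)
  prof <- moderation_profile(qm, pi_grid = c(-1, 0, 1))
  bp <- qm$table$estimate[qm$table$term == "participation_rate"]
  bi <- qm$table$estimate[qm$table$term == "participation_rate:pi_rew"]
  expect_equal(prof$slope[prof$pi_rew == 0], bp)
  expect_equal(prof$slope, bp + bi * prof$pi_rew)
  if (bi < 0) expect_true(all(diff(prof$slope) < 0))

  # parametric bootstrap of the slope SE at pi = 1
  set.seed(31)
  X <- stats::model.matrix(qm$fit)
  eta_hat <- as.numeric(X %*% coef(qm$fit))
  slopes <- replicate(300, {
    yb <- rbinom(length(eta_hat), 1, plogis(eta_hat))
    cf <- coef(glm(yb ~ X - 1, family = binomial()))
    cf[grep("participation_rate$", names(cf))] +
      cf[grep(":pi_rew$", names(cf))]
  })
  expect_lt(abs(sd(slopes) - prof$se[prof$pi_rew == 1]) /
              sd(slopes), 0.10)
  qm0 <- fit_quit_model(dat$cohort, dat$truth$eta1_pi_rew,
                        include_interaction = FALSE)
  expect_error(moderation_profile(qm0), "interaction")
})

test_that("credible change flags follow the 95% HDI exclusion rule", {
  set.seed(17)
  fit <- fake_group_fit(
    list("mu[quit].d_pi_rew" = rnorm(2000, 0.9, 0.2),
         "mu[nonquit].d_pi_rew" = rnorm(2000, 0, 0.2)),
    groups = c("quit", "nonquit"))
  gc <- credible_group_change(fit, params = "d_pi_rew")
  quit_row <- gc[gc$group == "quit", ]
  non_row <- gc[gc$group == "nonquit", ]
  expect_true(quit_row$credible)
  expect_equal(quit_row$direction, "increase")
  expect_false(non_row$credible)
  expect_equal(non_row$p_gt0, 0.5, tolerance = 0.05)
})
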