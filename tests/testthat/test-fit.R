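make_tiny_cohort <- function(n = 4, seed = 21, two_groups = FALSE) {
  cfg <- generation_config(n_quit = ceiling(n / 2),
                           n_nonquit = floor(n / 2), seed = seed)
  dat <- generate_cohort(cfg)
  groups <- if (two_groups) {
    setNames(ifelse(dat$cohort$quit == 1, "quit", "nonquit"),
             dat$cohort$subject)
  } else NULL
  list(dat = dat, model = build_model(dat$trials, groups = groups))
}

test_that("the model exposes the expected free quantities", {
  tc <- make_tiny_cohort(2)
  labels <- dimnames(fit_hierarchical(tc$model, chains = 2, iter = 6,
                                      warmup = 2, thin = 1,
                                      seed = 1)$draws)[[3]]
  # 14 group means + 14 group SDs + 2 x 14 subject deviations
  expect_length(labels, 14 + 14 + 2 * 14)
  expect_length(grep("^mu\\.", labels), 14)
  expect_length(grep("^sigma\\.", labels), 14)
  expect_length(grep("^z\\[", labels), 28)
})

test_that("group labels give separate means per group", {
  tc <- make_tiny_cohort(4, two_groups = TRUE)
  labels <- .subset2(tc$model, "groups")
  expect_setequal(labels, c("quit", "nonquit"))
  fit <- fit_hierarchical(tc$model, chains = 2, iter = 6, warmup = 2,
                          thin = 1, seed = 1)
  expect_true(all(c("mu[quit].d_pi_rew", "mu[nonquit].d_pi_rew") %in%
                    dimnames(fit$draws)[[3]]))
})

test_that("model assembly rejects inconsistent inputs", {
  tc <- make_tiny_cohort(2)
  tr <- tc$dat$trials
  expect_error(build_model(tr, groups = c(ghost = "quit")), "no trials")
  tr2 <- tr[!(tr$subject == tr$subject[1] & tr$session == 1L), ]
  expect_error(build_model(tr2), "session-1")
})

test_that("sampling is reproducible from the seed", {
  tc <- make_tiny_cohort(2)
  f1 <- fit_hierarchical(tc$model, chains = 2, iter = 20, warmup = 10,
                         thin = 1, seed = 33)
  f2 <- fit_hierarchical(tc$model, chains = 2, iter = 20, warmup = 10,
                         thin = 1, seed = 33)
  expect_identical(f1$draws, f2$draws)
})

test_that("split R-hat separates stationary from divergent chains", {
  set.seed(8)
  stationary <- matrix(rnorm(4 * 5000), ncol = 4)
  expect_equal(split_rhat(stationary), 1, tolerance = 0.01)
  apart <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  expect_gt(split_rhat(apart), 1.1)
  expect_error(split_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_warning(r <- split_rhat(matrix(1, 100, 2)), "undefined")
  expect_true(is.na(r))
})

test_that("the HDI matches normal quantiles and exhaustive search", {
  set.seed(12)
  x <- rnorm(10000)
  h <- hdi(x, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.08)
  expect_equal(h[2], 1.96, tolerance = 0.08)
  expect_equal(hdi(rep(3.2, 30), 0.5), c(3.2, 3.2))
  for (r in 1:25) {
    y <- rnorm(100, sd = runif(1, 0.5, 3))
    m <- runif(1, 0.3, 0.97)
    expect_equal(hdi(y, m), brute_hdi(y, m))
  }
  expect_error(hdi(x, 1.2), "mass")
})

test_that("posterior summaries report median, HDIs and sign probability", {
  set.seed(2)
  sym <- rnorm(5000)
  s <- summarize_draws(sym)
  expect_lt(abs(s[["p_gt0"]] - 0.5), 0.03)
  pos <- rexp(500) + 0.01
  sp <- summarize_draws(pos)
  expect_gt(sp[["hdi95_lo"]], 0)
  for (r in 1:20) {
    v <- rnorm(51)
    expect_equal(summarize_draws(v)[["median"]], sort(v)[26])
  }
})

test_that("penalized MAP estimation recovers generating parameters", {
  truth <- c(eps = 0.25, rho_rew = 3, rho_pun = 3, b = 0.3, pi_rew = 1.2,
             pi_pun = 0.8, xi = 0.1)
  tr <- simulate_session(truth, seed = 77)
  m <- map_estimate(tr)
  expect_lt(abs(m$theta1[["pi_rew"]] - truth[["pi_rew"]]), 0.5)
  expect_equal(m$convergence, 0)
  # without session 2, deltas sit at the penalty mode
  expect_equal(m$delta, rep(0, 7), tolerance = 1e-4)
  # the optimum is at least as good as the truth under the same objective
  obj <- function(eta1, delta) {
    session_loglik(tr, transform_params(eta1)) -
      0.5 * sum(c(eta1, delta)^2)
  }
  expect_gte(m$logpost, obj(inverse_transform(truth), rep(0, 7)) - 1e-6)
})

test_that("hierarchical estimates shrink relative to per-subject ML", {
  # partial pooling should give subject-level estimates with less spread
  # than independent per-subject fits; the reference uses a near-flat
  # penalty so it is effectively maximum likelihood
  tc <- make_tiny_cohort(12, seed = 303)
  fit <- fit_hierarchical(tc$model, chains = 2, iter = 300, warmup = 150,
                          thin = 6, seed = 7)
  post <- subject_parameter_means(fit)
  ml_pi <- sapply(tc$model$subjects, function(s) {
    tr <- tc$dat$trials
    map_estimate(tr[tr$subject == s & tr$session == 1L, ],
                 penalty_sd = 10)$eta1[5]
  })
  expect_lt(var(post$pi_rew), var(ml_pi))
})
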