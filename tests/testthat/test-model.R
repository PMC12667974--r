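test_that("the unconstrained-to-natural transform and its inverse agree", {
  th0 <- transform_params(rep(0, 7))
  expect_equal(unname(th0),
               c(0.5, 1, 1, 0, 0, 0, 0.5))
  # probit of 1.6449 is the 95th normal percentile
  expect_equal(transform_params(c(1.6449, rep(0, 6)))[["eps"]], 0.95,
               tolerance = 1e-4)
  set.seed(3)
  for (r in 1:20) {
    eta <- rnorm(7)
    expect_equal(inverse_transform(transform_params(eta)), eta,
                 tolerance = 1e-10)
  }
  expect_error(transform_params(c(Inf, rep(0, 6))), "finite")
})

test_that("session-2 parameters add deltas before the constraint", {
  eta1 <- c(0.3, -0.1, 0.2, 0.5, -0.4, 0.1, -0.2)
  expect_equal(session2_parameters(eta1, rep(0, 7)),
               transform_params(eta1))
  th2 <- session2_parameters(rep(0, 7), c(0, 0, 0, 0, 0.5, 0, 0))
  expect_equal(th2[["pi_rew"]], 0.5)
  # bounded parameters never leave their range for any delta
  th_big <- session2_parameters(rep(0, 7), c(0, 0, 0, 0, 0, 0, 10))
  expect_lte(th_big[["xi"]], 1)
  expect_lt(session2_parameters(rep(0, 7),
                                c(0, 0, 0, 0, 0, 0, 3))[["xi"]], 1)
})

test_that("value updates move Q and V a fraction eps toward rho * r", {
  p <- c(eps = 0.5, rho_rew = 2, rho_pun = 2, b = 0, pi_rew = 0, pi_pun = 0,
         xi = 0)
  st <- update_values(init_state(), "gw", "go", 1L, p)
  expect_equal(st$Q["gw", "go"], 1)
  expect_equal(unname(st$V["gw"]), 1)
  expect_equal(st$Q["gw", "nogo"], 0)  # only the chosen action updates
  st2 <- update_values(st, "gw", "go", 0L, p)
  expect_equal(st2$Q["gw", "go"], 0.5)  # decay toward 0 on null outcome
  p0 <- p; p0[["eps"]] <- 0
  expect_equal(update_values(st, "gw", "go", 1L, p0), st)
  expect_error(update_values(st, "gw", "go", 2L, p), "outcome")
})

test_that("value updates are contractions toward the outcome target", {
  set.seed(9)
  for (r in 1:25) {
    p <- random_params()
    cond <- sample(gng_conditions(), 1)
    rr <- if (condition_valence(cond) == "win") sample(c(1L, 0L), 1)
          else sample(c(0L, -1L), 1)
    st <- init_state()
    st$Q[] <- rnorm(8); st$V[] <- rnorm(4)
    rho <- if (condition_valence(cond) == "win") p[["rho_rew"]]
           else p[["rho_pun"]]
    s <- match(cond, gng_conditions())
    before <- abs(st$Q[s, "go"] - rho * rr)
    st2 <- update_values(st, cond, "go", rr, p)
    expect_equal(abs(st2$Q[s, "go"] - rho * rr),
                 (1 - p[["eps"]]) * before, tolerance = 1e-12)
  }
})

test_that("action weights add go bias and valence-specific Pavlovian pull", {
  p <- c(eps = 0.5, rho_rew = 1, rho_pun = 1, b = 0.7, pi_rew = 2,
         pi_pun = 2, xi = 0)
  expect_equal(action_weights(init_state(), "gw", p),
               c(go = 0.7, nogo = 0))
  st <- init_state(); st$V["gw"] <- 0.5
  p2 <- c(eps = 0.5, rho_rew = 1, rho_pun = 1, b = 0, pi_rew = 2, pi_pun = 2,
          xi = 0)
  expect_equal(action_weights(st, "gw", p2), c(go = 1.0, nogo = 0))
  st2 <- init_state(); st2$V["gal"] <- -0.5
  expect_equal(action_weights(st2, "gal", p2), c(go = -1.0, nogo = 0))
})

test_that("the noisy softmax is symmetric, bounded and normalized", {
  expect_equal(choice_probability(2, 2, 0.3), 0.5)
  expect_equal(choice_probability(5, -3, 1), 0.5)    # pure-noise limit
  expect_equal(choice_probability(1, 0, 0), 0.731059, tolerance = 1e-6)
  set.seed(4)
  for (r in 1:50) {
    w <- rnorm(2, 0, 5); xi <- runif(1)
    pg <- choice_probability(w[1], w[2], xi)
    pn <- choice_probability(w[2], w[1], xi)
    expect_equal(pg + pn, 1)
    expect_gte(pg, xi / 2)
    expect_lte(pg, 1 - xi / 2)
  }
  # stable at extreme weights
  expect_equal(choice_probability(800, -800, 0), 1)
  expect_error(choice_probability(NaN, 0, 0.1), "finite")
})

test_that("session log-likelihood matches a naive re-implementation", {
  tr1 <- data.frame(subject = "a", session = 1L, trial = 0L,
                    condition = "gw", response = "go", outcome = 1L)
  p <- c(eps = 0.3, rho_rew = 2, rho_pun = 2, b = 0, pi_rew = 1, pi_pun = 1,
         xi = 0)
  expect_equal(session_loglik(tr1, p), log(0.5))
  set.seed(11)
  for (r in 1:30) {
    tr <- random_trials(20)
    p <- random_params()
    expect_equal(session_loglik(tr, p), naive_session_loglik(tr, p),
                 tolerance = 1e-9)
  }
  # unsorted / duplicated indices are rejected
  bad <- random_trials(5); bad$trial <- c(0L, 1L, 1L, 3L, 4L)
  expect_error(session_loglik(bad, p), "unique and contiguous")
})

test_that("a larger go bias makes an all-go sequence more likely", {
  tr <- random_trials(30); tr$response <- "go"
  base <- c(eps = 0.2, rho_rew = 2, rho_pun = 2, b = 0, pi_rew = 0.5,
            pi_pun = 0.5, xi = 0.1)
  lls <- sapply(c(-1, 0, 1, 2), function(b) {
    p <- base; p[["b"]] <- b
    session_loglik(tr, p)
  })
  expect_true(all(diff(lls) > 0))
})

test_that("simulated sessions are reproducible and respect the noise limit", {
  p <- c(eps = 0.2, rho_rew = 3, rho_pun = 3, b = 0.2, pi_rew = 0.5,
         pi_pun = 0.5, xi = 1)
  s1 <- simulate_session(p, seed = 5)
  s2 <- simulate_session(p, seed = 5)
  expect_identical(s1, s2)
  # xi = 1: choices are coin flips
  go_rate <- mean(s1$response == "go")
  expect_lt(abs(go_rate - 0.5), 3 * sqrt(0.25 / 180))
  expect_equal(nrow(s1), 180L)
  expect_true(all(s1$outcome %in% c(-1L, 0L, 1L)))
})

test_that("unbiased agents show at most a small win/avoid go asymmetry", {
  # eps=0.3, rho=2, pi=0, b=0: without Pavlovian bias the go-win and
  # go-avoid accuracies stay close. (They are not exactly equal: the
  # valence-specific outcome sets {+1,0} vs {0,-1} give slightly different
  # learning trajectories even with symmetric sensitivities, so the check
  # bounds the magnitude of the gap rather than testing a point null.)
  p <- c(eps = 0.3, rho_rew = 2, rho_pun = 2, b = 0, pi_rew = 0, pi_pun = 0,
         xi = 0.05)
  accs <- t(sapply(1:100, function(i) {
    tr <- simulate_session(p, seed = 9000 + i)
    acc <- condition_accuracy(tr)
    c(gw = acc$accuracy[acc$condition == "gw"],
      gal = acc$accuracy[acc$condition == "gal"])
  }))
  expect_lt(abs(mean(accs[, "gw"] - accs[, "gal"])), 0.05)
  # and far smaller than the gap a real Pavlovian bias induces
  pb <- p; pb[["pi_rew"]] <- 1; pb[["pi_pun"]] <- 1
  accs_b <- t(sapply(1:100, function(i) {
    tr <- simulate_session(pb, seed = 9500 + i)
    acc <- condition_accuracy(tr)
    c(gw = acc$accuracy[acc$condition == "gw"],
      gal = acc$accuracy[acc$condition == "gal"])
  }))
  expect_gt(mean(accs_b[, "gw"] - accs_b[, "gal"]),
            2 * abs(mean(accs[, "gw"] - accs[, "gal"])))
})
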