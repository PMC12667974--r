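# Independent oracles: straight-line re-implementations used only to check
# the package's computational paths. They deliberately share no code with
# the package internals.

# Naive trial-by-trial log-likelihood of one session (natural parameters).
naive_session_loglik <- function(trials, params) {
  conds <- c("gw", "ngw", "gal", "ngal")
  Q <- matrix(0, 4, 2)
  V <- rep(0, 4)
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    s <- match(trials$condition[t], conds)
    win <- s <= 2
    piv <- if (win) params[["pi_rew"]] else params[["pi_pun"]]
    rho <- if (win) params[["rho_rew"]] else params[["rho_pun"]]
    wg <- Q[s, 1] + params[["b"]] + piv * V[s]
    wn <- Q[s, 2]
    pgo <- (1 - params[["xi"]]) * exp(wg) / (exp(wg) + exp(wn)) +
      params[["xi"]] / 2
    p <- if (trials$response[t] == "go") pgo else 1 - pgo
    ll <- ll + log(p)
    a <- if (trials$response[t] == "go") 1 else 2
    pe_t <- rho * trials$outcome[t]
    Q[s, a] <- Q[s, a] + params[["eps"]] * (pe_t - Q[s, a])
    V[s] <- V[s] + params[["eps"]] * (pe_t - V[s])
  }
  ll
}

# Random but structurally valid trial table (outcomes respect cue valence).
random_trials <- function(n = 20) {
  conds <- sample(c("gw", "ngw", "gal", "ngal"), n, replace = TRUE)
  resp <- sample(c("go", "nogo"), n, replace = TRUE)
  win <- conds %in% c("gw", "ngw")
  outcome <- integer(n)
  outcome[win] <- sample(c(1L, 0L), sum(win), replace = TRUE)
  outcome[!win] <- sample(c(0L, -1L), sum(!win), replace = TRUE)
  data.frame(subject = "x", session = 1L, trial = seq_len(n) - 1L,
             condition = conds, response = resp, outcome = outcome,
             stringsAsFactors = FALSE)
}

# Random natural-space parameters in a plausible range.
random_params <- function() {
  eta <- rnorm(7, 0, 0.8)
  c(eps = pnorm(eta[1]), rho_rew = exp(eta[2]), rho_pun = exp(eta[3]),
    b = eta[4], pi_rew = eta[5], pi_pun = eta[6], xi = pnorm(eta[7]))
}

# Exhaustive-search HDI over all contiguous sorted windows.
brute_hdi <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  best <- Inf
  bi <- 1L
  for (j in 1:(n - k + 1)) {
    wdt <- x[j + k - 1] - x[j]
    if (wdt < best) {
      best <- wdt
      bi <- j
    }
  }
  c(x[bi], x[bi + k - 1])
}

# Minimal fabricated gng_fit for functions that only read draws + groups.
fake_group_fit <- function(draw_list, groups) {
  labels <- names(draw_list)
  nd <- length(draw_list[[1]])
  half <- nd %/% 2
  draws <- array(NA_real_, dim = c(half, 2, length(labels)),
                 dimnames = list(NULL, c("chain1", "chain2"), labels))
  for (p in seq_along(labels)) {
    draws[, 1, p] <- draw_list[[p]][1:half]
    draws[, 2, p] <- draw_list[[p]][(half + 1):(2 * half)]
  }
  structure(list(draws = draws, model = list(groups = groups)),
            class = "gng_fit")
}
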