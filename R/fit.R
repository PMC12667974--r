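#' Assemble the two-session hierarchical model
#'
#' Packs long-format trial tables into the structure the sampler consumes
#' and records the grouping / covariate design. Subject-level unconstrained
#' parameters are represented non-centered: `eta[i, k] = mu[group(i), k] +
#' X[i, ] %*% beta[, k] + sigma[k] * z[i, k]` with standard-normal `z`, so
#' group means, group SDs and subject deviations sample independently.
#'
#' @param trials Long trial table for all subjects and sessions (columns
#'   `subject`, `session`, `trial`, `condition`, `response`, `outcome`).
#'   Every subject must have session-1 trials; session 2 is optional.
#' @param groups Optional named vector (names = subject ids) of group
#'   labels; each group gets its own mean per parameter, sharing SDs.
#' @param covariates Optional data frame of numeric covariates with a
#'   `subject` column; columns are z-scored and enter the group means
#'   linearly.
#' @return An object of class `gng_model`.
#' @export
build_model <- function(trials, groups = NULL, covariates = NULL) {
  stopifnot(is.data.frame(trials))
  .check_condition(trials$condition)
  subjects <- unique(trials$subject)
  if (!is.null(groups)) {
    miss <- setdiff(names(groups), subjects)
    if (length(miss) > 0L) {
      stop("subject(s) in groups with no trials: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    subjects <- intersect(subjects, names(groups))
  }
  n <- length(subjects)
  grp_labels <- if (is.null(groups)) rep("all", n)
                else as.character(groups[subjects])
  grp_levels <- unique(grp_labels)
  grp <- match(grp_labels, grp_levels) - 1L

  X <- matrix(numeric(0), nrow = n, ncol = 0L)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), "subject" %in% names(covariates))
    rows <- match(subjects, covariates$subject)
    if (anyNA(rows)) stop("covariates missing for some subjects",
                          call. = FALSE)
    cov_names <- setdiff(names(covariates), "subject")
    X <- scale(as.matrix(covariates[rows, cov_names, drop = FALSE]))
    X <- matrix(as.numeric(X), nrow = n)
  }

  stim <- integer(0); go <- integer(0); out <- integer(0)
  off1 <- integer(n); len1 <- integer(n)
  off2 <- integer(n); len2 <- integer(n)
  for (i in seq_len(n)) {
    for (sess in 1:2) {
      tt <- trials[trials$subject == subjects[i] & trials$session == sess, ]
      if (nrow(tt) == 0L) {
        if (sess == 1L) stop("subject ", subjects[i], " has no session-1 ",
                             "trials", call. = FALSE)
        next
      }
      tt <- tt[order(tt$trial), ]
      .validate_trials_one_session(tt)
      if (sess == 1L) { off1[i] <- length(stim); len1[i] <- nrow(tt) }
      else            { off2[i] <- length(stim); len2[i] <- nrow(tt) }
      stim <- c(stim, .stim_index(tt$condition))
      go <- c(go, as.integer(tt$response == "go"))
      out <- c(out, as.integer(tt$outcome))
    }
  }

  structure(
    list(subjects = subjects, groups = grp_levels, grp_index = grp,
         cov_names = cov_names, X = X,
         packed = list(n_sub = n, n_grp = length(grp_levels),
                       n_cov = length(cov_names), grp = grp,
                       X = as.numeric(X), stim = stim, go = go,
                       outcome = out, off1 = off1, len1 = len1,
                       off2 = off2, len2 = len2)),
    class = "gng_model"
  )
}

#' @export
print.gng_model <- function(x, ...) {
  cat("two-session go/no-go model:", x$packed$n_sub, "subjects,",
      x$packed$n_grp, "group(s),", x$packed$n_cov, "covariate(s);",
      sum(x$packed$len2 > 0), "subjects with session 2\n")
  invisible(x)
}

.param_labels <- function(model) {
  pn <- param_names(deltas = TRUE)
  G <- model$packed$n_grp; C <- model$packed$n_cov
  N <- model$packed$n_sub
  lab <- character(0)
  for (k in pn) for (g in model$groups)
    lab <- c(lab, if (G == 1L) paste0("mu.", k) else paste0("mu[", g, "].", k))
  for (k in pn) for (cv in model$cov_names)
    lab <- c(lab, paste0("beta[", cv, "].", k))
  lab <- c(lab, paste0("sigma.", pn))
  for (i in model$subjects) for (k in pn)
    lab <- c(lab, paste0("z[", i, "].", k))
  lab
}

#' Sample the hierarchical posterior by adaptive MCMC
#'
#' Componentwise adaptive random-walk Metropolis on the non-centered
#' parameterization: group means and covariate coefficients (normal(0,1)
#' priors), group SDs (half-normal(1), sampled on the log scale), and
#' subject-level standard-normal deviations. Step sizes adapt toward a 0.44
#' acceptance rate during warmup and are frozen afterwards. Each stored
#' iteration performs `thin` full update sweeps.
#'
#' @param model A [build_model()] object.
#' @param chains Number of independent chains (default 4).
#' @param iter Total iterations per chain, including warmup (default 4000).
#' @param warmup Warmup iterations discarded per chain (default 2000).
#' @param thin Update sweeps per stored iteration (default 16).
#' @param seed Integer seed; chain c runs under `seed + c - 1`.
#' @param init_jitter SD of the random initialization spread (default 0.3).
#' @return An object of class `gng_fit` with elements `draws` (array
#'   iterations x chains x parameters, named), `diagnostics` (per-parameter
#'   split R-hat and effective sample size, maxima, acceptance rates),
#'   `model` and `settings`.
#' @export
fit_hierarchical <- function(model, chains = 4L, iter = 4000L,
                             warmup = 2000L, thin = 16L, seed = 1L,
                             init_jitter = 0.3) {
  stopifnot(inherits(model, "gng_model"), chains >= 1L, iter > warmup)
  labels <- .param_labels(model)
  n_keep <- iter - warmup
  draws <- array(NA_real_, dim = c(n_keep, chains, length(labels)),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 labels))
  loglik <- matrix(NA_real_, n_keep, chains)
  arates <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- with_seed(seed + ch - 1L,
                     cpp_run_chain(model$packed, as.integer(iter),
                                   as.integer(warmup), as.integer(thin),
                                   init_jitter, 0.44))
    draws[, ch, ] <- res$draws
    loglik[, ch] <- res$loglik
    arates[[ch]] <- res$accept_rate
  }
  fit <- structure(
    list(draws = draws, loglik = loglik, model = model,
         accept_rates = arates,
         settings = list(chains = chains, iter = iter, warmup = warmup,
                         thin = thin, seed = seed)),
    class = "gng_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

#' @export
print.gng_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("hierarchical go/no-go fit: %d subjects, %d chains x ",
                     "%d iter (%d warmup)\n  max split R-hat %.3f, min ESS ",
                     "%.0f\n"),
              x$model$packed$n_sub, x$settings$chains, x$settings$iter,
              x$settings$warmup, d$max_rhat, min(d$ess, na.rm = TRUE)))
  invisible(x)
}

#' Split R-hat convergence diagnostic
#'
#' Classic Gelman-Rubin potential scale reduction computed on split chains:
#' each chain is halved, and `sqrt(((n - 1)/n * W + B/n) / W)` is returned
#' with `B` the between-half-chain and `W` the within-half-chain variance.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains and 4
#'   iterations).
#' @return R-hat; `NA` (with a warning) when all half-chains are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("split R-hat needs at least 2 chains",
                         call. = FALSE)
  n <- nrow(x)
  if (n < 4L) stop("split R-hat needs at least 4 iterations per chain",
                   call. = FALSE)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(halves); nh <- nrow(halves)
  W <- mean(apply(halves, 2, var))
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NA_real_)
  }
  B <- nh * var(colMeans(halves))
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

# Effective sample size via the initial-positive-sequence estimator on
# chain-centered draws.
.ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  v <- mean(apply(x, 2, var))
  if (!is.finite(v) || v == 0) return(NA_real_)
  max_lag <- min(n - 1L, 200L)
  rho <- numeric(max_lag)
  for (l in seq_len(max_lag)) {
    rho[l] <- mean(vapply(seq_len(m), function(j) {
      sum(xc[1:(n - l), j] * xc[(1 + l):n, j]) / n
    }, 0)) / v
  }
  # truncate at first lag pair with non-positive sum
  ssum <- 0; l <- 1
  while (l + 1 <= max_lag) {
    pair <- rho[l] + rho[l + 1]
    if (pair <= 0) break
    ssum <- ssum + pair
    l <- l + 2
  }
  n * m / (1 + 2 * ssum)
}

#' Convergence diagnostics for a hierarchical fit
#'
#' @param fit A `gng_fit`.
#' @return List: per-parameter `rhat` and `ess`, `max_rhat`, and the blockwise
#'   Metropolis acceptance rates per chain.
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gng_fit"))
  P <- dim(fit$draws)[3]
  rhat <- vapply(seq_len(P), function(p) split_rhat(fit$draws[, , p]), 0)
  ess <- vapply(seq_len(P), function(p) .ess(fit$draws[, , p]), 0)
  names(rhat) <- names(ess) <- dimnames(fit$draws)[[3]]
  list(rhat = rhat, ess = ess, max_rhat = max(rhat, na.rm = TRUE),
       accept_rates = fit$accept_rates)
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous interval of sorted draws containing
#' `ceiling(mass * n)` of them; ties broken by the earliest start.
#'
#' @param draws Numeric vector (>= 20 draws).
#' @param mass Probability mass in (0, 1); 0.50 and 0.95 are the
#'   conventional choices.
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!(mass > 0 && mass < 1)) stop("mass must lie in (0,1)", call. = FALSE)
  draws <- sort(as.numeric(draws))
  n <- length(draws)
  if (n < 20L) stop("need at least 20 draws for an HDI", call. = FALSE)
  k <- ceiling(mass * n)
  if (k >= n) return(c(draws[1], draws[n]))
  widths <- draws[(k):n] - draws[1:(n - k + 1)]
  j <- which.min(widths)  # which.min returns the earliest minimum
  c(draws[j], draws[j + k - 1])
}

#' Posterior summary of a vector of draws
#'
#' @param draws Numeric vector of posterior draws.
#' @return Named vector: median, 50% and 95% HDI bounds, and P(> 0).
#' @export
summarize_draws <- function(draws) {
  h50 <- hdi(draws, 0.50); h95 <- hdi(draws, 0.95)
  c(median = median(draws), hdi50_lo = h50[1], hdi50_hi = h50[2],
    hdi95_lo = h95[1], hdi95_hi = h95[2], p_gt0 = mean(draws > 0))
}

#' Posterior summary table for fit parameters
#'
#' @param fit A `gng_fit`.
#' @param pars Regular expression selecting parameter labels (default: the
#'   group-level means and SDs).
#' @return Data frame with one row per parameter: median, 50%/95% HDIs,
#'   P(> 0), split R-hat, ESS.
#' @export
posterior_summary <- function(fit, pars = "^(mu|sigma)") {
  labels <- dimnames(fit$draws)[[3]]
  sel <- grep(pars, labels, value = TRUE)
  rows <- lapply(sel, function(p) {
    x <- as.numeric(fit$draws[, , p])
    s <- summarize_draws(x)
    data.frame(parameter = p, t(s), rhat = fit$diagnostics$rhat[[p]],
               ess = fit$diagnostics$ess[[p]], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Subject-level unconstrained parameter draws
#'
#' Reconstructs `eta[i, k] = mu[g_i, k] + X beta + sigma[k] z[i, k]` for
#' every stored draw.
#'
#' @param fit A `gng_fit`.
#' @return Array draws x subjects x 14 (named).
#' @export
subject_eta_draws <- function(fit) {
  m <- fit$model; pk <- m$packed
  labels <- dimnames(fit$draws)[[3]]
  nd <- dim(fit$draws)[1] * dim(fit$draws)[2]
  flat <- matrix(fit$draws, nrow = nd, ncol = length(labels))
  colnames(flat) <- labels
  pn <- param_names(deltas = TRUE)
  N <- pk$n_sub
  out <- array(NA_real_, dim = c(nd, N, 14),
               dimnames = list(NULL, m$subjects, pn))
  for (i in seq_len(N)) {
    g <- m$groups[pk$grp[i] + 1L]
    for (k in seq_along(pn)) {
      mu_lab <- if (pk$n_grp == 1L) paste0("mu.", pn[k])
                else paste0("mu[", g, "].", pn[k])
      e <- flat[, mu_lab] +
        flat[, paste0("sigma.", pn[k])] * flat[, paste0("z[", m$subjects[i],
                                                        "].", pn[k])]
      if (pk$n_cov > 0L) {
        for (cv in seq_along(m$cov_names)) {
          e <- e + m$X[i, cv] * flat[, paste0("beta[", m$cov_names[cv], "].",
                                              pn[k])]
        }
      }
      out[, i, k] <- e
    }
  }
  out
}

#' Posterior means of subject-level parameters on both scales
#'
#' @param fit A `gng_fit`.
#' @return Data frame: subject, posterior-mean unconstrained `eta`/delta
#'   columns, and posterior-mean natural-scale session-1 and session-2
#'   parameters (columns `ses1_*`, `ses2_*`).
#' @export
subject_parameter_means <- function(fit) {
  eta <- subject_eta_draws(fit)
  N <- dim(eta)[2]
  pn <- param_names(deltas = TRUE)
  rows <- lapply(seq_len(N), function(i) {
    E <- eta[, i, ]
    nat1 <- t(apply(E[, 1:7, drop = FALSE], 1, transform_params))
    nat2 <- t(apply(E[, 1:7, drop = FALSE] + E[, 8:14, drop = FALSE], 1,
                    transform_params))
    v <- c(colMeans(E), colMeans(nat1), colMeans(nat2))
    names(v) <- c(pn, paste0("ses1_", .par_names), paste0("ses2_", .par_names))
    data.frame(subject = dimnames(eta)[[2]][i], t(v), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Penalized maximum-likelihood point estimate for one subject
#'
#' A fast deterministic alternative to the hierarchical fit: maximizes the
#' two-session log-likelihood with an independent standard-normal penalty on
#' every unconstrained parameter (the hierarchical prior collapsed to its
#' hyperprior location).
#'
#' @param trials_s1 Session-1 trial table (one subject).
#' @param trials_s2 Optional session-2 trial table; when absent the deltas
#'   sit at the penalty mode (0).
#' @param penalty_sd SD of the normal penalty (default 1).
#' @return List: `eta1`, `delta` (unconstrained), `theta1`, `theta2`
#'   (natural), `logpost`, `convergence` (0 = converged; otherwise the best
#'   iterate is returned and flagged).
#' @export
map_estimate <- function(trials_s1, trials_s2 = NULL, penalty_sd = 1) {
  .validate_trials_one_session(trials_s1[order(trials_s1$trial), ])
  s1 <- trials_s1[order(trials_s1$trial), ]
  s2 <- if (!is.null(trials_s2)) trials_s2[order(trials_s2$trial), ] else NULL
  have2 <- !is.null(s2) && nrow(s2) > 0L
  negobj <- function(par) {
    eta1 <- par[1:7]; delta <- par[8:14]
    ll <- session_loglik(s1, transform_params(eta1))
    if (have2) ll <- ll + session_loglik(s2, transform_params(eta1 + delta))
    -(ll - 0.5 * sum((par / penalty_sd)^2))
  }
  opt <- optim(rep(0, 14), negobj, method = "BFGS",
               control = list(maxit = 500))
  list(eta1 = opt$par[1:7], delta = opt$par[8:14],
       theta1 = transform_params(opt$par[1:7]),
       theta2 = transform_params(opt$par[1:7] + opt$par[8:14]),
       logpost = -opt$value, convergence = opt$convergence)
}
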