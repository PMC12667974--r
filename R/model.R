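#' @useDynLib gngbias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm rnorm runif rbinom sd cor median optim
#'   pt glm binomial coef vcov plogis quantile var complete.cases
NULL

# Canonical parameter order used everywhere: unconstrained eta and natural
# parameters share index; deltas take a "d_" prefix.
.par_names <- c("eps", "rho_rew", "rho_pun", "b", "pi_rew", "pi_pun", "xi")
.delta_names <- paste0("d_", .par_names)

#' Names of the seven session-level model parameters
#'
#' Order: learning rate `eps`, reward sensitivity `rho_rew`, punishment
#' sensitivity `rho_pun`, go bias `b`, reward Pavlovian bias `pi_rew`,
#' punishment Pavlovian bias `pi_pun`, irreducible noise `xi`.
#'
#' @param deltas If `TRUE`, return the 14 names of the two-session model
#'   (session-1 parameters followed by `d_`-prefixed session deltas).
#' @return Character vector of length 7 or 14.
#' @export
param_names <- function(deltas = FALSE) {
  if (deltas) c(.par_names, .delta_names) else .par_names
}

#' Map unconstrained parameters to the natural space
#'
#' Bounded parameters use the probit transform: `eps = pnorm(eta[1])`,
#' `xi = pnorm(eta[7])`. Outcome sensitivities are kept positive via the
#' exponential: `rho_rew = exp(eta[2])`, `rho_pun = exp(eta[3])`. Go bias and
#' the two Pavlovian biases are unbounded and pass through unchanged.
#'
#' @param eta Numeric 7-vector of unconstrained parameters.
#' @return Named numeric 7-vector of natural-space parameters.
#' @seealso [inverse_transform()]
#' @export
transform_params <- function(eta) {
  eta <- as.numeric(eta)
  if (length(eta) != 7L || any(!is.finite(eta))) {
    stop("eta must be a finite 7-vector", call. = FALSE)
  }
  out <- c(pnorm(eta[1]), exp(eta[2]), exp(eta[3]), eta[4], eta[5], eta[6],
           pnorm(eta[7]))
  names(out) <- .par_names
  out
}

#' Map natural-space parameters back to the unconstrained space
#'
#' @param theta Named or positional numeric 7-vector of natural parameters
#'   (order of [param_names()]).
#' @return Numeric 7-vector `eta` with `transform_params(eta)` equal to
#'   `theta`.
#' @export
inverse_transform <- function(theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 7L)
  c(qnorm(theta[1]), log(theta[2]), log(theta[3]), theta[4], theta[5],
    theta[6], qnorm(theta[7]))
}

#' Session-2 natural parameters from session-1 parameters plus deltas
#'
#' Deltas act additively in the unconstrained space before transformation, so
#' bounded parameters remain in range for any delta.
#'
#' @param eta1 Unconstrained session-1 7-vector.
#' @param delta Unconstrained delta 7-vector.
#' @return Named natural-space 7-vector for session 2.
#' @export
session2_parameters <- function(eta1, delta) {
  transform_params(as.numeric(eta1) + as.numeric(delta))
}

#' Initial latent state (action values Q and state values V)
#'
#' Both tables start at zero at the beginning of each session.
#'
#' @return List with `Q` (4 stimuli x 2 actions, columns `go`/`nogo`) and
#'   `V` (length-4 vector), all zero.
#' @export
init_state <- function() {
  list(Q = matrix(0, nrow = 4L, ncol = 2L,
                  dimnames = list(gng_conditions(), c("go", "nogo"))),
       V = stats::setNames(numeric(4L), gng_conditions()))
}

.stim_index <- function(condition) match(condition, gng_conditions())

#' Rescorla-Wagner update of action and state values
#'
#' Both the chosen action value `Q(a, s)` and the state value `V(s)` move a
#' fraction `eps` toward `rho * r`, where `rho` is the reward sensitivity on
#' win cues and the punishment sensitivity on avoid cues. `V(s)` updates on
#' every trial regardless of the action taken.
#'
#' @param state Latent state from [init_state()] or a previous update.
#' @param condition Condition token of the trial (identifies the stimulus
#'   and its valence).
#' @param action `"go"` or `"nogo"`.
#' @param r Outcome in {-1, 0, +1}.
#' @param params Natural-space parameters ([transform_params()]).
#' @return Updated state.
#' @export
update_values <- function(state, condition, action, r, params) {
  .check_condition(condition)
  if (!r %in% c(-1L, 0L, 1L)) stop("outcome r must be -1, 0 or +1",
                                   call. = FALSE)
  s <- .stim_index(condition)
  rho <- if (condition_valence(condition) == "win") params[["rho_rew"]]
         else params[["rho_pun"]]
  eps <- params[["eps"]]
  target <- rho * r
  state$Q[s, action] <- state$Q[s, action] + eps * (target - state$Q[s, action])
  state$V[s] <- state$V[s] + eps * (target - state$V[s])
  state
}

#' Action weights combining instrumental value, go bias and Pavlovian bias
#'
#' `W(go, s) = Q(go, s) + b + pi_v * V(s)` with `pi_v = pi_rew` on win cues
#' and `pi_pun` on avoid cues; `W(nogo, s) = Q(nogo, s)`. Because V(s) is
#' positive under reward learning and negative under punishment learning, a
#' positive Pavlovian bias invigorates go for win cues and suppresses it for
#' avoid cues.
#'
#' @inheritParams update_values
#' @return Named numeric vector `c(go = W_go, nogo = W_nogo)`.
#' @export
action_weights <- function(state, condition, params) {
  .check_condition(condition)
  s <- .stim_index(condition)
  piv <- if (condition_valence(condition) == "win") params[["pi_rew"]]
         else params[["pi_pun"]]
  c(go = unname(state$Q[s, "go"] + params[["b"]] + piv * state$V[s]),
    nogo = unname(state$Q[s, "nogo"]))
}

#' Choice probability: noisy softmax over action weights
#'
#' `p(go) = (1 - xi) * softmax(W)_go + xi / 2`. The irreducible-noise mixture
#' pulls both action probabilities toward 0.5; the softmax is evaluated with
#' max-subtraction for numerical stability.
#'
#' @param w_go,w_nogo Action weights.
#' @param xi Irreducible noise in (0, 1] (1 allowed to exercise the pure
#'   noise limit).
#' @return Probability of the go response.
#' @export
choice_probability <- function(w_go, w_nogo, xi) {
  if (any(!is.finite(c(w_go, w_nogo)))) stop("non-finite action weights",
                                             call. = FALSE)
  m <- pmax(w_go, w_nogo)
  eg <- exp(w_go - m)
  en <- exp(w_nogo - m)
  (1 - xi) * eg / (eg + en) + xi / 2
}

.validate_trials_one_session <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("trial", "condition", "response", "outcome") %in%
                  names(trials)))
  idx <- trials$trial
  if (anyDuplicated(idx) || !identical(sort(idx), seq_along(idx) - 1L)) {
    stop("trial indices must be unique and contiguous from 0", call. = FALSE)
  }
  if (is.unsorted(idx)) stop("trials must be sorted by trial index",
                             call. = FALSE)
  invisible(trials)
}

#' Log-likelihood of one subject-session under the model
#'
#' Values start at zero, each trial contributes the log-probability of the
#' observed response, and values update using the observed outcome.
#'
#' @param trials Data frame of one subject-session (columns `trial`,
#'   `condition`, `response`, `outcome`), sorted by trial index starting
#'   at 0.
#' @param params Natural-space parameters ([transform_params()]).
#' @return Scalar log-likelihood.
#' @export
session_loglik <- function(trials, params) {
  .validate_trials_one_session(trials)
  .check_condition(trials$condition)
  cpp_session_loglik(
    stim = .stim_index(trials$condition),
    go = as.integer(trials$response == "go"),
    outcome = as.integer(trials$outcome),
    theta = as.numeric(params[.par_names])
  )
}

#' Simulate one subject-session of behavior
#'
#' Generates a randomized trial sequence, then for each trial draws a
#' response from the model's choice probability, samples the outcome from
#' the probabilistic schedule, and updates values.
#'
#' @param params Natural-space parameters.
#' @param design A [task_design()].
#' @param seed Integer seed (the simulation is reproducible from it).
#' @param subject,session Identifiers stamped into the output table.
#' @return Trial table (data frame): `subject`, `session`, `trial`,
#'   `condition`, `response`, `outcome`.
#' @export
simulate_session <- function(params, design = task_design(), seed = NULL,
                             subject = "s1", session = 1L) {
  run <- function() {
    seq_cond <- generate_trial_sequence(design)
    n <- length(seq_cond)
    sim <- cpp_simulate_session(
      stim = .stim_index(seq_cond),
      correct_go = as.integer(correct_action(seq_cond) == "go"),
      is_win = as.integer(condition_valence(seq_cond) == "win"),
      theta = as.numeric(params[.par_names]),
      p_corr = design$p_optimal_correct,
      p_incorr = design$p_optimal_incorrect
    )
    data.frame(
      subject = subject, session = as.integer(session),
      trial = seq_len(n) - 1L, condition = seq_cond,
      response = ifelse(sim$go == 1L, "go", "nogo"),
      outcome = as.integer(sim$outcome),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
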