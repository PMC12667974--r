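#' Cue conditions of the orthogonalized go/no-go task
#'
#' The task crosses required action (go/no-go) with cue valence
#' (win/avoid-losing), giving four conditions. Tokens follow the trial-table
#' dialect used throughout the package: `gw` (go to win), `ngw` (no-go to
#' win), `gal` (go to avoid losing), `ngal` (no-go to avoid losing).
#'
#' @return Character vector of the four condition tokens, in stimulus order.
#' @export
gng_conditions <- function() c("gw", "ngw", "gal", "ngal")

.cond_action <- c(gw = "go", ngw = "nogo", gal = "go", ngal = "nogo")
.cond_valence <- c(gw = "win", ngw = "win", gal = "avoid", ngal = "avoid")

.check_condition <- function(condition) {
  bad <- setdiff(unique(condition), gng_conditions())
  if (length(bad) > 0L) {
    stop("unknown condition token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(condition)
}

#' Required (correct) action for a cue condition
#'
#' @param condition Character vector of condition tokens (see
#'   [gng_conditions()]).
#' @return Character vector, `"go"` or `"nogo"`.
#' @examples
#' correct_action("gw")    # "go"
#' correct_action("ngal")  # "nogo"
#' @export
correct_action <- function(condition) {
  .check_condition(condition)
  unname(.cond_action[condition])
}

#' Cue valence of a condition
#'
#' Win cues can only deliver outcomes in {+1, 0}; avoid cues only in {0, -1}.
#'
#' @inheritParams correct_action
#' @return Character vector, `"win"` or `"avoid"`.
#' @export
condition_valence <- function(condition) {
  .check_condition(condition)
  unname(.cond_valence[condition])
}

#' Task design: trial counts and outcome schedule
#'
#' Defaults encode the standard design: 45 trials per condition (180 total)
#' and a probabilistic outcome schedule delivering the optimal outcome with
#' probability 0.8 after a correct response and 0.2 after an incorrect one.
#'
#' @param trials_per_condition Trials per condition (default 45).
#' @param p_optimal_correct Probability of the optimal outcome after a
#'   correct response (default 0.8).
#' @param p_optimal_incorrect Probability of the optimal outcome after an
#'   incorrect response (default 0.2).
#' @return An object of class `gng_design`.
#' @export
task_design <- function(trials_per_condition = 45L,
                        p_optimal_correct = 0.8,
                        p_optimal_incorrect = 0.2) {
  trials_per_condition <- as.integer(trials_per_condition)
  stopifnot(trials_per_condition >= 1L)
  if (!(p_optimal_incorrect >= 0 && p_optimal_incorrect <= p_optimal_correct &&
        p_optimal_correct <= 1)) {
    stop("need 0 <= p_optimal_incorrect <= p_optimal_correct <= 1",
         call. = FALSE)
  }
  structure(
    list(trials_per_condition = trials_per_condition,
         p_optimal_correct = p_optimal_correct,
         p_optimal_incorrect = p_optimal_incorrect),
    class = "gng_design"
  )
}

#' @export
print.gng_design <- function(x, ...) {
  cat("orthogonalized go/no-go design:",
      4L * x$trials_per_condition, "trials",
      sprintf("(%d per condition), P(optimal | correct) = %.2f, P(optimal | incorrect) = %.2f\n",
              x$trials_per_condition, x$p_optimal_correct,
              x$p_optimal_incorrect))
  invisible(x)
}

#' Generate a randomized trial sequence
#'
#' Produces a uniformly random permutation in which each of the four
#' conditions occurs exactly `trials_per_condition` times.
#'
#' @param design A [task_design()].
#' @param seed Integer seed; the sequence is reproducible from it.
#' @return Character vector of condition tokens, length
#'   `4 * trials_per_condition`.
#' @export
generate_trial_sequence <- function(design = task_design(), seed) {
  stopifnot(inherits(design, "gng_design"))
  pool <- rep(gng_conditions(), each = design$trials_per_condition)
  if (!missing(seed) && !is.null(seed)) {
    return(with_seed(seed, sample(pool)))
  }
  sample(pool)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a trial outcome from the probabilistic schedule
#'
#' Given the emitted response and a uniform deviate, returns the delivered
#' outcome: the optimal outcome (+1 for win cues, 0 for avoid cues) with
#' probability `p_optimal_correct` or `p_optimal_incorrect` depending on
#' whether the response was correct, else the non-optimal outcome (0 for win
#' cues, -1 for avoid cues).
#'
#' @param condition Condition token(s).
#' @param response `"go"` or `"nogo"` (recycled with `condition`).
#' @param u Uniform deviate(s) in [0, 1).
#' @param design A [task_design()].
#' @return Integer outcome(s) in {-1, 0, +1}.
#' @export
sample_outcome <- function(condition, response, u, design = task_design()) {
  .check_condition(condition)
  stopifnot(all(response %in% c("go", "nogo")))
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  correct <- response == correct_action(condition)
  p <- ifelse(correct, design$p_optimal_correct, design$p_optimal_incorrect)
  win <- condition_valence(condition) == "win"
  optimal <- u < p
  out <- integer(length(optimal))
  out[optimal & win] <- 1L
  out[optimal & !win] <- 0L
  out[!optimal & win] <- 0L
  out[!optimal & !win] <- -1L
  out
}
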