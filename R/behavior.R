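#' Per-subject, per-session, per-condition accuracy
#'
#' Accuracy is the fraction of trials whose response equals the condition's
#' required action. Conditions with no trials for a subject-session are
#' reported as `NA` with `n = 0`.
#'
#' @param trials Long trial table.
#' @return Data frame: `subject`, `session`, `condition`, `n`, `accuracy`.
#' @export
condition_accuracy <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L)
  .check_condition(trials$condition)
  trials$correct <- trials$response == correct_action(trials$condition)
  grid <- expand.grid(subject = unique(trials$subject),
                      session = sort(unique(trials$session)),
                      condition = gng_conditions(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(s, ses, cond) paste(s, ses, cond, sep = "\r")
  agg_n <- tapply(trials$correct,
                  key(trials$subject, trials$session, trials$condition),
                  length)
  agg_acc <- tapply(trials$correct,
                    key(trials$subject, trials$session, trials$condition),
                    mean)
  k <- key(grid$subject, grid$session, grid$condition)
  grid$n <- as.integer(ifelse(is.na(agg_n[k]), 0L, agg_n[k]))
  grid$accuracy <- as.numeric(agg_acc[k])
  grid[order(grid$subject, grid$session, grid$condition), ]
}

#' Paired t test from first principles
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on differences `d = x - y`, with
#' `df = n - 1` and a two-sided p-value from the t distribution.
#'
#' @param x,y Paired per-subject values of equal length (n >= 3).
#' @return List: `t`, `df`, `p`, `mean_diff`; all `NA` (flagged via a
#'   warning) when the differences have zero variance.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  sdd <- sd(d)
  if (sdd == 0) {
    warning("zero-variance differences; t undefined")
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d)))
  }
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * pt(-abs(tval), df = n - 1L),
       mean_diff = mean(d))
}

#' Cohen's d with average-variance pooled SD
#'
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2) / 2)` -- the pooled-SD form for two
#' conditions with equal n, computed from summary statistics.
#'
#' @param m1,s1 Mean and SD of the first condition.
#' @param m2,s2 Mean and SD of the second condition.
#' @return Effect size d; `NA` with a warning when both SDs are zero.
#' @export
cohens_d_pooled <- function(m1, s1, m2, s2) {
  if (any(c(s1, s2) < 0)) stop("SDs must be non-negative", call. = FALSE)
  pooled <- sqrt((s1^2 + s2^2) / 2)
  if (pooled == 0) {
    warning("both SDs zero; d undefined")
    return(NA_real_)
  }
  (m1 - m2) / pooled
}

#' Pavlovian congruency contrasts for one session
#'
#' Two within-subject contrasts: go-to-win vs no-go-to-win (reward domain)
#' and no-go-to-avoid vs go-to-avoid (punishment domain). Positive values of
#' `t` and `d` indicate better accuracy in the Pavlovian-congruent condition.
#'
#' @param accuracy Output of [condition_accuracy()].
#' @param session Session to analyze.
#' @return Data frame: session, contrast, mean1, sd1, mean2, sd2, t, df, p,
#'   d -- one row per contrast.
#' @export
congruency_contrasts <- function(accuracy, session = 1L) {
  acc <- accuracy[accuracy$session == session, ]
  if (nrow(acc) == 0L) stop("no rows for session ", session, call. = FALSE)
  wide <- lapply(gng_conditions(), function(cond) {
    sub <- acc[acc$condition == cond, ]
    if (nrow(sub) == 0L || all(is.na(sub$accuracy))) {
      stop("missing condition in accuracy table: ", cond, call. = FALSE)
    }
    sub$accuracy[match(unique(acc$subject), sub$subject)]
  })
  names(wide) <- gng_conditions()
  one <- function(label, c1, c2) {
    x <- wide[[c1]]; y <- wide[[c2]]
    tt <- paired_t(x, y)
    data.frame(session = session, contrast = label,
               mean1 = mean(x, na.rm = TRUE), sd1 = sd(x, na.rm = TRUE),
               mean2 = mean(y, na.rm = TRUE), sd2 = sd(y, na.rm = TRUE),
               t = tt$t, df = tt$df, p = tt$p,
               d = cohens_d_pooled(mean(x, na.rm = TRUE), sd(x, na.rm = TRUE),
                                   mean(y, na.rm = TRUE), sd(y, na.rm = TRUE)),
               row.names = NULL)
  }
  rbind(one("gw_vs_ngw", "gw", "ngw"),
        one("ngal_vs_gal", "ngal", "gal"))
}
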