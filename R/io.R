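#' Write a trial table to CSV
#'
#' Long format, one row per trial: `subject`, `session`, `trial` (0-based),
#' `condition` (tokens `gw`/`ngw`/`gal`/`ngal`), `response` (`go`/`nogo`),
#' `outcome` (-1/0/1).
#'
#' @param trials Trial table.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject", "session", "trial", "condition", "response",
            "outcome")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(trials[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Schema violations are reported with the offending row numbers.
#'
#' @param path CSV path in the dialect written by [write_trials()].
#' @return Validated trial table.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("subject", "session", "trial", "condition", "response",
            "outcome")
  miss <- setdiff(cols, names(tr))
  if (length(miss) > 0L) stop("missing column(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  bad_row <- function(bad, what) {
    if (any(bad)) stop("invalid ", what, " in row(s): ",
                       paste(utils::head(which(bad), 10L), collapse = ", "),
                       call. = FALSE)
  }
  bad_row(!tr$condition %in% gng_conditions(), "condition token")
  bad_row(!tr$response %in% c("go", "nogo"), "response")
  bad_row(!tr$outcome %in% c(-1L, 0L, 1L), "outcome")
  bad_row(!tr$session %in% c(1L, 2L), "session")
  key <- paste(tr$subject, tr$session, tr$trial)
  bad_row(duplicated(key), "duplicate (subject, session, trial)")
  tr$subject <- as.character(tr$subject)
  tr$session <- as.integer(tr$session)
  tr$trial <- as.integer(tr$trial)
  tr$outcome <- as.integer(tr$outcome)
  tr
}

#' Write a cohort table to CSV
#' @param cohort Cohort data frame (one row per subject).
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot("subject" %in% names(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table
#' @param path CSV path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject" %in% names(co)) stop("cohort file lacks a subject column",
                                      call. = FALSE)
  co$subject <- as.character(co$subject)
  co
}

#' Write subject parameter estimates to CSV
#'
#' One row per subject x parameter x session with unconstrained and
#' natural values.
#'
#' @param means Output of [subject_parameter_means()].
#' @param path Output path.
#' @export
write_parameters <- function(means, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(means)), function(i) {
    do.call(rbind, lapply(1:2, function(sess) {
      eta <- if (sess == 1L) unlist(means[i, .par_names])
             else unlist(means[i, .par_names]) + unlist(means[i,
                                                             .delta_names])
      nat <- unlist(means[i, paste0("ses", sess, "_", .par_names)])
      data.frame(subject = means$subject[i], session = sess,
                 parameter = .par_names, unconstrained = unname(eta),
                 natural = unname(nat), row.names = NULL)
    }))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
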