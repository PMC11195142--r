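#' Step-count tally for one experimental condition
#'
#' A tally of analyzed photobleaching traces by observed step count:
#' `n1` one-step, `n2` two-step, `n3` three-or-more-step traces. There is no
#' zero-step category: complexes whose fluorophores all failed to mature are
#' invisible, which is exactly the bias the inference model corrects.
#'
#' @param n1,n2,n3 Non-negative integer counts of traces with 1, 2, and >= 3
#'   photobleaching steps.
#' @param rejections Optional named integer vector auditing traces excluded
#'   from the tally, by rejection reason (as produced by [bin_steps()]).
#' @return An object of class `step_counts`: a named integer vector
#'   `c(n1, n2, n3)` with a `rejections` attribute.
#' @examples
#' step_counts(120, 45, 10)
#' @export
step_counts <- function(n1, n2, n3, rejections = NULL) {
  n <- check_count_vector(c(n1, n2, n3))
  names(n) <- c("n1", "n2", "n3")
  structure(n, class = "step_counts", rejections = rejections)
}

#' @export
print.step_counts <- function(x, ...) {
  n <- unclass(x)
  cat("Photobleaching step counts (w = 1, 2, >=3):\n")
  cat(sprintf("  n1 = %d, n2 = %d, n3 = %d  (N = %d)\n",
              n[["n1"]], n[["n2"]], n[["n3"]], sum(n)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && sum(rej) > 0) {
    cat("Rejected traces:\n")
    for (nm in names(rej)) cat(sprintf("  %s: %d\n", nm, rej[[nm]]))
  }
  invisible(x)
}

#' Bin accepted step calls into monomer/dimer/higher-order tallies
#'
#' Accepted calls with one step go to `n1`, two steps to `n2`, and three or
#' more steps are collectively binned as higher-order (`n3`). Rejected calls
#' are excluded from the tally but audited by reason.
#'
#' @param calls A data frame of step calls as returned by [call_steps()]
#'   (columns `n_steps` and `status`), or a list of [detect_steps()] results.
#' @return A [step_counts()] object; the `rejections` attribute counts
#'   excluded traces by status.
#' @export
bin_steps <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- data.frame(
      n_steps = vapply(calls, function(z) as.integer(z$n_steps), integer(1)),
      status = vapply(calls, function(z) as.character(z$status), character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!all(c("n_steps", "status") %in% names(calls)))
    stop("`calls` must have columns `n_steps` and `status`", call. = FALSE)
  acc <- calls$status == "accepted"
  k <- pmin(calls$n_steps[acc], 3L)
  tal <- tabulate(k, nbins = 3L)
  reasons <- c("rejected_upward", "rejected_no_bleach",
               "rejected_zero_steps", "rejected_too_many")
  rej <- vapply(reasons, function(rs) sum(calls$status == rs), integer(1))
  step_counts(tal[1], tal[2], tal[3], rejections = rej)
}
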