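#' Maturation probability matrix
#'
#' Probability that a complex carrying `s` GFP copies (s = 1, 2, 3) shows
#' exactly `w` mature (fluorescent) copies, for w = 0, ..., 3, when each GFP
#' matures independently with probability `r`. Row `s` is the
#' Binomial(s, r) mass truncated at s: entry \eqn{\pi_{s \to w} =
#' \binom{s}{w} r^w (1-r)^{s-w}} for w <= s, and 0 for w > s.
#'
#' Immature GFP is non-fluorescent, so a dimer with one immature copy
#' photobleaches in a single step; these matrices are the bridge between the
#' true subunit number and the observed step count.
#'
#' @param r Maturation efficiency of a single GFP, in (0, 1]. About 0.7 for
#'   GFP expressed in mammalian cells.
#' @return A 3 x 4 numeric matrix with rows `s1..s3` and columns `w0..w3`;
#'   each row sums to 1.
#' @seealso [eta_matrix()] for the detection-conditioned version,
#'   [observed_marginal()] for the step-count distribution under a given
#'   oligomer mixture.
#' @examples
#' pi_matrix(0.7)
#' rowSums(pi_matrix(0.5))  # each row is a probability distribution
#' @export
pi_matrix <- function(r) {
  check_rate(r)
  s <- 1:3
  w <- 0:3
  m <- outer(s, w, function(s, w)
    ifelse(w > s, 0, choose(s, w) * r^w * (1 - r)^(s - w)))
  dimnames(m) <- list(s = paste0("s", s), w = paste0("w", w))
  m
}

#' Detection-conditioned maturation matrix
#'
#' Traces in which every GFP failed to mature show zero photobleaching steps
#' and are never selected for analysis. Conditioning the maturation matrix on
#' detection (at least one mature copy) gives
#' \eqn{\eta_{s \to 0} = 0} and
#' \eqn{\eta_{s \to w} = \pi_{s \to w} / (1 - \pi_{s \to 0})} for w >= 1.
#'
#' @inheritParams pi_matrix
#' @return A 3 x 4 numeric matrix with rows `s1..s3` and columns `w0..w3`;
#'   the `w0` column is zero and each row sums to 1 over w = 1..3.
#' @examples
#' eta_matrix(0.7)["s2", ]  # a dimer shows one step ~46% of the time
#' @export
eta_matrix <- function(r) {
  check_rate(r)
  if (r < 1e-8)
    stop("maturation efficiency `r` must be >= 1e-8 for the detection ",
         "correction (1 - pi[s -> 0] underflows)", call. = FALSE)
  p <- pi_matrix(r)
  e <- p / (1 - p[, "w0"])
  e[, "w0"] <- 0
  e
}

#' Marginal step-count distribution under an oligomer mixture
#'
#' For a population whose detected complexes are monomer/dimer/oligomer with
#' probabilities `q`, returns the distribution of the observed step count
#' w in \{1, 2, 3\}: \eqn{P(w) = \sum_s q_s \, \eta_{s \to w}}. Used for
#' posterior-predictive checks and by the simulator.
#'
#' @param q Numeric vector of three probabilities (monomer, dimer,
#'   trimer-or-larger) summing to 1.
#' @inheritParams pi_matrix
#' @return Named numeric vector of length 3 (`w1`, `w2`, `w3`) summing to 1.
#' @examples
#' observed_marginal(c(0, 1, 0), 0.7)  # pure dimers look ~46% monomeric
#' @export
observed_marginal <- function(q, r) {
  q <- check_simplex(q)
  e <- eta_matrix(r)
  out <- drop(crossprod(e[, c("w1", "w2", "w3")], q))
  names(out) <- c("w1", "w2", "w3")
  out
}
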