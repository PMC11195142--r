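#' Fit the oligomer distribution from photobleaching step counts
#'
#' Estimates the monomer/dimer/oligomer distribution
#' \eqn{q = (q_1, q_2, q_3)} from step-count tallies, correcting for
#' incomplete GFP maturation and for the loss of zero-step traces. The model
#' is, per analyzed trace n:
#' \deqn{s_n | q \sim \mathrm{Categorical}(q_1, q_2, q_3), \quad
#'       w_n | s_n \sim \mathrm{Categorical}(\eta_{s_n \to 1}, \ldots,
#'       \eta_{s_n \to 3}),}
#' with a \eqn{\mathrm{Dirichlet}(\alpha)} prior on q (non-informative
#' \eqn{\alpha = (1,1,1)} by default) and \eqn{\eta} from [eta_matrix()].
#' The posterior is sampled by a two-block Gibbs sampler with exact
#' conditionals: each latent subunit number \eqn{s_n} given
#' \eqn{(w_n, q)} (restricted to s >= w, since a complex cannot show more
#' steps than it has subunits), then q from the conjugate
#' Dirichlet(\eqn{\alpha} + latent tallies). Both conditionals are exact, so
#' the chain needs no tuning and mixes in a handful of iterations.
#'
#' With zero counts the posterior equals the prior; this is returned, not an
#' error. The maturation efficiency `r` is a fixed input (a literature
#' value), not estimated.
#'
#' @param counts A [step_counts()] object or a numeric vector
#'   `c(n1, n2, n3)` of traces with 1, 2, and >= 3 steps.
#' @param r Maturation efficiency of a single GFP, in (0, 1]. Default 0.7.
#' @param prior Dirichlet concentration parameters, three positive numbers.
#' @param iterations Total Gibbs iterations (default 20000).
#' @param burn_in Iterations discarded before retaining samples
#'   (default 5000); must be < `iterations`.
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#' @param seed Optional integer seed; identical inputs and seed give an
#'   identical sample stream. The caller's RNG state is left untouched.
#' @return An object of class `oligo_fit` with components `samples` (matrix
#'   of retained q draws), `mean`, `sd`, `ess` (effective sample sizes),
#'   `counts`, `N`, `r`, `prior`, and the sampler settings. Methods:
#'   [coef.oligo_fit()], [confint.oligo_fit()], [predict.oligo_fit()],
#'   [residuals.oligo_fit()], [simulate.oligo_fit()], [plot.oligo_fit()],
#'   `print`, `summary`, `vcov`.
#' @examples
#' fit <- oligo_fit(c(90, 40, 12), r = 0.7, iterations = 4000,
#'                  burn_in = 1000, seed = 1)
#' coef(fit)
#' summary(fit)
#' @export
oligo_fit <- function(counts, r = 0.7, prior = c(1, 1, 1),
                      iterations = 20000, burn_in = 5000, thin = 1,
                      seed = NULL) {
  n <- if (inherits(counts, "step_counts")) unclass(counts) else
    check_count_vector(counts)
  n <- as.integer(n)
  check_rate(r)
  if (!is.numeric(prior) || length(prior) != 3L || any(prior <= 0))
    stop("`prior` must be three positive Dirichlet concentrations",
         call. = FALSE)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (iterations < 1L) stop("`iterations` must be positive", call. = FALSE)
  if (burn_in < 0L || burn_in >= iterations)
    stop("`burn_in` must be non-negative and < `iterations`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be a positive integer", call. = FALSE)

  E <- eta_matrix(r)[, c("w1", "w2", "w3")]  # rows s = 1..3
  n_keep <- (iterations - burn_in) %/% thin
  samples <- matrix(NA_real_, n_keep, 3L,
                    dimnames = list(NULL, c("monomer", "dimer", "oligomer")))

  with_seed(seed, {
    g <- stats::rgamma(3L, prior)
    q <- g / sum(g)
    k <- 0L
    for (it in seq_len(iterations)) {
      tally <- numeric(3L)
      for (w in 1:3) {
        if (n[w] == 0L) next
        p <- q * E[, w]           # zero automatically for s < w
        if (sum(p) <= 0) p <- as.numeric(E[, w] > 0)
        tally <- tally + drop(stats::rmultinom(1L, n[w], p))
      }
      a <- prior + tally
      g <- stats::rgamma(3L, a)
      q <- g / sum(g)
      post <- it - burn_in
      if (post > 0L && post %% thin == 0L) {
        k <- k + 1L
        samples[k, ] <- q
      }
    }
  })

  names(n) <- c("n1", "n2", "n3")
  structure(list(
    samples = samples,
    mean = colMeans(samples),
    sd = apply(samples, 2L, stats::sd),
    ess = apply(samples, 2L, ess_ips),
    counts = n,
    N = sum(n),
    r = r,
    prior = prior,
    iterations = iterations,
    burn_in = burn_in,
    thin = thin,
    seed = seed,
    call = match.call()
  ), class = "oligo_fit")
}

# Effective sample size by Geyer's initial positive sequence: sum
# autocorrelations in consecutive pairs while the pair sums stay positive.
ess_ips <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(as.numeric(n))
  rho <- drop(stats::acf(x, lag.max = min(1000L, n - 1L),
                         plot = FALSE)$acf)[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Exact posterior moments by simplex quadrature
#'
#' Brute-force numerical integration of the posterior of q over a regular
#' barycentric grid on the 2-simplex, as an independent check of
#' [oligo_fit()]. The unnormalized log posterior
#' \deqn{\sum_w n_w \log \Big(\sum_s q_s \eta_{s \to w}\Big)
#'       + \sum_s (\alpha_s - 1) \log q_s}
#' is evaluated at every grid node, normalized by log-sum-exp, and the first
#' two moments are accumulated. The error decreases with `resolution`.
#'
#' @inheritParams oligo_fit
#' @param resolution Number of grid subdivisions per simplex edge
#'   (>= 100; default 400, about 80k nodes).
#' @return A list with `mean` and `sd` (named length-3 vectors) and
#'   `resolution`.
#' @examples
#' exact_posterior(c(10, 0, 0), r = 1)$mean  # Dirichlet(11, 1, 1) moments
#' @export
exact_posterior <- function(counts, r = 0.7, prior = c(1, 1, 1),
                            resolution = 400) {
  n <- if (inherits(counts, "step_counts")) unclass(counts) else
    check_count_vector(counts)
  check_rate(r)
  if (!is.numeric(prior) || length(prior) != 3L || any(prior <= 0))
    stop("`prior` must be three positive Dirichlet concentrations",
         call. = FALSE)
  resolution <- as.integer(resolution)
  if (resolution < 100L)
    stop("`resolution` must be >= 100 for a usable quadrature",
         call. = FALSE)

  E <- eta_matrix(r)[, c("w1", "w2", "w3")]
  # midpoint rule over the barycentric subdivision into resolution^2
  # equal-area triangles: centroids of upward and downward cells
  R <- resolution
  g_up <- expand.grid(i = 0:(R - 1L), j = 0:(R - 1L))
  g_up <- g_up[g_up$i + g_up$j <= R - 1L, ]
  Q_up <- cbind(g_up$i + 1 / 3, g_up$j + 1 / 3,
                R - 1L - g_up$i - g_up$j + 1 / 3) / R
  if (R >= 2L) {
    g_dn <- expand.grid(i = 0:(R - 2L), j = 0:(R - 2L))
    g_dn <- g_dn[g_dn$i + g_dn$j <= R - 2L, ]
    Q_dn <- cbind(g_dn$i + 2 / 3, g_dn$j + 2 / 3,
                  R - 2L - g_dn$i - g_dn$j + 2 / 3) / R
    Q <- rbind(Q_up, Q_dn)
  } else {
    Q <- Q_up
  }

  # (alpha - 1) * log q with the 0 * log 0 = 0 convention (alpha_s = 1)
  logq <- log(Q)
  lp <- numeric(nrow(Q))
  for (s in 1:3) {
    a1 <- prior[s] - 1
    if (a1 != 0) lp <- lp + a1 * logq[, s]
  }
  P <- Q %*% E                    # node x w marginal step probabilities
  for (w in 1:3) {
    if (n[w] > 0) lp <- lp + n[w] * log(P[, w])
  }
  lp[is.nan(lp)] <- -Inf
  m <- max(lp)
  wgt <- exp(lp - m)
  wgt <- wgt / sum(wgt)
  mu <- drop(crossprod(Q, wgt))
  m2 <- drop(crossprod(Q^2, wgt))
  sdv <- sqrt(pmax(m2 - mu^2, 0))
  names(mu) <- names(sdv) <- c("monomer", "dimer", "oligomer")
  list(mean = mu, sd = sdv, resolution = resolution)
}

#' Posterior-predictive check of a fitted oligomer distribution
#'
#' Averages the step-count distribution [observed_marginal()] over the
#' retained posterior draws and compares it with the empirical step
#' fractions, as a goodness-of-fit diagnostic.
#'
#' @param fit An [oligo_fit()] object.
#' @return A list with `predicted` and `empirical` step fractions (w = 1, 2,
#'   3) and `max_discrepancy`, their maximum absolute difference. With N = 0
#'   the empirical fractions and discrepancy are `NA`.
#' @export
posterior_predictive_check <- function(fit) {
  stopifnot(inherits(fit, "oligo_fit"))
  E <- eta_matrix(fit$r)[, c("w1", "w2", "w3")]
  pred <- colMeans(fit$samples %*% E)
  names(pred) <- c("w1", "w2", "w3")
  if (fit$N > 0) {
    emp <- fit$counts / fit$N
    names(emp) <- c("w1", "w2", "w3")
    disc <- max(abs(pred - emp))
  } else {
    emp <- stats::setNames(rep(NA_real_, 3L), c("w1", "w2", "w3"))
    disc <- NA_real_
  }
  list(predicted = pred, empirical = emp, max_discrepancy = disc)
}
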