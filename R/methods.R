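# S3 methods for the "oligo_fit" class.

#' @export
print.oligo_fit <- function(x, digits = 3, ...) {
  cat("Oligomer distribution corrected for GFP maturation\n")
  cat(sprintf("  counts: n1 = %d, n2 = %d, n3 = %d  (N = %d);  r = %g\n",
              x$counts[["n1"]], x$counts[["n2"]], x$counts[["n3"]],
              x$N, x$r))
  cat("  posterior mean (SD):\n")
  for (k in seq_along(x$mean))
    cat(sprintf("    %-9s %s (%s)\n", names(x$mean)[k],
                format(round(x$mean[k], digits), nsmall = digits),
                format(round(x$sd[k], digits), nsmall = digits)))
  invisible(x)
}

#' Posterior mean of the oligomer distribution
#' @param object An [oligo_fit()] object.
#' @param ... Unused.
#' @return Named numeric vector (monomer, dimer, oligomer) on the simplex.
#' @export
coef.oligo_fit <- function(object, ...) object$mean

#' @export
vcov.oligo_fit <- function(object, ...) stats::cov(object$samples)

#' Central posterior credible intervals
#' @param object An [oligo_fit()] object.
#' @param parm Components to report (names or indices); all by default.
#' @param level Credible level (default 0.95).
#' @param ... Unused.
#' @return Matrix of lower/upper quantiles, one row per component.
#' @export
confint.oligo_fit <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  ci <- t(apply(object$samples, 2L, stats::quantile, probs = c(a, 1 - a)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Posterior-predictive step fractions or corrected distribution
#'
#' @param object An [oligo_fit()] object.
#' @param type `"steps"` (default) for the posterior-predictive distribution
#'   of observed step counts w = 1, 2, 3; `"q"` for the posterior mean of
#'   the corrected oligomer distribution.
#' @param ... Unused.
#' @return Named numeric vector summing to 1.
#' @export
predict.oligo_fit <- function(object, type = c("steps", "q"), ...) {
  type <- match.arg(type)
  if (type == "q") return(object$mean)
  posterior_predictive_check(object)$predicted
}

#' @export
fitted.oligo_fit <- function(object, ...) predict(object, type = "steps")

#' Empirical minus predicted step fractions
#' @param object An [oligo_fit()] object.
#' @param ... Unused.
#' @return Named numeric vector over w = 1, 2, 3 (`NA` when N = 0).
#' @export
residuals.oligo_fit <- function(object, ...) {
  ppc <- posterior_predictive_check(object)
  ppc$empirical - ppc$predicted
}

#' Simulate step-count datasets from the posterior predictive
#'
#' Draws a retained posterior sample of q, computes the implied step-count
#' distribution [observed_marginal()], and draws N traces multinomially,
#' once per replicate.
#'
#' @param object An [oligo_fit()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @param ... Unused.
#' @return Data frame with `nsim` rows and columns `n1`, `n2`, `n3`.
#' @export
simulate.oligo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  E <- eta_matrix(object$r)[, c("w1", "w2", "w3")]
  with_seed(seed, {
    rows <- sample.int(nrow(object$samples), nsim, replace = TRUE)
    out <- t(vapply(rows, function(i) {
      p <- drop(object$samples[i, ] %*% E)
      drop(stats::rmultinom(1L, object$N, p))
    }, numeric(3L)))
    out <- as.data.frame(out)
    names(out) <- c("n1", "n2", "n3")
    out
  })
}

#' @export
summary.oligo_fit <- function(object, level = 0.95, ...) {
  ppc <- posterior_predictive_check(object)
  structure(list(fit = object, ci = confint(object, level = level),
                 level = level, ppc = ppc),
            class = "summary.oligo_fit")
}

#' @export
print.summary.oligo_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  %g%% credible intervals:\n", 100 * x$level))
  for (k in seq_len(nrow(x$ci)))
    cat(sprintf("    %-9s [%s, %s]   ESS %s\n", rownames(x$ci)[k],
                format(round(x$ci[k, 1], digits), nsmall = digits),
                format(round(x$ci[k, 2], digits), nsmall = digits),
                format(round(f$ess[k]))))
  if (!is.na(x$ppc$max_discrepancy)) {
    cat("  posterior-predictive step fractions (predicted / empirical):\n")
    for (k in 1:3)
      cat(sprintf("    w=%d  %s / %s\n", k,
                  format(round(x$ppc$predicted[k], digits), nsmall = digits),
                  format(round(x$ppc$empirical[k], digits), nsmall = digits)))
    cat(sprintf("  max predictive discrepancy: %s\n",
                format(round(x$ppc$max_discrepancy, digits))))
  }
  invisible(x)
}

#' Raw step fractions versus the corrected oligomer distribution
#'
#' Grouped bar chart contrasting the empirical fractions of 1-, 2- and
#' >=3-step traces with the maturation-corrected posterior means of
#' monomer/dimer/oligomer, with posterior-SD error bars.
#'
#' @param x An [oligo_fit()] object.
#' @param main Plot title.
#' @param ... Passed on to [graphics::barplot()].
#' @return Invisibly, the matrix of plotted heights.
#' @export
plot.oligo_fit <- function(x, main = "Raw steps vs corrected oligomer distribution",
                           ...) {
  raw <- if (x$N > 0) x$counts / x$N else rep(NA_real_, 3L)
  h <- rbind(`raw step fraction` = raw,
             `corrected (posterior mean)` = x$mean)
  colnames(h) <- c("1 / monomer", "2 / dimer", ">=3 / oligomer")
  mids <- graphics::barplot(h, beside = TRUE, ylim = c(0, 1),
                            legend.text = rownames(h), main = main,
                            ylab = "fraction", ...)
  graphics::arrows(mids[2, ], pmax(x$mean - x$sd, 0),
                   mids[2, ], pmin(x$mean + x$sd, 1),
                   angle = 90, code = 3, length = 0.04)
  invisible(h)
}
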