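# Shared fixtures and independent oracles, built in code at test time.

# The nine maturation probabilities written out literally (monomer, dimer,
# trimer rows), as an independent pin for the binomial implementation.
literal_pi <- function(r) {
  rbind(
    c(1 - r,       r,               0,               0),
    c((1 - r)^2,   2 * (1 - r) * r, r^2,             0),
    c((1 - r)^3,   3 * (1 - r)^2 * r, 3 * (1 - r) * r^2, r^3)
  )
}

# The detection-conditioned rows written out literally.
literal_eta <- function(r) {
  p <- literal_pi(r)
  e <- p / (1 - p[, 1])
  e[, 1] <- 0
  e
}

# Smaller sampler settings for unit tests; still hundreds of effective
# samples for this fast-mixing conjugate chain.
quick_fit <- function(counts, r = 0.7, seed = 1, iterations = 6000,
                      burn_in = 1000, ...) {
  oligo_fit(counts, r = r, seed = seed, iterations = iterations,
            burn_in = burn_in, ...)
}

# Monte-Carlo standard errors of a chain's mean and SD.
mcse_mean <- function(fit) fit$sd / sqrt(fit$ess)
mcse_sd <- function(fit) fit$sd / sqrt(2 * pmax(fit$ess - 1, 1))

# A noiseless staircase trace: `levels` intensity units per visible
# fluorophore, dwell frames per level, ending at background.
staircase <- function(n_fluor, dwell = 25, unit = 1, background = 0) {
  background + unit * rep(seq(n_fluor, 0), each = dwell)
}

# Empirical co-capture oracle: Poisson-distributed molecules placed
# uniformly on a torus at the density implied by `lambda` and the disc
# radius; discs dropped at random centers and molecules inside each disc
# counted geometrically. A fresh point field is drawn for each chunk of
# discs so field-level density fluctuations average out; the box is sized
# to hold ~2000 molecules so finite-field effects are negligible. Returns
# empirical P(K >= 2 | K >= 1) and the number of occupied discs.
cocapture_mc <- function(lambda, n_discs, disc_radius = 0.5,
                         chunk = 1000L) {
  density <- lambda / (pi * disc_radius^2)
  box <- sqrt(2000 / density)
  n_ge1 <- 0L
  n_ge2 <- 0L
  for (i0 in seq(1L, n_discs, by = chunk)) {
    nd <- min(chunk, n_discs - i0 + 1L)
    n_pts <- rpois(1L, density * box^2)
    px <- runif(n_pts, 0, box)
    py <- runif(n_pts, 0, box)
    cx <- runif(nd, 0, box)
    cy <- runif(nd, 0, box)
    dx <- abs(outer(cx, px, "-")); dx <- pmin(dx, box - dx)
    dy <- abs(outer(cy, py, "-")); dy <- pmin(dy, box - dy)
    counts <- rowSums(dx * dx + dy * dy < disc_radius^2)
    n_ge1 <- n_ge1 + sum(counts >= 1L)
    n_ge2 <- n_ge2 + sum(counts >= 2L)
  }
  list(p_hat = n_ge2 / n_ge1, n_occupied = n_ge1)
}
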