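#' Simulate photobleaching step-count data with ground truth
#'
#' Draws a population of complexes from a true oligomer distribution
#' `q` and generates observed step counts under one of two generative modes:
#' \describe{
#'   \item{`model_faithful`}{exactly the inference model's likelihood:
#'     s ~ Categorical(q), then w ~ Categorical(eta[s -> .]). Every
#'     attempted trace is delivered.}
#'   \item{`physical`}{the physical maturation process: s ~ Categorical(q),
#'     mature count m ~ Binomial(s, r); complexes with m = 0 are invisible
#'     and discarded (not delivered), and w = min(m, 3).}
#' }
#' The two modes agree exactly at r = 1. They differ subtly for r < 1:
#' under the physical process, detected complexes over-represent
#' higher-order species (each s is detected with probability
#' 1 - (1-r)^s), whereas the inference model places the Categorical(q)
#' prior on detected traces directly. Keeping both modes first-class makes
#' that model mismatch measurable.
#'
#' @param q True oligomer distribution, three probabilities summing to 1.
#' @param r Maturation efficiency in (0, 1].
#' @param n_traces Number of attempted complexes (positive integer).
#' @param mode `"model_faithful"` (default) or `"physical"`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A list with `counts` (a [step_counts()] tally of delivered
#'   traces), `truth` (data frame with per-trace `s_true`, `m_true`,
#'   `w`), `mode`, `attempted`, `delivered`, `discarded`.
#' @examples
#' sim <- simulate_counts(c(0, 1, 0), r = 0.7, n_traces = 1000, seed = 1)
#' sim$counts  # pure dimers look ~46% monomeric before correction
#' @export
simulate_counts <- function(q, r = 0.7, n_traces,
                            mode = c("model_faithful", "physical"),
                            seed = NULL) {
  q <- check_simplex(q)
  check_rate(r)
  mode <- match.arg(mode)
  n_traces <- as.integer(n_traces)
  if (n_traces < 1L) stop("`n_traces` must be positive", call. = FALSE)
  E <- eta_matrix(r)[, c("w1", "w2", "w3")]

  with_seed(seed, {
    s <- sample.int(3L, n_traces, replace = TRUE, prob = q)
    if (mode == "model_faithful") {
      w <- integer(n_traces)
      for (sv in 1:3) {
        idx <- which(s == sv)
        if (length(idx))
          w[idx] <- sample.int(3L, length(idx), replace = TRUE,
                               prob = E[sv, ])
      }
      m <- w  # visible (mature) copies are what the model sees
      keep <- rep(TRUE, n_traces)
    } else {
      m <- stats::rbinom(n_traces, s, r)
      keep <- m > 0L
      w <- pmin(m, 3L)
    }
    tal <- tabulate(w[keep], nbins = 3L)
    list(
      counts = step_counts(tal[1], tal[2], tal[3]),
      truth = data.frame(s_true = s[keep], m_true = m[keep], w = w[keep]),
      mode = mode,
      attempted = n_traces,
      delivered = sum(keep),
      discarded = sum(!keep)
    )
  })
}

#' Simulate single-molecule photobleaching intensity traces
#'
#' Generates TIRF-like intensity time traces with known ground truth for
#' benchmarking the step detector and the full pipeline. For each delivered
#' complex, the number of visible fluorophores is drawn as in
#' [simulate_counts()] (same two modes); each visible fluorophore bleaches
#' at an independent Exponential(`bleach_rate`) time; the intensity at frame
#' t is `background + unit_intensity * (number unbleached at t)` plus
#' additive Gaussian noise. Bleach events falling in the same frame are
#' pushed to consecutive frames so distinct events occupy distinct frames;
#' an event pushed past the end of the window (or landing there by chance)
#' stays unbleached and the per-trace ground-truth step count only counts
#' in-window events.
#'
#' @inheritParams simulate_counts
#' @param unit_intensity Fluorescence units contributed by one mature GFP
#'   (default 100).
#' @param noise_sigma Additive Gaussian noise SD in fluorescence units
#'   (default 12.5, i.e. step/noise = 8 at the default unit intensity).
#' @param bleach_rate Per-fluorophore bleaching hazard in 1/s (default 0.2).
#' @param n_frames Frames per trace (>= 20; default 400).
#' @param frame_interval Seconds per frame (default 0.1, i.e. 100 ms
#'   integration).
#' @param background Baseline fluorescence units (default 50).
#' @return A list with `traces` (a `trace_set`: `time`, `intensities`
#'   frames-x-traces matrix, `ids`, `frame_interval`) and `truth` (data
#'   frame: `trace_id`, `s_true`, `m_true`, `n_steps_true`, `coincident`),
#'   plus the bookkeeping fields of [simulate_counts()].
#' @examples
#' sim <- simulate_traces(c(0, 1, 0), r = 1, n_traces = 5,
#'                        noise_sigma = 0, seed = 1)
#' detect_steps(sim$traces$intensities[, 1])$n_steps
#' @export
simulate_traces <- function(q, r = 0.7, n_traces,
                            mode = c("model_faithful", "physical"),
                            unit_intensity = 100, noise_sigma = 12.5,
                            bleach_rate = 0.2, n_frames = 400,
                            frame_interval = 0.1, background = 50,
                            seed = NULL) {
  q <- check_simplex(q)
  check_rate(r)
  mode <- match.arg(mode)
  n_traces <- as.integer(n_traces)
  n_frames <- as.integer(n_frames)
  if (n_traces < 1L) stop("`n_traces` must be positive", call. = FALSE)
  if (unit_intensity <= 0) stop("`unit_intensity` must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (bleach_rate <= 0) stop("`bleach_rate` must be > 0", call. = FALSE)
  if (n_frames < 20L) stop("`n_frames` must be >= 20", call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  duration <- n_frames * frame_interval
  if (1 / bleach_rate > duration / 3)
    warning("mean bleach time (", format(1 / bleach_rate),
            " s) is large relative to the observation window (",
            format(duration), " s); many fluorophores may not bleach",
            call. = FALSE)

  with_seed(seed, {
    cnt <- simulate_counts(q, r = r, n_traces = n_traces, mode = mode)
    m <- cnt$truth$m_true
    nd <- length(m)
    mat <- matrix(NA_real_, n_frames, nd)
    n_true <- integer(nd)
    coincident <- logical(nd)
    for (i in seq_len(nd)) {
      tb <- stats::rexp(m[i], rate = bleach_rate)
      # a fluorophore bleaching during frame k first shows its lower level
      # at frame k + 1, so the earliest observable drop is at frame 2 and a
      # drop is in-window only if the new level appears before the end
      k_raw <- sort(floor(tb / frame_interval) + 2)
      k <- k_raw
      for (j in seq_along(k)[-1])
        if (k[j] <= k[j - 1]) k[j] <- k[j - 1] + 1L
      inw <- k[k <= n_frames]
      coincident[i] <- length(inw) < sum(k_raw <= n_frames)
      n_true[i] <- length(inw)
      drops <- tabulate(inw, nbins = n_frames)
      unbleached <- m[i] - cumsum(drops)
      y <- background + unit_intensity * unbleached
      if (noise_sigma > 0) y <- y + stats::rnorm(n_frames, 0, noise_sigma)
      mat[, i] <- y
    }
    ids <- sprintf("trace_%05d", seq_len(nd))
    colnames(mat) <- ids
    list(
      traces = structure(list(time = (seq_len(n_frames) - 1L) * frame_interval,
                              intensities = mat, ids = ids,
                              frame_interval = frame_interval),
                         class = "trace_set"),
      truth = data.frame(trace_id = ids, s_true = cnt$truth$s_true,
                         m_true = m, n_steps_true = n_true,
                         coincident = coincident,
                         stringsAsFactors = FALSE),
      mode = mode,
      attempted = cnt$attempted,
      delivered = cnt$delivered,
      discarded = cnt$discarded
    )
  })
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d traces x %d frames (%.3g s/frame)\n",
              ncol(x$intensities), nrow(x$intensities), x$frame_interval))
  invisible(x)
}
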