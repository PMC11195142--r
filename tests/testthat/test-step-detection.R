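test_that("noise estimator is consistent, robust to steps, and shift-invariant", {
  set.seed(101)
  x <- rnorm(1e4, sd = 1)
  expect_lt(abs(estimate_noise(x) - 1), 0.05)
  # a noiseless staircase has essentially zero noise scale
  st <- staircase(3, unit = 100)
  expect_lt(estimate_noise(st), 1e-9 * 100)
  # translation invariance
  expect_equal(estimate_noise(x), estimate_noise(x + 1e4),
               tolerance = 1e-9)
  # steps do not inflate the estimate much
  y <- x + 100 * rep(c(3, 2, 1, 0), each = 2500)
  expect_lt(abs(estimate_noise(y) - 1), 0.1)
  expect_error(estimate_noise(c(1, NA, 3)), "missing")
})

test_that("a noiseless staircase is called exactly", {
  call <- detect_steps(staircase(3, dwell = 25))
  expect_identical(call$status, "accepted")
  expect_identical(call$n_steps, 3L)
  expect_identical(call$changepoint_frames, c(26L, 51L, 76L))
  expect_equal(call$segment_levels, c(3, 2, 1, 0), tolerance = 1e-12)
})

test_that("rejection rules fire for pathological traces", {
  expect_identical(detect_steps(rep(5, 50))$status, "rejected_zero_steps")
  # upward jump (blinking / aggregation)
  up <- c(rep(1, 30), rep(2, 30), rep(0, 30))
  expect_identical(detect_steps(up)$status, "rejected_upward")
  # sub-threshold upward drift after the last bleach: the molecule ends
  # well above the lowest fitted level without a rejectable up-jump
  set.seed(33)
  nb <- c(rep(5, 40), rep(0, 40), rep(1.2, 40)) + rnorm(120, sd = 0.5)
  nb_call <- detect_steps(nb)
  expect_identical(nb_call$status, "rejected_no_bleach")
  # more steps than max_steps
  many <- staircase(5, dwell = 10)
  expect_identical(
    detect_steps(many, step_params(max_steps = 3))$status,
    "rejected_too_many")
  expect_identical(detect_steps(many)$status, "accepted")
  expect_error(detect_steps(rep(1, 10)), "at least 20 frames")
})

test_that("step calls are deterministic and scale-equivariant", {
  set.seed(55)
  x <- staircase(2, dwell = 40, unit = 100) + rnorm(120, sd = 12)
  c1 <- detect_steps(x)
  c2 <- detect_steps(x)
  expect_identical(c1[c("n_steps", "status", "changepoint_frames")],
                   c2[c("n_steps", "status", "changepoint_frames")])
  c3 <- detect_steps(x * 1000)
  expect_identical(c1$n_steps, c3$n_steps)
  expect_identical(c1$changepoint_frames, c3$changepoint_frames)
  expect_identical(c1$status, c3$status)
})

test_that("faint noise does not change accepted calls", {
  sim <- simulate_traces(c(0.3, 0.4, 0.3), r = 1, n_traces = 100,
                         noise_sigma = 0, seed = 61)
  mat <- sim$traces$intensities
  set.seed(62)
  noisy <- mat + rnorm(length(mat), sd = 100 / 20)  # step/noise = 20
  clean_calls <- call_steps(mat)
  noisy_calls <- call_steps(noisy)
  acc <- clean_calls$status == "accepted"
  expect_true(all(noisy_calls$status[acc] == "accepted"))
  expect_identical(noisy_calls$n_steps[acc], clean_calls$n_steps[acc])
})

test_that("detector recovers ground truth on a benchmark panel", {
  sim <- simulate_traces(c(1, 1, 1) / 3, r = 1, n_traces = 200,
                         noise_sigma = 12.5, seed = 71)  # step/noise = 8
  calls <- call_steps(sim$traces)
  acc <- calls$status == "accepted"
  expect_gt(mean(acc), 0.9)
  agree <- calls$n_steps[acc] == sim$truth$n_steps_true[acc]
  expect_gte(mean(agree), 0.95)
  # noiseless: every accepted call exact
  sim0 <- simulate_traces(c(1, 1, 1) / 3, r = 1, n_traces = 100,
                          noise_sigma = 0, seed = 72)
  calls0 <- call_steps(sim0$traces)
  acc0 <- calls0$status == "accepted"
  expect_identical(calls0$n_steps[acc0], sim0$truth$n_steps_true[acc0])
})

test_that("bin_steps applies the higher-order binning rule and audits rejections", {
  calls <- data.frame(
    trace_id = paste0("t", 1:7),
    n_steps = c(1L, 2L, 3L, 4L, 5L, 2L, 0L),
    status = c(rep("accepted", 5), "rejected_upward",
               "rejected_zero_steps"),
    stringsAsFactors = FALSE
  )
  n <- bin_steps(calls)
  expect_identical(as.integer(n), c(1L, 1L, 3L))
  rej <- attr(n, "rejections")
  expect_identical(rej[["rejected_upward"]], 1L)
  expect_identical(rej[["rejected_zero_steps"]], 1L)
  # all rejected: zero tally plus audit
  allrej <- transform(calls, status = "rejected_no_bleach")
  n0 <- bin_steps(allrej)
  expect_identical(as.integer(n0), c(0L, 0L, 0L))
  expect_identical(attr(n0, "rejections")[["rejected_no_bleach"]], 7L)
})

test_that("n3 is non-decreasing in max_steps", {
  set.seed(81)
  traces <- lapply(1:40, function(i) {
    k <- sample(2:6, 1)
    staircase(k, dwell = 15, unit = 100) + rnorm(15 * (k + 1), sd = 10)
  })
  n3 <- vapply(c(3, 4, 6, 10), function(ms) {
    calls <- call_steps(traces, step_params(max_steps = ms))
    unclass(bin_steps(calls))[["n3"]]
  }, integer(1))
  expect_true(all(diff(n3) >= 0))
})
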