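test_that("F/F0 normalization uses the pre-stimulus baseline", {
  t <- seq(0, 20, by = 0.3)
  constant <- normalize_trace(t, rep(500, length(t)), stim_start = 10)
  expect_true(all(abs(constant$normalized - 1) < 1e-12))
  expect_equal(attr(constant, "F0"), 500)
  stepped <- normalize_trace(t, ifelse(t < 10, 300, 600), stim_start = 10)
  expect_true(all(abs(stepped$normalized[t < 10] - 1) < 1e-12))
  expect_true(all(abs(stepped$normalized[t >= 10] - 2) < 1e-12))
  # normalizing a normalized trace with the same window is the identity
  renorm <- normalize_trace(constant$time_s, constant$normalized,
                            stim_start = 10)
  expect_equal(renorm$normalized, constant$normalized, tolerance = 1e-12)
})

test_that("normalization validates its baseline window", {
  t <- seq(0, 20, by = 0.3)
  expect_error(normalize_trace(t, rep(-5, length(t)), stim_start = 10),
               "positive")
  expect_error(normalize_trace(t, rep(1, length(t)), stim_start = 10,
                               baseline_window = c(9, 12)),
               "precede")
  expect_error(normalize_trace(t, rep(1, length(t)), stim_start = 0.2),
               "3 samples")
})

test_that("per-burst peaks recover the generated burst structure", {
  tr <- generate_trace(noise_sd = 0, rundown_fraction = 1,
                       first_amplitude = 0.9, seed = 1)
  nt <- normalize_trace(tr$trace, NULL, stim_start = tr$truth$stim_start)
  amps <- per_burst_peaks(nt, tr$protocol)
  expect_length(amps, 18L)
  expect_equal(amps, rep(0.9, 18), tolerance = 0.01)
  expect_equal(remaining_calcium(amps), 100, tolerance = 1)
  # rundown 0.6: log-linear decrease, last/first = 0.6
  tr6 <- generate_trace(noise_sd = 0, rundown_fraction = 0.6, seed = 1)
  nt6 <- normalize_trace(tr6$trace, NULL, stim_start = tr6$truth$stim_start)
  amps6 <- per_burst_peaks(nt6, tr6$protocol)
  expect_equal(amps6[18] / amps6[1], 0.6, tolerance = 0.01)
  expect_true(all(diff(amps6) < 0))
  # flat trace: all amplitudes clip to 0
  t <- seq(0, 190, by = 0.3)
  flat <- normalize_trace(t, rep(400, length(t)), stim_start = 5)
  expect_identical(per_burst_peaks(flat, stim_protocol(), stim_start = 5),
                   rep(0, 18))
  # truncated trace errors and names the missing bursts
  short <- flat[flat$time_s < 100, ]
  attr(short, "stim_start") <- 5
  class(short) <- class(flat)
  expect_error(per_burst_peaks(short, stim_protocol()), "missing burst")
})

test_that("responder classification is strict at the threshold", {
  expect_false(classify_responder(0.4))
  expect_true(classify_responder(0.6))
  expect_false(classify_responder(0.5))   # exact tie -> non-responder
  # threshold monotonicity: raising it never adds responders
  amps <- runif(50, 0, 1.5)
  counts <- vapply(seq(0, 1.5, by = 0.1),
                   function(th) sum(classify_responder(amps, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("decay time recovers the generator time constant", {
  for (tau in c(1, 2, 3)) {
    tr <- generate_trace(noise_sd = 0, decay_tau = tau, seed = 1)
    nt <- normalize_trace(tr$trace, NULL, stim_start = tr$truth$stim_start)
    dt <- decay_time(nt, tr$protocol)
    expect_false(dt$censored)
    expect_lt(abs(dt$decay_s - tau), 1 / 3.3)
    fit <- decay_time(nt, tr$protocol, method = "fit")
    expect_equal(fit$decay_s, tau, tolerance = 0.05)
  }
})

test_that("degenerate decays are flagged", {
  # instantaneous return to baseline: decay below one sample interval
  t <- seq(0, 30, by = 0.3)
  F <- rep(1, length(t)); F[t >= 10 & t < 10.3] <- 2.5
  nt <- normalize_trace(t, F, stim_start = 10)
  dt <- decay_time(nt, stim_protocol(total_duration = 15), stim_start = 10)
  expect_lte(dt$decay_s, 0.3 + 1e-9)
  # non-decaying plateau: censored
  Fp <- ifelse(t < 10, 1, 2.5)
  ntp <- normalize_trace(t, Fp, stim_start = 10)
  dp <- decay_time(ntp, stim_protocol(total_duration = 15), stim_start = 10)
  expect_true(dp$censored)
  expect_true(is.na(dp$decay_s))
  # flat trace: amplitude not positive -> undefined
  ntf <- normalize_trace(t, rep(2, length(t)), stim_start = 10)
  expect_error(decay_time(ntf, stim_protocol(total_duration = 15),
                          stim_start = 10),
               class = "myoquant_undefined")
})

test_that("remaining calcium is the last/first amplitude percentage", {
  expect_equal(remaining_calcium(c(1, 0.5, 1)), 100)
  expect_equal(remaining_calcium(c(1.0, 0.7, 0.25)), 25)
  expect_error(remaining_calcium(c(0, 1)), class = "myoquant_undefined")
  tr <- generate_trace(noise_sd = 0, rundown_fraction = 0.6, seed = 2)
  nt <- normalize_trace(tr$trace, NULL, stim_start = tr$truth$stim_start)
  expect_equal(remaining_calcium(per_burst_peaks(nt, tr$protocol)), 60,
               tolerance = 0.02)
})

test_that("population response rates count responders per group", {
  flags <- c(rep(TRUE, 19), FALSE)
  rates <- population_response_rates(flags, rep("nanopattern", 20))
  expect_equal(rates$rate, 0.95)
  none <- population_response_rates(rep(FALSE, 5), rep("flat", 5))
  expect_equal(none$rate, 0)
  expect_error(population_response_rates(logical(0), character(0)),
               class = "myoquant_undefined")
  # Monte-Carlo: recovered rate within the 99% binomial interval
  set.seed(11)
  p <- 0.7; n <- 200
  draw <- runif(n) < p
  r <- population_response_rates(draw, rep("g", n))$rate
  ci <- qbinom(c(0.005, 0.995), n, p) / n
  expect_gte(r, ci[1]); expect_lte(r, ci[2])
})

test_that("transient_metrics aggregates and tolerates non-responders", {
  tr <- generate_trace(responder = FALSE, noise_sd = 5, seed = 3)
  nt <- normalize_trace(tr$trace, NULL, stim_start = tr$truth$stim_start)
  m <- transient_metrics(nt, tr$protocol)
  expect_false(m$is_responder)
  expect_length(m$per_burst_amplitude, 18L)
  # flat trace: undefined remaining/decay become NA, not errors
  t <- seq(0, 190, by = 0.3)
  flat <- normalize_trace(t, rep(400, length(t)), stim_start = 5)
  mf <- transient_metrics(flat, stim_protocol(), stim_start = 5)
  expect_true(is.na(mf$remaining_pct))
  expect_true(is.na(mf$decay_s))
})
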