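test_that("empty generators return empty masks and tables", {
  f <- generate_nuclei_field(0)
  expect_identical(mask_labels(f$mask), integer(0))
  expect_identical(nrow(f$truth), 0L)
  a <- generate_achr_field(0)
  expect_identical(mask_labels(a$mask), integer(0))
  expect_identical(nrow(a$truth), 0L)
})

test_that("generators are pure functions of their seed", {
  f1 <- generate_nuclei_field(25, seed = 7)
  f2 <- generate_nuclei_field(25, seed = 7)
  expect_identical(f1$mask$labels, f2$mask$labels)
  expect_identical(f1$truth, f2$truth)
  expect_false(identical(f1$mask$labels,
                         generate_nuclei_field(25, seed = 8)$mask$labels))
  a1 <- generate_achr_field(10, seed = 3)
  a2 <- generate_achr_field(10, seed = 3)
  expect_identical(a1$mask$labels, a2$mask$labels)
  t1 <- generate_trace(seed = 4, noise_sd = 20)
  t2 <- generate_trace(seed = 4, noise_sd = 20)
  expect_identical(t1$trace$F, t2$trace$F)
  c1 <- generate_ct_table(c("g", "h1", "h2"), c("a", "b"), 2,
                          matrix(1, 3, 2), c("h1", "h2"), "a",
                          noise_sd = 0.1, seed = 5)
  c2 <- generate_ct_table(c("g", "h1", "h2"), c("a", "b"), 2,
                          matrix(1, 3, 2), c("h1", "h2"), "a",
                          noise_sd = 0.1, seed = 5)
  expect_identical(c1$table$ct, c2$table$ct)
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(generate_trace(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("mask truth tables record exact rasterized geometry", {
  f <- generate_nuclei_field(20, seed = 2)
  counts <- table(f$mask$labels[f$mask$labels > 0])
  expect_equal(f$truth$n_pixels, as.vector(counts))
  expect_equal(f$truth$area_um2,
               as.vector(counts) * f$mask$pixel_size^2)
  a <- generate_achr_field(12, seed = 2)
  counts_a <- table(a$mask$labels[a$mask$labels > 0])
  expect_equal(a$truth$area_um2,
               as.vector(counts_a) * a$mask$pixel_size^2)
})

test_that("singleton-only fields keep all pairs at least 3 um apart", {
  f <- generate_nuclei_field(30, cluster_size_prob = 1, seed = 6)
  g <- bf_gap_matrix(f$mask)
  offdiag <- g[upper.tri(g)]
  expect_true(all(offdiag >= 3))
  asg <- cluster_nuclei(f$mask)
  expect_true(all(asg$is_isolated))
})

test_that("uniform orientations have circular variance near 1, aligned near 0", {
  # Monte-Carlo over seeds on the doubled angles
  oris <- unlist(lapply(1:10, function(s)
    generate_nuclei_field(50, seed = s,
                          orientation_concentration = 0)$truth$orientation_deg))
  expect_length(oris, 500)
  doubled <- 2 * oris * pi / 180
  circ_var <- 1 - sqrt(mean(cos(doubled))^2 + mean(sin(doubled))^2)
  expect_gt(circ_var, 0.9)
  aligned <- generate_nuclei_field(60, seed = 1,
                                   orientation_concentration = 25)$truth
  expect_lt(stats::median(abs(aligned$orientation_deg)), 15)
})

test_that("placement failure is signalled on an overcrowded field", {
  expect_error(generate_nuclei_field(40, field_size = c(80L, 80L), seed = 1,
                                     max_retries = 25),
               class = "myoquant_placement_error")
})

test_that("noiseless traces have the constructed burst structure", {
  tr <- generate_trace(noise_sd = 0, rundown_fraction = 1,
                       first_amplitude = 1.2, seed = 1)
  expect_length(tr$truth$amplitudes, 18L)
  expect_true(all(abs(tr$truth$amplitudes - 1.2) < 1e-12))
  tr6 <- generate_trace(noise_sd = 0, rundown_fraction = 0.6, seed = 1)
  amps <- tr6$truth$amplitudes
  expect_equal(amps[length(amps)] / amps[1], 0.6, tolerance = 1e-12)
  # log-linear run-down: constant ratio between consecutive bursts
  expect_equal(diff(log(amps)), rep(log(0.6) / 17, 17), tolerance = 1e-9)
  expect_error(generate_trace(protocol = stim_protocol(total_duration = 0.5)),
               "shorter than one burst")
})

test_that("non-responder traces stay below the classification threshold", {
  tr <- generate_trace(responder = FALSE, first_amplitude = 1.5,
                       noise_sd = 0, seed = 1)
  nt <- normalize_trace(tr$trace, F = NULL,
                        stim_start = tr$truth$stim_start)
  amps <- per_burst_peaks(nt, tr$protocol)
  expect_true(all(amps < 0.5))
  expect_false(classify_responder(amps[1]))
})

test_that("explicit AChR areas land on the requested side of the filter", {
  f <- generate_achr_field(3, areas = c(3, 5, 8), seed = 2)
  kept <- filter_achr_clusters(f$mask, min_area = 5)
  expect_identical(nrow(kept), 1L)
  expect_gt(kept$area_um2, 5)
})

test_that("striation generator validates its preconditions", {
  expect_error(generate_striation_profile(2.5, n_periods = 1), ">= 3")
  expect_error(generate_striation_profile(0.5, 5, peak_width = 0.8),
               "exceed")
  expect_error(generate_striation_profile(2.5, 5, sampling = 1), "finer")
  pr <- generate_striation_profile(2.5, 6, noise_sd = 0)
  pk <- which(diff(sign(diff(pr$intensity))) == -2) + 1
  expect_equal(diff(pr$position_um[pk]), rep(2.5, length(pk) - 1),
               tolerance = 1e-9)
})

test_that("Ct generator demands two stable housekeeping genes", {
  fcm <- matrix(1, 2, 2, dimnames = list(c("g", "h"), c("a", "b")))
  expect_error(generate_ct_table(c("g", "h"), c("a", "b"), 2, fcm,
                                 hk_genes = "h", reference = "a"),
               "two housekeeping")
  fcm2 <- matrix(c(1, 2, 1, 1, 1, 1), 3, 2,
                 dimnames = list(c("g", "h1", "h2"), c("a", "b")))
  expect_error(generate_ct_table(c("g", "h1", "h2"), c("a", "b"), 2,
                                 rbind(fcm2[1, ], h1 = c(1, 2), h2 = c(1, 1)),
                                 hk_genes = c("h1", "h2"), reference = "a"),
               "unit true fold")
})
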