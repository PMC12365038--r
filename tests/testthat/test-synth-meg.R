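test_that("helmet arrays are triaxial, orthonormal and outside the sphere", {
  a <- build_helmet_array(64, 0.12)
  expect_equal(a$n_sensors, 64L)
  expect_length(a$channel_names, 192)
  for (s in seq_len(64)) {
    G <- a$axes[s, , ] %*% t(a$axes[s, , ])
    expect_lt(max(abs(G - diag(3))), 1e-10)
  }
  r <- sqrt(rowSums(a$positions^2))
  expect_true(all(abs(r - 0.12) < 1e-12))
  expect_true(all(r > 0.09))
  d <- as.matrix(dist(a$positions))
  diag(d) <- Inf
  expect_gt(min(d), 0)
  expect_error(build_helmet_array(0), "n_sensors")
})

test_that("spherical lead field is silent for central and radial dipoles", {
  sensor <- c(0.03, 0.05, 0.10)
  axis <- c(0, 0, 1)
  # dipole at the sphere centre
  expect_equal(sphere_lead_field(c(0, 0, 0), c(1e-9, 2e-9, -1e-9), sensor),
               c(0, 0, 0))
  # purely radial moment at an off-centre position
  r0 <- c(0.02, -0.01, 0.05)
  B <- sphere_lead_field(r0, 1e-9 * r0 / sqrt(sum(r0^2)), sensor)
  expect_lt(sqrt(sum(B^2)), 1e-25)
  # the tangential part of the moment carries the whole field
  set.seed(5)
  q <- rnorm(3) * 1e-9
  q_rad <- sum(q * r0) / sum(r0^2) * r0
  B_full <- sphere_lead_field(r0, q, sensor)
  B_tan <- sphere_lead_field(r0, q - q_rad, sensor)
  expect_equal(B_full, B_tan, tolerance = 1e-10)
})

test_that("lead field is linear and matches the potential-gradient oracle", {
  set.seed(8)
  for (i in 1:20) {
    r0 <- runif(3, -0.04, 0.04) + c(0, 0, 0.02)
    rs <- r0 / sqrt(sum(r0^2)) * 0.115 + runif(3, -0.01, 0.01)
    q <- rnorm(3) * 1e-9
    B <- sphere_lead_field(r0, q, rs)
    expect_equal(sphere_lead_field(r0, 2 * q, rs), 2 * B, tolerance = 1e-12)
    B_num <- sphere_field_numeric(r0, q, rs)
    expect_lt(sqrt(sum((B - B_num)^2)) / max(sqrt(sum(B^2)), 1e-30), 1e-5)
  }
  # geometry validation
  expect_error(sphere_lead_field(c(0, 0, 0.1), c(1e-9, 0, 0), c(0, 0, 0.12),
                                 conductor_radius = 0.09),
               "outside the conductor")
  expect_error(sphere_lead_field(c(0, 0, 0.05), c(1e-9, 0, 0), c(0, 0, 0.08),
                                 conductor_radius = 0.09),
               "inside the conductor")
})

test_that("burst rate calibration matches the Poisson generator", {
  set.seed(10)
  sched <- generate_schedule(0, 10)
  sched$total_duration_s <- 600
  spec <- burst_spec(baseline_rate = 2, attended_rate_factor = 1,
                     stim_suppression_factor = 1)
  sim <- simulate_source_timecourse(sched, spec, fs = 200,
                                    duration_s = 600)
  n_bursts <- nrow(sim$bursts)
  lambda <- 2 * 600
  expect_lt(abs(n_bursts - lambda), 3 * sqrt(lambda) + 2 * 2 * 0.26)
  expect_true(all(sim$bursts$onset_s >= 0 & sim$bursts$offset_s <= 600))
})

test_that("attended windows lose bursts in proportion to the rate factor", {
  set.seed(11)
  sched <- generate_schedule(100, 1e6, seed = 77)  # no rest trials needed
  spec <- burst_spec(baseline_rate = 2, attended_rate_factor = 0.5,
                     stim_suppression_factor = 1, background_sd = 0.1)
  sim <- simulate_source_timecourse(sched, spec, fs = 200, hand = "left")
  tr <- sched$trials
  count_in_cues <- function(cue) {
    sel <- tr$cue == cue
    sum(vapply(tr$start_s[sel], function(s0)
      sum(sim$bursts$onset_s >= s0 + 4 & sim$bursts$onset_s < s0 + 6), 1))
  }
  n_att <- count_in_cues("left")
  n_non <- count_in_cues("right")
  # Poisson counts: expected ratio 0.5, 3 SE propagated from both counts
  ratio <- n_att / n_non
  se <- ratio * sqrt(1 / n_att + 1 / n_non)
  expect_lt(abs(ratio - 0.5), 3 * se)
  # zero attended rate annihilates bursts in attended cue windows
  spec0 <- burst_spec(baseline_rate = 2, attended_rate_factor = 0,
                      stim_suppression_factor = 1)
  sim0 <- simulate_source_timecourse(sched, spec0, fs = 200, hand = "left")
  n0 <- sum(vapply(tr$start_s[tr$cue == "left"], function(s0)
    sum(sim0$bursts$onset_s >= s0 + 4 & sim0$bursts$onset_s < s0 + 6), 1))
  expect_equal(n0, 0)
})

test_that("burst packets are pan-spectral: alpha peak with a beta shoulder", {
  set.seed(12)
  sched <- generate_schedule(0, 10)
  spec <- burst_spec(baseline_rate = 4, background_sd = 0.02,
                     attended_rate_factor = 1, stim_suppression_factor = 1)
  sim <- simulate_source_timecourse(sched, spec, fs = 200, duration_s = 300)
  psd <- welch_psd(sim$x, fs = 200, segment_s = 2)
  band_power <- function(lo, hi) {
    sel <- psd$freqs >= lo & psd$freqs <= hi
    mean(psd$psd[1, sel])
  }
  alpha <- band_power(8, 13)
  beta <- band_power(13, 30)
  high <- band_power(35, 48)
  expect_gt(alpha, beta)     # dominant alpha peak
  expect_gt(beta, 3 * high)  # elevated beta shoulder above the 35-48 floor
  # alpha band contains a genuine local maximum of the spectrum
  sel <- psd$freqs >= 5 & psd$freqs <= 20
  f_peak <- psd$freqs[sel][which.max(psd$psd[1, sel])]
  expect_true(f_peak >= 8 && f_peak <= 13)
})

test_that("recordings superpose lead-field projections of the true sources", {
  sched <- generate_schedule(4, 10, seed = 21)
  model <- default_source_model(n_regions = 2)
  array <- build_helmet_array(8)
  ds <- simulate_recording(sched, model, array, spec = burst_spec(),
                           noise_asd = 0, drift_amplitude = 0, fs = 200,
                           seed = 22)
  ch <- channels_table(array)
  expected <- matrix(0, nrow(ch), ncol(ds$recording$data))
  for (r_ in 1:2) {
    L <- leadfield_matrix(ch, model$centroids[r_, ])
    gain <- L %*% ds$truth$orientations[r_, ]
    expected <- expected + gain %*% matrix(5e-9 * ds$truth$sources[r_, ], 1)
  }
  expect_equal(ds$recording$data, expected, tolerance = 1e-12)
  # bookkeeping: truth bursts lie inside the recording, per region
  expect_named(ds$truth$bursts, model$labels)
  for (b in ds$truth$bursts)
    expect_true(all(b$onset_s >= 0 & b$offset_s <= sched$total_duration_s))
})

test_that("identical seeds give bit-identical datasets", {
  sched <- generate_schedule(4, 10, seed = 31)
  model <- default_source_model(n_regions = 2)
  array <- build_helmet_array(8)
  d1 <- simulate_recording(sched, model, array, fs = 200, seed = 5)
  d2 <- simulate_recording(sched, model, array, fs = 200, seed = 5)
  expect_identical(d1$recording$data, d2$recording$data)
  expect_identical(d1$truth$bursts, d2$truth$bursts)
})
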