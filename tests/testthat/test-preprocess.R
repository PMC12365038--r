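test_that("Welch densities integrate to signal variance", {
  fs <- 1200
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  psd <- welch_psd(x, fs, segment_s = 2)
  df <- psd$freqs[2] - psd$freqs[1]
  expect_lt(abs(sum(psd$psd[1, ]) * df - 0.5) / 0.5, 0.05)
  # all-zero channel
  psd0 <- welch_psd(rep(0, fs * 10), fs)
  expect_true(all(psd0$psd == 0))
  # white noise sits at the flat analytic level sigma^2 / (fs / 2)
  set.seed(2)
  sigma <- 3e-13
  w <- rnorm(fs * 600, sd = sigma)
  psdw <- welch_psd(w, fs, segment_s = 2)
  sel <- psdw$freqs > 10 & psdw$freqs < 500
  expect_lt(abs(mean(psdw$psd[1, sel]) - sigma^2 / (fs / 2)) /
              (sigma^2 / (fs / 2)), 0.05)
  expect_error(welch_psd(rnorm(100), fs = 1200, segment_s = 2), "shorter")
})

test_that("bad channels are flagged by the noise floor rule", {
  freqs <- seq(0, 600, by = 0.5)
  nch <- 4
  # rows: flat 20, flat 5, dead, flat 15.9 fT/sqrt(Hz)
  lv <- c(20, 5, 0, 15.9) * 1e-15
  psd <- list(freqs = freqs,
              psd = matrix(lv^2, nch, length(freqs)))
  rownames(psd$psd) <- paste0("ch", 1:4)
  bad <- detect_bad_channels(psd, floor_limit = 16, band = c(5, 150))
  expect_setequal(names(bad), c("ch1", "ch3"))
  # monotone in the floor: raising the limit never flags more channels
  prev <- length(detect_bad_channels(psd, floor_limit = 4))
  for (fl in c(8, 16, 30)) {
    cur <- length(detect_bad_channels(psd, floor_limit = fl))
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(detect_bad_channels(psd, band = c(700, 800)), "band")
})

test_that("trial segmentation cuts clean 16 s blocks", {
  sched <- generate_schedule(4, 2, seed = 1)   # 4 task + 2 rest = 6 trials
  fs <- 200
  n <- sched$total_duration_s * fs
  rec <- list(data = matrix(rnorm(3 * n), 3, n), fs = fs,
              channels = data.frame(), events = schedule_to_events(sched),
              duration_s = sched$total_duration_s)
  class(rec) <- "opm_recording"
  tm <- segment_trials(rec)
  expect_equal(dim(tm$data), c(6, 3, 16 * fs))
  expect_equal(sum(tm$info$is_rest), 2)
  # segments reproduce the raw samples
  expect_equal(tm$data[2, , ], rec$data[, (16 * fs + 1):(32 * fs)])
  # empty events
  tm0 <- segment_trials(rec, events = rec$events[0, ])
  expect_equal(dim(tm0$data)[1], 0)
  # trial extending past the end errors
  rec2 <- rec
  rec2$data <- rec2$data[, 1:(n - 100)]
  expect_error(segment_trials(rec2), "past end")
})

test_that("high-variance trials are rejected by the 3 x SD rule", {
  set.seed(3)
  fs <- 100
  n_tr <- 11
  dat <- array(rnorm(n_tr * 2 * 16 * fs), c(n_tr, 2, 16 * fs))
  dat[7, , ] <- dat[7, , ] * 10
  tm <- structure(list(data = dat,
                       info = data.frame(trial_index = 1:n_tr,
                                         is_rest = FALSE, cue = "left"),
                       keep = rep(TRUE, n_tr), fs = fs),
                  class = "trial_matrix")
  out <- reject_bad_trials(tm, k = 3)
  expect_identical(which(!out$keep), 7L)
  # scale invariance
  tm2 <- tm; tm2$data <- tm2$data * 1e-13
  expect_identical(reject_bad_trials(tm2, k = 3)$keep, out$keep)
  # identical trials: none rejected
  tm3 <- tm; for (i in 1:n_tr) tm3$data[i, , ] <- tm$data[1, , ]
  expect_true(all(reject_bad_trials(tm3, k = 3)$keep))
  expect_true(all(reject_bad_trials(tm, k = Inf)$keep))
})

test_that("streaming trial QC agrees with the segment-and-reject path", {
  sched <- generate_schedule(6, 3, seed = 9)
  fs <- 150
  n <- sched$total_duration_s * fs
  set.seed(4)
  X <- matrix(rnorm(4 * n), 4, n)
  X[, (3 * 16 * fs + 1):(4 * 16 * fs)] <- X[, (3 * 16 * fs + 1):(4 * 16 * fs)] * 8
  rec <- structure(list(data = X, fs = fs, channels = data.frame(),
                        events = schedule_to_events(sched),
                        duration_s = sched$total_duration_s),
                   class = "opm_recording")
  slow <- reject_bad_trials(segment_trials(rec), k = 3)
  fast <- opmburst:::.trial_qc(rec, k = 3)
  expect_equal(unname(fast$keep), slow$keep)
  expect_equal(fast$trial_sd, slow$trial_sd, tolerance = 1e-10)
  expect_equal(fast$mask,
               kept_sample_mask(slow, ncol(X)))
})

test_that("homogeneous field correction annihilates uniform fields only", {
  array <- build_helmet_array(16)
  ch <- channels_table(array)
  ch$bad <- FALSE
  S <- as.matrix(ch[, c("ax", "ay", "az")])
  n <- 2000
  set.seed(6)
  b <- matrix(rnorm(3 * n), 3, n)              # arbitrary uniform field
  rec <- structure(list(data = S %*% b, fs = 100, channels = ch,
                        events = data.frame(), duration_s = n / 100),
                   class = "opm_recording")
  out <- homogeneous_field_correction(rec)
  expect_lt(sqrt(sum(out$recording$data^2)) / sqrt(sum(rec$data^2)), 1e-10)
  # data orthogonal to the axis model pass through untouched
  sv <- svd(S)
  P_perp <- diag(nrow(S)) - sv$u %*% t(sv$u)
  Xo <- P_perp %*% matrix(rnorm(nrow(S) * n), nrow(S), n)
  rec$data <- Xo
  out2 <- homogeneous_field_correction(rec)
  expect_lt(max(abs(out2$recording$data - Xo)) / max(abs(Xo)), 1e-12)
  # idempotence
  out3 <- homogeneous_field_correction(out2$recording)
  expect_lt(max(abs(out3$recording$data - out2$recording$data)) /
              max(abs(out2$recording$data)), 1e-12)
})

test_that("field correction recovers sources under heavy uniform drift", {
  sched <- generate_schedule(4, 2, seed = 41)
  model <- default_source_model(n_regions = 2)
  array <- build_helmet_array(16)
  clean <- simulate_recording(sched, model, array, noise_asd = 0,
                              drift_amplitude = 0, fs = 200, seed = 42)
  drifty <- simulate_recording(sched, model, array, noise_asd = 0,
                               drift_amplitude = 1e-11, fs = 200, seed = 42)
  out <- homogeneous_field_correction(drifty$recording)
  # uniform-component power attenuated by > 60 dB
  resid <- out$recording$data - clean$recording$data
  drift_part <- drifty$recording$data - clean$recording$data
  expect_lt(10 * log10(sum(resid^2) / sum(drift_part^2)), -60)
  # single-channel correlation with the clean projection
  i <- which.max(rowSums(clean$recording$data^2))
  expect_gt(cor(out$recording$data[i, ], clean$recording$data[i, ]), 0.99)
})
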