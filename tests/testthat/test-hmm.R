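test_that("time-delay embedding stacks centred lag windows", {
  emb <- tde_embed(rep(4, 100), fs = 100, n_lags = 5, target_fs = 100)
  # constant series z-scores to NaN-free zeros only if sd > 0; use a ramp
  x <- seq_len(100)
  emb <- tde_embed(x, fs = 100, n_lags = 5, target_fs = 100)
  expect_equal(dim(emb$X), c(96, 5))
  z <- (x - mean(x)) / sd(x)
  expect_equal(emb$X[1, ], z[1:5])
  expect_equal(emb$time_s, (emb$centre_idx - 1) / 100)
  # n_lags = 1 is the identity embedding
  emb1 <- tde_embed(x, fs = 100, n_lags = 1, target_fs = 100)
  expect_equal(as.numeric(emb1$X), z)
  expect_error(tde_embed(x, fs = 100, n_lags = 4), "odd")
  expect_error(tde_embed(x[1:10], fs = 100, n_lags = 15, target_fs = 100),
               "shorter")
})

test_that("embedded tone columns carry the analytic lag covariance", {
  fs <- 100
  f <- 8
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f * t)
  emb <- tde_embed(x, fs, n_lags = 9, target_fs = 100)
  C <- cov(emb$X)
  # cov(x_t, x_{t+d}) of a unit-variance tone is cos(2 pi f d / fs)
  for (d in 0:8) {
    expected <- cos(2 * pi * f * d / fs)
    got <- mean(C[cbind(seq_len(9 - d), seq_len(9 - d) + d)])
    expect_lt(abs(got - expected), 0.02)
  }
})

test_that("EM recovers a well-separated two-state generator", {
  set.seed(11)
  sim <- sample_two_state_series(2000)
  model <- fit_hmm(sim$x, K = 2, n_restarts = 3, seed = 12)
  post <- forward_backward(model, sim$x)
  z_hat <- max.col(post$gamma)
  al <- align_two_states(z_hat, sim$z)
  expect_gt(al$acc, 0.98)
  A_hat <- model$A[al$perm, al$perm]
  expect_lt(max(abs(A_hat - sim$A)), 0.05)
  # log-likelihood trace is monotone non-decreasing
  expect_true(all(diff(model$trace) > -1e-8 * abs(model$trace[-1])))
})

test_that("a one-state model degenerates to a single Gaussian", {
  set.seed(13)
  x <- rnorm(500, 2, 1.5)
  model <- fit_hmm(x, K = 1, n_restarts = 1, seed = 14)
  post <- forward_backward(model, x)
  expect_true(all(post$gamma == 1))
  ll_gauss <- sum(dnorm(x, mean(x), sqrt(var(x) * 499 / 500), log = TRUE))
  expect_equal(post$loglik, ll_gauss, tolerance = 1e-6)
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(15)
  for (i in 1:10) {
    T_ <- sample(6:8, 1)
    par <- random_hmm_params(T_, 3)
    fb <- opmburst:::.fb_cpp(par$logB, par$pi, par$A)
    expect_lt(abs(fb$loglik - enum_hmm_loglik(par$logB, par$pi, par$A)),
              1e-8)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-8))
  }
  # absorbing chain locks the posterior
  T_ <- 10
  logB <- matrix(0, T_, 3)
  fb <- opmburst:::.fb_cpp(logB, c(1, 0, 0), diag(3))
  expect_equal(fb$gamma[, 1], rep(1, T_))
})

test_that("binarisation keeps at most one state above the 2/3 threshold", {
  G <- rbind(c(0.70, 0.20, 0.10),
             c(0.60, 0.30, 0.10),
             c(0.10, 0.85, 0.05))
  B <- binarise(G)
  expect_equal(B[1, ], c(1, 0, 0))
  expect_equal(B[2, ], c(0, 0, 0))     # 0.60 is below 2/3
  expect_equal(B[3, ], c(0, 1, 0))
  set.seed(16)
  G2 <- matrix(rexp(300), 100, 3)
  G2 <- G2 / rowSums(G2)
  expect_true(all(rowSums(binarise(G2)) <= 1))
})

test_that("the burst state is the one tracking the beta envelope", {
  set.seed(17)
  env <- abs(rnorm(500)) + 1
  b2 <- as.integer(env > quantile(env, 0.7))
  B <- cbind(rbinom(500, 1, 0.2), b2, rbinom(500, 1, 0.2))
  expect_equal(select_burst_state(B, env), 2)
  # a state equal to the thresholded envelope itself wins
  expect_equal(select_burst_state(cbind(b2, 1 - b2, rbinom(500, 1, 0.5)),
                                  env), 1)
  expect_error(select_burst_state(B, rep(1, 500)), "constant")
  Bc <- B; Bc[, 1] <- 1
  expect_error(select_burst_state(Bc, env), "state 1")
})

test_that("burst events encode runs with duration and peak amplitude", {
  ev <- burst_events(c(0, 1, 1, 1, 0), fs = 100, envelope = c(1, 5, 2, 3, 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 0.03)
  expect_equal(ev$peak_amplitude, 5)
  expect_equal(nrow(burst_events(rep(0, 50), 100)), 0)
  ev2 <- burst_events(c(1, 1, 0, 0, 1, 0, 1, 1, 1), fs = 10)
  expect_equal(nrow(ev2), 3)
  expect_equal(ev2$duration_s, c(0.2, 0.1, 0.3))
})

test_that("burst probability is the across-trial occupancy fraction", {
  sched <- generate_schedule(4, 10, seed = 18)
  fs <- 10
  n <- sched$total_duration_s * fs
  time_s <- (0:(n - 1)) / fs
  binary <- rep(0L, n)
  # burst at 5 s into trials 1 and 3 only
  for (tr in c(1, 3)) binary[round((sched$trials$start_s[tr] + 5) * fs) + 1] <- 1L
  cond <- paste0("cue_", sched$trials$cue[1])
  bp <- burst_probability(binary, time_s, sched, cond)
  same_cue <- sum(sched$trials$cue == sched$trials$cue[1], na.rm = TRUE)
  i5 <- which(bp$time == 5)
  hits <- sum(sched$trials$cue[c(1, 3)] == sched$trials$cue[1], na.rm = TRUE)
  expect_equal(bp$prob[i5], hits / same_cue)
  # binomial sampling check: per-timepoint Bernoulli occupancy
  set.seed(19)
  sched2 <- generate_schedule(1000, 1e6, seed = 20)
  n2 <- sched2$total_duration_s * fs
  b2 <- rbinom(n2, 1, 0.3)
  bp2 <- burst_probability(b2, (0:(n2 - 1)) / fs, sched2, "cue_left")
  se <- sqrt(0.3 * 0.7 / bp2$n_trials)
  expect_lt(abs(bp2$prob[80] - 0.3), 3 * se)
  expect_lt(abs(mean(bp2$prob) - 0.3), 3 * se / sqrt(10))
})

test_that("burst counting requires full encapsulation in the window", {
  ev <- data.frame(onset_s = c(4.2, 3.8, 5.9), offset_s = c(4.5, 4.5, 6.1))
  expect_equal(burst_count_in_window(ev, c(4, 6)), 1)
  expect_equal(burst_count_in_window(ev[0, ], c(4, 6)), 0)
  expect_equal(burst_count_in_window(ev, c(0, 16)), 3)
})

test_that("DPSS tapers are orthonormal and concentrated", {
  H <- dpss_tapers(128, nw = 3, k = 5)
  expect_equal(crossprod(H), diag(5), tolerance = 1e-8)
  expect_true(all(colSums(H) [1] > 0))
  # first taper is bell-shaped: no sign changes
  expect_true(all(H[, 1] > 0))
})

test_that("state-wise spectra honour occupancy weighting", {
  fs <- 100
  n <- 6000
  t <- (0:(n - 1)) / fs
  # 10 Hz tone only while state 1 is active (1 s alternating blocks)
  in_state1 <- ((floor(t) %% 2) == 0)
  x <- ifelse(in_state1, sin(2 * pi * 10 * t), 0) + rnorm(n, sd = 0.05)
  occ <- cbind(as.numeric(in_state1), as.numeric(!in_state1))
  sw <- statewise_multitaper(x, occ, fs, window_s = 1)
  i10 <- which.min(abs(sw$freqs - 10))
  expect_gt(sw$spectra[1, i10] / sw$spectra[2, i10], 10)
  expect_true(all(sw$spectra >= 0))
  # full occupancy recovers the plain equal-weight multitaper average
  sw_full <- statewise_multitaper(x, matrix(1, n, 1), fs, window_s = 1)
  H <- dpss_tapers(fs, 3, 5)
  nf <- fs / 2 + 1
  plain <- rowMeans(sapply(seq_len(floor(n / fs)), function(w) {
    seg <- x[((w - 1) * fs + 1):(w * fs)]
    seg <- seg - mean(seg)
    p <- rowMeans(Mod(stats::mvfft(H * seg)[1:nf, ])^2) / fs
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    p
  }))
  sel <- seq(0, fs / 2) >= 1 & seq(0, fs / 2) <= 48
  expect_equal(sw_full$spectra[1, ], plain[sel], tolerance = 1e-10)
  # never-active state is flagged, not fabricated
  expect_warning(
    sw0 <- statewise_multitaper(x, cbind(1, 0 * occ[, 1]), fs),
    "never active")
  expect_true(all(is.na(sw0$spectra[2, ])))
})

test_that("relabelling HMM states leaves burst metrics unchanged", {
  set.seed(21)
  env <- abs(rnorm(400)) + 1
  G <- matrix(rexp(1200), 400, 3)
  G <- G / rowSums(G)
  B <- binarise(G, threshold = 0.5)
  k1 <- select_burst_state(B, env)
  ev1 <- burst_events(B[, k1], fs = 50, envelope = env)
  perm <- c(3, 1, 2)
  B2 <- B[, perm]
  k2 <- select_burst_state(B2, env)
  ev2 <- burst_events(B2[, k2], fs = 50, envelope = env)
  expect_equal(ev1, ev2)
})

test_that("bursts injected by the generator are found by the pipeline", {
  # clean single source at default generator settings -> embedded HMM
  set.seed(22)
  sched <- generate_schedule(0, 10)
  spec <- burst_spec()
  sim <- simulate_source_timecourse(sched, spec, fs = 200, duration_s = 400)
  x <- band_filter(sim$x, 200, c(1, 48))
  emb <- tde_embed(x, 200, n_lags = 15, target_fs = 100, pca_dims = 6)
  model <- fit_hmm(emb, K = 3, n_restarts = 3, seed = 23, max_iter = 60,
                   zero_mean = TRUE)
  post <- forward_backward(model, emb)
  bin <- binarise(post)
  beta_env <- resample_envelope(hilbert_envelope(band_filter(sim$x, 200,
                                                             c(13, 30))),
                                200, emb$time_s)
  ks <- select_burst_state(bin, beta_env)
  # ground-truth occupancy on the embedded grid
  truth <- rep(FALSE, length(emb$time_s))
  for (i in seq_len(nrow(sim$bursts)))
    truth <- truth | (emb$time_s >= sim$bursts$onset_s[i] &
                        emb$time_s < sim$bursts$offset_s[i])
  found <- bin[, ks] == 1
  jaccard <- sum(found & truth) / sum(found | truth)
  expect_gt(jaccard, 0.7)
})
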