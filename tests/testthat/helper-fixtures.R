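# Shared fixture builders (all generated in code at test time).

# small random transition matrix / initial distribution / emissions
random_hmm_params <- function(T_, K) {
  A <- matrix(stats::rexp(K * K), K, K)
  A <- A / rowSums(A)
  pi_ <- stats::rexp(K); pi_ <- pi_ / sum(pi_)
  logB <- matrix(stats::rnorm(T_ * K), T_, K)
  list(logB = logB, pi = pi_, A = A)
}

# sample a state path + 1-D Gaussian emissions from a 2-state chain
sample_two_state_series <- function(T_, means = c(-5, 5), sd_ = 1,
                                    A = matrix(c(0.95, 0.05, 0.05, 0.95),
                                               2, 2, byrow = TRUE)) {
  z <- integer(T_)
  z[1] <- sample(1:2, 1)
  for (t in 2:T_) z[t] <- sample(1:2, 1, prob = A[z[t - 1], ])
  list(x = stats::rnorm(T_, means[z], sd_), z = z, A = A)
}

# minimal single-dipole recording over a spherical conductor: one source
# with a known tangential orientation and a sinusoid-modulated time course
single_dipole_recording <- function(n_sensors = 24, fs = 300,
                                    duration_s = 30, noise_sd = 2e-14,
                                    source_pos = c(-0.042, -0.018, 0.058),
                                    freq = 19) {
  array <- build_helmet_array(n_sensors)
  ch <- channels_table(array)
  n <- round(duration_s * fs)
  t <- seq(0, by = 1 / fs, length.out = n)
  src <- sin(2 * pi * freq * t) * (1 + 0.5 * sin(2 * pi * 0.2 * t))
  cen <- source_pos / sqrt(sum(source_pos^2))
  ref <- c(0, 0, 1)
  u <- c(cen[2] * ref[3] - cen[3] * ref[2],
         cen[3] * ref[1] - cen[1] * ref[3],
         cen[1] * ref[2] - cen[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  L <- leadfield_matrix(ch, source_pos)
  data <- (L %*% u) %*% matrix(5e-9 * src, 1) +
    matrix(stats::rnorm(nrow(ch) * n, sd = noise_sd), nrow(ch), n)
  ch$bad <- FALSE
  rec <- list(data = data, fs = fs, channels = ch,
              events = data.frame(), duration_s = duration_s)
  class(rec) <- "opm_recording"
  list(recording = rec, source = src, orientation = u, position = source_pos,
       leadfield = L)
}

# tiny validated configuration for fast pipeline runs
tiny_config <- function(n_trials = 20, ...) {
  validate_config(list(
    paradigm = list(n_trials = n_trials, rest_every = 10),
    simulation = list(fs = 200, n_sensors = 12L, n_regions = 4L),
    preprocessing = list(welch_overlap = 0),
    hmm = list(n_restarts = 2L, max_iter = 25L, tol = 1e-4, pca_dims = 4L,
               fit_duration_s = 120)))
}
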