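#' Time-delay embedding of a univariate time course
#'
#' Optionally anti-alias filters and downsamples the series to `target_fs`,
#' z-scores it, then stacks `n_lags` consecutive samples (centred window)
#' into each row, so that the embedded space carries local spectral as well
#' as amplitude structure. An optional PCA reduces the lag space.
#'
#' @param x Univariate time course.
#' @param fs Sampling rate of `x` (Hz).
#' @param n_lags Odd embedding width in (downsampled) samples.
#' @param target_fs Pre-embedding sampling rate; `fs / target_fs` must be a
#'   whole number. `NULL` keeps `fs`.
#' @param pca_dims Optional dimensionality after PCA of the embedded rows.
#' @return A `tde_embedding`: list with `X` (rows = time points, columns =
#'   lags or principal components), `time_s` (centre-sample times on the
#'   experiment clock), `fs` (the embedded grid rate), `n_lags`, `x_ds`
#'   (the downsampled z-scored series), `centre_idx`, `pca` (rotation and
#'   centring, or `NULL`).
#' @export
tde_embed <- function(x, fs, n_lags = 15, target_fs = 100, pca_dims = NULL) {
  if (n_lags < 1 || n_lags %% 2 != 1) stop("n_lags must be odd and >= 1")
  if (is.null(target_fs)) target_fs <- fs
  if (target_fs > fs) stop("target_fs must not exceed fs")
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("fs / target_fs must be an integer")
  q <- round(q)
  if (q > 1) {
    bf <- signal::butter(4, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
    x <- zerophase_filter(bf$b, bf$a, as.numeric(x))
    x <- x[seq(1, length(x), by = q)]
  }
  if (length(x) <= n_lags) stop("series shorter than the embedding window")
  x <- (x - mean(x)) / stats::sd(x)
  Tds <- length(x)
  Tp <- Tds - n_lags + 1L
  X <- matrix(NA_real_, Tp, n_lags)
  for (l in seq_len(n_lags)) X[, l] <- x[l:(l + Tp - 1L)]
  half <- (n_lags - 1L) / 2L
  centre_idx <- (half + 1L):(Tds - half)
  pca <- NULL
  if (!is.null(pca_dims) && pca_dims < n_lags) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    # principal axes from the lag-space covariance (n_lags x n_lags)
    e <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
    rot <- e$vectors[, seq_len(pca_dims), drop = FALSE]
    pca <- list(centre = mu, rotation = rot, dims = pca_dims)
    X <- Xc %*% rot
  }
  out <- list(X = X, time_s = (centre_idx - 1L) / target_fs, fs = target_fs,
              n_lags = n_lags, x_ds = x, centre_idx = centre_idx, pca = pca)
  class(out) <- "tde_embedding"
  out
}

# log density of each row of X under each state's Gaussian
.state_loglik <- function(X, means, covs) {
  T_ <- nrow(X); K <- nrow(means); d <- ncol(X)
  logB <- matrix(NA_real_, T_, K)
  for (k in seq_len(K)) {
    R <- chol(covs[, , k])
    Z <- forwardsolve(t(R), t(X) - means[k, ])
    logB[, k] <- -0.5 * colSums(Z^2) - sum(log(diag(R))) -
      0.5 * d * log(2 * pi)
  }
  logB
}

# M-step covariance with eigenvalue floor against collapse
.floor_cov <- function(S, floor_val) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor_val)
  e$vectors %*% (v * t(e$vectors))
}

#' Fit a Gaussian hidden Markov model by expectation-maximisation
#'
#' Baum-Welch with full-covariance Gaussian emissions. Each restart is
#' initialised from a seeded k-means partition of the rows; the restart with
#' the highest converged log-likelihood wins (ties broken by the earliest
#' restart). The log-likelihood is non-decreasing across iterations; state
#' covariances are floored at `1e-6` times the data variance to prevent
#' collapse.
#'
#' @param X Embedded data matrix (rows = time points) or numeric vector.
#' @param K Number of states (default 3).
#' @param n_restarts Seeded k-means initialisations (default 5).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed Optional base seed; restart `r` uses `seed + r - 1`.
#' @param fit_rows Optional number of leading rows the parameters are
#'   estimated from (the model can then decode the full series); `NULL`
#'   uses all rows.
#' @param zero_mean Fix every state's mean at zero so states differ only in
#'   their (auto)covariance. This is the standard observation model for
#'   time-delay-embedded oscillatory data: with free means, EM splits an
#'   oscillation's phase ring into antipodal mean states instead of
#'   separating burst from background.
#' @return A `gaussian_hmm`: list with `K`, `pi`, `A`, `means` (K x d),
#'   `covs` (d x d x K), `loglik`, `trace` (per-iteration log-likelihood of
#'   the winning restart), `converged`.
#' @export
fit_hmm <- function(X, K = 3, n_restarts = 5, max_iter = 100, tol = 1e-6,
                    seed = NULL, fit_rows = NULL, zero_mean = FALSE) {
  if (inherits(X, "tde_embedding")) X <- X$X
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (!is.null(fit_rows) && fit_rows < nrow(X))
    Xf <- X[seq_len(fit_rows), , drop = FALSE]
  else Xf <- X
  T_ <- nrow(Xf); d <- ncol(Xf)
  if (T_ < 10 * K) stop("too few rows to fit ", K, " states")
  floor_val <- 1e-6 * mean(apply(Xf, 2, stats::var))

  best <- NULL
  for (r_ in seq_len(n_restarts)) {
    if (!is.null(seed)) set.seed(seed + r_ - 1L)
    km <- suppressWarnings(stats::kmeans(Xf, centers = K, nstart = 1,
                                         iter.max = 30))
    gamma <- matrix(0, T_, K)
    gamma[cbind(seq_len(T_), km$cluster)] <- 1
    model <- .m_step(Xf, gamma, NULL, floor_val, K, d, zero_mean)
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      logB <- .state_loglik(Xf, model$means, model$covs)
      fb <- if (K == 1L) {
        list(gamma = matrix(1, T_, 1), xi_sum = matrix(T_ - 1, 1, 1),
             loglik = sum(logB))
      } else .fb_cpp(logB, model$pi, model$A)
      trace <- c(trace, fb$loglik)
      if (is.finite(prev) &&
          abs(fb$loglik - prev) < tol * (abs(prev) + 1e-12)) {
        converged <- TRUE
        break
      }
      prev <- fb$loglik
      model <- .m_step(Xf, fb$gamma, fb$xi_sum, floor_val, K, d, zero_mean)
    }
    if (!converged)
      warning("EM reached max_iter without convergence; best-so-far kept")
    ll <- trace[length(trace)]
    if (is.null(best) || ll > best$loglik + 1e-12) {
      best <- list(K = K, pi = model$pi, A = model$A, means = model$means,
                   covs = model$covs, loglik = ll, trace = trace,
                   converged = converged)
    }
  }
  class(best) <- "gaussian_hmm"
  best
}

.m_step <- function(X, gamma, xi_sum, floor_val, K, d, zero_mean = FALSE) {
  Nk <- colSums(gamma)
  means <- matrix(0, K, d)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    w <- gamma[, k]
    if (!zero_mean) means[k, ] <- colSums(X * w) / Nk[k]
    Xc <- sweep(X, 2, means[k, ])
    S <- crossprod(Xc * sqrt(w)) / Nk[k]
    covs[, , k] <- .floor_cov(S, floor_val)
  }
  if (is.null(xi_sum)) {
    # initial transition estimate from hard assignments
    z <- max.col(gamma)
    A <- matrix(1, K, K)
    for (t in seq_len(nrow(gamma) - 1L)) A[z[t], z[t + 1L]] <-
        A[z[t], z[t + 1L]] + 1
    A <- A / rowSums(A)
  } else {
    A <- xi_sum + 1e-12
    A <- A / rowSums(A)
  }
  pi_ <- pmax(gamma[1, ], 1e-12)
  list(pi = pi_ / sum(pi_), A = A, means = means, covs = covs)
}

#' Posterior state probabilities by the forward-backward algorithm
#'
#' Scaled forward-backward recursion under a fitted model; every posterior
#' row sums to one and the total log-likelihood is exact (it matches
#' exhaustive path enumeration on small problems).
#'
#' @param model A `gaussian_hmm`.
#' @param X Data matrix (or `tde_embedding`) with the model's dimensionality.
#' @return A `state_posterior`: list with `gamma` (T x K), `loglik`,
#'   `xi_sum`.
#' @export
forward_backward <- function(model, X) {
  if (inherits(X, "tde_embedding")) X <- X$X
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  stopifnot(ncol(X) == ncol(model$means))
  logB <- .state_loglik(X, model$means, model$covs)
  out <- if (model$K == 1L) {
    list(gamma = matrix(1, nrow(X), 1), xi_sum = matrix(nrow(X) - 1, 1, 1),
         loglik = sum(logB))
  } else .fb_cpp(logB, model$pi, model$A)
  class(out) <- "state_posterior"
  out
}

#' Binarise state posteriors
#'
#' State k is scored active at time t iff its posterior probability exceeds
#' `threshold` (default 2/3). Because the threshold exceeds 1/2 and rows sum
#' to one, at most one state is active per sample.
#'
#' @param posterior A `state_posterior` or T x K probability matrix.
#' @param threshold Activation threshold in (0, 1].
#' @return T x K binary (0/1) matrix.
#' @export
binarise <- function(posterior, threshold = 2 / 3) {
  G <- if (inherits(posterior, "state_posterior")) posterior$gamma
  else posterior
  (G > threshold) * 1L
}

#' Identify the burst state
#'
#' The burst state is the state whose binary occupancy time course has the
#' highest Pearson correlation with the beta-band amplitude envelope
#' (resampled to the state grid).
#'
#' @param binary T x K binary state matrix.
#' @param beta_env Beta envelope on the same time grid (length T).
#' @return Integer state index; ties resolve to the lowest index with a
#'   warning.
#' @export
select_burst_state <- function(binary, beta_env) {
  stopifnot(nrow(binary) == length(beta_env))
  if (stats::sd(beta_env) == 0)
    stop("degenerate series: beta envelope is constant")
  r <- vapply(seq_len(ncol(binary)), function(k) {
    if (stats::sd(binary[, k]) == 0)
      stop("degenerate series: state ", k, " time course is constant")
    stats::cor(binary[, k], beta_env)
  }, numeric(1))
  top <- which(r >= max(r) - 1e-12)
  if (length(top) > 1) warning("burst-state correlation tie; lowest index kept")
  top[1]
}

#' Sample an envelope onto the embedded state grid
#'
#' @param env Whole-recording envelope at rate `fs`.
#' @param fs Sampling rate of `env`.
#' @param time_s Target time stamps (s), e.g. `tde_embedding$time_s`.
#' @return Envelope values at the nearest samples.
#' @export
resample_envelope <- function(env, fs, time_s) {
  idx <- pmin(pmax(round(time_s * fs) + 1L, 1L), length(env))
  env[idx]
}

#' Extract burst events from a binary time course
#'
#' Maximal runs of ones become events; the peak amplitude is read from the
#' broadband Hilbert envelope within each run.
#'
#' @param burst_binary 0/1 vector (the burst state's occupancy).
#' @param fs Sampling rate of the binary grid.
#' @param envelope Broadband envelope on the same grid.
#' @param t0 Time (s) of the first sample on the experiment clock.
#' @return Data frame with `onset_s`, `offset_s`, `duration_s`,
#'   `peak_amplitude`; zero rows if no bursts.
#' @export
burst_events <- function(burst_binary, fs, envelope = NULL, t0 = 0) {
  r <- rle(as.integer(burst_binary))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  out <- data.frame(onset_s = t0 + (starts[on] - 1L) / fs,
                    offset_s = t0 + ends[on] / fs)
  out$duration_s <- out$offset_s - out$onset_s
  out$peak_amplitude <- if (is.null(envelope)) rep(NA_real_, nrow(out)) else
    vapply(which(on), function(i) max(envelope[starts[i]:ends[i]]),
           numeric(1))
  out
}

#' Across-trial burst probability time course
#'
#' For each trial-relative time point, the fraction of the condition's
#' trials in which the burst state is active. Trials whose full 16 s window
#' is not covered by the state grid (embedding edges) are dropped.
#'
#' @param burst_binary 0/1 vector on the state grid.
#' @param time_s Time stamps of the state grid (experiment clock, s).
#' @param schedule A `braille_schedule`.
#' @param condition `"cue_left"` or `"cue_right"`.
#' @param keep Optional trial rejection mask over schedule trials.
#' @return List with `time` (trial-relative s), `prob` (fractions in
#'   [0, 1]), `n_trials`.
#' @export
burst_probability <- function(burst_binary, time_s, schedule,
                              condition = c("cue_left", "cue_right"),
                              keep = NULL) {
  condition <- match.arg(condition)
  cue <- sub("^cue_", "", condition)
  fs <- 1 / (time_s[2] - time_s[1])
  tr <- schedule$trials
  sel <- !tr$is_rest & !is.na(tr$cue) & tr$cue == cue
  if (!is.null(keep)) sel <- sel & keep
  starts <- tr$start_s[sel]
  nspt <- round(16 * fs)
  rows <- list()
  for (s0 in starts) {
    i0 <- which.min(abs(time_s - s0))
    if (time_s[i0] - s0 > 0.5 / fs || i0 + nspt - 1L > length(burst_binary))
      next                                   # window not covered by the grid
    rows[[length(rows) + 1L]] <- burst_binary[i0:(i0 + nspt - 1L)]
  }
  if (length(rows) == 0) stop("no trials covered by the state grid")
  M <- do.call(rbind, rows)
  list(time = seq(0, nspt - 1) / fs, prob = colMeans(M), n_trials = nrow(M))
}

#' Count bursts fully inside a window
#'
#' A burst is counted only if it starts and ends within `[a, b)`.
#'
#' @param events Burst event table ([burst_events()]).
#' @param window `c(a, b)` seconds.
#' @return Integer count.
#' @export
burst_count_in_window <- function(events, window) {
  sum(events$onset_s >= window[1] & events$offset_s < window[2])
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS tapers of length `n` with time-bandwidth product `nw`,
#' computed from the standard symmetric tridiagonal eigenproblem;
#' unit-energy, leading taper sign-positive.
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  w <- nw / n
  t_ <- 0:(n - 1)
  diag_ <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  off <- (t_[-n] + 1) * (n - 1 - t_[-n]) / 2
  M <- diag(diag_)
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(M, symmetric = TRUE)
  H <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    H[, j] <- H[, j] / sqrt(sum(H[, j]^2))
    if (sum(H[, j]) < 0) H[, j] <- -H[, j]
  }
  H
}

#' State-wise multitaper spectra
#'
#' Splits the series into non-overlapping windows, forms a DPSS multitaper
#' periodogram per window, and averages windows weighted by each state's
#' mean occupancy, yielding one spectrum per state. A state with occupancy
#' identically one recovers the plain (equal-weight) multitaper PSD; a state
#' that is never active yields an `NA` spectrum and a warning rather than a
#' fabricated one.
#'
#' @param x Time course (e.g. broadband virtual electrode on the state
#'   grid).
#' @param occupancy T x K matrix of state posteriors or binary occupancies
#'   on the same grid.
#' @param fs Sampling rate.
#' @param window_s Window length (s).
#' @param nw,k DPSS time-bandwidth product and taper count.
#' @param freq_range Reported frequency range (Hz).
#' @return List with `freqs` and `spectra` (K x freqs, units of `x`^2 / Hz).
#' @export
statewise_multitaper <- function(x, occupancy, fs, window_s = 1, nw = 3,
                                 k = 2 * nw - 1, freq_range = c(1, 48)) {
  if (is.vector(occupancy)) occupancy <- matrix(occupancy, ncol = 1)
  stopifnot(length(x) == nrow(occupancy))
  N <- round(window_s * fs)
  n_win <- floor(length(x) / N)
  if (n_win < 1) stop("series shorter than one window")
  H <- dpss_tapers(N, nw, k)
  nf <- floor(N / 2) + 1L
  P <- matrix(0, n_win, nf)
  Wgt <- matrix(0, n_win, ncol(occupancy))
  for (wdx in seq_len(n_win)) {
    idx <- ((wdx - 1L) * N + 1L):(wdx * N)
    seg <- x[idx] - mean(x[idx])
    ft <- stats::mvfft(H * seg)[1:nf, , drop = FALSE]
    p <- rowMeans(Mod(ft)^2) / fs
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    P[wdx, ] <- p
    Wgt[wdx, ] <- colMeans(occupancy[idx, , drop = FALSE])
  }
  freqs <- seq(0, nf - 1L) * fs / N
  K <- ncol(occupancy)
  spectra <- matrix(NA_real_, K, nf)
  for (kk in seq_len(K)) {
    tot <- sum(Wgt[, kk])
    if (tot == 0) {
      warning("state ", kk, " never active: spectrum undefined")
      next
    }
    spectra[kk, ] <- colSums(P * Wgt[, kk]) / tot
  }
  sel <- freqs >= freq_range[1] & freqs <= freq_range[2]
  list(freqs = freqs[sel], spectra = spectra[, sel, drop = FALSE])
}
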