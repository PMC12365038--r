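#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann taper. The one-sided density
#' is normalised so its integral over frequency equals the signal variance
#' (up to taper bias).
#'
#' @param x Numeric vector, channels x samples matrix, or `opm_recording`.
#' @param fs Sampling rate (ignored when `x` is a recording).
#' @param segment_s Segment length in seconds (default 2 s).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freqs` (Hz) and `psd` (channels x freqs, units of
#'   `x`^2 / Hz).
#' @export
welch_psd <- function(x, fs = NULL, segment_s = 2, overlap = 0.5) {
  if (inherits(x, "opm_recording")) {
    fs <- x$fs
    x <- x$data
  }
  if (is.null(fs)) stop("fs required")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nseg <- round(segment_s * fs)
  if (nseg < 8) stop("segment too short: need segment_s * fs >= 8")
  if (ncol(x) < nseg) stop("recording shorter than one Welch segment")
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, ncol(x) - nseg + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))  # Hann
  U <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  psd <- matrix(0, nrow(x), nf)
  for (s0 in starts) {
    seg <- t(x[, s0:(s0 + nseg - 1L), drop = FALSE]) * w   # nseg x channels
    ft <- t(stats::mvfft(seg)[1:nf, , drop = FALSE])       # channels x nf
    p <- Mod(ft)^2 / (fs * U)
    p[, 2:(nf - 1L)] <- 2 * p[, 2:(nf - 1L)]   # one-sided doubling
    psd <- psd + p
  }
  psd <- psd / length(starts)
  rownames(psd) <- rownames(x)
  list(freqs = seq(0, nf - 1L) * fs / nseg, psd = psd)
}

#' Amplitude spectral density in fT / sqrt(Hz)
#'
#' @param psd A [welch_psd()] result (T^2 / Hz).
#' @return Matrix of the same shape, sqrt(psd) scaled to femtotesla.
#' @export
asd_fT <- function(psd) sqrt(psd$psd) * 1e15

#' Flag noisy or dead channels
#'
#' A channel is bad if its median amplitude spectral density within `band`
#' exceeds `floor_limit` fT / sqrt(Hz), or its PSD is identically zero. The
#' median (rather than the mean) makes the rule robust to narrow line-noise
#' spikes.
#'
#' @param psd A [welch_psd()] result in T^2 / Hz.
#' @param floor_limit Noise ceiling in fT / sqrt(Hz) (default 16).
#' @param band Frequency band (Hz) the statistic is computed over
#'   (default 5-150, clipped to the available grid).
#' @return Integer indices of bad channels (named if the PSD rows are).
#' @export
detect_bad_channels <- function(psd, floor_limit = 16, band = c(5, 150)) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) stop("band contains no PSD frequencies")
  a <- sqrt(psd$psd[, sel, drop = FALSE]) * 1e15
  med <- apply(a, 1, stats::median)
  dead <- apply(psd$psd, 1, function(p) all(p == 0))
  which(med > floor_limit | dead)
}

#' Segment a recording into fixed-length trials
#'
#' Cuts the continuous data on 16 s boundaries into one row per trial (task
#' and rest), samples in the half-open window `[start, start + 16 s)`.
#' Trial starts are taken as `(trial_index - 1) * trial_duration_s` on the
#' experiment clock (trials are contiguous from t = 0).
#'
#' @param recording An `opm_recording` (or channels x samples matrix with
#'   `fs` and `events` supplied).
#' @param events Event table; defaults to the recording's.
#' @param trial_duration_s Trial length in seconds.
#' @param fs Sampling rate when `recording` is a bare matrix.
#' @return A `trial_matrix`: list with `data` (trials x channels x samples
#'   array), `info` (data frame `trial_index`, `is_rest`, `cue`), `keep`
#'   (logical mask, all `TRUE` initially), `fs`.
#' @export
segment_trials <- function(recording, events = NULL, trial_duration_s = 16,
                           fs = NULL) {
  if (inherits(recording, "opm_recording")) {
    if (is.null(events)) events <- recording$events
    fs <- recording$fs
    X <- recording$data
  } else X <- recording
  if (is.null(fs)) stop("fs required")
  nspt <- round(trial_duration_s * fs)
  ids <- sort(unique(events$trial_index))
  if (length(ids) == 0L) {
    out <- list(data = array(0, c(0, nrow(X), nspt)),
                info = data.frame(trial_index = integer(),
                                  is_rest = logical(), cue = character()),
                keep = logical(0), fs = fs)
    class(out) <- "trial_matrix"
    return(out)
  }
  dat <- array(NA_real_, c(length(ids), nrow(X), nspt))
  info <- data.frame(trial_index = ids, is_rest = FALSE,
                     cue = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    start <- (ids[k] - 1) * trial_duration_s
    i0 <- round(start * fs) + 1L
    i1 <- i0 + nspt - 1L
    if (i1 > ncol(X)) stop(sprintf("trial %d extends past end of recording",
                                   ids[k]))
    dat[k, , ] <- X[, i0:i1]
    ev <- events[events$trial_index == ids[k], , drop = FALSE]
    info$is_rest[k] <- any(ev$trial_type == "rest")
    cuer <- ev$trial_type[startsWith(ev$trial_type, "cue_")]
    if (length(cuer) == 1L) info$cue[k] <- sub("^cue_", "", cuer)
  }
  out <- list(data = dat, info = info, keep = rep(TRUE, length(ids)), fs = fs)
  class(out) <- "trial_matrix"
  out
}

#' Reject high-variance trials
#'
#' Computes the standard deviation of all trials' data combined, then each
#' trial's own standard deviation pooled over channels and samples; trials
#' whose SD exceeds `k` times the combined SD are marked rejected (rest
#' blocks included). Scale-invariant by construction.
#'
#' @param trials A `trial_matrix`.
#' @param k SD multiplier (default 3).
#' @return The `trial_matrix` with its `keep` mask updated.
#' @export
reject_bad_trials <- function(trials, k = 3) {
  stopifnot(inherits(trials, "trial_matrix"))
  n <- dim(trials$data)[1]
  if (n < 1) stop("need at least one trial")
  combined_sd <- stats::sd(as.numeric(trials$data))
  per_trial <- vapply(seq_len(n),
                      function(i) stats::sd(as.numeric(trials$data[i, , ])),
                      numeric(1))
  trials$keep <- per_trial <= k * combined_sd
  trials$trial_sd <- per_trial
  trials$combined_sd <- combined_sd
  trials
}

#' Homogeneous field correction
#'
#' Interference from distant sources is spatially uniform across the array.
#' With `S` the channels x 3 matrix of measurement-axis unit vectors, any
#' uniform field b(t) appears in the data as `S b(t)`; projecting the data
#' onto the orthogonal complement of the column space of `S`
#' (`X <- (I - S S^+) X`) removes it while leaving spatially structured
#' brain fields largely intact. Applied to non-bad channels only.
#'
#' @param recording An `opm_recording`.
#' @return List with `recording` (corrected) and `removed` (the excised
#'   uniform-field component, channels x samples over the good channels).
#' @export
homogeneous_field_correction <- function(recording) {
  stopifnot(inherits(recording, "opm_recording"))
  good <- !recording$channels$bad
  if (sum(good) < 4) stop("need >= 4 good channels for field correction")
  S <- as.matrix(recording$channels[good, c("ax", "ay", "az")])
  sv <- svd(S)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (r < 3) warning("axis model rank < 3; projecting achievable subspace only")
  U <- sv$u[, seq_len(r), drop = FALSE]
  if (all(good)) {
    removed <- U %*% crossprod(U, recording$data)
    recording$data <- recording$data - removed
  } else {
    X <- recording$data[good, , drop = FALSE]
    removed <- U %*% crossprod(U, X)
    recording$data[good, ] <- X - removed
  }
  # downstream forward models must live in the same projected space
  recording$proj_axes <- U
  list(recording = recording, removed = removed, rank = r)
}

# streaming trial QC: identical statistics to segment_trials +
# reject_bad_trials (pooled per-trial SD vs k x combined SD) without
# materialising the trials x channels x samples array
.trial_qc <- function(recording, k = 3, trial_duration_s = 16) {
  X <- recording$data
  fs <- recording$fs
  nspt <- round(trial_duration_s * fs)
  ids <- sort(unique(recording$events$trial_index))
  n_per <- nspt * nrow(X)
  s1 <- s2 <- numeric(length(ids))
  for (i in seq_along(ids)) {
    i0 <- round((ids[i] - 1) * trial_duration_s * fs) + 1L
    blk <- X[, i0:(i0 + nspt - 1L), drop = FALSE]
    s1[i] <- sum(blk)
    s2[i] <- sum(blk * blk)
  }
  sd_of <- function(s1, s2, n) sqrt(pmax(0, (s2 - s1^2 / n) / (n - 1)))
  per_trial <- sd_of(s1, s2, n_per)
  combined <- sd_of(sum(s1), sum(s2), n_per * length(ids))
  keep <- per_trial <= k * combined
  names(keep) <- ids
  mask <- rep(FALSE, ncol(X))
  for (i in seq_along(ids)) {
    if (!keep[i]) next
    i0 <- round((ids[i] - 1) * trial_duration_s * fs) + 1L
    mask[i0:min(ncol(X), i0 + nspt - 1L)] <- TRUE
  }
  list(trial_index = ids, keep = keep, mask = mask,
       trial_sd = per_trial, combined_sd = combined)
}

#' Logical per-sample mask of samples belonging to kept trials
#'
#' @param trials A `trial_matrix` (after [reject_bad_trials()]).
#' @param n_samples Total samples in the continuous recording.
#' @param trial_duration_s Trial length (s).
#' @return Logical vector of length `n_samples`.
#' @export
kept_sample_mask <- function(trials, n_samples, trial_duration_s = 16) {
  m <- rep(FALSE, n_samples)
  nspt <- round(trial_duration_s * trials$fs)
  for (k in seq_len(nrow(trials$info))) {
    if (!trials$keep[k]) next
    i0 <- round((trials$info$trial_index[k] - 1) * trial_duration_s *
                  trials$fs) + 1L
    m[i0:min(n_samples, i0 + nspt - 1L)] <- TRUE
  }
  m
}
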