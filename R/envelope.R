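#' Hilbert envelope of a band-limited signal
#'
#' Modulus of the analytic signal, computed by zeroing negative frequencies
#' in the discrete Fourier transform. Must be applied to the continuous
#' (whole-experiment) time course before any epoching; the first and last
#' ~0.5 s are edge-affected.
#'
#' @param x Numeric vector or regions x samples matrix.
#' @return Non-negative envelope, same shape as `x`.
#' @export
hilbert_envelope <- function(x) {
  env1 <- function(v) {
    n <- length(v)
    H <- stats::fft(v)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1; h[2:((n + 1) / 2)] <- 2
    }
    Mod(stats::fft(H * h, inverse = TRUE) / n)
  }
  if (is.matrix(x)) t(apply(x, 1, env1)) else env1(as.numeric(x))
}

#' Baseline statistics from rest trials
#'
#' Mean and standard deviation of the envelope over the last
#' `window_s` seconds of every kept rest trial (a window starting well after
#' the final stimulus, so it reflects unstimulated activity).
#'
#' @param envelope Whole-recording envelope (vector).
#' @param schedule A `braille_schedule`.
#' @param fs Sampling rate of the envelope.
#' @param keep Optional logical mask over schedule trials (rejection mask,
#'   indexed by trial); rest trials marked `FALSE` are excluded.
#' @param window_s Baseline window length at the end of each rest trial.
#' @return List with `mu`, `sigma`, `n_samples`.
#' @export
baseline_stats <- function(envelope, schedule, fs, keep = NULL,
                           window_s = 8) {
  tr <- schedule$trials
  rest <- tr[tr$is_rest, , drop = FALSE]
  if (!is.null(keep)) rest <- rest[keep[match(rest$index, tr$index)], ,
                                   drop = FALSE]
  if (nrow(rest) == 0) stop("no kept rest trials: baseline undefined")
  idx <- integer(0)
  nw <- round(window_s * fs)
  for (k in seq_len(nrow(rest))) {
    end_i <- round((rest$start_s[k] + 16) * fs)
    idx <- c(idx, (end_i - nw + 1L):end_i)
  }
  idx <- idx[idx >= 1 & idx <= length(envelope)]
  list(mu = mean(envelope[idx]), sigma = stats::sd(envelope[idx]),
       n_samples = length(idx))
}

#' Envelope contrast-to-noise ratio
#'
#' Change in envelope from the rest baseline, as a percentage of the
#' baseline standard deviation: `100 * (env - mu_b) / sigma_b`. Invariant to
#' common positive rescaling of the virtual electrode.
#'
#' @param envelope Envelope time course (vector or matrix).
#' @param baseline A [baseline_stats()] result.
#' @return CNR in %, same shape as `envelope`.
#' @export
cnr <- function(envelope, baseline) {
  if (!is.finite(baseline$sigma) || baseline$sigma <= 0)
    stop("degenerate baseline: sigma is zero or non-finite")
  100 * (envelope - baseline$mu) / baseline$sigma
}

#' Average a time course over trials of one condition
#'
#' Segments a whole-recording time course on 16 s trial boundaries and
#' averages across the kept task trials of the requested cue condition.
#'
#' @param x Whole-recording time course (e.g. a CNR trace).
#' @param schedule A `braille_schedule`.
#' @param fs Sampling rate of `x`.
#' @param condition `"cue_left"` or `"cue_right"`.
#' @param keep Optional logical rejection mask over schedule trials.
#' @return List with `time` (trial-relative s), `mean`, `trials`
#'   (trials x samples matrix), `n`.
#' @export
average_trials <- function(x, schedule, fs, condition = c("cue_left",
                                                          "cue_right"),
                           keep = NULL) {
  condition <- match.arg(condition)
  cue <- sub("^cue_", "", condition)
  tr <- schedule$trials
  sel <- !tr$is_rest & !is.na(tr$cue) & tr$cue == cue
  if (!is.null(keep)) sel <- sel & keep
  starts <- tr$start_s[sel]
  if (length(starts) == 0) stop("no kept trials in condition ", condition)
  nspt <- round(16 * fs)
  M <- matrix(NA_real_, length(starts), nspt)
  for (k in seq_along(starts)) {
    i0 <- round(starts[k] * fs) + 1L
    M[k, ] <- x[i0:(i0 + nspt - 1L)]
  }
  list(time = seq(0, nspt - 1) / fs, mean = colMeans(M), trials = M,
       n = length(starts))
}

#' Epoch a time course around probe stimuli
#'
#' Cuts epochs in the half-open window `[onset - 0.18, onset + 0.65) s`
#' around every qualifying probe, split into four categories by attention
#' and stimulated hand. Target probes and probes with an incorrect response
#' are excluded (they carry button-press confounds).
#'
#' @param x Whole-recording time course.
#' @param events Event table ([schedule_to_events()] layout).
#' @param fs Sampling rate of `x`.
#' @param window `c(start, end)` seconds relative to probe onset.
#' @param exclude_targets,exclude_errors Exclusion switches.
#' @param keep_trials Optional vector of trial indices to keep (rejection).
#' @return List with `categories` (named list `attended_left`,
#'   `attended_right`, `nonattended_left`, `nonattended_right` of
#'   epochs x samples matrices; the suffix is the stimulated hand), `time`
#'   (epoch-relative s), `n_dropped` (epochs falling off the recording).
#' @export
epoch_probes <- function(x, events, fs, window = c(-0.180, 0.650),
                         exclude_targets = TRUE, exclude_errors = TRUE,
                         keep_trials = NULL) {
  pb <- events[startsWith(events$trial_type, "probe_"), , drop = FALSE]
  if (exclude_targets && "is_target" %in% names(pb))
    pb <- pb[!pb$is_target %in% TRUE, , drop = FALSE]
  if (exclude_errors && "response_error" %in% names(pb))
    pb <- pb[!pb$response_error %in% TRUE, , drop = FALSE]
  if (!is.null(keep_trials))
    pb <- pb[pb$trial_index %in% keep_trials, , drop = FALSE]
  nsamp <- round((window[2] - window[1]) * fs)
  cats <- c("attended_left", "attended_right",
            "nonattended_left", "nonattended_right")
  out <- stats::setNames(
    lapply(cats, function(z) matrix(NA_real_, 0, nsamp)), cats)
  n_dropped <- 0L
  if (nrow(pb) > 0) {
    att <- ifelse(pb$trial_type == "probe_attended", "attended",
                  "nonattended")
    cat_of <- paste(att, pb$hand, sep = "_")
    for (k in seq_len(nrow(pb))) {
      i0 <- round((pb$onset[k] + window[1]) * fs) + 1L
      i1 <- i0 + nsamp - 1L
      if (i0 < 1 || i1 > length(x)) {
        n_dropped <- n_dropped + 1L
        warning("probe epoch outside recording dropped")
        next
      }
      out[[cat_of[k]]] <- rbind(out[[cat_of[k]]], x[i0:i1])
    }
  }
  list(categories = out,
       time = window[1] + seq(0, nsamp - 1) / fs,
       n_dropped = n_dropped)
}

#' Equalise epoch counts across matched sets
#'
#' Randomly discards epochs from the larger sets until all sets carry the
#' minimum count (mirrors the removal of surplus non-attended probes after
#' target exclusion).
#'
#' @param sets Named list of epochs x samples matrices.
#' @param seed Optional seed for the (seeded, reproducible) subsampling.
#' @return List of matrices, all with `min(sapply(sets, nrow))` rows.
#' @export
equalise_trial_counts <- function(sets, seed = NULL) {
  stopifnot(length(sets) >= 1, all(vapply(sets, nrow, 1L) >= 1))
  if (!is.null(seed)) set.seed(seed)
  m <- min(vapply(sets, nrow, 1L))
  lapply(sets, function(M) {
    if (nrow(M) == m) M else M[sort(sample.int(nrow(M), m)), , drop = FALSE]
  })
}

#' Average over a half-open time window
#'
#' Arithmetic mean of the samples whose time stamps fall in `[a, b)`. For a
#' matrix (epochs x samples) the mean is taken over all epochs and window
#' samples.
#'
#' @param x Vector (time course) or matrix (epochs x samples).
#' @param time Time stamps of the samples (s).
#' @param window `c(a, b)` seconds.
#' @return Scalar mean.
#' @export
window_average <- function(x, time, window) {
  sel <- time >= window[1] & time < window[2]
  if (!any(sel)) stop("window contains no samples")
  if (is.matrix(x)) mean(x[, sel]) else mean(x[sel])
}
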