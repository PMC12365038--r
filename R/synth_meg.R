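#' Build a triaxial sensor helmet
#'
#' Places `n_sensors` triaxial magnetometers quasi-uniformly over the upper
#' hemisphere of radius `helmet_radius` (Fibonacci lattice), each with one
#' radial and two tangential orthonormal measurement axes, giving
#' `3 * n_sensors` channels.
#'
#' @param n_sensors Number of sensor heads (>= 1).
#' @param helmet_radius Helmet radius in metres; must exceed the conductor
#'   radius used for the forward model.
#' @param centre Head centre (3-vector, metres).
#' @return A `sensor_array`: list with `n_sensors`, `positions`
#'   (n x 3), `axes` (n x 3 x 3 array, `axes[s, a, ]` the unit vector of
#'   axis `a` for sensor `s`; axis 1 radial), `channel_names`, `radius`,
#'   `centre`.
#' @export
build_helmet_array <- function(n_sensors, helmet_radius = 0.12,
                               centre = c(0, 0, 0)) {
  if (n_sensors < 1) stop("n_sensors must be >= 1")
  i <- seq_len(n_sensors)
  z <- (i - 0.5) / n_sensors                 # upper hemisphere: z in (0, 1)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- helmet_radius * cbind(rho * cos(phi), rho * sin(phi), z)
  pos <- sweep(pos, 2, centre, `+`)

  axes <- array(NA_real_, c(n_sensors, 3, 3))
  for (s in i) {
    er <- pos[s, ] - centre
    er <- er / sqrt(sum(er^2))
    ref <- if (abs(er[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- c(er[2] * ref[3] - er[3] * ref[2],
            er[3] * ref[1] - er[1] * ref[3],
            er[1] * ref[2] - er[2] * ref[1])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(er[2] * t1[3] - er[3] * t1[2],
            er[3] * t1[1] - er[1] * t1[3],
            er[1] * t1[2] - er[2] * t1[1])
    axes[s, 1, ] <- er
    axes[s, 2, ] <- t1
    axes[s, 3, ] <- t2
  }
  names_ <- as.vector(t(outer(sprintf("S%03d", i), c("rad", "tan1", "tan2"),
                              paste, sep = "-")))
  out <- list(n_sensors = as.integer(n_sensors), positions = pos,
              axes = axes, channel_names = names_,
              radius = helmet_radius, centre = centre)
  class(out) <- "sensor_array"
  out
}

#' Per-channel geometry table for a sensor array
#'
#' @param array A `sensor_array`.
#' @return Data frame with one row per channel: `name`, position `x,y,z` (m)
#'   and measurement axis unit vector `ax,ay,az`.
#' @export
channels_table <- function(array) {
  n <- array$n_sensors
  idx <- rep(seq_len(n), each = 3)
  ax <- matrix(NA_real_, 3 * n, 3)
  for (s in seq_len(n)) for (a in 1:3) ax[3 * (s - 1) + a, ] <- array$axes[s, a, ]
  data.frame(name = array$channel_names,
             x = array$positions[idx, 1], y = array$positions[idx, 2],
             z = array$positions[idx, 3],
             ax = ax[, 1], ay = ax[, 2], az = ax[, 3],
             stringsAsFactors = FALSE)
}

#' Cortical source model inside a spherical conductor
#'
#' A small set of labelled region centroids strictly inside a homogeneous
#' conducting sphere. The default eight-region layout includes the left and
#' right postcentral (primary somatosensory) regions used by the attention
#' contrasts; coordinates are metres, head-centred (x right, y anterior,
#' z superior).
#'
#' @param conductor_radius Sphere radius (m).
#' @param centre Sphere centre.
#' @param n_regions Number of regions kept (2..8); the two somatosensory
#'   regions always come first.
#' @return A `source_model`: list with `n_regions`, `centroids` (n x 3),
#'   `labels`, `conductor_radius`, `centre`.
#' @export
default_source_model <- function(conductor_radius = 0.09, centre = c(0, 0, 0),
                                 n_regions = 8) {
  centroids <- rbind(
    left_postcentral  = c(-0.042, -0.018, 0.058),
    right_postcentral = c( 0.042, -0.018, 0.058),
    left_frontal      = c(-0.038,  0.050, 0.042),
    right_frontal     = c( 0.038,  0.050, 0.042),
    left_occipital    = c(-0.028, -0.062, 0.030),
    right_occipital   = c( 0.028, -0.062, 0.030),
    left_temporal     = c(-0.060,  0.005, 0.012),
    right_temporal    = c( 0.060,  0.005, 0.012)
  )
  stopifnot(n_regions >= 2, n_regions <= nrow(centroids))
  centroids <- centroids[seq_len(n_regions), , drop = FALSE]
  centroids <- sweep(centroids, 2, centre, `+`)
  r <- sqrt(rowSums(sweep(centroids, 2, centre)^2))
  stopifnot(all(r < conductor_radius))
  out <- list(n_regions = nrow(centroids), centroids = centroids,
              labels = rownames(centroids),
              conductor_radius = conductor_radius, centre = centre)
  class(out) <- "source_model"
  out
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form external field of a current dipole inside a homogeneous
#' conducting sphere. The field depends only on the dipole's tangential
#' moment (radial dipoles and dipoles at the centre are magnetically silent)
#' and is independent of the sphere radius and conductivity.
#'
#' @param source_pos Dipole position (3-vector, m, relative to lab frame).
#' @param moment Dipole moment (3-vector, A m).
#' @param sensor_pos Field point (3-vector, m); must be farther from the
#'   centre than the source.
#' @param sensor_axis Optional unit 3-vector; if given the scalar projection
#'   of the field onto it is returned, otherwise the 3-vector field (tesla).
#' @param centre Sphere centre.
#' @param conductor_radius Optional radius used to validate that the source
#'   is inside and the sensor outside the conductor.
#' @return Field 3-vector in tesla, or its projection on `sensor_axis`.
#' @export
sphere_lead_field <- function(source_pos, moment, sensor_pos,
                              sensor_axis = NULL, centre = c(0, 0, 0),
                              conductor_radius = NULL) {
  r0 <- as.numeric(source_pos) - centre
  r <- as.numeric(sensor_pos) - centre
  if (!is.null(conductor_radius)) {
    if (sqrt(sum(r0^2)) >= conductor_radius)
      stop("source lies outside the conductor sphere")
    if (sqrt(sum(r^2)) <= conductor_radius)
      stop("sensor lies inside the conductor sphere")
  }
  if (sum(r^2) <= sum(r0^2))
    stop("field point must be farther from the centre than the source")
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  R <- sqrt(sum(r^2))
  adotr <- sum(a_vec * r)
  r0dotr <- sum(r0 * r)
  F_ <- a * (R * a + R^2 - r0dotr)
  gradF <- (a^2 / R + adotr / a + 2 * a + 2 * R) * r -
    (a + 2 * R + adotr / a) * r0
  q <- as.numeric(moment)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  B <- 1e-7 * (F_ * qxr0 - sum(qxr0 * r) * gradF) / F_^2
  if (is.null(sensor_axis)) B else sum(B * sensor_axis)
}

#' Lead field matrix for a region over an array of channels
#'
#' Field per unit dipole moment along the three canonical axes at a region
#' centroid, projected on every channel's measurement axis. For the
#' spherical conductor the radial moment column is numerically null.
#'
#' @param channels Channel geometry data frame ([channels_table()] layout).
#' @param source_pos Region centroid (3-vector, m).
#' @param centre Conductor centre.
#' @return channels x 3 matrix (tesla per A m).
#' @export
leadfield_matrix <- function(channels, source_pos, centre = c(0, 0, 0)) {
  n <- nrow(channels)
  L <- matrix(0, n, 3)
  pos <- as.matrix(channels[, c("x", "y", "z")])
  ax <- as.matrix(channels[, c("ax", "ay", "az")])
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- 1
    for (c_ in seq_len(n)) {
      L[c_, j] <- sphere_lead_field(source_pos, e, pos[c_, ], ax[c_, ],
                                    centre = centre)
    }
  }
  rownames(L) <- channels$name
  L
}

#' Burst generator parameters
#'
#' Parameters of the condition-dependent burst process used by the synthetic
#' source dynamics: an inhomogeneous Poisson stream of oscillatory packets
#' riding on a 1/f background. Packets mix an alpha-band carrier with a
#' beta-band component under a Tukey window, reproducing the pan-spectral
#' shape of measured burst states (alpha peak with a beta shoulder).
#'
#' @param baseline_rate Burst rate at rest (bursts / s).
#' @param duration_meanlog,duration_sdlog Log-normal burst duration law (s).
#' @param amplitude Packet amplitude (source units).
#' @param carrier Named weights `c(alpha=, beta=)` for the fundamental and
#'   its phase-locked second harmonic (the arc-shaped waveform of the
#'   sensorimotor mu rhythm: an alpha fundamental whose harmonic puts the
#'   "shoulder" in the beta band).
#' @param alpha_freq Frequency range (Hz) the per-burst fundamental is
#'   drawn from; the beta component sits at twice that frequency.
#' @param harmonic_phase Fixed phase offset of the second harmonic relative
#'   to the fundamental (radians; pi/2 gives the classic arc shape).
#' @param attended_rate_factor Multiplier (< 1 = suppression) on the burst
#'   rate during cue and probe windows of trials where the region's hand is
#'   attended.
#' @param stim_suppression_factor Multiplier on the burst rate while a
#'   stimulus is being delivered to the region's hand.
#' @param background_sd Standard deviation of the 1/f background
#'   (source units).
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(baseline_rate = 2, duration_meanlog = log(0.25),
                       duration_sdlog = 0.4, amplitude = 1,
                       carrier = c(alpha = 1, beta = 0.6),
                       alpha_freq = c(9, 12), harmonic_phase = pi / 2,
                       attended_rate_factor = 0.75,
                       stim_suppression_factor = 0.6,
                       background_sd = 0.3) {
  stopifnot(baseline_rate > 0, amplitude > 0,
            attended_rate_factor >= 0, attended_rate_factor <= 1,
            stim_suppression_factor >= 0, stim_suppression_factor <= 1)
  out <- as.list(environment())
  class(out) <- "burst_spec"
  out
}

# windows (absolute s) where the burst rate is modulated, for a region
# driven by stimuli on `hand`:
#  - stimulus suppression: bilateral target window (1-3 s) + probes on `hand`
#  - attentional suppression: cue (4-6 s) and probe period (7-12.5 s) of
#    trials where `hand` is the cued hand
.rate_windows <- function(schedule, hand) {
  tr <- schedule$trials
  task <- tr[!tr$is_rest, , drop = FALSE]
  stim <- cbind(task$start_s + 1, task$start_s + 3)
  if (!is.null(schedule$probes) && nrow(schedule$probes) > 0) {
    pb <- schedule$probes[schedule$probes$hand == hand, , drop = FALSE]
    if (nrow(pb) > 0) {
      on <- tr$start_s[pb$trial_index] + pb$onset_s
      stim <- rbind(stim, cbind(on, on + .probe_duration))
    }
  }
  att_tr <- task[!is.na(task$cue) & task$cue == hand, , drop = FALSE]
  attn <- if (nrow(att_tr) > 0) {
    rbind(cbind(att_tr$start_s + 4, att_tr$start_s + 6),
          cbind(att_tr$start_s + 7, att_tr$start_s + 12.5))
  } else matrix(numeric(0), 0, 2)
  list(stim = stim, attn = attn)
}

.in_windows <- function(t, win) {
  if (nrow(win) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(win))) out <- out | (t >= win[i, 1] & t < win[i, 2])
  out
}

# 1/f (power ~ 1/f) coloured noise, unit sd, via spectral shaping
.pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency magnitude
  g <- 1 / sqrt(pmax(f, 1))                  # flat below 1 Hz
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

.tukey_window <- function(n, alpha = 0.5) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

#' Simulate one region's bursty source time course
#'
#' Draws burst onsets from an inhomogeneous Poisson process (thinning of a
#' homogeneous stream at `spec$baseline_rate`): the rate is multiplied by
#' `spec$stim_suppression_factor` while a stimulus is delivered to the
#' region's hand (the bilateral target window and this hand's probes) and by
#' `spec$attended_rate_factor` throughout the cue and probe windows of trials
#' in which that hand is attended. Each burst is a Tukey-windowed arc-shaped
#' packet (an alpha-band fundamental of random frequency and phase plus its
#' phase-locked second harmonic in the beta band), of log-normal duration,
#' added to a continuous 1/f background.
#'
#' @param schedule A `braille_schedule`.
#' @param spec A [burst_spec()].
#' @param fs Sampling rate (Hz, >= 200).
#' @param hand `"left"`, `"right"` for a somatosensory region driven by that
#'   hand's stimuli, or `NULL` for a region with no task modulation.
#' @param duration_s Optional duration override (defaults to the schedule
#'   length); useful for open-ended rest simulations.
#' @return List with `x` (source time course), `bursts` (data frame
#'   `onset_s`, `offset_s` of every injected burst), `fs`.
#' @export
simulate_source_timecourse <- function(schedule, spec = burst_spec(),
                                       fs = 1200, hand = NULL,
                                       duration_s = NULL) {
  if (fs < 200) stop("fs must be >= 200 Hz")
  T_s <- if (is.null(duration_s)) schedule$total_duration_s else duration_s
  n <- round(T_s * fs)
  if (n < 1) stop("empty schedule: nothing to simulate")
  x <- spec$background_sd * .pink_noise(n, fs)

  win <- if (!is.null(hand)) .rate_windows(schedule, hand) else
    list(stim = matrix(numeric(0), 0, 2), attn = matrix(numeric(0), 0, 2))

  n_cand <- stats::rpois(1, spec$baseline_rate * T_s)
  onsets <- sort(stats::runif(n_cand, 0, T_s))
  fac <- rep(1, length(onsets))
  fac[.in_windows(onsets, win$stim)] <- spec$stim_suppression_factor
  in_attn <- .in_windows(onsets, win$attn)
  fac[in_attn] <- fac[in_attn] * spec$attended_rate_factor
  keep <- stats::runif(length(onsets)) < fac
  onsets <- onsets[keep]

  durs <- stats::rlnorm(length(onsets), spec$duration_meanlog,
                        spec$duration_sdlog)
  ok <- onsets + durs < T_s
  onsets <- onsets[ok]; durs <- durs[ok]

  for (b in seq_along(onsets)) {
    i0 <- floor(onsets[b] * fs) + 1
    nb <- max(2L, round(durs[b] * fs))
    i1 <- min(n, i0 + nb - 1)
    tt <- (seq.int(i0, i1) - i0) / fs
    fa <- stats::runif(1, spec$alpha_freq[1], spec$alpha_freq[2])
    theta <- 2 * pi * fa * tt + stats::runif(1, 0, 2 * pi)
    pk <- spec$carrier[["alpha"]] * sin(theta) +
      spec$carrier[["beta"]] * sin(2 * theta + spec$harmonic_phase)
    x[i0:i1] <- x[i0:i1] + spec$amplitude * .tukey_window(length(tt)) * pk
  }
  list(x = x,
       bursts = data.frame(onset_s = onsets, offset_s = onsets + durs),
       fs = fs)
}

#' Simulate a full OPM-MEG recording with ground truth
#'
#' Composes the forward model over all regions: each region's bursty source
#' time course (fixed random tangential orientation, moment `dipole_moment`)
#' is projected through the spherical-conductor lead field onto every
#' channel; white sensor noise and a spatially uniform interference field
#' (three independent random walks band-limited below 2 Hz, projected on the
#' channel axes) are added. The left/right postcentral regions are driven by
#' the contralateral hand's stimuli and carry the attention effect; all other
#' regions are task-independent.
#'
#' @param schedule A `braille_schedule`.
#' @param source_model A `source_model`.
#' @param array A `sensor_array`.
#' @param spec A [burst_spec()] applied to every region.
#' @param noise_asd White sensor-noise amplitude spectral density
#'   (T / sqrt(Hz)); the per-sample sd is `noise_asd * sqrt(fs / 2)`.
#' @param drift_amplitude Standard deviation (T) of each spatial component
#'   of the uniform interference field.
#' @param fs Sampling rate (Hz).
#' @param dipole_moment Source moment scale (A m) mapping source units to
#'   dipole strength.
#' @param seed Optional seed.
#' @return A `synthetic_dataset`: list with `recording` (an
#'   `opm_recording`: `data` channels x samples in tesla, `fs`, `channels`
#'   geometry + `bad` flags, `events`, `duration_s`), `schedule`, and
#'   `truth` (`sources` regions x samples, `bursts` per-region interval
#'   tables, `orientations`, `uniform_field`).
#' @export
simulate_recording <- function(schedule, source_model = default_source_model(),
                               array = build_helmet_array(32),
                               spec = burst_spec(), noise_asd = 1e-14,
                               drift_amplitude = 5e-12, fs = 1200,
                               dipole_moment = 5e-9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (array$radius <= source_model$conductor_radius)
    stop("helmet radius must exceed the conductor radius")
  n <- round(schedule$total_duration_s * fs)
  if (n < 1) stop("schedule has zero duration")
  ch <- channels_table(array)
  nch <- nrow(ch)
  nr <- source_model$n_regions

  hands <- rep(list(NULL), nr)
  names(hands) <- source_model$labels
  if ("left_postcentral" %in% source_model$labels)
    hands[["left_postcentral"]] <- "right"
  if ("right_postcentral" %in% source_model$labels)
    hands[["right_postcentral"]] <- "left"

  sources <- matrix(0, nr, n)
  bursts <- vector("list", nr)
  names(bursts) <- source_model$labels
  for (r_ in seq_len(nr)) {
    sim <- simulate_source_timecourse(schedule, spec, fs,
                                      hand = hands[[r_]])
    sources[r_, ] <- sim$x
    bursts[[r_]] <- sim$bursts
  }

  # fixed random tangential orientation per region
  orientations <- matrix(0, nr, 3)
  gain <- matrix(0, nch, nr)
  for (r_ in seq_len(nr)) {
    cen <- source_model$centroids[r_, ] - source_model$centre
    er <- cen / sqrt(sum(cen^2))
    ref <- if (abs(er[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- c(er[2] * ref[3] - er[3] * ref[2],
            er[3] * ref[1] - er[1] * ref[3],
            er[1] * ref[2] - er[2] * ref[1])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(er[2] * t1[3] - er[3] * t1[2],
            er[3] * t1[1] - er[1] * t1[3],
            er[1] * t1[2] - er[2] * t1[1])
    th <- stats::runif(1, 0, 2 * pi)
    u <- cos(th) * t1 + sin(th) * t2
    orientations[r_, ] <- u
    L <- leadfield_matrix(ch, source_model$centroids[r_, ],
                          centre = source_model$centre)
    gain[, r_] <- L %*% u
  }

  data <- gain %*% (dipole_moment * sources)

  noise_sd <- noise_asd * sqrt(fs / 2)
  if (noise_sd > 0)
    data <- data + matrix(stats::rnorm(nch * n, sd = noise_sd), nch, n)

  uniform <- NULL
  if (drift_amplitude > 0) {
    bf <- signal::butter(2, min(2 / (fs / 2), 0.99), type = "low")
    uniform <- sapply(1:3, function(k) {
      w <- cumsum(stats::rnorm(n))
      w <- zerophase_filter(bf$b, bf$a, w)
      drift_amplitude * (w - mean(w)) / stats::sd(w)
    })                                        # n x 3
    S <- as.matrix(ch[, c("ax", "ay", "az")])
    data <- data + S %*% t(uniform)
  }

  ch$bad <- FALSE
  rownames(data) <- ch$name
  recording <- list(data = data, fs = fs, channels = ch,
                    events = schedule_to_events(schedule),
                    duration_s = schedule$total_duration_s)
  class(recording) <- "opm_recording"
  out <- list(recording = recording, schedule = schedule,
              truth = list(sources = sources, bursts = bursts,
                           orientations = orientations,
                           dipole_moment = dipole_moment,
                           uniform_field = uniform,
                           source_model = source_model, array = array))
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.opm_recording <- function(x, ...) {
  cat(sprintf("OPM recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), x$duration_s, x$fs))
  invisible(x)
}
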