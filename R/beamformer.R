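#' Zero-phase band-pass filter
#'
#' Forward-backward 4th-order Butterworth band-pass (zero group delay by
#' construction), applied per channel.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param band `c(f_lo, f_hi)` in Hz, `0 < f_lo < f_hi < fs / 2`.
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered data, same shape as `x`.
#' @export
band_filter <- function(x, fs, band, order = 4) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("band edges must satisfy 0 < f_lo < f_hi < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  zerophase_filter(bf$b, bf$a, x)
}

#' Zero-phase IIR filtering
#'
#' Forward-backward application of the filter `(b, a)` with reflected edge
#' padding, giving zero group delay and squared magnitude response. Works on
#' vectors or channels x samples matrices (channels filtered independently).
#'
#' @param b,a Numerator and denominator filter coefficients.
#' @param x Numeric vector or channels x samples matrix.
#' @param n_pad Reflection pad length per edge (default 10 x filter length,
#'   capped by the series length).
#' @return Filtered data, same shape as `x`.
#' @export
zerophase_filter <- function(b, a, x, n_pad = NULL) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x          # channels x samples
  if (is.null(n_pad))
    n_pad <- min(ncol(X) - 1L, 10L * max(length(a), length(b)))
  Y <- .filtfilt_cpp(as.numeric(b), as.numeric(a), X, as.integer(n_pad))
  if (vec) as.numeric(Y) else {
    dimnames(Y) <- dimnames(X)
    Y
  }
}

#' Tikhonov-regularise a covariance matrix
#'
#' Adds `mu` times the largest eigenvalue of the unregularised covariance to
#' the diagonal (default 5%), guaranteeing a well-conditioned positive
#' definite matrix for the beamformer inversion.
#'
#' @param C Symmetric positive semidefinite covariance matrix.
#' @param mu Regularisation fraction of the maximum eigenvalue.
#' @param band Optional band label carried in the result.
#' @param n_samples Optional sample count carried in the result.
#' @return A `band_covariance`: list with `C`, `C_reg`, `lambda_max`,
#'   `regularisation` (the scalar added to the diagonal), `band`,
#'   `n_samples`.
#' @export
tikhonov_regularise <- function(C, mu = 0.05, band = NULL, n_samples = NA) {
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C), 1e-300))
    stop("covariance matrix is not symmetric")
  C <- (C + t(C)) / 2
  lmax <- eigen(C, symmetric = TRUE, only.values = TRUE)$values[1]
  reg <- mu * lmax
  out <- list(C = C, C_reg = C + diag(reg, nrow(C)), lambda_max = lmax,
              regularisation = reg, band = band, n_samples = n_samples)
  class(out) <- "band_covariance"
  out
}

.creg <- function(C_reg) {
  if (inherits(C_reg, "band_covariance")) C_reg$C_reg else C_reg
}

#' Data-driven source orientation
#'
#' Returns the unit dipole orientation maximising beamformer output power
#' `1 / (u' L' C^-1 L u)`, i.e. the eigenvector of `L' C^-1 L` with the
#' smallest eigenvalue, restricted to the subspace where the lead field is
#' non-null (for the spherical conductor the radial column is silent and is
#' excluded automatically). Sign convention: first non-zero component
#' positive.
#'
#' @param L channels x 3 region lead field.
#' @param C_reg Regularised covariance (`band_covariance` or matrix).
#' @param null_tol Relative singular-value threshold declaring a lead-field
#'   direction null.
#' @return Unit 3-vector.
#' @export
optimal_orientation <- function(L, C_reg, null_tol = 1e-8) {
  C_reg <- .creg(C_reg)
  sv <- svd(L)
  keep <- sv$d > null_tol * sv$d[1]
  if (!any(keep) || sv$d[1] == 0) stop("lead field is effectively rank 0")
  V <- sv$v[, keep, drop = FALSE]
  R <- chol(C_reg)
  CiL <- backsolve(R, forwardsolve(t(R), L))
  M <- crossprod(L, CiL)
  M <- (M + t(M)) / 2
  Mred <- crossprod(V, M %*% V)
  e <- eigen((Mred + t(Mred)) / 2, symmetric = TRUE)
  v <- e$vectors[, ncol(Mred)]          # smallest eigenvalue -> largest power
  u <- as.numeric(V %*% v)
  u <- u / sqrt(sum(u^2))
  nz <- which(abs(u) > 1e-12)[1]
  if (!is.na(nz) && u[nz] < 0) u <- -u
  u
}

#' LCMV beamformer weights
#'
#' Minimum-variance spatial filter with unit gain on the target lead field:
#' `w = C^-1 l / (l' C^-1 l)`, so `w' l = 1` by construction.
#'
#' @param l Channels vector (lead field at the chosen orientation).
#' @param C_reg Regularised covariance (`band_covariance` or matrix).
#' @return Weight vector (channels).
#' @export
lcmv_weights <- function(l, C_reg) {
  C_reg <- .creg(C_reg)
  if (sqrt(sum(l^2)) == 0) stop("lead field vector is zero")
  R <- chol(C_reg)
  Ci_l <- backsolve(R, forwardsolve(t(R), l))
  as.numeric(Ci_l / sum(l * Ci_l))
}

#' Reconstruct regional virtual electrodes
#'
#' Per band and region: band-pass filter the (good-channel) sensor data,
#' compute the data covariance over samples surviving trial rejection,
#' regularise it (5% Tikhonov), pick the power-maximising tangential source
#' orientation, form LCMV weights, and project the sensor data to a regional
#' source time course ("virtual electrode").
#'
#' @param recording A preprocessed `opm_recording`.
#' @param source_model A `source_model` giving centroids and labels.
#' @param band `c(f_lo, f_hi)` Hz.
#' @param regions Optional character vector restricting output regions.
#' @param sample_mask Optional logical vector of samples entering the
#'   covariance (kept-trial samples); all samples if `NULL`.
#' @param mu Tikhonov fraction.
#' @param min_leadfield Minimum acceptable lead-field Frobenius norm; guards
#'   the orientation criterion against noise-only degenerate regions.
#' @return A `virtual_electrodes`: list with `data` (regions x samples),
#'   `band`, `orientations` (regions x 3), `weights` (regions x good
#'   channels), `labels`, `fs`, `covariance` (the `band_covariance`).
#' @export
reconstruct_virtual_electrodes <- function(recording, source_model, band,
                                           regions = NULL, sample_mask = NULL,
                                           mu = 0.05, min_leadfield = 1e-30) {
  stopifnot(inherits(recording, "opm_recording"))
  good <- !recording$channels$bad
  ch <- recording$channels[good, , drop = FALSE]
  Xf <- band_filter(recording$data[good, , drop = FALSE], recording$fs, band)
  Xc <- if (is.null(sample_mask)) Xf else Xf[, sample_mask, drop = FALSE]
  C <- tcrossprod(Xc - rowMeans(Xc)) / (ncol(Xc) - 1)
  bc <- tikhonov_regularise(C, mu = mu, band = band, n_samples = ncol(Xc))

  labels <- if (is.null(regions)) source_model$labels else regions
  idx <- match(labels, source_model$labels)
  if (anyNA(idx)) stop("unknown region label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  W <- matrix(0, length(idx), nrow(ch))
  orient <- matrix(0, length(idx), 3)
  U <- recording$proj_axes     # HFC projector, if the data were corrected
  for (k in seq_along(idx)) {
    L <- leadfield_matrix(ch, source_model$centroids[idx[k], ],
                          centre = source_model$centre)
    if (!is.null(U)) L <- L - U %*% crossprod(U, L)
    if (sqrt(sum(L^2)) < min_leadfield)
      stop("lead field norm below threshold for region ", labels[k])
    u <- optimal_orientation(L, bc)
    orient[k, ] <- u
    W[k, ] <- lcmv_weights(as.numeric(L %*% u), bc)
  }
  out <- list(data = W %*% Xf, band = band, orientations = orient,
              weights = W, labels = labels, fs = recording$fs,
              covariance = bc)
  rownames(out$data) <- labels
  class(out) <- "virtual_electrodes"
  out
}

#' @export
print.virtual_electrodes <- function(x, ...) {
  cat(sprintf("virtual electrodes: %d regions, band %g-%g Hz, %d samples\n",
              nrow(x$data), x$band[1], x$band[2], ncol(x$data)))
  invisible(x)
}
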