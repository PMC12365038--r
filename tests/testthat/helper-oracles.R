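# Independent oracles used across the suite. Each one is deliberately
# brute-force / closed-form and shares no code with the implementation paths
# it checks.

# HMM data log-likelihood by exhaustive enumeration over all K^T state paths
enum_hmm_loglik <- function(logB, pi, A) {
  T_ <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lls <- apply(paths, 1, function(z) {
    ll <- log(pi[z[1]]) + logB[1, z[1]]
    for (t in 2:T_) ll <- ll + log(A[z[t - 1], z[t]]) + logB[t, z[t]]
    ll
  })
  m <- max(lls)
  m + log(sum(exp(lls - m)))
}

# two-sided Wilcoxon sign-rank p-value by exhaustive sign-flip enumeration
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(Ws <= W_obs)
  p_ge <- mean(Ws >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg by direct step-up sweep over all m thresholds
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_max <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_max <- k
  rej <- rep(FALSE, m)
  if (k_max > 0) rej[o[seq_len(k_max)]] <- TRUE
  rej
}

# spherical-conductor dipole field from the magnetic scalar potential,
# differentiated numerically (independent of the analytic gradient route)
sphere_field_numeric <- function(source_pos, moment, sensor_pos,
                                 centre = c(0, 0, 0), h = 1e-6) {
  potential <- function(r) {
    r0 <- source_pos - centre
    rr <- r - centre
    a_vec <- rr - r0
    a <- sqrt(sum(a_vec^2))
    R <- sqrt(sum(rr^2))
    F_ <- a * (R * a + R^2 - sum(r0 * rr))
    qxr0 <- c(moment[2] * r0[3] - moment[3] * r0[2],
              moment[3] * r0[1] - moment[1] * r0[3],
              moment[1] * r0[2] - moment[2] * r0[1])
    -sum(qxr0 * rr) / (4 * pi * F_)
  }
  g <- numeric(3)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    g[j] <- (potential(sensor_pos + e) - potential(sensor_pos - e)) / (2 * h)
  }
  -4 * pi * 1e-7 * g     # B = -mu0 grad U
}

# align estimated 2-state labels to truth by best permutation
align_two_states <- function(z_hat, z_true) {
  acc_id <- mean(z_hat == z_true)
  acc_sw <- mean((3 - z_hat) == z_true)
  if (acc_sw > acc_id) list(z = 3 - z_hat, perm = c(2, 1), acc = acc_sw)
  else list(z = z_hat, perm = c(1, 2), acc = acc_id)
}
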