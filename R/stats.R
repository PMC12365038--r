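#' Wilcoxon sign-rank test for paired samples
#'
#' Signed-rank statistic on the nonzero paired differences with midrank
#' ties. For `n_effective <= 25` the two-sided p-value is exact, computed
#' from the full sign-flip distribution of the statistic (which handles
#' midranks exactly); above that a normal approximation with continuity
#' correction and tie-adjusted variance is used.
#'
#' @param x,y Paired numeric vectors; `y` may be omitted to test `x`
#'   against zero.
#' @param exact_max Largest `n_effective` for which the exact distribution
#'   is enumerated.
#' @return List with `statistic` (W, sum of positive-difference ranks),
#'   `p_value`, `n_effective`, `method`, `direction` (+1 if the positive
#'   ranks dominate).
#' @export
wilcoxon_signrank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero: test degenerate")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    # distribution of 2W over sign flips; doubling makes midranks integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)          # f[s + 1] = #assignments with 2W = s
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
        f[1:(total - ri + 1L)]
      f <- g
    }
    w2 <- as.integer(round(2 * W))
    tot <- 2^n
    p_le <- sum(f[1:(w2 + 1L)]) / tot
    p_ge <- sum(f[(w2 + 1L):(total + 1L)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact sign-flip enumeration"
  } else {
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = W, p_value = p, n_effective = n, method = method,
       direction = if (W >= mu) 1 else -1)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up false discovery rate control at level `q` over one family of
#' p-values.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical rejection flags, same order as `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value family")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Attention contrast report
#'
#' Runs the full across-subject inference: the envelope family (4 tests:
#' beta CNR in left / right somatosensory cortex, cue window and probe
#' window, attended versus non-attended) and the burst-metric family (12
#' tests: count, amplitude and duration in cue and probe windows for both
#' hemispheres), each Wilcoxon sign-rank tested and Benjamini-Hochberg
#' corrected within its own family.
#'
#' @param subject_summary Data frame with one row per subject x test cell:
#'   columns `subject`, `family` (`"envelope"` or `"burst"`), `metric`,
#'   `window` (`"cue"` or `"probe"`), `hemisphere` (`"left"` / `"right"`),
#'   `attended`, `nonattended` (the per-subject condition means).
#' @param q FDR level per family.
#' @return Data frame with one row per test: `family`, `metric`, `window`,
#'   `hemisphere`, `n`, `W`, `p`, `bh_rejected`, `direction` (`+1` when the
#'   attended value is larger).
#' @export
attention_contrast_report <- function(subject_summary, q = 0.05) {
  need <- c("subject", "family", "metric", "window", "hemisphere",
            "attended", "nonattended")
  stopifnot(all(need %in% names(subject_summary)))
  key <- interaction(subject_summary$family, subject_summary$metric,
                     subject_summary$window, subject_summary$hemisphere,
                     drop = TRUE)
  rows <- lapply(split(subject_summary, key), function(g) {
    ok <- is.finite(g$attended) & is.finite(g$nonattended)
    if (any(!ok))
      warning(sprintf("%d subject(s) dropped pairwise for %s/%s/%s/%s",
                      sum(!ok), g$family[1], g$metric[1], g$window[1],
                      g$hemisphere[1]))
    g <- g[ok, , drop = FALSE]
    tst <- wilcoxon_signrank(g$attended, g$nonattended)
    data.frame(family = g$family[1], metric = g$metric[1],
               window = g$window[1], hemisphere = g$hemisphere[1],
               n = tst$n_effective, W = tst$statistic, p = tst$p_value,
               direction = tst$direction, stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  rownames(rep_) <- NULL
  rep_$bh_rejected <- FALSE
  for (fam in unique(rep_$family)) {
    sel <- rep_$family == fam
    rep_$bh_rejected[sel] <- bh_fdr(rep_$p[sel], q = q)
  }
  rep_[order(rep_$family, rep_$metric, rep_$window, rep_$hemisphere), ,
       drop = FALSE]
}
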