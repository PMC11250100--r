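# Independent brute-force oracles for the feature bank. These are
# deliberately written as direct transcriptions of the definitions
# (explicit loops, no shared code with the package internals) so that a
# feature and its oracle can only agree by computing the same quantity.

o_moments_kurtosis <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  if (m2 == 0) return(0)
  m4 <- sum((x - m)^4) / length(x)
  m4 / (m2 * m2)
}

o_moments_skewness <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  if (m2 == 0) return(0)
  (sum((x - m)^3) / length(x)) / m2^(3 / 2)
}

o_amplitude_change <- function(x, fs, window_s = 0.05) {
  w <- round(window_s * fs)
  best <- 0
  for (i in 1:(length(x) - w + 1L)) {
    win <- x[i:(i + w - 1L)]
    best <- max(best, max(win) - min(win))
  }
  best
}

o_mean_local_skew <- function(x, fs, seg_s = 0.015) {
  w <- round(seg_s * fs)
  k <- length(x) %/% w
  vals <- numeric(k)
  for (j in seq_len(k))
    vals[j] <- abs(o_moments_skewness(x[((j - 1L) * w + 1L):(j * w)]))
  mean(vals)
}

o_amplitude_variance <- function(x) {
  y <- x^2
  m <- mean(y)
  sum((y - m)^2) / (length(y) - 1L)
}

o_derivative_sum <- function(x, fs, window_s) {
  w <- round(window_s * fs)
  av <- o_amplitude_variance(x)
  if (av == 0) return(0)
  best <- 0
  for (i in 1:(length(x) - w + 1L)) {
    s <- sum(diff(x[i:(i + w - 1L)]))      # telescopes to net change
    best <- max(best, abs(s))
  }
  best / av
}

# Direct DFT of the demeaned zero-padded series at selected bins; the
# package's one-sided PSD at bin k must equal mult * |DFT_k|^2 / (fs*n),
# with the epoch mean's power assigned to the DC bin.
o_psd_bins <- function(x, fs, nfft, bins) {
  n <- length(x)
  mx <- mean(x)
  xp <- c(x - mx, rep(0, nfft - n))
  tt <- seq_len(nfft) - 1L
  vapply(bins, function(k) {
    Xk <- sum(xp * exp(-2i * pi * (k - 1L) * tt / nfft))
    mult <- if (k == 1L || (nfft %% 2L == 0L && k == nfft / 2 + 1L)) 1 else 2
    v <- mult * Mod(Xk)^2 / (fs * n)
    if (k == 1L) v <- v + mx^2 / (fs / nfft)
    v
  }, numeric(1))
}

o_band_power <- function(freqs, power, lo, hi) {
  df <- freqs[2L] - freqs[1L]
  tot <- 0
  for (i in seq_along(freqs))
    if (freqs[i] >= lo && freqs[i] < hi) tot <- tot + power[i] * df
  tot
}

o_spectral_fit <- function(freqs, power, lo, hi) {
  keep <- freqs >= lo & freqs < hi & freqs > 0 & power > 0
  fit <- stats::lm(log10(power[keep]) ~ log10(freqs[keep]))
  c(lambda = unname(stats::coef(fit)[2L]),
    fit_error = sqrt(mean(stats::residuals(fit)^2)))
}

o_higuchi <- function(x, kmax = 8L) {
  N <- length(x)
  logL <- numeric(0); logk <- numeric(0)
  for (k in 1:kmax) {
    Ls <- c()
    for (m in 1:k) {
      pts <- x[seq(m, N, by = k)]
      if (length(pts) < 2L) next
      Lmk <- 0
      for (q in 2:length(pts)) Lmk <- Lmk + abs(pts[q] - pts[q - 1L])
      norm <- (N - 1) / ((length(pts) - 1L) * k)
      Ls <- c(Ls, Lmk * norm / k)
    }
    L <- mean(Ls)
    if (L > 0) { logL <- c(logL, log(L)); logk <- c(logk, log(1 / k)) }
  }
  if (!length(logL)) return(0)
  unname(stats::coef(stats::lm(logL ~ logk))[2L])
}

o_katz <- function(x) {
  L <- 0
  for (i in 2:length(x)) L <- L + abs(x[i] - x[i - 1L])
  if (L == 0) return(1)
  d <- max(abs(x - x[1L]))
  nn <- length(x) - 1L
  log10(nn) / (log10(nn) + log10(d / L))
}

o_fd_kurtosis <- function(x, fs, method, window_s = 0.1, overlap = 0.5) {
  w <- round(window_s * fs)
  step <- round(w * (1 - overlap))
  fds <- c()
  i <- 1L
  while (i + w - 1L <= length(x)) {
    win <- x[i:(i + w - 1L)]
    fds <- c(fds, if (method == "higuchi") o_higuchi(win) else o_katz(win))
    i <- i + step
  }
  o_moments_kurtosis(fds)
}

o_haar_details <- function(x) {
  m <- 2^ceiling(log2(length(x)))
  a <- c(x, rep(x[length(x)], m - length(x)))
  det <- c()
  while (length(a) > 1L) {
    nd <- length(a) / 2L
    d <- numeric(nd); s <- numeric(nd)
    for (i in seq_len(nd)) {
      d[i] <- (a[2L * i - 1L] - a[2L * i]) / sqrt(2)
      s[i] <- (a[2L * i - 1L] + a[2L * i]) / sqrt(2)
    }
    det <- c(det, d)
    a <- s
  }
  det
}

# Full 31-feature oracle vector for one epoch (same manifest order).
oracle_features <- function(ep) {
  x <- ep$samples; fs <- ep$fs
  sp <- periodogram(ep)                    # grid shared; PSD checked via o_psd_bins
  out <- c(
    amplitude_change_50ms = o_amplitude_change(x, fs),
    mean_local_skew_15ms = o_mean_local_skew(x, fs),
    temporal_kurtosis = o_moments_kurtosis(x),
    amplitude_variance = o_amplitude_variance(x),
    deriv_sum_50ms = o_derivative_sum(x, fs, 0.05),
    deriv_sum_100ms = o_derivative_sum(x, fs, 0.1),
    deriv_sum_200ms = o_derivative_sum(x, fs, 0.2),
    deriv_sum_300ms = o_derivative_sum(x, fs, 0.3),
    deriv_sum_500ms = o_derivative_sum(x, fs, 0.5),
    power_below_0p5hz = o_band_power(sp$freqs, sp$power, 1e-12, 0.5))
  for (b in names(feature_bands())) {
    bd <- feature_bands()[[b]]
    ft <- o_spectral_fit(sp$freqs, sp$power, bd[1L], bd[2L])
    v <- c(o_band_power(sp$freqs, sp$power, bd[1L], bd[2L]),
           ft[["lambda"]], ft[["fit_error"]])
    names(v) <- paste(c("bandpower", "lambda", "fiterror"), b, sep = "_")
    out <- c(out, v)
  }
  c(out,
    fd_kurtosis_higuchi = o_fd_kurtosis(x, fs, "higuchi"),
    fd_kurtosis_katz = o_fd_kurtosis(x, fs, "katz"),
    haar_kurtosis = o_moments_kurtosis(o_haar_details(x)))
}

# Small random epochs for property loops.
random_epoch <- function(seed, n = 3000L, fs = 2000) {
  set.seed(seed)
  eeg_epoch(stats::rnorm(n, sd = 20) + 10 * sin(2 * pi * 7 * seq_len(n) / fs),
            fs = fs)
}

sim_spec <- function(seed = 42, ...) generator_spec(seed = seed, ...)
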