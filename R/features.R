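# Feature bank: 31 scalar descriptors per epoch, in a frozen canonical
# order. Conventions used throughout:
#   * kurtosis and skewness are the moment ("Pearson") forms, normal -> 3
#     and 0 respectively;
#   * any feature whose defining moment is degenerate (0/0) returns 0, so
#     the bank is a total function and downstream ensembles never see NaN;
#   * variances are the n-1 sample form (stats::var).

FEATURE_BANDS <- list(
  delta = c(0.2, 3.5), theta = c(4, 7.5), alpha = c(8, 13),
  beta = c(14, 30), gamma = c(30, 70), broadband = c(2, 70))

FEATURE_MANIFEST_VERSION <- "1"

FEATURE_MANIFEST <- c(
  "amplitude_change_50ms", "mean_local_skew_15ms", "temporal_kurtosis",
  "amplitude_variance",
  "deriv_sum_50ms", "deriv_sum_100ms", "deriv_sum_200ms",
  "deriv_sum_300ms", "deriv_sum_500ms",
  "power_below_0p5hz",
  as.vector(outer(c("bandpower", "lambda", "fiterror"),
                  names(FEATURE_BANDS), paste, sep = "_")),
  "fd_kurtosis_higuchi", "fd_kurtosis_katz", "haar_kurtosis")

#' The canonical feature manifest
#'
#' Names of the 31 epoch features in their frozen order. Feature tables
#' and trained models carry this ordering; prediction refuses mismatched
#' manifests. The same list ships as a plain-text file under
#' `inst/extdata/` for non-R consumers.
#'
#' @return Character vector of 31 names with a `"version"` attribute.
#' @export
feature_manifest <- function() {
  structure(FEATURE_MANIFEST, version = FEATURE_MANIFEST_VERSION)
}

#' @rdname feature_manifest
#' @export
feature_bands <- function() FEATURE_BANDS

moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (!is.finite(m2) || m2 <= 0) return(0)
  mean((x - m)^4) / m2^2
}

moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (!is.finite(m2) || m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Maximum amplitude change within any short window
#'
#' Largest peak-to-trough range (max - min) over all sliding windows of
#' `window_s` seconds.
#'
#' @param epoch An `eeg_epoch`.
#' @param window_s Window length in seconds (default 0.05).
#' @return Amplitude change in microvolts, >= 0.
#' @export
amplitude_change <- function(epoch, window_s = 0.05) {
  x <- epoch$samples
  w <- round(window_s * epoch$fs)
  if (w >= length(x)) stop("amplitude_change: window not shorter than epoch")
  if (w < 2L) return(0)
  m <- stats::embed(x, w)                       # one row per window
  hi <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  lo <- m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
  max(hi - lo)
}

#' Mean absolute local skewness over short segments
#'
#' The epoch is cut into contiguous non-overlapping segments of `seg_s`
#' seconds (trailing partial segment dropped); the absolute moment
#' skewness of each is averaged. Zero-variance segments contribute 0.
#'
#' @param epoch An `eeg_epoch`.
#' @param seg_s Segment length in seconds (default 0.015).
#' @return Dimensionless mean |skewness|.
#' @export
mean_local_skewness <- function(epoch, seg_s = 0.015) {
  x <- epoch$samples
  w <- round(seg_s * epoch$fs)
  k <- length(x) %/% w
  if (k < 1L) stop("mean_local_skewness: epoch shorter than one segment")
  segs <- matrix(x[seq_len(k * w)], nrow = w)
  mean(abs(apply(segs, 2L, moment_skewness)))
}

#' Kurtosis of the whole epoch
#'
#' Moment (Pearson) kurtosis, so Gaussian noise gives ~3 and a full-period
#' sinusoid exactly 1.5. Degenerate (constant) epochs return 0.
#'
#' @param epoch An `eeg_epoch`.
#' @return Dimensionless kurtosis.
#' @export
temporal_kurtosis <- function(epoch) moment_kurtosis(epoch$samples)

#' Variance of the point-wise signal power
#'
#' Sample variance of the squared amplitude series x(t)^2; sensitive both
#' to bursts (heavy right tail of power) and to flat/detached segments
#' (collapsed power).
#'
#' @param epoch An `eeg_epoch`.
#' @return Variance in microvolts^4.
#' @export
amplitude_variance <- function(epoch) {
  x2 <- epoch$samples^2
  if (length(x2) < 2L) return(0)
  stats::var(x2)
}

#' Maximum absolute windowed net amplitude change, variance-normalised
#'
#' The sum of first differences inside a window telescopes to the net
#' change across it, so the statistic is the largest |x(end) - x(start)|
#' over all sliding windows of `window_s` seconds, divided by
#' [amplitude_variance()] of the epoch (0 if that variance is 0).
#'
#' @param epoch An `eeg_epoch`.
#' @param window_s Window length in seconds; the bank uses 0.05, 0.1, 0.2,
#'   0.3 and 0.5.
#' @return Dimensionless, >= 0.
#' @export
derivative_sum <- function(epoch, window_s) {
  x <- epoch$samples
  w <- round(window_s * epoch$fs)
  if (w >= length(x)) stop("derivative_sum: window not shorter than epoch")
  av <- amplitude_variance(epoch)
  if (av <= 0) return(0)
  n <- length(x)
  max(abs(x[w:n] - x[seq_len(n - w + 1L)])) / av
}

#' One-sided periodogram of an epoch
#'
#' Rectangular-window FFT periodogram, evaluated on a zero-padded grid
#' (default four times the next power of two) so that band edges well
#' below the epoch's native 1/T resolution — notably the 0.5 Hz
#' low-frequency bound — still contain bins. The epoch mean is removed
#' before padding (otherwise the pad boundary leaks DC into every
#' low-frequency bin) and its power is assigned to the DC bin, so the
#' spectral integral still equals the mean squared amplitude (Parseval).
#'
#' @param epoch An `eeg_epoch`.
#' @param nfft FFT length; default `4 * 2^ceiling(log2(n))`.
#' @return An `eeg_spectrum`: list of `freqs` (Hz) and `power`
#'   (microvolts^2 / Hz).
#' @export
periodogram <- function(epoch, nfft = NULL) {
  x <- epoch$samples
  n <- length(x)
  fs <- epoch$fs
  if (is.null(nfft)) nfft <- 4L * 2L^ceiling(log2(n))
  nfft <- max(nfft, n)
  mx <- mean(x)
  X <- stats::fft(c(x - mx, rep(0, nfft - n)))
  half <- floor(nfft / 2) + 1L
  p <- Mod(X[seq_len(half)])^2 / (fs * n)
  mult <- rep(2, half)
  mult[1L] <- 1
  if (nfft %% 2L == 0L) mult[half] <- 1
  p <- p * mult
  df <- fs / nfft
  p[1L] <- p[1L] + mx^2 / df             # DC power carried by the mean
  eeg_spectrum(freqs = (seq_len(half) - 1L) * fs / nfft, power = p)
}

#' Construct a power spectrum container
#'
#' @param freqs Strictly increasing frequency grid in Hz.
#' @param power Non-negative PSD values in microvolts^2 / Hz.
#' @return An `eeg_spectrum` object.
#' @export
eeg_spectrum <- function(freqs, power) {
  stopifnot(length(freqs) == length(power), !is.unsorted(freqs, strictly = TRUE),
            all(power >= 0))
  structure(list(freqs = freqs, power = power), class = "eeg_spectrum")
}

#' Integrated power in a frequency band
#'
#' Sums PSD x bin width over bins whose centre lies in `[lo, hi)`
#' (half-open). An empty band at the spectral resolution yields 0 with a
#' warning.
#'
#' @param spec An `eeg_spectrum`.
#' @param band Numeric `c(lo, hi)` in Hz, or a band name from
#'   [feature_bands()].
#' @return Band power in microvolts^2.
#' @export
band_power <- function(spec, band) {
  if (is.character(band)) band <- FEATURE_BANDS[[match.arg(band, names(FEATURE_BANDS))]]
  df <- spec$freqs[2L] - spec$freqs[1L]
  idx <- spec$freqs >= band[1L] & spec$freqs < band[2L]
  if (!any(idx)) {
    warning(sprintf("band_power: no bins in [%g, %g) Hz at this resolution",
                    band[1L], band[2L]))
    return(0)
  }
  sum(spec$power[idx]) * df
}

#' Total power below 0.5 Hz (DC excluded)
#'
#' @param spec An `eeg_spectrum`.
#' @return Power in microvolts^2 over bins with 0 < f < 0.5 Hz.
#' @export
power_below_0p5hz <- function(spec) {
  df <- spec$freqs[2L] - spec$freqs[1L]
  idx <- spec$freqs > 0 & spec$freqs < 0.5
  sum(spec$power[idx]) * df
}

#' Power-law fit of the spectrum in a band
#'
#' Least-squares line of log10(power) on log10(frequency) over the band's
#' usable bins (f > 0, power > 0): the slope is the spectral exponent
#' lambda, and the fit error is the RMSE of the residuals in log-power
#' units. Fewer than 3 usable bins yields `(0, 0, 0)` with a warning.
#'
#' @param spec An `eeg_spectrum`.
#' @param band `c(lo, hi)` in Hz or a band name.
#' @return Named vector `c(lambda, C, fit_error)`.
#' @export
spectral_fit <- function(spec, band) {
  if (is.character(band)) band <- FEATURE_BANDS[[match.arg(band, names(FEATURE_BANDS))]]
  idx <- spec$freqs >= band[1L] & spec$freqs < band[2L] &
    spec$freqs > 0 & spec$power > 0
  if (sum(idx) < 3L) {
    warning(sprintf("spectral_fit: <3 usable bins in [%g, %g) Hz",
                    band[1L], band[2L]))
    return(c(lambda = 0, C = 0, fit_error = 0))
  }
  lf <- log10(spec$freqs[idx])
  lp <- log10(spec$power[idx])
  fit <- stats::lm.fit(cbind(1, lf), lp)
  res <- fit$residuals
  c(lambda = unname(fit$coefficients[2L]), C = unname(fit$coefficients[1L]),
    fit_error = sqrt(mean(res^2)))
}

#' Higuchi fractal dimension of a series
#'
#' Curve-length estimator: average normalised length L(k) over lags
#' k = 1..k_max, with the dimension the slope of log L(k) on log(1/k).
#' White noise approaches 2, a smooth line 1.
#'
#' @param x Numeric series.
#' @param k_max Maximum lag (default 8).
#' @return Estimated fractal dimension (0 for a degenerate constant
#'   series).
#' @export
higuchi_fd <- function(x, k_max = 8L) {
  N <- length(x)
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, N, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) { Lm[m] <- NA_real_; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (N - 1) / (ni * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  if (all(Lk <= 0)) return(0)
  keep <- Lk > 0
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(k_max))[keep]), log(Lk[keep]))
  unname(fit$coefficients[2L])
}

#' Katz fractal dimension of a series
#'
#' Waveform-length / diameter form: D = log10(n) / (log10(n) +
#' log10(d/L)) with L the summed absolute first differences, d the
#' maximum excursion from the first sample and n the number of steps.
#' A straight segment gives exactly 1 (a constant counts as a flat line).
#'
#' @param x Numeric series.
#' @return Estimated fractal dimension.
#' @export
katz_fd <- function(x) {
  L <- sum(abs(diff(x)))
  if (L <= 0) return(1)
  d <- max(abs(x - x[1L]))
  n <- length(x) - 1L
  log10(n) / (log10(n) + log10(d / L))
}

fd_windows <- function(x, fs, fd_window_s, overlap) {
  w <- round(fd_window_s * fs)
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, length(x) - w + 1L, by = step)
  lapply(starts, function(s) x[s:(s + w - 1L)])
}

#' Kurtosis of windowed fractal-dimension estimates
#'
#' The fractal dimension is estimated in sliding windows (default 100 ms,
#' 50% overlap) by either the Higuchi or the Katz estimator and the
#' moment kurtosis of the resulting FD series is returned. Artefacts that
#' switch the waveform between regimes (e.g. detachment, bursts) make
#' this series heavy-tailed.
#'
#' @param epoch An `eeg_epoch`.
#' @param method `"higuchi"` or `"katz"`.
#' @param fd_window_s Window length in seconds (default 0.1).
#' @param overlap Fractional window overlap (default 0.5).
#' @param k_max Higuchi maximum lag (default 8).
#' @return Dimensionless kurtosis (0 when the FD series is degenerate).
#' @export
fd_kurtosis <- function(epoch, method = c("higuchi", "katz"),
                        fd_window_s = 0.1, overlap = 0.5, k_max = 8L) {
  method <- match.arg(method)
  wins <- fd_windows(epoch$samples, epoch$fs, fd_window_s, overlap)
  if (length(wins) < 4L) stop("fd_kurtosis: need at least 4 FD windows")
  fd <- vapply(wins, function(w)
    if (method == "higuchi") higuchi_fd(w, k_max) else katz_fd(w), numeric(1))
  moment_kurtosis(fd)
}

#' Full-depth Haar wavelet detail coefficients
#'
#' Orthonormal Haar decomposition down to a single approximation
#' coefficient; the series is padded to the next power of two by
#' replicating the final sample (so a constant epoch yields all-zero
#' details, with no spurious boundary step). Level-1 details are
#' `(x[2i-1] - x[2i]) / sqrt(2)`.
#'
#' @param x Numeric series, length >= 2.
#' @return Numeric vector of all detail coefficients, coarse levels last.
#' @export
haar_details <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  m <- 2L^ceiling(log2(n))
  a <- c(x, rep(x[n], m - n))
  details <- numeric(0)
  while (length(a) > 1L) {
    odd <- a[seq(1L, length(a), by = 2L)]
    even <- a[seq(2L, length(a), by = 2L)]
    details <- c(details, (odd - even) / sqrt(2))
    a <- (odd + even) / sqrt(2)
  }
  details
}

#' Kurtosis of the Haar wavelet detail coefficients
#'
#' @param epoch An `eeg_epoch`.
#' @return Moment kurtosis of all detail levels concatenated (0 when
#'   degenerate). Spiky epochs give values far above 3.
#' @export
haar_kurtosis <- function(epoch) moment_kurtosis(haar_details(epoch$samples))

#' Compute the full 31-feature vector for one epoch
#'
#' Deterministic; degenerate-input conventions guarantee 31 finite values
#' in the canonical [feature_manifest()] order.
#'
#' @param epoch An `eeg_epoch`.
#' @return Named numeric vector of length 31.
#' @export
extract_features <- function(epoch) {
  validate_epoch(epoch)
  spec <- periodogram(epoch)
  out <- c(
    amplitude_change_50ms = amplitude_change(epoch, 0.05),
    mean_local_skew_15ms = mean_local_skewness(epoch, 0.015),
    temporal_kurtosis = temporal_kurtosis(epoch),
    amplitude_variance = amplitude_variance(epoch),
    deriv_sum_50ms = derivative_sum(epoch, 0.05),
    deriv_sum_100ms = derivative_sum(epoch, 0.1),
    deriv_sum_200ms = derivative_sum(epoch, 0.2),
    deriv_sum_300ms = derivative_sum(epoch, 0.3),
    deriv_sum_500ms = derivative_sum(epoch, 0.5),
    power_below_0p5hz = power_below_0p5hz(spec))
  for (b in names(FEATURE_BANDS)) {
    fit <- spectral_fit(spec, FEATURE_BANDS[[b]])
    v <- c(band_power(spec, FEATURE_BANDS[[b]]), fit[["lambda"]],
           fit[["fit_error"]])
    names(v) <- paste(c("bandpower", "lambda", "fiterror"), b, sep = "_")
    out <- c(out, v)
  }
  out <- c(out,
           fd_kurtosis_higuchi = fd_kurtosis(epoch, "higuchi"),
           fd_kurtosis_katz = fd_kurtosis(epoch, "katz"),
           haar_kurtosis = haar_kurtosis(epoch))
  stopifnot(identical(names(out), FEATURE_MANIFEST))
  out
}

#' Feature table for a list of epochs
#'
#' @param epochs List of `eeg_epoch`.
#' @return data.frame, one row per epoch, 31 manifest-ordered columns.
#' @export
extract_feature_table <- function(epochs) {
  rows <- lapply(epochs, extract_features)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- FEATURE_MANIFEST
  df
}
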