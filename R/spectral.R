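#' Fourier oscillation statistics of a uniformly sampled series
#'
#' After mean removal, the DFT bin of maximal power (DC excluded) defines
#' the major period; amplitude is `2|X_k|/n`, the peak phase is the phase
#' angle at which the fitted cosine peaks (expressed on the respiratory
#' axis when a phase map is supplied, otherwise as `360 t_peak / period`),
#' and the signal-to-noise ratio is the power at the major bin over the
#' median power of the remaining non-DC bins. The reported period is the
#' raw bin value (no spectral interpolation), so a 67-min oscillation
#' sampled 33 times at 6 min reports the nearest bin, 66 min. The p-value
#' comes from a permutation test: the time order of the series is randomly
#' permuted and the maximal non-DC power is compared with the observed one.
#'
#' @param x numeric series (uniform sampling, length >= 8).
#' @param sampling_min sampling interval in minutes.
#' @param n_perm number of permutations (0 = skip, p is `NA`).
#' @param phase optional per-sample respiratory phases in degrees, used to
#'   express the peak phase on the respiratory axis.
#' @param seed optional seed for the permutations.
#' @return an `oscillation_stats` list: `major_period_min`, `amplitude`,
#'   `peak_phase_deg`, `snr`, `p_value`, `n`.
#' @export
fourier_stats <- function(x, sampling_min, n_perm = 1000, phase = NULL,
                          seed = NULL) {
  stopifnot(length(x) >= 8, all(is.finite(x)))
  n <- length(x)
  xm <- x - mean(x)
  if (diff(range(x)) == 0) {
    return(structure(list(major_period_min = NA_real_, amplitude = 0,
                          peak_phase_deg = NA_real_, snr = 0, p_value = 1,
                          n = n), class = "oscillation_stats"))
  }
  X <- fft(xm)
  kmax_bin <- floor(n / 2)
  pw <- Mod(X[2:(kmax_bin + 1)])^2
  k <- which.max(pw)
  period <- n * sampling_min / k
  amplitude <- 2 * Mod(X[k + 1]) / n
  # x(t) ~ A cos(2 pi k t / (n dt) + arg X_k); peak where the argument is 0
  t_peak <- ((-Arg(X[k + 1])) %% (2 * pi)) / (2 * pi) * period
  if (is.null(phase)) {
    peak_phase <- (360 * t_peak / period) %% 360
  } else {
    tt <- (seq_len(n) - 1) * sampling_min
    unw <- phase + 360 * c(0, cumsum(diff(phase) < 0))
    peak_phase <- approx(tt, unw, xout = t_peak, rule = 2)$y %% 360
  }
  snr <- if (length(pw) > 1) pw[k] / median(pw[-k]) else Inf

  p_value <- NA_real_
  if (n_perm > 0) {
    obs <- max(pw)
    p_value <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        Xp <- fft(xm[sample.int(n)])
        if (max(Mod(Xp[2:(kmax_bin + 1)])^2) >= obs) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(list(major_period_min = period, amplitude = amplitude,
                 peak_phase_deg = peak_phase, snr = snr, p_value = p_value,
                 n = n), class = "oscillation_stats")
}

#' @export
print.oscillation_stats <- function(x, ...) {
  cat(sprintf(
    "oscillation: period %.1f min, amplitude %.3g, peak %.0f deg, snr %.1f, p %s\n",
    x$major_period_min, x$amplitude, x$peak_phase_deg, x$snr,
    format(x$p_value)))
  invisible(x)
}

#' Fourier scan of a matrix of series
#'
#' Vectorised major-period/amplitude/SNR statistics for every row of a
#' matrix (e.g. all probes of an occupancy matrix); no permutation
#' p-values.
#'
#' @param mat rows = series, columns = timepoints.
#' @param sampling_min sampling interval in minutes.
#' @return data.frame `id`, `major_period_min`, `amplitude`, `snr`.
#' @export
fourier_scan <- function(mat, sampling_min) {
  n <- ncol(mat)
  stopifnot(n >= 8)
  xm <- mat - rowMeans(mat)
  X <- mvfft(t(xm))
  kmax_bin <- floor(n / 2)
  pw <- Mod(X[2:(kmax_bin + 1), , drop = FALSE])^2
  k <- max.col(t(pw), ties.method = "first")
  amp <- 2 * sqrt(pw[cbind(k, seq_len(ncol(pw)))]) / n
  snr <- vapply(seq_len(ncol(pw)), function(j) {
    others <- pw[-k[j], j]
    if (length(others)) pw[k[j], j] / median(others) else Inf
  }, numeric(1))
  data.frame(id = rownames(mat) %||% seq_len(nrow(mat)),
             major_period_min = n * sampling_min / k,
             amplitude = amp, snr = snr, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DFT band-pass filter around the respiratory frequency
#'
#' The series is transformed by DFT; bins with `|f| < f_osc` (including
#' DC) or `|f| > 4 f_osc` are zeroed, band edges inclusive, and the signal
#' is reconstructed by the inverse transform (real part). Applying the
#' filter twice gives the same result as applying it once.
#'
#' @param x numeric series, uniformly sampled.
#' @param f_osc respiratory (oscillation) frequency in Hz.
#' @param fs sampling frequency in Hz.
#' @param upper_mult upper band edge as a multiple of `f_osc` (default 4).
#' @return the filtered series.
#' @export
bandpass_filter <- function(x, f_osc, fs, upper_mult = 4) {
  stopifnot(f_osc > 0, fs > 0, upper_mult * f_osc <= fs / 2)
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n      # folded (two-sided) frequency axis
  tol <- 1e-9 * f_osc
  keep <- f >= f_osc - tol & f <= upper_mult * f_osc + tol
  X <- fft(x)
  X[!keep] <- 0 + 0i
  Re(fft(X, inverse = TRUE) / n)
}
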