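#' Smooth a dissolved-oxygen trace by a running mean
#'
#' Centred running mean whose window is specified as a frequency: a
#' `window_hz` of 0.01 corresponds to a 100 s window, i.e. 10 samples of a
#' 0.1 Hz trace. Edges use shrinking windows. For an even window length the
#' extra sample is taken on the left (documented convention).
#'
#' @param trace data.frame with `time_s` and `value`, uniformly sampled.
#' @param window_hz window as a frequency in Hz (window length =
#'   `1/window_hz` seconds).
#' @return the trace with smoothed `value`.
#' @export
smooth_do <- function(trace, window_hz = 0.01) {
  stopifnot(all(c("time_s", "value") %in% names(trace)))
  dt <- median(diff(trace$time_s))
  stopifnot(dt > 0)
  w <- max(1L, round(1 / (window_hz * dt)))
  n <- nrow(trace)
  if (n < w) stop("trace shorter than the smoothing window")
  lh <- ceiling((w - 1) / 2)   # left half (left-heavy for even w)
  rh <- w - 1 - lh
  cs <- c(0, cumsum(trace$value))
  i <- seq_len(n)
  lo <- pmax(i - lh, 1L)
  hi <- pmin(i + rh, n)
  trace$value <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  trace
}

#' First derivative of a trace
#'
#' Central differences; one-sided at the endpoints.
#'
#' @param trace data.frame with `time_s` and `value`.
#' @return data.frame `time_s`, `dvalue` (units of value per second).
#' @export
do_derivative <- function(trace) {
  t <- trace$time_s; x <- trace$value
  n <- length(x)
  stopifnot(n >= 3)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  data.frame(time_s = t, dvalue = d)
}

# local extrema with earliest-wins tie-break on plateaus
local_extrema <- function(x, maxima = FALSE) {
  if (maxima) x <- -x
  n <- length(x)
  left <- c(Inf, x[1:(n - 1)])
  right <- c(x[2:n], Inf)
  which(x < left & x <= right)
}

#' Detect respiratory anchors in the DO derivative
#'
#' One derivative minimum (oxidative onset) and one maximum (reductive
#' onset) per cycle. The expected period is estimated from the dominant
#' non-DC DFT bin of the derivative; candidate extrema closer together than
#' `refractory_frac` of that period are pruned, keeping the more extreme
#' one, and strict min/max alternation is enforced. A flat or
#' non-oscillatory derivative (Fisher-type spectral test) raises an error.
#'
#' @param deriv data.frame `time_s`, `dvalue` from [do_derivative()].
#' @param refractory_frac minimum anchor separation as a fraction of the
#'   estimated period (default 0.5).
#' @param p_max significance level of the dominant-oscillation test.
#' @param edge_s candidate extrema within `edge_s` seconds of the trace
#'   ends are ignored (smoothing and one-sided differences distort the
#'   edges; default 100 s, the DO smoothing window).
#' @return data.frame `time_s`, `kind` (`"min_deriv"` / `"max_deriv"`),
#'   ordered in time, alternating.
#' @export
find_anchors <- function(deriv, refractory_frac = 0.5, p_max = 1e-3,
                         edge_s = 100) {
  x <- deriv$dvalue
  t <- deriv$time_s
  n <- length(x)
  if (n < 8 || diff(range(x)) < .Machine$double.eps * 100 * max(1, max(abs(x)))) {
    stop("derivative is flat: no oscillation to anchor")
  }
  # dominant-frequency test: exponential-tail bound on the peak of a white
  # spectrum; rejects when no oscillation stands out
  X <- fft(x - mean(x))
  pw <- Mod(X[2:(floor(n / 2) + 1)])^2
  m <- length(pw)
  p_white <- m * exp(-max(pw) / mean(pw))
  if (!is.finite(p_white) || p_white > p_max) {
    stop("no dominant oscillation in the derivative (p = ",
         signif(p_white, 3), ")")
  }
  k <- which.max(pw)
  period_s <- n * median(diff(t)) / k
  refractory <- refractory_frac * period_s

  interior <- t >= t[1] + edge_s & t <= t[n] - edge_s

  pick <- function(idx, depth) {
    idx <- idx[interior[idx]]
    # greedy: most extreme first (earliest wins ties), enforce separation
    ord <- idx[order(depth[idx], t[idx])]
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) || all(abs(t[i] - t[chosen]) >= refractory)) {
        chosen <- c(chosen, i)
      }
    }
    sort(chosen)
  }
  mins <- pick(local_extrema(x), x)
  maxs <- pick(local_extrema(x, maxima = TRUE), -x)
  if (!length(mins) || !length(maxs)) stop("no alternating anchors found")

  anc <- rbind(data.frame(time_s = t[mins], kind = "min_deriv",
                          depth = -x[mins]),
               data.frame(time_s = t[maxs], kind = "max_deriv",
                          depth = x[maxs]))
  anc <- anc[order(anc$time_s), ]
  # enforce alternation: among same-kind runs keep the most extreme
  keep <- rep(TRUE, nrow(anc))
  i <- 1
  while (i < nrow(anc)) {
    j <- i + 1
    while (j <= nrow(anc) && anc$kind[j] == anc$kind[i]) j <- j + 1
    run <- i:(j - 1)
    if (length(run) > 1) {
      best <- run[which.max(anc$depth[run])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j
  }
  anc <- anc[keep, c("time_s", "kind")]
  rownames(anc) <- NULL
  anc
}

#' Assign respiratory phase angles to sample times
#'
#' Within each cycle, time is mapped piecewise-linearly: derivative-minimum
#' anchors to 0 degrees, derivative-maximum anchors to `oxidative_deg`
#' (default 94), and the reductive segment from `oxidative_deg` back to 360
#' at the next minimum. Samples outside the anchored span get `NA` phase
#' and are counted in a warning (they are excluded from cycle averaging
#' downstream, not extrapolated).
#'
#' @param sample_times_s sample times in seconds.
#' @param anchors anchor table from [find_anchors()].
#' @param oxidative_deg phase angle of the reductive onset (default 94).
#' @return a `phase_map` data.frame: `time_s`, `phase_deg`, `cycle`
#'   (1-based index of the enclosing cycle), with the anchors attached as
#'   attribute `anchors`.
#' @export
assign_phase <- function(sample_times_s, anchors, oxidative_deg = 94) {
  stopifnot(nrow(anchors) >= 2, oxidative_deg > 0, oxidative_deg < 360)
  kinds <- anchors$kind
  if (any(kinds[-1] == kinds[-length(kinds)])) {
    stop("anchors must alternate in kind")
  }
  at <- anchors$time_s
  phase <- rep(NA_real_, length(sample_times_s))
  cycle <- rep(NA_integer_, length(sample_times_s))
  mins <- which(kinds == "min_deriv")

  for (s in seq_along(sample_times_s)) {
    tt <- sample_times_s[s]
    seg <- findInterval(tt, at)
    if (seg < 1 || seg >= nrow(anchors) && tt > at[nrow(anchors)]) {
      if (tt == at[nrow(anchors)]) seg <- nrow(anchors) - 1 else next
    }
    if (seg == nrow(anchors)) seg <- seg - 1  # exactly at last anchor
    t0 <- at[seg]; t1 <- at[seg + 1]
    frac <- (tt - t0) / (t1 - t0)
    if (kinds[seg] == "min_deriv") {
      phase[s] <- oxidative_deg * frac
      cycle[s] <- match(seg, mins)
    } else {
      phase[s] <- oxidative_deg + (360 - oxidative_deg) * frac
      prev_min <- mins[mins < seg]
      cycle[s] <- if (length(prev_min)) match(max(prev_min), mins) else NA
    }
    if (!is.na(phase[s]) && phase[s] >= 360) phase[s] <- phase[s] %% 360
  }
  n_out <- sum(is.na(phase))
  if (n_out > 0) {
    warning(n_out, " samples fall outside the anchored span; phase set NA")
  }
  structure(data.frame(time_s = sample_times_s, phase_deg = phase,
                       cycle = cycle),
            anchors = anchors,
            class = c("phase_map", "data.frame"))
}

#' Full DO-to-phase pipeline
#'
#' Smooths the DO trace, differentiates it, detects anchors and assigns
#' phases to the requested sample times.
#'
#' @param do_trace data.frame `time_s`, `value`.
#' @param sample_times_s times to phase (defaults to the DO time base).
#' @inheritParams assign_phase
#' @inheritParams smooth_do
#' @return a `phase_map` (see [assign_phase()]).
#' @export
phase_from_do <- function(do_trace, sample_times_s = do_trace$time_s,
                          oxidative_deg = 94, window_hz = 0.01) {
  sm <- smooth_do(do_trace, window_hz = window_hz)
  dv <- do_derivative(sm)
  anc <- find_anchors(dv)
  assign_phase(sample_times_s, anc, oxidative_deg = oxidative_deg)
}
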