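# shared internal helpers

.datatable.aware <- TRUE

# Evaluate `code` with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Circular (von Mises shaped) bump: 1 at mu_deg, decaying with angular
# distance; kappa is the concentration parameter.
vm_bump <- function(phase_deg, mu_deg, kappa) {
  exp(kappa * (cos((phase_deg - mu_deg) * pi / 180) - 1))
}

# Sum of bumps at several peak phases.
vm_wave <- function(phase_deg, peaks_deg, kappa) {
  out <- 0
  for (mu in peaks_deg) out <- out + vm_bump(phase_deg, mu, kappa)
  out
}

# Midpoint of the forward arc from a to b, in degrees on [0, 360).
circular_midpoint <- function(a, b) {
  (a + ((b - a) %% 360) / 2) %% 360
}

# Row variances of a matrix, NA-tolerant.
row_vars <- function(x) {
  n <- rowSums(is.finite(x))
  mu <- rowMeans(x, na.rm = TRUE)
  out <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
  out[n < 2] <- NA_real_
  out
}

#' Locate the peaks of a cyclic profile
#'
#' Finds local maxima of a profile defined on the circular phase grid
#' (each point compared with its two circular neighbours) and returns the
#' phases of the `n_peaks` highest ones, sorted by phase.
#'
#' @param value numeric profile values on the phase grid.
#' @param phase_deg phase grid in degrees, same length as `value`.
#' @param n_peaks how many peaks to report (default: all local maxima).
#' @return numeric vector of peak phases in degrees, sorted increasing.
#' @export
profile_peaks <- function(value, phase_deg, n_peaks = NULL) {
  stopifnot(length(value) == length(phase_deg), length(value) >= 3)
  n <- length(value)
  up <- value[c(2:n, 1)]
  dn <- value[c(n, 1:(n - 1))]
  is_peak <- value > dn & value >= up
  peaks <- data.frame(phase = phase_deg[is_peak], height = value[is_peak])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  if (!is.null(n_peaks)) peaks <- utils::head(peaks, n_peaks)
  sort(peaks$phase)
}

# smallest circular distance between two angles in degrees
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
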