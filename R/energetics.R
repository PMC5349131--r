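#' Chromatin-remodeler activity under competitive product inhibition
#'
#' Relative velocity `v / Vmax = ATP / (Km (1 + ADP/Ki) + ATP)` of an
#' ATP-consuming remodeler whose product ADP competes for the nucleotide
#' site. Defaults are the in vitro constants for ISWI: Michaelis constant
#' 0.15 mM for ATP and inhibition constant 0.1 mM for ADP. Vectorised over
#' concentrations.
#'
#' @param atp,adp concentrations in mM (non-negative).
#' @param km ATP Michaelis constant in mM (default 0.15).
#' @param ki ADP inhibition constant in mM (default 0.1).
#' @return relative activity in `[0, 1)`.
#' @export
remodeling_activity <- function(atp, adp, km = 0.15, ki = 0.1) {
  stopifnot(km > 0, ki > 0, all(atp >= 0), all(adp >= 0))
  atp / (km * (1 + adp / ki) + atp)
}

#' Adenylate energy charge
#'
#' `EC = (ATP + ADP/2) / (ATP + ADP + AMP)`, the standard 0-1 index of the
#' adenylate energy state.
#'
#' @param atp,adp,amp concentrations (same units), not all zero.
#' @return energy charge in `[0, 1]`.
#' @export
energy_charge <- function(atp, adp, amp) {
  total <- atp + adp + amp
  if (any(total <= 0)) stop("adenylate pool must be positive")
  (atp + adp / 2) / total
}

#' Correlate two cycle profiles with a cyclic-shift permutation p-value
#'
#' Pearson correlation over the common phase grid. Because cycle profiles
#' are strongly autocorrelated, the null distribution is built by cyclic
#' rotation of one profile over all grid offsets; the two-sided p-value is
#' the fraction of offsets (including zero) whose absolute correlation
#' reaches the observed one.
#'
#' @param x,y numeric profiles on the same phase grid (or `cycle_profile`
#'   data.frames).
#' @return list `r`, `p_value`, `n`.
#' @export
phase_correlation <- function(x, y) {
  if (inherits(x, "cycle_profile")) x <- x$value
  if (inherits(y, "cycle_profile")) y <- y$value
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant profile; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  n <- length(x)
  r_lag <- vapply(0:(n - 1), function(l) {
    cor(x, y[((seq_len(n) - 1 + l) %% n) + 1])
  }, numeric(1))
  r <- r_lag[1]
  p <- mean(abs(r_lag) >= abs(r) - 1e-12)
  list(r = r, p_value = p, n = n)
}

#' Normalize a qPCR/ChIP signal to a reference series
#'
#' Per matched timepoint, `log2(signal / reference)`; timepoints with a
#' nonpositive reference (or signal) are flagged missing with a warning.
#'
#' @param signal,reference numeric series of equal length.
#' @return log2 ratio series, `NA` where undefined.
#' @export
normalize_to_reference <- function(signal, reference) {
  stopifnot(length(signal) == length(reference))
  bad <- !(reference > 0 & signal > 0)
  out <- rep(NA_real_, length(signal))
  out[!bad] <- log2(signal[!bad] / reference[!bad])
  if (any(bad)) {
    warning(sum(bad), " timepoints with nonpositive values flagged missing")
  }
  out
}

#' Energy-state and remodeler-activity cycle profiles
#'
#' Convenience wrapper turning a metabolite series plus phases into
#' average-cycle profiles of ATP, ATP:ADP, energy charge and inferred
#' remodeling activity.
#'
#' @param metabolites data.frame with `ATP`, `ADP`, `AMP` columns.
#' @param phases per-sample phase angles (degrees).
#' @param km,ki kinetic constants (mM), see [remodeling_activity()].
#' @param df spline degrees of freedom per cycle (see [fit_cycle()]).
#' @return named list of `cycle_profile`s: `atp`, `atp_adp`, `ec`,
#'   `activity`.
#' @export
energetics_profiles <- function(metabolites, phases, km = 0.15, ki = 0.1,
                                df = NULL) {
  act <- remodeling_activity(metabolites$ATP, metabolites$ADP, km, ki)
  ec <- energy_charge(metabolites$ATP, metabolites$ADP, metabolites$AMP)
  list(atp = fit_cycle(metabolites$ATP, phases, df = df),
       atp_adp = fit_cycle(metabolites$ATP / metabolites$ADP, phases,
                           df = df),
       ec = fit_cycle(ec, phases, df = df),
       activity = fit_cycle(act, phases, df = df))
}
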