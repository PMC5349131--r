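#' Fit an average-cycle profile by spline smoothing over phase angles
#'
#' All (phase, value) observations, pooled across cycles, are fitted with a
#' cubic smoothing spline and evaluated on the regular phase grid
#' (24 points every 15 degrees by default). Approximate periodicity is
#' enforced by replicating the data at -360 and +360 degrees before
#' fitting; the requested `df` counts degrees of freedom per cycle and is
#' tripled internally to keep the per-cycle flexibility of the replicated
#' fit unchanged.
#'
#' The conventional `df` is the number of samples per respiratory cycle
#' (e.g. `round(67 / 6) = 11` for 6-min sampling of a 67-min cycle).
#'
#' @param values numeric observations.
#' @param phases phase angles in degrees (same length; NA pairs dropped).
#' @param df degrees of freedom per cycle; default: a third of the number
#'   of observations (three-cycle datasets).
#' @param grid_step grid spacing in degrees (default 15).
#' @return a `cycle_profile` data.frame: `phase_deg`, `value`; attribute
#'   `df`.
#' @export
fit_cycle <- function(values, phases, df = NULL, grid_step = 15) {
  ok <- is.finite(values) & is.finite(phases)
  x <- phases[ok] %% 360
  y <- values[ok]
  if (is.null(df)) df <- max(4, round(length(y) / 3))
  if (df > length(y)) {
    stop("df (", df, ") exceeds the number of observations (", length(y), ")")
  }
  if (length(y) < 4) stop("need at least 4 observations")
  grid <- seq(0, 360 - grid_step, by = grid_step)

  if (diff(range(y)) == 0) {  # constant input: constant profile
    out <- data.frame(phase_deg = grid, value = rep(y[1], length(grid)))
    attr(out, "df") <- df
    class(out) <- c("cycle_profile", "data.frame")
    return(out)
  }
  xx <- c(x - 360, x, x + 360)
  yy <- rep(y, 3)
  df_ext <- min(3 * df, length(unique(xx)) - 1)
  fit <- smooth.spline(xx, yy, df = df_ext, cv = FALSE)
  out <- data.frame(phase_deg = grid,
                    value = predict(fit, grid)$y)
  attr(out, "df") <- df
  class(out) <- c("cycle_profile", "data.frame")
  out
}

#' Rate of change on the phase grid
#'
#' Differences between consecutive samples in time order are assigned the
#' circular midpoint of the two sample phases, spline-smoothed like any
#' other cycle variable, and rescaled to units of change per 15 degrees of
#' phase (multiplying by 15 over the mean inter-sample phase step), the
#' axis convention used for the summed-transcript rate profiles.
#'
#' @param values observations in time order.
#' @param phases per-sample phase angles in degrees, same order.
#' @inheritParams fit_cycle
#' @return a `cycle_profile` of the per-15-degree rate.
#' @export
rate_of_change <- function(values, phases, df = NULL, grid_step = 15) {
  ok <- is.finite(values) & is.finite(phases)
  v <- values[ok]; p <- phases[ok]
  if (length(v) < 3) stop("need at least 3 samples")
  d <- diff(v)
  mid <- circular_midpoint(p[-length(p)], p[-1])
  step <- diff(p) %% 360
  step[step == 0] <- NA
  mean_step <- mean(step, na.rm = TRUE)
  prof <- fit_cycle(d, mid, df = df, grid_step = grid_step)
  prof$value <- prof$value * (15 / mean_step)
  prof
}

#' Sum transcript abundances per cluster and supercluster
#'
#' Row-sums the expression matrix by cluster label and appends the anabolic
#' (A, AB, B, B.C, B.D, ab.n) and catabolic (C, D, cd.n, cd.ab)
#' supercluster sums. Labelled genes absent from the matrix are ignored;
#' clusters with no expressed genes yield a zero series with a warning.
#'
#' @param expr genes x timepoints abundance matrix with gene rownames.
#' @param labels data.frame `gene_id`, `cluster`.
#' @param anabolic,catabolic cluster names making up each supercluster.
#' @return clusters (+ superclusters) x timepoints matrix.
#' @export
sum_clusters <- function(expr, labels,
                         anabolic = c("A", "AB", "B", "B.C", "B.D", "ab.n"),
                         catabolic = c("C", "D", "cd.n", "cd.ab")) {
  stopifnot(all(c("gene_id", "cluster") %in% names(labels)))
  cl_names <- unique(labels$cluster)
  out <- matrix(0, nrow = length(cl_names), ncol = ncol(expr),
                dimnames = list(cl_names, colnames(expr)))
  for (cl in cl_names) {
    genes <- intersect(labels$gene_id[labels$cluster == cl], rownames(expr))
    if (!length(genes)) {
      warning("cluster ", cl, " has no expressed genes; zero series")
      next
    }
    out[cl, ] <- colSums(expr[genes, , drop = FALSE])
  }
  super <- rbind(
    anabolic = colSums(out[intersect(anabolic, cl_names), , drop = FALSE]),
    catabolic = colSums(out[intersect(catabolic, cl_names), , drop = FALSE]))
  rbind(out, super)
}

#' Remove the temporal average from cycle profiles
#'
#' Each series (row) loses its own mean over the phase grid; the removed
#' means are reported separately (the "side bar" of the cluster occupancy
#' figures), so input = delta + mean reconstructs exactly.
#'
#' @param profiles numeric matrix, one series per row, columns = phase
#'   grid; a plain vector is treated as one series.
#' @return list with `delta` (same shape, zero row means) and `means`.
#' @export
subtract_temporal_mean <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  mns <- rowMeans(profiles, na.rm = TRUE)
  list(delta = profiles - mns, means = mns)
}
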