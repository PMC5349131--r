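#' Select the least-variant probe set
#'
#' Probes whose log2-intensity variance across arrays is below `threshold`
#' in *both* the protein-bound (pDNA) and genomic (gDNA) channels form the
#' least-variant set (LVS) used to anchor between-array normalization.
#'
#' @param pdna,gdna probe tables sharing probe ids.
#' @param threshold variance cutoff on the log2 scale (default 0.1).
#' @return character vector of selected probe ids.
#' @export
select_least_variant <- function(pdna, gdna, threshold = 0.1) {
  stopifnot(threshold > 0)
  shared <- intersect(pdna$probe_id, gdna$probe_id)
  if (!length(shared)) stop("no shared probes between channels")
  vp <- row_vars(log2_matrix(pdna)[shared, , drop = FALSE])
  vg <- row_vars(log2_matrix(gdna)[shared, , drop = FALSE])
  keep <- !is.na(vp) & !is.na(vg) & vp < threshold & vg < threshold
  if (!any(keep)) {
    stop("least-variant set is empty at threshold ", threshold,
         "; increase the threshold")
  }
  shared[keep]
}

#' Array-level offsets on the least-variant set
#'
#' Per array, the mean log2 deviation from the across-array mean reference,
#' computed over the LVS probes. The variance of these offsets across
#' arrays is the inter-array variance that LOESS normalization removes;
#' compare before/after to quantify normalization efficacy.
#'
#' @param pt a probe table.
#' @param lvs probe ids of the least-variant set.
#' @return numeric vector of per-array offsets (log2).
#' @export
array_offsets <- function(pt, lvs) {
  l2 <- log2_matrix(pt)
  rows <- pt$probe_id %in% lvs
  ref <- rowMeans(l2, na.rm = TRUE)
  colMeans(l2[rows, , drop = FALSE] - ref[rows], na.rm = TRUE)
}

#' LOESS-normalize one channel against the across-array mean
#'
#' For each array, the deviation of its log2 intensities from the
#' across-array mean log2 intensity (the reference) is modelled by a locally
#' weighted regression fitted on the least-variant probes only, evaluated at
#' every probe, and subtracted. The correction curve is re-centred so that
#' the LVS probes have zero mean residual after normalization. Channels are
#' normalized independently of each other.
#'
#' For speed the local regression is fitted on at most `max_fit` LVS probes
#' (an even subsample along the reference axis) and evaluated through a
#' dense interpolation grid; probes outside the LVS reference range receive
#' the boundary correction.
#'
#' @param pt a probe table.
#' @param lvs probe ids of the least-variant set (from
#'   [select_least_variant()]).
#' @param span LOESS span (default 0.3).
#' @param max_fit maximum number of LVS probes used in each fit.
#' @param grid_n interpolation grid size.
#' @return the probe table with normalized intensities.
#' @export
loess_normalize <- function(pt, lvs, span = 0.3, max_fit = 3000,
                            grid_n = 256) {
  l2 <- log2_matrix(pt)
  lvs_idx <- which(pt$probe_id %in% lvs)
  if (length(lvs_idx) < 10) {
    stop("fewer least-variant probes (", length(lvs_idx),
         ") than the smoother's minimum window")
  }
  ref <- rowMeans(l2, na.rm = TRUE)
  for (j in seq_len(ncol(l2))) {
    d <- l2[, j] - ref
    fit_idx <- lvs_idx[is.finite(d[lvs_idx]) & is.finite(ref[lvs_idx])]
    if (length(fit_idx) < 10) stop("too few finite LVS probes in array ", j)
    if (length(fit_idx) > max_fit) {
      ord <- fit_idx[order(ref[fit_idx])]
      fit_idx <- ord[round(seq(1, length(ord), length.out = max_fit))]
    }
    fit_df <- data.frame(x = ref[fit_idx], y = d[fit_idx])
    lo <- loess(y ~ x, data = fit_df, span = span, degree = 1,
                control = loess.control(surface = "direct"))
    grid <- seq(min(fit_df$x), max(fit_df$x), length.out = grid_n)
    corr <- approx(grid, predict(lo, data.frame(x = grid)),
                   xout = ref, rule = 2)$y
    # zero mean residual on the LVS after correction
    corr <- corr + mean(d[fit_idx] - corr[fit_idx])
    l2[, j] <- l2[, j] - corr
  }
  set_log2(pt, l2)
}

#' Average paired forward/reverse strand probes
#'
#' Probes sharing identical (chrom, start, end) on opposite strands are
#' collapsed to a single probe whose log2 intensities are the pair average
#' (geometric mean of intensities). Unpaired probes are kept as-is and
#' counted in a warning. Averaged probes are re-identified by their
#' coordinates (`chrom:start-end`) with strand `"*"`.
#'
#' @param pt a probe table.
#' @return a probe table with one probe per paired position.
#' @export
average_strand_pairs <- function(pt) {
  key <- paste(pt$chrom, pt$start, pt$end, sep = ":")
  arr <- array_names(pt)
  l2 <- log2_matrix(pt)

  dt <- data.table::data.table(i = seq_len(nrow(pt)), pos_key = key,
                               strand = pt$strand)
  grp <- dt[, list(n = .N,
                   paired = .N == 2L && all(c("+", "-") %in% strand),
                   i1 = i[1L], i2 = i[.N]), by = "pos_key"]
  pg <- grp[grp$paired == TRUE, ]

  paired_rows <- NULL
  if (nrow(pg)) {
    avg <- (l2[pg$i1, , drop = FALSE] + l2[pg$i2, , drop = FALSE]) / 2
    meta <- pt[pg$i1, PT_META]
    meta$probe_id <- paste0(meta$chrom, ":", meta$start, "-", meta$end)
    meta$strand <- "*"
    paired_rows <- cbind(meta, as.data.frame(2^avg))
  }
  unpaired <- setdiff(seq_len(nrow(pt)), c(pg$i1, pg$i2))
  if (length(unpaired)) {
    warning(length(unpaired), " probes had no strand pair; kept as-is")
  }
  out <- rbind(paired_rows,
               if (length(unpaired)) pt[unpaired, c(PT_META, arr)])
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("probe_table", "data.frame")
  out
}

#' Estimate the MNase digestion bias
#'
#' Per probe, the bias is the mean log2 intensity over the MNase-digested
#' naked-DNA control arrays (mDNA) minus the mean log2 intensity over the
#' undigested genomic arrays (gDNA). Probes missing from either table are
#' excluded with a warning.
#'
#' @param mdna,gdna probe tables (typically normalized and strand-averaged).
#' @return an `mnase_bias` data.frame: `probe_id`, `chrom`, `start`, `end`,
#'   `bias` (log2).
#' @export
compute_mnase_bias <- function(mdna, gdna) {
  shared <- intersect(mdna$probe_id, gdna$probe_id)
  dropped <- length(union(mdna$probe_id, gdna$probe_id)) - length(shared)
  if (dropped > 0) {
    warning(dropped, " probes missing from one channel; excluded from bias")
  }
  if (!length(shared)) stop("no shared probes between mDNA and gDNA")
  m <- rowMeans(log2_matrix(mdna)[shared, , drop = FALSE], na.rm = TRUE)
  g <- rowMeans(log2_matrix(gdna)[shared, , drop = FALSE], na.rm = TRUE)
  out <- mdna[match(shared, mdna$probe_id), c("probe_id", "chrom", "start",
                                              "end")]
  out$bias <- unname(m - g)
  rownames(out) <- NULL
  class(out) <- c("mnase_bias", "data.frame")
  out
}

#' Compute the DNA occupancy matrix
#'
#' `occ(p, t) = log2(pDNA) - log2(gDNA) - bias(p)` per probe and timepoint.
#' Arrays of the two channels are matched by column order (one pair per
#' timepoint). Nonpositive intensities yield missing occupancy at that
#' probe/timepoint.
#'
#' @param pdna,gdna normalized, strand-averaged probe tables with matched
#'   arrays.
#' @param bias an `mnase_bias` from [compute_mnase_bias()].
#' @param time_min optional sampling times; by default parsed from
#'   `T<minutes>` array names.
#' @return an `occupancy_matrix`: list with `occ` (probes x timepoints),
#'   `probes` (metadata) and `time_min`.
#' @export
compute_occupancy <- function(pdna, gdna, bias, time_min = NULL) {
  if (length(array_names(pdna)) != length(array_names(gdna))) {
    stop("pDNA and gDNA must have the same number of arrays")
  }
  shared <- Reduce(intersect, list(pdna$probe_id, gdna$probe_id,
                                   bias$probe_id))
  if (!length(shared)) stop("no probes shared by pDNA, gDNA and bias")
  lp <- log2_matrix(pdna)[shared, , drop = FALSE]
  lg <- log2_matrix(gdna)[shared, , drop = FALSE]
  b <- bias$bias[match(shared, bias$probe_id)]
  occ <- lp - lg - b
  if (is.null(time_min)) time_min <- array_times(pdna)
  structure(list(occ = occ,
                 probes = pdna[match(shared, pdna$probe_id),
                               PT_META, drop = FALSE],
                 time_min = time_min),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix: %d probes x %d timepoints (mean %.3f, sd %.3f)\n",
              nrow(x$occ), ncol(x$occ), mean(x$occ, na.rm = TRUE),
              sd(x$occ, na.rm = TRUE)))
  invisible(x)
}

#' One-call channel normalization
#'
#' Runs the full normalization chain: LVS selection on pDNA/gDNA, LOESS
#' normalization of all three channels, strand-pair averaging, bias
#' estimation and occupancy computation.
#'
#' @inheritParams compute_occupancy
#' @param mdna MNase-control probe table.
#' @param lvs_threshold LVS variance cutoff.
#' @param span LOESS span.
#' @return list with `occupancy` (an `occupancy_matrix`), `bias`, `lvs`
#'   (selected probe ids) and the normalized channels.
#' @export
normalize_channels <- function(pdna, gdna, mdna, lvs_threshold = 0.1,
                               span = 0.3) {
  lvs <- select_least_variant(pdna, gdna, lvs_threshold)
  pn <- loess_normalize(pdna, lvs, span = span)
  gn <- loess_normalize(gdna, lvs, span = span)
  mn <- loess_normalize(mdna, lvs, span = span)
  pa <- average_strand_pairs(pn)
  ga <- average_strand_pairs(gn)
  ma <- average_strand_pairs(mn)
  bias <- compute_mnase_bias(ma, ga)
  occ <- compute_occupancy(pa, ga, bias)
  list(occupancy = occ, bias = bias, lvs = lvs,
       pdna = pa, gdna = ga, mdna = ma)
}
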