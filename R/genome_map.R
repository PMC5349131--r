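#' Index probes by TSS-relative position
#'
#' For every gene, probes whose midpoint lies within `half_window` bp of
#' the TSS are indexed by signed, strand-aware relative position (upstream
#' negative, downstream positive).
#'
#' @param probes probe metadata (`probe_id`, `chrom`, `start`, `end`).
#' @param annotations gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param half_window window half-width in bp (default 1000).
#' @return data.frame `gene_id`, `probe_id`, `rel_pos`.
#' @export
map_probes_to_tss <- function(probes, annotations, half_window = 1000) {
  mids <- (probes$start + probes$end) %/% 2
  pg <- GenomicRanges::GRanges(probes$chrom, IRanges::IRanges(mids, mids))
  tg <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(pmax(1, annotations$tss - half_window),
                     annotations$tss + half_window))
  hits <- GenomicRanges::findOverlaps(pg, tg, ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  rel <- ifelse(annotations$strand[gi] == "+",
                mids[pi] - annotations$tss[gi],
                annotations$tss[gi] - mids[pi])
  data.frame(gene_id = annotations$gene_id[gi],
             probe_id = probes$probe_id[pi],
             rel_pos = rel, stringsAsFactors = FALSE)
}

# long-format (group, rel_bin, time, value) -> per-group median matrix.
# Probes sharing a (gene|dyad, bin) are averaged within the alignment unit
# first; the median is then taken across units, never across probes.
median_profile_dt <- function(dt, n_time) {
  unit_mean <- dt[, list(value = mean(value, na.rm = TRUE)),
                  by = c("unit", "rel_bin", "time_idx")]
  med <- unit_mean[, list(value = median(value, na.rm = TRUE)),
                   by = c("rel_bin", "time_idx")]
  bins <- sort(unique(med$rel_bin))
  m <- matrix(NA_real_, length(bins), n_time,
              dimnames = list(bins, NULL))
  m[cbind(match(med$rel_bin, bins), med$time_idx)] <- med$value
  m
}

#' Median TSS-aligned occupancy profile
#'
#' Per TSS-relative position bin and timepoint, the median occupancy over
#' genes. Probes of one gene falling in the same bin are averaged within
#' the gene first, so the median is over genes, not probes. An optional
#' display floor (`cap`) is applied only at this summary stage.
#'
#' @param occm an `occupancy_matrix`.
#' @param tss_index output of [map_probes_to_tss()].
#' @param bin bin width in bp (default: the probe spacing inferred from the
#'   probe starts).
#' @param cap optional lower display cap (e.g. -1); `NULL` = none.
#' @return a `position_profile` list: `profile` (position x timepoint
#'   median matrix, rownames = bin centres), `n_genes` (genes with at
#'   least one mapped probe), `time_min`.
#' @export
median_tss_profile <- function(occm, tss_index, bin = NULL, cap = NULL) {
  stopifnot(inherits(occm, "occupancy_matrix"))
  if (is.null(bin)) {
    bin <- median(diff(sort(unique(occm$probes$start))))
  }
  idx <- tss_index[tss_index$probe_id %in% rownames(occm$occ), ]
  rows <- match(idx$probe_id, rownames(occm$occ))
  nt <- ncol(occm$occ)
  dt <- data.table::data.table(
    unit = rep(idx$gene_id, nt),
    rel_bin = rep(round(idx$rel_pos / bin) * bin, nt),
    time_idx = rep(seq_len(nt), each = nrow(idx)),
    value = as.vector(occm$occ[rows, , drop = FALSE]))
  prof <- median_profile_dt(dt, nt)
  if (!is.null(cap)) prof <- pmax(prof, cap)
  structure(list(profile = prof,
                 n_genes = length(unique(idx$gene_id)),
                 time_min = occm$time_min),
            class = "position_profile")
}

#' Classify nucleosome dyads by ordinal position relative to the TSS
#'
#' Each dyad is assigned to the gene with the nearest TSS among genes for
#' which the dyad lies within `upstream_cutoff` bp upstream of the TSS or
#' inside the transcript; ties go to the + strand gene. Within each gene,
#' dyads at or downstream of the TSS-covering register (strand-aware
#' relative position >= `-tss_cover`) receive ordinals +1, +2, ... in
#' transcription direction; dyads further upstream receive -1, -2, ...
#' counting away from the TSS. Classes: the +1 dyad is `TSS`
#' (TSS-covering), the last genic dyad `terminal`, ordinals +2 to the
#' penultimate `GB`, and negative ordinals `upstream`. A gene whose only
#' genic dyad is the +1 keeps class `TSS`. Genes with no genic dyad are
#' excluded with a message. The TSS analysis group used for the
#' NDR-flanking profiles is {upstream, TSS, terminal}.
#'
#' @param dyads data.frame `chrom`, `pos` (dyad centre, 1-based bp).
#' @param annotations gene table (`gene_id`, `chrom`, `tss`, `strand`,
#'   `transcript_end`).
#' @param upstream_cutoff maximal upstream distance for dyad-gene
#'   assignment (bp).
#' @param tss_cover half-width of the TSS-covering test, half the wrapped
#'   DNA length (73 bp).
#' @return a `dyad_classification` data.frame: `chrom`, `pos`, `gene_id`,
#'   `rel_pos`, `ordinal`, `class`.
#' @export
classify_dyads <- function(dyads, annotations, upstream_cutoff = 1000,
                           tss_cover = 73) {
  ann <- annotations
  glen <- abs(ann$transcript_end - ann$tss) + 1L
  lo <- ifelse(ann$strand == "+", ann$tss - upstream_cutoff,
               pmin(ann$tss, ann$transcript_end))
  hi <- ifelse(ann$strand == "+", pmax(ann$tss, ann$transcript_end),
               ann$tss + upstream_cutoff)
  dg <- GenomicRanges::GRanges(dyads$chrom,
                               IRanges::IRanges(dyads$pos, dyads$pos))
  gg <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(pmax(1, lo), hi))
  hits <- GenomicRanges::findOverlaps(dg, gg, ignore.strand = TRUE)
  di <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  rel <- ifelse(ann$strand[gi] == "+",
                dyads$pos[di] - ann$tss[gi],
                ann$tss[gi] - dyads$pos[di])
  cand <- data.frame(di = di, gi = gi, rel = rel,
                     strand = ann$strand[gi],
                     dist = abs(rel))
  # keep candidates in the allowed strand-aware span
  cand <- cand[cand$rel >= -upstream_cutoff & cand$rel <= glen[cand$gi] - 1L, ]
  # nearest TSS wins; ties to the + strand gene
  cand <- cand[order(cand$di, cand$dist, cand$strand != "+"), ]
  cand <- cand[!duplicated(cand$di), ]

  out <- do.call(rbind, lapply(split(cand, cand$gi), function(cc) {
    genic <- cc[cc$rel >= -tss_cover, ]
    ups <- cc[cc$rel < -tss_cover, ]
    if (!nrow(genic)) return(NULL)
    genic <- genic[order(genic$rel), ]
    k <- nrow(genic)
    cls <- rep("GB", k)
    cls[1] <- "TSS"
    if (k >= 2) cls[k] <- "terminal"
    res <- data.frame(di = genic$di, gi = genic$gi, rel = genic$rel,
                      ordinal = seq_len(k), class = cls)
    if (nrow(ups)) {
      ups <- ups[order(-ups$rel), ]  # closest to TSS first
      res <- rbind(res, data.frame(di = ups$di, gi = ups$gi, rel = ups$rel,
                                   ordinal = -seq_len(nrow(ups)),
                                   class = "upstream"))
    }
    res
  }))
  skipped <- setdiff(unique(cand$gi), unique(out$gi))
  if (length(skipped)) {
    message(length(skipped), " genes had no genic dyad; excluded")
  }
  res <- data.frame(chrom = dyads$chrom[out$di], pos = dyads$pos[out$di],
                    gene_id = ann$gene_id[out$gi], rel_pos = out$rel,
                    ordinal = out$ordinal, class = out$class,
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene_id, res$ordinal), ]
  rownames(res) <- NULL
  class(res) <- c("dyad_classification", "data.frame")
  res
}

# probes around each classified dyad, strand-aware relative positions
dyad_probe_index <- function(occm, classification, annotations, half_window) {
  probes <- occm$probes
  mids <- (probes$start + probes$end) %/% 2
  pg <- GenomicRanges::GRanges(probes$chrom, IRanges::IRanges(mids, mids))
  dgr <- GenomicRanges::GRanges(
    classification$chrom,
    IRanges::IRanges(pmax(1, classification$pos - half_window),
                     classification$pos + half_window))
  hits <- GenomicRanges::findOverlaps(pg, dgr, ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(hits)
  di <- S4Vectors::subjectHits(hits)
  strand <- annotations$strand[match(classification$gene_id,
                                     annotations$gene_id)]
  rel <- ifelse(strand[di] == "+",
                mids[pi] - classification$pos[di],
                classification$pos[di] - mids[pi])
  data.frame(dyad_idx = di, probe_row = pi, rel_pos = rel,
             class = classification$class[di],
             gene_id = classification$gene_id[di])
}

#' Dyad-aligned median occupancy profiles per nucleosome class
#'
#' Probes are re-indexed relative to each classified dyad (strand-aware)
#' and the median over dyads is taken per class, position bin and
#' timepoint. Additionally a per-class central temporal profile is
#' computed from probes within the dyad core (`+/- center_halfwidth` bp).
#'
#' @param occm an `occupancy_matrix`.
#' @param classification a [classify_dyads()] result.
#' @param annotations gene table (for strands).
#' @param half_window alignment half-window in bp (default 500).
#' @param bin position bin width (default: probe spacing).
#' @param center_halfwidth half-width of the dyad core (default 73 bp).
#' @param classes classes to profile.
#' @return list with `profiles` (named list of position x timepoint median
#'   matrices), `central` (class x timepoint matrix), `n_dyads` (per
#'   class), `time_min`.
#' @export
dyad_aligned_profile <- function(occm, classification, annotations,
                                 half_window = 500, bin = NULL,
                                 center_halfwidth = 73,
                                 classes = c("upstream", "TSS", "GB",
                                             "terminal")) {
  stopifnot(inherits(occm, "occupancy_matrix"))
  if (is.null(bin)) bin <- median(diff(sort(unique(occm$probes$start))))
  idx <- dyad_probe_index(occm, classification, annotations, half_window)
  nt <- ncol(occm$occ)

  profiles <- list(); central <- list(); n_dyads <- integer(0)
  for (cl in classes) {
    sub <- idx[idx$class == cl, ]
    n_dyads[cl] <- length(unique(sub$dyad_idx))
    if (!nrow(sub)) {
      warning("no dyads of class ", cl)
      profiles[[cl]] <- NULL
      next
    }
    dt <- data.table::data.table(
      unit = rep(sub$dyad_idx, nt),
      rel_bin = rep(round(sub$rel_pos / bin) * bin, nt),
      time_idx = rep(seq_len(nt), each = nrow(sub)),
      value = as.vector(occm$occ[sub$probe_row, , drop = FALSE]))
    profiles[[cl]] <- median_profile_dt(dt, nt)

    core <- sub[abs(sub$rel_pos) <= center_halfwidth, ]
    if (nrow(core)) {
      cm <- data.table::data.table(
        unit = rep(core$dyad_idx, nt), rel_bin = 0,
        time_idx = rep(seq_len(nt), each = nrow(core)),
        value = as.vector(occm$occ[core$probe_row, , drop = FALSE]))
      central[[cl]] <- median_profile_dt(cm, nt)[1, ]
    }
  }
  central_m <- do.call(rbind, central)
  list(profiles = profiles, central = central_m, n_dyads = n_dyads,
       time_min = occm$time_min)
}

#' Per-cluster dyad-aligned occupancy profiles
#'
#' As [dyad_aligned_profile()], but dyads are grouped by their gene's
#' expression cluster. For each cluster the position x timepoint median
#' matrix is returned together with its temporal-mean-subtracted version
#' (the delta-occupancy of the cluster figures) and the removed means (the
#' side bar). Differential clusters can be merged (by default B.C and B.D
#' into the expanded cluster B).
#'
#' @inheritParams dyad_aligned_profile
#' @param annotations gene table carrying a `cluster` column.
#' @param merge named character vector mapping cluster labels onto merged
#'   labels.
#' @param classes dyad classes to include (default: all genic).
#' @return list per cluster: `profile`, `delta`, `means`, `central`,
#'   `n_dyads`.
#' @export
cluster_profiles <- function(occm, classification, annotations,
                             half_window = 500, bin = NULL,
                             center_halfwidth = 73,
                             merge = c(B.C = "B", B.D = "B"),
                             classes = c("upstream", "TSS", "GB",
                                         "terminal")) {
  stopifnot("cluster" %in% names(annotations))
  if (is.null(bin)) bin <- median(diff(sort(unique(occm$probes$start))))
  idx <- dyad_probe_index(occm, classification, annotations, half_window)
  idx <- idx[idx$class %in% classes, ]
  cl_of_gene <- annotations$cluster[match(idx$gene_id,
                                          annotations$gene_id)]
  hit <- match(cl_of_gene, names(merge))
  cl_of_gene[!is.na(hit)] <- merge[hit[!is.na(hit)]]
  nt <- ncol(occm$occ)

  out <- list()
  for (cl in sort(unique(stats::na.omit(cl_of_gene)))) {
    sub <- idx[cl_of_gene == cl & !is.na(cl_of_gene), ]
    if (!nrow(sub)) {
      warning("cluster ", cl, " has no aligned dyads; omitted")
      next
    }
    dt <- data.table::data.table(
      unit = rep(sub$dyad_idx, nt),
      rel_bin = rep(round(sub$rel_pos / bin) * bin, nt),
      time_idx = rep(seq_len(nt), each = nrow(sub)),
      value = as.vector(occm$occ[sub$probe_row, , drop = FALSE]))
    prof <- median_profile_dt(dt, nt)
    dm <- subtract_temporal_mean(prof)
    core <- sub[abs(sub$rel_pos) <= center_halfwidth, ]
    central <- if (nrow(core)) {
      cm <- data.table::data.table(
        unit = rep(core$dyad_idx, nt), rel_bin = 0,
        time_idx = rep(seq_len(nt), each = nrow(core)),
        value = as.vector(occm$occ[core$probe_row, , drop = FALSE]))
      median_profile_dt(cm, nt)[1, ]
    } else NULL
    out[[cl]] <- list(profile = prof, delta = dm$delta, means = dm$means,
                      central = central,
                      n_dyads = length(unique(sub$dyad_idx)))
  }
  out
}
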