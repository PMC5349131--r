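# Readers/writers for the standard interchange formats. Annotations travel
# as GFF3 and dyads as BED (via rtracklayer); traces are two-column CSV;
# everything tabular is TSV.

#' Write / read gene annotations as GFF3
#'
#' One `gene` feature per gene; the TSS is the strand-aware 5' end of the
#' feature. The expression cluster (if present) is stored in the `cluster`
#' attribute.
#'
#' @param annotations data.frame `gene_id`, `chrom`, `tss`, `strand`,
#'   `transcript_end`, optional `cluster`.
#' @param path file path (`.gff3`).
#' @export
write_annotations_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(pmin(annotations$tss, annotations$transcript_end),
                     pmax(annotations$tss, annotations$transcript_end)),
    strand = annotations$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotations$gene_id
  S4Vectors::mcols(gr)$Name <- annotations$gene_id
  if (!is.null(annotations$cluster)) {
    S4Vectors::mcols(gr)$cluster <- annotations$cluster
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotations_gff3
#' @return `read_annotations_gff3()` returns the annotation data.frame.
#' @export
read_annotations_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  out <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr)),
    strand = strand,
    transcript_end = ifelse(strand == "+", GenomicRanges::end(gr),
                            GenomicRanges::start(gr)),
    stringsAsFactors = FALSE)
  cl <- S4Vectors::mcols(gr)$cluster
  if (!is.null(cl)) out$cluster <- as.character(cl)
  out
}

#' Write / read nucleosome dyad positions as BED
#'
#' One single-bp interval per dyad centre (BED half-open coordinates are
#' handled by the exporter); the associated gene, when known, is stored in
#' the BED name column.
#'
#' @param dyads data.frame `chrom`, `pos`, optional `gene_id`.
#' @param path file path (`.bed`).
#' @export
write_dyads_bed <- function(dyads, path) {
  gr <- GenomicRanges::GRanges(dyads$chrom,
                               IRanges::IRanges(dyads$pos, dyads$pos))
  if (!is.null(dyads$gene_id)) S4Vectors::mcols(gr)$name <- dyads$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_dyads_bed
#' @return `read_dyads_bed()` returns the dyad data.frame.
#' @export
read_dyads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    pos = GenomicRanges::start(gr),
                    stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$gene_id <- as.character(nm)
  out
}

#' Write / read a two-column trace as CSV
#'
#' @param trace data.frame whose first column is time and second the value.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cycle profile (or several) as TSV
#'
#' @param profiles a `cycle_profile`, or a named list of them sharing a
#'   grid (written as one wide table: `phase_deg` + one column each).
#' @param path file path.
#' @export
write_cycle_profiles <- function(profiles, path) {
  if (inherits(profiles, "cycle_profile")) profiles <- list(value = profiles)
  out <- data.frame(phase_deg = profiles[[1]]$phase_deg)
  for (nm in names(profiles)) out[[nm]] <- profiles[[nm]]$value
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a position x timepoint profile matrix in long format
#'
#' Columns: `group`, `rel_pos`, `time_idx`, `median_occ`.
#'
#' @param mats named list of position x timepoint matrices (rownames =
#'   relative positions).
#' @param path file path.
#' @export
write_position_profiles <- function(mats, path) {
  long <- do.call(rbind, lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    data.frame(group = nm,
               rel_pos = rep(as.integer(rownames(m)), ncol(m)),
               time_idx = rep(seq_len(ncol(m)), each = nrow(m)),
               median_occ = as.vector(m))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a phase map as TSV
#' @param phase_map a `phase_map` from [assign_phase()].
#' @param path file path.
#' @export
write_phase_map <- function(phase_map, path) {
  utils::write.table(as.data.frame(phase_map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_map
#' @export
read_phase_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a cluster membership table as TSV
#' @param labels data.frame `gene_id`, `cluster`.
#' @param path file path.
#' @export
write_cluster_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_labels
#' @export
read_cluster_labels <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as TSV (genes x timepoints)
#' @param expr numeric matrix with gene rownames.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(expr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  m
}
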