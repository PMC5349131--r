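#' Probe tables
#'
#' A probe table is a plain `data.frame` holding the probe design of one
#' channel (pDNA, gDNA or mDNA) together with one positive intensity column
#' per hybridised array. The first five columns are fixed:
#' `probe_id`, `chrom`, `start`, `end` (1-based inclusive) and `strand`
#' (`"+"`, `"-"`, or `"*"` after strand-pair averaging); every remaining
#' column is an array. Time-course arrays are conventionally named
#' `T<minutes>` (e.g. `T0`, `T6`, ...) so that sampling times round-trip
#' through TSV files; replicate arrays (mDNA) are named `R1`, `R2`, ...
#'
#' @param probes data.frame with `probe_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param intensities numeric matrix, rows matching `probes`, one column per
#'   array (column names become array names).
#' @return a `probe_table` data.frame.
#' @export
probe_table <- function(probes, intensities) {
  stopifnot(nrow(probes) == nrow(intensities))
  need <- c("probe_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(probes))) {
    stop("probe metadata must contain: ", paste(need, collapse = ", "))
  }
  if (any(probes$start > probes$end)) stop("probe start must be <= end")
  out <- cbind(probes[need], as.data.frame(intensities))
  class(out) <- c("probe_table", "data.frame")
  out
}

PT_META <- c("probe_id", "chrom", "start", "end", "strand")

#' Array (intensity) column names of a probe table
#' @param pt a probe table.
#' @return character vector of array names.
#' @export
array_names <- function(pt) setdiff(names(pt), PT_META)

#' Intensity matrix of a probe table
#' @inheritParams array_names
#' @return numeric matrix probes x arrays, rownames = `probe_id`.
#' @export
intensity_matrix <- function(pt) {
  m <- as.matrix(pt[array_names(pt)])
  rownames(m) <- pt$probe_id
  m
}

# log2 intensities; nonpositive intensities are treated as missing rather
# than clipped, so no log ratio is fabricated for them.
log2_matrix <- function(pt) {
  m <- intensity_matrix(pt)
  m[m <= 0] <- NA_real_
  log2(m)
}

# replace the intensity columns from a (log2) matrix
set_log2 <- function(pt, l2) {
  stopifnot(nrow(l2) == nrow(pt))
  pt[colnames(l2)] <- as.data.frame(2^l2)
  pt
}

# parse sampling times (minutes) from T<min> array names; NA where not parseable
array_times <- function(pt) {
  nm <- array_names(pt)
  tm <- suppressWarnings(as.numeric(sub("^T", "", nm)))
  tm[!grepl("^T[0-9]+(\\.[0-9]+)?$", nm)] <- NA_real_
  tm
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes x %d arrays (%s)\n",
              nrow(x), length(array_names(x)),
              paste(utils::head(array_names(x), 4), collapse = ", ")))
  invisible(x)
}

#' Read / write probe tables as TSV
#'
#' Plain tab-separated text with the five metadata columns followed by one
#' column per array.
#'
#' @param path file path.
#' @return `read_probe_table()` returns a `probe_table`.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probe_table(df[PT_META], as.matrix(df[setdiff(names(df), PT_META)]))
}

#' @param pt a probe table.
#' @rdname read_probe_table
#' @export
write_probe_table <- function(pt, path) {
  utils::write.table(pt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a probe table from per-array two-column files
#'
#' Reads NimbleScan-style ".pair" exports: each file holds `probe_id` and
#' one intensity column for a single array. A design table maps files to
#' array names; probe coordinates come from a separate design probe table.
#'
#' @param files character vector of file paths (tab-separated, two columns:
#'   probe_id, intensity; a header line is expected).
#' @param array_ids array names, one per file (e.g. `T0`, `T6`, ...).
#' @param probe_design data.frame with `probe_id`, `chrom`, `start`, `end`,
#'   `strand` describing the array layout.
#' @return a `probe_table` with one intensity column per file.
#' @export
read_pair_files <- function(files, array_ids, probe_design) {
  stopifnot(length(files) == length(array_ids))
  cols <- lapply(files, function(f) {
    d <- utils::read.delim(f, stringsAsFactors = FALSE)
    stats::setNames(d[[2]], d[[1]])
  })
  ids <- probe_design$probe_id
  m <- vapply(cols, function(v) unname(v[ids]), numeric(length(ids)))
  colnames(m) <- array_ids
  probe_table(probe_design, m)
}
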