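#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run with its conventional
#' default: LVS variance threshold 0.1, LOESS span 0.3, reductive anchor at
#' 94 degrees, 15-degree phase grid, and the ISWI kinetic constants
#' Km = 0.15 mM / Ki = 0.1 mM.
#'
#' Inputs come either from a simulation config (`sim`) or from files
#' (`inputs`): probe tables (TSV) for the three channels, gene annotations
#' (GFF3), dyads (BED), cluster labels (TSV), a DO trace (CSV),
#' metabolites (CSV), transcripts (TSV) and an optional NAD(P)H trace
#' (CSV).
#'
#' @param sim a [synth_config()], or `NULL` when reading real inputs.
#' @param inputs named list of file paths (`pdna`, `gdna`, `mdna`,
#'   `annotations`, `dyads`, `clusters`, `do`, `metabolites`,
#'   `transcripts`, `nadph`); unused when simulating.
#' @param lvs_threshold,loess_span normalization parameters.
#' @param oxidative_deg reductive-onset anchor angle (degrees).
#' @param grid_step_deg phase-grid spacing (degrees).
#' @param km,ki remodeler kinetic constants (mM).
#' @param tss_half_window,dyad_half_window alignment windows (bp).
#' @param period_min,sampling_min oscillation period and sampling interval
#'   (minutes), used for the spline df rule and Fourier statistics; taken
#'   from `sim` when simulating.
#' @param seed seed for any stochastic step (permutations).
#' @return a `run_config` list.
#' @export
run_config <- function(sim = synth_config(), inputs = NULL,
                       lvs_threshold = 0.1, loess_span = 0.3,
                       oxidative_deg = 94, grid_step_deg = 15,
                       km = 0.15, ki = 0.1,
                       tss_half_window = 1000, dyad_half_window = 500,
                       period_min = if (!is.null(sim)) sim$period_min else 67,
                       sampling_min = if (!is.null(sim)) sim$sampling_min else 6,
                       seed = if (!is.null(sim)) sim$seed else 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim) && is.null(cfg$inputs)) {
    stop("either a simulation config or input paths are required")
  }
  class(cfg) <- "run_config"
  cfg
}

read_inputs <- function(paths) {
  need <- c("pdna", "gdna", "mdna", "annotations", "dyads", "do",
            "metabolites", "transcripts")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop("missing inputs: ", paste(missing, collapse = ", "))
  }
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      stop("input file for '", nm, "' not found: ", paths[[nm]])
    }
  }
  ann <- read_annotations_gff3(paths$annotations)
  if (!is.null(paths$clusters)) {
    lab <- read_cluster_labels(paths$clusters)
    ann$cluster <- lab$cluster[match(ann$gene_id, lab$gene_id)]
  }
  list(pdna = read_probe_table(paths$pdna),
       gdna = read_probe_table(paths$gdna),
       mdna = read_probe_table(paths$mdna),
       annotations = ann,
       dyads = read_dyads_bed(paths$dyads),
       do = read_trace_csv(paths$do),
       metabolites = read_trace_csv(paths$metabolites),
       transcripts = read_expression_tsv(paths$transcripts),
       nadph = if (!is.null(paths$nadph)) read_trace_csv(paths$nadph))
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the inputs, normalize the channels, derive phases
#' from dissolved oxygen, build TSS- and dyad-aligned median profiles and
#' cluster dynamics, scan the occupancy matrix for its major Fourier
#' period, band-pass the NAD(P)H trace, and compute energy-state and
#' remodeler-activity profiles. When `outdir` is given, stage outputs are
#' written as TSV/CSV together with a JSON manifest recording the package
#' version, parameters, seeds and md5 checksums of every file.
#'
#' @param config a [run_config()].
#' @param outdir output directory (`NULL` = nothing written).
#' @return a `pipeline_result` list with elements `norm`, `phase_map`,
#'   `tss_profile`, `classification`, `dyad_profiles`, `cluster_prof`,
#'   `cluster_sums`, `mrna_rate`, `spectra`, `nadph_filtered`,
#'   `energetics`, `correlations`, and (when simulating) `truth`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$sim)) {
    ds <- stage("simulate", simulate_dataset(config$sim))
    pdna <- ds$series$pdna; gdna <- ds$series$gdna; mdna <- ds$series$mdna
    ann <- ds$genome$annotations
    dyads <- ds$genome$dyads[c("chrom", "pos", "gene_id")]
    do_trace <- ds$do
    metabolites <- ds$metabolites
    transcripts <- ds$transcripts
    nadph <- ds$nadph
    truth <- ds$series$truth
  } else {
    inp <- stage("read-inputs", read_inputs(config$inputs))
    pdna <- inp$pdna; gdna <- inp$gdna; mdna <- inp$mdna
    ann <- inp$annotations; dyads <- inp$dyads
    do_trace <- inp$do; metabolites <- inp$metabolites
    transcripts <- inp$transcripts; nadph <- inp$nadph
    truth <- NULL
  }
  labels <- if (!is.null(ann$cluster)) ann[c("gene_id", "cluster")]

  norm <- stage("normalize",
                normalize_channels(pdna, gdna, mdna,
                                   lvs_threshold = config$lvs_threshold,
                                   span = config$loess_span))
  occm <- norm$occupancy

  names(do_trace)[1:2] <- c("time_s", "value")
  pm <- stage("phase", phase_from_do(
    do_trace, sample_times_s = occm$time_min * 60,
    oxidative_deg = config$oxidative_deg))
  df_cycle <- round(config$period_min / config$sampling_min)

  tss_idx <- stage("profiles", map_probes_to_tss(
    occm$probes, ann, half_window = config$tss_half_window))
  tss_prof <- median_tss_profile(occm, tss_idx)
  classification <- stage("profiles", classify_dyads(dyads, ann))
  dyad_prof <- stage("profiles", dyad_aligned_profile(
    occm, classification, ann, half_window = config$dyad_half_window))
  cluster_prof <- if (!is.null(labels)) {
    stage("profiles", cluster_profiles(
      occm, classification, ann, half_window = config$dyad_half_window))
  }

  cluster_sums <- if (!is.null(labels)) {
    stage("cycle", sum_clusters(transcripts, labels))
  }
  mrna_rate <- if (!is.null(cluster_sums)) {
    lapply(c(anabolic = "anabolic", catabolic = "catabolic"), function(sc) {
      rate_of_change(cluster_sums[sc, ], pm$phase_deg, df = df_cycle)
    })
  }

  spectra <- stage("spectra", fourier_scan(occm$occ,
                                           config$sampling_min))
  nadph_filtered <- if (!is.null(nadph)) {
    names(nadph)[1:2] <- c("time_s", "value")
    fs <- 1 / median(diff(nadph$time_s))
    stage("spectra", bandpass_filter(nadph$value,
                                     f_osc = 1 / (config$period_min * 60),
                                     fs = fs))
  }

  en <- stage("energetics", energetics_profiles(
    metabolites,
    phases = metabolite_phases(metabolites, pm, config$oxidative_deg),
    km = config$km, ki = config$ki, df = df_cycle))
  correlations <- if (!is.null(mrna_rate)) {
    atp_prof <- en$atp
    list(atp_vs_anabolic_rate = phase_correlation(atp_prof,
                                                  mrna_rate$anabolic),
         atp_vs_catabolic_rate = phase_correlation(atp_prof,
                                                   mrna_rate$catabolic))
  }

  res <- structure(list(
    norm = norm, phase_map = pm, tss_profile = tss_prof,
    classification = classification, dyad_profiles = dyad_prof,
    cluster_prof = cluster_prof, cluster_sums = cluster_sums,
    mrna_rate = mrna_rate, spectra = spectra,
    nadph_filtered = nadph_filtered, energetics = en,
    correlations = correlations, truth = truth, config = config),
    class = "pipeline_result")

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

# phase the metabolite sampling times through the same DO anchors
metabolite_phases <- function(metabolites, pm, oxidative_deg) {
  tmin <- metabolites$time_min %||% metabolites[[1]]
  assign_phase(tmin * 60, attr(pm, "anchors"),
               oxidative_deg = oxidative_deg)$phase_deg
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_probe_table(res$norm$pdna, fp("pdna_normalized.tsv"))
  write_probe_table(res$norm$gdna, fp("gdna_normalized.tsv"))
  utils::write.table(res$norm$bias, fp("mnase_bias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  occ_df <- data.frame(probe_id = rownames(res$norm$occupancy$occ),
                       res$norm$occupancy$occ, check.names = FALSE)
  utils::write.table(occ_df, fp("occupancy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_phase_map(res$phase_map, fp("phase_map.tsv"))
  write_position_profiles(list(TSS_aligned = res$tss_profile$profile),
                          fp("tss_profile.tsv"))
  write_position_profiles(res$dyad_profiles$profiles,
                          fp("dyad_profiles.tsv"))
  utils::write.table(res$classification, fp("dyad_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$spectra, fp("fourier_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_cycle_profiles(res$energetics, fp("energetics_profiles.tsv"))
  if (!is.null(res$mrna_rate)) {
    write_cycle_profiles(res$mrna_rate, fp("mrna_rate.tsv"))
  }

  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package = "occycle",
    version = as.character(utils::packageVersion("occycle")),
    r_version = R.version.string,
    seed = res$config$seed,
    parameters = res$config[c("lvs_threshold", "loess_span",
                              "oxidative_deg", "grid_step_deg", "km", "ki",
                              "tss_half_window", "dyad_half_window",
                              "period_min", "sampling_min")],
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("occycle pipeline result\n")
  print(x$norm$occupancy)
  cat(sprintf("  phased samples: %d (%d NA)\n", nrow(x$phase_map),
              sum(is.na(x$phase_map$phase_deg))))
  cat(sprintf("  TSS profile: %d genes\n", x$tss_profile$n_genes))
  invisible(x)
}
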