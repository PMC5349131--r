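#' Configuration for the synthetic respiratory-oscillation dataset
#'
#' Collects every knob of the synthetic-data generator. The defaults encode
#' the study conditions the analysis was designed for: a 67-min respiratory
#' oscillation sampled every 6 min over three cycles (33 arrays), an
#' oxidative phase spanning 94 of 360 degrees, gene-body occupancy peaks at
#' 60 and 225 degrees, TSS/NDR-flanking peaks at 75, 225 and 330 degrees,
#' NDR occupancy minima at 45 and 240 degrees, bulk ATP oscillating between
#' 21 and 51 mM with the peak in oxidative phase, ATP:ADP traversing
#' 1.2-8 and energy charge 0.65-0.9, and a 10 Hz NAD(P)H fluorescence trace
#' carrying the oscillation fundamental plus harmonics 2-4, an out-of-band
#' slow drift and high-frequency noise.
#'
#' @param n_genes number of genes (laid alternately on + and - strands along
#'   one synthetic chromosome).
#' @param gene_length_mean,gene_length_sd gene length distribution (bp).
#' @param intergenic_gap gap between neighbouring gene bodies (bp).
#' @param probe_spacing tiling step of the array (bp); the 360K whole-genome
#'   design implies roughly one probe pair every 32 bp.
#' @param probe_length probe length (bp).
#' @param nuc_spacing nucleosome repeat length (bp, dyad-to-dyad).
#' @param ndr_center NDR centre relative to the TSS (bp, negative =
#'   upstream).
#' @param first_dyad position of the +1 dyad relative to the TSS (bp).
#' @param n_cycles,period_min,sampling_min number of respiratory cycles,
#'   oscillation period and array sampling interval (minutes).
#' @param oxidative_deg phase angle assigned to the oxidative-to-reductive
#'   transition (degrees; the reductive anchor).
#' @param class_phases named list of occupancy peak phases (degrees) per
#'   nucleosome class (`GB`, `TSS`) plus the `NDR` minima.
#' @param class_amplitudes named log2 amplitudes per class; the negative NDR
#'   amplitude turns its bumps into occupancy minima.
#' @param kappa concentration of the circular (von Mises shaped) peaks.
#' @param noise_sd log2-scale s.d. of multiplicative intensity noise.
#' @param bias_amplitude MNase bias is drawn uniformly from
#'   `[-bias_amplitude, bias_amplitude]` (log2).
#' @param scale_sd log2-scale s.d. of per-array multiplicative scale factors
#'   (0 = none; turn on to exercise LVS/LOESS normalization).
#' @param mdna_replicates number of MNase-control (mDNA) arrays.
#' @param do_baseline,do_amplitude,do_noise_sd,do_kappa dissolved-oxygen
#'   trace: baseline and amplitude (percent air saturation), additive noise
#'   s.d., and sharpness of the phase transitions.
#' @param atp_range,atp_adp_range,ec_range metabolite ranges: ATP (mM),
#'   ATP:ADP ratio, adenylate energy charge.
#' @param atp_peak_deg phase of the ATP maximum (degrees, oxidative phase).
#' @param met_amplitude scales all metabolite oscillation amplitudes
#'   (1 = configured ranges, 0 = constant).
#' @param cluster_phases named peak phases (degrees) for the transcript
#'   clusters; A/AB/B are anabolic (oxidative), C/D catabolic (reductive).
#' @param bump_deg,bump_amplitude the shared transient transcript increase
#'   near 225 degrees seen across all clusters.
#' @param transcript_amplitude,transcript_noise_sd log2 amplitude of the
#'   cluster oscillation and lognormal noise s.d.
#' @param nadph_harmonics amplitudes of the oscillation fundamental and its
#'   harmonics 2-4 in the NAD(P)H trace.
#' @param nadph_drift_amplitude,nadph_noise_amplitude amplitude of the
#'   below-band drift component and of the above-band (> 4x fundamental)
#'   noise.
#' @param seed integer seed controlling every random draw.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 60,
                         gene_length_mean = 1000, gene_length_sd = 200,
                         intergenic_gap = 600,
                         probe_spacing = 32, probe_length = 50,
                         nuc_spacing = 165, ndr_center = -75, first_dyad = 75,
                         n_cycles = 3, period_min = 67, sampling_min = 6,
                         oxidative_deg = 94,
                         class_phases = list(GB = c(60, 225),
                                             TSS = c(75, 225, 330),
                                             NDR = c(45, 240)),
                         class_amplitudes = c(GB = 1, TSS = 1, NDR = -1),
                         kappa = 8,
                         noise_sd = 0.2,
                         bias_amplitude = 0.5,
                         scale_sd = 0,
                         mdna_replicates = 3,
                         do_baseline = 40, do_amplitude = 30,
                         do_noise_sd = 0, do_kappa = 12,
                         atp_range = c(21, 51),
                         atp_adp_range = c(1.2, 8),
                         ec_range = c(0.65, 0.9),
                         atp_peak_deg = 60,
                         met_amplitude = 1,
                         cluster_phases = c(A = 30, AB = 45, B = 60,
                                            C = 200, D = 250),
                         bump_deg = 225, bump_amplitude = 0.3,
                         transcript_amplitude = 1, transcript_noise_sd = 0,
                         nadph_harmonics = c(1, 0.4, 0.2, 0.1),
                         nadph_drift_amplitude = 0.5,
                         nadph_noise_amplitude = 0.3,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$period_min > 0, cfg$sampling_min > 0,
            cfg$probe_spacing >= 1, cfg$n_cycles >= 1,
            cfg$oxidative_deg > 0, cfg$oxidative_deg < 360,
            cfg$noise_sd >= 0, cfg$bias_amplitude >= 0, cfg$kappa > 0,
            all(names(cfg$class_amplitudes) %in% names(cfg$class_phases)))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "synth_config"
  cfg
}

# number of array samples over the configured span (33 for 3 x 67 min at 6 min)
n_samples <- function(config) {
  floor(config$n_cycles * config$period_min / config$sampling_min)
}

sample_times_min <- function(config) {
  (seq_len(n_samples(config)) - 1) * config$sampling_min
}

# true respiratory phase of an arbitrary time (minutes); the synthetic DO
# waveform is built so that its derivative anchors sit exactly at phase 0
# and oxidative_deg, making the phase-time map linear.
true_phase <- function(config, time_min) {
  (360 * time_min / config$period_min) %% 360
}

#' Generate the synthetic genome: genes, nucleosome dyads and probe layout
#'
#' Genes alternate between the + and - strand along one chromosome. Each
#' gene gets a nucleosomal dyad array starting at the +1 dyad
#' (`first_dyad` bp downstream of the TSS) with fixed `nuc_spacing`, running
#' to the gene end, plus one -1 dyad upstream of the NDR. A gene too short
#' to hold the +1 register (length below `first_dyad`) receives a single +1
#' dyad at its midpoint (degenerate case). Probes tile both strands at
#' `probe_spacing`, with a paired forward/reverse probe at every position.
#'
#' @param config a [synth_config()].
#' @return a `synth_genome` list with `annotations` (gene_id, chrom, tss,
#'   strand, transcript_end, length, cluster), `dyads` (chrom, pos, gene_id,
#'   ordinal, class), `probes` (probe design data.frame) and `chrom_length`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    lens <- pmax(200L, round(rnorm(n, config$gene_length_mean,
                                   config$gene_length_sd)))
    strands <- rep(c("+", "-"), length.out = n)
    clusters <- rep(c("A", "AB", "B", "C", "D"), length.out = n)

    gstart <- integer(n); gend <- integer(n)
    cursor <- config$intergenic_gap
    for (i in seq_len(n)) {
      gstart[i] <- cursor + 1L
      gend[i] <- gstart[i] + lens[i] - 1L
      cursor <- gend[i] + config$intergenic_gap
    }
    chrom_length <- cursor
    tss <- ifelse(strands == "+", gstart, gend)
    tes <- ifelse(strands == "+", gend, gstart)

    ann <- data.frame(
      gene_id = sprintf("G%03d", seq_len(n)), chrom = "chrS",
      tss = as.integer(tss), strand = strands,
      transcript_end = as.integer(tes), length = as.integer(lens),
      cluster = clusters, stringsAsFactors = FALSE)

    dyads <- do.call(rbind, lapply(seq_len(n), function(i) {
      L <- lens[i]
      k <- floor((L - config$first_dyad) / config$nuc_spacing) + 1
      rel <- if (k >= 1) {
        config$first_dyad + config$nuc_spacing * (seq_len(k) - 1)
      } else {
        floor(L / 2)  # degenerate: single +1 dyad
      }
      cls <- rep("GB", length(rel))
      cls[1] <- "TSS"
      if (length(rel) >= 2) cls[length(rel)] <- "terminal"
      rel <- c(config$ndr_center - config$nuc_spacing, rel)
      cls <- c("upstream", cls)
      ords <- c(-1L, seq_len(length(rel) - 1L))
      pos <- if (strands[i] == "+") tss[i] + rel else tss[i] - rel
      data.frame(chrom = "chrS", pos = as.integer(pos),
                 gene_id = ann$gene_id[i], ordinal = ords, class = cls,
                 stringsAsFactors = FALSE)
    }))

    pos <- seq(1L, chrom_length, by = config$probe_spacing)
    probes <- data.frame(
      probe_id = sprintf("P%07d_%s", rep(pos, each = 2), c("f", "r")),
      chrom = "chrS",
      start = rep(pos, each = 2),
      end = pmin(rep(pos, each = 2) + config$probe_length - 1L, chrom_length),
      strand = rep(c("+", "-"), times = length(pos)),
      stringsAsFactors = FALSE)

    structure(list(annotations = ann, dyads = dyads, probes = probes,
                   chrom_length = chrom_length, config = config),
              class = "synth_genome")
  })
}

# spatial occupancy baseline and dynamic class per probe midpoint
probe_landscape <- function(config, genome) {
  mids <- (genome$probes$start + genome$probes$end) / 2
  dy <- sort(genome$dyads$pos)
  dy_class <- genome$dyads$class[order(genome$dyads$pos)]
  idx <- findInterval(mids, dy)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(dy))
  d_lo <- abs(mids - dy[lo]); d_hi <- abs(mids - dy[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  d_dyad <- pmin(d_lo, d_hi)
  near_class <- dy_class[nearest]

  ann <- genome$annotations
  ndr <- sort(ifelse(ann$strand == "+", ann$tss + config$ndr_center,
                     ann$tss - config$ndr_center))
  idx <- findInterval(mids, ndr)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(ndr))
  d_ndr <- pmin(abs(mids - ndr[lo]), abs(mids - ndr[hi]))

  baseline <- -0.3 + 0.8 * exp(-(d_dyad / 50)^2) - 1.2 * exp(-(d_ndr / 55)^2)

  cls <- rep("background", length(mids))
  cls[d_ndr <= 75] <- "NDR"
  at_dyad <- d_dyad <= 73 & d_ndr > 75
  cls[at_dyad & near_class[seq_along(cls)] %in%
        c("upstream", "TSS", "terminal")] <- "TSS"
  cls[at_dyad & near_class == "GB"] <- "GB"

  list(baseline = baseline, class = cls)
}

#' Generate the occupancy time series and the three intensity channels
#'
#' True occupancy per probe is a spatial baseline (elevated at dyads,
#' depressed in the NDR) plus class-specific circular peaks at the
#' configured phases. The channels follow the generative model
#' `log2 gDNA = g0 + noise`, `log2 mDNA = g0 + bias + noise`,
#' `log2 pDNA = g0 + bias + occupancy + noise`, with optional per-array
#' scale factors (`scale_sd`) injected on every channel to exercise
#' normalization. At zero noise and zero scale factors,
#' `log2(pDNA) - log2(gDNA) - bias` recovers the truth exactly.
#'
#' @param config a [synth_config()].
#' @param genome output of [generate_genome()].
#' @return a `synth_series` list: probe tables `pdna`, `gdna`, `mdna`, and
#'   `truth` (occupancy matrix probes x timepoints, per-probe `bias`,
#'   per-sample `phase` and `time_min`, per-probe `class`).
#' @export
generate_occupancy_series <- function(config, genome) {
  stopifnot(inherits(genome, "synth_genome"))
  nt <- n_samples(config)
  if (nt < 1) stop("configuration yields zero timepoints")
  tmin <- sample_times_min(config)
  phase <- true_phase(config, tmin)
  land <- probe_landscape(config, genome)
  np <- nrow(genome$probes)

  shape <- matrix(0, nrow = np, ncol = nt)
  for (cl in names(config$class_phases)) {
    amp <- config$class_amplitudes[[cl]]
    if (is.null(amp) || amp == 0) next
    rows <- land$class == cl
    if (!any(rows)) next
    w <- amp * vm_wave(phase, config$class_phases[[cl]], config$kappa)
    shape[rows, ] <- matrix(w, nrow = sum(rows), ncol = nt, byrow = TRUE)
  }
  occ <- land$baseline + shape
  rownames(occ) <- genome$probes$probe_id
  tnames <- sprintf("T%d", round(tmin))
  colnames(occ) <- tnames

  with_seed(config$seed + 1L, {
    # paired probes at the same position interrogate the same locus: share
    # base intensity and MNase bias
    pos_fac <- match(genome$probes$start, unique(genome$probes$start))
    npos <- max(pos_fac)
    g0 <- (10 + rnorm(npos, 0, 0.8))[pos_fac]
    bias <- runif(npos, -config$bias_amplitude, config$bias_amplitude)[pos_fac]

    nzm <- function(nc) matrix(rnorm(np * nc, 0, config$noise_sd), np, nc)
    # always consume the draws so that runs differing only in scale_sd
    # share every other random component
    scl <- function(nc) rnorm(nc) * config$scale_sd
    sc_p <- scl(nt); sc_g <- scl(nt); sc_m <- scl(config$mdna_replicates)

    l2_p <- g0 + bias + occ + nzm(nt) +
      matrix(sc_p, np, nt, byrow = TRUE)
    l2_g <- g0 + matrix(0, np, nt) + nzm(nt) +
      matrix(sc_g, np, nt, byrow = TRUE)
    l2_m <- g0 + bias + nzm(config$mdna_replicates) +
      matrix(sc_m, np, config$mdna_replicates, byrow = TRUE)
    colnames(l2_p) <- colnames(l2_g) <- tnames
    colnames(l2_m) <- sprintf("R%d", seq_len(config$mdna_replicates))

    structure(list(
      pdna = probe_table(genome$probes, 2^l2_p),
      gdna = probe_table(genome$probes, 2^l2_g),
      mdna = probe_table(genome$probes, 2^l2_m),
      truth = list(occupancy = occ, bias = bias, phase = phase,
                   time_min = tmin, class = land$class,
                   baseline = land$baseline,
                   scale_factors = list(pdna = sc_p, gdna = sc_g, mdna = sc_m))),
      class = "synth_series")
  })
}

#' Generate a dissolved-oxygen trace at 0.1 Hz
#'
#' Builds an asymmetric periodic waveform whose first derivative has exactly
#' one minimum (start of the oxidative phase, phase 0) and one maximum
#' (start of the reductive phase, phase `oxidative_deg`) per cycle: DO drops
#' steeply at the oxidative onset, stays low through the short oxidative
#' phase and recovers after the reductive onset. The trace extends
#' `lead_cycles` before time zero and after the sampled span so that every
#' array sample lies inside the anchored range.
#'
#' @param config a [synth_config()].
#' @param lead_cycles extra cycles prepended/appended (default 1).
#' @return data.frame `time_s`, `value` (class `do_trace`).
#' @export
generate_do_trace <- function(config, lead_cycles = 1) {
  period_s <- config$period_min * 60
  dt <- 10  # 0.1 Hz
  t <- seq(-lead_cycles * period_s, (config$n_cycles + lead_cycles) * period_s,
           by = dt)
  th <- (360 * t / period_s) %% 360

  # derivative shape: negative pulse at 0 deg, positive pulse at the
  # reductive anchor; integrate on a dense grid to get the waveform
  grid <- seq(0, 360, by = 0.05)
  dshape <- -vm_bump(grid, 0, config$do_kappa) +
    vm_bump(grid, config$oxidative_deg, config$do_kappa)
  g <- cumsum(dshape) * 0.05
  g <- g - grid / 360 * g[length(g)]        # enforce exact periodicity
  g <- (g - min(g)) / max(1e-12, diff(range(g)))
  shape <- approx(grid, g, xout = th, rule = 2)$y

  value <- config$do_baseline + config$do_amplitude * shape
  if (config$do_noise_sd > 0) {
    value <- value + with_seed(config$seed + 2L,
                               rnorm(length(t), 0, config$do_noise_sd))
  }
  structure(data.frame(time_s = t, value = value),
            class = c("do_trace", "data.frame"))
}

#' Generate adenylate nucleotide time series (mM)
#'
#' ATP follows a raised cosine between the configured bounds, peaking at
#' `atp_peak_deg` in the oxidative phase; ATP:ADP oscillates
#' log-symmetrically over its configured range in phase with ATP, and AMP is
#' set so that the adenylate energy charge traverses its configured range.
#' `met_amplitude = 0` gives constant concentrations.
#'
#' @param config a [synth_config()].
#' @return data.frame `time_min`, `phase_deg`, `ATP`, `ADP`, `AMP`
#'   (class `metabolite_series`).
#' @export
generate_metabolites <- function(config) {
  tmin <- sample_times_min(config)
  th <- true_phase(config, tmin)
  a <- config$met_amplitude
  cosw <- cos((th - config$atp_peak_deg) * pi / 180)

  atp_mid <- mean(config$atp_range)
  atp_amp <- diff(config$atp_range) / 2
  atp <- atp_mid + a * atp_amp * cosw

  lr <- log(config$atp_adp_range)
  ratio <- exp(mean(lr) + a * diff(lr) / 2 * cosw)
  adp <- atp / ratio

  ec <- mean(config$ec_range) + a * diff(config$ec_range) / 2 * cosw
  amp_conc <- (atp + adp / 2) * (1 / ec - 1) - adp / 2
  amp_conc <- pmax(amp_conc, 0)

  structure(data.frame(time_min = tmin, phase_deg = th,
                       ATP = atp, ADP = adp, AMP = amp_conc),
            class = c("metabolite_series", "data.frame"))
}

#' Generate cluster-phased transcript abundances
#'
#' Each gene's abundance oscillates with its cluster's peak phase (anabolic
#' clusters A/AB/B in oxidative phase, catabolic C/D in reductive phase),
#' with a shared transient bump near `bump_deg` affecting all clusters, and
#' optional lognormal noise.
#'
#' @param config a [synth_config()].
#' @param cluster_labels data.frame `gene_id`, `cluster`; clusters must be
#'   among the names of `config$cluster_phases`.
#' @return genes x timepoints abundance matrix (linear scale), with
#'   attributes `time_min` and `phase_deg`.
#' @export
generate_transcripts <- function(config, cluster_labels) {
  stopifnot(all(c("gene_id", "cluster") %in% names(cluster_labels)))
  bad <- setdiff(unique(cluster_labels$cluster), names(config$cluster_phases))
  if (length(bad)) stop("unknown clusters: ", paste(bad, collapse = ", "))
  tmin <- sample_times_min(config)
  th <- true_phase(config, tmin)
  ng <- nrow(cluster_labels)

  mu <- config$cluster_phases[cluster_labels$cluster]
  l2 <- matrix(6, ng, length(th))
  for (i in seq_len(ng)) {
    l2[i, ] <- 6 +
      config$transcript_amplitude * vm_bump(th, mu[i], config$kappa) +
      config$bump_amplitude * vm_bump(th, config$bump_deg, config$kappa)
  }
  if (config$transcript_noise_sd > 0) {
    l2 <- l2 + with_seed(config$seed + 4L,
                         matrix(rnorm(length(l2), 0,
                                      config$transcript_noise_sd),
                                nrow = ng))
  }
  out <- 2^l2
  rownames(out) <- cluster_labels$gene_id
  colnames(out) <- sprintf("T%d", round(tmin))
  attr(out, "time_min") <- tmin
  attr(out, "phase_deg") <- th
  out
}

#' Generate a 10 Hz NAD(P)H fluorescence trace
#'
#' The trace is the sum of (i) an in-band component: the respiratory
#' fundamental and its 2nd-4th harmonics; (ii) a slow drift strictly below
#' the respiratory frequency (one cycle over the whole record); and (iii)
#' high-frequency noise confined, by DFT masking at generation time, to
#' frequencies strictly above 4x the fundamental. Components (ii) and (iii)
#' are exactly out of the analysis band, so the band-pass filter recovers
#' component (i) alone.
#'
#' @param config a [synth_config()].
#' @return data.frame `time_s`, `value`.
#' @export
generate_nadph <- function(config) {
  fs <- 10
  period_s <- config$period_min * 60
  nsec <- config$n_cycles * period_s
  t <- seq(0, nsec - 1 / fs, by = 1 / fs)
  f0 <- 1 / period_s

  with_seed(config$seed + 5L, {
    ph <- runif(length(config$nadph_harmonics), 0, 2 * pi)
    sig <- 0
    for (h in seq_along(config$nadph_harmonics)) {
      sig <- sig + config$nadph_harmonics[h] *
        sin(2 * pi * h * f0 * t + ph[h])
    }
    # drift: exactly one cycle over the record -> DFT bin 1, below f0
    drift <- config$nadph_drift_amplitude *
      sin(2 * pi * t / nsec + runif(1, 0, 2 * pi))
    noise <- 0
    if (config$nadph_noise_amplitude > 0) {
      w <- rnorm(length(t))
      W <- fft(w)
      fr <- seq_along(W) - 1
      fr <- pmin(fr, length(W) - fr) * fs / length(W)
      W[fr <= 4.5 * f0] <- 0+0i          # confine noise above the band
      noise <- config$nadph_noise_amplitude *
        Re(fft(W, inverse = TRUE) / length(W))
    }
    data.frame(time_s = t, value = 2 + sig + drift + noise)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running every generator under one config: genome,
#' intensity channels, DO trace, metabolites, transcripts and NAD(P)H.
#'
#' @param config a [synth_config()].
#' @return a `synth_dataset` list with elements `genome`, `series`, `do`,
#'   `metabolites`, `transcripts`, `nadph` and `config`.
#' @export
simulate_dataset <- function(config = synth_config()) {
  genome <- generate_genome(config)
  series <- generate_occupancy_series(config, genome)
  labels <- genome$annotations[c("gene_id", "cluster")]
  structure(list(
    genome = genome,
    series = series,
    do = generate_do_trace(config),
    metabolites = generate_metabolites(config),
    transcripts = generate_transcripts(config, labels),
    nadph = generate_nadph(config),
    config = config), class = "synth_dataset")
}
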