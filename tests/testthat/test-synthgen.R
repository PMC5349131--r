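test_that("genome layout: dyad registers, strand symmetry, probe tiling", {
  cfg <- synth_config(n_genes = 1, gene_length_mean = 1000,
                      gene_length_sd = 0, intergenic_gap = 600,
                      probe_spacing = 32, seed = 1)
  g <- generate_genome(cfg)
  # floor((1000 - 75)/165) + 1 = 6 genic dyads plus one -1 dyad
  expect_equal(nrow(g$dyads), 7)
  expect_equal(sum(g$dyads$ordinal == -1), 1)
  expect_equal(sum(g$dyads$ordinal > 0), 6)
  expect_equal(g$dyads$class[g$dyads$ordinal == 1], "TSS")
  expect_equal(g$dyads$class[g$dyads$ordinal == 6], "terminal")
  # genic dyads sit at +75 + 165 k from the TSS
  plus <- g$dyads[g$dyads$ordinal > 0, ]
  tss <- g$annotations$tss[1]
  expect_equal(sort(plus$pos - tss), 75 + 165 * (0:5))
  # chromosome 600 + 2000 + 600 = 3200 bp at 32 bp spacing: 100 positions
  cfg2 <- synth_config(n_genes = 1, gene_length_mean = 2000,
                       gene_length_sd = 0, intergenic_gap = 600,
                       probe_spacing = 32, seed = 1)
  g2 <- generate_genome(cfg2)
  expect_equal(g2$chrom_length, 3200)
  expect_equal(length(unique(g2$probes$start)), 100)
  expect_true(all(table(g2$probes$start) == 2))  # paired f/r probes
})

test_that("minus-strand genes have dyad coordinates decreasing with ordinal", {
  cfg <- synth_config(n_genes = 2, gene_length_sd = 0, seed = 1)
  g <- generate_genome(cfg)
  minus <- g$annotations$gene_id[g$annotations$strand == "-"][1]
  d <- g$dyads[g$dyads$gene_id == minus & g$dyads$ordinal > 0, ]
  d <- d[order(d$ordinal), ]
  expect_true(all(diff(d$pos) < 0))
})

test_that("a gene shorter than one nucleosome register gets a single +1 dyad", {
  cfg <- synth_config(n_genes = 1, gene_length_mean = 60, gene_length_sd = 0,
                      seed = 1)
  g <- generate_genome(cfg)
  genic <- g$dyads[g$dyads$ordinal > 0, ]
  expect_equal(nrow(genic), 1)
  expect_equal(genic$class, "TSS")
})

test_that("zero noise inverts the generative occupancy formula exactly", {
  s <- fx_series0()
  lp <- log2(intensity_matrix(s$pdna))
  lg <- log2(intensity_matrix(s$gdna))
  expect_lt(max(abs(lp - lg - s$truth$bias - s$truth$occupancy)), 1e-12)
  # mDNA = gDNA shifted by the bias
  lm <- log2(intensity_matrix(s$mdna))
  expect_lt(max(abs(lm[, 1] - lg[, 1] - s$truth$bias)), 1e-12)
})

test_that("zero class amplitudes give time-constant occupancy", {
  cfg <- synth_config(n_genes = 5, noise_sd = 0,
                      class_amplitudes = c(GB = 0, TSS = 0, NDR = 0),
                      seed = 3)
  s <- generate_occupancy_series(cfg, generate_genome(cfg))
  expect_equal(max(apply(s$truth$occupancy, 1, function(r) diff(range(r)))),
               0)
})

test_that("generators are bit-identical under the same seed and differ across seeds", {
  cfg <- synth_config(n_genes = 5, seed = 42)
  a <- generate_occupancy_series(cfg, generate_genome(cfg))
  b <- generate_occupancy_series(cfg, generate_genome(cfg))
  expect_identical(a, b)
  cfg2 <- synth_config(n_genes = 5, seed = 43)
  c2 <- generate_occupancy_series(cfg2, generate_genome(cfg2))
  expect_false(identical(intensity_matrix(a$pdna),
                         intensity_matrix(c2$pdna)))
  lab <- data.frame(gene_id = paste0("g", 1:5),
                    cluster = c("A", "AB", "B", "C", "D"))
  expect_identical(generate_transcripts(cfg, lab),
                   generate_transcripts(cfg, lab))
  expect_identical(generate_nadph(cfg)$value, generate_nadph(cfg)$value)
})

test_that("DO trace has one derivative min and max per cycle, 94/360 apart", {
  cfg <- synth_config(seed = 2)
  trace <- generate_do_trace(cfg)
  sm <- smooth_do(trace)
  dv <- do_derivative(sm)
  anc <- find_anchors(dv)
  mins <- anc$time_s[anc$kind == "min_deriv"]
  maxs <- anc$time_s[anc$kind == "max_deriv"]
  # interior cycles only (one lead cycle each side)
  expect_gte(length(mins), cfg$n_cycles)
  # construction puts minima exactly at multiples of the period
  expect_true(all(abs(mins %% (67 * 60)) <= 10 |
                    abs(mins %% (67 * 60) - 67 * 60) <= 10))
  # oxidative span: 67 * 94/360 = 17.49 min
  spans <- vapply(mins, function(m) {
    nxt <- maxs[maxs > m]
    if (length(nxt)) min(nxt) - m else NA_real_
  }, numeric(1))
  expect_true(all(abs(stats::na.omit(spans) / 60 - 67 * 94 / 360) < 0.5))
})

test_that("metabolites respect configured ranges and collapse at zero amplitude", {
  cfg <- synth_config(seed = 5)
  met <- generate_metabolites(cfg)
  expect_true(abs(min(met$ATP) - 21) / 21 < 0.01)
  expect_true(abs(max(met$ATP) - 51) / 51 < 0.01)
  ratio <- met$ATP / met$ADP
  expect_true(all(ratio >= 1.2 - 1e-9 & ratio <= 8 + 1e-9))
  expect_equal(max(ratio) / min(ratio), 8 / 1.2, tolerance = 0.02)
  ec <- energy_charge(met$ATP, met$ADP, met$AMP)
  expect_true(all(ec >= 0.65 - 1e-9 & ec <= 0.9 + 1e-9))
  flat <- generate_metabolites(synth_config(seed = 5, met_amplitude = 0))
  expect_equal(diff(range(flat$ATP / flat$ADP)), 0)
})

test_that("metabolite ranges hold for arbitrary seeds", {
  for (seed in c(1, 99, 4242)) {
    met <- generate_metabolites(synth_config(seed = seed))
    expect_true(all(met$ATP >= 21 - 0.3 & met$ATP <= 51 + 0.3))
    expect_true(all(met$AMP >= 0))
  }
})

test_that("cluster transcript sums peak at configured phases, with anabolic before the reductive onset", {
  cfg <- synth_config(seed = 8, transcript_noise_sd = 0)
  lab <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    cluster = rep(c("A", "AB", "B", "C", "D"), 2))
  tr <- generate_transcripts(cfg, lab)
  cs <- sum_clusters(tr, lab)
  ph <- attr(tr, "phase_deg")
  for (cl in names(cfg$cluster_phases)) {
    pk <- ph[which.max(cs[cl, ])]
    expect_lt(min(abs(c(pk - cfg$cluster_phases[[cl]],
                        pk - cfg$cluster_phases[[cl]] + 360,
                        pk - cfg$cluster_phases[[cl]] - 360))), 15)
  }
  expect_lt(ph[which.max(cs["anabolic", ])], 94)
  # one gene per cluster: sum equals the gene's own series
  lab1 <- lab[1:5, ]
  tr1 <- generate_transcripts(cfg, lab1)
  cs1 <- sum_clusters(tr1, lab1)
  expect_equal(unname(cs1["A", ]), unname(tr1["g01", ]))
})

test_that("NAD(P)H trace is 10 Hz with out-of-band drift and noise", {
  cfg <- synth_config(seed = 6)
  nad <- generate_nadph(cfg)
  expect_equal(median(diff(nad$time_s)), 0.1)
  f0 <- 1 / (67 * 60)
  # filtering the full trace recovers the in-band-only construction
  clean <- generate_nadph(synth_config(seed = 6, nadph_drift_amplitude = 0,
                                       nadph_noise_amplitude = 0))
  filt <- bandpass_filter(nad$value, f0, 10)
  expect_lt(max(abs(filt - (clean$value - mean(clean$value)))), 1e-9)
  # no in-band content: filter output is ~0
  silent <- generate_nadph(synth_config(seed = 6,
                                        nadph_harmonics = c(0, 0, 0, 0)))
  expect_lt(max(abs(bandpass_filter(silent$value, f0, 10))), 1e-9)
})
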