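mini_ann <- function() {
  data.frame(gene_id = c("gp", "gm"), chrom = "chrT",
             tss = c(1000L, 5000L), strand = c("+", "-"),
             transcript_end = c(1999L, 4001L),
             stringsAsFactors = FALSE)
}

test_that("TSS mapping is strand-aware with upstream negative", {
  probes <- data.frame(probe_id = c("a", "b"), chrom = "chrT",
                       start = c(1100L, 5100L), end = c(1100L, 5100L),
                       strand = "+")
  idx <- map_probes_to_tss(probes, mini_ann(), half_window = 500)
  expect_equal(idx$rel_pos[idx$gene_id == "gp" & idx$probe_id == "a"], 100)
  # probe 100 bp downstream in genomic coords of a minus-strand TSS: -100
  expect_equal(idx$rel_pos[idx$gene_id == "gm" & idx$probe_id == "b"], -100)
})

test_that("every synthetic gene has mapped probes", {
  g <- fx_genome0()
  idx <- map_probes_to_tss(g$probes, g$annotations, half_window = 1000)
  expect_setequal(unique(idx$gene_id), g$annotations$gene_id)
})

test_that("median TSS profile: identity, robustness, and NDR localization", {
  g <- fx_genome0()
  s <- fx_series0()
  occm <- occm_from_truth(g, s$truth$occupancy, s$truth$time_min)
  idx <- map_probes_to_tss(g$probes, g$annotations, half_window = 1000)
  prof <- median_tss_profile(occm, idx)
  expect_equal(prof$n_genes, nrow(g$annotations))

  # NDR minimum at -75 within one bin of the probe spacing
  avg <- rowMeans(prof$profile)
  ndr_pos <- as.integer(rownames(prof$profile)[which.min(avg)])
  expect_lte(abs(ndr_pos - (-75)), 32)

  # median is unchanged by one outlier gene among many
  occ2 <- s$truth$occupancy
  gene1 <- idx$probe_id[idx$gene_id == "G001"]
  occ2[rownames(occ2) %in% gene1, ] <- occ2[rownames(occ2) %in% gene1, ] + 50
  prof2 <- median_tss_profile(occm_from_truth(g, occ2, s$truth$time_min), idx)
  common <- intersect(rownames(prof$profile), rownames(prof2$profile))
  delta <- abs(prof2$profile[common, ] - prof$profile[common, ])
  expect_lt(quantile(delta, 0.9), 0.2)

  # display cap applies at export only
  prof3 <- median_tss_profile(occm, idx, cap = -1)
  expect_gte(min(prof3$profile), -1)
})

test_that("profiles are invariant to gene permutation and shift with a constant", {
  g <- fx_genome0()
  s <- fx_series0()
  occm <- occm_from_truth(g, s$truth$occupancy, s$truth$time_min)
  idx <- map_probes_to_tss(g$probes, g$annotations, half_window = 1000)
  prof <- median_tss_profile(occm, idx)
  perm <- idx[sample(nrow(idx)), ]
  expect_equal(median_tss_profile(occm, perm)$profile, prof$profile)
  occ_up <- occm_from_truth(g, s$truth$occupancy + 2, s$truth$time_min)
  expect_equal(median_tss_profile(occ_up, idx)$profile, prof$profile + 2)
})

test_that("dyad classification follows ordinal rules on hand-built genes", {
  ann <- mini_ann()
  # plus-strand gene with dyads +1 .. +5 and one upstream
  dyads <- data.frame(chrom = "chrT",
                      pos = c(1000 + 75 + 165 * (0:4), 1000 - 240))
  cls <- classify_dyads(dyads, ann[1, ])
  expect_equal(cls$ordinal[order(cls$pos)], c(-1L, 1:5))
  expect_equal(cls$class[cls$ordinal == 1], "TSS")
  expect_equal(cls$class[cls$ordinal == 5], "terminal")
  expect_setequal(cls$class[cls$ordinal %in% 2:4], "GB")
  # two genic dyads: +1 TSS, +2 terminal, no GB
  d2 <- data.frame(chrom = "chrT", pos = c(1075, 1240))
  cls2 <- classify_dyads(d2, ann[1, ])
  expect_equal(cls2$class[order(cls2$ordinal)], c("TSS", "terminal"))
})

test_that("minus-strand ordinals increase with decreasing coordinate", {
  g <- fx_genome0()
  cls <- classify_dyads(g$dyads[c("chrom", "pos")], g$annotations)
  minus <- g$annotations$gene_id[g$annotations$strand == "-"]
  d <- cls[cls$gene_id == minus[1] & cls$ordinal > 0, ]
  d <- d[order(d$ordinal), ]
  expect_true(all(diff(d$pos) < 0))
  # classification matches the generator's ground truth everywhere
  truth <- g$dyads
  m <- merge(cls, truth, by = c("chrom", "pos"))
  expect_equal(m$ordinal.x, m$ordinal.y)
  expect_equal(m$class.x, m$class.y)
})

test_that("dyad-aligned profiles recover class dynamics and degenerate cleanly", {
  g <- fx_genome0()
  s <- fx_series0()
  occm <- occm_from_truth(g, s$truth$occupancy, s$truth$time_min)
  cls <- classify_dyads(g$dyads[c("chrom", "pos")], g$annotations)
  pm <- phase_from_do(generate_do_trace(fx_cfg0()),
                      sample_times_s = s$truth$time_min * 60)
  prof <- dyad_aligned_profile(occm, cls, g$annotations)
  gb <- fit_cycle(prof$central["GB", ], pm$phase_deg, df = 11)
  expect_phase_near(profile_peaks(gb$value, gb$phase_deg, 2), c(60, 225))

  # uniform occupancy: flat in position and phase
  flat <- occm_from_truth(g, matrix(1.5, nrow(s$truth$occupancy),
                                    ncol(s$truth$occupancy),
                                    dimnames = dimnames(s$truth$occupancy)),
                          s$truth$time_min)
  pf <- dyad_aligned_profile(flat, cls, g$annotations)
  expect_equal(diff(range(pf$profiles$GB)), 0)
  expect_equal(unique(as.vector(pf$central)), 1.5)

  # class with no dyads: warning, omitted
  cls_no_up <- cls[cls$class != "upstream", ]
  expect_warning(dyad_aligned_profile(occm, cls_no_up, g$annotations),
                 "upstream")
})

test_that("mirrored genome (all strands and coordinates flipped) gives identical profiles", {
  cfg <- synth_config(n_genes = 10, noise_sd = 0, probe_length = 51,
                      seed = 77)
  g <- generate_genome(cfg)
  s <- generate_occupancy_series(cfg, g)
  occm <- occm_from_truth(g, s$truth$occupancy, s$truth$time_min)
  L <- g$chrom_length

  gm <- g
  gm$annotations$tss <- L + 1L - g$annotations$tss
  gm$annotations$transcript_end <- L + 1L - g$annotations$transcript_end
  gm$annotations$strand <- ifelse(g$annotations$strand == "+", "-", "+")
  gm$probes$start <- L + 1L - g$probes$end
  gm$probes$end <- L + 1L - g$probes$start
  gm$probes$strand <- ifelse(g$probes$strand == "+", "-", "+")
  occm_m <- occm_from_truth(gm, s$truth$occupancy, s$truth$time_min)

  idx <- map_probes_to_tss(g$probes, g$annotations, half_window = 1000)
  idx_m <- map_probes_to_tss(gm$probes, gm$annotations, half_window = 1000)
  p1 <- median_tss_profile(occm, idx, bin = 32)
  p2 <- median_tss_profile(occm_m, idx_m, bin = 32)
  expect_equal(p1$profile, p2$profile)
})

test_that("cluster profiles: single cluster equals the global profile; deltas have zero mean", {
  g <- fx_genome0()
  s <- fx_series0()
  occm <- occm_from_truth(g, s$truth$occupancy, s$truth$time_min)
  cls <- classify_dyads(g$dyads[c("chrom", "pos")], g$annotations)
  ann_one <- g$annotations
  ann_one$cluster <- "ALL"
  cp <- cluster_profiles(occm, cls, ann_one)
  expect_equal(names(cp), "ALL")
  global <- dyad_aligned_profile(occm, cls, g$annotations,
                                 classes = c("upstream", "TSS", "GB",
                                             "terminal"))
  # all dyads pooled: same medians as the class-agnostic pooled profile
  dt_all <- cluster_profiles(occm, cls, ann_one)$ALL
  expect_equal(rowMeans(dt_all$delta), rep(0, nrow(dt_all$delta)),
               ignore_attr = TRUE)
  expect_equal(dt_all$delta + dt_all$means, dt_all$profile)
  # per-cluster profiles match per-cluster synthetic truth
  cpc <- cluster_profiles(occm, cls, g$annotations)
  expect_setequal(names(cpc), c("A", "AB", "B", "C", "D"))
  for (nm in names(cpc)) expect_gt(cpc[[nm]]$n_dyads, 0)
})
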