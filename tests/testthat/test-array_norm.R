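make_pt <- function(l2, strand = "+", start = NULL) {
  n <- nrow(l2)
  if (is.null(start)) start <- seq(1, by = 32, length.out = n)
  probe_table(data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                         chrom = "chrT", start = start, end = start + 49,
                         strand = strand, stringsAsFactors = FALSE),
              2^l2)
}

test_that("least-variant selection follows per-probe variance in both channels", {
  # identical arrays: every probe has zero variance
  l2 <- matrix(8, nrow = 6, ncol = 4,
               dimnames = list(NULL, paste0("T", 0:3)))
  pt <- make_pt(l2)
  expect_setequal(select_least_variant(pt, pt, 0.1), pt$probe_id)

  # 3 probes built with variance 0.05, 7 with variance 0.5
  set.seed(1)
  base <- matrix(10, 10, 6, dimnames = list(NULL, paste0("T", 0:5)))
  # rows rescaled to an exact target variance
  mk_rows <- function(k, v) t(apply(matrix(rnorm(k * 6), k, 6), 1, function(r) {
    (r - mean(r)) / sd(r) * sqrt(v)
  }))
  l2b <- base + rbind(mk_rows(3, 0.05), mk_rows(7, 0.5))
  ptb <- make_pt(l2b)
  # brute-force oracle: per-probe variance across arrays
  v <- apply(l2b, 1, var)
  expect_equal(sort(which(v < 0.1)), 1:3)
  expect_setequal(select_least_variant(ptb, ptb, 0.1), ptb$probe_id[1:3])
  expect_error(select_least_variant(ptb, ptb, 1e-6), "threshold")
})

test_that("LOESS normalization removes constant offsets and leaves matched arrays alone", {
  set.seed(2)
  n <- 300
  ref <- rnorm(n, 10, 1)
  l2 <- cbind(T0 = ref, T1 = ref, T2 = ref + 0.8)  # one array offset by 0.8
  pt <- make_pt(l2)
  lvs <- pt$probe_id
  out <- loess_normalize(pt, lvs)
  l2o <- log2(intensity_matrix(out))
  # matched arrays barely move; the offset array lands on the reference
  newref <- rowMeans(l2)
  expect_lt(max(abs(l2o[, "T2"] - l2o[, "T0"])), 0.01)
  expect_lt(max(abs(l2o[, "T0"] - l2o[, "T1"])), 1e-9)
  expect_error(loess_normalize(pt, pt$probe_id[1:3]), "window")
})

test_that("LOESS normalization removes a smooth intensity-dependent distortion", {
  set.seed(3)
  n <- 1000
  ref <- rnorm(n, 10, 1)
  noise <- matrix(rnorm(n * 4, 0, 0.05), n, 4)
  l2 <- ref + noise
  distorted <- l2
  distorted[, 2] <- distorted[, 2] + 0.3 * (ref - 10)^2 / 3 + 0.4
  distorted[, 4] <- distorted[, 4] - 0.2 * (ref - 10) + 0.3
  colnames(distorted) <- paste0("T", 0:3)
  pt <- make_pt(distorted)
  lvs <- pt$probe_id
  pre <- var(array_offsets(pt, lvs))
  out <- loess_normalize(pt, lvs)
  post <- var(array_offsets(out, lvs))
  expect_gte(pre / post, 10)
  # probe-level deviations from the array-mean reference also shrink
  dev_pre <- distorted - rowMeans(distorted)
  l2o <- log2(intensity_matrix(out))
  dev_post <- l2o - rowMeans(l2o)
  expect_gte(mean(apply(dev_pre, 1, var)) / mean(apply(dev_post, 1, var)), 5)
})

test_that("re-normalizing already-normalized data is a near no-op", {
  set.seed(4)
  n <- 400
  ref <- rnorm(n, 10, 1)
  l2 <- cbind(T0 = ref + 0.5, T1 = ref - 0.3, T2 = ref + 0.1)
  pt <- make_pt(l2)
  once <- loess_normalize(pt, pt$probe_id)
  twice <- loess_normalize(once, pt$probe_id)
  expect_lt(max(abs(log2(intensity_matrix(twice)) -
                      log2(intensity_matrix(once)))), 1e-6)
})

test_that("strand-pair averaging halves paired probes and warns on orphans", {
  l2 <- matrix(c(1, 3, 2, 4), nrow = 2, ncol = 2,
               dimnames = list(NULL, c("T0", "T1")))
  pt <- probe_table(data.frame(probe_id = c("a_f", "a_r"), chrom = "chrT",
                               start = 1L, end = 50L,
                               strand = c("+", "-")), 2^l2)
  avg <- average_strand_pairs(pt)
  expect_equal(nrow(avg), 1)
  expect_equal(unname(log2(intensity_matrix(avg))[1, ]), c(2, 3))
  expect_equal(avg$strand, "*")

  # all unpaired: unchanged except the warning
  pt2 <- probe_table(data.frame(probe_id = c("a", "b"), chrom = "chrT",
                                start = c(1L, 100L), end = c(50L, 149L),
                                strand = "+"), 2^l2)
  expect_warning(avg2 <- average_strand_pairs(pt2), "no strand pair")
  expect_equal(nrow(avg2), 2)
  expect_equal(intensity_matrix(avg2), intensity_matrix(pt2))

  # synthetic paired table: exactly half the rows
  s <- fx_series0()
  expect_equal(nrow(average_strand_pairs(s$gdna)), nrow(s$gdna) / 2)
})

test_that("MNase bias estimation matches its defining ratios and recovers truth", {
  l2 <- matrix(10, 4, 2, dimnames = list(NULL, c("R1", "R2")))
  pt <- make_pt(l2)
  b0 <- compute_mnase_bias(pt, pt)
  expect_equal(b0$bias, rep(0, 4))
  pt2 <- make_pt(l2 + 1)  # mDNA = 2 x gDNA
  expect_equal(compute_mnase_bias(pt2, pt)$bias, rep(1, 4))

  s <- fx_series0()
  ma <- average_strand_pairs(s$mdna)
  ga <- average_strand_pairs(s$gdna)
  est <- compute_mnase_bias(ma, ga)
  key <- paste0(s$pdna$chrom, ":", s$pdna$start, "-", s$pdna$end)
  truth <- rowsum(s$truth$bias, key) / 2
  expect_lt(max(abs(est$bias - truth[est$probe_id, 1])), 1e-12)
})

test_that("occupancy formula and missing-value handling", {
  l2 <- matrix(10, 3, 2, dimnames = list(NULL, c("T0", "T6")))
  g <- make_pt(l2)
  bias0 <- compute_mnase_bias(g, g)
  occ <- compute_occupancy(g, g, bias0)
  expect_equal(unname(occ$occ), matrix(0, 3, 2))
  expect_equal(occ$time_min, c(0, 6))
  p2 <- make_pt(l2 + 1)
  expect_equal(unname(compute_occupancy(p2, g, bias0)$occ),
               matrix(1, 3, 2))
  # nonpositive intensity flagged missing, not clipped
  p3 <- p2
  p3$T0[2] <- -1
  occ3 <- compute_occupancy(p3, g, bias0)
  expect_true(is.na(occ3$occ[2, 1]))
  expect_false(anyNA(occ3$occ[-2, ]))
})

test_that("occupancy is invariant to a common per-timepoint scale factor after normalization", {
  s <- fx_series0()
  n1 <- fx_norm0()
  pdna <- s$pdna; gdna <- s$gdna
  pdna[["T12"]] <- pdna[["T12"]] * 1.25
  gdna[["T12"]] <- gdna[["T12"]] * 1.25
  n2 <- suppressWarnings(normalize_channels(pdna, gdna, s$mdna))
  # the scale factor moves the (unidentifiable) global level by delta/n
  # through the channel reference; occupancy is relative, so compare
  # grand-mean-centred matrices
  d1 <- n1$occupancy$occ - mean(n1$occupancy$occ)
  d2 <- n2$occupancy$occ - mean(n2$occupancy$occ)
  expect_lt(max(abs(d2 - d1)), 1e-6)
})
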