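# shared fixtures, built once per test run and cached

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- force(expr)
  .fx_cache[[name]]
}

# small, noise-free dataset: the backbone of the exact-inversion checks
fx_cfg0 <- function() {
  synth_config(n_genes = 20, noise_sd = 0, do_noise_sd = 0, seed = 101)
}
fx_genome0 <- function() fx("genome0", generate_genome(fx_cfg0()))
fx_series0 <- function() {
  fx("series0", generate_occupancy_series(fx_cfg0(), fx_genome0()))
}
fx_norm0 <- function() {
  fx("norm0", suppressWarnings(
    normalize_channels(fx_series0()$pdna, fx_series0()$gdna,
                       fx_series0()$mdna)))
}

# the study-condition dataset (defaults: noise_sd 0.2, 3 cycles, 33 samples)
fx_default_ds <- function() fx("default_ds", simulate_dataset(synth_config(seed = 11)))
fx_default_res <- function() {
  fx("default_res",
     run_pipeline(run_config(sim = synth_config(seed = 11))))
}

# truth occupancy aggregated to strand-averaged probe keys
truth_avg <- function(series) {
  pt <- series$pdna
  key <- paste0(pt$chrom, ":", pt$start, "-", pt$end)
  rowsum(series$truth$occupancy, key) / 2
}

# occupancy_matrix built directly from a truth matrix (bypasses channels)
occm_from_truth <- function(genome, occ, time_min) {
  structure(list(occ = occ, probes = genome$probes, time_min = time_min),
            class = "occupancy_matrix")
}

expect_phase_near <- function(found, expected, tol = 15) {
  for (e in expected) {
    expect_true(any(abs(((found - e + 180) %% 360) - 180) <= tol),
                label = sprintf("peak near %d (found: %s)", e,
                                paste(round(found), collapse = ", ")))
  }
}
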