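# occycle

Nucleosome (DNA) occupancy dynamics over the yeast respiratory oscillation.

Continuously grown, metabolically synchronous *Saccharomyces cerevisiae*
cultures alternate between an oxidative and a reductive phase with a period
of about an hour, monitored through residual dissolved oxygen (DO). Against
this metabolic clock one can measure genome-wide protein–DNA occupancy over
time: protein-bound MNase-digested DNA (pDNA) and genomic DNA (gDNA) are
hybridised to tiling arrays at each timepoint, and an MNase-digested
naked-DNA control (mDNA) corrects for the nuclease's sequence bias,

```
DNA occ(p, t) = log2 pDNA(p, t) − log2 gDNA(p, t) − MNase bias(p).
```

`occycle` is for chromatin and systems biologists who want to go from raw
probe-level channel intensities to phase-resolved occupancy landscapes:

* **Normalization** — least-variant-set (LVS) probe selection (variance
  across arrays < 0.1 in both channels), per-array LOESS normalization
  against the cross-array mean, strand-pair averaging, MNase-bias
  subtraction.
* **Phase alignment** — DO smoothing (100-s running mean), derivative
  anchors (minimum = oxidative onset = 0°, maximum = reductive onset =
  94°), piecewise-linear phase assignment, so datasets with different
  periods share one axis.
* **Cycle statistics** — cubic smoothing-spline average cycles resampled
  every 15° (24 points), rate-of-change profiles in units of change per
  15°, cluster and supercluster transcript sums, Δ-occupancy.
* **Genome maps** — TSS-aligned and nucleosome-dyad-aligned median
  occupancy profiles; dyad classification into −1 / +1 (TSS-covering) /
  gene-body / terminal nucleosomes.
* **Spectral tools** — per-probe Fourier major-period/amplitude/SNR
  statistics with permutation p-values; the DFT band-pass filter
  (passband `[f_osc, 4 f_osc]`) for 10 Hz NAD(P)H fluorescence.
* **Energetics** — adenylate energy charge `(ATP + ADP/2)/(ATP + ADP +
  AMP)` and chromatin-remodeler activity under competitive product
  inhibition, `v/Vmax = ATP / (Km (1 + ADP/Ki) + ATP)` with ISWI defaults
  `Km = 0.15 mM`, `Ki = 0.1 mM`; cyclic-permutation correlations between
  cycle profiles.
* **A seeded synthetic-data generator** (`simulate_dataset()`) emulating
  the whole experiment — oscillating occupancy landscape with an NDR at
  −75 bp, class-specific peak phases (gene body 60°/225°; TSS
  75°/225°/330°), an asymmetric DO cycle, ATP 21–51 mM, ATP:ADP 1.2–8,
  phased transcript clusters and a 10 Hz NAD(P)H trace — used throughout
  the tests as ground truth.

See the methods vignette (`vignettes/occupancy-dynamics.Rmd`) for the
models, design decisions and limitations.

## Worked example

```r
library(occycle)

cfg <- synth_config(seed = 1)                 # 67-min period, 33 samples, 60 genes
res <- run_pipeline(run_config(sim = cfg))
res
#> occycle pipeline result
#> occupancy_matrix: 3060 probes x 33 timepoints (mean 0.133, sd 0.717)
#>   phased samples: 33 (0 NA)
#>   TSS profile: 60 genes

# where do gene-body and TSS nucleosomes peak over the cycle?
pmv <- res$phase_map$phase_deg
gb  <- fit_cycle(res$dyad_profiles$central["GB", ],  pmv, df = 11)
tss <- fit_cycle(res$dyad_profiles$central["TSS", ], pmv, df = 11)
profile_peaks(gb$value,  gb$phase_deg, 2)     #> 60 225
profile_peaks(tss$value, tss$phase_deg, 3)    #> 75 225 330

# nucleosome-depleted region in the TSS-aligned median profile
avg <- rowMeans(res$tss_profile$profile)
names(avg)[which.min(avg)]                    #> "-64"  (bp relative to TSS)

# inferred remodeler activity over the metabolite cycle
met <- generate_metabolites(cfg)
act <- remodeling_activity(met$ATP, met$ADP)  # Km 0.15 mM, Ki 0.1 mM
range(act)                                    #> 0.44 0.84
```

The gene-body occupancy peaks at 60° and 225°, the TSS/NDR-flanking
nucleosomes at 75°, 225° and 330° — recovered from noisy simulated arrays
(log2 noise s.d. 0.2) to within one 15° grid step of the generator's
configured phases. The NDR minimum lands within one probe spacing (32 bp)
of its true position at −75 bp. The remodeler-activity range says that
swings in ATP and ADP of the size this system produces modulate an
ISWI-class enzyme over roughly half its dynamic range.

`run_pipeline(..., outdir = "run1")` additionally writes every stage
output as TSV plus a JSON manifest with parameters, seeds and checksums.
A thin command-line front end with `simulate`, `normalize`, `phase`,
`cycle`, `spectra`, `energetics` and `run-all` subcommands is installed at
`inst/cli/occycle-cli.R`.

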