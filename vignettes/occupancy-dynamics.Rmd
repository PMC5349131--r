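---
title: "Time-resolved DNA occupancy over the yeast respiratory oscillation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved DNA occupancy over the yeast respiratory oscillation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occycle)
```

## The system and the measurement

Continuously grown *Saccharomyces cerevisiae* cultures under tight nutrient
and aeration control spontaneously synchronise their metabolism: the
population alternates between a short **oxidative phase** of high oxygen
uptake and a longer **reductive phase**, with a period of roughly an hour.
The residual dissolved oxygen (DO) in the vessel tracks this respiratory
oscillation and provides a clock against which any other measurement on the
culture can be aligned.

`occycle` analyses time series of **DNA occupancy** over this cycle.
Protein-bound, MNase-digested DNA (pDNA) and undigested genomic DNA (gDNA)
are co-hybridised to whole-genome tiling arrays at every sampling time;
an MNase-digested naked-DNA control (mDNA) is hybridised a few times per
experiment. The occupancy of probe $p$ at array (timepoint) $t$ is

$$
\mathrm{occ}(p,t) \;=\; \log_2 \mathrm{pDNA}_{p,t} \;-\;
\log_2 \mathrm{gDNA}_{p,t} \;-\; \mathrm{bias}_p ,
$$

where the MNase bias

$$
\mathrm{bias}_p \;=\; \frac{1}{m}\sum_i \log_2 \mathrm{mDNA}_{p,i}
\;-\; \frac{1}{n}\sum_j \log_2 \mathrm{gDNA}_{p,j}
$$

captures the sequence preference of micrococcal nuclease, estimated from
the control channel. Occupancy values are **relative**: ratios carry no
absolute channel level, so a global additive constant is unidentifiable.
Every comparison the package's tests make between two occupancy matrices is
therefore made modulo the grand mean.

## Between-array normalization: least-variant set + LOESS

Arrays differ in labelling efficiency, hybridisation and scanning. The
package normalizes each channel with a least-variant-set (LVS) strategy:

1. `select_least_variant()` keeps probes whose log2-intensity variance
   across arrays is below a threshold (default 0.1) in **both** the pDNA
   and gDNA channels. These probes are the ones that move least over the
   experiment and can anchor the between-array fit without absorbing
   genome-wide biology. The variance is computed on raw log2 intensities;
   an array-median pre-centring variant was deliberately rejected because
   the genome-wide, phase-coherent occupancy dynamics this system exhibits
   leak into per-array medians and corrupt the ranking — coherent global
   signal is precisely why a least-variant set is used instead of median
   scaling.
2. `loess_normalize()` regresses, for each array, the deviation of its
   log2 intensities from the across-array mean (the reference) on the
   reference, using only LVS probes (span 0.3, local degree 1), evaluates
   the curve at every probe and subtracts it. The correction is re-centred
   so the LVS probes have zero mean residual. The reference choice (the
   across-array mean) is a design decision; any fixed reference works
   because only deviations are modelled.
3. `average_strand_pairs()` collapses the paired forward/reverse probes at
   each position to their log2 mean after normalization.
4. `compute_mnase_bias()` and `compute_occupancy()` finish the formulae
   above. Nonpositive intensities are treated as missing, never clipped —
   no log ratio is fabricated.

Two properties are worth knowing. First, the LVS threshold is an absolute
variance, so there is a design envelope: any per-array distortion with
variance above ~0.09 log2² inflates every probe past the 0.1 threshold and
empties the selection. Within the envelope (per-array scale errors up to
~±20%), the procedure removes the distortion essentially exactly; the
fixture the tests use injects scale factors of s.d. 0.25 log2. Second,
normalization is signal-preserving only insofar as the LVS excludes
oscillating probes; at the threshold boundary a strongly shifted array can
push borderline oscillating probes into the set, which is a threshold
effect of the published procedure itself.

## The respiratory phase axis

The oxidative and reductive phases have unequal lengths, so clock time is a
poor axis for averaging cycles. `phase_from_do()` builds the phase axis the
way the field does:

1. the DO trace (0.1 Hz) is smoothed by a centred running mean whose
   window is specified as a frequency, 0.01 Hz = 100 s = 10 samples
   (`smooth_do()`);
2. the first derivative is taken by central differences
   (`do_derivative()`);
3. each cycle's derivative **minimum** (sharpest DO drop, oxidative onset)
   and **maximum** (sharpest DO rise, reductive onset) are detected
   (`find_anchors()`), with a Fisher-type spectral test rejecting traces
   with no dominant oscillation, a refractory window of half the estimated
   period between same-kind anchors, earliest-wins tie-breaks, and an
   exclusion buffer at the trace edges where smoothing and one-sided
   differences distort extrema;
4. `assign_phase()` maps each cycle piecewise-linearly: minima to 0°,
   maxima to 94° (the oxidative fraction of the cycle; configurable), and
   the reductive segment back to 360° at the next minimum. Samples outside
   the anchored span are flagged `NA` and excluded from cycle averages,
   not extrapolated.

Whether 94° is a universal constant or should be re-derived per experiment
is left open by the source material; the package exposes it as
`oxidative_deg` with 94 as the default.

## Average-cycle profiles

`fit_cycle()` pools all (phase, value) observations across cycles, fits a
cubic smoothing spline and evaluates it at 24 grid points (every 15°). The
spline's degrees of freedom follow the convention *df = samples per cycle*
(e.g. `round(67/6) = 11`). Periodicity is enforced by replicating the data
at ±360° before fitting; the requested df is tripled internally so the
per-cycle flexibility is unchanged. This replication is a design choice the
source method is silent about; it preserves the stated cubic-spline
machinery while making the two grid ends meet.

`rate_of_change()` differences consecutive samples in time order, assigns
the circular midpoint of the two sample phases, fits the same spline, and
rescales to units of change per 15° of phase (multiplying by 15 over the
mean inter-sample phase step). The rescaling convention is explicit and
invertible.

`sum_clusters()` aggregates transcript abundances into the consensus
clusters and the anabolic (A, AB, B, B.C, B.D, ab.n) and catabolic (C, D,
cd.n, cd.ab) superclusters. `subtract_temporal_mean()` produces the
Δ-occupancy representation (each series minus its own temporal mean, the
removed means reported separately).

## Genome maps: TSS and dyad alignment

`map_probes_to_tss()` indexes probe midpoints by signed, strand-aware
TSS-relative position (±1000 bp default). `median_tss_profile()` computes,
per position bin (default: the probe spacing) and timepoint, the median
over *genes* — probes of one gene sharing a bin are averaged within the
gene first, so no gene is overweighted. The optional display floor (e.g.
−1) exists only at export.

`classify_dyads()` assigns nucleosome dyad positions to the gene with the
nearest TSS (within 1 kb upstream or inside the transcript; ties to the +
strand), then numbers them along the transcription direction: the
TSS-covering register (strand-aware position ≥ −73 bp, half of the ~147 bp
of wrapped DNA) starts the +1, +2, … series, the last genic dyad is
*terminal*, ordinals +2 to the penultimate are gene-body (GB), and dyads
further upstream are −1, −2, …. The TSS analysis group — the
NDR-flanking nucleosomes — is {−1, +1, terminal}. A gene whose only genic
dyad is the +1 keeps class TSS; genes with no genic dyad are excluded with
a message.

`dyad_aligned_profile()` and `cluster_profiles()` then compute median
occupancy around dyads per nucleosome class and per expression cluster,
including the central (dyad ± 73 bp) temporal profiles used for the
supercluster comparisons, with B.C/B.D mergeable into an expanded B.

## Spectral statistics

`fourier_stats()` reports, after mean removal, the DFT bin of maximal
power (DC excluded) as the major period, the amplitude `2|X_k|/n`, the
peak phase on the respiratory axis, and an SNR defined as the major-bin
power over the median power of the other non-DC bins. No spectral
interpolation is applied: a 67-min oscillation observed for 33 samples at
6 min lives on the 198/k-min bin grid and reports 66 min. The p-value is a
permutation test that randomly permutes the time order and compares the
maximal non-DC power with the observed one. A cyclic time-shift null was
considered and rejected on mathematical grounds: integer circular shifts
leave every $|X_k|$ invariant, so such a test cannot discriminate at all.
Random permutation preserves the marginal distribution, destroys the
temporal structure, and is calibrated under an i.i.d. null (the test suite
verifies a 5% rejection rate at α = 0.05).

One caveat the package documents rather than hides: when a waveform has
two peaks per cycle — as the gene-body occupancy does — the DFT
legitimately concentrates power in the second harmonic, and the "major
period" is half the cycle length. Period-recovery checks therefore use a
single-peak, low-concentration configuration of the generator, where the
fundamental dominates.

`bandpass_filter()` implements the DFT band-pass used for the 10 Hz
NAD(P)H fluorescence trace: bins below the respiratory frequency (drift,
including DC) and above four times it (instrument noise) are zeroed, band
edges inclusive, and the signal is reconstructed by the inverse transform.
The filter is exactly idempotent and never adds energy.

## Energetics

`energy_charge()` is the standard adenylate energy charge
$(\mathrm{ATP} + \mathrm{ADP}/2)/(\mathrm{ATP} + \mathrm{ADP} +
\mathrm{AMP})$ — used because the source quotes "EC" ranges without
printing a formula. `remodeling_activity()` infers the relative velocity
of an ATP-consuming chromatin remodeler under competitive product
inhibition,

$$
\frac{v}{V_{max}} = \frac{\mathrm{ATP}}{K_m\,(1 + \mathrm{ADP}/K_i) +
\mathrm{ATP}},
$$

with the ISWI in vitro constants $K_m = 0.15$ mM and $K_i = 0.1$ mM as
defaults. Mixed inhibition is plausible for these enzymes but is out of
scope; the competitive form is the computed model.
`phase_correlation()` correlates two 24-point cycle profiles and obtains a
two-sided p-value from cyclic rotations over the 24 grid offsets, which
respects the strong autocorrelation of smoothed profiles (a t-based p
would be wildly anticonservative there).

## The synthetic-data generator

`synth_config()` / `simulate_dataset()` generate a full synthetic
experiment under one seed. The defaults encode the study conditions:

* 67-min period, 6-min sampling, three cycles (33 arrays); oxidative
  fraction 94°/360°;
* a gene-dense chromosome (60 genes of ~1 kb, alternating strands), a
  nucleosome-depleted region centred 75 bp upstream of each TSS, a +1 dyad
  at +75 bp and a 165-bp repeat to the gene end, one −1 dyad upstream;
  probe pairs every 32 bp (the 360K whole-genome array implies ~33 bp;
  the exact layout is unpublished, so this is an assumption);
* class-specific occupancy dynamics as circular von Mises bumps: gene-body
  peaks at 60° and 225°, TSS/NDR-flanking peaks at 75°, 225° and 330°,
  NDR minima at 45° and 240°. The bump shape is a design decision — the
  source shows peaks but no functional form;
* log2 amplitudes of 1 (GB, TSS) and −1 (NDR). These are anchored to the
  one quantitative constraint available: in the real dataset only 6.35% of
  probes had across-array variance below 0.1, so realistic per-probe
  temporal variance must exceed 0.1 log2², which requires amplitudes of
  this order. It also makes the zero-noise least-variant set exactly the
  static intergenic probes, which the exact-inversion property
  presupposes;
* intensities are positive and analysed in log2, so all intensity noise is
  multiplicative lognormal (`noise_sd`, default 0.2 log2); per-array scale
  factors (`scale_sd`) are off by default and switched on by the
  normalization fixtures;
* ATP 21–51 mM peaking at 60° in the oxidative phase, ATP:ADP traversing
  1.2–8 log-symmetrically, AMP set so the energy charge traverses
  0.65–0.9 (metabolite noise defaults to zero so configured ranges are
  exact; the sampled extrema sit within 1% of the bounds because 33
  samples over three cycles cover phase densely);
* cluster-phased transcripts (A/AB/B oxidative at 30/45/60°, C/D reductive
  at 200/250°) with a shared transient bump at 225°;
* a 10 Hz NAD(P)H trace = respiratory fundamental + harmonics 2–4, plus a
  drift component placed exactly one DFT bin below the band and
  high-pass-filtered noise strictly above 4× the fundamental, so the
  band-pass analysis is exactly invertible on it;
* the DO waveform is constructed from a von Mises derivative pair so its
  derivative extrema sit exactly at phases 0° and 94°, which makes the
  true phase–time map linear and the generator's truth directly
  comparable to the pipeline's phase assignment. One lead cycle is
  prepended and appended so every array sample lies inside the anchored
  span.

What the generator does **not** emulate: sequence-level structure (no
FASTA, the MNase bias is a per-position draw rather than a GC model),
probe-specific noise heterogeneity, gene-to-gene phase dispersion within a
class, ChIP-qPCR chemistry, and the irregular anchor-to-anchor period
jitter of real cultures. Passing tests therefore demonstrate correctness
of the computations under the stated statistical structure, not robustness
to every pathology of real arrays.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF convention); BED
  half-open coordinates are converted at the boundary by `rtracklayer`.
* Strand averaging happens after normalization, matching the stated order
  of the source procedure.
* The LOESS fit subsamples at most 3000 LVS probes (evenly along the
  reference) and evaluates through a 256-point interpolation grid; probes
  outside the LVS reference range get the boundary correction.
* `fit_cycle()` with constant input short-circuits to a constant profile;
  `df` larger than the number of observations is an error.
* Anchor detection fails loudly on flat or non-oscillatory derivatives
  (Fisher-type tail bound, p > 10⁻³); ties at extrema resolve to the
  earliest time.
* Problem sizes in the tests — 20–60 genes, ~3–6 thousand probe pairs,
  33 arrays, 500-replicate calibration loops — were chosen as the smallest
  sizes at which medians and rejection-rate estimates are stable.

## Known limitations

* The "major period" of multi-peaked waveforms is reported as the raw
  dominant bin, by design; users wanting the fundamental should inspect
  the harmonic structure or use a single-peak reference signal.
* LVS selection assumes some genuinely static probes exist and that
  per-array distortions stay inside the variance-threshold envelope.
* The dyad-to-gene assignment resolves ambiguity by TSS distance with a
  documented tie-break; in compact genomes a dyad between two close TSSs
  can be assigned differently than manual curation would.
* Correlations between energy state and transcription-rate profiles are
  reported with cyclic-permutation p-values over only 24 offsets, so the
  smallest attainable p is 1/24.
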