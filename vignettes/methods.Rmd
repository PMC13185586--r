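---
title: "Exposure profiling and crosslink transition analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure profiling and crosslink transition analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptclickseq)
```

## The two assays this package models

Partially disassembled icosahedral virus particles expose only part of
their packaged RNA genome. Two sequencing readouts probe this state
without disrupting it:

1. **Particle-templated, randomly primed, azido-terminated libraries.**
   A random hexamer can anneal only to solvent-exposed RNA; reverse
   transcription extends it until a chain-terminating 3'-azido
   nucleotide is incorporated. The terminated cDNA is click-ligated to
   an adapter carrying a 12-nt unique molecular identifier (UMI).
   Per-position read coverage, *ratiometrically normalised* to the
   segment's total depth, therefore reports relative RNA accessibility,
   and the 5'-most genomic coordinate of the trimmed R2 mate recovers
   the exact priming site. Heating particles through a temperature
   series turns the per-region coverage trend into an estimate of the
   energy barrier that region must overcome before release.

2. **Photoactivatable-ribonucleoside crosslinking (4SU).** 4-thiouridine
   incorporated into the genome crosslinks under UV to directly
   contacting capsid residues. Reverse transcriptase reads through the
   adduct but inserts G opposite the crosslinked U, so U-to-C
   transitions in the final library mark RNA-protein contact sites. The
   per-U signal is the fold change of the transition rate between
   crosslinked (CL+) and non-crosslinked (CL-) samples.

The package implements both readouts end to end on synthetic or
pre-aligned data for small (&le; 5 kb) segmented references, plus a
generative simulator so every stage is testable without external
sequencing data.

## The generative model

**Exposure.** Each responsive region has a logistic accessibility curve
$e(T) = b + a/(1 + \exp(-(T - T_{50})/k))$ with baseline $b$, amplitude
$a \le 1 - b$, midpoint $T_{50}$ (the "energy barrier", in &deg;C) and
width $k$. Real disassembly data only demonstrates region-specific
thresholds empirically; the logistic is the minimal monotone form with
an interpretable midpoint. Overlapping regions combine by position-wise
maximum; unlisted positions get a constant default.

**Priming.** The hexamer anneals over $[p+1, p+6]$; the anchor $p$ (the
position immediately 5' of the hexamer on the genome sense) is drawn
with probability proportional to the mean exposure over that window.
Anchors require $p + 6 \le L$ and $p \ge$ the minimum fragment length.

**Termination.** With a 1:5 terminator:extender ratio and no polymerase
discrimination, each extended nucleotide terminates with probability
$p_\mathrm{term} = 1/6$ (a discrimination multiplier is exposed as
`az_bias`). Fragment length is $\min(m + G,\ p)$ where $G$ is geometric
and $m = 20$ the minimum usable length — extension cannot run past
position 1, and shorter molecules are never rendered.

**Reads.** R1 = 12-nt UMI + sense sequence from the fragment 5' end; R2
= 7-nt prefix (reverse-complemented hexamer + 1 buffer base) + antisense
sequence from $p$ downward; both capped at 75 nt. Converted U positions
read C on the sense strand. PCR duplication replicates molecules
(sharing UMI, coordinates and conversion state) with independent
sequencing errors per copy, drawn uniformly at `p_err` per base over the
whole read, UMI included.

**Crosslinking.** Designated reference-T positions convert with
probability $p_{xl} + p_{bg}$ in CL+ and $p_{bg}$ in CL- libraries.
`p_err` sits in `library_params()` (it is a property of sequencing, not
of the crosslink chemistry).

## Read processing

The reference is small, so the external trim/align/dedup/pileup chain is
replaced by native equivalents with explicit contracts and counters:

- **Alignment** is exact k-mer seeding (k = 12; offsets 1, 1+k, 1+2k and
  the read tail) followed by full-length ungapped comparison on both
  strands; best placement by mismatch count, ties broken by segment
  order, then leftmost coordinate, then plus strand; unaligned above a
  10 % mismatch fraction. A read whose every seed window carries an
  error can be missed and is counted unaligned; for reads of 36 nt or
  more, any two substitutions still leave one exact seed. Quality
  scores are ignored (synthetic reads have uniform quality; transition
  calling uses depth masking instead).
- **Deduplication** keeps the first molecule per (segment, R2 anchor,
  UMI) key — PCR duplicates share both the UMI and the priming anchor
  under the library model. An optional 1-mismatch UMI clustering mode
  exists but is off by default.
- **Pileup** counts each molecule's merged mate footprint once; base
  calls in the mate overlap come from R1. Antisense (R2) base calls are
  complemented into sense orientation at alignment time. Depth is the
  row sum by construction.
- **Conservation**: parsed = dropped + unaligned + aligned is asserted
  by tests at every stage.
- Coordinates are 1-based inclusive everywhere internally; conversion
  to 0-based half-open happens only at the bedGraph boundary and is
  round-trip tested. SAM export/ingest uses umi-tools-style `name_UMI`
  read names, pure-`M` CIGARs, and recomputes mismatches from SEQ
  against the reference; indel or clipped records are rejected with
  counts.

## Analysis statistics

- **Coverage**: percent of segment total depth per position (a warning,
  and all-zero percents, for an uncovered segment). Normalisation is
  per segment because the two genome segments are reported separately.
- **Priming**: percent of retained molecules anchored per position.
- **Window statistics**: percent-of-length (one decimal, the precision
  such windows are conventionally quoted at) and percent-of-coverage
  (full precision internally).
- **Moving averages** use centered windows that shrink at segment edges
  (no padding or wrap-around — the segment is linear); a window wider
  than the track collapses to the global mean with a warning.
- **Trend classes** over a temperature series: a window is `increasing`
  / `decreasing` when Spearman |rho| vs temperature &ge; 0.7 **and**
  relative dynamic range (max−min)/max &ge; 0.25; `flat_low` when the
  range is < 0.25 and the mean share sits below the uniform expectation
  (its percent of length); otherwise `fluctuating`. The range condition
  on the directional classes is this package's choice: ratiometric
  normalisation makes every non-responsive window drift slightly
  downward whenever any region rises, and rank correlation is blind to
  magnitude, so a pure-rho rule would misclassify essentially flat
  backgrounds as decreasing. All thresholds are configurable.
- **Transition rates**: C count / depth at reference-T positions with
  depth &ge; 1000 deduplicated molecules (the conventional floor);
  positions below threshold are masked (NA), never silently zero, and a
  position masked in *any* replicate of either condition is excluded
  from the signal entirely.
- **Signal**: (mean CL+ rate + pseudo)/(mean CL- rate + pseudo), with
  pseudo = 1/min_depth by default (a one-molecule equivalent, scale-free
  with the mask). Replicates are averaged as rates, not pooled counts,
  matching how replicate experiments are averaged in practice; a
  pooled-count mode can be had by summing pileups before calling.
- **K-S tests** compare the two conditions' per-U mean rates: D is the
  maximal ECDF gap over the pooled support (tie-correct), the p-value is
  exact (`stats::psmirnov`, tie-aware) for n&middot;m &le; 10000 and the
  asymptotic Kolmogorov series otherwise.
- **Correlations** (Pearson/Spearman) run over the intersection of
  unmasked positions with the usual t-distribution p-value — for a
  simple correlation this equals the one-way-ANOVA F-test p reported in
  the field. Constant inputs give a flagged undefined result, not NaN.
- The priming-vs-contact comparison smooths the priming percent track
  with a 15-nt moving average and uses Spearman correlation; coverage
  maps use 50-nt smoothing.

## The bundled calibration worlds, and what a green test establishes

The simulator is a *stated world*, not a dial; its defaults encode the
conditions the calibration suite asserts against, chosen once:

- `demo_exposure_world()`: 3000-nt segment; background accessibility
  varies sinusoidally (0.35–0.55 in 100-nt strips, temperature-flat);
  two planted 100-nt barrier regions at $T_{50}$ = 55 and 65 &deg;C with
  k = 6 and amplitude 0.5; 100k fragments per temperature. Two design
  constraints force this shape. First, *tie attenuation*: against a
  flat background the truth profile is two-valued, and Spearman
  correlation against a noisy estimate is then capped near 0.45 for
  small planted fractions regardless of data quality; a continuous
  background gradient removes the ties. Second, *ratiometric
  see-saw*: a region that saturates early loses share when a later
  region rises, so narrow logistic transitions would make the early
  region's share non-monotone; wide transitions (k = 6) and a
  high-mass background keep both planted shares monotone and background
  shares flat.
- `demo_crosslink_world()`: 500-nt segment with exactly 50 U positions,
  20 of them crosslink sites ($p_{xl}$ = 0.4 over $p_{bg}$ = 0.01), read
  at uniform exposure to depth &ge; 2000 (4+4 replicates for detection,
  2+2 for the null). The low U count is deliberate: a two-sample K-S
  test on per-U rates can only reach p &lt; 0.01 with 20 shifted
  positions if the total U count is &le; ~75 (D &approx; 20/n must beat
  ~1.63&radic;(2/n)); real analyses pool far more crosslink sites. The
  segment is synthetic and labelled as such.
- `demo_anticorrelation_world()`: 2000-nt segment, half of it exposed
  (0.5 vs 0.05), 100 crosslink sites placed either exclusively outside
  the exposed half or uniformly. With ~500 usable U positions this
  yields Spearman &rho; &approx; −0.3 for exclusion and |&rho;| &lt;
  0.05 for uniform placement; fewer sites or a smaller exposed fraction
  provably cap the effect below detectability.

What the simulator does **not** emulate: GC or hexamer composition
bias, RNA secondary structure, capsid geometry, quality-score
distributions, antisense RNA, adapter read-through. A green calibration
run establishes that the statistics recover what this generative model
plants — not that the model captures every bias of real libraries.
Real data can enter mid-pipeline through `ingest_sam()`.

Two further numerical notes. The uniform-coverage null is asserted on
100-nt windows tiling the *priming-competent interior* (from position
80 to ~186 nt before the segment end, shares renormalised within the
tiled range): the generative chemistry itself has no anchors past
$L-6$ and truncates extension at position 1, so terminal windows are
mechanistically, not statistically, below the uniform expectation.
And repeated 20-run calibrations use the simulator's truth molecules
directly (skipping render/parse/align), while the detection run
exercises the full reads route once; dedicated closure tests show the
two routes agree exactly on error-free data and recover &ge; 99 % of
(terminus, anchor) pairs at a 0.5 % error rate.

## Reproducibility

Every pipeline run is reproducible from its config alone: the master
seed spawns one sub-seed per simulation stage (so the truth and reads
routes draw identical fragments), the manifest records all parameters,
and rerunning a config byte-identically reproduces the truth tables and
report numbers.

## Known limitations

- The aligner is ungapped by design; indel-bearing reads are rejected
  (counted) rather than realigned. Large references would need a real
  seed-and-extend aligner.
- Exact K-S p-values fall back to the asymptotic series for large
  samples; with heavy ties the asymptotic p is conservative.
- The 1-mismatch UMI clustering mode is greedy (count-ordered), not the
  full directional network algorithm.
- Single-end mode is not implemented; the priming-site readout requires
  the paired-end R2 geometry.
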