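# ptclickseq

Profiling genomic RNA exposure in partially disassembled virus
particles, and mapping RNA–capsid contacts, from sequencing data — with
a full generative simulator so every stage runs and is testable on
synthetic data.

## The problem

Non-enveloped icosahedral viruses (the package's model system is a
bipartite nodavirus: segments RNA1, 3107 nt, and RNA2, 1400 nt) release
their genome through ordered, step-wise disassembly. Two sequencing
readouts probe that process:

- **Particle-templated, randomly primed, azido-terminated libraries.**
  Random hexamers can only anneal to solvent-exposed RNA; reverse
  transcription is stochastically terminated by 3'-azido nucleotides
  (1:5 terminator:extender, so termination probability 1/6 per
  nucleotide), and the cDNA is adapter-ligated with a 12N unique
  molecular identifier (UMI). After UMI deduplication, per-position
  coverage *ratiometrically normalised to the segment's total depth*
  reports relative RNA accessibility, and the 5'-most coordinate of the
  trimmed R2 mate is the exact priming site. Across a disassembly
  temperature series (50–75 °C), each region's coverage trend reveals
  the energy barrier it must overcome before release.
- **4-thiouridine crosslinking (CL+/CL−).** UV crosslinks incorporated
  4SU to contacting capsid residues; reverse transcriptase inserts G
  opposite the crosslinked U, so U→C transitions mark contact sites.
  The per-U signal is
  `(mean CL+ rate + ψ) / (mean CL− rate + ψ)` with pseudocount
  ψ = 1/min_depth, computed only where every replicate clears a
  1000-molecule depth mask. Conditions are compared by two-sample
  Kolmogorov–Smirnov tests on per-U mean rates; priming density
  (15-nt smoothed) versus signal quantifies whether release avoids
  contact sites (Spearman ρ).

The package implements, natively for ≤5 kb references: paired FASTQ
parsing, UMI extraction and R2 prefix trimming (hexamer + 1 buffer
base), k-mer-seeded ungapped alignment, exact-key UMI deduplication,
pileup, coverage/priming statistics, trend classification, transition
calling, signal tracks, and an end-to-end pipeline driver — plus the
simulator (logistic per-region exposure, hexamer-window priming,
truncated-geometric termination, PCR duplication, crosslink
conversions, sequencing error). Externally aligned data can enter
mid-pipeline via `ingest_sam()`.

## Worked example

Simulate a temperature series with one planted barrier region
(T50 = 57 °C) on a 600-nt segment, process it, and classify trends:

```r
library(ptclickseq)
set.seed(7)
ref <- random_genome(c(S1 = 600L))
cfg <- run_config(
  ref = ref,
  barrier = barrier_model(data.frame(segment = "S1", start = 100, end = 250,
                                     b = 0.1, a = 0.6, t50 = 57, k = 2),
                          default_exposure = 0.1),
  params = library_params(n_fragments = 20000L),
  temperatures = c(50, 55, 60, 65, 70),
  regions = c("S1:100-250", "S1:300-450"),
  route = "truth", seed = 7L)
bundle <- run_pipeline(cfg)
subset(bundle$window_stats, region == "S1:100-250")
#>       region temperature pct_of_length pct_of_coverage
#> 1 S1:100-250          50          25.2        29.69629
#> 2 S1:100-250          55          25.2        44.73330
#> 3 S1:100-250          60          25.2        62.44327
#> 4 S1:100-250          65          25.2        64.62332
#> 5 S1:100-250          70          25.2        64.84669
bundle$trends[c("region", "class", "rho", "dynamic_range")]
#>       region      class rho dynamic_range
#> 1 S1:100-250 increasing   1     0.5420538
#> 2 S1:300-450 decreasing  -1     0.5882149
region_fold_change(bundle$series, "S1:100-250", 50, 60)$ratio
#> [1] 2.102176
```

The planted region occupies 25.2 % of the segment but collects 29.7 %
of coverage already at 50 °C (its baseline exposure matches the
background, the excess is its share of the hexamer-window smoothing),
rising to 64.8 % once the barrier is crossed — class `increasing`. The
non-responsive window's *share* necessarily falls as the planted region
rises (ratiometric normalisation), here strongly enough to classify as
`decreasing`.

Crosslink detection on the bundled 50-U calibration world (20 planted
sites, p_xl = 0.4 over a 0.01 background, two replicates per
condition):

```r
world <- demo_crosslink_world()
set.seed(11)
rates <- function(cond) {
  fr <- simulate_fragments(world$ref, world$profile, world$xl, world$params, cond)
  mol <- dedup_molecules(truth_molecules(fr, world$params))
  transition_rates(build_pileup(mol, world$ref), world$ref, world$min_depth,
                   condition = cond)
}
plus <- lapply(1:2, function(i) rates("CL+")); minus <- lapply(1:2, function(i) rates("CL-"))
signal <- vparcl_signal(plus, minus)
ks_compare(rowMeans(sapply(plus, `[[`, "rate")),
           rowMeans(sapply(minus, `[[`, "rate")))[c("D", "p_value")]
#> $D        [1] 0.48
#> $p_value  [1] 1.408e-05
threshold_signals(signal, 1.5)$n_unmasked
#> [1] 50
```

All 20 planted sites exceed the 1.5 signal cutoff (median planted
signal 37.1 versus 1.06 for background U positions) and the K-S test
separates the conditions at p ≈ 1e−05.

A command-line driver with `simulate`, `process` and `all` subcommands
lives at `inst/cli/ptclickseq.R` (JSON config; see its header).

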