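# depcr

Quantifying primer–template interactions in amplicon PCR with a
deconstructed-PCR (DePCR) measurement model.

## The problem

Degenerate primer pools amplify mixed templates unevenly: mismatches between
a primer and a template's priming site — especially near the primer 3′ end —
suppress annealing and extension, distorting the template ratios in the
final amplicon pool (PCR bias). Standard PCR cannot reveal *which* primer
annealed to *which* source template, because after the first cycles primers
anneal to amplicon copies whose priming sites carry earlier primers'
sequences: the signal is scrambled toward the input primer proportions.
DePCR separates two cycles of linear copying (locus-specific primers) from
exponential amplification (linker-targeting primers), so every read retains
the primer that annealed to the original template.

`depcr` implements this measurement system in silico for R users studying
amplicon PCR bias: a combinatorial design space of synthetic templates and
primer variants, simulators for both amplification regimes, an exact-match
read classifier, and the system's metrics.

## The model in brief

* **Design space.** A 20-base forward priming site varies at three positions
  (−14 "5′", −8 "M", −2 "3′" from the 3′ end), giving 64 primers (V0–V63);
  10 templates (ST0–ST9) carry the triples of V0–V9 plus a unique 12-base
  recognition sequence (pairwise Hamming distance ≥ 4) at offset 99 from
  the priming-site start, so 640 primer×template interactions are
  distinguishable by exact matching.
* **Annealing efficiency.** Each mismatch contributes a penalty
  e ∈ (0, 1] keyed by position, temperature and base pairing;
  profile efficiency is the product. Defaults (from equimolar head-to-head
  calibration): 5′ 0.65/0.21, M 0.54/0.155 (C-A pairing 0.36/0.10),
  3′ 0.13/0.01 at 45/55 °C.
* **DePCR.** Copy events are multinomial over pairs with probability ∝
  template proportion × primer proportion × efficiency; the recorded pair
  is immutable afterwards.
* **Standard PCR.** Branching over (origin template, current site-triple)
  classes for 28 cycles; copies inherit the priming primer's triple, and
  copy annealing is either mismatch-independent ("neutral", the default)
  or efficiency-weighted ("penalized").
* **Metrics.** Ideal Score `IS = Σ|100·obs − 100·exp|` ∈ [0, 200]
  (= 200 × Bray–Curtis on proportions), applied to template margins (ITS,
  distortion of input template ratios) and primer margins (IPS, selectivity
  of primer use); mismatch ratio (mismatch counts / perfect-match counts,
  0 … ∞); positional error-rate windows; Bray–Curtis + classical MDS;
  Welch t and ANOVA/Tukey comparisons with star labels.

## Worked example

Amplify the single template ST0 with ten equimolar primers (one perfect
match, nine single mismatches) using DePCR at 45 °C, classify the simulated
reads, rarefy to 7000, and score the result:

```r
library(depcr)

design <- default_design()
cfg <- experiment_config("A10", method = "depcr", temperature = 45,
                         n_replicates = 4, reads_per_replicate = 20000,
                         error_preset = "none", seed = 42)
run <- run_experiment(cfg, design = design)
print(run$metrics, digits = 3)
#>   replicate its  ips mismatch_ratio
#> 1      rep1   0 48.4           3.69
#> 2      rep2   0 48.3           3.75
#> 3      rep3   0 48.3           3.73
#> 4      rep4   0 48.8           3.77

usage <- colSums(split_matrix(run$rarefied)$primer)
round(100 * usage / sum(usage), 1)
#>   V0   V1   V2   V3   V4   V5   V6   V7   V8   V9
#> 21.1 13.5 13.5 13.6 11.1  7.5 11.4  2.6  2.8  2.9
```

Read: with one template there is nothing to distort (ITS = 0), but primer
use is strongly selective (IPS ≈ 48): the perfect-match primer V0 takes 21%
of copy events instead of its 10% input share, 5′-mismatch primers (V1–V3)
are well tolerated, and 3′-mismatch primers (V7–V9) make under 3% of copies
each. The mismatch ratio ≈ 3.7 equals the sum of the nine single-mismatch
penalties at 45 °C, as the closed form predicts. Comparing against the same
run at 55 °C:

```r
run55 <- run_experiment(experiment_config("A10", method = "depcr",
           temperature = 55, n_replicates = 4, reads_per_replicate = 20000,
           error_preset = "none", seed = 42), design = design)
cmp <- group_comparison("mismatch_ratio",
                        list(`45C` = run$metrics$mismatch_ratio,
                             `55C` = run55$metrics$mismatch_ratio))
#> Welch t = 128.58, df = 5.5, p = 7.9e-11 (****)
```

Higher annealing stringency collapses mismatch tolerance. The same
machinery runs the other pool designs (`"B1"`, `"B27"`, `"C64"`, …), the
paired-primer competition grid (`run_head_to_head()`), and standard-PCR
comparisons (`method = "standard"`).

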