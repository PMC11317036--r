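---
title: "Modelling primer-template interactions with deconstructed PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling primer-template interactions with deconstructed PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcr)
```

## The problem

When a pool of primers amplifies a mixture of templates, mismatches between
primer and template distort the final amplicon pool ("PCR bias"). Standard
PCR makes the mechanism hard to observe: after the first cycles, primers
anneal to amplicon *copies*, and a copy's priming site carries the sequence
of whichever primer created it, not the original template's site. The
primer-usage signal is progressively *scrambled* toward the input primer
proportions. Deconstructed PCR (DePCR) separates two cycles of linear
copying of source templates from the later exponential amplification, which
targets linker sequences instead of the locus. The primer that annealed to
the original template is therefore preserved in every read.

`depcr` implements this measurement system *in silico*: a synthetic design
space, stochastic simulators for both amplification regimes, an exact-match
read classifier, and the associated metrics, so that each class of result
the system produces can be exercised and tested at desk scale without
sequencing data.

## The design space

Templates and primers share a 20-base forward priming site
(`GGACTACCAGGGTATCTAAT` as reference) that varies only at three positions:
-14 ("5p"), -8 ("M") and -2 ("3p") bases from the primer 3' end (string
positions 7, 13, 19, counting the terminal base as -1). Enumerating all
bases at the three positions gives 4^3 = 64 primers (`V0`-`V63`). Ten
templates (`ST0`-`ST9`) carry the variant triples of `V0`-`V9`, so each of
`ST1`-`ST9` has exactly one mismatch with `V0`. Every template also carries
a unique 12-base *recognition sequence* at offset 99 from the start of the
priming site, generated by rejection sampling under a minimum pairwise
Hamming distance of 4, so a read identifies its source template
independently of its primer region. Outside these windows the templates are
identical; the interior is seeded random sequence, fixed as a package
constant, with a 250-nt amplicon so merged 2 x 153 read pairs cover it.

Two conventions are worth stating because the source material is ambiguous
about them:

* **Recognition window.** The window is described both as positions 99-109
  (11 bases) and as a 12-base sequence. We use length 12 at 1-based offset
  99 (occupying 99-110); both offset and length are arguments to
  `build_template_set()`, so the 11-base reading is available.
* **Variant-base identities.** The base assignments of `V1`-`V6` follow the
  published order (5': G, T, A; middle: A, C, G). The 3' assignments are
  only available in supplementary material, so `V7`-`V9` take the
  alternatives to `A` alphabetically (C, G, T); `enumerate_primer_variants()`
  accepts an explicit id table to impose any other assignment. Remaining
  ids are assigned deterministically: grouped by mismatch count against the
  base core (so `V10`-`V36` are the 27 double mismatches and `V37`-`V63`
  the triples), by position combination (5'-most first), then bases in
  A < C < G < T order.

All 640 primer-by-template combinations, each annotated with its mismatch
profile, form the `interaction_space()` -- the mapping file used for
classification.

```{r design}
design <- default_design()
head(design$space[, c("pair_id", "n_mismatches", "mismatch_labels",
                      "mismatch_pairings")])
```

A mismatch *pairing* is written as the primer base against the complement of
the template's coding-strand base -- the two bases actually facing each
other in the annealed duplex.

## The annealing-efficiency model

Each mismatch contributes a penalty in (0, 1] keyed by position label and
annealing temperature, optionally refined by pairing; a profile's efficiency
is the product of its penalties, and a perfect match has efficiency 1. The
multiplicative composition is a model assumption (no composition rule has
been measured); a user-supplied penalty table overrides it implicitly by
assigning whatever per-position values are wanted.

The default calibration comes directly from the head-to-head measurement
design: with one perfect-match and one single-mismatch primer at equimolar
input, the expected mismatch-to-match ratio *is* the penalty. Midpoints of
the measured ranges give:

| position | 45 °C | 55 °C |
|----------|-------|-------|
| 5' (-14) | 0.65  | 0.21  |
| M (-8)   | 0.54 (C-A pairing: 0.36) | 0.155 (C-A pairing: 0.10) |
| 3' (-2)  | 0.13  | 0.01  |

Temperatures are model keys, not a thermodynamic axis: requesting an
uncalibrated temperature is an error rather than an interpolation.

## The two amplification regimes

**DePCR** (`simulate_depcr()`). Each copy event pairs one template molecule
with one primer with probability proportional to template proportion x
primer proportion x annealing efficiency. The recorded (primer, template)
pair is fixed at the event; the later linker-targeted exponential stage only
amplifies what was copied, so the per-replicate multinomial over pairs is
the final read-class distribution. Expected quantities have closed forms --
for a perfect-match primer competing with one single-mismatch primer of
penalty p, the expected mismatch fraction is p / (1 + p) -- and the test
suite checks the simulator against them.

**Standard PCR** (`simulate_standard_pcr()`). Molecule classes are (origin
template, current site triple). In every cycle the original templates are
linearly copied under the same efficiency rule as DePCR; from cycle 3
onward primers also anneal to existing copies, and a new copy's site triple
becomes the triple of the primer that made it. Copy priming is
mismatch-independent in `scrambling_mode = "neutral"` (probability
proportional to primer proportion) or efficiency-weighted against the
copy's site triple in `"penalized"` mode. The class dynamics are propagated
as expected values -- at the default 28 cycles the copy population is ~10^8
molecule equivalents, where the multinomial read sample at the end is the
only sampling noise that matters -- and reads report (primer implied by the
site triple, origin template).

Neutral mode is the default because it reproduces the observed behaviour of
standard PCR directly: the primer-usage distribution converges to the input
primer proportions (total-variation distance below 0.02 after 28 cycles in
the property tests), so with ten equimolar primers the perfect-match primer
ends up on ~10% of reads. Whether real primer-copy annealing is neutral or
penalized is not settled by the measurements the model is calibrated to;
both modes are exposed.

Modelling choices, stated once:

* Primer concentrations are non-limiting (proportions constant over
  cycles); no saturation ceiling is applied.
* Original templates remain priming targets in every cycle. The
  alternative (originals retired after cycle 2) differs negligibly because
  the copy population grows exponentially, but keeping them matches the
  physical reaction.
* Strand identity and the constant reverse site are not tracked: reverse
  priming is efficiency 1 for every template, and the two barcode-attachment
  cycles of DePCR stage 1 are pure bookkeeping (they add adapters but
  cannot change the recorded pair).
* One root seed drives everything; per-replicate streams are derived as
  `derive_seed(root, k) = (root + 7919 k) mod (2^31 - 1)`, with emission
  and rarefaction streams at documented counter offsets, so replicates are
  independent but every run is reproducible.

## Reads and errors

`emit_reads()` writes one merged read per counted event: the primer core
followed by the template body, so reads begin at the priming site and span
the amplicon. Substitution errors (`apply_errors()`) are independent
per-base events to a uniformly chosen different base; the per-base rate
stands in for polymerase plus sequencing error. The crucial asymmetry is
preserved: in DePCR the primer region of a read is a *copy* of the oligo
and receives errors like every other base, while in standard PCR it is the
synthetic oligo itself and is emitted error-free. This reproduces the
diagnostic error-rate signature -- primer-window (bases 1-20) error above
the downstream windows in DePCR, zero in standard PCR. Error-rate presets
for the experiment runner: `MT` (non-proofreading) 0.010/base, `DT`/`QB`
(phosphorothioate-protected) 0.004/base. Qualities follow a two-tier model
(constant Phred per read, default Q37 with an optional low-quality
fraction); indels, chimeras and quality-dependent miscalls are out of the
error model.

`split_read_pairs()` and `merge_pairs()` exercise the paired-read path: a
gap-free overlap merger that maximizes matches minus mismatches over
overlaps of at least `min_overlap` bases with at most a 25% disagreement
fraction, resolving disagreements toward the higher-quality base.

## Classification and the observation matrix

`classify_reads()` assigns a read if and only if its primer region matches
exactly *and* its recognition window matches exactly; there is no error
tolerance. Two modes reflect the two analysis pipelines the system
supports: `full_primer` (all 20 primer bases must match a core) and
`variant_positions` (only the three variant bases must match a triple).
Reads are otherwise labelled `filtered_quality` (mean Phred below 20, the
filter applied first; the boundary is inclusive, so a mean of exactly 20 is
retained), `unassigned_primer`, `unassigned_recognition` (also used for
reads too short to reach the window), or `excluded_not_in_design` for legal
pairs outside the experiment's pools -- exclusion happens before
rarefaction. Every input read lands in exactly one category, which the
tests assert as a conservation law.

`build_interaction_matrix()` collates assigned reads into a replicates x
pairs count matrix carrying the per-status accounting; `rarefy()`
subsamples each replicate without replacement (vegan's `rrarefy`) to a
fixed depth, default 7000, dropping and reporting replicates below depth;
`split_matrix()` sums the matrix to its 10-column template margin and
64-column primer margin.

## Metrics

* **Ideal Score** (`ideal_score()`): `IS = sum(|100 o_i - 100 e_i|)` over
  features, with observed and expected vectors normalized to proportions --
  percent units, so the range is 0 (exact recovery) to 200 (disjoint
  support). On proportion vectors `IS = 200 x` Bray-Curtis, which the tests
  use as a cross-check against vegan. The **ITS** scores a template margin
  against the *input pool concentrations* (not uniform -- an uneven pool
  recovered exactly scores 0); the **IPS** scores the primer margin against
  the input primer ratios. A uniform expectation is available via
  `uniform_expectation = TRUE`.
* **Mismatch ratio** (`mismatch_ratio()`): counts on mismatched pairs over
  counts on perfect-match pairs; 0 when only perfect matches were used, and
  `Inf` (a typed sentinel, serialized as the string `"Inf"`) when mismatch
  counts exist but no perfect-match pair was counted -- the designed
  outcome for the 27-primer pool, which contains no perfect match for any
  template.
* **Error profile** (`error_profile()`): per-position mismatch fractions of
  reads against their truth references (the template with the true primer
  substituted at the site), averaged over 1-based inclusive windows,
  default 1-20 / 21-40 / 41-100. Alignment is gap-free since the error
  model is substitution-only.
* **Ordination and diversity**: Bray-Curtis via vegan, classical MDS via
  `cmdscale` with axes ordered by eigenvalue and a fixed sign convention
  (first above-tolerance loading on each axis positive, tolerance 1e-8;
  coincident points embed at the origin), Shannon diversity and richness.

## Statistics and reporting

Group comparisons use Welch's two-sample t-test (two-sided,
Welch-Satterthwaite degrees of freedom, no multiple-comparison correction)
and one-way ANOVA with Tukey HSD for three or more groups, with the
five-level star labelling: `ns` (p >= 0.05), `*` (< 0.05), `**` (< 0.01),
`***` (< 0.001), `****` (< 0.0001). `experiment_report()` bundles manifest
(echoed verbatim, plus an MD5 hash), matrix summaries, tidy metrics and
comparisons into JSON/TSV; regeneration from the same inputs is
byte-identical.

`run_experiment()` drives the whole pipeline from an `experiment_config()`
-- an id like `"B27"` names the template pool (A-E) and primer pool
(1/9/10/27/64); defaults are 8 technical replicates, 20,000 reads per
replicate (so rarefaction at 7000 always succeeds), 2 DePCR or 28 standard
cycles. `run_head_to_head()` reproduces the paired-primer competition grid
(default 4 replicates) with Welch comparisons between temperatures. These
functions, rather than a shell wrapper, are the package's orchestration
interface.

```{r headtohead}
hh <- run_head_to_head(mismatch_primers = c("V1", "V7"),
                       reads_per_replicate = 5000, seed = 2)
hh[, c("primer", "temperature", "position", "pairing",
       "mean_ratio", "expected_ratio", "stars")]
```

## What the generator does and does not emulate

The synthetic generator reproduces the *designed* structure of the
measurement system: the combinatorial priming-site space, recognition
barcoding, pool compositions (including the uneven C/D/E pools), both
amplification regimes, replicate structure, substitution error, and read
geometry. Passing tests therefore demonstrate that the pipeline measures
what the design intends under the stated model. They do not demonstrate
robustness to features of real sequencing data that are deliberately out of
the model: indels and chimeric reads, position- and cycle-dependent quality,
primer synthesis errors, saturation kinetics, pipetting stochasticity
beyond multinomial sampling, or template secondary structure. The headline
empirical values from the sequencing runs themselves (ITS tables, B-series
mismatch ratios, absolute error percentages) are calibration anchors for
the defaults, not quantities the simulator is claimed to predict.

One model-dependent caveat deserves emphasis. The observed DePCR advantage
(lower ITS than standard PCR) emerges in this model through *penalized*
primer-copy annealing, and only when the primer pool contains competing
primers of unequal match to the templates (the B10 design): cohorts of
copies descending from different templates then grow at different rates,
compounding distortion over 26 exponential cycles -- ITS roughly 18-26 for
DePCR versus 42-45 for standard PCR in the packaged property test. With a
single primer (B1) the model predicts *equal* distortion for both methods
(the closed forms coincide), and with the all-mismatch 27-primer pool at
stringent annealing the one-shot DePCR selection can exceed the small
copy-growth differences. Real reactions show DePCR winning across all
three designs, so mechanisms outside this model (early-cycle stochasticity,
saturation, strand-level effects) evidently contribute; quantifying them
is beyond what desk-scale simulation can support.

## Problem sizes and numerical choices

The packaged tests run the simulators at 10^5 events where a percentage is
checked against a closed form (binomial/delta-method 3-4 sigma bands),
2,000-20,000 reads per replicate elsewhere, 10^4 reads for the
classifier-versus-brute-force identity, 500-10^4 random vector pairs for
the Ideal Score properties, and 100 seeds for the rarefaction
unbiasedness check. Proportion vectors must sum to 1 within 1e-9 after
normalization; all-zero abundance vectors, empty count rows, degenerate
variances and infeasible recognition constraints raise errors naming the
constraint rather than returning sentinel values.
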