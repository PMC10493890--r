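---
title: "Sort-seq screening of saturation libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-seq screening of saturation libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
```

## The problem

Whole-cell biosensors for buried explosives couple a transcriptional
regulator that senses 2,4-dinitrotoluene (DNT, the volatile signature of
TNT-filled landmines) to a fluorescent or bioluminescent reporter.
Improving the regulator — a 298-residue LysR-type transcription factor —
by screening individual colonies explores only a vanishing fraction of
sequence space. A *focused saturation library* instead diversifies a small
set of residue positions known to matter (here six: 31, 87, 154, 162, 233
and 274) to all 20 amino acids, giving a 20^6 = 6.4 × 10⁷ variant space
that fluorescence-activated cell sorting (FACS) can actually traverse.
`sortscreen` implements the full computational side of such a campaign:

1. **library design** — enumerate or sample the variant space and
   synthesize codon-sampled, GC-constrained DNA for any variant;
2. **sort-seq simulation** — a generative model of the experiment
   (induction, gating, multi-round sorting, amplicon sequencing,
   plate-reader kinetics) used both for power analysis and for testing the
   analysis code against known ground truth;
3. **flow analysis** — gating, selection, MFI, sorting statistics and
   library-coverage arithmetic;
4. **enrichment** — decoding variant keys from reads and computing
   per-variant and per-position log2 enrichment;
5. **dose-response** — EC200, ΔRLU and time-to-ratio-2 metrics and
   cross-strain fold changes.

## Library design

A `saturation_design` is a template protein plus an ordered set of 1-based
diversified positions. Residue coordinates are 1-based throughout,
matching mutation nomenclature (L31M means leucine 31 to methionine); they
are converted to nucleotide coordinates once, inside the decoder. A
variant is identified by its *key*: the residues at the diversified
positions, e.g. `"MVTFRV"` for the sextuple mutant
L31M/D87V/M154T/I162F/Q233R/A274V.

The actual regulator sequence is not bundled; `synthetic_template_protein()`
generates a deterministic synthetic 298-residue stand-in whose six
canonical positions carry the wild-type residues (L, D, M, I, Q, A), so
that all position arithmetic and nomenclature behave exactly as for the
real protein. Conclusions about the real protein's biology obviously do
not transfer; everything the package computes is sequence-generic.

### Codon sampling and the GC cap

Gene synthesis of the template failed on long GC-rich stretches in the
native gene, so the package regenerates genes by *codon sampling*: each
residue's codon is drawn independently with its relative frequency within
that amino acid's codon set (the bundled table is the standard E. coli
K-12 usage; any TSV with `codon`, `aa`, `fraction` columns can be
loaded). Stop codons are never sampled. The sampled gene therefore mirrors
the transcriptome-wide codon composition, which empirically keeps GC
content near 51%.

The GC constraint is implemented as a sliding-window cap: every
`window_nt` (default 100 nt, step 1) window must have GC ≤ `gc_cap`
(default 0.70). Offending windows have their codons resampled, up to
`max_retries = 10000` rounds, after which the constraint is declared
unsatisfiable with an error rather than silently ignored. The window
length is a design choice: the experimental report of "long high-GC
stretches above 70%" names no window, and 100 nt is the scale at which
synthesis vendors flag GC problems.

```{r design}
design <- example_design()
design
dna <- sample_codon_dna(design$template_protein, seed = 1, gc_cap = 0.70)
max(gc_windows(dna, 100))
```

## The generative sort-seq model

The simulator is first-class, tested code: its closed-form expectations
are what the analysis-side tests check against.

**Phenotype.** Each variant responds to DNT through a Hill function: mean
single-cell fluorescence at concentration $d$ is

$$\mu(d) = B\left(1 + (F-1)\frac{d^h}{d^h + K^h}\right)$$

with basal signal $B$ (default 100 a.u.), saturating induction fold $F$
(default 5), half-max concentration $K$ (default 10 mg/L, matching a
GFP-based assay whose detection limit sits in the low mg/L range), and
Hill coefficient $h$ (default 1.5). Cell-to-cell noise is multiplicative
log-normal with $\sigma = 0.3$ on the natural-log scale, mean-matched so
that the expected fluorescence equals $\mu(d)$. The Hill form is a
modeling choice — the experiment only establishes a dose-dependent
response — but it is the standard minimal model for an effector-activated
transcription factor.

**Pool.** `make_pool()` draws distinct keys with per-position *doping*:
the template residue appears with probability `wt_doping` (default 0.27,
the midpoint of the 25–30% per-site wild-type frequency observed in
synthesized doped libraries) and every other residue with probability
$(1-w)/19$. A configurable number of keys are designated true
high-performers: induction fold ×10 and half-max ÷5 by default, a
deliberately explicit effect size so that recovery tests have defined
signal. All other variants share the baseline phenotype; the simulator
does not include a separate constitutively-fluorescent class, so in
simulation the negative round prunes only the noise tail rather than true
false positives.

**Events.** Forward/side scatter are drawn from a correlated bivariate
log-normal *independent of genotype* — scatter gating is genotype-neutral
by construction, and a label-permutation test verifies that no gating or
counting step reads the ground-truth `source_key` column.

**Reads.** Amplicon reads are the reference gene with the six diversified
codons replaced by codons sampled for the variant's residues, plus i.i.d.
substitution errors. Indel and homopolymer error structure of real
long-read chemistry is deliberately out of scope; the decoder's
alignment fallback handles indels, but the error model does not generate
them.

**Plate kinetics.** Optical density follows logistic growth; per-cell
reporter signal is a basal component accumulating with a 120-min time
constant plus an induced component $B(F-1)\,h(d)$ that starts after a
40-min lag and accumulates with a 240-min time constant (inducer uptake,
transcription and reporter maturation are slower than the constitutive
background). This makes the DNT-free control positive at every observable
time (so induction ratios are well defined), drives the ratio
monotonically towards $1 + (F-1)h(d)$, and gives a finite
threshold-crossing time that decreases with induction strength. Well
noise in a plate reader averages millions of cells, so the scenario
default is $\sigma = 0.05$ at the well level, not the single-cell 0.3.

## Flow analysis

The scatter gate keeps the requested fraction of events closest (in
Mahalanobis distance on log FSC/SSC) to the population centroid — a
density gate, defaulting to the 77% main-population gate. Fluorescence
selection is by GFP rank with stable tie-breaking and
`round(fraction * n)` count. In campaign statistics, `events_scanned`
counts events inside the scatter gate, so the reported collected
percentage equals the configured fluorescence-gate fraction; the raw
event count is kept in `events_total`. (In the motivating campaign's
published statistics, the later rounds' printed percentages cannot be
reconciled with their printed counts under any single denominator; the
package therefore always exposes both counts and computes the fraction
explicitly.)

Library coverage uses the Poisson approximation
$1 - e^{-N/L}$ for the expected fraction of distinct variants sampled at
least once in $N$ uniform draws from $L$ variants; at $N, L \sim 10^7$ –
$10^8$ the exact inclusion–exclusion answer is numerically
indistinguishable.

```{r coverage}
expected_coverage(9e7, 6.4e7)   # scanning 9e7 cells of the 6.4e7 space
collected_fraction(3680000, 9e7)
```

The default campaign is two positive rounds under decreasing inducer
(15 mg/L top 4.1%, 9 mg/L top 1.1%) and one negative round without
inducer (bottom 18.1%), which in the laboratory removes constitutively
active false positives.

## Enrichment

The decoder aligns each read to the reference. Substitution-only reads
(equal length) take a vectorized exact-position path; length-discordant
reads are globally aligned with affine gaps, and the reverse complement
is tried when the forward comparison fails. A read is rejected — and
counted as rejected, never dropped — if any diversified codon contains an
indel, ambiguity or stop, or if it has more than `max_mismatch_outside`
(default 30) mismatches elsewhere.

Per-variant enrichment compares pre-sort (R0) and post-sort (default
post-R3) frequencies with a pseudocount $p$ (default 1 read per key per
pool, since no zero-handling rule is canonical):

$$\log_2\frac{(c^{post}_k + p)/(N^{post} + pK)}{(c^{pre}_k + p)/(N^{pre} + pK)}$$

with $K$ the number of keys observed in either pool. The per-position
matrix applies the same pseudocounted ratio to marginal (slot, residue)
counts. Enrichment is exactly antisymmetric under swapping the pools, and
the correlation helper reports both Pearson $r$ and $r^2$ (published
screens sometimes conflate the two).

## Dose-response metrics

Signals are normalized per cell (÷OD600), background-subtracted (minus
the well's time-zero value), replicate-averaged, and divided by the
DNT-free control to give induction ratios. The metrics are:

- **EC200** — smallest concentration at which the maximal induction ratio
  within the analysis window (default 360 min) reaches 2. An exactly
  measured crossing is returned as-is; otherwise the crossing is
  interpolated linearly in log10(concentration), taking the smallest
  crossing for non-monotone curves. If the lowest tested concentration is
  already above ratio 2, that concentration is returned as a conservative
  upper bound. A never-reached threshold yields `NA` with a classed
  `sortscreen_undefined` warning — undefined is a result, not an error.
- **ΔRLU** — maximal (sample − control) signal difference within the
  window. `compute_dose_response()` reports it *at* the EC200
  concentration, log-linearly interpolated between tested concentrations
  when the EC200 itself was interpolated (flagged in the
  `delta_rlu_interpolated` attribute, since published tables do not state
  which convention they use).
- **time-to-ratio-2** — first crossing time of the induction ratio,
  linearly interpolated between sampling points.
- **fold metrics** — threshold fold (reference EC200 / variant EC200),
  signal fold (variant ΔRLU / reference ΔRLU) and percent response-time
  reduction; exactly reciprocal under swapping strains, and `NA` inputs
  propagate.

Concentrations are µg/L internally; the plate simulator accepts mg/L and
converts explicitly.

```{r ec200}
ec200(c("10" = 1.5, "100" = 3.0))   # log-linear interpolation
```

## Scenario orchestration

`scenario_config()` + `run_scenario()` run the whole pipeline from one
master seed; per-stage seeds are derived deterministically, every output
table carries the configuration hash, and identical configurations give
byte-identical outputs. Configurations round-trip through YAML
(`write_scenario_yaml()` / `read_scenario_yaml()`), and
`inst/scripts/run_scenario.R` is a thin command-line wrapper. The package
is function-first: the exported functions are the interface, and the
script is a convenience, not a separate code path.

```{r scenario, eval = FALSE}
res <- run_scenario(scenario_config(seed = 42))
res$campaign$stats
head(res$enrichment)
res$dose$folds
```

## Problem sizes, tolerances and what the tests show

The default scenario (2,000 distinct variants, 2 × 10⁵ cells,
2 × 10⁵/5 × 10⁴/2 × 10⁴ events over three rounds, 2 × 10⁴ reads per pool
at 0.5% per-base error) runs in seconds; the recovery study in the test
suite scales to 10⁴ variants, 10⁶ cells and 6 × 10⁴ reads per pool, the
size at which per-variant pre-sort coverage (~6 reads/variant, smoothed
by the pseudocount) still ranks the true winners reliably — in the seeded
study, all 10 planted winners land in the top 20 by log2 enrichment, and
the acceptance property requires at least 8.

Stochastic checks use mean-matched closed forms (log-normal means,
binomial error rates, multinomial codon frequencies, the chi-square
median for the density-gate cutoff) at 3 standard errors; the codon
sampler is additionally held to a chi-square goodness-of-fit at
α = 0.001 on 10⁴ draws. The EC200 estimator is required to recover the
analytic ratio-2 crossing of a noise-free simulated curve within 5% at 8
concentrations per decade; on coarser decade grids the log-linear
interpolant is visibly biased low on convex stretches of the sigmoid,
which is a property of the estimator, not a bug.

What passing these tests does *not* show: the simulator's Hill/log-normal
cell model, substitution-only reads, genotype-independent scatter and
lag-plus-saturation plate kinetics are idealizations. Real campaigns add
constitutive false positives (hence the negative round), sorter droplet
physics, indel-rich long-read error profiles and growth-phase effects,
none of which are modeled. Quantities derived purely from arithmetic
(space size, coverage, sorting percentages, fold changes) transfer to
real data directly; recovery rates measured in simulation are
best-case.

## Known limitations

- Absolute published reporter values (EC200s in µg/L, raw RLU) are
  instrument- and strain-specific and are not reproduced by simulation;
  only their ratios and the estimators themselves are testable.
- The decoder assumes reads spanning the full amplicon; partial reads are
  rejected by the mismatch rule rather than soft-clipped.
- `enumerate_variants()` refuses exhaustive enumeration beyond 5 × 10⁶
  keys; sample with `limit` instead.
- Scatter gating assumes a unimodal main population; debris-bimodal
  scatter would need a mixture gate.
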