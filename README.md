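# sortscreen

Design, simulation and analysis of **FACS-based sort-seq screens of
focused saturation mutagenesis libraries**, motivated by the engineering
of a bacterial explosives' biosensor: a 298-residue LysR-type
transcriptional regulator that senses 2,4-dinitrotoluene (DNT) is
diversified at six residue positions (31, 87, 154, 162, 233, 274) to all
20 amino acids — a 20⁶ = 6.4 × 10⁷ variant space — and enriched for
high-performing variants by multi-round fluorescence-activated sorting
followed by amplicon sequencing.

The package is for computational biologists running or planning such
campaigns. It covers:

- **Library design** — variant-space arithmetic, key enumeration/sampling,
  and gene synthesis by codon sampling from a usage table under a
  sliding-window GC cap (default: no 100-nt window above 70% GC).
- **Sort-seq simulation** — a seeded generative model: Hill-type
  DNT-inducible fluorescence `μ(d) = B(1 + (F−1)·d^h/(d^h+K^h))` with
  log-normal cell noise, doped variant pools, genotype-neutral scatter,
  multi-round positive/negative sorting, substitution-error amplicon
  reads, and plate-reader kinetics.
- **Flow analysis** — Mahalanobis density gating, rank selection, MFI,
  sorting statistics, and expected library coverage `1 − e^(−N/L)`.
- **Enrichment** — read decoding against a reference (fast exact path +
  affine-gap alignment fallback), pseudocounted per-variant
  `log2((c_post+p)/(N_post+pK) ÷ (c_pre+p)/(N_pre+pK))` and per-position
  × amino-acid enrichment matrices.
- **Dose-response** — EC200 (concentration at which the signal doubles
  over the analyte-free control, log-linear interpolation), ΔRLU,
  time-to-ratio-2, and cross-strain fold changes.

## Worked example

A scaled screening scenario — design, doped pool with 10 planted
high-performers among 2,000 variants, three sorting rounds (15 mg/L top
4.1%, 9 mg/L top 1.1%, 0 mg/L bottom 18.1%), sequencing of the pre- and
post-sort pools, enrichment, and a plate-reader comparison:

```r
library(sortscreen)
res <- run_scenario(scenario_config(seed = 42))

res$campaign$stats
#>   round dnt_mg_per_l events_total events_scanned cells_collected percent_collected     mfi
#> 1    R1           15       200000         154000            6314               4.1 1149.57
#> 2    R2            9        50000          38500             424               1.1 7468.67
#> 3    R3            0        20000          15400            2787              18.1   62.27

head(res$enrichment, 4)
#>      key pre_count post_count log2_enrichment
#> 1 HRLIKP         6       2044            8.19
#> 2 GDVIKA         7       2159            8.08
#> 3 ADTAQW         8       1835            7.67
#> 4 RAFIQV        10       2051            7.54

res$dose$folds
#> $threshold_fold               32.9
#> $signal_fold                  1.03
#> $response_time_reduction_pct  67.6
```

Reading the output: each sorting round collects exactly its configured
gate fraction of the scatter-gated events (`percent_collected`), and the
sorted pool's MFI rises sharply in the induced rounds and collapses in
the DNT-free negative round. The top of the enrichment table — variants
whose read frequency rose ~250-fold across the campaign — is exactly the
10 planted winners (log2 enrichment ≈ 8, i.e. pre-sort frequency 0.03%
rising to ~9%). In the plate comparison, the winner phenotype's detection
threshold (EC200) is ~33-fold lower than the baseline's and its
threshold-crossing response time ~68% shorter.

Static arithmetic needs no simulation:

```r
library_space_size(example_design())   # 64000000
expected_coverage(9e7, 6.4e7)          # 0.755 — scanning 9e7 cells covers ~75%
collected_fraction(3680000, 9e7)       # 4.1 (% collected in a 9e7-event round)
```

## Documentation

The methods vignette (`vignettes/sortseq-screening.Rmd`) describes the
models, parameter defaults and units, numerical choices, and what the
simulation does and does not establish about real campaigns.
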