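# mitopq

Quantification of mitochondrial protein solubility from detergent-fractionated,
spike-in-normalized isobaric-labeling (TMT) proteomics.

## The problem

Mitochondrial protein-folding stress drives a subset of the mitochondrial
proteome out of solution. Fractionating isolated mitochondria into a
Triton X-100-**soluble** and an **insoluble** fraction, labeling both with
tandem mass tags and quantifying them in one multiplexed run makes the split
measurable — provided the two fractions can be put on a common scale. `mitopq`
implements that analysis for MaxQuant-dialect protein-group tables:

- **Spike-in normalization.** A bacterial protein (Ag85A) is added to every
  fraction in fixed ratio to starting material. Within each multiplexed batch
  its reporter intensities are averaged and each channel *c* is rescaled by
  `factor_c = mean(spike) / spike_c`, which equalizes effective loading across
  soluble and insoluble channels.
- **Percent insoluble.** For protein *p* in sample *s*, the derived total is
  `T = S + I` (normalized soluble + insoluble intensity) and the insoluble
  share is `pct = 100 · I / (S + I)`. Proteins detected in only one fraction
  are flagged and excluded from shift analysis.
- **Solubility shifts and classes.** Per cell line, the replicate-averaged
  insoluble share at the stress peak is compared with the vehicle baseline;
  shifts `Δ` in percentage points are classified with strict thresholds:
  `Δ > 50` highly aggregating, `Δ > 25` aggregating, `Δ < −25`
  resolubilizing, otherwise stable.
- **Aggregation index (AI).** The unweighted mean insoluble share over a
  protein group (globally, or per functional process group, sub-compartment,
  respiratory complex or assembly sub-module) in each sample.
- **Recovery rate.** With `A(t) = max(AI(t) − AI(baseline), 0)`, the rate is
  `100 · (A(peak) − A(end)) / A(peak) · 24 / (t_end − t_peak)` — the percent
  of peak above-baseline aggregation removed per 24 h.
- **Left-censored imputation (QRILC).** Proteins absent in exactly one batch
  of a fraction group are imputed per channel from a censored-Gaussian fit of
  the log2 intensities, drawing from the fitted normal truncated at the
  channel's observed minimum.
- **Transcription-factor dependency partition.** Differential-expression
  tables (gene, log2FC, FDR per contrast) are partitioned into a stress
  regulon (FDR ≤ 0.05, |log2FC| > 0.2 in the WT contrast) whose members are
  factor-dependent when significantly decreased in a knockout contrast, with
  the mosaic single/pair/triple composition reported.

A synthetic-data generator (`simulate_experiment()`) produces multi-batch
reporter tables with known ground truth — true insoluble fractions, channel
loadings, censoring bound — so every stage is testable end to end.

## Worked example

```r
library(mitopq)
library(dplyr)

sim <- simulate_experiment(sim_config(n_proteins = 500, seed = 1))
dir <- tempfile(); paths <- write_fixture(sim, dir)

cfg <- pipeline_config(protein_groups = paths[["protein_groups"]],
                       layout = paths[["layout"]],
                       annotation = paths[["annotation"]], seed = 1)
bundle <- run_pipeline(cfg)

bundle$shifts |> filter(cell_line == "WT") |> count(class)
#>   class                  n
#> 1 aggregating           33
#> 2 highly_aggregating    67
#> 3 stable               397

bundle$recovery
#>   cell_line t_peak t_end rate_pct_per_24h
#> 1 ATF4_KO       12    60             22.5
#> 2 ATF5_KO       12    60             19.6
#> 3 CHOP_KO       12    60             22.0
#> 4 TKO           12    60             24.4
#> 5 WT            12    36            100
```

The 100 proteins called aggregating or highly aggregating in the wild-type
line are exactly the generator's aggregation-prone proteins (20% of 500, true
shifts ≥ 35 percentage points). The recovery table shows the wild-type
analogue clearing its above-baseline aggregation within the first 24-hour
window (rate 100%/24 h), while the knockout analogues — stronger aggregation,
slower return to baseline — recover at roughly a fifth of that rate over the
full 48-hour window.

`vignettes/mitopq-methods.Rmd` documents the measurement model, the
imputation and classification rules, and every tunable parameter.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "mitopq.R", package = "mitopq")`) with
`simulate`, `run` and `regulon` subcommands.

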