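---
title: "Methods: quantifying mitochondrial protein solubility with mitopq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitochondrial protein solubility with mitopq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mitopq)
library(dplyr)
```

## The measurement model

`mitopq` analyses experiments in which isolated mitochondria are split by
detergent extraction into a soluble and an insoluble protein fraction, both
fractions are labeled with isobaric (TMT) reporters and quantified together
in multiplexed runs, and a bacterial spike-in protein (Ag85A) is added to
every fraction in fixed proportion to starting material. The quantity of
interest for protein $p$ in sample $s$ is its insoluble share

$$\mathrm{pct}_{ps} = 100 \cdot \frac{I_{ps}}{S_{ps} + I_{ps}},$$

where $S$ and $I$ are the spike-normalized reporter intensities of the
soluble and insoluble channel of that sample and $S + I$ is the
computationally derived total. This is meaningful only because the spike-in
fixes the relative scale of the two channels: within each multiplexed batch
the spike intensities are averaged and channel $c$ is rescaled by
$f_c = \overline{\mathrm{spike}} / \mathrm{spike}_c$, after which the spike
is constant across the batch and any per-channel loading bias cancels.
Normalization assumptions: the spike is detected in every channel (the
pipeline aborts otherwise, since the scale is undefined without it), and
isotope-impurity correction has already been applied upstream ("Reporter
intensity corrected" columns).

Two consequences of the definition are used as internal checks: the soluble
and insoluble shares sum to 100 for every defined profile, and the share is
invariant under any common positive rescaling of both fractions — so the
aggregation metrics do not depend on absolute abundance.

## From shares to biology

**Shifts and classes.** Shares are computed per replicate and averaged over
the replicates of a condition (the alternative — summing replicate
intensities before taking the share — is available via
`condition_means(method = "sum_intensity")`). The shift of a protein is the
difference of condition means in percentage points, stress peak minus
vehicle baseline, and is classified with strict thresholds: above 50 points
highly aggregating, above 25 aggregating, below −25 resolubilizing,
otherwise stable. Proteins detected in only one fraction in a condition are
recorded (as 0 or 100) but flagged non-comparable and excluded from shifts:
a one-fraction detection confounds solubility with detectability. A
permissive mode is deliberately not the default.

**Aggregation index.** The AI of a protein group in a sample is the
unweighted mean insoluble share over the group's eligible proteins.
Eligibility is complete-case across the samples being compared, so that AI
differences between time points reflect solubility changes rather than
membership churn; imputed values are included by default (imputation exists
precisely to let those proteins stay in the denominator), and
`include_imputed = FALSE` quantifies their influence.

**Recovery rate.** With $A(t) = \max(\mathrm{AI}(t) -
\mathrm{AI}(\mathrm{baseline}),\, 0)$, the recovery rate over the window
from the stress peak $t_1$ to $t_2$ is

$$100 \cdot \frac{A(t_1) - A(t_2)}{A(t_1)} \cdot \frac{24}{t_2 - t_1}
\ \ [\%\ \mathrm{per}\ 24\,\mathrm{h}].$$

Flooring $A$ at zero avoids negative rates from slight undershoot of the
baseline. The window is chosen per cell line: the first 24-hour window when
the series has effectively recovered within it ($A(t_1 + 24) \le 5\%$ of
$A(t_1)$), otherwise the full window to the last time point, both
normalized per 24 h; explicit windows can be forced. The 5% rule is a
sharp threshold, so series sitting near it can switch windows between
otherwise similar runs — the reported rate is well-defined either way
(a fully recovered series yields 100%/24 h over 24 h or 50%/24 h over
48 h), but comparisons across cell lines should use the reported `t_end`.

## Left-censored imputation (QRILC)

Missing reporter values in this design are dominated by left-censoring —
proteins whose signal in a run fell below the detection limit. Imputation
is deliberately restricted to the cells where the study design justifies
it: a (protein, batch, fraction) cell qualifies when the protein is
detected in that fraction group in at least one batch but entirely missing
in exactly one other batch ("strict" reading; `mode = "at_least_one"`
relaxes it, and proteins missing two or more batches are reported
separately). All other missingness propagates, because imputing everywhere
would silently change AI denominators.

Per channel, the log2 intensities are modeled as Gaussian with the missing
values occupying the lowest ranks: sorted observed values are regressed on
standard-normal quantile positions $\Phi^{-1}((r - 0.5)/n)$, the intercept
and slope estimating $\hat\mu$ and $\hat\sigma$. The fit uses the upper 75%
of observed ranks by default (`fit_quantile_range = c(0.25, 1)`), where the
observed quantiles are least distorted by censoring. Each missing entry is
drawn from $N(\hat\mu, (\texttt{tune\_sigma}\cdot\hat\sigma)^2)$ truncated
above at the channel's minimum observed value — the natural empirical
censoring point — via inverse-CDF sampling, and exponentiated back.
Numerical guards: at least 10 observed values are required (the rank
regression is unstable below that), a non-positive slope aborts, and the
uniform draw is clamped away from 0 and 1 before `qnorm`. Determinism:
draws are seeded per channel (base seed + channel index) and the session
RNG state is restored afterwards.

The test suite checks the estimator against two independent oracles: the
mean of the imputed draws against the truncated-normal mean obtained by
numerical integration of the fitted density, and convergence of
$(\hat\mu, \hat\sigma)$ to the complete-data moments as censoring vanishes.

## The dependency partition

For transcriptome analyses, a gene belongs to the stress regulon when its
WT stress-versus-vehicle contrast is significant at FDR $\le 0.05$ with
$|\log_2 \mathrm{FC}| > 0.2$. The fold threshold is interpreted on the
log2 scale; this is an assumption where ">±0.2-fold" could also be read as
a linear 20% change, and it is surfaced as the `de_lfc` parameter. Among
members, dependency on a factor is a significant *decrease* in that
knockout's stress contrast, one-sided at $-0.2$, using the same FDR bound —
the knockout thresholds are not separately specified in the source design,
so the WT thresholds are reused. Mosaic categories (single, pair, triple)
are keyed on the three single knockouts; genes decreased only in the triple
knockout form their own `TKO_only` category rather than being folded into
triple dependence, and the triple-knockout contrast otherwise annotates
redundancy. Category counts sum exactly to the member count, and
percentages are reported to integer precision.

## What the synthetic generator emulates

`simulate_experiment()` generates the full study design so that every
pipeline stage can be validated against known truth:

- **Design.** Five cell lines — a wild-type analogue and four
  knockout analogues — across a vehicle control (0 h), a stress peak
  (12 h) and two recovery points (+24 h, +48 h after the peak), three
  replicates, one multiplexed batch per (cell line, replicate) holding the
  paired soluble/insoluble channels plus a pooled-control channel
  (9 channels of a 10/11-plex used).
- **Signal.** Protein abundance $A_p$ is log-normal (log2 mean 20, SD 2);
  soluble and insoluble intensities are $A_p(1-\theta)L_c\varepsilon$ and
  $A_p\theta L_{c'}\varepsilon'$ with per-channel log-normal loadings
  (log2 SD 0.25) and measurement noise (log2 SD 0.1); the spike-in row is a
  constant $2^{18}$ times loading and noise in every channel.
- **Dynamics.** The true insoluble fraction $\theta$ sits at a baseline
  drawn from $U(0.02, 0.30)$, jumps under stress by a per-protein shift
  (drawn from $U(35, 70)$ percentage points for the 20% of proteins that
  are aggregation-prone, scaled by the line's effect multiplier — 1 for
  the wild-type analogue, 1.5 for knockouts — and capped at $\theta =
  0.99$), then decays exponentially back toward baseline at the line's
  rate constant (0.135 h⁻¹ wild type, 0.012 h⁻¹ knockouts; chosen so the
  wild-type analogue is back at baseline within the recovery window while
  knockouts recover at well under half its per-24-h rate). Exponential
  return is a modeling choice — the simplest monotone recovery — not a
  claim about the underlying biology.
- **Structure.** Aggregation proneness concentrates in "sensitive" process
  groups (translation, transcription, oxidative phosphorylation,
  metabolism) with a configurable strength, so grouped-AI analyses see
  realistic contrast; OXPHOS proteins carry complex labels (CI–CV) and
  complex I carries sub-module labels (N, Q, ND1, ND5).
- **Missingness.** Left-censoring operates at the run level: a protein
  whose total signal within one batch falls below the detection-limit
  quantile (default 0.01) is missing from every channel of that batch.
  This mirrors how reporter-ion quantification actually loses values —
  identification happens once per multiplexed run, and an identified
  protein yields reporter intensities in all channels of the plex — and it
  is exactly the batch-level absence pattern the QRILC eligibility rule
  addresses.
- **QC rows.** Reverse-decoy, contaminant, site-only and
  non-mitochondrial rows (half annotated non-mitochondrial, half absent
  from the annotation) exercise both drop paths of the ingest filters.

What the generator does **not** emulate: peptide-level digestion and
roll-up, co-isolation interference and ratio compression, batch effects
beyond per-channel loading, and correlated replicate structure. Passing
tests therefore demonstrate correctness of the quantification arithmetic
and the recovery of parameters under the stated noise model — not
robustness to every artifact of real reporter-ion data.

## Numerical and design choices

- MaxQuant encodes "not quantified" as 0; exact zeros become missing at
  ingest, so no zero ever enters a denominator.
- Protein identity is the leading accession of "Majority protein IDs"
  (the keying used for the mitochondrial match is not standardized across
  studies; the full ID string is kept as metadata). Flag columns follow
  the "+" convention; any non-empty value counts as flagged.
- The spike average is arithmetic (matching "averaged"), taken over all
  channels of a batch; a fraction-matched variant is exposed
  (`per_fraction = TRUE`). Cross-batch bridging via the pooled-control
  channel is not applied by default — each plex is a separate
  labeling/fractionation run, and within-run normalization is what the
  spike supports.
- Shift thresholds are strict inequalities, so a shift of exactly 25 (or
  50) points stays in the lower class.
- Classification by threshold, not by test: no per-protein statistical
  testing of shifts is performed, by design.
- Heatmap export (`ai_heatmap()`) clusters with Euclidean distance and
  average linkage by default; both are parameters.
- All stochastic steps (generator, imputation) take explicit seeds; the
  pipeline manifest records seed, configuration hash and per-stage record
  counts, and identical configuration plus seed reproduces the bundle
  exactly.

## Problem sizes

The bundled validation suite runs the generator at 25–500 proteins for
unit-level checks and 1000 proteins (five lines, four time points, three
replicates, 135 channels) for the end-to-end identity, parameter-recovery
and acceptance runs; the imputation oracle uses channels of 20,000 values
with ~16% censoring. These sizes give stable Monte-Carlo comparisons while
keeping the full suite in the tens of seconds on a single CPU.

## Known limitations

- The derived total is conditional on detection in both fractions;
  proteins saturating one fraction near the detection limit drop out of
  shift analysis rather than being called at 0/100.
- AI is an unweighted mean, so small groups inherit the variance of their
  members; `n_proteins` is reported alongside every AI for that reason.
- The QRILC rank regression assumes an approximately Gaussian log2
  channel distribution; strongly multimodal channels would bias
  $(\hat\mu, \hat\sigma)$.
- The dependency partition takes differential-expression summaries as
  given; estimation uncertainty in the log-fold-changes is not propagated
  through the threshold rules.
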