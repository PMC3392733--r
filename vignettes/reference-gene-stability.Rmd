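---
title: "Reference gene stability analysis: models, estimation and design choices"
author: "qpcrstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference gene stability analysis: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

## The problem

RT-qPCR measures transcript abundance through the quantification cycle Cq:
the PCR cycle at which amplification fluorescence crosses a threshold.
Lower Cq means more template. Between tissue sampling and the final read
there are many opportunities for purely technical variation — extraction
yield, reverse-transcription efficiency, pipetting — so Cq values are
normalized to internal reference genes assumed to be stably expressed.
When that assumption fails, normalization injects the reference gene's own
biology into every target gene, and treatment effects can appear or vanish
artifactually. This package screens candidate reference genes in
multi-group, multi-timepoint designs (its motivating setting is hepatic
expression in female Atlantic salmon under thermal and hormonal
treatments), runs three standard stability algorithms from scratch,
validates them with distribution-free statistics, and quantifies the
downstream consequences of a bad choice.

## From Cq to relative quantities

Assay efficiency is estimated from a standard curve: regressing Cq on
log10 relative template amount gives a slope $M < 0$, and the fractional
per-cycle gain is $E = 10^{-1/M} - 1$, so the amplification base is
$E + 1$ (perfect doubling: $M = -3.3219$, $E = 1$). `validate_assay()`
checks fitted assays against the conventional acceptance thresholds
(efficiency $\ge 0.96$, $R^2 \ge 0.95$ by default).

The ΔCq transform converts a gene's Cq vector to relative quantities

$$Q_s = (E + 1)^{\min_s \mathrm{Cq} - \mathrm{Cq}_s} \in (0, 1],$$

anchored so the most expressed sample is exactly 1. Two choices are
deliberate:

* **minCq is taken over the whole dataset being analysed**, not per group
  or timepoint, so each dataset receives exactly one transform before any
  algorithm sees it. A per-group anchor would erase the very group
  differences NormFinder models.
* **Missing Cq values stay missing** and are pairwise-deleted downstream
  (per pairwise variation in geNorm, listwise within the NormFinder
  decomposition, pairwise-complete correlations in BestKeeper). Zeros
  would masquerade as maximal expression.

One Cq per sample per gene is assumed (technical replicates pre-averaged;
`read_cq(aggregate_replicates = TRUE)` averages arithmetically on request).
Cq values above 45 cycles are rejected as a validation guard — typical runs
stop at 40 cycles, and values beyond that indicate a parsing or labelling
problem, not biology.

## geNorm

For genes $j, k$ the pairwise variation is the sample standard deviation
(n−1 denominator) of $\log_2(q_j/q_k)$; two genes that track each other
perfectly have $V_{jk} = 0$ regardless of their absolute levels. The
stability measure $M_j$ averages $V_{jk}$ over the other panel members,
and the least stable gene (highest $M$ recomputed on the surviving subset)
is eliminated stepwise until two remain, which share rank 1. Ties in the
elimination step are broken by removing the gene later in input column
order, and flagged.

The *reported* per-gene $M$ is the full-panel value before any
elimination; the elimination ranking is reported separately. For the final
pair the at-elimination values are uninformative — each equals the single
pairwise variation between them ($M_a = M_b = V_{ab}$, a property the test
suite asserts) — whereas full-panel $M$ still distinguishes them.

Normalization factors are per-sample geometric means of the selected
genes' quantities, and $V_{n,n+1} = \mathrm{SD}(\log_2 NF_n / NF_{n+1})$
measures what adding the $(n{+}1)$-th ranked gene changes. The classic
0.15 cut-off for "enough genes" is a convention, not a theorem; the
package reports the series and leaves the decision to the analyst.

## NormFinder

On $y = \log_2 Q$, the model within group $g$ is

$$y_{igj} = \alpha_{ig} + b_{gj} + \varepsilon_{igj}, \qquad
\varepsilon_{igj} \sim N(0, \sigma^2_{ig}),$$

with a per-sample effect $b_{gj}$ shared by all $k$ genes — the technical
component normalization should remove. The intergroup deviation of gene
$i$ is the doubly centred group mean
$d_{ig} = \bar y_{ig\cdot} - \bar y_{i\cdot\cdot} - \bar y_{\cdot g\cdot} +
\bar y_{\cdot\cdot\cdot}$, with gene and grand means weighted by group
size so that $\sum_g n_g d_{ig} = 0$ per gene.

Because $b_{gj}$ is estimated from only $k$ genes, the naive residual
mean square $s^2_{ig}$ (from the within-group two-way decomposition) is
biased. Taking expectations under the model gives
$E[s^2_{ig}] = \sigma^2_{ig}(1 - 2/k) + \bar\sigma^2_g/k$, which inverts
to the unbiased estimator used here:

$$\hat\sigma^2_{ig} = \frac{k}{k-2}\left(s^2_{ig} -
\frac{\bar s^2_{g}}{k-1}\right), \quad \text{truncated at } 0 .$$

This is why at least three genes are required: at $k = 2$ the per-sample
effect absorbs half of every contrast and the decomposition is degenerate.

The observed $d_{ig}$ mixes true group dependence with sampling noise of
variance $v_{ig} = \hat\sigma^2_{ig}/n_g$. With a $N(0, \gamma^2)$ prior
on the true deviations and the moment estimator
$\gamma^2 = \max\!\big(0, \sum_{ig} d_{ig}^2 / ((k-1)(G-1)) -
\overline{v}\big)$, the posterior-mean shrinkage is
$\tilde d_{ig} = d_{ig}\,\gamma^2/(\gamma^2 + v_{ig})$. The stability
value combines systematic group dependence with sampling uncertainty,

$$\rho_i = \frac{1}{G}\sum_g \left( |\tilde d_{ig}| + \sqrt{v_{ig}} \right),$$

so that with a single group (or no detectable intergroup variation,
$\gamma^2 = 0$) the ranking reduces to ordering by intragroup variance —
a limit the tests check in closed form. The best two-gene combination
minimizes the same criterion applied to the averaged pair (shrunken
deviations averaged, so opposite signs cancel; sampling variance
quartered), which is why the best pair need not be the two best singles.

The seed literature for this algorithm describes the inter/intra-group
principle and publishes ranked stability values rather than a full
estimating recipe; the derivation above is this package's formulation of
that model and is frozen here so results are reproducible against this
document.

Grouping default: the experiment's treatment groups collapsed over time
(`groups = "group"`), so time trends register as intragroup variance
rather than as artificial group structure; `groups = "cell"` switches to
group-by-timepoint cells. Groups reduced to a single sample are dropped,
not merged.

## BestKeeper

BestKeeper works on raw Cq. Per gene it reports the geometric mean, the
mean absolute deviation from that geometric mean (the "SD" of the
BestKeeper convention, reported alongside the classical SD), and
CV% = SD/GM·100. All gene pairs are Pearson-correlated
(pairwise-complete); the index is the per-sample geometric mean of Cq
across the included genes; and each gene is ranked by its Pearson
correlation with the index (two-sided p from the t transform, descriptive
only — no multiplicity correction). The historical rule excluding genes
with more than one cycle of variation from the index is implemented
(`exclude_sd_above = 1`) but off by default: exclusion changes index
membership only, and excluded genes are still correlated and ranked.

A structural caveat the simulator made quantitative: every gene is a
member of its own index, so a very noisy gene drags the index toward
itself and its correlation stops falling — with few genes the index
correlation is a blunt instrument unless the remaining genes share real
covariation. This is visible in the preset design below.

## Independent validation and consensus

Three distribution-free summaries are computed per gene:

1. **Within-timepoint tests.** At each timepoint, a Kruskal–Wallis
   omnibus across groups (groups with fewer than two samples are skipped
   with a warning). Omnibus p-values are Bonferroni-corrected across the
   timepoints tested; only where the corrected omnibus is significant are
   the pairwise rank-sum post-hocs run, Bonferroni-corrected across the
   pairs within that timepoint. The total count of significant pairwise
   comparisons is the gene's score. The two-stage gating keeps the
   family-wise error at or below the nominal level (checked by simulation
   at n = 7 per group; the measured rate is conservative because the
   rank tests are discrete at these sample sizes).
2. **Cq–time correlation.** Kendall's τ between Cq and the timepoint
   index over all samples, in the tie-corrected τ-b form — timepoints
   always tie across fish sampled together, so the uncorrected form would
   be deflated by design. The share of Cq variation attributed to time is
   reported as $100\,\tau^2$; squaring a rank correlation is statistically
   unconventional but is the established reading in this workflow, so it
   is implemented as stated and named `r2_percent`.
3. **Variability.** Mean and SEM per group-by-timepoint cell, and an
   overall standard error across the set of cell means. Alternatives
   (SE over all samples, or over group means pooled across time) measure
   partly different things; the cell-mean version was chosen because it is
   on the same footing for genes with and without time trends.

The consensus ranking is a rank-sum over the three criteria (each
ascending = more stable), with ties broken by the overall standard error
and then input order, both logged. A missing criterion is imputed the
worst rank and flagged rather than silently dropped.

## REST-style target-gene normalization

The expression ratio between a control and a treatment group is
$(E_t+1)^{\Delta Cq_t} / \mathrm{geomean}_r (E_r+1)^{\Delta Cq_r}$ with
$\Delta Cq$ the difference of group mean Cq per gene — group means, not
per-sample pairing, matching the unpaired design; multiple reference
genes combine by the geometric mean of their correction factors, for
consistency with the geNorm normalization factor. Significance comes from
a fixed-reallocation randomization test: group labels are reallocated
(sizes preserved), the ratio recomputed, and the two-sided p-value is the
fraction of permutations with $|\log \text{ratio}|$ at least the observed,
with the add-one correction $(b+1)/(n_{perm}+1)$. Given a seed the
p-value is bit-reproducible. `compare_normalizations()` runs the same
contrast under two reference sets and flags discordant significance calls
at $\alpha = 0.05$ two-sided.

## The synthetic-data generator

`simulate_cq()` draws

$$Cq_{sj} = \beta_j + \text{effect}_j(g_s) + \text{slope}_j\, t_s +
\delta_s + \varepsilon_{sj},$$

with $\delta_s \sim N(0, \text{shift}^2)$ shared by all genes of sample
$s$ and independent $\varepsilon_{sj} \sim N(0, \text{noise}_j^2)$.
Gaussian noise on the Cq scale is multiplicative (log-normal) on the
quantity scale, the accepted error model for qPCR. The shared shift is
the load-bearing feature: it is exactly the variation reference genes
exist to remove, it makes all genes positively correlated (as BestKeeper
assumes), and it cancels in every log-ratio geNorm forms. A generator
with independent noise only would make the problem artificially easy.
Constructor defaults (group effect 1.5 cycles, slope 0.15
cycles/timepoint, noise 0.5, shift 0.7) are realistic mid-range values
for liver panels; all are per-gene settable.

Two presets emulate the designs this package was built around, with
per-gene efficiencies in the 0.96–0.98 range typical of validated liver
assays:

* `adult_like` — 4 genes, 4 groups (maiden/repeat spawners × 14/22 °C),
  6 monthly samplings, n = 7 per cell, shift 1.0. The Tbp-like gene
  (baseline Cq 28, noise 0.35) is stable by construction. The Ef1a-like
  gene (baseline 18) carries a small seasonal trend (slope 0.30, ~9% of
  its Cq variance) and the Hprt1-like gene a strong one (slope 0.65,
  calibrated so the median $100\tau^2$ is ≈30%). The β-tubulin-like gene
  responds to warm rearing (+2.2 cycles at 22 °C) with elevated noise
  (1.2).
* `juvenile_like` — 3 genes, 4 groups (blank/E2 implant × 14/22 °C),
  3 samplings over 14 days, n = 7, shift 1.2. The Ef1a-like gene is
  stable by construction (noise 0.2); the Hprt1-like gene has a mild
  implant-by-temperature response (+1.0 cycle in E2-22) and a visible
  trend (slope 0.7, noise 0.4); the Tbp-like gene responds to the implant
  (+2.2 cycles in both E2 groups, noise 0.75).

Two design choices deserve justification because they were genuinely
open:

* **The mild trends on the non-focal genes are not decoration.** Because
  a gene sits inside its own BestKeeper index, a gene whose only flaw is
  *unshared* variance cannot fall much below the index-correlation
  minimum; what separates the group-responsive gene at the bottom is that
  the other genes share seasonal covariation it lacks. Seasonal trends of
  a few percent on otherwise well-behaved liver genes are also what such
  experiments report. Consequently only one gene per preset is flagged
  stable-by-construction (Tbp-like in `adult_like`, Ef1a-like in
  `juvenile_like`).
* **Effect sizes were calibrated once, then frozen.** The constraints
  were: the trending gene's median time-$R^2$ near 30%; and, over 100
  seeded datasets per preset, the stable gene tops the consensus while
  the injected unstable gene is ranked last by all three algorithms in at
  least 95 — the regime where the method headline ("all algorithms catch
  the worst gene; consensus catches the best") is actually true at n = 7.
  Measured recovery after freezing: 99–100/100 (`adult_like`) and
  98–99/100 (`juvenile_like`) on two disjoint 100-seed blocks.

What the simulator does *not* model — plate effects, replicate wells,
amplification curves, inhibition, non-Gaussian outliers, correlated
biological co-regulation beyond shared trends — bounds what passing tests
mean: they certify the estimators and the workflow, not robustness of the
algorithms to every pathology of real data.

## Numerical choices and degenerate inputs

* All SDs use the n−1 denominator; geNorm and NormFinder work in log2.
* Identical datasets and seeds reproduce bit-identically; the simulator
  and the randomization test restore the caller's RNG stream.
* Degenerate cases return missing values with warnings rather than
  errors where the original tools tolerate them: pairwise variation with
  fewer than 2 complete pairs, correlations of constant genes (ranked
  last, flagged), time correlation at a single timepoint. Hard errors are
  reserved for structural problems: duplicate sample ids, non-numeric Cq
  (reported with row/column coordinates), genes without assays (named),
  fewer than 3 genes for NormFinder, empty reference sets.
* Cq columns are written with 17 significant digits so read/write round
  trips are bit-exact.

## Problem sizes in the test suite

The test suite exercises brute-force equivalence on panels up to 5 genes
× 10 samples (100 random instances, 1e-12 tolerance), Kendall τ against
exhaustive pair enumeration up to 30 samples, the type-I error of the
corrected within-timepoint procedure on 1000 null datasets at n = 7 per
group, and end-to-end recovery on 100 seeded datasets of each preset;
the whole suite runs in about half a minute on one core, keeping the
feedback loop short while the simulation counts match those quoted above.

## Known limitations

* NormFinder here is this package's derivation of the published model
  (documented above); stability values from other implementations may
  differ in shrinkage details even when rankings agree.
* The Bonferroni family structure (omnibus across timepoints, post-hocs
  across pairs within a timepoint) is one defensible convention among
  several; both corrections are applied where stated and nowhere else.
* `100·τ²` inherits the oddity of squaring a rank correlation; it is a
  reporting convention, not a variance decomposition.
* No confidence intervals on stability values, no combinations beyond
  two genes, no paired-sample mode for the expression ratio, and no
  fluorescence-curve processing — inputs are Cq tables.
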