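---
title: "Reference-gene stability analysis with rgstab: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability analysis with rgstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgstab)
```

## The problem

Relative quantification by real-time qPCR divides a target gene's signal
by that of one or more reference genes (RGs) assumed to be stably
expressed. If the RG itself responds to the contrast under study — leaf
colour, tissue, drought — every downstream fold change is biased. No gene
is universally stable, so RGs must be validated per experimental context.
`rgstab` implements the two-stage workflow now standard in plant
transcriptomics: screen candidates from RNA-seq, then validate their qPCR
Cq profiles with several stability estimators and aggregate the verdicts.

## Data model

A **Cq table** is long-format: one row per technical replicate of one gene
in one sample, with the sample's group and optionally the gene's
amplification efficiency $E$ (per-cycle amplification factor,
$1 < E \le 2$; $E = 2$ is perfect doubling). Cq is the cycle at which
fluorescence crosses threshold; it is inherently a $\log$-scale quantity
(one cycle $\approx$ one doubling), and *lower* Cq means *higher*
expression.

An **expression matrix** (gene × sample) carries one of three declared
scales, and every estimator states which it consumes:

| scale | meaning | construction |
|---|---|---|
| `CQ` | mean raw cycles | arithmetic mean of technical replicates, on the Cq scale |
| `CQE` | cycles at perfect doubling | $Cq_E = Cq \cdot \log E / \log 2$ |
| `QUANTITY` | relative quantity, per-gene max 1 | $Q = b^{\,Cq_{\min} - Cq}$, default base $b = 2$ |

The $Cq_E$ transform is exactly "cycles at perfect efficiency": converting
$Cq_E$ to quantities with base 2 equals converting raw Cq with base $E$, a
property the test suite verifies numerically. Efficiency has **no silent
default**: callers must pass $E$ (or explicitly request $E = 2$, which
reproduces the uncorrected pipeline), because a low-efficiency assay
re-ranked without correction is precisely the failure mode this workflow
exists to catch.

Distribution summaries use quartiles by linear interpolation
(`quantile(type = 7)`; quartile conventions differ, so this is stated),
the Tukey $1.5 \times \mathrm{IQR}$ rule for outliers, and whiskers equal
to the extreme non-outlier values. One subtlety: at small $n$ an
interpolated quartile can fall outside all retained observations, which
would put a "min/max of non-outliers" whisker inside the box; whiskers are
therefore clamped to the box edges, the usual box-plot convention.
Outliers always lie strictly outside the whisker interval.

## Candidate screening

The screen consumes an upstream differential-expression summary (gene,
log2FC, FDR, mean count — e.g. from edgeR; refitting that model is out of
scope) and per-experiment count matrices. A gene is a candidate RG iff in
**every** experiment it

1. is *not* differentially expressed: $|\log_2 FC| \le 1$ **and**
   $\mathrm{FDR} \ge 0.05$ (both thresholds configurable; note the filter
   keeps the *non*-significant genes — stability, not response, is the
   selection criterion);
2. has wide coverage: mean count at or above a threshold (no principled
   universal value exists; the default of 100 is documented as arbitrary);
3. shows no significant group difference in counts: one-way fixed-effects
   ANOVA $p \ge 0.05$, plus a classic equal-variance Student *t*-test in
   two-group designs. Counts are CPM-normalised by default (a raw-counts
   switch exists) because library-size differences would otherwise
   dominate the group tests. When all groups are constant and equal the
   ANOVA p-value is 1 by convention.

The output table records every component decision (p-values with ns/*/**
codes at 0.05/0.01, pass flags per filter per experiment), so a failed
candidate can be traced to the experiment and criterion that killed it.

## The four estimators

All standard deviations throughout the package use the $n-1$ denominator.

**geNorm** works on relative quantities. For genes $j,k$ define
$A_{jk}(s) = \log_2 Q_j(s)/Q_k(s)$ and $V_{jk} = \mathrm{SD}_s\,A_{jk}$;
then $M_j = \operatorname{mean}_{k \ne j} V_{jk}$. The gene with the
largest $M$ is removed and $M$ recomputed, until two genes remain; each
gene's reported stability is its $M$ at exclusion, and the final pair
shares the 2-gene $M$. Because a pairwise ratio cannot attribute variation
to one member, geNorm *never separates its two most stable genes* — the
published tied top pairs are a structural property, and the test suite
asserts it on random data. Mid-iteration $M$ ties are broken by removing
the lexicographically last gene name (deterministic, documented).
$V_{n/n+1}$ values — SDs of the log-ratio of normalisation factors built
from the $n$ and $n+1$ most stable genes — are computed but no "optimal
gene number" cutoff decision is taken.

**NormFinder** works on a log-like scale (CqE preferred). Samples are
centred across genes, removing sample-wide effects; within-group variances
of the centred values are then decontaminated for the gene-averaging step:
with $k$ genes, $s^2_{gj}$ the within-group variance and
$S_j = \tfrac{k}{k-1}\sum_g s^2_{gj}$,
$\hat\sigma^2_{gj} = \max\!\big(0, (s^2_{gj} - S_j/k^2)/(1 - 2/k)\big)$,
which requires $k \ge 3$. With $G \ge 2$ groups, the gene × group
deviations $d_{gj}$ (group mean of centred values minus the gene's overall
mean) are shrunk towards zero by the empirical-Bayes factor
$\gamma_{gj} = \hat\sigma^2_d / (\hat\sigma^2_d + \hat\sigma^2_{gj}/n_j)$,
and $SV_g = \tfrac1G \sum_j \big(|\tilde d_{gj}| +
\sqrt{\hat\sigma^2_{gj}/n_j}\big)$. With one group,
$SV_g = \hat\sigma_g$. Two groups use the same general-$G$ formulas. A
`shrink = FALSE` switch exists because simplified reimplementations omit
the shrinkage and the variant matters when comparing against web tools;
which variant those tools use is not documented, so no attempt is made to
calibrate against published SV columns.

**BestKeeper** is descriptive, on raw mean Cq: per gene the SD, the CV
($100 \cdot \mathrm{SD}/\bar{Cq}$), and the Pearson correlation $r$ with
the BestKeeper index (per-sample geometric mean of all genes' Cq). The
ranking uses the SD alone — published tables order BestKeeper by a single
stability column — while CV and $r$ are reported; the classic
spreadsheet's mean-absolute-deviation variant is available via
`use_mad = TRUE` but is not the default. A constant gene has undefined
$r$ (reported `NA`) and ranks first by SD.

**Comparative ΔCt** is the fully pairwise view on raw mean Cq:
$SV_g = \operatorname{mean}_{h \ne g} \mathrm{SD}_s\!\left[Cq_g(s) -
Cq_h(s)\right]$. Descriptions of this method sometimes mention
treated-vs-control Cq differences as a preliminary step; that sentence has
no computable counterpart in the gene-pair SD procedure actually used, and
only the standard procedure is implemented.

All four estimators are invariant under per-gene constant Cq shifts
(BestKeeper's CV shifts, but its ranking statistic, the SD, does not) —
the property-test suite checks this, since it is the main structural
guarantee that baseline expression level does not masquerade as
(in)stability.

## Meta-ranking

Within-method stability values are converted to ranks (ascending, 1 = most
stable; ties either averaged or broken by gene name under the default
strict policy), and the comprehensive ranking orders genes by the
geometric mean of their ranks, the RefFinder-style aggregation:
$GM_g = \big(\prod_m r_{m}(g)\big)^{1/|m|}$. Geometric-mean ties are
broken by arithmetic-mean rank, then gene name — the aggregation source is
silent on ties, so the policy is fixed and documented. Two subset rankings
aggregate the CqE-based methods (geNorm + NormFinder) and the raw-Cq
methods (BestKeeper + ΔCt) separately.

When aggregating *published* rank tables, the printed orderings are taken
as the input ranks (printed stability values are rounded to 2 decimals;
the printed order resolves their ties at full precision). When aggregating
*computed* results, strict ordering of unrounded values is used. On the
packaged published-rank fixture, plain geometric-mean aggregation
reproduces the known comprehensive positions 1, 2 and 6 in all three
experiments — but **not** two mid-table position pairs (4/5 in the tissue
comparison, 2/3 in drought), where the product-of-ranks order differs from
the published table. Either the original aggregation used unrounded
stability values that reordered an input ranking, or a different
weighting; the discrepancy is documented and those positions are excluded
from the acceptance test rather than forced.

One related inconsistency in the source material: the published
candidate-screen description states a $\log_2 FC \le 1$ filter, yet the
selected genes' reported log2FC range extends to 1.03. The filter here is
implemented strictly ($|\log_2 FC| \le$ threshold, default 1.0); keeping a
1.03 gene requires raising the threshold explicitly.

## The simulator: what it emulates, what it does not

`simulate_cq()` draws
$Cq_{gsr} = \beta_g + \delta_{g,j(s)} + u_s + \varepsilon_{gs} +
\eta_{gsr}$, Gaussian on the Cq scale — the standard qPCR error model and
the implicit assumption of all four estimators. Defaults mirror the
study-shaped world: 6 genes named as in a lettuce RG panel, baselines
spread over 31–38 cycles (inside the 30.4–39.2 span such experiments
report), synthetic efficiencies in 1.76–1.97 (real per-gene efficiencies
are not published; the fixture values are synthetic and labelled so),
groups of 3 biological samples, 2 technical replicates, sample-effect SD
0.3, gene noise SD 0.25–0.4, replicate SD 0.15 cycles — values a qPCR
practitioner would call ordinary bench variability. `simulate_counts()`
draws negative-binomial counts with $\mu = \text{base mean} \cdot
2^{\text{log2FC}} \cdot \text{library factor}$ and
$\mathrm{Var} = \mu + \phi\mu^2$, and emits the ground-truth DE table
(true log2FC; FDR encoded as an indicator — 1 for null genes, 0 for
planted effects) so the screen can be tested *exactly* against truth.

What a green test on simulated data establishes: the estimators recover
planted order (a gene with a group effect $\ge 5\times$ the noise SD is
ranked last by every estimator and the comprehensive ranking in ≥95% of
seeds; a low-noise stable gene floats to the top two in ≥90%), the ANOVA
screen holds its nominal 5% level on null NB counts (within ±2% over
1000 simulations), and the NormFinder intragroup estimator is unbiased
(within 10% relative bias at $n = 1000$, assessed on the estimator
averaged over replicate simulations — a single draw carries ~4.5%
sampling error before the $k$-gene decontamination amplifies it). What it
does **not** establish: robustness to features real Cq data have and the
generator lacks — non-Gaussian heavy-tailed outliers, plate/batch
effects, efficiency misestimation, missing reactions, or correlated
noise between genes sharing a pathway. Seeds are mandatory in simulation
specs and the generators never touch global RNG state.

## Numerical and interface choices

- SDs: $n-1$ denominator everywhere, including inside geNorm's $V_{jk}$.
- geNorm requires $\ge 3$ genes; NormFinder $\ge 3$ genes and $\ge 2$
  samples per group; ΔCt and BestKeeper $\ge 2$ genes / samples.
- Degenerate inputs: all-constant matrices give all-zero stabilities (and
  rank by the documented name-order tie-break); zero-variance ANOVA gives
  $p = 1$ when means are equal.
- Filters accept infinite / zero thresholds (the vacuous-filter limit
  selects every gene), though the defaults are finite.
- I/O is plain delimited text: long CSV for Cq tables, TSV + design file
  for counts, `gene,stability_value,rank` CSVs per method, and a sidecar
  `.meta` file carrying matrix scale and group map so matrices round-trip.
- The CLI (`rgstab_main()`, wrapped by `inst/scripts/rgstab`) exposes
  `simulate` / `screen` / `stability` / `rank`; config files are
  INI-style `key: value` text with CLI-flag precedence; exit codes are
  0 / 1 / 2 for success / usage / data-integrity.

## Known limitations

- Published per-method stability *values* cannot be recomputed here: the
  underlying Cq measurements live in supplementary material only, so
  validation of the estimators rests on hand-computed small cases,
  closed-form and brute-force oracles, and parameter-recovery simulations
  rather than on reproducing printed SV columns.
- The comprehensive ranking is a rank aggregation: it discards stability
  magnitudes, and two methods disagreeing mildly can outvote one method
  disagreeing strongly. Alternative schemes (Borda, median rank) are
  deliberately out of scope.
- NormFinder's shrinkage constant is estimated from few gene × group
  cells in small panels; with 6 genes and 2 groups it is noisy, which is
  the documented cost of the small designs this workflow targets.
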