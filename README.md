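# rgstab

Selection and validation of reference genes (RGs) for real-time qPCR
normalisation.

Accurate qPCR expression results depend on normalising against internal
control genes whose expression is stable across the samples and conditions
under study. Classic housekeeping genes often fail that requirement, so
modern workflows (i) pre-select candidate RGs from RNA-seq data and then
(ii) validate them on qPCR quantification-cycle (Cq) profiles with several
expression-stability estimators. `rgstab` implements both stages for
R users:

- **Candidate screening** from RNA-seq summaries: keep genes that are
  *not* differentially expressed (|log2FC| ≤ 1 and FDR ≥ 0.05 by
  default), have wide coverage, and show no significant group differences
  in counts (one-way ANOVA; Student's equal-variance *t*-test for
  two-group designs), jointly across all supplied experiments.
- **Cq data modelling**: technical-replicate averaging, amplification-
  efficiency correction `CqE = Cq · log(E)/log(2)` (the cycle count at
  perfect doubling), relative quantities `Q = base^(Cq_min − Cq)`, and
  box-plot style distribution summaries (Tukey 1.5×IQR outlier rule).
- **Four stability estimators**, each producing per-gene stability values
  (lower = more stable) and a within-method ranking:
  - *geNorm*: `M_j = mean_k SD_s[log2(Q_j/Q_k)]`, with iterative exclusion
    of the worst gene down to the final, tied pair, plus the pairwise
    variations `V_n/n+1` of successive normalisation factors;
  - *NormFinder*: ANOVA-type decomposition into intragroup variances
    `σ²_gj` and empirical-Bayes-shrunk intergroup deviations `d̃_gj`, with
    `SV_g = mean_j(|d̃_gj| + sqrt(σ²_gj/n_j))`;
  - *BestKeeper*: SD and CV of raw Cq plus the Pearson correlation of each
    gene with the per-sample geometric-mean index (ranked by SD);
  - *comparative ΔCt*: mean over partner genes of `SD_s[Cq_g − Cq_h]`.
- **Comprehensive meta-ranking**: geometric mean of the four within-method
  ranks (the RefFinder-style aggregation), plus the two input-scale subset
  rankings (geNorm+NormFinder on CqE vs BestKeeper+ΔCt on raw Cq).
- **A seeded simulator** for Cq tables (gene baselines, group effects,
  sample effects, replicate noise) and negative-binomial count matrices
  with ground-truth DE tables, so the whole pipeline is testable without
  any external data.

Input scales follow the standard workflow: BestKeeper and ΔCt consume mean
raw Cq; geNorm and NormFinder consume efficiency-corrected CqE (geNorm via
base-2 relative quantities).

## Worked example

```r
library(rgstab)

# a deterministic, study-shaped fixture ships with the package:
# 6 candidate RGs, green vs red groups, 3 biological x 2 technical reps
tab <- read_cq_table(system.file("extdata", "paperlike_cq_table.csv",
                                 package = "rgstab"))
tab
#> <cq_table> experiment 'paperlike_cq_table': 72 records, 6 genes, 6 samples

res <- stability_suite(tab)     # all four estimators, per-method scales
res$geNorm
#> <geNorm stability>
#>  rank    gene stability
#>     1   SCL13 0.2206164
#>     2   VHA-H 0.2206164
#>     ...

comp <- geometric_mean_ranking(lapply(names(res), function(m)
  assign_ranks(res[[m]])))
comp[, 1:3]
#>   position    gene  gm_rank
#> 1        1   SCL13 1.495349
#> 2        2   iPGAM 2.632148
#> 3        3    ADF2 2.942831
#> 4        4   VHA-H 3.833659
#> 5        5    CYB5 3.935979
#> 6        6 TRXL3-3 4.119534
```

The `stability` column is geNorm's M value at each gene's exclusion step
(the two most stable genes always share the final 2-gene M — geNorm cannot
separate them); `gm_rank` is the geometric mean of a gene's ranks across
the four estimators, and `position` the resulting comprehensive ranking
(1 = recommended RG).

Aggregating the published within-method rank orders shipped as a fixture
reproduces the known recommendations, e.g. for the leaf-colour comparison:

```r
geometric_mean_ranking(published_rankings("green_vs_red"))[, 1:3]
#>   position    gene  gm_rank
#> 1        1    CYB5 1.565085
#> 2        2 TRXL3-3 1.861210
#> 3        3    ADF2 2.828427
#> 4        4   VHA-H 4.119534
#> 5        5   SCL13 4.242641
#> 6        6   iPGAM 5.000000
```

## Command line

```sh
Rscript inst/scripts/rgstab simulate  --seed 11 --out sim/
Rscript inst/scripts/rgstab screen    --de sim/de_truth.csv \
    --counts sim/counts.tsv --design sim/design.tsv --out screen.csv
Rscript inst/scripts/rgstab stability --cq sim/cq_table.csv --out stab/
Rscript inst/scripts/rgstab rank \
    --methods stab/geNorm.csv,stab/NormFinder.csv,stab/BestKeeper.csv,stab/DeltaCt.csv \
    --out comprehensive.csv
```

Exit codes: 0 success, 1 usage/config error, 2 data-integrity error. Logs
go to stderr; results to files only.

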