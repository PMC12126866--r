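# osmi — one-sample imputation of missing DNA-methylation values

Methylation microarrays and sequencing protocols routinely leave a fraction
of CpG sites unmeasured, and most imputation methods (methyLImp,
impute.knn/KNNimpute, missForest) fill those gaps by borrowing the same CpG's
values from *other* samples. That fails exactly where personalised
epigenomics needs it most: single-sample settings — one patient, one tumour
profile, one case study — or cohorts with strong inter-individual
variability.

`osmi` implements **One-Sample Methyl Imputation (OSMI)**: a missing
β-value is replaced using only the sample's own methylome, exploiting the
fact that nearby CpG sites tend to share their methylation state. For each
chromosome strand let **β** and **p** be the vectors of β-values and
positions; a pair (βⱼ, pⱼ) with both entries known is a *complete CpG
record*. A missing βᵢ is imputed as

* the β-value of the complete record minimising |pⱼ − pᵢ| on the same
  chromosome and strand (exact-distance ties are averaged);
* if pᵢ is unknown, the mean of the observed values on that chromosome
  strand;
* if the chromosome strand holds no observed value at all, the genome-wide
  mean of the sample's observed values.

The **advanced** variant first looks *inside the query's CpG island*: if the
island holds at least one complete record, the nearest-neighbour search is
confined to it (by default on either strand — CpG methylation is
strand-symmetric), and falls back to the basic rule otherwise. Because CpGs
within an island share methylation state, this prioritisation improves
accuracy on island CpGs.

No information ever crosses sample boundaries; matrices are imputed
column by column, so accuracy is independent of how many samples you have.

The package also provides

* parsers for generic/Illumina-450K-style CpG annotation and UCSC
  `cpgIslandExt` island tracks (with the 0-based half-open → 1-based
  inclusive conversion handled on read);
* the iterative greedy filter that reduces a matrix with missing entries to
  a complete submatrix (delete the worst rows or columns by missing
  fraction, whichever axis dominates, and repeat);
* an evaluation harness: MCAR masking, RMSE/MAE/bias/IQR on masked entries,
  paired Wilcoxon signed-rank comparison with rank-biserial correlation and
  Cohen's d, and density–accuracy curves;
* a synthetic methylome generator (island-clustered CpG positions,
  distance-decaying co-methylation exp(−d/λ), bimodal β marginals) so that
  everything is testable offline;
* a command-line front end
  (`inst/cli/osmi.R`: `simulate | filter-complete | mask | impute | evaluate
  | compare-modes`).

## Worked example

```r
library(osmi)

# a synthetic methylome: 2 chromosomes, islands dense in CpGs, open sea
# sparse, co-methylation decaying with lambda = 200 bp
cfg <- simulation_config(n_samples = 4, seed = 11)
sim <- simulate_methylome(cfg)          # 2,680 CpGs x 4 samples, 40 islands

# hide 10% of entries in 90% of rows, then impute island-aware
mk  <- mask_mcar(sim$beta, entry_fraction = 0.10,
                 eligible_row_fraction = 0.90, seed = 12)
imp <- impute_matrix(mk$masked, sim$annotation, mode = "advanced")
imp
#> OSMI imputation (advanced mode): 2680 x 4 matrix, 965 entries imputed
#>   ISLAND_NN_TIE_AVG  5
#>   ISLAND_NN_UNIQUE   243
#>   NN_UNIQUE          717

score_imputation(sim$beta, imp$values, mk$mask)
#> masked-entry evaluation (n = 965): RMSE 0.1696, MAE 0.1042, bias +0.0174, IQR 0.1081
```

Every imputed entry carries a provenance code; `provenance_summary()`
reports how many imputations had a neighbour within 50 bp (the range where
co-methylation is strongest) and how many fell back to chromosome/genome
means. Comparing the two modes on the stratum where the island route was
actually used:

```r
cmp <- island_stratified_compare(sim$beta, sim$annotation, seed = 13)
cmp$basic                               # n = 219 masked in-island entries
#> masked-entry evaluation (n = 219): RMSE 0.0812, MAE 0.0417, bias +0.0065, IQR 0.0476
cmp$advanced
#> masked-entry evaluation (n = 219): RMSE 0.0427, MAE 0.0278, bias +0.0021, IQR 0.0304
cmp$paired$rank_biserial                # -0.570: island-aware errors smaller
```

The island-aware mode roughly halves RMSE and IQR on that stratum; the
negative rank-biserial correlation of the paired absolute residuals says the
improvement holds entry by entry, not just in aggregate.

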