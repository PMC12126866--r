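---
title: "One-sample methylation imputation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample methylation imputation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmi)
```

## The problem and the model

DNA methylation at CpG sites is spatially organised: the closer two CpGs
lie on a chromosome, the more likely they share their methylation level,
and CpGs inside the same CpG island are particularly homogeneous. OSMI
(one-sample methyl imputation) turns this into an imputation rule that
needs nothing beyond a single methylome: a missing β-value is replaced by
the β-value of the nearest *complete CpG record* — a CpG whose β-value and
genomic position are both known — on the same chromosome and strand.

The full decision cascade for a missing entry, in order:

1. **Island route (advanced mode only).** If the CpG belongs to a CpG
   island holding at least one complete record, impute from the nearest
   record within that island (`ISLAND_NN_UNIQUE` / `ISLAND_NN_TIE_AVG`).
2. **Chromosome-strand nearest neighbour.** If the CpG has a position and
   its chromosome strand holds a complete record, impute from the nearest
   record; records tied at the minimal distance are averaged
   (`NN_UNIQUE` / `NN_TIE_AVG`).
3. **Chromosome-strand mean.** If the position is unknown but chromosome
   and strand are known and carry observed values, impute their mean
   (`CHROM_STRAND_MEAN`).
4. **Genome-wide mean.** Otherwise — no observed value on the strand, or
   chromosome/strand themselves unknown — impute the mean of all observed
   values of the sample (`GENOME_MEAN`). A sample with no observed value at
   all cannot be imputed and is reported as failed.

Every imputed entry is therefore a mean of one or more observed values of
its own column, which gives the method its invariants: output in
`[min, max]` of the column's observed values, observed entries untouched,
idempotence on complete input, and strict per-column independence —
duplicating a sample duplicates its imputations. Each entry also records a
provenance code and, for neighbour-based codes, the donor distance in base
pairs, so downstream analyses can ask how much of an imputation actually
exploited local correlation (e.g. the fraction of donors within 50 bp,
where co-methylation is strongest).

The nearest-record lookup is a binary search (`findInterval`) over the
sorted positions of each chromosome strand's complete records, contracted
to agree exactly with a linear scan; the test suite enforces that contract
on hundreds of random instances. Single-donor imputations copy the donor's
value bit-exactly; multi-donor imputations average with `mean()` over the
donor values rather than prefix-sum differences — an earlier prefix-sum
formulation could drift one ulp outside the observed range.

## Tunable parameters

* `mode` (`"basic"`/`"advanced"`): whether the island route is tried first.
  Advanced equals basic wherever the island route is infeasible.
* `neighbor_mode` (default `"tie_average"`): the minimal reading of
  "nearest neighbour(s)" — use the unique nearest record and average only
  exact-distance ties. The alternative `"flank_average"` always averages
  the nearest upstream and nearest downstream records when both exist;
  it is provided for sensitivity analysis because the method description
  admits both readings.
* `island_strand_filter` (default `FALSE`): whether the island route is
  additionally confined to the query's strand. The default deliberately
  relaxes the strand constraint inside islands: CpG methylation is
  strand-symmetric (methyltransferase maintenance acts on both strands of a
  CpG dyad), so the nearest in-island probe is an equally valid donor on
  either strand and is typically closer than the nearest same-strand
  record. Empirically this relaxation is where most of the island variant's
  benefit comes from: with the filter on, basic and advanced modes pick the
  same donor for almost every in-island query and the island variant only
  acts at island borders; with it off, roughly half of the in-island
  imputations use a better, closer donor. Set it to `TRUE` to mirror the
  base method's strand constraint exactly.
* `threshold_bp` (default 50) in `provenance_summary()`: the distance below
  which a donor is counted as "near", following the literature's estimate
  of the range of strong co-methylation.

Distances are unsigned base-pair differences; a duplicate position
(distance 0) is legal and treated as nearest.

## The greedy complete-case filter

Evaluation needs a fully observed ground-truth matrix, extracted from raw
data by an iterative heuristic: compute per-row and per-column missing
fractions `p_r`, `p_c`; if `max p_r >= max p_c` delete all rows with
`p_r >= max p_c`, otherwise all columns with `p_c >= max p_r`; recompute
and repeat until nothing is missing. Ties delete rows. Each pass removes at
least one line (the argmax line always qualifies), bounding the iteration
count by rows + columns. Fractions are compared by exact count
cross-multiplication (`missing_r * m >= max_missing_c * n`) so that ties
are decided by arithmetic rather than floating-point rounding; rows and
columns with no missing values are never deleted while anything is missing
elsewhere, since their fraction is zero. The rule is applied to the matrix
as given; `orient_wlog = TRUE` restores the presentation that assumes at
least as many rows as columns by transposing first. The test suite replays
the implementation's iteration log against an independent step-by-step
simulator on hundreds of random masks.

## Evaluation protocol

`mask_mcar()` implements the benchmark masking: choose
`round(0.9 * n_rows)` eligible rows at random, then hide
`round(0.1 * eligible_entries)` entries uniformly without replacement
inside the eligible block, keeping the other rows fully observed (several
multi-sample imputers require some complete rows). The "10% of the
eligible block" reading is the default; `mask_basis = "total"` switches the
count's denominator to all entries while still confining the mask to
eligible rows.

`score_imputation()` reports RMSE, MAE, bias and IQR of the raw residuals
(truth − imputed, so over-imputation yields negative bias; both the signed
bias and its magnitude are worth reporting since the sign convention is
easy to flip). Quantiles use the type-7 linear-interpolation definition.
RMSE ≥ MAE always (power-mean inequality), with equality only for
equal-magnitude residuals — asserted property-style in the tests.

`compare_paired()` compares two residual vectors paired by masked entry:
Wilcoxon signed-rank test (zero differences dropped — the two OSMI modes
frequently produce identical imputations — and ties mid-ranked; p-value
from the tie-corrected normal approximation), rank-biserial correlation
`(W⁺ − W⁻)/(W⁺ + W⁻)`, and paired Cohen's d `mean(d)/sd(d)` with the
sample (n − 1) standard deviation over all pairs. When every difference is
zero the test is undefined and reported as such, with both effect sizes 0.

## The synthetic generator

`simulate_methylome()` produces annotation, island track and a complete
β-matrix with exactly the three structural features the method exploits:

* **Clustered positions.** Islands are placed uniformly without overlap
  (exponential lengths, default mean 600 bp); CpG positions advance by
  geometric gaps — mean 20 bp inside islands, 1,000 bp in the open sea —
  so islands are CpG-dense. Strands are random per CpG.
* **Distance-decaying co-methylation.** Per chromosome and sample, a
  standard-normal AR latent field over the sorted positions with step
  correlation `exp(-gap/λ)` (default λ = 200 bp). On a line this sequential
  construction realises the exponential covariance kernel exactly, so the
  field restricted to either strand also decorrelates as `exp(-d/λ)`. The
  field spans both strands of a chromosome because CpG methylation is
  strand-symmetric; a per-strand field would make opposite-strand
  neighbours spuriously independent and invert the value of any cross-
  strand donor.
* **Bimodal marginals.** Region-level logit means (−2 inside islands,
  +2 in the open sea: islands typically unmethylated, open sea methylated)
  shifted by the latent field and mapped through the inverse logit — one
  mechanism yields spatial correlation, island homogeneity, boundary
  discontinuities and the characteristic two-peaked β distribution, with
  every value strictly inside (0, 1).

Defaults (2 chromosomes of 1 Mb, 20 islands each, 4 samples) give ~2,500
CpGs — large enough for stable error estimates, small enough that the full
test suite runs in about a minute. The density–accuracy analyses use a
larger geometry (4 chromosomes of 2 Mb, open-sea gap 800 bp, ~13,000 CpGs)
so that densities up to 8,000 CpGs can be subsampled; 10 replicate masks
per density give standard errors an order of magnitude below the effects
being tested.

What the generator does **not** emulate: probe chemistry (type I/II bias),
normalisation artifacts, non-MCAR missingness, sample covariance structure
(samples are independent draws around the same regional means), and
genome-scale CpG counts. Passing tests therefore demonstrate the method's
contractual behaviour and the direction and mechanism of its accuracy
properties, not the error magnitudes to expect on real arrays.

## Numerical and degenerate-input choices

* Internal coordinates are 1-based inclusive; UCSC island tracks
  (0-based half-open) are converted on read, `[start+1, end]`. Illumina
  F/R strand codes map to +/−. No genome-build liftover is attempted —
  build consistency between annotation and island track is the caller's
  responsibility.
* Overlapping island intervals (possible only in dirty tracks) resolve
  deterministically to the smallest start, then smallest end, with a
  warning.
* Missing markers accepted on read: empty cell, `NA`, `NaN`; written as
  `NA`. Unparseable positions or strands become missing values, never
  dropped rows.
* A column with no observed value is reported per column
  (`failed_samples`), not a global abort; a fully-missing matrix legally
  reduces to an empty complete-case selection with a warning.
* All stochastic steps (generator, masks, subsampling) take explicit seeds
  and restore the caller's RNG state; fixed seed + fixed input is
  bit-reproducible, including through the command-line interface.

## Known limitations

* Open-sea CpGs on sparse arrays rarely have a donor within the strong
  co-methylation range, so single-sample accuracy is intrinsically bounded
  by array density; the density–accuracy curve quantifies exactly this.
* When several samples *are* available and reasonably similar,
  cross-sample methods are more accurate; OSMI's niche is the single-sample
  case and sensitivity analysis alongside such methods.
* The island route requires island annotation; CpGs that are their
  island's only member gain nothing over the basic rule.
* M-values are out of scope; convert to β upstream.
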