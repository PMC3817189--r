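# cgsa — Correlated Gene Set Analysis

`cgsa` extracts **correlated gene sets (CGSs)** — disjoint groups of
positively co-expressed genes, each built around a "center" gene — from a
variance-stabilised (glog-scale) expression matrix, and provides the
machinery to work with them: per-set summary scores, unsupervised sample
ordering on the principal plane, projection of external samples,
cross-platform mapping of set collections, PAM clustering with
silhouette-based selection of the number of clusters, level-controlled
association testing against phenotypes, differential-expression and
fold-change-density utilities, and gene set enrichment (hypergeometric and
PAGE).  A latent-factor cohort simulator with truth-recovery metrics makes
every stage testable without external data.

## The method

Every gene *c* is treated as the center of a candidate set

&nbsp;&nbsp;&nbsp;&nbsp;*S(c) = { j : r(c, j) ≥ r_min }*,

where *r(c, j)* is the Pearson correlation across samples (negatively
correlated genes are never included).  Candidates are ranked by the score

&nbsp;&nbsp;&nbsp;&nbsp;*score(c) = s²_c · Σ_{j∈S(c)} r²(c, j)*,

(center variance times summed squared center correlations — it grows with
set size, center variance and correlation tightness), and a top-*K*
pairwise-disjoint collection is selected greedily in score order.  Each set
is then summarised per sample by the weighted sum *Σ_j x_ji / s_j* with
inverse total-SD weights, oriented to correlate positively with the center.

Every ingredient — membership, score, weights — depends on the data only
through overall variances and covariances, so the whole construction is
**invariant under permutation of the sample labels**.  That is what makes
downstream permutation tests exact: when set summaries are tested against a
phenotype with single-step max-T adjustment (Westfall–Young; B = 999 gives
the attainable floor of adjusted p = 0.001), the family-wise error level
holds *despite* the sets having been built from the same expression matrix.

## Worked example

```r
library(cgsa)

co   <- simulate_cohort(synthetic_design(), seed = 42)   # 2000 genes x 150 samples
coll <- extract_cgs(co$expr, K = 10, r_min = 0.6)
coll
#> CGS collection: 10 set(s) [K=10, r_min=0.6, min_size=2, score=var_center_x_sum_r2]
#>   #1 g0026: 12 genes, score 185.2
#>   #2 g0012: 11 genes, score 140.1
#>   #3 g0005: 10 genes, score 131.8
#>   ...

S <- summarize_cgs(co$expr, coll)            # 10 x 150 standardized summaries
recovery_metrics(coll, co$truth)$mean_jaccard
#> [1] 1

res <- associate(S, co$pheno, B = 999, seed = 7)
head(as.data.frame(res), 3)
#>   set_id phenotype   n r_squared   auc        p_raw p_adjusted
#> 1  g0026     group 150     0.151 0.717 8.81e-07          0.001
#> 2  g0012     group 150     0.155 0.692 6.27e-07          0.001
#> 3  g0005     group 150     0.752 0.999 1.06e-46          0.001
```

The first ten extracted sets recover the ten planted co-expression modules
exactly (mean Jaccard 1).  The set built around the module tracking the
phenotype-linked factor explains 75% of the phenotype's variance
(AUC 0.999); its family-wise adjusted p sits at the permutation floor
1/(B+1) = 0.001.

A shell interface wraps the same functions:

```sh
exec/cgsa simulate --seed 5 --out-prefix co
exec/cgsa extract  --expr co_expr.tsv --k 10 --r-min 0.6 --out-prefix cgs
exec/cgsa cluster  --summary summary.tsv --out-prefix cl
```

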