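---
title: "Correlated gene set analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated gene set analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsa)
```

## The model

`cgsa` works on an expression matrix on a variance-stabilised
(generalized-log) scale, genes in rows, samples in columns, complete and
finite.  The central object is the *correlated gene set* (CGS): starting
from a center gene $c$, the candidate set collects every gene whose Pearson
correlation with $c$ is at least $r_{\min}$,

$$S(c) = \{\, j : r_{cj} \ge r_{\min} \,\},$$

so negatively correlated genes are never members, whatever their magnitude
(such genes are rare in practice and including them would complicate the
summary orientation).  One candidate is built per gene, candidates are
ranked by

$$\mathrm{score}(c) = s_c^2 \sum_{j \in S(c)} r_{cj}^2,$$

and a top-$K$ collection is selected greedily in score order, accepting a
candidate only if it is disjoint from every previously accepted set and has
at least `min_size` members.  The score grows with set size, with the
center's variance, and with how tightly members track the center — the
three properties a useful co-expression hub should have — and it is a
function of the total covariance matrix only.

Each selected set is summarised per sample by the inverse-SD weighted sum
$z_i = \sum_{j \in S} x_{ji}/s_j$, oriented to correlate positively with
the center and (by default) standardised to mean 0, variance 1 across
samples.

**Why permutation invariance matters.**  Membership, score, selection and
summary weights all depend on the data only through per-gene variances and
gene–gene covariances, which are unchanged when the sample columns are
permuted.  Consequently the set construction cannot leak phenotype
information, and permutation tests of the summaries against a phenotype
remain exact at their nominal level even though the sets were learned from
the same matrix.  This is the property the association stage relies on, and
the test suite asserts it directly (identical collections after column
permutation; family-wise error simulations).

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `r_min` | 0.7 (extraction default); 0.6 in the synthetic benchmarks | membership threshold on the center correlation. 0.7 yields set sizes in the tens on typical cohorts; the benchmarks use 0.6 because the reference design plants within-module correlations near 0.75, so 0.6 sits below the planted signal and far above the background null (sampling SD of a null correlation at $n = 150$ is about 0.08). |
| `K` | 50 | number of sets retained; 50 captures the main factors of a microarray-scale cohort while keeping the collection readable.  Robustness re-runs at other $K$ are a parameter sweep, not a different algorithm. |
| `min_size` | 2 | a set must contain at least one non-center member to represent co-expression; singletons are excluded. |
| summary weights | $1/s_j$ | inverse *total* standard deviation: weights that depend only on the total sums-of-products matrix preserve the exact-level guarantee; equal weights are available. |
| `B` | 999 | permutations for max-T; the smallest attainable adjusted p is $1/(B+1) = 0.001$. |
| `k_range` | 2–10 | candidate cluster numbers for PAM; the average silhouette width (ASW) selects $k$, ties toward smaller $k$. |
| `min_fraction` | 0.5 | minimum fraction of a set's members present on a target platform for the set to count as mapped. |
| mapping/projection limits | 50% / 20% | a set missing more than half its genes on an external platform is dropped; a sample missing more than 20% of sets is not projected. |

## Association testing

Effect sizes are $R^2$: the squared Pearson correlation for quantitative
phenotypes, $\eta^2$ (between-group over total sum of squares) for
categorical ones; binary phenotypes additionally get the rank-form AUC with
ties counted 1/2.  Raw p-values come from the corresponding F statistic.
Family-wise adjustment is single-step max-T: for each of $B$ permutations
of the phenotype all per-set statistics are recomputed and their maximum
recorded; the adjusted p of set $s$ is $(1 + \#\{b : \max_b \ge T_s\})/(B+1)$.
The permuted statistic is the one-way F (categorical) or squared
correlation (quantitative), so one procedure covers both and is monotone in
$R^2$.  Because the parametric raw p can in principle undercut the
permutation floor for extreme statistics, the `associate()` wrapper reports
`max(maxT, raw)`; `adjust_maxT()` itself returns the pure max-T values.
Missing phenotype entries are deleted pairwise per phenotype, with the n
used reported.  Signature contrasts use a two-way ANOVA on the signature's
first principal component (sign-oriented with the signature mean), type-II
main effects without interaction via `drop1`.

## Clustering

Samples are clustered with classical partitioning around medoids
(BUILD + SWAP, deterministic, via `cluster::pam`) on Euclidean distances
over row-standardised summaries; the number of clusters maximises the ASW.
Two caveats worth knowing:

* PAM's SWAP phase is a *single-swap* local search.  On tiny unstructured
  inputs it can terminate in a local optimum whose cost exceeds the global
  (double-swap-reachable) optimum; on data with genuine cluster structure
  it reliably finds the global optimum, which is what the brute-force
  comparison in the tests checks.
* ASW-based selection of $k$ needs the cluster signal to occupy a
  substantial fraction of the summary dimensions.  With $k$ equally mixed
  clusters, the centred cluster-mean patterns span only $k-1$ dimensions of
  factor space, so in a collection where most sets track
  cluster-uninformative factors the silhouette is diluted and the selected
  $k$ becomes unstable (we observe ASW near 0.14 and a median margin of
  0.01 over competing $k$ on the 10-module reference design).  The
  cluster-recovery benchmark therefore uses a cohort whose modules all
  track cluster contrasts (ASW near 0.6), the regime in which such profiles
  are interpretable in practice.

## The synthetic cohort generator

`simulate_cohort()` draws from a linear latent-factor model: gene $g$ in
module $m$ has $x_{gi} = \mu_g + \lambda f_{m,i} + \varepsilon_{gi}$ with
$\varepsilon \sim N(0, \sigma^2)$ and standard-normal factors; background
genes are baseline plus noise.  Within a cluster, the module correlation is
$\lambda^2/(\lambda^2 + \sigma^2)$, so loadings are chosen for a target
correlation.  Sample clusters shift factor means; phenotypes are derived
from chosen factors (thresholding for categorical, linear plus unit noise
for quantitative) or generated as pure noise.

Reference design (the package default): 2000 genes — 10 modules with a
fixed size ladder of 10–20 genes plus 1850 background genes — $n = 150$
samples, $\lambda = \sqrt3$, $\sigma = 1$ (within-cluster module
correlation 0.75), three equally mixed clusters, cluster $c$ shifting
factor $c$ by 4 SD.  Shifting one factor per cluster keeps every
between-module covariance non-positive, which is what lets
positive-correlation extraction recover the planted partition exactly; the
price is the silhouette dilution discussed above.  Benchmarks that need a
different regime declare their own design:

* *cluster-number recovery*: 3 modules of 25 genes, all cluster-linked
  (every summary informative, ASW ≈ 0.6);
* *split-half ordering stability*: modules of 120 and 60 genes with
  loadings 3 and $\sqrt3$, $n = 220$, and a dominant two-lobe contrast
  (mixing 0.4/0.6, shift 3 on the dominant factor) — without the lobes most
  samples sit near the centred plane origin, where an angular position is
  maximally sensitive to noise and no gene split can order them stably.
  Even with the lobes, replicates in which many samples land near the
  origin still dip below 0.9 in circularly aligned Spearman agreement
  (median ≈ 0.95, roughly one replicate in ten below 0.9) — an honest
  limitation of angular ordering for samples without a clear position on
  the principal plane.

What the generator emulates: block-correlated modules driven by shared
factors, an uncorrelated background, planted sample clusters, and
factor-linked phenotypes.  What it does not: probe-level effects, batch
structure, heavy-tailed noise, overlapping modules, and survival outcomes.
Passing tests therefore demonstrate correctness of the algorithms under the
stated statistical model, not performance on any particular real cohort.

## Numerical choices

* Ties in candidate scores are broken by center gene id (ascending), making
  extraction deterministic and its GMT output byte-identical across runs.
* Principal-plane loadings are sign-fixed so the largest-magnitude loading
  on each axis is positive; coordinates follow.
* The angular ordering places zero-length coordinate vectors last, ordered
  by sample id; angle ties break by sample id.
* Permutations in `adjust_maxT()` are drawn as `sample.int(n)` after
  `set.seed(seed)` — the documented stream that reference implementations
  can replay.
* Kernel densities share one Silverman bandwidth computed on the pooled
  classified genes; with a shared bandwidth the class-share-scaled
  densities sum *exactly* (to numerical precision) to the density of all
  classified genes, because kernel density estimation is linear in the
  empirical distribution.
* Zero-variance genes cannot center a set, are excluded from summaries with
  a warning, and get correlation 0 as members.
* Genes constant in both groups of a differential contrast get $t = 0$,
  $p = 1$ rather than an error.

## Known limitations

* Extraction is greedy: a slightly lower-scoring candidate that would allow
  two further disjoint sets is never preferred; the method aims for
  interpretable hubs, not an optimal set cover.
* The exhaustive-search equivalence of PAM holds on clustered data; no
  claim is made for adversarial unstructured inputs (see above).
* External-sample projection assumes the external cohort shares the
  reference scale; sets with fewer than half their genes on the external
  platform are dropped rather than re-weighted.
* Angular ordering is only as stable as a sample's distance from the plane
  origin; orderings of origin-near samples should not be over-interpreted.
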