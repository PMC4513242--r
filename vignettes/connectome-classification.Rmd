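---
title: "Classifying brain connectomes with tensor decomposition and sparse logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brain connectomes with tensor decomposition and sparse logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conntensor)
```

## The problem

A structural connectome summarizes a subject's white-matter wiring as a
symmetric, zero-diagonal, nonnegative matrix: entry $(i, j)$ counts (or
weights) the fiber streamlines connecting brain regions $i$ and $j$. In
degenerative disease studies, the question is whether such networks separate
diagnostic groups — for instance Alzheimer's disease (AD), mild cognitive
impairment (MCI) and normal controls (NC). Two obstacles dominate. First,
dimensionality: a 113-region parcellation yields $113 \times 112 / 2 = 6328$
edge features per subject, against cohorts of a few dozen subjects per group.
Second, nuisance structure: edge weights drift with age and differ by sex, so
raw group contrasts are confounded.

`conntensor` implements a pipeline that addresses both. Subject matrices are
max-normalized, adjusted for age and sex by linear-model residualization,
stacked into an $n \times p \times p$ tensor, reduced by higher-order
singular value decomposition (HO-SVD), and classified with L1-penalized
logistic regression inside an undersampling-bagging protocol. Raw
upper-triangle features and SVD/PCA scores serve as baselines, and classical
group statistics (element-wise and metric-level $t$-tests with Bonferroni
correction) complete the picture.

## Preprocessing and confound removal

Fiber counts live on subject-specific scales, so each matrix is divided by
its own maximum entry (`normalize_by_max()`), putting every network on
$[0, 1]$ with its strongest connection at 1. An all-zero matrix is passed
through with a warning rather than an error so batch runs survive degenerate
subjects. One side effect worth knowing: if the *same* cell is the maximum
for every subject (common when a strong shared connection dominates), that
cell is exactly 1 across the cohort and carries zero variance; downstream
tests treat it as a degenerate edge ($p = 1$, with a warning).

Confound removal is ordinary least squares on the design
$[1, \text{age}, \text{sex}]$, applied across subjects to each unordered
edge (`adjust_cohort()`) and to each global network measure
(`adjust_metrics()`). Residuals $y - X\hat\beta$ are kept; they are mean-zero,
orthogonal to the design, and may be negative, which is why metrics are
computed on the nonnegative normalized networks *first* and residualized
afterwards, while element-wise residual networks feed the group tests and
feature extraction. Residualization is pooled across all subjects, not within
groups; pooling can absorb a little true group signal when group membership
correlates with age, which is the conservative direction. A rank-deficient
design (all ages equal, one sex absent) falls back to the pseudoinverse with
a warning.

## HO-SVD feature extraction

The cohort tensor $\mathcal{X} \in \mathbb{R}^{n \times p \times p}$ (mode 1
= subjects) is decomposed as
$$\mathcal{X} = \mathcal{S} \times_1 U^{(1)} \times_2 U^{(2)} \times_3 U^{(3)},$$
where each factor $U^{(k)}$ is the full left singular matrix of the mode-$k$
unfolding and the core $\mathcal{S}$ is all-orthogonal with mode-$k$
subtensor norms (the $k$-mode singular values) in decreasing order. Keeping
the leading $k$ components in both node modes and multiplying the truncated
core back along the sample mode only gives every subject a $k \times k$
reduced slice; stacking it row-major yields $k^2$ features
(`extract_hosvd()`). The sample mode is never truncated, so no subject is
mixed into another's features beyond the shared node bases.

Numerical conventions, fixed so features are bitwise reproducible:

* Unfoldings use a cyclic column order (modes $k{+}1, \dots, N, 1, \dots,
  k{-}1$, first varying fastest). Singular values are invariant to this
  choice; only factor signs and the core's internal layout depend on it.
* Each singular vector's sign is flipped, if needed, so its
  largest-magnitude entry is positive (first such entry on ties).
* `k = 15` is the default for both SVD and HO-SVD features; performance is
  flat for `k` roughly between 10 and 30 on the kind of low-rank-plus-noise
  data the generator produces.
* The raw feature matrix is column-centered before the SVD/PCA baseline (so
  SVD scores are exactly PCA scores); the tensor is *not* centered before
  HO-SVD by default (`center = TRUE` is available). Centering is part of the
  PCA definition, whereas the tensor decomposition is conventionally applied
  to the data as-is; both choices are exposed.
* Decompositions are fit on the full cohort before any train/test split.
  This mirrors transductive practice for unsupervised feature construction
  and does leak unlabeled feature geometry (not labels) across the split;
  fitting on training data alone is possible by splitting before extraction.

`extract_raw()` stacks the upper triangle in row-major $i < j$ order
($p(p-1)/2$ features); `symmetric_from_vector()` inverts it.

## Sparse logistic regression

With labels $y_i \in \{-1, +1\}$, the model is
$\Pr(y \mid x) = 1 / (1 + e^{-y(x^\top w + c)})$ and the fit minimizes
$$\frac{1}{n}\sum_i \log\!\big(1 + e^{-y_i (x_i^\top w + c)}\big)
  + \lambda \lVert w \rVert_1,$$
with the intercept unpenalized. The solver (`splr()`) is a monotone
accelerated proximal-gradient scheme: gradient steps from an extrapolated
point, soft-thresholding of $w$, backtracking line search on the smooth part,
and a fallback plain proximal step (with momentum restart) whenever the
accelerated candidate would increase the objective, so the recorded objective
trace is non-increasing. Convergence requires both a relative objective
change below `tol` (default `1e-7`) and a subgradient-optimality violation
below `kkt_tol` (default `1e-6`); the objective criterion alone can stall
short of the optimum on flat, nearly separable problems. `lambda_max()`
computes the smallest penalty that zeroes every coefficient (evaluated at the
optimal intercept-only model), and `lambda_path()` builds a log-spaced grid
from there down to $10^{-3} \lambda_{\max}$ — the grid shape is this
package's choice. At $\lambda = 0$ the solver agrees with iteratively
reweighted least squares (`glm`) to well under $10^{-6}$ in the coefficients
on the toy problems in the test suite.

## Evaluation protocol

`run_experiment()` repeats, `n_repeats = 20` times by default:

1. a stratified 85/15 train/test split (stratification is this package's
   choice; with as few as 39 subjects in a class an unstratified split can
   produce empty-class test sets),
2. 5-fold cross-validation *on the training data alone* to choose
   $\lambda$ from the path by mean fold accuracy, ties broken toward the
   larger (sparser) penalty,
3. an undersampling-bagging refit on the whole training set: `n_bags = 21`
   models (odd, so a majority vote is defined), each on an independent
   undersample that keeps all minority-class subjects and an equal-size
   random draw of the majority class; predicted probabilities are averaged,
4. accuracy, sensitivity, specificity and AUC (midrank Mann–Whitney) on the
   held-out test set, with the clinically worse diagnosis as the positive
   class.

Inside the cross-validation each fold/penalty cell uses a single
undersampled fit, warm-started down the path, rather than the full bag —
penalty selection is insensitive to the ensemble averaging and this keeps the
protocol tractable; the final refit uses the full ensemble. On balanced data
every undersample is the complete sample, so the ensemble provably collapses
to one fit and is computed that way. Interior CV fits run under slightly
looser solver settings (`experiment_config(solver = ...)`); the iteration cap
can be hit at the smallest penalties and is deliberately not a warning there.

Every split, fold assignment, undersample and bag is derived from
`master_seed`, and all internal seeding saves and restores the caller's RNG
state, so one seed reproduces an entire evaluation bitwise.

Group-level statistics use equal-variance Student's $t$-tests:
per upper-triangle edge with Bonferroni threshold $0.05 / (p(p-1)/2)$
($\approx 7.9 \times 10^{-6}$ at $p = 113$), and per global measure with
threshold $0.05 / 5 = 0.01$ ($-\log_{10} = 2$). Method comparisons across
repeats use a *paired*, one-sided $t$-test (`compare_methods_ttest()`) with a
declared degenerate convention — $p = 0.5$ when all per-repeat differences
are exactly zero, 0 / 1 for constant nonzero differences — and McNemar's test
on paired predictions (exact binomial below 25 discordant pairs, chi-square
with continuity correction above).

## Network measures

Five weighted global measures (`global_metrics()`), computed on
max-normalized networks:

* **MOD** — Newman weighted modularity, optimized by Louvain with 10
  restarts over permuted node orders under a fixed seed (the greedy passes
  depend on node order); on graphs small enough for exhaustive partition
  search the optimum is attained in the test suite.
* **MCC** — mean Onnela clustering coefficient: per node, the sum of
  geometric means of triangle weights (scaled by the matrix maximum) over
  $k(k-1)$; degree-< 2 nodes contribute 0.
* **CPL** — characteristic path length with distance $1/w$, averaged over
  reachable ordered pairs only; a graph with no edges is an error.
* **GLOB** — mean inverse shortest-path distance, 0 for unreachable pairs.
* **SW** — small-worldness $\sigma = (C/C_{\text{null}}) /
  (L/L_{\text{null}})$ against 10 Maslov–Sneppen null networks
  (degree-preserving rewiring of the binarized topology, 10 swap passes per
  edge, weights reshuffled). The null-model count and rewiring depth are this
  package's defaults, not a published convention; `swap_passes = 0` keeps the
  graph as its own null ($\sigma \equiv 1$), a useful self-check. A
  disconnected null is resampled up to 10 times, then errors; a
  zero-clustering null ensemble errors as degenerate.

All five are permutation-invariant and validated against brute-force oracles
(exhaustive partitions, triple enumeration, Floyd–Warshall) on small graphs.

## The synthetic cohort generator

`simulate_cohort()` builds cohorts with known ground truth:
$$W = \big| M + s_g S + a(\text{age} - \overline{\text{age}}) + b\,
      \text{sex} + E \big|,$$
with $M$ a shared symmetric nonnegative low-rank mean network (rank
`base_rank`, scaled to maximum 1), $S$ the planted effect pattern, group
shifts $s_g = (0, 0.5, 1)\,\delta\,\sigma_\varepsilon$ for NC, MCI, AD (the
disease gradient), scalar age/sex terms on all off-diagonal cells, and
symmetric i.i.d. Gaussian noise $E$. The absolute value keeps weights
nonnegative without a point mass at zero; diagonals are zeroed and each
matrix max-normalized, so outputs satisfy exactly the invariants of real
networks. Ages are uniform on 60–85 (optionally per-group, to construct age
confounding), sex is Bernoulli(0.5), and default group sizes are
AD 39 / MCI 112 / NC 51.

Three effect patterns: `"random"` edges (sparse, independent signals),
`"block"` (all edges of a small clique), and `"lowrank"` (a dense rank-one
pattern $uu^\top$ with unit root-mean-square cells). The low-rank pattern is
the regime the tensor method is built for — each edge individually weak, the
aggregate concentrated in one tensor direction — and the package's validation
uses it for the head-to-head comparison below.

What the generator does *not* emulate: fiber-count marginal distributions
(real counts are heavy-tailed and zero-inflated), distance-dependent
connectivity, hemispheric structure, or site/scanner effects. Passing tests
therefore demonstrate algorithmic correctness and the intended statistical
behavior on controlled structure, not clinical performance on real cohorts.

## Validation problem sizes and calibration notes

The shipped validation (test suite and `scripts/acceptance.R`) uses sizes
chosen to exercise each property at desk scale: 50 random $8 \times 10
\times 12$ tensors for decomposition exactness; 20 small toy problems for
solver/oracle agreement; 200 no-effect cohorts at $p = 20$, 20 subjects per
group, for family-wise false-positive calibration; and, for the headline
comparison, 20 cohorts at $p = 60$, 40 subjects per group, rank-4 mean
structure, dense rank-one group effect with $\delta = 0.13$ (in noise-sd
units, noise sd 0.1), $k = 15$, 3 protocol repeats per cohort. $\delta$ was
set so that raw-edge features land near 0.6 accuracy — above chance but far
from ceiling — which is the regime where the comparison is informative; at
much larger effects both feature sets saturate and at much smaller ones both
sit at chance.

One calibration subtlety: the protocol's repeats share a single cohort (and,
in the permuted-label null check, a single fixed permutation), so per-repeat
accuracies are dependent; the mean of 20 repeats scatters around chance far
more than $\text{sd}/\sqrt{20}$ would suggest, and null checks band it by the
per-repeat spread instead.

## Known limitations

* The HO-SVD bases are interference-prone: group signal outside the leading
  mode subspaces is discarded, so for *sparse* strong effects raw features
  can win (visible with the `"random"`/`"block"` generator patterns at small
  effect sizes).
* Equal-variance $t$-tests on residualized edges ignore the 2 degrees of
  freedom spent on the confound model; at the cohort sizes used the effect is
  negligible but it is a known approximation.
* The lasso path bottom ($10^{-3}\lambda_{\max}$) can be effectively
  unregularized for wide feature matrices; cross-validation rarely selects
  it, but pathological grids are not guarded against.
* Metrics assume undirected nonnegative networks; directed or signed
  connectivity is out of scope, and GLM-adjusted (signed) networks must not
  be fed to the graph measures.

## A worked example

```{r example}
sim <- worked_fixture()          # 12 subjects, 6 nodes, 3 groups, planted effect
sim$cohort
adj <- adjust_cohort(sim$cohort)
feats <- extract_hosvd(adj, k = 2)
feats
fit <- splr(unclass(extract_raw(adj)), sim$cohort$phenotypes$label,
            lambda = 0.05, positive = "AD")   # AD vs everyone else
fit
```
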