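---
title: "Methods: dissecting community assembly along elevation gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting community assembly along elevation gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`elevassembly` asks, for a soil bacterial community sampled along an
elevation gradient, how much of its structure is deterministic (niche
filtering by environment) and how much is stochastic (dispersal and drift).
It combines five classical analyses — niche-breadth classification, the
Sloan neutral community model, C-score null-model analysis, multivariate
regression trees, and constrained ordination with variance partitioning —
and ships a synthetic-data generator with known ground truth so every stage
can be validated end to end. This vignette records the models, the defaults
and their rationale, and the numerical choices that are not visible from
the function signatures.

## The data model

All stages consume one object: an integer OTU-by-sample count matrix
(`otu_table`), internally always oriented OTUs-as-rows. Sample covariates
fall into three named blocks — topography (MEA mean altitude, CON
convexity, SLO slope, ASP aspect), light (ALA, CC, TR, SR, DR, LT, LAI)
and soil (pH, organic matter, alkaline N, available P, water content).
Missing covariates stay missing: a stage that needs a block refuses to run
rather than imputing, because zero is a legal covariate value and silent
imputation would bias variance partitioning.

## Niche breadth and the generalist/specialist classification

For OTU $j$ with relative abundance $P_{ij}$ in sample $i$ (normalized
over the OTU's own total — each sample is one "habitat"), the Levins
breadth is

$$B_j = \frac{1}{\sum_i P_{ij}^2},$$

the inverse Simpson concentration of the OTU across habitats: $B = k$ for
an OTU spread evenly over $k$ samples. Whether an observed $B$ is large or
small is judged against a count-preserving *quasiswap* permutation null
that fixes row sums, column sums, grand total and fill. Empirical 2.5% and
97.5% quantiles of the per-OTU null breadth form the bounds; above them an
OTU is a generalist, below a specialist, within (including exact ties —
conservative) neutral. 1000 permutations is the default; no
multiple-testing correction is applied, matching the convention of this
classification (so about 5% of truly exchangeable OTUs are flagged by
construction).

Two numerical points deserve record. First, the count quasiswap is
realized as a Patefield (`r2dtable`) draw with the right margins, followed
by random one-unit $2\times2$ diagonal shifts until the fill is restored,
*followed by a fill-preserving mixing phase* (2 trials per matrix cell).
The mixing phase matters: stopping at the greedy repair endpoint is
measurably non-uniform over the fixed-margin/fixed-fill set (chi-squared
p-values around $10^{-37}$ against exhaustive enumeration on a 3×3
instance), whereas the mixing chain — symmetric proposals with a hard fill
constraint — is reversible and passes the same enumeration check. Second,
repair continues in bursts on the same matrix instead of redrawing on
failure; dense matrices with near-uniform rows need several hundred
thousand trials and a fresh Patefield start would discard that progress.

**A caution on "neutral" labels.** A community assembled by the Sloan
neutral process with finite $Nm$ is *overdispersed* relative to the
fixed-margin permutation ensemble: each taxon's local abundances have
Beta-law variance $p(1-p)/(Nm+1)$, far larger than the sampling variance
the null allows. In our synthetic tests at $Nm \approx 1000$ roughly 90%
of process-neutral taxa classify as "specialists". This is not a bug of
either method; the permutation null defines neutrality as exchangeability,
not as neutral demography. Recovery tests therefore score the classifier
on the *planted* generalists and specialists, and a green test establishes
that planted signal is found — not that process-neutral taxa are labeled
neutral.

## The Sloan neutral community model

For a local community of size $N$ receiving immigrants at rate $m$ from a
metacommunity where taxon $i$ has relative abundance $p_i$, the stationary
local relative abundance is approximately
$\mathrm{Beta}(N m p_i,\; N m (1 - p_i))$. A taxon is observed when its
abundance exceeds a detection limit $d$, so its expected occurrence
frequency across samples is

$$\hat f_i(m) = 1 - I_d\!\left(N m p_i,\; N m (1 - p_i)\right),$$

with $I$ the regularized incomplete beta function. `fit_ncm()` estimates
$m$ by bounded nonlinear least squares of observed frequency on mean
relative abundance (three starts at 0.01/0.1/0.5 against flat local
minima), reports the generalized $R^2 = 1 - SSE/SST$ about the mean
observed frequency, and wraps the prediction in Wilson-score 95% binomial
bands ($n$ = number of samples; Wilson rather than Wald for correct
behaviour near frequencies of 0 and 1), labeling each OTU above/within/
below.

**Detection limit.** The conventional $d = 1/N$ treats detection as a
step function. With multinomial read sampling the true detection
probability is smooth, $1 - (1 - x)^N$, and on data simulated exactly
under the model the $d = 1/N$ convention overestimates $m$ by 30–40%
(verified by refitting with the exact beta-binomial zero probability,
which recovers $m$ to under 1%). The default is therefore
$d = \log(2)/N$ — the abundance at which the smooth detection probability
crosses one half, a derived constant rather than a tuned one — which
recovers generative $m$ within ±15% across $m \in \{0.1, 0.3, 0.5\}$ at
$N = 2000$. Pass `d = 1/N` to reproduce the convention. Depths are not
rarefied by default; $N$ is the mean sample total.

## C-score and standardized effect size

The Stone–Roberts C-score is the mean checkerboardedness over OTU pairs,
$(R_i - S_{ij})(R_j - S_{ij})$, on the presence/absence matrix (presence
= count ≥ 1). The null fixes both margins and is sampled by a sequential
trial-swap chain (burn-in $10\times$ fill, thinning fill), whose
stationary distribution over fixed-margin binary matrices is uniform. The
standardized effect size $(\mathrm{obs} - \mu_{null})/\sigma_{null}$ is
negative for aggregation, positive for segregation; $|SES| < 2$ is
reported as random.

Two structural facts matter for interpretation and for building positive
controls. Block-diagonal "groups in different habitats" matrices are
*segregated* (between-group pairs are perfect checkerboards), not
aggregated; and margin conditioning absorbs all sample-quality and
taxon-prevalence effects, so aggregation requires genuine excess pairwise
co-occurrence. Perfectly nested matrices, meanwhile, can be margin-frozen
(a singleton ensemble; SES undefined, reported as `random`). The test
suite therefore constructs known-sign matrices by margin-preserving greedy
swaps that push the C-score into the stated tail of its own ensemble.

## Elevation banding by multivariate regression tree

Samples are partitioned on mean altitude by CART with a multivariate
response: each split on MEA minimizes the within-child sum of squared
deviations of Hellinger-transformed composition (square-root of sample
relative abundances — the standard transform that makes Euclidean
distances, and hence SS impurity, ecologically meaningful). Growth stops
at node size 5 or depth 4; impurity ties break toward the lower
threshold, so trees are deterministic. Pruning is 10-fold cross-validation
(seeded fold assignment, per-fold errors normalized by the fold's share of
total SS) with the 1-SE rule over the weakest-link pruning path. Leaves
ordered by mean elevation become LEG/MEG/HEG bands when there are exactly
three, `L1..Lk` otherwise. With the default synthetic design the tree
recovers the planted 49/27/44 bands exactly.

## Ordination, envfit and variance partitioning

RDA is implemented directly: PCA of the fitted values of the multivariate
least-squares regression of the (centered) community matrix on
standardized predictors; the constrained proportion equals the trace-form
redundancy statistic and is oracle-tested against explicit least squares
at $10^{-10}$. The default response is the Hellinger transform; a centered
log-ratio transform (`clr_transform()`, pseudocount 0.5 added to zero
cells only) is available for compositional workflows. Each environmental
variable is tested envfit-style: $r^2$ of the variable regressed on the
first two constrained axes, with p-values from 999 permutations of the
variable across samples, $p = (1 + \#\{r^2_{perm} \ge r^2\})/(n_{perm}+1)$.

Variance partitioning decomposes the Ezekiel-adjusted trace $R^2$,
$1 - (1 - R^2)(n-1)/(n-k-1)$, over the three covariate blocks by
inclusion–exclusion across the seven block unions. Small negative
fractions are an expected artifact of the adjustment and are reported as
computed; the seven fractions plus residual reconstruct every union's
adjusted $R^2$ to $10^{-8}$ by construction, and the suite asserts it.

## The synthetic world

`synth_spec()` states the generative world once; tests never move it:

* **Design**: 120 quadrat samples in three elevation bands of 49/27/44
  (rescaled proportionally for other sizes), 2000 reads per sample.
* **Neutral backbone**: metacommunity abundances are lognormal with
  `sdlog = 1`. Real soil SADs are often more uneven; the moderate choice
  keeps most taxa informative for parameter-recovery tests, which is the
  generator's purpose — it is a flagged modeling choice, not an estimate.
  Each sample's composition is Dirichlet with concentration
  $N m_{true} p$, so local abundances are marginally exactly the Beta law
  the Sloan fit assumes (oracle/model coherence), and reads are
  multinomial at depth $N$. Default $m_{true} = 0.5$, the magnitude
  typical of forest-soil estimates.
* **Planted niche structure**: 6% generalists and 41.5% specialists (the
  category proportions of the motivating study design). Specialists keep
  reads only in one randomly assigned home band; generalists are spread
  deterministically even across samples. Samples are renormalized to
  exactly $N$ reads by largest-remainder rounding — deliberately *not* a
  multinomial redraw, because even expected weights resampled
  multinomially are statistically indistinguishable from the permutation
  null, which would erase the planted generalist signal by construction.
* **Covariates**: band-wise non-overlapping MEA ranges
  (1300–1480 / 1520–1680 / 1720–1900 m, breakpoints 1500 and 1700);
  every other covariate is a linear function of standardized MEA (block
  effect size 1, i.e. covariate–elevation correlation ≈ 0.71) plus unit
  Gaussian noise, mapped to natural units and clipped to valid ranges.

What the generator does **not** emulate: phylogenetic structure, spatial
autocorrelation within bands, sequencing-error inflation of rare taxa,
overdispersion beyond the neutral Beta law, and block-specific causal
effects of covariates on composition (covariates influence the community
only through their shared elevation dependence). A green recovery test
therefore establishes correctness of the estimators under the stated
world, not robustness to these real-data features.

## Known limitations

* Niche classification power depends on OTU total abundance; rare planted
  taxa (a few reads) are indistinguishable from neutral and are the main
  source of the residual error in recovery tests.
* The quasiswap mixing chain is uniform over the *reachable* set of
  margin/fill-preserving matrices; connectivity of that move graph is
  verified empirically on enumerable instances, not proven in general.
* The MRT uses a single numeric predictor (elevation); multi-predictor
  trees, categorical splits and surrogate splits are out of scope.
* Exact reproduction of any particular field study's printed numbers is
  out of scope: those depend on raw-read processing and unstated choices;
  the package targets the methods, validated against synthetic truth.
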