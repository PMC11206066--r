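# elevassembly

Deterministic or stochastic? `elevassembly` dissects the assembly of soil
bacterial communities sampled along an elevation gradient, for microbial
ecologists who have an OTU count table (OTUs × samples) and per-sample
environmental covariates (topography, light, soil). It re-implements, as
one tested pipeline, the standard toolkit for this question:

* **Niche breadth & classification** — Levins breadth
  `B_j = 1/Σ_i P_ij²` per OTU, judged against a count-preserving
  *quasiswap* permutation null (row sums, column sums, total and fill all
  fixed): above the null's 95% bounds → habitat **generalist**, below →
  **specialist**, within → neutral.
* **Sloan neutral community model** — occurrence frequency vs mean
  relative abundance, `f̂_i(m) = 1 − I_d(Nmp_i, Nm(1−p_i))`, fitted by
  nonlinear least squares; reports the migration rate `m`, `Nm`, the
  goodness of fit `R² = 1 − SSE/SST`, and an above/within/below partition
  against Wilson-score 95% prediction bands.
* **C-score / SES** — Stone–Roberts checkerboard score
  `(R_i − S_ij)(R_j − S_ij)` averaged over OTU pairs, with a fixed-margin
  trial-swap null; `SES = (obs − μ_null)/σ_null`, negative = aggregation,
  positive = segregation.
* **Elevation banding** — a multivariate regression tree (CART with a
  Hellinger-transformed community response) splits samples on mean
  altitude, with 10-fold cross-validated 1-SE pruning; three leaves become
  the LEG/MEG/HEG (low/medium/high) bands, and per-band analyses are run
  on the result.
* **RDA / envfit / VPA** — redundancy analysis of composition on
  environmental predictors, per-variable permutation tests on the first
  two axes (999 permutations), and variance partitioning of the
  Ezekiel-adjusted `R²` into unique and joint fractions of the
  topography/light/soil blocks.
* **Diversity & sharing** — per-sample richness and Shannon index (nats),
  Kruskal–Wallis comparisons across bands, and Venn-style shared/unique
  OTU counts per band and per niche category.

A first-class **synthetic-data generator** (`synth_spec()`,
`simulate_dataset()`) produces the world these analyses assume — a neutral
Dirichlet-multinomial backbone with known migration rate, planted
generalists/specialists, and elevation-structured covariates — so every
stage is validated against ground truth. See
`vignettes/community-assembly-methods.Rmd` for the models, defaults and
caveats.

## Worked example

```r
library(elevassembly)

spec <- synth_spec(n_otus = 500, rng_seed = 11)   # 120 samples, 3 bands
d <- simulate_dataset(spec)
d$table
#> OTU table: 500 OTUs x 120 samples; total reads 240000

fit <- fit_mrt(d$table, d$metadata, seed = 5)     # elevation banding
fit$model
#> Multivariate regression tree on MEA — 3 leaves
#>   split at MEA <= 1696.901 (76 | 44)
#>   split at MEA <= 1497.730 (49 | 27)
table(fit$band)
#> LEG MEG HEG
#>  49  27  44
```

The tree recovers the planted design exactly: splits at ~1497 m and
~1697 m sit on the generator's true breakpoints (1500/1700 m), giving the
49/27/44 band sizes.

```r
fit_ncm(d$table)                                   # neutral model
#> Sloan neutral community model fit
#>   m = 0.1452  Nm = 290.3  N = 2000.0  R2 = 0.638
#>   partition above/within/below: 0.310 / 0.526 / 0.164 (n = 500 OTUs)

cls <- classify_otus(d$table, run_config(2, 300))  # niche classification
table(cls$category)
#> generalist    neutral specialist
#>         37        132        331

ses_cscore(d$table, run_config(3, 200))            # co-occurrence null
#> C-score: obs 339.7647, null 321.2535 +/- 0.0541 (n = 200), SES 341.97 [segregated]
```

This table was planted with heavy niche structure (41.5% band-restricted
specialists), and the numbers show it: the neutral fit degrades (R² 0.64,
`m` pulled below the backbone's 0.5), the classifier flags a large
specialist pool, and the C-score SES is strongly positive — band-restricted
OTUs are segregated. On a purely neutral table
(`synth_spec(frac_generalist = 0, frac_specialist = 0)`) the same fit
recovers the generative `m` within a few percent with R² > 0.9.

```r
div <- diversity_summary(d$table)
kruskal_wallis(div$shannon, fit$band)
#>   statistic df   p_value
#> 1   3.47426  2 0.1760249

vn <- venn_shared(d$table, fit$band, cls)
round(attr(vn, "shared_fraction"), 3)
#>        all generalist    neutral specialist
#>      0.584      1.000      0.841      0.435
```

Generalists are shared across all three bands by construction; planted
specialists mostly are not.

One call runs everything and writes TSVs plus a seed-stamped
`manifest.json`:

```r
run_pipeline(run_config(rng_seed = 1, n_permutations = 1000,
                        output_dir = "run_out"),
             synth = synth_spec(rng_seed = 1))
```

or from the shell: `Rscript inst/scripts/run-all.R --out run_out --seed 1`
(use `--otu-table`/`--metadata` for real data;
`inst/scripts/simulate.R` writes a synthetic dataset with its ground
truth).

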