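---
title: "Multi-kernel pedigree and genomic prediction across environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel pedigree and genomic prediction across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a large wheat (or other line-breeding) pipeline, each candidate line is
phenotyped in a single year: last year's lines are never grown again, and
next year's lines have never been grown at all. Selection decisions
therefore hinge on predicting the performance of unobserved lines, either
in years that have already been observed (new lines, known environments) or
in a year that has not happened yet (new lines, new environment). The only
bridge between a new line and the training data is genetic relatedness —
expected relatedness from the pedigree, or realized relatedness from
genome-wide markers — and, for environment-specific deviations, the
interaction of that relatedness with the year.

`kernpred` implements this reasoning as a family of Gaussian multi-kernel
("reaction norm") models, a Gibbs sampler to fit them, the two validation
schemes that mimic the two prediction problems, and a breeding-pipeline
simulator so that every stage can be tested end to end without external
data.

## The model family

All models are special cases of

$$y = \mathbf{1}\mu + \sum_k u_k + e, \qquad
  u_k \sim N(0, K_k \sigma^2_k), \qquad e \sim N(0, I\sigma^2),$$

where each $K_k$ is an observation-level covariance kernel:

* **E** — environment incidence, $Z_E Z_E'$: 1 for two observations in the
  same year, 0 otherwise (an iid year effect).
* **A** — the pedigree numerator relationship matrix, built by the tabular
  method ($a_{ii} = 1 + \tfrac12 a_{sd}$, $a_{ij} = \tfrac12 (a_{js} +
  a_{jd})$, terms with unknown parents dropped), expanded to observations
  as $Z_g A Z_g'$. Inbreeding accumulates on the diagonal; we compute the
  full Wright/Henderson matrix rather than assuming non-inbred lines, and
  use whatever pedigree depth the input contains.
* **G** — the genomic relationship matrix $XX'/p$ from the
  column-standardized marker matrix ($p$ = marker count). The marker-effect
  view $g_j = \sum_m x_{jm} b_m$ with $b_m \sim N(0, \sigma^2_b)$ is
  equivalent, with $\sigma^2_g = p\,\sigma^2_b$; the test suite asserts this
  duality numerically against an explicit ridge sampler.
* **AE, GE, GA, GAE** — Hadamard (elementwise) products of the expanded
  main-effect kernels, e.g. $(Z_g G Z_g') \circ (Z_E Z_E')$ for GE and
  $(Z_g G Z_g') \circ (Z_g A Z_g') \circ (Z_E Z_E')$ for the three-way
  term. The Schur product theorem guarantees these stay positive
  semidefinite. When observations are sorted by environment (the package's
  canonical order), every kernel containing the E factor is literally
  block-diagonal, which the factorization exploits.

Eight named models combine these terms: M1 = E+A, M2 = E+A+AE, M3 = E+G,
M4 = E+G+GE, M5 = E+G+A, M6 = E+G+A+GE+AE, M7 = E+G+A+GA,
M8 = E+G+A+GA+GAE. `list_models()` and `make_model()` expose the registry;
because each line is observed once, the GA kernel built at line level
(G∘A, then expanded) coincides with the Hadamard product of the expanded
kernels, and the tests assert that equality.

## Marker quality control

Markers with **more than 30%** missing calls are discarded, then markers
with minor allele frequency **below 0.05** (both boundaries taken
literally: equality survives). MAF is computed from observed calls;
remaining missing codes are imputed by the marker's observed mean before
standardization. These are the package defaults and can be changed per
call; the QC report (counts removed by each rule) travels with the data.

## Inference

`fit_gibbs()` re-parameterizes each kernel through its eigen factorization
$K = BB'$ (eigenvalues below `eigen_tol` = 1e-8 relative are dropped), so
each random effect becomes a ridge regression $u_k = B_k \delta_k$ with iid
coefficients. Because the columns of $B_k$ are orthogonal, the full
conditional of $\delta_k$ is diagonal and one Gibbs update costs two
matrix-vector products. Variance components get scaled-inverse-chi-square
full conditionals with weakly informative priors (df = 5; prior modes split
`prior_R2` = 0.5 of the phenotypic variance equally across the random
terms, the rest to the residual — the convention of standard Bayesian
genomic-regression software). The intercept has a flat prior. Defaults are
12,000 iterations, 2,000 burn-in, thinning 5; the examples and tests use
shorter chains sized to their problems.

Missing phenotypes are handled by data augmentation: they are drawn from
their predictive distribution each iteration, so a held-out observation is
predicted by exactly the same machinery in both validation schemes. For a
held-out *year*, the year's environment and interaction effects have
posterior mean near 0 (nothing informs them), so predictions reduce to the
intercept plus genetic main effects transmitted through relatives — this
falls out of the model rather than being a special case.

Two numerical conventions matter: a kernel is accepted as PSD when its
smallest eigenvalue is ≥ −tol·(largest); and no ridge is ever stored on a
kernel — degenerate directions are simply dropped by the factorization.
Convergence is not auto-diagnosed; `summary()` reports
autocorrelation-based effective sample sizes and `plot(fit, "trace")` shows
the chains, with thresholds left to the user.

### What the sampler mixes poorly on

When the residual variance is nearly zero and a full-rank kernel has many
eigenvalues of similar magnitude, the split between that component and the
residual is weakly identified per-direction and the variance chains mix
very slowly (the likelihood still identifies the split — a direct ML check
does — but the Gibbs path to it is long). This regime is far from the
breeding data the models target, where residual shares of 15–40% are
typical; the test suite deliberately probes recovery in the realistic
regime and documents the ceiling cases instead of asserting them.

## Validation schemes and scoring

* **CV1** — fivefold random partitioning of lines, repeated (20 replicates
  by default; smaller in the bundled checks), the five held-out prediction
  vectors joined and correlated with the observations *within each
  environment*. This measures prediction of lines never observed anywhere,
  in observed environments.
* **V00** — leave one year out entirely, fit on the remaining years, score
  within the held-out year. Run once, as no random partitioning exists.

Per-environment Pearson correlations are combined as a weighted mean with
weights $n_e / \sum_e n_e$. The per-environment standard deviation reported
for CV1 is across replicates (the weighted mean's sd is the sd of
per-replicate weighted means); environments with fewer than two scorable
observations or zero variance are skipped for that replicate with a
warning and excluded from the weights. Replicate and fold seeds derive
deterministically from the master seed. In V00, training pools the
remaining years as separate environment levels.

## The simulator

`simulate_breeding()` generates the structure the models assume:

* founders, several generations of crosses (depth 5 by default), and a
  final round of full-sib families with sizes from a shifted geometric law
  (minimum 1, capped at 116 by default) — family sizes in real pipelines
  are extremely skewed, with many singletons and a few very large families;
* marker genotypes by gene dropping: founder haplotypes at
  Hardy–Weinberg with uniform MAF in [0.05, 0.5], one allele per parent
  per locus chosen uniformly (Mendelian sampling; loci unlinked — the
  analysis only ever consumes relationship matrices, so a recombination map
  would add cost without exercising anything);
* one phenotyping year per line, families placed to balance year sizes,
  with ~15% of multi-member families split across two years by default
  (mirroring the minority of families observed in more than one cycle);
* phenotypes assembled additively from components drawn through the same
  kernel factorizations the fitting code uses, plus iid residual.

Component kernels are normalized to mean diagonal 1 before drawing so that
variance fractions are comparable across kernels, and each drawn component
is rescaled by a scalar to make its realized variance match its requested
fraction exactly. The rescale preserves the covariance shape; without it a
low-rank component (four year effects!) would realize its fraction only up
to enormous sampling noise, and parameter-recovery tests would measure the
generator's luck rather than the sampler's accuracy.

What the simulator does *not* emulate: linkage and LD, selection across
cycles, non-Gaussian traits (an ordinal lodging score is treated as
Gaussian, as is common), spatial field trends (the package consumes
line-level adjusted means, not plots), and genotyping error. Passing tests
on simulated data therefore demonstrate correctness of the machinery and
qualitative behavior of the schemes, not real-data accuracy levels.

## Design choices worth recording

* **Canonical observation order** (environment, then line id) is applied
  once at assembly; all kernels share it, making the env-product kernels
  block-diagonal and letting `factorize()` eigendecompose block by block.
* **Kernels are stored dense**; the intended scale (thousands of
  observations) fits comfortably, and provenance strings record how each
  kernel was built.
* **Unknown parents** are founders; with one parent known the tabular
  recursion keeps only the known parent's terms. Whether the original
  pedigrees carried selfing-generation inbreeding is not stated anywhere;
  we compute the general inbred form and let the input decide.
* **Prediction of a fixed-variance fit** is cross-checked against the
  closed-form mixed-model solution; the two agree to within Monte Carlo
  error, which is the package's primary guard against sampler bugs.
* **Effective problem sizes in the bundled checks** (chosen to exercise the
  study's structure at desk scale): ~1,400–1,600 lines across 4 years for
  variance-partition recovery, ~800 lines with 1,000 markers for the
  validation-scheme contrast, 100–200 observations for the exact-oracle
  comparisons.

## Known limitations

* Single trait, Gaussian likelihood, homogeneous residual variance across
  years.
* Variance percentages from non-orthogonal kernels (A, G and their
  products overlap substantially) are descriptive, not mechanistic — the
  same caution applies to the real-data analyses this package mirrors.
* With few environment levels (e.g. 4 years), the environment variance
  component is strongly influenced by its prior; its *predictive* role is
  unaffected, but its share of the percent table should be read with care.
* No REML/EM alternative; the Gibbs sampler is the only fitting engine.

## A worked run

```{r, eval = FALSE}
library(kernpred)

sim <- simulate_breeding(n_founders = 60, n_families = 80,
                         mean_family_size = 8, p_markers = 500, n_years = 3,
                         variance_fractions = c(E = 0.3, A = 0.2, G = 0.1,
                                                GE = 0.2, Res = 0.2),
                         seed = 42)
d <- kern_data(sim$pheno, trait = "y", pedigree = sim$pedigree,
               markers = sim$markers)
fit <- fit_gibbs(d, model = "M6", n_iter = 4000, burn_in = 1000, seed = 1)
summary(fit)

cv <- run_cv1(d, model = "M4", n_reps = 5, seed = 1,
              n_iter = 2000, burn_in = 500)
cv
v <- run_v00(d, model = "M3", seed = 1, n_iter = 2000, burn_in = 500)
v
```
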