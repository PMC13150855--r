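---
title: "Models and methods in metgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in metgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metgp` models multi-environment trials (METs): the same genotypes
phenotyped at several sites or years, with daily weather records per
site. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generator does
and does not emulate, and the design decisions that were genuinely open.

## 1. The environmental index

A MET environment is summarized by one scalar: the mean of one weather
factor over one day window. The search (`search_index()`) enumerates
every (factor, start, end) candidate on a step grid and scores each by
the R² of a simple across-environment regression of environment-mean
phenotype on the candidate's per-environment window mean. The winner is
the environmental index; its centred form `x_j = e_j − ē` enters all
downstream models.

Parameters and defaults:

* `min_width = 7` days — windows shorter than a week mostly fit daily
  noise; seven days also bounds the grid at O(D²) per factor for season
  lengths D ≤ 365.
* `step = 1` day — all start/end pairs on the daily grid. The
  "equal-sized bins" reading (windows aligned to fixed bins) is a strict
  subset of this enumeration, so the exhaustive default can only find a
  better or equal optimum.
* Ties are broken deterministically: earlier start, then shorter window,
  then factor name. Exhaustive grids on smooth synthetic data produce
  exact ties; a deterministic rule keeps runs reproducible.
* Environment-mean phenotypes use only the genotypes passed in
  `genotype_subset`. During cross-validation this is the training fold,
  so the index is re-searched inside every fold and no held-out
  phenotype influences it.

Degenerate cases: with two environments any non-constant factor fits
perfectly, so `m < 3` is refused. A window whose means are constant
across environments carries no information and scores R² = 0 (not NA), so
fully degenerate searches return the first candidate with a warning
rather than an arbitrary "perfect" fit.

The regression is unweighted least squares across environments;
environments are not weighted by their sample sizes. Sites in a designed
trial are deliberate choices, not a random sample whose precision should
set their leverage.

## 2. Reaction-norm framework

Per genotype, ordinary least squares of its phenotypes on the centred
index: `y_ij = b_i + k_i x_j + e_ij`. The intercept is the expected
phenotype at the across-environment index mean; the slope is the
sensitivity. Genotypes observed in fewer than three environments cannot
anchor a line and are excluded (with a warning listing them). The two
derived traits are then predicted independently for untested genotypes
with any registered estimator — a deliberate two-stage design; no
bivariate model is attempted because the slope/intercept sampling
covariance is dominated by the between-genotype signal at the trial
sizes this package targets.

For novel environments, `x_j` is centred with the **training** centre
(`index_environment()` carries it), so an environment whose raw index
equals the training mean predicts exactly the intercepts. Re-centring on
the extended environment set would silently shift every prediction.

## 3. Polygenic-environment-interaction framework

Every marker carries a main effect and an index-interaction effect.
Within environment `j` the design block is `[M | x_j M]`; stacking blocks
over environments with a **single shared** length-2p effect vector gives
the marker form, and the induced kinship has blocks
`K_(j,j') = (1 + x_j x_j') G`. Shared effects are what lets training
environments inform a left-out one; a literal per-environment
(block-diagonal) parameterization would pass zero information across
environments — within a block the interaction columns are exactly
collinear with the main columns — and is kept only as a comparison mode
(`effects = "by_env"`).

The bare index enters as a fixed regression `μ + β x_j`, not as
per-environment free intercepts, so novel environments remain
predictable from their own `x_j`.

Two further choices matter and were made deliberately:

* **Index scaling** (`scale_index = TRUE`): the centred index is divided
  by its standard deviation across environments before interaction terms
  are built. With a single shrinkage parameter shared by main and
  interaction columns, the measurement units of the index (°C vs
  standardized units) would otherwise set the implicit prior share of
  the interaction block arbitrarily — an index in °C with sd 2.5 gives
  the interaction kernel roughly six times the prior weight of the main
  kernel. Standardizing makes the fit unit-invariant.
* **Per-block variance components** (`variance = "per_block"`): for the
  GBLUP and rr-BLUP routes the main kernel `G` and the interaction
  kernel `(x x') ∘ G` get separate variance components; their relative
  weight is chosen by REML (a 1-D profile search over the mix). This is
  the standard structure for main + interaction kernels in G×E mixed
  models. Its practical consequence, verified by the test suite: when no
  interaction was simulated, the PEI fit is statistically
  indistinguishable from a main-effects-only fit, because REML shrinks
  the unused kernel away; under a single common variance the superfluous
  interaction block costs accuracy systematically.
  `variance = "common"` restores the literal single-component model and
  is used in the construction oracles, where the algebraic identity
  `K = X_all X_all'` must hold exactly.

Estimator routing inside `fit_predict_pei()`: GBLUP consumes the
kinship; the penalized and Bayesian regressions consume the stacked
design (their per-marker shrinkage handles the interaction columns
individually); kernel and tree learners consume per-record features
`[dosages, x_j]` by default (`features = "augment"` mirrors the
parametric design instead — doubling features tends to hurt tree
learners, hence not the default). Residuals are homoscedastic across
environments.

## 4. The estimator ensemble

All fifteen estimators satisfy `gp_fit(spec, y, X or K, covariates)` /
`predict()`, are seeded, and return effects plus variance components
where defined.

* **rr-BLUP / GBLUP**: REML through one spectral decomposition of the
  kinship and a 1-D profile likelihood over the log variance ratio
  (interval [−14, 14], tolerance 1e-10). The two are the same model in
  different coordinates; the package computes them along different
  arithmetic paths and the test suite checks they agree to 1e-8.
* **RR vs rr-BLUP**: the registry distinguishes them by how the ridge
  penalty is chosen — RR uses a fixed `lambda` (or a cross-validated
  grid when unset), rr-BLUP estimates it by REML. With `lambda` fixed,
  RR solves the penalized normal equations exactly, with the fixed part
  unpenalized.
* **Bayesian alphabet** (BRR, BayesA, BayesB, BayesC, BL): single-site
  Gibbs samplers with the conventional priors — common normal (BRR),
  per-marker scaled-inverse-χ² variances (BayesA), spike-and-slab with
  per-marker (BayesB, default π = 0.95) or common (BayesC) slab
  variance, and the double-exponential via inverse-Gaussian mixing with
  a Gamma hyperprior on λ² (BL). Defaults: 6000 iterations, 1000
  burn-in, thin 5, df₀ = 5, prior scales from the usual R² = 0.5
  elicitation against var(y) and the realized marker sum of squares.
  Variances can be pinned (`var_u`, `var_e`), which turns BRR/BayesC/
  BayesB(π = 0) into finite-sample ridge posteriors — the test oracles.
  A non-finite sampler state aborts with the iteration index.
* **RKHS / MKRKHS**: Gaussian kernel `exp(−h d²/median(d²))`, `h = 1`.
  The multi-kernel variant fits each bandwidth in {0.1, 0.5, 1, 2.5, 5}
  by REML, forms evidence weights (softmax of the REML log-likelihoods),
  refits on the weighted-average kernel, and predicts with the same
  weights. This is kernel averaging: a pragmatic, deterministic stand-in
  for fully Bayesian multi-kernel variance estimation.
* **SVM / RF / GBM**: ε-regression RBF SVM (e1071), 500-tree random
  forest (randomForest), depth-3 / 500-round / shrinkage-0.05 gradient
  boosting (xgboost, single thread). All run under a local, restored RNG
  seed so identical specs give identical fits.

## 5. Cross-validation, accuracy, heritability

Scenario (i), untested genotypes: genotypes are partitioned into k folds
per replicate (defaults k = 10, 5 replicates; k = 2 is the half-split
variant). Per fold the index search reruns on training genotypes only,
the framework refits, and held-out genotypes are predicted in all
environments. Accuracy is the Pearson correlation per environment; the
overall figure is the unweighted mean of per-environment means
(fold-level correlations are averaged; a pooled-prediction correlation
is reported alongside as `pooled_accuracy` since either convention is
defensible). Correlations over fewer than three pairs or against a
constant are NA with a warning, never silently zero.

Scenario (ii), novel environments: each environment in turn is masked
entirely, the index is re-searched on the remainder, the framework
refits, and the masked environment is predicted from its own weather
series (window mean of the selected factor, centred with the training
centre). RN needs at least three training environments per genotype, so
the scheme requires m ≥ 4 to be informative for RN; PEI works from m ≥ 2.

Variance components come from the balanced two-way expected-mean-squares
decomposition (`aov`-style mean squares; negative moment estimates
truncate at zero with a warning). With a single replicate the
interaction and residual variances are confounded; the interaction mean
square is then reported as Ve with Vge = 0, with a warning, rather than
inventing a split. Heritability is the entry-mean formula
`H = Vg / (Vg + Vge/L + Ve/(RL))`.

The `gp_dimension()` helper reports floor(log10(lines × markers)) and
warns at dimension ≥ 8, where the samplers and kernel methods become
expensive for little gain — guidance, not a hard limit.

## 6. The synthetic MET generator

`sim_met()` draws dosages Binomial(2, p) with allele frequencies uniform
in `maf_range` (independent markers by default, so estimator oracles stay
clean), smooth seasonal weather (sinusoid + per-environment offset +
daily noise), and phenotypes from the generative PEI structure with
sparse main and interaction marker effects and a grand index trend.

Two exactness choices make the configuration the *condition* rather than
a lottery over seeds:

* environment offsets are rescaled so their between-environment standard
  deviation equals `env_sd` exactly (random directions, fixed spread) —
  the index variance across environments is a design property;
* drawn effects are rescaled so the realized genetic variances equal
  their nominal budgets (`n_qtl × sd² × mean marker variance`). The
  attainability bound for the heritability target,
  `h² ≤ Vg / (Vg + Vge/L)`, is then a deterministic property of the
  configuration, and an unattainable target errors instead of silently
  clamping.

Residual variance is calibrated against the realized genetic surface so
the entry-mean heritability hits `h2` (or is pinned directly with `Ve`;
`Ve = 0` gives noiseless data for exact-recovery oracles). Defaults
(n = 200, p = 100, m = 4, 60 days, two temperature-like factors,
`sd_main = 0.3`, `sd_inter = 0.1`) put the interaction variance at
roughly a quarter of the genetic variance — the typical MET regime where
G×E is real but smaller than G — and keep h² targets up to ~0.9
attainable.

What the generator does **not** emulate: linkage disequilibrium,
population structure and kinship beyond random mating, multi-trait
correlations, heteroscedastic or correlated residuals, non-linear
(threshold, optimum-type) environmental response, and measurement
artifacts. Passing tests therefore demonstrate correctness of the
machinery and recovery under the stated generative model — not field
performance on real METs, where index misspecification and non-linear
response are the dominant risks.

## 7. Test and verification scale

The suite verifies every operation against an independent oracle where
one exists: direct linear solves for ridge, explicit matrix products for
the kinship construction, brute-force grid enumeration for the index
search, analytic posterior means for fixed-variance Gibbs, the
rr-BLUP/GBLUP equivalence on random instances, and generative ground
truth for end-to-end recovery. Simulation sizes in the tests (hundreds
of genotypes, ≤ 100 markers, 3–5 environments, 10–50 replicates of the
contrast experiments) were chosen so the full suite completes in a few
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances; the same code paths scale to dimension-7 problems
unchanged.

## 8. Known limitations

* Single environmental index; multiple simultaneous indices are out of
  scope by design.
* Balanced-design method of moments for variance components; REML for
  unbalanced data is not provided.
* The Gibbs samplers are plain R single-site updates — correct and
  adequate at desk scale, but not tuned for dimension ≥ 8 problems.
* `estimate_components()` with one replicate cannot separate Vge from
  Ve (reported confounded, with a warning).
* VCF ingestion is out of scope; convert to dosage matrices upstream.
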