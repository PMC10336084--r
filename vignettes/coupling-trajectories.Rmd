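---
title: "Modelling developmental structure-function coupling with sfcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental structure-function coupling with sfcoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Functional connectivity (FC) — correlated spontaneous activity between
brain regions — is scaffolded by structural connectivity (SC), the white
matter tracts linking those regions. *Structure–function coupling* asks,
region by region, how tightly a region's functional connectivity profile
follows its structural one. In development this coupling is itself
dynamic: association cortex couples more strongly through late childhood,
sensory cortex earlier, and neurodevelopmental conditions such as ADHD may
follow different trajectories.

`sfcoupling` implements that analysis end to end for a longitudinal
two-group design:

1. **Connectome construction** — FC as the Pearson correlation between
   regional time courses; SC from streamline counts with each edge scaled
   by the mean of its two endpoint regions' inverse volumes,
   $w_{ij} = c_{ij}\,\tfrac12(1/v_i + 1/v_j)$, symmetric with a zero
   diagonal.
2. **Quality control** — scans whose mean functional frame-wise
   displacement exceeds 0.5 mm are excluded.
3. **Consistency thresholding** — for each edge, the coefficient of
   variation (CV = sd/mean) of its weight across all analyzed scans;
   edges above the 75th percentile of the candidate CV distribution are
   removed, suppressing inconsistent (likely spurious) tractography edges.
   Regions left with no surviving edges are excluded everywhere.
4. **The coupling statistic** — for region $i$ in one scan, Spearman's
   rank correlation between $\{SC_{ij}\}$ and $\{FC_{ij}\}$ over the
   $j \ne i$ with non-zero (masked) structural weight. FC zeros are
   legitimate correlation values and are retained.
5. **Developmental trajectories** — per region, penalized-spline
   generalized additive mixed models (GAMMs) with subject random
   intercepts, compared along a nested ladder and corrected across
   regions by Benjamini–Hochberg FDR.

```{r, eval = FALSE}
library(sfcoupling)
cfg <- sim_config(seed = 1)
res <- run_pipeline(run_config(out_dir = "run1", sim = cfg))
```

## The trajectory model

For each region, with $y_{st}$ the coupling of subject $s$ at scan $t$:

$$y_{st} = \mathbf{x}_{st}^\top\beta + f(\mathrm{age}_{st}) + b_s +
\varepsilon_{st}, \qquad b_s \sim N(0, \sigma_b^2),\ \varepsilon_{st}
\sim N(0, \sigma^2)$$

where $\mathbf{x}$ always contains the nuisance covariates (diffusion and
functional head motion in mm, scanner upgrade flag, sex, medication
status) and $f$ is a cubic-spline smooth of age with basis dimension
$k = 4$. The four-model ladder is

* **M0** — covariates only,
* **M1** — M0 + $f(\mathrm{age})$,
* **M2** — M1 + group main effect,
* **M3** — M2 + a group-specific smooth deviation (so M2 $\subset$ M3).

All models are fitted by **exact marginal maximum likelihood**: the
penalized part of each smooth is re-expressed as a Gaussian random-effect
block with identity penalty, $\beta$ and $\sigma^2$ are profiled out in
closed form, and the remaining one to three log variance ratios are
maximized by a deterministic bounded search (five fixed starts on a log
grid for multi-parameter models; Brent-type scalar search otherwise —
no randomness in fitting). The reported log-likelihood is reproducible by
dense evaluation of the marginal Gaussian density at the estimates, which
is exactly how the test suite checks it (tolerance 1e-6).

### The spline basis

The smooth uses `k` cubic B-spline functions (for `k > 4`, interior knots
at age quantiles; `k = 4` spans the cubics on the observed range) with a
second-order smoothness penalty and sum-to-zero centering. The penalty is
built from second-order *divided differences* of the coefficients with
respect to the Greville abscissae rather than raw coefficient
differences: with quantile (non-uniform) knots, raw differences have a
null space linear in coefficient *index*, not in age, whereas the
divided-difference penalty's null space maps exactly onto
$\{1, \mathrm{age}\}$ by B-spline linear precision. Two consequences we
rely on: the centered basis splits cleanly into one unpenalized
linear-age column plus $k-2$ penalized columns, and as
$\lambda \to \infty$ the fitted smooth collapses onto the ordinary
least-squares line in age (a property the tests verify at
$\lambda = 10^8$ against an `lm()` oracle).

### Model comparison

A candidate model is adopted only if the likelihood-ratio test against
the currently accepted model has $p < 0.05$ **and** it improves that
model's AIC by at least 2 units, with
$\mathrm{AIC} = -2\ell_{ML} + 2(\text{fixed and smooth basis columns} +
\text{variance parameters})$. LRT degrees of freedom count unconstrained
smooth basis columns ($k - 1$ per smooth), an upper bound for penalized
terms that makes the test conservative; the type-I simulations in the
test suite confirm the stage-1 rejection rate stays below the nominal
level.

Two deliberate choices here were genuinely open:

* *"AIC units < 2"* is read as "the more complex model must improve AIC
  by at least 2 units" (`aic_margin = 2`, configurable).
* The walk is **forward with skipping** by default
  (`select_model(mode = "forward")`): each candidate is tested against
  the currently accepted model, and a failed stage does not end the walk.
  A strict stop-at-first-failure walk (`mode = "strict"`, also provided)
  can never reach the group model for a region with a pure group offset
  and no age effect — the age stage fails by construction — so strict
  sequential selection is structurally blind to one of the effect classes
  the analysis is designed to detect. Every pair along the ladder is
  nested, so the skipped comparison (e.g. M0 vs M2, df 4) remains a valid
  LRT.

FDR is applied per contrast family across regions: the age p-values form
one family, group another, interaction a third, each adjusted by
Benjamini–Hochberg with significance at $q \le 0.05$.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `fd_limit` | 0.5 | mm | motion exclusion on functional scans (strictly greater excludes) |
| `percentile` | 75 | — | CV percentile for consistency thresholding (type-7 quantile; ties at the threshold kept) |
| `min_edges` | 3 | edges | minimum non-zero structural edges for a defined rank correlation |
| `k` | 4 | basis functions | flexibility cap of the age smooth |
| `alpha` | 0.05 | — | LRT and FDR significance level |
| `aic_margin` | 2 | AIC units | required improvement per ladder step |

Conventions that matter for exact reproducibility: matrices are
symmetrized by averaging after an asymmetry check at tolerance 1e-8;
edges absent from every scan get an infinite CV sentinel and can never be
kept; zero weights count as observations in the CV (an absent edge *is*
evidence of inconsistency); the CV is computed across all analyzed scans
pooled over groups and waves, yielding one common mask so coupling is
comparable across groups; missing coupling values are dropped per region
(complete case within region); negative LRT deviances from optimizer
noise are clipped to zero.

## The synthetic cohort

Real multimodal MRI for this design is restricted and its preprocessing
(tractography, denoising) is far outside this package's scope, so the
generator in `sim_config()` / `simulate_study()` emulates the study's
*statistical* structure:

* 91 + 84 subjects, up to three waves ~1.4 years apart from age ~10.4
  (SD 0.5), ~60% male; per-wave retention defaults `(0.51, 0.53, 0.30)`
  with every subject attending at least one wave, chosen so expected
  attendance matches the published per-wave pattern and the expected
  total of ≈278 analyzed scans; head motion drawn from gamma
  distributions matching the published group-by-wave means and SDs (the
  heavy right tail also reproduces a realistic handful of QC
  exclusions); scanner upgrade at wave 3; wave-dependent medication
  rates in the ADHD group only.
* A shared community-structured base topology (stochastic-block, density
  0.25, log-normal weights); per-scan log-normal edge noise
  (`subject_sigma = 0.3`) and 5% edge dropout give the across-scan
  variability the CV thresholding consumes.
* Regional coupling is **planted through a Gaussian copula**: each
  region's latent functional profile over its structural neighbours is
  $r\,z + \sqrt{1-r^2}\,\epsilon$ with $z$ the Gaussian scores of the
  structural ranks and $r = 2\sin(\pi\rho_s/6)$ calibrated so the profile
  hits a target Spearman $\rho_s$; values are squashed into $(-1,1)$ by
  `tanh` and the matrix symmetrized by averaging the two row
  constructions.
* Planted targets follow per-region scenarios (default map: 20
  `increasing` at 0.04/yr, 10 `increase_then_plateau` flattening at age
  12, 10 `group_offset` at −0.10 in ADHD, 10 `group_by_age` with ADHD
  +0.05/yr vs flat controls, the rest null), on top of a regionally
  varying baseline (0.10–0.40, mirroring the real sensory-high /
  association-low coupling gradient), a subject-by-region random
  intercept (SD 0.03), covariate effects (default: −0.10 per mm of
  functional motion, +0.02 scanner offset) and residual noise (SD 0.05),
  clipped to $[-0.95, 0.95]$.

**Calibration.** Averaging the $(i,j)$ and $(j,i)$ constructions mixes
each region's planted signal with its neighbours' — roughly halving a
planted slope against mostly-null neighbours. The study generator
therefore pre-compensates the row targets by solving
$(I + A)\,x = 2\,t$ on the base topology's row-normalized adjacency $A$
(damped Jacobi iterations), so the *measured* statistic tracks the
planted target per node with slope ≈ 1. `simulate_fc_given_sc()` itself
is uncalibrated; compensation is a `sim_config` switch (`compensate`).

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: no haemodynamics or neural dynamics (FC
is planted, not simulated from time series), no distance- or
geometry-dependent tractography artifacts, no indirect (polysynaptic)
functional coupling, no scanner-specific spatial noise structure, and
attrition is missing-completely-at-random whereas real attrition is not.
The tests establish that the *pipeline measures and detects what it
claims to* under known ground truth; they cannot validate the
neuroscience of any particular dataset.

## Problem sizes used in validation

The test suite exercises the statistical machinery at the sizes that make
each check informative: exact oracles (Spearman, thresholding,
likelihood) on thousands of small random instances; type-I and FDR
calibration on 500 statistic-level null regions at the full cohort size;
and one full-scale connectome-route study (360 regions, ≈280 scans) for
scenario recovery, on which the ladder classifies ≥80% of effect regions
correctly, leaves >85% of null regions at M0, and recovers the planted
regional coupling with rank correlation >0.98. Smaller cohorts
(40–60 regions) are used where only mechanics, determinism or
input/output behaviour is under test.

## Known limitations

* The marginal-ML fitter handles subject random intercepts plus smooth
  blocks; it is not a general mixed-model engine (no nested/crossed
  random effects, no REML, no smooth-term confidence bands beyond
  pointwise Gaussian approximations of the fitted curve).
* LRT df counting is deliberately conservative for penalized smooths;
  borderline effects pay that price in power.
* AIC uses the simple ML definition above; it is internally consistent
  but not numerically comparable to `mgcv`'s conditional/edf-based AIC
  (`mgcv` agreement is checked on fitted curves, not on AIC values).
* The inverse-node-volume scaling convention (mean of inverse volumes) is
  one of the conventions in circulation for streamline connectomes; it is
  stated here explicitly so results are interpretable, not asserted as
  the only choice.
* `increase_then_plateau` regions are the hardest class to classify (their
  planted change is smaller and concentrated early); they dominate the
  ladder's residual error rate.
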