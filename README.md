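# sfcoupling

Regional **structure–function coupling** in longitudinal brain
connectomes: how tightly does each brain region's functional connectivity
profile follow its structural connectivity profile, and how does that
coupling develop across late childhood in a two-group (e.g. ADHD vs
control) longitudinal design?

The package is aimed at developmental neuroimaging groups who already
have per-scan connectome matrices (a structural and a functional 360×360
matrix per scan under the HCP-MMP parcellation, or any other square
parcellation) plus a cohort table, and want the full statistical pipeline
from matrices to FDR-corrected regional developmental effects — together
with a synthetic cohort generator that makes every stage testable without
access to restricted MRI data.

## The statistic and the model

For region *i* in one scan, coupling is Spearman's rank correlation
between the region's structural and functional connectivity profiles,
restricted to its non-zero structural edges:

ρᵢ = spearman( {SCᵢⱼ}, {FCᵢⱼ} ; j ≠ i, SCᵢⱼ > 0 )

computed after group-level consistency thresholding of the structural
matrices (edges above the 75th percentile of the across-scan
coefficient of variation are removed). Regional trajectories are then
modelled by penalized-spline GAMMs fitted by exact marginal maximum
likelihood,

yₛₜ = xₛₜᵀβ + f(ageₛₜ) + bₛ + εₛₜ,  bₛ ~ N(0, σ_b²),  εₛₜ ~ N(0, σ²)

with head motion (dMRI and fMRI), scanner upgrade, sex and medication as
covariates, a subject random intercept, and a k = 4 smooth of age. Four
nested models (null / + age / + group / + group×age deviation) are
compared by likelihood-ratio tests (p < 0.05) plus an AIC improvement of
at least 2 units, and each contrast's p-values are Benjamini–Hochberg
corrected across regions (q ≤ 0.05). See the methods vignette
(`vignettes/coupling-trajectories.Rmd`) for every convention and default.

## Worked example

A small synthetic study end to end (30 + 30 subjects, 80 regions):

```r
library(sfcoupling)
cfg <- sim_config(n_adhd = 30, n_control = 30, n_nodes = 80, seed = 2026)
res <- run_pipeline(run_config(out_dir = tempfile("run"), sim = cfg))
#> stage simulate: seed 2026, 30 + 30 subjects, 80 nodes
#> stage qc: 98 scans kept, 0 excluded (fd > 0.50 mm)
#> stage threshold: 599 / 799 edges kept (CV <= 0.4097), 0 node(s) excluded
#> stage couple: 7840 rows (98 scans x 80 regions), 0 missing
#> stage fit (typical): 80 regions, 0 FDR-significant age effects
#> stage fit (group): 80 regions; selected models: M0=75 M1=3 M2=2
```

The stage log reads as a flow diagram: 98 of 98 simulated scans survive
the 0.5 mm motion filter, exactly 75% of candidate structural edges
survive consistency thresholding (the CV cutoff that achieves this was
0.41), and 98 scans × 80 regions coupling values feed the models. Per
region results:

```r
subset(res$group$results, selected != "M0",
       select = c(region, p_age, p_group, selected, q_group))
#>    region       p_age      p_group selected    q_group
#> 17     17 0.010354859 0.9599338444       M1 0.97208491
#> 18     18 0.008360109 0.4014857531       M1 0.65404499
#> 21     21 0.013312481 0.4056624337       M1 0.65404499
#> 42     42 0.998268149 0.0001208346       M2 0.00966677
#> 45     45 0.217915254 0.0033338828       M2 0.05334213
```

Regions 17–21 carry planted age effects and are selected as M1 (age
smooth); regions 42 and 45 carry a planted ADHD coupling deficit with no
age trend — the forward ladder finds them as M2, and region 42 survives
FDR (q = 0.0097). A cohort this small is deliberately underpowered; at
the default study size (91 + 84 subjects, 360 regions, ≈278 scans) the
ladder recovers over 80% of planted effect regions and leaves >98% of
null regions at the null model.

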