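---
title: "Minicolumn-referenced cortical diffusivity and progression risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minicolumn-referenced cortical diffusivity and progression risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortodyn)
```

## The problem

Cortical minicolumns — vertical assemblies of neurons spanning the cortical
ribbon — impose a radial organization on gray-matter microstructure. In
neurodegeneration this columnar architecture degrades, and the degradation
is visible in diffusion MRI before macrostructural atrophy becomes
pronounced. `cortodyn` implements the full analysis chain for asking a
prognostic question with such measurements: *given a cohort of mild
cognitive impairment (MCI) patients, does a cortical microstructural marker
identify who will progress to dementia, and does it do so better than the
standard macrostructural markers (hippocampal volume fraction, a cortical
thickness meta-region, cortical volume fraction)?*

The chain is: per-vertex diffusivity metrics referenced to the radial
minicolumn axis → regional and meta-regional ("AD signature") averages →
confound adjustment → dichotomization at the crossing of the
cognitively-unimpaired (CU) and dementia (AD) densities → Kaplan–Meier and
log-rank survival comparison of the resulting N⁺/N⁻ MCI subgroups.

## The three metrics

Let $D$ be the diffusion tensor at a sample point, with eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ and eigenvectors
$e_1,e_2,e_3$, and let $r$ be the local radial axis (unit vector from the
white-surface vertex to its paired pial vertex). The package computes:

* **AngleR** $= \arccos |e_1 \cdot r| \in [0, \pi/2]$ (radians): the angle
  between the principal diffusion direction and the radial axis, treated
  axially so that sign flips of either vector are irrelevant.
* **ParlPD** $= \lambda_1 |e_1 \cdot r|$ (mm²/s): the principal diffusion
  component parallel to the minicolumn axis.
* **PerpPD⁺** $= \sum_i \lambda_i (1 - (e_i\cdot r)^2)
  = \operatorname{tr}(D) - r^\top D r$ (mm²/s): all diffusion components
  perpendicular to the radial axis, including the secondary and tertiary
  contributions.

No printed formulas exist for the latter two in the source literature, so
the definitions are configuration-selectable (`variant` arguments offer
$\lambda_1 (e_1\cdot r)^2$ for ParlPD and quadrature / principal-only forms
for PerpPD⁺). The defaults were chosen because (a) the trace form of
PerpPD⁺ is exactly rotation invariant and basis-independent under
eigenvalue degeneracy, and (b) both defaults land in the published
magnitude range for cortical gray matter (≈0.6×10⁻³ for ParlPD, ≈2×10⁻³
mm²/s for PerpPD⁺ with typical cortical eigenvalues).

### Profiles and aggregation order

A cortical profile is the straight segment from a white vertex to its
index-matched pial vertex, sampled at `n_samples = 7` evenly spaced points
including both endpoints. The radial axis comes from the vertex pair, not
from mesh normals — the least-assumption reading of a radially sampled
cortex. Metrics are computed **per sample against the profile's single
radial axis and then averaged**: first along the profile, then across the
vertices of each Desikan–Killiany region, then (unweighted, pooling
hemispheres) across the member regions of the signature. The alternative —
averaging tensors before eigendecomposition — is *not* done; a smoothing
operator applied before metric computation is mentioned in the source
analysis but unspecified, so it is exposed only as a disabled-by-default
hook rather than guessed.

Vertices with white–pial separation < 0.5 mm are flagged excluded;
profiles whose samples all fall outside the cortical mask are flagged
unmeasurable and skipped in aggregation; regions with no measurable vertex
propagate as missing with a warning.

The default diffusivity signature is the seven thickness-signature regions
(superior temporal, parahippocampal, middle temporal, inferior parietal,
inferior temporal, fusiform, precuneus) plus the posterior cingulate and
isthmus cingulate — the published description names the thickness regions
exactly but characterizes the diffusivity set only as extending into
medial posterior cortex, so the two cingulate additions are the minimal
faithful reading and the set is a plain argument everywhere.

### Numerical conventions

Tensors are stored packed (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz). Eigendecomposition
sorts eigenvalues descending, clamps negatives to zero (counting them), and
canonicalizes each eigenvector's sign so its largest-magnitude component is
positive. Sampling is nearest-neighbour by default; trilinear interpolation
of components followed by re-eigendecomposition is available. Coordinates
are world mm with 0-based voxel indices and a voxel-to-world affine.

## The phantoms

`gen_surface_pair()` / `gen_tensor_field()` build geometry with known
ground truth: a flat slab (radial axis $(0,0,1)$ everywhere) or a spherical
shell (radial axis = outward normal), with per-vertex labels forming
contiguous Desikan–Killiany patches. In cortical voxels the principal
eigenvector is drawn from a **Watson distribution** about the local radial
axis with concentration $\kappa$; the Watson family is the natural choice
because it is axially symmetric and controls exactly the quantity the
metrics measure (the angle to the axis), with axis sign irrelevant.
Sampling is by rejection on $t = |\cos\theta| \in [0,1]$ with density
$\propto e^{\kappa t^2}$ against a uniform proposal; $\kappa = 0$ gives
uniformly random axes ($t \sim U(0,1)$), and $\kappa \ge 10^6$ is treated
as the perfectly radial limit. Two closed forms anchor the tests: for
uniform axes the mean angle is $\int_0^{\pi/2}\theta\sin\theta\,d\theta = 1$
rad, and in the radial limit AngleR is identically zero. Outside the
cortex tensors are isotropic at the mean diffusivity; optional Gaussian
component noise is followed by eigenvalue flooring at $10^{-6}$ of the
mean diffusivity to keep every tensor positive-definite.

What the phantoms do *not* emulate: raw diffusion-weighted signal, gradient
schemes, eddy currents, motion, partial-volume mixing at the gray/white and
pial boundaries, and folded gyral geometry. Passing phantom tests therefore
demonstrates the correctness of the geometry → metric → aggregation chain,
not robustness to acquisition artifacts.

## The cohort simulator

`gen_cohort()` draws one record per subject in four groups (CU, MCI
non-converter, MCI converter, AD; defaults 474/110/86/156). Biomarkers are
Gaussian per group — the published summaries are means and SDs, so nothing
richer is identifiable — truncated at physical bounds (positive
diffusivities, fractions in (0,1)). The three signature metrics use their
published group moments; the macrostructural markers have **placeholder
moments** (no per-group SDs are published) chosen at physiologically
plausible values with the same qualitative ordering, and both matrices are
plain arguments. Demographics follow the published cohort table (age
means/SDs, sex ratios per group); scanner model and b-value are simple
categorical draws. Covariate effects on biomarkers are linear coefficients,
zero by default so that the group moments are exactly the configured ones.

MCI subjects carry a **latent neurodegeneration status**: PerpPD⁺ signature
at or above the midpoint of the generative CU and AD means (2.0825). Event
times are exponential with median 777 days (latent N⁺) or 2447 days (latent
N⁻); censoring is independent uniform on (0, 9 years) — the simplest
mechanism consistent with administrative follow-up — and the observed time
is the minimum. Tying survival to the latent label makes label-recovery
testable without circularity: the pipeline re-derives N status from the
cutpoint machinery and can be compared against the generative truth.
`simulate_survival_arms()` provides the bare two-arm design (42 N⁺ / 154
N⁻) for scaled replication runs. CSF biomarkers are constructed as linear
combinations of the standardized target metrics plus independent noise,
with weights solved from the metric correlation matrix (requests implying
explained variance ≥ 1 raise an infeasibility error).

One known simplification: survival depends only on the latent biomarker
status, not on the generative MCI_NC/MCI_C label, so a subject drawn in the
"converter" stratum can be censored. The labels describe baseline cohort
structure; events are what the survival analysis consumes.

## Statistics

**Confound adjustment** fits value ~ age + sex + scanner + b-value by
least squares (continuous covariates mean-centred, categorical covariates
dummy-coded against the most frequent level) and returns residual +
intercept, i.e. the value at reference covariates. The fitting population
defaults to CU ∪ AD — the sample that defines the cutpoint — so that MCI
outcomes cannot leak into their own adjustment; `fit_subset = "all"` is
available since the source analysis does not state its choice.
Macrostructural markers omit the b-value term. Adjustment is idempotent up
to numerical tolerance.

**Group comparisons** use a linear model with diagnostic group as a fixed
factor plus the covariates; all 6 pairwise adjusted-mean contrasts are
tested with Bonferroni correction over the family and α = 0.05 two-sided.
Regional analyses run one model per region and control FDR with
Benjamini–Hochberg within each (metric, contrast) family across regions —
per-hemisphere regions (68) by default. `bh_fdr()` wraps `p.adjust()` with
an explicit step-up rejection set. CSF associations use partial Pearson
correlations (residualizing on age, sex, assay) with the t transform on
n − 2 − k degrees of freedom.

**Cutpoints.** Each group's density is estimated with a Gaussian kernel and
Silverman's bandwidth on a shared 2048-point grid spanning the pooled range
± 3 pooled SD. The threshold is the sign-change of $f_{CU} - f_{AD}$
between the group medians, refined by linear interpolation; multiple
crossings resolve to the one with the lowest balanced (equal-prior)
misclassification rate, ties toward the median midpoint. Balanced error is
the right empirical counterpart because density equality is the equal-prior
Bayes boundary; a raw-count criterion would be dragged toward the larger
group. When no crossing lies between the sample medians — which genuinely
happens under the calibrated moments, where the crossing sits close to the
AD median — the pipeline falls back to an exhaustive balanced-error scan
(`fallback = "empirical"`), and the method used is recorded in the result.
Boundary semantics are asymmetric by convention: for high-is-positive
metrics a value equal to the threshold is N⁺; for low-is-positive markers
only values strictly below it are N⁺.

**Survival.** The Kaplan–Meier estimator, Greenwood variance, median with
confidence interval, restricted mean, log-rank and pairwise log-rank are
implemented from first principles (the `survival` package serves only as an
independent cross-check in the test suite). Conventions: time origin at
the scan, days as the unit, years reported as days/365.25 rounded to one
decimal; events precede censorings at tied times; the median is the
smallest time with $S(t) \le 0.5$; its CI inverts the pointwise log(−log)
CI of $S$ (the plain transform is available); the restricted mean is the
area under $S$ limited to the largest observed time even if censored, with
the standard Greenwood-type variance. The pairwise log-rank between
overlapping classifications (the same subject can be positive under two
measures) replicates the published procedure verbatim; the stretched
independence assumption is documented here rather than "fixed", and
identical classifications short-circuit to χ² = 0.

## Pipeline and reproducibility

`run_pipeline()` sequences cohort → acquisition filter (slice thickness
> 3 mm, b-value > 3000, or sub-3T field excluded, strict inequalities) →
descriptives → group GLMs → adjustment → cutpoints → classification →
per-measure survival analysis, writing deterministic CSV/JSON artifacts.
Config plus seed fully determine every number; the determinism test
byte-compares two runs. Stage failures abort with stage-named diagnostics.
In synthetic mode the biomarkers come from the cohort simulator; the
imaging stages (`compute_vertex_metrics()` etc.) run on phantom or file
inputs and are exercised separately, because generating per-subject tensor
volumes for an 826-subject cohort would add nothing to what the phantom
tests establish.

## Problem sizes used by the tests

The suite sizes simulations to keep each property statistically decisive:
the uniform-disarray closed form uses ≈10⁵ profile samples (mean AngleR
within 0.01 of 1 rad); estimator-oracle agreement uses 1000 random small
instances at 10⁻¹⁰ tolerance; the Watson sampler's uniform limit uses
5×10⁵ draws against a Kolmogorov–Smirnov bound of 0.005; the scaled
survival replication uses 200 replicates of the 42/154 design; calibrated
cohort properties use 100 replicates at the full 826-subject design.
Monotonicity-in-κ uses 400-vertex slabs, the smallest size at which the
region-mean signature resolves κ = 1 from κ = 0 (single-vertex region
means are too noisy below that).

## Limitations

* The KDE bandwidth, grid and crossing refinement are reasonable defaults,
  not a bit-level reproduction of any particular statistics package.
* Placeholder macrostructural moments mean the simulator's HVF/CT/CVF
  group separations are illustrative, not literature-calibrated.
* The pairwise log-rank over overlapping groups inherits the procedure's
  independence caveat.
* Phantom realism ends at the tensor level; no claim is made about
  preprocessing robustness.
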