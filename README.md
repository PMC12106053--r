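# cortodyn

Minicolumn-referenced cortical diffusivity metrics and their use as
prognostic biomarkers for progression from mild cognitive impairment (MCI)
to dementia.

Cortical minicolumns give gray matter a radial microarchitecture. As
neurodegeneration disorganizes it, the principal diffusion direction in
cortical voxels drifts away from the radial axis. `cortodyn` computes three
metrics that quantify this along radial cortical profiles (white-surface
vertex → paired pial vertex), for a diffusion tensor $D$ with eigensystem
$\lambda_1\ge\lambda_2\ge\lambda_3$, $e_1,e_2,e_3$ and radial axis $r$:

* **AngleR** $= \arccos|e_1\cdot r|$ (rad) — disarray angle;
* **ParlPD** $= \lambda_1|e_1\cdot r|$ (mm²/s) — principal component
  parallel to the minicolumns;
* **PerpPD⁺** $= \mathrm{tr}(D) - r^\top D r$ (mm²/s) — all components
  perpendicular to the minicolumns.

Metrics are averaged along each profile, across Desikan–Killiany regions,
and over a temporo-parietal + posterior-cingulate "AD signature"
meta-region. The prognostic pipeline then: adjusts each biomarker for age,
sex, scanner and b-value; derives a neurodegeneration cutpoint as the
crossing point of the cognitively-unimpaired and dementia probability
densities; classifies MCI participants N⁺/N⁻; and compares
progression-free survival of the two arms with from-scratch Kaplan–Meier
estimation and log-rank tests, including pairwise log-rank comparisons
between competing measures (PerpPD⁺ signature vs hippocampal volume
fraction, cortical-thickness signature, cortical volume fraction).

Synthetic generators make everything testable without clinical data:
cortical phantoms whose principal directions follow a Watson distribution
with known concentration about the radial axis, and cohort simulation
calibrated to published group moments and survival medians.

## Worked example

```r
library(cortodyn)
rep <- run_pipeline(run_config(seed = 1))
print(rep)
#> Pipeline report: 826 subjects, 196 MCI in survival analysis
#>     measure arm   n median_days logrank_chi_square    logrank_p
#>  perppd_sig  N+  73    828.2442        17.70995174 2.572771e-05
#>  perppd_sig  N- 123   2132.7064        17.70995174 2.572771e-05
#>         hvf  N+  99   1294.4006         0.50535304 4.771574e-01
#>         hvf  N-  97   1723.6554         0.50535304 4.771574e-01
#>      ct_sig  N+ 102   1593.3043         0.02214398 8.817047e-01
#>      ct_sig  N-  94   1257.4911         0.02214398 8.817047e-01
#>         cvf  N+  89   1593.3043         0.21920982 6.396427e-01
#>         cvf  N- 107   1537.7114         0.21920982 6.396427e-01
print(rep$cutpoints$perppd_sig)
#> Cutpoint for perppd_sig: threshold = 2.13688 (high_is_positive), n_CU = 474, n_AD = 156
```

Reading the output: one synthetic 826-subject cohort was generated (474 CU,
110 MCI non-converters, 86 MCI converters, 156 AD); the four survival
measures were adjusted and dichotomized at their CU/AD density crossings,
and the 196 MCI participants' progression-free survival was compared
between N⁺ and N⁻ arms per measure. In this cohort the PerpPD⁺-signature
classification separates the arms sharply (median 828 vs 2133 days,
log-rank χ² = 17.7, p ≈ 2.6×10⁻⁵) while the macrostructural
classifications do not — the expected behaviour, since the simulator ties
progression hazard to the latent PerpPD⁺ status. The PerpPD⁺ threshold
2.137 ×10⁻³ mm²/s lies between the CU and AD group centres (1.986 and
2.179).

Phantom-level example:

```r
spec <- phantom_spec("slab", n_vertices = 400, kappa = 0, seed = 1)
surf <- gen_surface_pair(spec)
vol  <- gen_tensor_field(surf, spec)
vm   <- compute_vertex_metrics(surf, vol)
mean(vm$angler[vm$measurable])   # ~1.0 rad: closed form for uniform axes
```

A thin command-line wrapper over the same functions lives at
`inst/cli/cortodyn.R` (subcommands `simulate`, `metrics`, `all`).

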