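# periaq

Free-water corrected diffusion-tensor analysis of the **periependymal
lining** — the one-voxel layer of normal-appearing white matter around the
brain ventricles — for two-group neuroimaging studies, with a synthetic
DWI phantom cohort so the whole pipeline runs and is tested without any
patient data.

The package is aimed at neuroimaging researchers comparing
aquaporin-4–seropositive neuromyelitis optica spectrum disorder (NMOSD)
against multiple sclerosis (MS), where AQP4 concentrates on the ependymal
surfaces of the third and fourth ventricles, but the machinery is generic:
any study of ventricle-lining tissue on single-shell DWI can use it.

## The model

Voxels near CSF are contaminated by partial-volume free water. periaq fits
the two-compartment bi-tensor model per voxel,

    S(g, b) = S0 [ (1 − f) exp(−b gᵀ D g) + f exp(−b d_w) ],

with free-water fraction `f ∈ [0, 1]`, tissue tensor `D`, and fixed
free-water diffusivity `d_w = 3.0e−3 mm²/s`. Corrected FA/MD/AD/RD are the
eigenvalue metrics of `D`. Because one shell cannot identify `(f, MD)` on
its own, the fit combines eigenvalue box constraints, a Gaussian tissue-MD
prior (MAP tensor refit), and an optional spatial smoothness penalty on
the `f` field, with the data term scaled by an estimated noise variance so
the priors vanish on clean data — see the methods vignette
(`vignettes/periependymal-free-water.Rmd`) for the estimation details.

Around the core fit the package provides: phantom/cohort synthesis with
Rician noise, NIfTI + FSL bval/bvec I/O, standard tensor fitting and tSNR
QC, 1-voxel shell extraction with lesion subtraction, ROI summaries, and
the inference layer (propensity matching, Mahalanobis screening, MANCOVA
with Wilks λ / Rao F / partial η² / observed power, post-hoc ANCOVA,
demographic tests, and MANOVA power analysis).

## Worked example

One synthetic subject through the image pipeline, then a simulated cohort
through the statistics:

```r
library(periaq)

spec   <- phantom_spec(snr_b0 = 25, n_lesions = 1L, seed = 7L)
labels <- build_label_volume(spec)
gtab   <- design_gradient_table(32, b = 1000)
params <- tissue_params(ring_evals = list(
  third = as.numeric(fa_md_to_evals(0.4962, 0.632e-3))))
dwi    <- synthesize_dwi(labels, params, gtab, snr_b0 = 25, seed = 7L)

fit <- fit_fwe_volume(dwi, gtab, label_mask(labels, "wm"))
#> <fwe_result: 66117 voxels, spatial regularization, 2 sweeps, median f = 0.185>
summarize_roi(fit, periependymal_shells(labels))
#>     shell n_voxels    fa       md       ad       rd missing
#> 1 lateral      876 0.624 0.000597 0.001094 0.000349   FALSE
#> 2   third      142 0.489 0.000598 0.000958 0.000417   FALSE
#> 3  fourth      114 0.618 0.000597 0.001087 0.000352   FALSE
```

The third-ventricle lining mean FA (0.489) recovers the value injected
into that shell's tissue (0.4962) from noisy data; the `f` map medians
0.185 across white matter, rising toward the ventricles. A cohort drawn
with the default NMOSD-vs-MS contrasts, screened and tested:

```r
cohort <- simulate_cohort_table(seed = 2)            # 20 NMOSD, 24 MS
scr <- mahalanobis_screen(cohort, c("fa_v3", "md_v3", "ad_v3", "rd_v3"))
mancova(scr$cohort, c("fa_v3", "md_v3", "ad_v3", "rd_v3"),
        covariates = c("age", "edss"))
#> MANCOVA (group: NMOSD vs MS; covariates: age, edss)
#>   Wilks lambda = 0.6975, F(4, 37) = 4.011, p = 0.008419
#>   partial eta^2 = 0.302, observed power = 0.869 (ncp = F * df1 (observed statistic))
#> Post-hoc ANCOVA per dependent variable:
#>     dv       F        p adj_mean_NMOSD adj_mean_MS
#>  fa_v3 12.0394 0.001262       0.485030   0.5344996
#>  md_v3  0.1802 0.673440       0.000638   0.0006448
#>  ad_v3  5.2078 0.027880       0.001022   0.0010893
#>  rd_v3  2.7489 0.105142       0.000444   0.0004215
```

The group factor separates the four third-ventricle metrics (λ = 0.70,
p = 0.008), driven by lower FA in NMOSD after age/EDSS adjustment — the
qualitative pattern such studies report. A-priori sample size for a
MANOVA global effect at Pillai V = 0.4, α = 0.05, power 0.80 over the full
8-variable response set:

```r
manova_power(pillai_v = 0.4, n_groups = 2, n_dvs = 8)$N
#> [1] 32
```

A thin CLI (`exec/periaq`) wraps the same functions:
`periaq simulate`, `periaq fit-fwe`, `periaq qc-tsnr`, `periaq roi-stats`,
`periaq group-stats`, `periaq power`.

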