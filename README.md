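# mbmorph

Mode-based morphometry (MBM) of cortical thickness on triangular surface
meshes, with permutation inference on modal coefficients, two
interhemispheric asymmetry indices, nonparametric cohort statistics, and
a fully synthetic cortical-cohort generator.

## What it is for

Neurodegenerative diseases such as *GRN*-related frontotemporal dementia
thin the cortex asymmetrically and across multiple spatial scales.
Vertex-wise surface-based morphometry (SBM) tests thickness one vertex at
a time; MBM instead decomposes maps into the geometric eigenmodes of the
cortical surface — solutions of the Helmholtz equation on the mesh,

    Δψ_k = −λ_k ψ_k,

ordered from coarse (hemisphere-wide gradients) to fine (focal patterns).
A map *f* is represented by modal loading coefficients β from the
least-squares fit *f* ≈ Σ_k β_k ψ_k, and group inference is performed on
β rather than on vertices: the observed two-sample t map is projected
onto the basis and compared against a permutation null of |β|, flagging
the spatial scales that carry the group difference. Two asymmetry
indices summarize left–right differences per subject:

* **SBM-AI** — `(CT_RH − CT_LH) / (0.5 (CT_RH + CT_LH))` over a
  symmetric bilateral mask (plus the similarity form `1 − |AI|`);
* **MBM-AI** — `|corr(β_LH, β_RH)|` over the first 25 modes (the
  constant mode plus the first four eigengroups); 1 = spectrally
  identical hemispheres, lower = more asymmetric.

The package is aimed at method developers and simulation studies: its
synthetic module generates three-group cohorts (controls /
presymptomatic / symptomatic) on a shared mirrored template with planted
left-lateralized modal atrophy and clinical scores linked to the planted
modal weights, so calibration, power, and recovery of every pipeline
stage can be quantified without any imaging data.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic cohort; each is a thin driver over the package API.

```sh
Rscript analysis/01_simulate_cohort.R   # 61-subject cohort -> results/cohort
Rscript analysis/02_eigenmodes.R        # 150-mode basis + spectrum check
Rscript analysis/03_mode_inference.R    # permutation mode tests (10000 perms)
Rscript analysis/04_asymmetry.R         # SBM-AI / MBM-AI + group stats
Rscript analysis/05_clinical_models.R   # Spearman + mode-wise GLM
Rscript analysis/06_recovery_experiment.R  # power / type-I sweep
```

With the default seed, stage 3 prints (planted modes: 1, 2, 9, 10, 13 on
the left, 9 and 13 attenuated on the right):

```
lh_symptomatic_vs_hc: significant modes (by |beta|): 1, 13, 9, 2, 10, 18, ...
lh_presymptomatic_vs_hc: significant modes (by |beta|): 123, 43, 147
rh_symptomatic_vs_hc: significant modes (by |beta|): 13, 9
```

— the symptomatic contrast recovers the planted coarse modes and ranks
them first; the right hemisphere flags exactly its two planted modes;
the presymptomatic contrast (no planted effect) flags only a
chance-level handful. Stage 4 prints the asymmetry summary:

```
bilateral mask: 443 vertices per hemisphere
mbm_ai: HC 0.9999 | presympt 0.9999 | sympt 0.9983 (KW p = 2.13e-10)
sbm_ai_similarity: HC 0.9980 | presympt 0.9977 | sympt 0.9347 (KW p = 6.19e-10)
```

i.e. controls and presymptomatic carriers are indistinguishable while
symptomatic carriers are markedly more asymmetric under both indices —
the qualitative signature the indices are designed to detect. (MBM-AI
values sit close to 1 by construction: the constant-mode loading
dominates the correlation; group differences, not absolute values, carry
the signal.)

A minimal programmatic session:

```r
library(mbmorph)
cohort <- generate_cohort(simulation_config(seed = 1))
basis  <- cohort$basis
grp    <- cohort$subjects$group
test <- mbm_group_test(cohort$thickness_lh[, grp == "hc"],
                       cohort$thickness_lh[, grp == "symptomatic"],
                       basis, n_perm = 1000, seed = 1,
                       mask = cohort$mask, mesh = cohort$mesh_lh)
test$ranking          # significant modes by decreasing |beta|
ai <- asymmetry_table(cohort, basis, bilateral_mask = cohort$mask)
tapply(ai$mbm_ai, ai$group, mean)
```

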