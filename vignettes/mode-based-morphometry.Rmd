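---
title: "Mode-based morphometry of cortical thickness: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mode-based morphometry of cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vertex-wise surface-based morphometry (SBM) tests cortical thickness one
vertex at a time, at a single spatial scale. Mode-based morphometry (MBM)
instead decomposes a cortical map — or a group-difference statistic map —
into the *geometric eigenmodes* of the cortical surface, the solutions of
the Helmholtz equation on the mesh,

$$\Delta \psi_k = -\lambda_k \psi_k,$$

where $\Delta$ is the Laplace–Beltrami operator (LBO) of the surface.
Eigenmodes are ordered from coarse ($\lambda$ small: whole-hemisphere
gradients) to fine (localized, high-frequency patterns), so inference on
their loading coefficients characterizes *at which spatial scales* two
groups differ. This package implements the full workflow — operator
assembly, eigenmodes, least-squares modal projection, permutation
inference on modal coefficients, two interhemispheric asymmetry indices,
and nonparametric cohort statistics — together with a synthetic cohort
generator that emulates the asymmetric, left-lateralized atrophy of
progranulin (*GRN*)-related frontotemporal dementia, so every stage is
testable without any imaging data.

## Discretization and eigensolver

The LBO is discretized as the classical cotangent stiffness matrix $K$
with **lumped barycentric mass**: vertex $i$ carries one third of the
area of its incident triangles, giving a diagonal mass matrix $M$. The
off-diagonal stiffness entry for edge $(i,j)$ is
$-(\cot\alpha + \cot\beta)/2$ over the two angles opposite the edge; rows
sum to zero. Lumping makes the generalized eigenproblem
$K\psi = \lambda M\psi$ equivalent to the *standard* symmetric problem
$(M^{-1/2} K M^{-1/2})u = \lambda u$ with $\psi = M^{-1/2}u$.

We solve that whitened problem with a full dense symmetric
eigendecomposition (LAPACK). At the mesh resolutions this package targets
(icosphere subdivisions 3–4, i.e. 642–2562 vertices — chosen so the
entire analysis, including permutation and replication studies, runs on a
single CPU in minutes) the dense solve is exact, deterministic, and takes
seconds; an iterative shift-invert Krylov solver would add stochastic
start-vector machinery for no accuracy benefit at this scale. Three
numerical conventions follow:

* $\lambda_1$ is clamped to zero when $|\lambda_1| < 10^{-10}\lambda_2$
  (the analytic kernel of the LBO on a closed surface is the constant).
* Eigenvector signs are arbitrary, so every basis is sign-fixed by a
  canonical rule (the vertex of largest absolute value is made positive,
  ties broken by lowest vertex index); `align_mode_signs()` can instead
  align a basis to a reference via mass-weighted inner products.
* Modes are returned **mass-orthonormal**
  ($\Psi^\top M \Psi = I$), which ties modal amplitudes to physical
  surface area.

Correctness is anchored to the sphere: on an icosphere the spectrum must
reproduce the spherical-harmonic multiplets $\lambda_\ell =
\ell(\ell+1)/r^2$ with multiplicity $2\ell+1$. At subdivision 4 the first
four multiplets agree with the closed form to better than 0.7%; at
subdivision 3 the $\ell = 4$ group is ~2.5% low, which is ordinary
cotangent-FEM discretization error and is why degenerate-subspace tests
compare *projectors per eigengroup*, never individual degenerate
eigenvectors.

### Eigengroups

Mirroring the sphere, mode 1 (constant) forms group 0 and groups
$g \ge 1$ contain $2g+1$ consecutive modes. The constant mode plus groups
1–4 is exactly $1+3+5+7+9 = 25$ modes — the truncation used for the
asymmetry index.

## Modal projection

`project_map()` computes the loading coefficients $\beta$ of a map $f$ by
**unweighted least squares over masked-in vertices**, all modes fitted
jointly: $\hat\beta = \arg\min \sum_{v \in \text{mask}} (f_v - \sum_k
\beta_k \psi_{kv})^2$. Two deliberate choices:

* *Unweighted*, not mass-weighted: the plain least-squares reading of the
  projection step; the columns are near-orthogonal on quasi-uniform
  meshes so the difference is small, but the convention matters for
  reproducibility.
* *Truncation refits jointly.* Under a cortex mask the restricted columns
  are not orthogonal, so the 25-mode fit used by the asymmetry index is a
  joint fit on 25 columns, **not** the first 25 entries of the 150-mode
  fit. The slicing alternative exists internally (`beta_slice()`) for
  sensitivity analysis; tests assert the two genuinely differ under
  masking.

Rank deficiency (mask too small or degenerate) raises an error carrying
the condition number rather than returning unstable coefficients.

## Group inference on modes

`mbm_group_test()` computes the pooled-variance two-sample t map
(default direction: reference group minus patients, so thinner cortex in
patients appears positive), projects it onto the basis, and builds a
per-mode permutation null by relabeling subjects `n_perm` times. The
p-value uses the add-one estimator
$p_k = (1 + \#\{|\beta^{\text{null}}_k| \ge |\beta^{\text{obs}}_k|\}) /
(n_{\text{perm}} + 1)$ — ties count toward the numerator, the observed
labeling is implicitly included, and $p \ge 1/(n_{\text{perm}}+1)$, so a
warning fires when `n_perm` cannot reach the requested alpha. Modes with
$p \le \alpha$ are flagged, ranked by $|\beta^{\text{obs}}|$, and
combined into the significant-pattern map.

Per-mode p-values are **not** additionally corrected across the 150
modes: the permutation scheme itself is the multiplicity device of the
reference design, and the package reports raw mode-wise p at
$\alpha = 0.05$ by default. A max-$|\beta|$ family-wise null is
implemented (`family_wise = TRUE`) for users who want strong control.
Statistic maps can also be thresholded vertex-wise
(`threshold_map()`, default two-tailed $p < 0.001$) with a deterministic
minimum-cluster-area rule (default 100 mm², barycentric vertex areas) —
a deliberate, reproducible simplification of Monte-Carlo cluster-wise
correction, which is out of scope.

Permutations are drawn uniformly with replacement across permutations
(uniqueness is not enforced), chunked matrix-algebra makes $10^4$
permutations over a 642-vertex cohort a few seconds, and the seed is
recorded in the result; identical seeds give bit-identical results.

## Asymmetry indices

Both hemispheres live on one shared template: the right-hemisphere mesh
is the mirrored left template with *identical vertex indexing*, so
homotopic correspondence is vertex-index identity and both hemispheres
project onto one shared, sign-aligned basis. (This replaces
cross-hemispheric spherical registration, which is out of scope; with
real data, maps must be resampled to such a shared template upstream.)

* **SBM-AI** (conventional): within a symmetric bilateral region of
  interest — the dominant hemisphere's significance map binarized at
  $p < 0.05$ and copied to the other hemisphere —
  $\mathrm{AI} = (\overline{CT}_{RH} - \overline{CT}_{LH}) /
  \tfrac12(\overline{CT}_{RH} + \overline{CT}_{LH})$.
  The raw index is 0 for perfect symmetry and $\approx +0.105$ for a 10%
  unilateral left thinning. Because the reference analyses plot a
  *similarity* (values near 1 in controls), the package reports both the
  raw index and $1 - |\mathrm{AI}|$; the similarity form is what should
  be compared against plotted control values near 0.98.
* **MBM-AI**: the absolute Pearson correlation of the hemispheres'
  first-25-mode loading vectors, $|\mathrm{corr}(\beta^{LH}_{1..25},
  \beta^{RH}_{1..25})|$; 1 means spectrally identical hemispheres, lower
  means greater asymmetry. The constant mode is included by default (the
  literal first-$N$-modes convention; a flag excludes it). Note the
  constant-mode loading is large for thickness maps, which compresses the
  index toward 1 — control-group values around 0.996–0.9999 are expected
  behavior of this index, and group *differences*, not absolute values,
  carry the signal.

## The synthetic cohort generator

The generator *defines the study conditions*; its defaults are fixed by
design, not tuned:

* **Groups 19 / 15 / 27** (controls / presymptomatic / symptomatic),
  the study's cohort sizes.
* **Template**: icosphere, subdivision 3, radius 90 mm (sphere area
  $\approx 1018$ cm², close to a human hemisphere's pial area), with a
  25° polar cap excluded as a medial-wall stand-in. Subdivision 3 keeps a
  200-replicate calibration affordable while resolving the first ~150
  modes stably.
* **Baseline thickness**: 2.5 mm plus fixed low-order modal structure on
  modes 2–13 with coefficients of 0.03–0.12 mm RMS, giving smooth
  regional variation of roughly ±0.2 mm, as in smoothed real maps.
* **Planted atrophy** (symptomatic group only; presymptomatic carriers
  deliberately carry no effect, mirroring the null finding for that
  contrast): left-hemisphere amplitudes of 0.15, 0.10, 0.08, 0.08 and
  0.12 mm RMS on modes 1, 2, 9, 10 and 13 — the coarse-scale subset of
  the reported significant-mode set; the two fine-scale reported modes
  (25, 68) are excluded from defaults because a subdivision-3 template
  does not resolve them robustly. Right-hemisphere atrophy is 40% of the
  left on modes 9 and 13 only, producing the left-lateralized pattern.
  Total planted thinning is ~0.25 mm RMS, the magnitude of symptomatic
  FTD atrophy.
* **Severity**: each subject's amplitudes scale with a CDR-stage weight
  (0.5 → 0.5, 1 → 0.8, 2 → 1.2, 3 → 1.4) plus independent per-mode
  Gaussian jitter (sd 0.35), giving realistic between-subject and
  between-mode heterogeneity (and keeping the modal weights of different
  modes from being perfectly collinear in regressions). Stage
  probabilities follow the published stage counts (9/12/7/11/3 across
  CDR 0/0.5/1/2/3, split between carrier groups).
* **Noise**: i.i.d. Gaussian vertex noise, sd 0.1 mm. Real smoothed maps
  have spatially correlated noise; here the *signal* is generated smooth
  (modal baseline) and the noise left white, which makes the calibration
  results cleaner than real data would be — a stated limitation, not a
  bug. Thickness is floored at 0.1 mm (clips are counted and reported).
* **Clinical linkage**: TMT-A $= 150 - 800\,\beta_9 - 1200\,\beta_{13} +
  \varepsilon$ (sd 30 s), TMT-B $= 420 - 600\,\beta_9 - 800\,\beta_{13} +
  \varepsilon$ (sd 60 s), both floored at 10 s, computed from the
  subject's *planted* left-hemisphere modal weights (mm RMS) and
  generated for symptomatic subjects only. With the planted amplitude
  spread this yields symptomatic TMT-A means near 130 s with a wide
  range, matching the reported scale.

All randomness flows from one master seed through per-subject derived
seeds, so cohorts are bit-reproducible and a subject's draws do not
change when another group's size changes. Amplitude-sweep experiments
reuse replicate seeds across sweep points (common random numbers), making
monotonicity checks paired.

### What passing tests do and do not show

The acceptance suite demonstrates: exact eigengroup structure; sphere
spectra within 2%; machine-precision agreement with dense oracles;
permutation calibration (null rejection 3–7% at $\alpha = 0.05$ over 200
replicates); ≥90% detection and top-ranking of a single planted mode at
the design amplitude; exact symmetric-case values and strictly monotone
MBM-AI response over a five-point amplitude sweep; and ≥90% recovery of
the planted clinical-linkage coefficients at $n = 27$. Because the
synthetic data are white-noise-plus-smooth-signal on a sphere, these
results certify the *machinery*, not clinical performance on real
cortical geometry, real spatial noise correlation, or registration error.

## Degenerate inputs and tie-breaks

Zero-area faces and disconnected meshes are rejected at construction;
zero pooled variance at a vertex yields $t = 0$ with a logged count (not
an error); an empty mode subset reconstructs a zero map with a warning;
an empty bilateral mask after thresholding is an error (the index is
undefined); $|\beta|$ ranking ties break toward the lower mode index;
all-identical samples give Kruskal–Wallis $H = 0$, $p = 1$. Vertex
indices are 1-based in memory (R convention) and 0-based in every
on-disk format, including label files.

## Known limitations

* Spherical (or mildly perturbed) templates only are generated; real
  cortical folding changes mode shapes, though not the machinery.
* The shared-template identity correspondence sidesteps cross-hemisphere
  registration entirely; with real data that step must happen upstream.
* The cluster-area rule is a deterministic stand-in for cluster-wise
  Monte-Carlo correction and will not match FreeSurfer cluster p-values.
* Nuisance covariates (age, sex) are not modeled in the two-sample
  permutation design; group matching is assumed done at the sample
  level, as in the reference design.
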