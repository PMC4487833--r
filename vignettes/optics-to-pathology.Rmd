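---
title: "From diffuse optics to histopathology: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From diffuse optics to histopathology: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dothisto)
```

## The scientific question

Diffuse optical tomography (DOT) images deep-tissue hemoglobin physiology in
vivo: oxyhemoglobin and deoxyhemoglobin concentration, total hemoglobin
(THC) and tissue oxygen saturation (StO2), plus reduced scattering.  Diffuse
correlation spectroscopy (DCS) measures microvascular blood flow from the
decay of the temporal intensity autocorrelation of multiply scattered
coherent light.  Pathologists, meanwhile, grade breast tumors
microscopically: the Ki67 fraction of proliferating nuclei, CD34-stained
microvessel density and area, and nuclear shape.  `dothisto` implements the
full analysis chain that connects the two scales — tumor-to-normal ratios
of the optical parameters on one side, slide-level biomarker quantification
on the other, and the small-sample correlation statistics between them —
together with a synthetic-cohort generator that renders all three raw data
modalities from known per-subject ground truth, so that every stage can be
validated by parameter recovery rather than by eye.

Because tumor-to-normal *ratios* are used on both sides (written rX:
rStO2, rTHC, rHbO2, rHb, rmusp, rBF, rKi67), inter-subject variation in
absolute baseline physiology largely divides out.

## Stage models and their assumptions

### Chromophore unmixing

Reconstructed absorption volumes at wavelengths $\lambda$ obey the spectral
Beer-Lambert mix $\mu_a(\lambda, v) = \varepsilon_{HbO_2}(\lambda)\,
C_{HbO_2}(v) + \varepsilon_{Hb}(\lambda)\, C_{Hb}(v)$.  `fit_chromophores()`
solves this per voxel by non-negative least squares; with two unknowns the
constrained optimum is found in closed form by enumerating the boundary
candidates, which makes the inversion exact (machine precision) on
noise-free input.  Water and lipid are omitted deliberately — the analysis
carries only hemoglobin-derived parameters — and the extinction table is a
configurable input (`default_extinction()` ships a standard compilation at
690/750/786/830 nm in mm⁻¹ µM⁻¹).  Concentration maps yield
$StO_2 = C_{HbO_2}/(C_{HbO_2}+C_{Hb})$, masked (`NA`) where total
hemoglobin falls below 10⁻³ µM rather than propagating 0/0.

### Tumor segmentation

The tumor region is grown from the maximum-intensity voxel inside a seed
hint, keeping the connected component (26-neighborhood by default) above
half of the seed intensity — a literal full-width-at-half-maximum cutoff,
with ties broken to the lowest linear index so segmentation is
deterministic.  Two practical points the implementation had to resolve:

* **Half-maximum needs a contrast map.**  On an absolute absorption map a
  half-of-peak threshold falls below the background whenever tumor contrast
  is under 2:1, and the "region" floods the volume.  The pipeline therefore
  segments the background-subtracted total-hemoglobin map (volume median
  removed).  THC was chosen because its tumor contrast is sign-definite
  (every tumor in the emulated cohort has rTHC > 1), whereas oxy/deoxy
  absorption contrast can cancel near the isosbestic region for highly
  oxygenated, low-THC tumors.
* **A flat plateau is not missing contrast.**  A seed hint lying entirely
  inside the tumor plateau is constant; the no-contrast error is raised
  only when a constant hint sits *below* the global maximum.

The half-maximum rule is invariant under positive rescaling of the input
map (the threshold is relative to the peak), and mask volume is monotone
non-increasing in the cutoff fraction; both are property-tested.

Ratios are then means over the mask versus means over its complement.
Regional StO2 is computed from the masked-mean concentrations (mean HbO2 /
mean THC per region), which makes the identity
$rStO_2 \equiv rHbO_2 / rTHC$ hold to machine precision; the voxelwise
alternative (mean of per-voxel StO2) is available via
`sto2_mode = "mean_of_voxels"`.  Averaging over the FWHM mask dilutes the
tumor mean slightly, because the mask includes the blend shell where
contrast runs from 1 down to ½ of peak; with the generator's default edge
width (below) this bias stays under 2 % for every ratio.

### DCS blood flow

`g2_model()` implements the correlation diffusion equation in the
homogeneous semi-infinite geometry with an extrapolated boundary:
$G_1(\tau) \propto e^{-K\tau r_1}/r_1 - e^{-K\tau r_b}/r_b$ with
$K^2(\tau) = 3\mu_a\mu_s' + 6\mu_s'^2 k_0^2\,\mathrm{BFI}\,\tau$
(Brownian-motion flow model, $\mathrm{BFI} = \alpha D_B$),
$z_0 = 1/\mu_s'$, $z_b = 2(1+R_\mathrm{eff})/(3\mu_s'(1-R_\mathrm{eff}))$,
$R_\mathrm{eff} = 0.493$ for $n = 1.4$, and the Siegert relation
$g_2 = 1 + \beta |g_1|^2$.  Lengths are converted to a single unit (mm)
internally; BFI is accepted in the conventional cm²/s and the probe
separation in cm (2.5 cm default).  The forward model is verified in tests
against a second, independently coded evaluation in cm units.

`fit_bfi()` fits $(\log_{10}\mathrm{BFI}, \beta)$ jointly by bounded
Levenberg-Marquardt, multi-started over a log-spaced grid of initial flow
values; $\beta$ is fitted rather than fixed because curve normalization is
instrument-dependent.  The fit window runs from the first delay to the
point where the curve reaches the mean of its last 10 % of values, so the
noise floor is not fitted.  Curves that do not decay (amplitude below
`min_decay = 0.02`) are *rejected* — `converged = FALSE` — not errored,
and `compute_rbf()` excludes them (with a count) before forming
rBF = mean tumor BFI / mean normal BFI.  Tumor/normal position labels are
taken from the input, as in a palpation-guided line scan; no automatic
relabeling is attempted.

### Oxygen metabolism

With $\gamma$ the venous fraction of blood volume,
$StO_2 = (1-\gamma)SaO_2 + \gamma SvO_2$, so
$\gamma = (SaO_2 - StO_2)/(SaO_2 - SvO_2)$, and the tumor-to-normal
metabolic rate of oxygen is
$rMMRO_2 = (\gamma_N/\gamma_T)\,(rHb / rTHC)\; rBF$.
A saturation outside $[SvO_2, SaO_2]$ has no physical venous fraction and
raises a structured error carrying the offending value.  When saturations
are unavailable the ratio $\gamma_N/\gamma_T$ falls back to 1, and the
result records which mode produced it (`gamma_source`), since the choice is
a modeling assumption, not a measurement.  In the pipeline, tumor and
normal $\gamma$ are derived from the tumor- and normal-mean StO2 maps; the
default arterial/venous anchors there are $SaO_2 = 0.98$ and
$SvO_2 = 0.55$ — the venous anchor sits below the lowest StO2 the 2:1
oxy:deoxy normal reference can produce (0.67), keeping every derived
$\gamma$ inside (0, 1].

### Histology quantification

Brightfield IHC color formation is multiplicative, so analysis happens in
optical density, $OD_c = -\log_{10}(I_c / I^0_c)$, where the two stains
(hematoxylin, DAB) mix linearly.  Deconvolution projects each pixel's OD
vector onto a fixed two-vector basis (standard published OD triplets,
configurable); per-slide basis estimation is deliberately out of scope
since the renderer and the quantifier must share one color model.

* **Dark artifacts.**  Near-black dye clusters would otherwise read as
  strongly positive nuclei; connected regions with minimum channel below
  30/255 and area ≥ 200 µm² are masked automatically (a reproducible
  surrogate for manual exclusion during slide review).
* **Nuclei.**  Hematoxylin-channel thresholding, connected components
  within 8–200 µm², positivity by mean DAB amount above 0.2.  An optional
  single watershed pass splits touching nuclei but is off by default — the
  renderer keeps nuclei separated, and the paired thresholds were tuned on
  it.
* **Ki67 scoring.**  Per ROI, percent positive of total nuclei; per
  subject, the ROI-area-weighted average (ROIs without nuclei carry no
  information about the fraction and are excluded from the weighting).
  Subjects whose normal tissue shows no Ki67 expression return an
  undefined-ratio signal for rKi67 and participate only in cancer-only
  analyses.
* **Vessels.**  DAB-stained, hematoxylin-free components are traced; a
  structure is a *closed* cross-section iff its wall topologically encloses
  a lumen — filling holes adds at least 5 px — after a 1-px binary closing
  that bridges staining gaps.  The closing is applied per component, not to
  the whole mask: a global closing was observed to bridge the small gaps
  *between* neighboring structures and fuse them, inflating mean vessel
  area by ~14 %.  Only closed cross-sections enter MVD (count per µm²),
  MVA (lumen + wall) and mean vascular area (wall only); open arcs are
  detected and excluded.  Subject-level values are ROI-area-weighted means
  of per-ROI means, and the renderer records its ground truth under the
  same convention — with a handful of vessels per ROI, a pooled mean and a
  mean-of-ROI-means differ materially, and the two sides must agree on the
  estimand.
* **Nuclear compactness.**  $4\pi A / P^2$ per nucleus: 1 for a circle,
  smaller for elongated shapes.  The perimeter estimator matters more than
  anything else here.  Counting boundary pixels inflates P by up to ~8 %;
  a corner-corrected chain-code estimator is better but still biases
  compactness high by 3–5 % at nucleus scale (radius 5–7 px), enough to
  push round nuclei above unity.  The estimator used is the perimeter of
  the low-pass Fourier-smoothed boundary polygon plus the 0.5-px Minkowski
  offset (boundary pixel centers sit half a pixel inside the true
  outline); it is accurate to ~2 % down to r ≈ 5 px and keeps the
  isoperimetric bound intact.  The chain-code estimator remains as the
  fallback for contours of fewer than 8 points.

### Statistics

Pearson (with the classical t-transform p-value), Spearman as Pearson on
mid-ranks with an exact permutation p for n ≤ 9 (full enumeration, ties
preserved) and the t approximation beyond, and the two-sided Wilcoxon
rank-sum test — exact by enumeration when the pooled sample is ≤ 12 and
tie-free, otherwise normal approximation with tie and continuity
corrections.  Two identical constant groups return p = 1.  Ki67 positivity
uses the strict > 15 % convention (a value exactly at the cutoff is
negative; the cutoff is a parameter because clinical practice varies
between 10 and 20 %).  `npv_scan()` tabulates confusion counts and
predictive values over candidate thresholds with undefined (not zero) rates
on empty denominators, `linear_fit_ci()` adds the t-based pointwise
confidence band for the mean response, and `build_association_table()`
crosses optical ratios with histology markers using pairwise-complete
observations and per-cell n — subjects enter exactly the analyses their
data support.  No multiple-testing correction is applied by default,
matching exploratory-study convention; Benjamini-Hochberg columns are
available behind `p_adjust = "BH"`.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` samples ten primary latents per subject — rStO2, rTHC,
rBF, rmusp, tumor and normal Ki67 percent, mean vessel area, microvessel
density, tumor and normal nuclear compactness — from a Gaussian copula
with a configurable correlation matrix and truncated-normal marginals.
Design choices worth knowing:

* **Derived, never sampled.**  $rHbO_2 = rStO_2 \cdot rTHC$ and
  $rHb = (rTHC \cdot THC_N - rHbO_2 \cdot HbO_2_N)/Hb_N$, so the
  saturation/total-hemoglobin identities hold exactly by construction and
  are tested as invariants.
* **Marginals are truncated normals**, not lognormals: the copula then
  behaves as a near-linear transform of its Gaussian drivers, so a designed
  driver correlation of 0.9 survives to the rendered parameters with little
  attenuation — which is what makes end-to-end correlation recovery a
  sharp test.  Defaults place rTHC above 1 for every subject (tumors carry
  more blood), tumor Ki67 in the 0–35 % range with a ~12 % center, normal
  Ki67 a few percent with half the subjects showing none at all
  (`p_no_normal_ki67 = 0.5`, mirroring a 9-of-18 split), and tumor nuclei
  more elongated than normal ones.
* **The default correlation structure** encodes the sign pattern the
  pipeline exists to detect: oxygenation with proliferation (0.9), total
  hemoglobin and scattering with vessel area, oxygenation with nuclear
  compactness, flow with proliferation.  The matrix is validated positive
  semi-definite, with the offending eigenvalue named if not.
* **Normal-reference absolutes** (HbO2 20 µM, Hb 10 µM, µs' 0.8 mm⁻¹,
  BFI 10⁻⁸ cm²/s) are plausible normal-breast values and pure placeholders:
  the analysis consumes only ratios, and the config flags them as such.
* **Phantom geometry.**  Ellipsoidal tumors (semi-axes 5–9 mm) on a 48³
  grid of 1 mm voxels, blended into background by a Gaussian edge in the
  distance from the ellipsoid surface.  The default edge width of 0.3 mm
  was chosen so that FWHM-mask dilution keeps noise-free ratio recovery
  within the 2 % contract; the analytic half-maximum location
  ($\sigma\sqrt{2\ln 2}$ beyond the surface) is what the segmentation tests
  check against.
* **Slides.**  Two tissue regions (tumor, normal), each under two
  rectangular ROIs; nuclei are filled ellipses whose axis ratio realizes
  the compactness latent, with *exact* positive counts so Ki67 truth is
  count-determined; vessels are DAB annuli with known lumen/wall areas, 20 %
  of them drawn as open arcs to exercise the closed-cross-section rule;
  three near-black artifact blobs exercise the exclusion step.  Object
  placement is rejection sampling with no overlap; when a subject's
  elongated nuclei or large vessels would exceed the packing regime the
  canvas auto-expands (counts and sizes preserved) — on a fixed canvas
  (`auto_expand = FALSE`) the same situation is a layout error.  Vessel
  count follows the MVD latent but is capped by an area budget, so MVD
  saturates for extreme subjects while MVA stays faithful.
* **Seeding.**  All randomness derives from one integer seed through a
  (subject × modality) sub-stream scheme, so any stage can be re-rendered
  in isolation and whole runs are byte-reproducible.

What the generator does *not* emulate: the photon-migration measurement and
image reconstruction that would precede the absorption volumes (those are
inputs here), realistic tissue texture, scanner color calibration,
out-of-focus or uneven-thickness slides, and nucleus overlap heavy enough
to require segmentation-splitting.  Passing round-trip tests therefore
demonstrates that the quantification stages are correct and unbiased under
the stated rendering model — not that they would match a commercial
scanner's output on real tissue bit-for-bit.

## Problem sizes and numerical choices

The validation suite uses: 64³ voxels for the unmixing round trip; a
σ = 4 voxel Gaussian blob for segmentation; 60-delay curves with 50 noisy
replicates (σ = 0.005) for DCS recovery; 50 rendered slides for the
histology round trip; full enumeration for the statistics oracles (all
C(18,3) = 816 label assignments for the rank-sum attained level, 5000
simulated null datasets for its type-I check); and a 200-subject cohort on
the demo-scale layout (768 × 512 px slides, 80 tumor nuclei; 40³ phantom
grids) for end-to-end correlation recovery.  These sizes give sampling
error comfortably below each tolerance while keeping a full run in
minutes.

Numerical details that are deliberate: NNLS clamps rather than projects
(exact for 2 columns); segmentation ties break to the lowest linear index;
the region grower works on the bounding box of above-threshold voxels; the
Levenberg-Marquardt fit bounds β in (10⁻³, 1] and log₁₀BFI in [−12, −4];
undefined results (empty ROI, zero normal Ki67, no closed vessels, zero
variance) are explicit `NA` signals with reasons, never silent zeros.

## Known limitations

* The FWHM mask dilutes tumor means toward background; the bias is edge-
  width dependent and only bounded (< 2 %) under the generator's defaults.
* MVD is a weak estimand on a bounded canvas (count data, budget-capped
  for extreme subjects); MVA is the vessel metric the validation leans on.
* The venous-fraction model is a two-compartment simplification; γ anchors
  are assumptions surfaced in the output, not measurements.
* Statistics are exploratory by design: no multiplicity correction by
  default, two-sided tests throughout.
* Whether a real study's Spearman p-values at n = 9 were exact or
  asymptotic is generally unknowable from a report; both are available here
  (`exact` argument) and the exact mode is the default at that size.

## A worked sketch

```{r, eval = FALSE}
set.seed(1)
res <- demo_pipeline(seed = 1, n_subjects = 12)
print(res)               # per-analysis n and the association table
res$subjects[, c("subject_id", "rStO2", "Ki67_T_pct", "rKi67", "MVA")]

# one subject, stage by stage
co <- generate_cohort(cohort_config(n_subjects = 1, seed = 1))
ph <- render_phantom(co[1, ])
cm <- fit_chromophores(ph$vols, default_extinction())
tm <- grow_tumor_region(pmax(cm$THC - median(cm$THC), 0),
                        seed_box(dim(cm$THC), round(ph$center_mm), 4))
relative_params(cm, ph$vols$musp, tm)
```
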