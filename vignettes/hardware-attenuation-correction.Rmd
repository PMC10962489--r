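---
title: "Quantifying radiotherapy-hardware attenuation correction in PET-MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiotherapy-hardware attenuation correction in PET-MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrtac)
```

## The problem

PET images used for radiotherapy planning are acquired in the treatment
position: the patient lies on a flat couch top with the anterior MR coil held
on a rigid coil bridge. All of that hardware sits inside the PET lines of
response and attenuates the 511 keV annihilation photons, but none of it is
visible to the MR-based workflows that scanners use to assemble attenuation
correction (AC) maps. If the AC map only contains the patient and the scanner
bed ("CTACstd" in this package), the reconstruction under-corrects every line
of response crossing the hardware and the whole image is depressed by roughly
ten to twenty percent in SUV. Adding couch, bridge and anterior coil models to
the map ("CTACcba") removes that bias.

`petrtac` implements the full evaluation of that effect as a reproducible
synthetic study: what happens to gross tumour volume (GTV) delineation, to SUV
metrics and to total lesion glycolysis (TLG) based prognosis when the
hardware is left out of the AC map, with every other part of the chain held
fixed — the *same* emission data is reconstructed twice, once per AC variant.

## The forward model and its deliberate simplifications

Real scanners use 3-D Bayesian penalized-likelihood reconstruction with
time-of-flight and point-spread-function modelling. None of that changes what
an AC map does to the data, so the package uses the smallest physically
faithful surrogate:

* slice-wise parallel-beam line integrals (the LOR set),
* emission attenuation by the *true* μ-map:
  `expected = P(activity) · exp(−P(μ_true))`,
* optional Poisson noise at a configurable total-count budget, seeded,
* attenuation correction factors `ACF = exp(+P(μ_ac))` from the *assumed*
  μ-map,
* ramp-filtered back-projection (Hann apodisation available), with negative
  values clipped so SUV semantics hold.

When `μ_ac = μ_true` and noise is off, the attenuation factors cancel
exactly and the pipeline reduces to plain FBP — the test suite asserts the
uniform-disc reconstruction is unbiased to within 2% inside 80% of the disc
radius. When hardware is omitted from `μ_ac`, the per-LOR deficit is
`exp(−∫μ_hw)`, and the image-domain mean deficit matches the
activity-weighted LOR average of that expression to well under one
percentage point (the acceptance script recomputes both).

μ-maps come from CT-like volumes through the standard bilinear conversion:
`μ = 0.0096·(1 + HU/1000) mm⁻¹` below 0 HU (clamped at zero), a bone slope
of 5.25·10⁻⁵ mm⁻¹/HU above. Both constants are arguments.

SUV conversion uses the body-weight convention,
`SUV = C·W·1000 / A(t)`, with the injected activity decay-corrected to the
acquisition start (a single short bed position makes the start/mid-scan
distinction negligible; the half-life defaults to 109.77 min for 18F).

## The synthetic cohort

No public imaging data accompanies the clinical analysis this package
operationalises, so the phantom generator is a first-class module. Each
synthetic patient is:

* an elliptic water cylinder (0 HU) in air, default semi-axes 85 × 65 mm on
  a 96 × 96 × 8 grid at 2.5 × 2.5 × 3 mm — a deliberately desk-scale pelvis;
* a uniform background uptake of 1.5 g/mL;
* one primary lesion per patient with a gaussian falloff profile
  (σ = radius/2) and peak SUVs log-spaced over ≈6.5–38 g/mL across the
  cohort so lesion SUVmean spans the low-to-high avidity range where the
  delineation mechanism changes behaviour; a smaller nodal lesion in most
  patients (6–12 g/mL peaks);
* a bowel-gas air pocket (−1000 HU, zero uptake) that exercises the
  water-fill rule;
* injection metadata jittered around 3.5 MBq/kg (±10%) with 60–86 min
  uptake, mirroring typical clinical ranges;
* every fourth patient's primary is tagged as abutting the bladder, which
  switches the threshold-delineation expansion to 0 mm in that direction.

Placement jitter and Poisson draws are the only randomness, and both flow
from the single study seed through named substreams, so a config + seed pair
reproduces every number bit-for-bit.

Hardware defaults are a 20 mm couch slab abutting the posterior body
surface, an 8 mm coil-bridge arc and a 10 mm anterior-coil arc above the
pelvis, plus a thin scanner-bed slab that is present in *both* AC variants
(the "std" map is a strict subset of the "cba" map's hardware content). The
μ values (0.0032, 0.0024, 0.0032 mm⁻¹) were chosen once so that the
simulated whole-image SUV loss falls in the high-single-digit to high-teens
percent range reported for real radiotherapy hardware; they are
configuration, not claims about any specific device.

What the generator does **not** emulate: anatomical texture and organ
heterogeneity, bladder filling, respiratory or bowel motion, scatter and
randoms, detector normalisation, and the resolution/noise structure of
Bayesian reconstruction. Passing tests therefore demonstrate the *mechanism*
and the integrity of the analysis chain, not clinical effect sizes.

## AC-map construction rules

The map builder reproduces the clinical harmonisation chain on the synthetic
CT:

1. rigid resampling onto the reference grid (the transform is an input —
   registration estimation is out of scope; identity in synthetic mode);
2. crop to the MR external contour; tissue inside the MR contour but outside
   the CT contour becomes water (0 HU);
3. internal air below −400 HU becomes water ("water-fill"); the threshold is
   a config choice — any value separating gas from soft tissue on a
   water-equivalent phantom behaves identically, and the fill is idempotent;
4. HU→μ conversion (single conversion path: fills are expressed in HU first);
5. hardware overlays composed by voxelwise **maximum**, not sum — overlap
   should resolve to the physical μ of the occupying material, and max keeps
   the composition idempotent at touching faces.

Every step appends a provenance record, and composition asserts
`μ(CTACcba) ≥ μ(CTACstd)` voxelwise.

## Delineation

Two procedures are modelled:

* **semi-manual surrogate**: fixed threshold at SUV ≥ 2.5 g/mL (the value
  regarded as diagnostic for malignant ano-rectal uptake), 26-connected
  component intersecting a seed region, then an *edit hook* — an explicit
  function injection point standing in for the radiologist's manual
  adjustment. Manual editing is inherently irreproducible; making it an
  identity-by-default hook keeps the surrogate deterministic while letting
  tests inject morphological edits.
* **relative threshold**: strictly *above* 40% of the SUVmax inside the
  manual contour (single maximum voxel, no peak smoothing), constrained to a
  5 mm euclidean expansion of the manual contour, with per-direction
  overrides (0 mm towards an abutting bladder). The fixed threshold is
  ≥-inclusive while the relative threshold is strict — the wording for the
  relative rule is "above that threshold" — and both comparisons are config
  options.

Expansion is metric (millimetres, anisotropic, per axis and sign), not voxel
counts, so the margins survive anisotropic grids.

These two rules carry the study's central mechanism: a hardware-omission
deficit acts approximately multiplicatively on SUV, so the relative
threshold is invariant (both SUVmax and the boundary scale together) while
the fixed threshold moves along the lesion profile. On gaussian-profile
lesions the induced volume change shrinks as peak uptake grows, which is why
low-avidity lesions are the vulnerable ones. The acceptance suite asserts
all three facets on a seeded 10-phantom cohort: semi-manual |%ΔV| exceeds
threshold |%ΔV| lesion-by-lesion (≥85% of lesions, and in the mean),
semi-manual |%ΔV| anti-correlates with lesion SUVmean, and the threshold
mask is bit-identical under a global multiplicative bias.

## Metrics and statistics

* Dice `2|A∩B|/(|A|+|B|)`; **mean distance to agreement** is implemented as
  the *symmetric* mean surface distance (surface voxels = mask voxels with a
  non-mask 6-neighbour, centre-to-centre distances in mm). The clinical
  planning-system implementation is not publicly specified; symmetry makes
  the metric order-independent, and both Dice and MDA are verified against
  exhaustive brute-force oracles on all masks up to 7³ voxels.
* Per-voxel percentage differences `(std − cba)/cba` inside a 0.05 g/mL
  external contour of the reference image, binned into 400 left-closed bins
  spanning ±100% (the last bin closed). Out-of-range values are discarded,
  not clamped; zero-reference voxels are excluded and counted for QC. The
  cross-patient curve reports the per-bin mean ± standard error.
* Paired t-tests on per-patient percentages (equivalently a one-sample t on
  the differences — the two framings coincide), two-sided (the conservative
  default), with a Bonferroni-corrected level of 0.05/(4 × 2) = 0.006 for
  the four parameters × two contour methods. Zero-variance pairs raise an
  error rather than silently returning NaN.
* TLG = SUVmean × volume (g/mL × cm³ = g). Prognostic volumes re-threshold
  at each literature rule's own fraction (50% of SUVmax with a 125.84 g
  primary-lesion cut-off; 30% with a 341 g primary-plus-nodal cut-off) by
  default; `prognosis_use_study_fraction = TRUE` reuses the study's 40%
  contours instead, since the literature fractions bracket it. TLG at or
  **above** the cut-off classifies as poor prognosis (the equality case is
  undocumented in the source rules; ties-to-poor matches the direction
  "higher TLG, poorer prognosis"). Patients lacking a primary lesion are
  skipped for the primary-only rule and reported as skipped.

## Numerical choices

* Detector bin width = in-plane voxel size; bins cover the grid diagonal;
  180 angles over [0, π). Ray sampling at half the voxel size.
* Ramp filter evaluated on a zero-padded power-of-two FFT grid (minimal
  artifact baseline for quantitation); Hann optional.
* Default count budget 2·10⁷ expected counts per patient — enough that
  Poisson noise perturbs but does not dominate the contour comparisons, as a
  desk-scale stand-in for a 5-minute bed position.
* Degenerate inputs raise early with messages: empty masks, lesions below
  threshold ("not FDG-avid"), zero-variance pairs, zero reference values.
* Problem sizes (96 × 96 × 8 voxels, 10 patients) were chosen as the
  package's desk-scale study conditions: large enough for stable FBP
  quantitation, small enough that the entire cohort simulates in about a
  minute.

## Worked example

```{r example, eval = FALSE}
library(petrtac)

config <- study_config(n_patients = 10, seed = 1)
report <- run_study(config)

report            # cohort tables and the corrected alpha
tidy(report)      # one row per parameter x method
glance(report)    # one-row summary
autoplot(report, "volumes")    # volume shift vs lesion avidity
autoplot(report, "histogram")  # per-voxel SUV difference histogram

write_study_report(report, "study-out")
```

## Known limitations

* 2-D slice-wise parallel-beam geometry: no oblique LORs, no scatter, no
  randoms, no TOF — adequate for AC-map content, silent on everything else.
* The semi-manual surrogate is deterministic; real intra-observer
  variability is not modelled (the edit hook is the place to inject it).
* Hardware geometry is parametric (slabs and arcs), not a CAD model, and μ
  values are configuration.
* Clinical effect sizes from the 17-patient study this pipeline
  operationalises are not reproducible from synthetic data; only directions,
  mechanisms and the analytic printed values are asserted.
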