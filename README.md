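# petrtac

Quantifying the impact of radiotherapy-hardware attenuation correction on
PET-MR images acquired in the radiotherapy position.

## The problem

PET-MR scans for ano-rectal radiotherapy planning are acquired on a flat
couch top with the anterior MR coil on a rigid coil bridge. That hardware
attenuates the 511 keV annihilation photons but is invisible to MR, so the
scanner's standard attenuation-correction (AC) map omits it. `petrtac`
simulates and analyses the consequence: the same emission data reconstructed
with two AC maps —

* **CTACstd** — patient + scanner bed only (hardware omitted), and
* **CTACcba** — patient + couch + coil bridge + anterior coil —

and measures what the omission does to gross tumour volume (GTV)
delineation, SUV quantitation and prognostic classification. The package is
aimed at medical-physics and radiotherapy researchers who want the analysis
chain as tested, reproducible code.

## What is inside

For an attenuating object with attenuation coefficient μ along a line of
response (LOR), the measured counts are scaled by `exp(−∫μ dl)` and AC
multiplies by `ACF = exp(+∫μ_ac dl)`. Omitting hardware from `μ_ac` leaves a
per-LOR deficit `exp(−∫μ_hw dl)`, which depresses every SUV measure
downstream. The package provides:

* a synthetic digital-pelvis phantom cohort (water-equivalent body, bowel
  gas, gaussian-profile FDG-avid lesions spanning SUVmean ≈ 3–20 g/mL,
  parametric couch/bridge/coil hardware);
* a simplified PET forward model: parallel-beam line integrals, Poisson
  emission noise, attenuation by the true μ-map, correction by an assumed
  μ-map, filtered back-projection, bilinear HU→μ conversion and body-weight
  SUV conversion with decay correction;
* AC-map construction (external-contour harmonisation, internal-air
  water-fill, hardware placement, voxelwise-max composition) with full
  provenance;
* GTV delineation: a semi-manual surrogate (fixed SUV ≥ 2.5 g/mL threshold +
  explicit edit hook) and the relative threshold (strictly above 40% of
  SUVmax, limited to a 5 mm expansion, 0 mm towards an abutting bladder);
* contour metrics (Dice, symmetric mean distance to agreement, volumes),
  per-voxel SUV difference histograms (400 bins, ±100%, 0.05 g/mL external
  contour);
* metabolic parameters (SUVmax, SUVmean, TLG = SUVmean × volume) and TLG
  prognosis rules (50% of SUVmax vs 125.84 g primary-only; 30% vs 341 g
  primary + nodal);
* cohort statistics: paired t-tests on per-patient percentage differences
  with a Bonferroni-corrected level of 0.05/(4×2) = 0.006.

Results are tibbles throughout; the study report supports `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(petrtac)

report <- run_study(study_config(n_patients = 10, seed = 1))
print(report)
```

```
<study_report> 10 patients, 36 lesion-method rows
  whole-image mean SUV difference: -14.3%
  corrected alpha: 0.00625
# A tibble: 8 x 6
  parameter  method      mean_pct se_pct          p significant
  <chr>      <chr>          <dbl>  <dbl>      <dbl> <lgl>
1 volume_cm3 semi_manual   -8.55  1.62   0.0000493  TRUE
2 suv_max    semi_manual   -9.45  0.0973 0.00000454 TRUE
3 suv_mean   semi_manual   -5.90  0.432  0.00000598 TRUE
4 tlg_g      semi_manual  -14.1   1.16   0.000409   TRUE
5 volume_cm3 threshold      0.282 0.307  0.249      FALSE
6 suv_max    threshold     -9.45  0.0973 0.00000454 TRUE
7 suv_mean   threshold     -9.45  0.106  0.00000527 TRUE
8 tlg_g      threshold     -9.20  0.249  0.00101    TRUE
```

Reading this: omitting the hardware from the AC map depressed the whole
image by 14.3% in SUV. The *fixed*-threshold (semi-manual) GTVs shrank by
8.6% on average — the shift pushes lesion boundaries below the 2.5 g/mL
cut — while the *relative* 40%-of-SUVmax GTVs barely moved (+0.3%, not
significant), because a multiplicative deficit scales SUVmax and the
boundary together. SUV metrics and TLG drop by roughly the whole-image
deficit regardless of contour method. `autoplot(report, "volumes")` shows
the volume shift shrinking as lesion avidity grows;
`autoplot(report, "histogram")` shows the per-voxel difference histogram.

A thin CLI wraps the same pipeline:

```sh
Rscript inst/exec/petmr-rtac run --config study.yaml --out out/ --seed 1
```

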