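# l3comp

Body-composition analysis in oncology conventionally measures skeletal muscle
(SM), visceral adipose tissue (VAT) and subcutaneous adipose tissue (SAT) on a
*single* axial CT slice at the mid-point of the third lumbar vertebra (mid-L3).
Whole-vertebra imaging makes every L3 slice available, which raises a practical
question for anyone using these measures as biomarkers (e.g. for sarcopenia or
chemotherapy dosing): **how much do body-composition measures vary across the
L3 level, and does that variability differ by sex?**

`l3comp` is an R package for quantifying exactly that. It provides:

- a minimal DICOM reader/writer for 512×512 axial CT slices (explicit-VR
  little endian), with Hounsfield-unit conversion `HU = pixel × slope +
  intercept` and automated quality-control flags (tissue cut off at the image
  border, excess noise, metal-like artefacts);
- threshold-plus-morphology segmentation of SM/VAT/SAT using the
  Alberta-protocol HU ranges (SM −29…150, VAT −150…−50, SAT −190…−30 HU),
  with the overlapping fat ranges disambiguated by a morphological
  visceral/subcutaneous compartment separation, scored by the Sørensen–Dice
  coefficient;
- per-slice measures: surface area (pixel count × pixel area, cm²) and mean
  radiodensity (HU) per tissue;
- the per-patient **average percent difference** (APD) statistic
  `mean over non-mid slices of |(value − mid)/mid| × 100`,
  summarised as median (IQR) overall and by sex, with a two-sided
  Mann–Whitney male-vs-female comparison (exact enumeration for small
  groups, tie-corrected normal approximation otherwise);
- a parametric CT phantom generator (nested elliptical rings with analytic
  ground-truth areas) so the full pipeline is testable without patient data.

## Worked example

```r
library(l3comp)

# a synthetic cohort of 8 female + 8 male phantom studies (ground truth only)
coh <- generate_cohort(n_female = 8, n_male = 8, seed = 1)
tm  <- cohort_truth_measures(coh)
fit <- l3_variability(tm$measures, tm$patients)
fit
```

```
Mid-L3 vs whole-L3 body-composition variability (16 patients: 8 F, 8 M)
Average percent difference, median% (IQR); Mann-Whitney male vs female

          measure               all            female              male p_value
          SM_area 3.12% (2.23–3.60) 3.36% (2.66–3.75) 2.82% (2.15–3.30)    0.28
  SM_radiodensity 2.28% (1.90–3.01) 2.35% (1.79–3.46) 2.28% (2.08–2.74)    0.88
         VAT_area 5.37% (4.30–6.63) 6.65% (4.89–7.51) 4.49% (4.30–5.52)    0.13
 VAT_radiodensity 1.25% (0.99–1.70) 1.24% (1.06–1.78) 1.25% (0.92–1.46)    0.65
         SAT_area 2.80% (0.40–4.22) 0.64% (0.33–2.38) 4.03% (2.92–4.74)    0.10
 SAT_radiodensity 0.92% (0.73–1.38) 1.10% (0.68–1.43) 0.92% (0.77–1.12)    0.80
```

Each row is one body-composition measure; cells are the cohort median (IQR)
of the per-patient APD between the mid-L3 slice and all other L3 slices, and
the p-value tests whether that variability differs between the sexes. On a
pixel-level cohort the same analysis runs end to end from DICOM files:

```r
dir <- tempfile()
for (ph in generate_cohort(3, 3, seed = 2, render = TRUE))
  write_dicom_series(ph$study, dir)
res <- run_pipeline(run_config(file.path(dir, "manifest.tsv"),
                               file.path(dir, "out")))
res$fit          # the fitted l3_variability object
coef(res$fit)    # overall median APD per measure
```

A thin CLI wrapper with `simulate` and `run-all` subcommands is installed at
`exec/l3comp`.

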