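---
title: "Quantifying mid-L3 vs whole-L3 body-composition variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mid-L3 vs whole-L3 body-composition variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l3comp)
```

## The problem

CT body-composition studies usually reduce a patient's abdomen to one axial
slice at the mid-point of the L3 vertebra and report, per tissue, a
cross-sectional area (cm²) and a mean radiodensity (HU) for skeletal muscle
(SM), visceral adipose tissue (VAT) and subcutaneous adipose tissue (SAT).
Because the whole L3 level typically spans around ten axial slices, the choice
of the single "representative" slice is a source of measurement variability
that propagates into any downstream biomarker (sarcopenia thresholds, dosing
models, survival covariates). `l3comp` quantifies that variability: for each
patient and measure it compares every non-mid L3 slice against the designated
mid-L3 slice, and asks whether the amount of slice-to-slice variability
differs between the sexes.

Two design commitments run through the package. First, the mid-L3 designation
is always an *input* — clinically it is a human grader's judgement, so the
package never tries to infer it from the images. Second, every stage is
testable against analytic ground truth via a built-in phantom generator,
because clinical CT archives cannot be redistributed.

## The statistic

For one measure $m$ of one patient with mid-slice value $m_{\text{mid}}$ and
non-mid values $m_1, \dots, m_k$, the **average percent difference** is

$$\mathrm{APD} = \frac{1}{k}\sum_{i=1}^{k}
  \left|\frac{m_i - m_{\text{mid}}}{m_{\text{mid}}}\right| \times 100 .$$

The absolute value handles negative denominators (fat radiodensities are
negative). APD is scale-invariant and zero exactly when every slice equals
the mid slice. It is *undefined* when the mid value is zero or missing (a
tissue absent at mid-L3) or when no non-mid value exists; undefined records
are carried as explicit `NA` markers and excluded per measure — not per
patient — so one absent tissue does not shrink the sample for the other five
measures.

Cohorts are summarised by median and IQR (quartiles by linear interpolation,
`quantile` type 7, the default convention of standard statistics
environments). The male-female comparison uses a two-sided Mann–Whitney test.
Sidedness is deliberately two-sided: variability differences are reported in
both directions. No multiple-testing correction is applied across the six
measures; the raw 0.05 threshold is applied per comparison, matching common
reporting practice in this literature, and `alpha` is a parameter for users
who prefer otherwise.

### Exact and asymptotic Mann–Whitney

`mann_whitney()` exposes both modes. U follows the standard convention
(pairs with $a > b$ plus half the ties, i.e. `wilcox.test`'s W; the
complement identity $U + U' = n_a n_b$ holds for every input). The exact mode
enumerates the permutation distribution of U over all
$\binom{n_a+n_b}{n_a}$ group assignments of the pooled values — valid under
ties, unlike the classical null tables — using integer arithmetic on doubled
mid-ranks so tied p-values are exact. The asymptotic mode uses the normal
approximation with tie-corrected variance and a 0.5 continuity correction.
`auto` switches to enumeration when $\min(n) \le 8$ and neither group exceeds
12; beyond that the enumeration is combinatorially pointless since the normal
approximation is already within a few thousandths of exact (empirically the
two differ by at most ~0.015 at $n = 6$ per group). Clinical cohort sizes
(~100 per sex) always take the asymptotic path; the exact mode exists for
small phantom experiments and for testing the asymptotic path against an
independent oracle.

## Segmentation model

The package segments by HU thresholds plus morphology, the deterministic core
of the semi-automated grading convention used to produce reference
segmentations in this field (SM −29…150 HU, VAT −150…−50 HU, SAT −190…−30 HU,
inclusive bounds — stated ranges carry no open/closed qualification and
inclusive is the segmentation software convention). Thresholds alone cannot
separate VAT from SAT because the two fat ranges overlap (−150…−50 is a
subset of −190…−30); geometry must decide. The pipeline is:

1. **Body mask** — pixels above −190 HU, morphological closing (disc, radius
   5 px), largest 8-connected component, interior holes filled 4-connected
   (bowel gas is interior air and belongs to the body).
2. **SM** — muscle-range pixels inside the body, minus connected components
   smaller than 20 px (isolated soft-tissue speckle such as small bowel
   content).
3. **Muscle contour** — hole-filled closing of SM; its interior approximates
   the visceral cavity.
4. **VAT** — VAT-range pixels inside the contour; **SAT** — SAT-range pixels
   between the contour and the body boundary. Fat pixels inside the cavity
   that fall only in the SAT range (below −150 HU) stay background; the
   converse rule (outer fat only in the VAT range) is vacuous because the VAT
   range is contained in the SAT range.

Labels live in a single integer grid, so disjointness holds by construction.
Connectivity is fixed (8-neighbour components, 4-neighbour hole filling) to
make outputs deterministic; closing radius and minimum object size are
configuration with the defaults above — they are not clinical claims, and on
anatomies with an open muscle wall (hernias, stomas) the contour
approximation degrades, which is a known limitation. A pure HU-threshold
approach also cannot distinguish large soft-tissue organs from muscle when
they touch the muscle wall; the method is intended for the compartmentalised
geometry the phantoms emulate, and real-world use should treat the QC report
and Dice validation against reference masks as first-class outputs, not
afterthoughts.

Agreement with reference masks is scored by the Sørensen–Dice coefficient
$2|A \cap B| / (|A| + |B|)$, defined as 1 when both masks are empty.

## Measures

Area is pixel count × pixel area / 100 (cm²). The area formula multiplies
both pixel spacings — row spacing × column spacing — rather than a single
linear "pixel spacing" factor: units only resolve to cm² with an area factor,
and anisotropic spacing must not be averaged. Radiodensity is the plain mean
of the *unmodified* HU image under the final mask (no re-thresholding or
smoothing), and an empty mask yields an explicit undefined marker rather
than 0, because 0 HU is water and would silently bias averages.

## The phantom generator

`phantom_params()` / `generate_phantom_study()` build axial abdominal
phantoms as nested elliptical rings: a SAT ring at the surface, a muscle ring
inside it, and a visceral cavity holding a VAT ring around a bowel-gas core
(−1000 HU), plus a few small soft-tissue blobs (20 ± 10 HU) deliberately
below the segmenter's 20-px minimum object size. The blobs and gas core are
intentional stress cases: gas exercises interior hole-filling, the blobs
exercise small-object removal. A large coherent organ at soft-tissue HU would
be indistinguishable from muscle by thresholds — that is a genuine limitation
of threshold segmentation, so the phantom geometry keeps soft tissue inside
the cavity either small or absent, and what passing tests demonstrate is
correctness of the pipeline's arithmetic and compartment logic, not
segmentation performance on real anatomy.

Everything about a phantom is analytic: each ring's area is
$\pi(a_1 b_1 - a_2 b_2)$ in pixels, converted by the pixel area, so segmented
and measured output can be compared against closed-form truth. Defaults
emulate the acquisition characteristics reported for clinical L3 stacks:
512×512 pixels, slice counts drawn from a discrete triangular distribution on
8–12 (median 10, IQR 9–11), slice thickness 5 mm within the clinical 1–8 mm
range, pixel spacing 0.9766 mm (a 500 mm field of view), and tissue HU means
strictly inside their threshold ranges (SM 40 ± 10, VAT −90 ± 15, SAT
−105 ± 15 HU). Default ring dimensions were chosen so mid-slice areas land in
the range clinical cohorts report (SM ≈ 140 cm², VAT ≈ 190 cm², SAT ≈
150 cm² for the male defaults).

Slice-to-slice change is a monotone modulation profile, zero at the mid slice
and ±1 at the stack ends: body axes scale by `1 + body_amp·profile`, the SAT
ring thickness by `1 + sat_amp·profile`, and VAT area by
`1 + vat_amp·profile`. The VAT modulation acts on VAT *area* relative to the
mid slice (the cavity fat fraction is derived per slice), so the programmed
amplitude is exactly the realized VAT-area change and does not entangle with
the body-outline modulation. Real L3 anatomy has no published quantitative
slice-to-slice geometry model, so the profile is a stand-in; the default
amplitudes (`body_amp` 0.04, `sat_amp` 0.04, `vat_amp` 0.10, each jittered
per patient by a uniform 0.5–1.5 magnitude factor and a random sign) were
chosen once so that the resulting APD magnitudes sit in the few-percent range
clinical cohorts report for areas, with VAT most variable. Radiodensity
variability comes from a per-slice drift of each tissue mean (SD 1 HU), which
yields radiodensity APDs of roughly 1–3% — again the clinically reported
order. Noise is independent Gaussian per pixel, quantised to integer HU;
there is no beam hardening or streak modelling, and QC artefact cases are
constructed explicitly rather than simulated physically.

`generate_cohort()` applies sex-effect multipliers (female defaults: SAT ring
×1.9, muscle ring ×0.85, body ×0.97, visceral fat fraction ×0.82) chosen to
reproduce the qualitative sex orderings of clinical mid-L3 tables — females
with more SAT, less SM and VAT — not any cohort's numeric medians. The
modulation-amplitude multipliers default to 1 for both sexes, i.e. the null
configuration: by default there is *no* sex difference in variability, and
injected-effect experiments switch it on explicitly (e.g.
`sex_effects$female$vat_amp <- 2`).

```{r example}
coh <- generate_cohort(n_female = 8, n_male = 8, seed = 1)
tm <- cohort_truth_measures(coh)
fit <- l3_variability(tm$measures, tm$patients)
fit
```

## Data interfaces

Slices are stored one per DICOM file (16-bit signed pixels, slope 1,
intercept −1024, explicit-VR little endian), a dialect chosen so integer HU
grids round-trip bit-exactly; the reader honours arbitrary slope/intercept
and rejects what it cannot parse (sequences, compressed transfer syntaxes,
non-512×512 images) with named-tag error messages. The codec is a minimal
purpose-built implementation covering exactly this tag set — it is not a
general DICOM library. Studies are described by a tab-separated manifest
(patient, sex, age, file, mid-flag); HU values are clamped to the physically
plausible [−1100, 3100] on construction. Label masks persist as single-channel
PNGs (grey levels 0/85/170/255 for background/SM/VAT/SAT) with a JSON sidecar
recording the source slice and thresholds.

## Quality control

Automated flags mirror the exclusion criteria used when assembling clinical
cohorts: `sat_cutoff` / `muscle_cutoff` when the tissue touches the image
border (anatomy extending outside the field of view), `low_quality` when a
robust noise estimate (1.4826 × MAD in a central 64×64 window) exceeds 25 HU,
and `major_artefact` when any |HU| inside the body exceeds 3000. The
thresholds are configuration defaults, made explicit because the source
criteria are human judgements. QC-flagged patients are excluded from the
statistics by default but always listed with reasons — never silently
dropped — and a flag allows including them for sensitivity analysis.

## Numerical and reproducibility choices

- All generator randomness is a pure function of the seed; per-patient seeds
  derive from the master seed. DICOM output contains no timestamps and uses
  deterministic UIDs, so regeneration is byte-identical.
- Pipeline outputs (CSV tables, log) contain no wall-clock information; a
  rerun on unchanged inputs is byte-identical, and the log records a hash of
  the analysis-relevant configuration.
- The exact Mann–Whitney p works on integers (doubled mid-ranks), avoiding
  floating-point ties.
- Degenerate inputs have defined behaviour rather than incidental one:
  empty-vs-empty Dice is 1, empty-mask area is 0 with undefined radiodensity,
  zero or undefined mid-L3 values make the APD undefined (recorded, not
  raised), and an all-air image is a hard `no body` error.

## Test problem sizes

The test suite validates the formula properties on 1000 randomised cases, the
exact Mann–Whitney against brute-force enumeration for all group sizes up to
6 including ties, the type-I error of the sex comparison on 200 null cohorts
of 15 + 15 patients (ground-truth measures), detection of a doubled female
VAT modulation on 50 cohorts of 30 + 30, and segmentation recovery on 20
phantoms (areas within 2% of the analytic rings, radiodensities within
0.5 HU, Dice ≥ 0.98 at 5 HU noise). Statistical replicates run on analytic
ground-truth measures rather than rendered pixels, which is what makes
hundreds of replicates practical; the pixel path is exercised end-to-end by
the segmentation, pipeline and reproducibility tests. What these phantom
results do *not* show is performance on real anatomy — irregular body
outlines, open muscle walls, intramuscular fat — for which validation against
manually segmented references (the Dice tooling is provided) remains
necessary.
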