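---
title: "Measuring net water uptake on stroke CT: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring net water uptake on stroke CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Ischemic brain takes up water as cytotoxic and vasogenic edema develop, and
water dilutes the X-ray attenuation of tissue. Net water uptake (NWU)
exploits this: if `D_ischemic` is the mean CT density (HU) of the infarcted
region and `D_normal` the mean density of the homologous, mirror-image
region of the healthy hemisphere, then

    NWU = 100 (1 - D_ischemic / D_normal)  [%]

is, to first order, the fraction of the lesion volume that is excess water.
The quantity is a ratio of within-scan means, which cancels scanner
calibration offsets; its accuracy therefore rests entirely on *which voxels
enter the two means*. `nwukit` automates the voxel selection:

1. **Brain extraction** — soft-tissue/CSF window (−10..85 HU), morphological
   opening, largest 3D component, closing. Deliberately simple: the skull
   makes head CT brain extraction benign compared to MRI.
2. **CSF segmentation** — brain voxels within the CSF window (default −5 to
   15 HU), opened with a 1-voxel ball, components under 0.3 ml dropped.
   CSF must be excluded from both regions because it is 30 HU darker than
   tissue and would masquerade as edema.
3. **Midline estimation** — the mid-sagittal plane is found by maximising
   the normalized cross-correlation between the image and its reflection
   over brain voxels (coarse grid over yaw/lateral offset, Nelder-Mead
   refinement of yaw, roll and offset). Head CTs of acute stroke patients
   are routinely tilted; the plane, not the grid, defines "contralateral".
4. **Ischemic region** — on follow-up CT, the visible hypodensity is
   segmented from the smoothed contralateral density difference (below); on
   baseline CT, where infarct is rarely visible, the CT-perfusion core
   (CBF below 30% of the Tmax<4s-tissue median) is registered onto the
   NCCT by rigid normalized-mutual-information registration.
5. **Mirroring, exclusion, windows** — the region is reflected across the
   midline voxel-center-wise (nearest neighbour); mirrored voxels landing
   back in the lesion or outside the brain are dropped with a warning; CSF
   is removed from both regions first, then each region is restricted to a
   closed HU window; means and NWU follow.

### The asymmetric HU windows

The classical NWU protocol windows both regions to 20–80 HU. Severely
edematous infarct, however, falls below 20 HU — excluding those voxels
*raises* `D_ischemic` and underestimates exactly the severe edema the
biomarker exists to measure. Conversely hemorrhagic transformation (HT) and
contrast staining are hyperdense (> 40 HU) and would mask edema in the
other direction. The package therefore defaults to

| region                    | window (HU) |
|---------------------------|-------------|
| visible infarct (follow-up) | 0–40      |
| CTP core (baseline)       | 20–80       |
| mirrored normal region    | 20–80       |

All windows are closed intervals, configurable in `thresholdConfig()` /
`nwuConfig()`. Every exclusion is counted per region in the `NWUResult`, so
a measurement is auditable: on an HT-laden phantom the ischemic threshold
counter equals or exceeds the number of hyperdense voxels injected, and NWU
moves by well under a point.

## The classical infarct segmenter

The production approach to infarct segmentation is a trained network; this
package ships a classical stand-in honouring the same contract (and a
plug-in hook for any callable `(volume, brain, csf, plane) -> mask`). The
stand-in is contralateral-difference thresholding:

* both the image and its mirror are smoothed (2 mm Gaussian) and the
  difference `contra − self` computed over parenchyma, excluding a 3.5 mm
  margin around CSF and the brain boundary, where partial-volume gradients
  of 30–700 HU amplify sub-voxel midline error into spurious differences;
* the comparison is only accepted where both smoothed densities are
  tissue-plausible (20–45 HU);
* the inclusion margin is `max(delta_hu, 3.5 robust SDs of the difference
  map, 0.8 × plateau)`, where the plateau is the median difference over
  voxels above half the 99.9th percentile — i.e. the demarcated lesion's
  own depth. A fixed HU margin cannot serve across severities: mild edema
  (w = 0.05 on 38 HU tissue) is a 1.9 HU signal, far below any margin that
  would be safe against noise at coarse resolution, while a margin
  proportional to the lesion's plateau tracks both. Thresholding at 80% of
  the plateau also erodes the partial-volume transition shell, keeping the
  region mean representative of demarcated infarct;
* candidates are closed (1-voxel ball), re-restricted to the contract
  (brain, non-CSF, 0–40 HU), filtered at 1 ml, and reduced to the largest
  26-connected component — small disconnected islands are treated as noise,
  the largest region as the primary infarct territory. Size ties break by
  lower mean HU, then lowest linear index, so repeated runs are identical.

## The digital phantom

Real scans come with no ground truth, so the package carries its own: an
adult-sized head (≈1.38 l brain) on a 156×188×134 grid at 1 mm isotropic
spacing — parenchyma 38 ± 2 HU, CSF 8 ± 3 HU, skull shell ≈700 HU, air
background. CSF compartments (enlarged lateral ventricles ≈30 ml each, an
interhemispheric fissure and paired 8 mm sulcal wedges, widths typical of
the atrophic brains of elderly LVO patients) are mirror-symmetric about the
construction midline. One ellipsoidal infarct (default 110 ml, the median
automated infarct volume reported for LVO follow-up CT) is carved into the
left hemisphere with safety margins to skull (5 mm), CSF (3 mm) and midline
(5 mm), its size solved by binary search so the carved volume matches the
request. Its voxel densities are tissue draws scaled by `(1 − w)`, so the
true NWU is exactly `100 w`.

Partial volume is simulated by smoothing the label-mean image with a
1-voxel-sigma Gaussian before noise. This choice has a quantifiable
consequence: the blur moves a fraction ≈ `1.2 σ/r` of a lesion's density
deficit outside its own mask (σ the blur, r the equivalent-sphere radius),
so means taken over ground-truth masks are biased towards zero NWU by that
fraction. At 1 mm spacing and 110 ml (r ≈ 30 voxels) the bias is ≈5% of the
deficit (≈1.2 NWU points at w = 0.25); tests that demand tighter recovery
from ground-truth masks use a finer 0.7 mm grid with a 200 ml (malignant
MCA-scale) lesion, where the bias drops to ≈3%. The automated segmenter is *less* affected because its
plateau-fraction threshold does not include the transition shell. Scanner
noise (default 2 HU) and tissue texture are added after the blur; optional
petechial HT voxels (uniform 50–80 HU draws on scattered infarct voxels)
are inserted after the blur so that each one stays unambiguously above the
40 HU ceiling — an exact accounting oracle for the exclusion counters.
Optional head tilt rotates image and masks rigidly about the
inferior-superior axis; the returned midline truth rotates with them. The
same spec and seed reproduce a phantom bit-identically.

### The perfusion forward model

`makeCTPSeries()` emulates a dynamic acquisition on a 3× block-mean
downsampled grid (a CTP voxel averages the underlying fine voxels, so
partial-volume voxels carry proportional enhancement — the physical
behaviour of a coarser detector). Each tissue voxel's time-attenuation
curve is `CBF · (AIF ⊛ R)(t − delay)` on top of its NCCT baseline, with an
exponential residue `R(t) = exp(−t/MTT)` (MTT 4 s), a gamma-variate AIF
(arrival 8 s, ~4 s FWHM — a compact power-injector bolus), 2 s frames over
50 s, and a small arterial block carrying the undiluted AIF for selection.
Core voxels get 20% of normal flow and a 6 s delay. Deconvolution uses the
standard non-circulant truncated SVD (threshold 0.2 of the largest singular
value) — the delay-*sensitive* formulation, documented so users can compare
against delay-insensitive (block-circulant) implementations. With the
acquisition parameters above, the noise-free forward model is inverted
essentially exactly (flow ratio and core Tmax recovered to the frame); at
1 HU frame noise the core mask still overlaps truth with Dice > 0.95. The
normal-flow reference for the core rule is a *median* over Tmax < 4 s
tissue — robust to residual lesion voxels — and the rule is scale-invariant
because only the CBF ratio enters.

## Numerical choices and edge cases

* HU intervals are closed; voxels exactly at a bound are kept, a voxel at
  exactly 30% of the reference CBF is *not* core (strict inequality).
* Order of exclusions is CSF first, then HU window; observable only in the
  counters.
* Fewer than 50 surviving voxels in either region is an error ("region
  vanished after exclusions") — a mean over fewer voxels is noise-dominated.
* Empty outputs are meaningful results for the segmenters ("no visible
  infarct", "no measurable core") and errors for the pipelines, mirroring
  how such scans are excluded from studies.
* Masks resample nearest-neighbour (binarity), intensities trilinearly
  (densitometry). Mirrored voxels falling outside the grid are dropped; a
  mask reflected entirely off the grid is an error.
* The midline optimiser and the rigid registration fall back to their
  initialisation (mid-sagittal plane / identity) with a warning flag when
  they cannot improve on it.
* ICC(2,1) is computed from the two-way ANOVA mean squares with the
  Shrout–Fleiss / McGraw–Wong F-based 95% CI; Bland–Altman uses the
  classical fixed 1.96 multiplier with the n−1 sd. Dice of two empty masks
  is defined as 1 (perfect agreement on absence). Dice uses the standard
  intersection form.

## What the phantom validation shows — and what it cannot

Passing the phantom suite establishes that the *measurement machinery* is
correct: geometry (midline, mirroring, registration, resampling),
accounting (CSF and window exclusions), the deconvolution inverse, and the
end-to-end recovery of a known uptake fraction within ~1.5 points across
w = 0.05–0.35, monotonically. It does not establish clinical performance of
the classical segmenters: real infarcts are not ellipsoids, real follow-up
hypodensity overlaps CSF density (the phantom keeps a 3 mm margin; real
pipelines solve this with learned models), real noise is structured, and
beam hardening and motion are absent. The classical CSF window also misses
sulci thinner than ~3 voxels, so coarse (≳2 mm) reconstructions are outside
the supported operating point for scans without visible lesions; thin-slice
input is assumed. Parameter defaults were chosen once from the physics and
population above and are exposed in `nwuConfig()` rather than hidden.
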