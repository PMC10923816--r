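---
title: "Methods: electromagnetic stroke imaging with emibrain"
author: "emibrain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electromagnetic stroke imaging with emibrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the measurement

A portable electromagnetic (microwave) brain scanner surrounds the head with
16 antennas operating over 0.7--1.8 GHz, immersed in a lossy coupling medium
(relative permittivity 45, conductivity 0.15 S/m near 1 GHz). A vector
network analyzer excites each antenna in turn and records all received
signals, giving a complex 16 x 16 scattering matrix per frequency point.
Stroke alters the dielectric properties of brain tissue: an intracerebral
hemorrhage (ICH, a blood pool) *raises* permittivity and conductivity, an
ischemic region (IS, reduced perfusion) *lowers* both. The software's job is
to decide from the S-parameters whether a stroke is present, of which type,
and in which head quadrant -- fast enough for pre-hospital triage, where the
ICH/IS distinction decides between opposite treatments.

`emibrain` implements the full software chain: calibration and quality
gating, a boundary estimator, four complementary detection/localization
algorithms, and image/decision fusion. Because clinical scan data are
restricted, the package ships a physics-based simulator that stands in for
the device end-to-end, and every claim the package makes is tested against
that simulator.

## The synthetic scattering model

The simulator (`forward_scatter()`) solves the 2-D scalar Helmholtz problem
in the Born (single-scattering) approximation on a head slice:

$$S_{ij}(f) = k_b^2 \sum_{p} G(\mathbf r_i, \mathbf r_p)\,
\chi(\mathbf r_p)\, G(\mathbf r_p, \mathbf r_j)\, \Delta A,$$

with the background Green's function $G = (j/4) H_0^{(1)}(k_b |\mathbf r -
\mathbf r'|)$ and contrast $\chi = (\varepsilon - \varepsilon_b)/
\varepsilon_b$ over complex permittivities. Conventions: $e^{-j\omega t}$,
outgoing $H_0^{(1)}$, and $\mathrm{Im}(k_b) > 0$ so waves decay in the lossy
medium (the opposite sign produces unphysical growth). $H_0^{(1)}$ for
complex argument is computed in compiled code by an ascending series below
$|z| = 10$ and the Hankel asymptotic expansion above, validated against base
R's `besselJ`/`besselY` on the real axis.

The phantom is deliberately two-layer: coupling background outside an
elliptical boundary, a homogeneous brain-average interior
($\varepsilon_r = 42$, $\sigma = 0.6$ S/m), and at most one circular
inclusion. Contrast magnitudes for stroke are unpublished for the clinical
device; the defaults (+18 / +0.8 S/m for ICH, -12 / -0.4 S/m for IS) encode
the known *signs* at plausible 1 GHz magnitudes and are arguments, not
constants. Head size is randomized per subject (semi-axes 72--88 x 92--108
mm) with the centre kept on the sagittal axis, so healthy heads are
mirror-symmetric -- the modelling assumption every differential algorithm
relies on.

What the simulator does *not* emulate: multiple scattering (the Born model
is linear in contrast by construction), dispersive multi-tissue anatomy
(skull, CSF), 3-D propagation, and antenna coupling. Passing tests therefore
demonstrate algorithmic correctness and internal consistency under the
stated physics, not clinical performance: real heads are only approximately
symmetric, and skull-borne multipath is far harsher than anything a linear
model produces.

Acquisition emulation follows the clinical protocol: 20 consecutive scans
per patient at 30 dB per-channel SNR, optional per-port complex gain/offset
drift, an optional motion-corrupted scan, and two homogeneous calibration
phantom sweeps ($\varepsilon_r = 38$ and $52$, bracketing the head average;
the clinical values are unpublished).

## Calibration and gating

`two_phantom_calibrate()` fits, per channel and frequency, the complex
affine map sending the two measured reference responses onto their
model-predicted ideals, and applies it to patient data. Two references
identify exactly a gain and an offset, so any per-channel affine instrument
error (port gain products $g_i g_j$, leakage offsets) is removed to machine
precision -- that is the richest error model identifiable from two
references, and the reason the hardware's in-line switches are collapsed
into it. Channels where the two references coincide numerically are flagged
uncalibratable and excluded.

`stability_gate()` monitors consecutive-scan RMS deltas in dB relative to
mean signal power and drops scans whose neighbouring deltas all exceed the
threshold. Its documented default (-35 dB) reflects a quiet idle system;
under the cohort's own 30 dB SNR the *expected* consecutive delta is
$2\sigma^2$, about -27 dB, so the pipeline gates at -15 dB -- between the
noise floor and any genuine motion jump (> +10 dB). The gate is
deliberately order-sensitive: it judges *consecutive* acquisition, so
permuting scans changes which runs are flagged.

Averaging the kept scans lowers the noise floor by $10\log_{10} N \approx
13$ dB for $N = 20$, which the tests verify empirically.

## Boundary estimation

The clinical device estimates the head contour with a deep network on
reflection coefficients. The package keeps the same interface --
reflection magnitudes in, ellipse out -- with a desk-scale gradient-boosted
regressor (`train_boundary_model()`): per antenna, mean log $|S_{ii}|$,
unwrapped phase slope (round-trip delay), and four band samples; one
booster per parameter (cx, cy, a, b). Trained on randomized synthetic
ellipses it reaches ~2 mm held-out mean absolute semi-axis error (the
acceptance bar is 3 mm). Predictions outside 60--120 mm are clamped with a
warning.

## The four algorithms

**Horizontal visibility graphs (shared core).** Calibrated sweeps are
windowed (Hamming), hermitian-extended and inverse-transformed to real
time-domain signals (`to_time_domain()`; the band is placed at the nearest
FFT bin, an offset below half a bin, i.e. < 0.4% of the carrier -- exact
placement is impossible for grids whose start frequency is not a multiple
of the spacing). Each channel's series becomes a horizontal visibility
graph: samples $i < j$ are linked iff every sample between them is lower
than both. Construction is a stack algorithm, linear-time amortized, tested
for exact edge-set equality against the brute-force definition. Weights are
amplitude differences $|x_i - x_j|$ (the simplest choice making strength
distinct from degree; a 1e-12 floor keeps strengths positive), and each
node carries degree, strength, and the entropy of its incident weight
distribution (nats). Per-channel means give three 16 x 16 metric matrices.

**Algorithm II -- classification and line crossing.** Healthy heads being
symmetric, each metric matrix $M$ is compared with its mirror conjugate:
$D = M - P M P^\top$ with $P$ the mirror permutation. $D$ vanishes for
symmetric heads and is antisymmetric under mirror conjugation. Thirteen
summaries per matrix (norms, quantiles, row statistics, and a *signed*
row-sum hemisphere contrast -- row norms are mirror-invariant and carry no
side information) give 39 features. These magnitude summaries are blind to
the *sign* of the dielectric contrast: a small bleed and a somewhat larger
ischemic region carry the same asymmetry energy, and a waveform-polarity
probe shows the band-pass carrier phase scrambles any direct time-domain
sign cue. The vector is therefore extended (the feature list is a
configuration point, not a fixed contract) with three kernel-coherence
features: the matched-filter statistic $T(\mathbf r) = \sum_f \sum_{ij}
\Delta S_{ij} \overline{G_i G_j}$ of the mirror-differenced data is
maximized over the head interior, and $\cos(\arg T)$, $\sin(\arg T)$ and
$\log |T|$ at that maximum enter the feature vector -- the real part's
sign tracks the contrast sign (positive for hemorrhage), the magnitude
the anomaly scale. The 42 features feed four classifiers: random forest,
k-nearest neighbours, naive Bayes, and an RBF support vector machine, all
with probability outputs, fused by a certainty-weighted mean (weight =
each classifier's maximum probability). For localization, each channel
paints its differential entropy onto a 6 mm half-width corridor between
its two antennas, normalized by per-pixel ray coverage.

**Algorithm III -- direct mapping.** Each antenna pair maps to a polar
cell: angle = the pair's circular-midpoint angle, depth ring = circular
separation, following the principle that close pairs sense shallow tissue
and far pairs deep tissue. The ring law is linear ($r = R(1 -
\mathrm{sep}/8)$), the simplest monotone choice. Cells aggregate
$w_{ij}\sum_f |\Delta S_{ij}|$ with an array-specific sensitivity profile
$w = 1/|S^{cal}|$ clipped to [1, 100]. Detection thresholds total image
mass at 3 standard deviations over a 30-phantom healthy null. Typing uses
the sign of the real part of the kernel correlation $T(\mathbf r) = \sum_f
\sum_{ij} w_{ij} \Delta S_{ij} \overline{G_i G_j}$: positive contrast (ICH)
gives positive real part. Two numerical facts shape the implementation.
First, $T$'s phase decoheres within a few millimetres, and the polar image
peak is cell-coarse, so typing is evaluated at the coherence maximum
$\arg\max |T|$ near the image peak rather than at the literal peak pixel.
Second, symmetry referencing cannot distinguish an ICH at $\mathbf r_0$
from an IS at the mirrored point (the mirror ghost carries the opposite
sign), so the search is restricted to the affected hemisphere reported by
the distance-correlation stage. The sign convention itself is verified on
labelled synthetic phantoms when the model bundle is built, and recorded in
it.

**Algorithm IV -- beamography.** The affected side comes from Szekely
distance correlation. The mirror-pair formulation (dCor between a channel
and its mirrored channel) is provably side-blind -- dCor is symmetric in
its arguments and the hemisphere channel sets are mirror-images of each
other, so both hemisphere means are identical. Each channel is instead
compared against the cross-hemisphere template for its antenna separation
(the mean magnitude profile over all equal-separation channels); the
stroke-side channels deviate more, giving that hemisphere the lower score.
Ties below 0.01 are flagged ambiguous. Clutter is then removed in two
steps: symmetry subtraction $\Delta S_{ij} = S_{ij} -
S_{m(i)m(j)}$ (symmetric clutter cancels exactly; healthy-side channels
carry a redundant negated copy and are down-weighted by 1/2), and average
subtraction (per-frequency channel mean removed; idempotent). The cleaned
data are back-propagated by phase conjugation -- the matched filter
$I(\mathbf r) = |\sum_f \sum_{ij} u_{ij} \Delta S_{ij} \overline{G_i
G_j}|$ -- which is stable where a true inverse propagator would amplify
noise. Pixels within 3 mm of an antenna are excluded (Green's-function
singularity).

**Algorithm V -- EVSLA.** Same-hemisphere antenna pairs at separations 1--3
define wedge quadrilaterals between the antennas and their radial
contractions toward the centre; the mirrored pair's wedge is the partner
patch, so pairing is a bijection of exact mirror images covering over 80%
of the interior. (A literal quadrilateral on antennas $i, j, m(j), m(i)$ is
its *own* mirror image and cannot form a pair -- hence the wedge
construction.) Each patch's statistic is the mean absolute difference of
bounding-channel HVG entropies between patient and calibration reference,
mirror-differenced and floored at zero; patches at or below the cohort
median are deactivated. Pixel values are the mean statistic of the active
patches covering them -- the expected anomaly value per pixel.

## Fusion

All four images live on one head-centred grid (2 mm pixels, +y anterior,
+x patient-left -- fixed here since no published convention exists), so
co-registration reduces to bilinear resampling; elastic warping would only
be needed for modality-specific geometries that do not arise in this
artifact. After min-max normalization, the agreement mask keeps pixels
where at least K = 3 of 4 modalities exceed tau = 0.5, decrementing K until
the mask is non-empty (the K-used and fallback state are reported).
Modalities are Gaussian-smoothed (sigma 2 px), the mask dilated by a 2 px
disk, and the fused heatmap is the masked mean, renormalized. The decision
side fuses the ensemble's probability vector with the DMM verdict mapped
to (0.8, 0.1, 0.1) pseudo-probabilities -- a documented convention, not a
calibrated posterior.

The *agreed target location* needs more care than the heatmap argmax. Two
of the four modalities are symmetry-referenced and therefore exactly
left-right symmetric (the mirror ghost), and the coarse modalities can
pile the masked mean tens of millimetres from the target even when
beamography has focused it to a few. The pipeline therefore leans on the
uniform background reference: the boundary estimate feeds the package's
own forward model to synthesize a homogeneous head, and the ghost-free
backprojection of the residual (a rim band absorbs boundary-estimate
mismatch) supplies both the affected side -- by hemisphere image energy --
and the reported target location, restricted to that side. The agreement
mask is deliberately not applied to this locator: it is built from the
coarse modalities and drags the much sharper residual peak onto its own
edges; it backstops instead (masked smoothed beamography, then the
heatmap, when the primary locator is empty). The same side call feeds the
DMM typing restriction and the classifier's coherence features, whose sign
otherwise flips for near-axis lesions when the mirror-based side detector
coin-flips. The distance-correlation side call remains the beamography
module's own, self-contained detector. The report quadrant follows the
stated sign convention, ties breaking toward anterior then left.

The canonical JSON report excludes stage timings (they are returned
separately on the result object): the determinism contract -- identical
inputs give byte-identical reports -- would otherwise be unsatisfiable.

## Numerical choices and degenerate inputs

* Touchstone I/O: v1 `.sNp`, RI/MA/DB formats, any unit; files written in
  RI/Hz at 17 significant digits so round-trips are value-exact at 1e-12.
* Descending frequency files are re-sorted (flagged); non-uniform grids are
  refused rather than silently interpolated.
* Polar sector indices tie-break half-up (banker's rounding at exact sector
  boundaries would break rotation equivariance); the innermost ring is a
  single centre point, so its sectors are pooled before resampling.
* The phantom rasterizer builds its lattice symmetrically about the
  boundary centre; otherwise a symmetric phantom would scatter
  asymmetrically at the percent level and every null test would leak.
* Constant images normalize to all-zeros with a degenerate flag; constant
  time series give flagged flat HVGs; dCor of a constant signal is NA and
  the channel is masked.
* Patch statistics below 1e-12 are treated as zero so floating-point dust
  never activates a patch.

## Problem sizes

Simulations are sized for a desk-scale run: cohort sweeps use 31 frequency
points over the full band (the device grid is configurable and defaults to
201), the image grid is 2 mm, ensemble training uses 60 balanced subjects
with 20 scans each, the DMM null 30 healthy phantoms, boundary training 200
phantoms at 6 frequency points, and the evaluation cohort 50 diseased
phantoms (radius 10--25 mm, SNR 30 dB). The acceptance script reruns all of
this from scratch in roughly a quarter of an hour on one CPU.

## Known limitations

* Born linearity understates clutter for strong contrasts; the symmetry
  nulls are cleaner here than any real head would give.
* The classifier ensemble and DMM typing exploit amplitude differences
  between the ICH and IS default contrasts; with contrasts of equal
  magnitude only the phase-based typing would separate the classes.
* The mirror ghost limits symmetric-reference localization to the affected
  hemisphere; a uniform-background reference avoids the ghost at the cost
  of a per-patient homogeneous forward solve (both are supported, symmetry
  is the default).
* Boundary rotation is fixed at zero; tilted heads are out of scope for
  the 2-D surrogate.
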