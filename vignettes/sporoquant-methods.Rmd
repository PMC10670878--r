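---
title: "Methods: quantifying metabolic differentiation and intercellular trafficking in sporulating B. subtilis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying metabolic differentiation and intercellular trafficking in sporulating B. subtilis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporoquant)
```

# Scope

During *Bacillus subtilis* sporulation an asymmetric division produces a
sporangium of two sister cells — a small forespore and a large mother cell —
that differentiate metabolically while remaining physically coupled. The
questions this package quantifies are: how do reporter concentrations differ
between the two cells; how fast are small molecules exchanged through the
intercellular (A-Q) channel; and into which cell's proteome are imported
building blocks (heavy arginine) incorporated. `sporoquant` implements the
measurement side of those questions — segmentation, ratiometry, BONCAT and
phase-bright scoring, FRAP/FLIP photobleaching analysis, and cell-specific
SILAC classification — together with seeded synthetic-data generators that
provide exact ground truth for every estimator. Wet-lab procedures, MS
acquisition/search, and image deconvolution are out of scope; peptide tables
and images enter the package as files.

# Synthetic data as the validation substrate

The raw microscopy and mass-spectrometry data behind these assays are not
available in machine-readable form, so every estimator is validated against
generators whose defaults encode the study conditions:

* **Images** (`generate_sporangium_image`): mother cells are 2D
  spherocylinders (length 2.5 um, radius 0.45 um) and forespores are
  ellipses (semi-axes 0.5 x 0.35 um) aligned with the cell axis at one
  pole, rendered at 0.065 um/px. The membrane channel carries 1-px
  outlines; the forespore's double membrane is brighter by
  `fs_outline_multiplier` (default 2). Engulfed forespores are omitted from
  the impermeable-dye (membrane) channel, rendered in the permeable-dye
  (mito) channel, and carry no DAPI signal — the three facts the engulfment
  classifier relies on. Noise is Poisson shot noise on expected counts plus
  additive Gaussian read noise (`background_sd`), the standard fluorescence
  camera model; reporter expectations near 100--200 counts with read noise
  2 give the SNR ~ 10 regime used in the noisy validations. The phase
  channel lives on its own arbitrary-unit scale (a mature spore renders at
  0.3 AU) and is left noise-free: the camera model is for photon counts,
  and phase-bright scoring is a thresholding operation whose boundary
  behaviour is what needs testing.
* **Photobleaching traces** (`generate_photobleach_trace`): the sporangium
  is two well-mixed compartments with volumes `v_fs = 0.35` fL and
  `v_mc = 3` fL, initial calcein concentration `c0 = 100` AU/fL, exchanging
  amount at rate `J = k (c_mc - c_fs)` with `k` in fL/s. Frames are 3 s
  apart (30 postbleach frames, a 90 s window, one prebleach frame); the
  0.1 s bleach pulse is far shorter than a frame, so bleaching is an
  instantaneous multiplicative loss of the target compartment's amount.
  Each acquisition retains a fraction `acq_loss` (default 0.99) of every
  cell's fluorophore; measurement noise is additive Gaussian
  (`noise_sd = 10`, i.e. SNR ~ 10 against `c0`).
* **Peptide tables** (`generate_peptide_table`): a surrogate proteome of
  520 proteins across regulon classes (80 sigF, 80 sigG, 120 sigE,
  120 sigK, 120 vegetative), ~10 tryptic peptides per protein,
  Poisson-distributed arginine counts (lambda 1.5), yielding over 3000
  sporulation-specific arginine-containing peptides per run. The heavy
  label is Bernoulli per peptide at its compartment's probability:
  background incorporation 0.12 everywhere in the control scenario;
  mother-cell importer scenario raises mother-cell peptides to 0.30
  (2.5-fold) and forespore peptides to 0.25 (transport across the two
  membranes); forespore importer scenario raises forespore peptides to
  0.162 (1.35-fold) and mother-cell peptides modestly to 0.14. The 0.12,
  2.5-fold and 1.35-fold values are the published observations this
  scenario set mirrors; the remaining two are qualitative statements given
  one concrete value each, chosen once.

What the generators deliberately do **not** emulate: 3D optical sectioning
and the microscope PSF, deconvolution artefacts, touching/overlapping
sporangia, intra-compartment diffusion gradients, realistic tryptic
cleavage chemistry, razor peptides, or identification FDR. Passing tests
therefore demonstrate correctness of the estimators under the stated data
model, not robustness to every pathology of real data.

All generators draw from a single RNG stream per call, seeded by one
integer; identical parameters and seed give bit-identical output, and the
caller's RNG state is untouched.

# Segmentation and pairing

Following the dual-threshold strategy for FM 4-64 images: thresholding high
isolates the bright forespore double membranes, thresholding low the whole
sporangium outlines. Components are 8-connected, hole-filled before the
minimum-area filter (default 20 px^2). Thresholds default to intensity
quantiles of the membrane channel (high 0.995, low 0.95) because absolute
values do not survive exposure changes; both can be given as absolute AU
(`threshold_absolute`), which the validation suite uses since the synthetic
intensities are known. Mother cells are the whole-cell masks minus the
forespore masks dilated by 1 px — outline pixels are shared boundary signal
and must not count as mother-cell cytoplasm.

Pairing filters candidate mother cells by centroid distance (default max
3 um, about one sporangium length) and then by the angle between the mother
cell's major axis and the centroid-to-centroid vector (default max 30
degrees); both limits are deliberately strict to suppress false matches.
Matching is greedy and one-to-one in forespore-label order; ties break by
distance, then angle, then label, and the tie-break is part of the tested
contract. Orientation comes from image second moments, reported in
(-90, 90] degrees.

# Cytometry

**Concentration ratio.** Per-cell means of the background-subtracted
reporter channel; background is estimated from the complement of the
dilated low-threshold membrane mask. Negative corrected means clip to zero
(concentrations are nonnegative), and a zero mother-cell concentration
flags the ratio undefined instead of emitting `NaN`. Two concentration
proxies are exposed because "normalized to cell volume" admits both
readings: the default is the per-pixel mean (intensity per unit projected
area); `volume_mode = TRUE` divides integrated intensity by a model volume
— spherocylinder `V = pi r^2 (L - 2r) + 4/3 pi r^3` for the mother cell,
prolate spheroid `V = 4/3 pi a b^2` for the forespore, with dimensions
taken from the mask geometry. Neither is asserted to be the published
choice; the default is documented and the validation targets use it.

**Depletion time courses.** Each frame is segmented independently and the
sporangium is linked across frames by nearest forespore centroid within
1 um/frame; a lost track truncates the series with a warning rather than
interpolating. Both cells' background-subtracted means are divided by
their own first value, so every series starts at exactly 1.

**BONCAT.** Optical sections are sum-projected; the cell mean is corrected
by subtracting the background mean plus two background SDs (clipped at
zero) and divided by the cell-type reference median. The formula is exact
arithmetic and is tested as such; the reference median is supplied by the
caller because it belongs to a reference strain cohort, not to the image
at hand.

**Engulfment and phase-bright scoring.** A forespore is engulfed when its
outline signal in the clipped (mito - membrane) difference image exceeds
threshold and no DAPI-positive object overlaps its mask; any overlap
excludes (the fractional-overlap alternative is unstated in the source
method, and any-overlap is the conservative reading). Default thresholds
are robust image statistics (median + 3 MAD for the difference image,
median + 5 MAD for DAPI, DAPI objects under 5 px^2 ignored). Engulfed
forespores are phase-bright when their background-subtracted average phase
intensity strictly exceeds 0.1 AU; the strict inequality is a tested
boundary convention — a spore at exactly 0.1 AU is not bright.

# Photobleaching analysis

**The exchange model.** With amounts `A = cV`, the linear system
`dA_fs/dt = k (c_mc - c_fs) = -dA_mc/dt` conserves total amount and
relaxes the concentration difference exponentially:
`c_fs(t) - c_mc(t) = d0 exp(-k (1/v_fs + 1/v_mc) t)`. The simulator
advances per frame with this closed form (no integration error); a
forward-Euler integrator is retained purely as an independent test oracle.
The oracle-equivalence test tolerates 1e-6 relative error down to an
absolute floor of `1e-8 c0`, because the difference of two ~`c0`-sized
doubles cannot be resolved below machine cancellation once `rate * t`
exceeds ~30.

**cFR.** The bleached cell's intensity relative to an unbleached reference
sporangium (which cancels acquisition bleaching), rescaled so the
prebleach ratio is exactly 1 and the first-postbleach ratio exactly 0.
Both anchors are exact to machine precision on every accepted trace; a
trace with no detectable bleach (`r0 = rb`) is rejected with a diagnostic.
The reference is the nearest unbleached sporangium's whole-cell intensity
(the source method says only "the unbleached cell"; whole-sporangium
intensity is the lower-noise choice and is stated, not inferred).

**The recovery plateau.** Because bleached molecules are destroyed, the
shared pool after a forespore bleach re-equilibrates below the prebleach
level: noise-free cFR follows `P (1 - exp(-rate t))` with
`P = v_mc / (v_fs + v_mc)` (~0.90 at the default volumes), not
`1 - exp(-rate t)`. This is a property of finite-pool FRAP, verified
against the Euler oracle, and it is why `estimate_exchange_rate` takes the
volumes: the plateau is known, not fitted.

**Rate estimation.** Bounded nonlinear least squares (rate in [0, 10]/s)
on the postbleach frames, initialized from a log-linear regression on
`1 - cFR/P`. The fit is two-stage: first with the amplitude fixed at `P`,
then — only when the first stage detects recovery (rate > 1e-3/s) — with a
bounded free amplitude `A` in [0.2, 5]. The amplitude absorbs the scale
noise of the cFR anchors, which are single acquisitions: with anchor noise
`eps`, the per-replicate cFR scale is `1/(1 + eps)`, whose expectation
exceeds 1 and biases a fixed-scale fit upward. Gating the release on
detected recovery keeps a flat (`k = 0`) trace, where the amplitude is
unidentifiable, from chasing noise. On noise-free series the fit recovers
the rate to machine precision; at SNR ~ 10 the suite checks the median
over 50 replicates against a 10% band, and `k = 0` scenarios pin the
estimate below 1e-4 fL/s.

**FLIP.** The acquisition-loss standard curve is the per-frame average of
distal-cell traces, each normalized to its own prebleach value — empirical
per-frame averaging, with no functional form imposed (an exponential fit
would be a special case and is not needed at 31 frames). Corrected traces
are normalized so both cells' prebleach values equal 1 and the mother
cell's first-postbleach value equals 0; the forespore's first-postbleach
value is deliberately not forced to 0, because forespore loss is the
transport signal being measured. With `k = 0` and acquisition loss only,
the corrected forespore series is identically 1 — the channel-mutant
pattern — while `k > 0` drains it toward the mother-cell level.

# SILAC classification

Proteins map to compartments through their regulons with vegetative
precedence: membership of SigA, SigH or Spo0A marks a protein vegetative
regardless of other memberships (the one explicit rule in the source
method); otherwise sigF/sigG imply forespore and sigE/sigK mother cell;
membership of both cell types is ambiguous and excluded, since
misassignment would bias transport inference in an unknown direction. The
headline fractions use peptides with at least one arginine from
mother-cell or forespore proteins; everything else (no-arginine,
vegetative, ambiguous, unmapped) is tallied in a filter report whose
categories partition the input exactly — the partition is a tested
invariant. Whether the sporulation-specificity filter ran before or after
the arginine filter in the original analysis is unstated; the order does
not change any fraction, only which report bucket a no-arginine vegetative
peptide lands in, and no-arginine is counted first here. Shared (razor)
peptides are not modelled: each record carries one protein.

Incorporation fractions carry 95% Wilson score intervals (well-behaved at
small n and extreme fractions, unlike the Wald interval), computed via
`prop.test(correct = FALSE)`. Fold changes divide fractions; their
interval is the conservative ratio of Wilson bounds, and a zero control
fraction flags the fold undefined. Calibration is tested directly: across
200 seeded runs of ~3000 peptides, the true labeling probability must fall
inside the reported interval in 93--97% of compartment summaries. The
sigF-vs-sigG stratification of forespore peptides is reported so that
engulfment-window effects can be read off when the generator (or real
data) encodes them; the default generator uses one forespore-wide
probability, so the strata differ only by sampling noise.

# Numerical and degenerate-input conventions

* Coordinates are 0-based (row, col); physical quantities derive from
  `pixel_size`. Label images are 16-bit TIFFs; intensity stacks are 32-bit
  TIFF pages on [0, 1] with the AU scale recorded in the JSON sidecar so
  values round-trip.
* Quantile thresholds resolve against the membrane channel per image;
  raising the high threshold can only shrink or merge-away forespore
  components (tested monotonicity).
* Empty masks, empty compartments, lost tracks, unmapped proteins,
  nonpositive reference medians, degenerate anchors and non-converged fits
  all produce explicit errors, warnings or flags — never silent `NaN`s.
* Validation problem sizes: 96--224 px images, 1--4 sporangia, 50-replicate
  noise studies, 200-run calibration, 20 random layouts for pairing. These
  sizes make the full suite and the acceptance script each run in a couple
  of minutes on one CPU while keeping Monte-Carlo bands meaningful.

# Known limitations

Touching sporangia are not split (no watershed); time-lapse tracking is
nearest-centroid, not globally optimal; compartments are well-mixed (no
intra-cell diffusion); the volume models assume the cells are axially
symmetric rods/spheroids; and the published biological effect sizes
(enrichment ratios of specific enzymes, absolute incorporation
percentages of specific strains) are not reproducible here because the
underlying raw data are not machine-readable — the package validates its
estimators on synthetic ground truth and exposes the same measurements for
real images and peptide exports.
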