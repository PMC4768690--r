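---
title: "STFT-DA: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STFT-DA: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stftda)
```

This vignette documents the model behind `stftda`, the parameters that
matter, the numerical conventions adopted where several were defensible,
and what the synthetic validation does and does not demonstrate.

## The pipeline

An otolith photograph is reduced to a species prediction in three stages.

**Contour.** The grayscale image (intensities normalised to [0, 1]) is
thresholded: a pixel is foreground when its intensity strictly exceeds 0.1.
That threshold is deliberately low so that otoliths across a wide range of
transparency all segment; it assumes a dark background, as produced by
transmitted-light stereomicroscopy. Components touching the image border
are then removed (partial objects cannot contribute a closed outline),
holes fully enclosed by foreground are filled (otolith interiors can
contain translucent patches darker than the threshold), and components
below `min_area = 50000` px are dropped (debris, dust). The default area
assumes roughly the magnification of the study design this package
follows (6.3x); synthetic fixtures and lower-magnification images should
lower it explicitly. The external boundary of the largest surviving
component is traced with the Moore neighbourhood (8-connectivity,
counterclockwise in a y-up frame), and the centre of gravity is the mean
pixel coordinate of the filled region — of the region, not of the boundary,
so thin protrusions do not drag the centre. The 1D contour signal is the
Euclidean distance of each boundary pixel to the centroid, indexed by its
polar angle (0 along the positive x-axis, the anatomical convention with
the posterior end facing right).

Two orderings of the signal are provided. `traversal` (the default) keeps
boundary-trace order, whose unit pixel steps approximate uniform
arc-length spacing — the better assumption for the Fourier resampling that
follows, and well defined even where the outline is not star-convex.
`angle_sorted` sorts by ascending angle, matching the conventional
radius-versus-angle plot. For star-convex shapes the two nearly coincide.
In both cases the sequence starts at the point with angle closest to zero,
making the signal deterministic and comparable across images.

**Spectral features.** The contour signal is resampled to N = 1000 points
by band-limited trigonometric interpolation: forward FFT, symmetric
truncation or zero-padding of the spectrum, inverse FFT. Treating the
signal as periodic is the natural choice for a closed contour — there is
no boundary discontinuity to suppress. The short-time Fourier transform
then uses a window of L = 100 samples with O = 40 samples of overlap
(hop 60), giving S = ⌊(1000 − 40)/60⌋ = 16 segments, each zero-padded to
nfft = 256 and transformed; the one-sided spectrum keeps
F = nfft/2 + 1 = 129 bins. The automatic FFT length
`max(256, 2^ceiling(log2(L)))` is the unique power-of-two choice
consistent with 129 bins at L = 100.

Within each segment the 129 magnitudes are z-scored (sample standard
deviation, n − 1; `zscore_ddof = 0` switches to the population form) and
their maximum retained; likewise for the 129 principal-value phase angles
in (−π, π], without unwrapping. The 16 + 16 maxima form the descriptor.
Z-scoring inside each segment across bins — rather than across segments
per bin — makes each feature a measure of how sharply one frequency
dominates its segment, and renders the descriptor exactly invariant to
uniform scaling of the signal (photometric gain, and in combination with
the contour stage, largely insensitive to specimen size). Phase features
carry outline asymmetry information that magnitudes discard; ablations via
`cmd_sweep(..., what = "feature_sets")` show both contribute.

The window kind is configurable over sixteen classical choices. The
Gaussian window (reciprocal-sigma shape parameter alpha = 2.5) is the
default; shape parameters for Kaiser (beta = 0.5), Chebyshev (100 dB) and
Tukey (ratio 0.5) follow the MATLAB-style conventions of classical DSP
toolboxes, since those are the definitions the original window ablation
was computed with. Eight kinds are delegated to the `signal` package,
whose definitions match those conventions; the Gaussian, flat-top,
Bartlett–Hann, Blackman–Harris, Bohman, Nuttall, Parzen and Tukey windows
are computed in-package because `signal`'s Octave-derived forms differ
(different Gaussian denominator, different flat-top coefficients).

**Classifier.** A linear discriminant with pooled within-class covariance
S = Σ_k Σ_{i∈k} (x − μ_k)(x − μ_k)ᵀ/(n − K). Linear rather than quadratic
is forced by the data regime: with d = 32 features and ~18–20 training
specimens per species, per-class covariances are unestimable, while the
pooled estimate needs only n − K ≥ d overall. Priors default to uniform
(the designs this method targets are balanced); empirical priors are
available. If the pooled covariance has condition number above 1e12 and a
`ridge` factor is supplied, `ridge · trace(S)/d` is added to the diagonal
and recorded in the fitted object; with `ridge = 0` a singular covariance
is an error that names the remedy. Score ties are broken toward the
earlier class in class order, for reproducibility. Predictions expose the
full score matrix for audit.

## The synthetic generator

`species_shape_spec()` defines a species as
r(θ) = R · (1 + Σ a_k cos(kθ + φ_k) + ε(θ)): a base radius R (default
150 px, whose rasterised area comfortably exceeds the 50,000 px cleaning
threshold on a 512² canvas), a small set of fixed harmonics that play the
role of the species-diagnostic outline signature, and smooth specimen
noise ε built from random harmonics of orders 2–13 scaled to a target
standard deviation (default 0.01 of R). The noise is smooth rather than
per-pixel because biological outline variation is smooth; sensor noise is
not what the contour stage is sensitive to after thresholding. Amplitudes
are constrained (Σa_k + 3·sd < 0.5) so every shape is star-convex with
strictly positive radius, which keeps the two signal orderings consistent
and isolates pipeline correctness from the ordering ambiguity. Each
specimen is fully determined by an integer stream seed derived from
(species seed, specimen index), so datasets are bit-reproducible.

The end-to-end validation uses three species with harmonic orders 2, 3
and 5, amplitude 0.15, noise sd 0.01, 18 training and 10 test specimens
per species — mirroring the balanced designs the classifier targets.
Recovery is essentially perfect under these conditions, and a control with
three identical species specifications falls to chance (1/3). What this
does and does not show: it demonstrates that contour extraction, Fourier
resampling, STFT feature extraction and the discriminant are correctly
wired and jointly able to separate genuinely distinct outline signatures;
it does not emulate real otolith difficulty — uneven illumination,
texture, off-axis orientation, inter-specimen allometry, or species whose
outlines differ in subtler ways than distinct harmonic orders. Published
accuracies on real photographs (90–97% over three fish families) are
therefore not claims this package re-establishes; the shipped reference
confusion matrices only anchor the accuracy arithmetic, and
`inst/scripts/real_data_experiment.R` reruns the full experiment for
users who hold an image collection.

## Numerical choices and degenerate inputs

* Resampling follows the standard spectral-truncation algorithm including
  Nyquist-bin handling: when downsampling to an even length the conjugate
  negative-Nyquist energy is folded into the retained bin; when upsampling
  from an even length the Nyquist bin is split. This keeps the output
  real, preserves constants exactly, and reproduces band-limited signals
  to machine precision.
* Thresholding is strict (`> 0.1`), so a pixel exactly at the threshold is
  background; integer images are rescaled by their type maximum first.
* Component labelling is 8-connected for foreground (diagonal contact is
  contact) and the hole filling treats background 4-connectedly — the
  standard Moore-boundary pairing that keeps the traced outline a single
  cycle.
* A mask that cleans to empty raises a no-object error naming the likely
  cause; batch extraction records such failures per image and only fails
  outright when every image fails.
* A contour whose centroid coincides with a boundary pixel (radius 0) is
  rejected as degenerate rather than producing an angle singularity.
* An all-constant spectrum (zero variance in magnitudes or phases of a
  segment) cannot be z-scored and raises a degenerate-spectrum error;
  this only arises for pathological inputs such as an identically zero
  signal.
* The feature maximum needs no tie-break: the feature is the maximal
  value, not its location.

## Problem sizes in the test-suite

Unit and property tests run on reduced geometries chosen to keep the
default suite quick while preserving every code path: canvases of
160–300 px, base radii 50–120 px, `min_area` lowered accordingly, and
13 + 5 specimens per species in the small end-to-end runs (13 per class is
the minimum that keeps the 32-feature pooled covariance estimable for
three classes, since n − K must reach d = 32). The acceptance checks run
the full-scale conditions: 512² canvases, radius 150, default cleaning
threshold, 18 + 10 specimens per species. Sweep tests reduce the segment
count (window 250/50 → 4 segments, 8 features) so that all sixteen windows
can be swept against small training sets.

## Known limitations

* One otolith per image; no multi-object scene splitting, no left/right
  mirroring, no illumination correction.
* The contour signal is single-valued per boundary pixel, but ordering by
  angle is only meaningful for near-star-convex outlines; strongly lobed
  shapes should use the default traversal ordering.
* No wavelet or elliptic-Fourier-descriptor extractors, no quadratic DA or
  other classifiers, no cross-validation machinery beyond the seeded fixed
  split — the scope is the STFT + linear-DA pipeline.
* Feature extraction assumes the otolith dominates the cleaned mask; when
  several objects survive cleaning, the largest is used silently.
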