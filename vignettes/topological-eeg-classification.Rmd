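---
title: "Methods: topological classification of multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological classification of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toposeize)
```

This vignette is the package's account of what it computes, the choices
that were open when it was designed, and what its tests do and do not
establish.

## The pipeline

A recording is a bundle of channels sharing length and sampling rate
(23 bipolar scalp derivations at 256 Hz in the setting the package
targets; both are configurable). The classification pipeline is:

1. **Preprocessing** per channel: band-pass 1–70 Hz, power-line notch,
   decimation.
2. **Sublevel-set ("piecewise") filtration** per channel: one vertex per
   sample entering at its amplitude (µV), one edge per consecutive pair
   entering at the larger endpoint amplitude. A length-N channel yields
   exactly N vertices and N−1 edges.
3. **Zero-dimensional persistent homology** of that complex: components are
   born at local minima and die, by the elder rule, when they merge at a
   saddle (the younger dies). One interval per vertex, one infinite
   interval per connected component.
4. **Persistent entropy**: with infinite bars replaced by $[x, m)$,
   $m = \max F + 1$, the Shannon entropy of the normalized bar lengths,
   $H = -\sum p_i \log p_i$, $p_i = \ell_i / L$; the normalized form
   $\mathcal{H} = H / \log \ell_{\max}$.
5. **Classification**: the per-recording feature is the mean of
   $\mathcal{H}$ over channels; a single threshold, fitted by maximising
   Youden's J on a training split, is the whole model. Evaluation is by
   ROC/AUC on a held-out split, with a Wilcoxon rank-sum comparison of the
   two feature populations. Sample Entropy (mean over channels) is the
   baseline feature computed by the same machinery.

A separate analysis treats the channels of one recording as a point cloud
(one point per sensor in $\mathbb{R}^N$) under the standardized Euclidean
metric — each coordinate divided by the across-channel standard deviation
at that sample position — and computes Vietoris–Rips persistence with
representative cycles, mapping persistent holes back to the sensors whose
vertices realise them.

### Assumptions

- Amplitudes are finite and in µV throughout; no unit conversion is
  attempted.
- All channels of a recording share fs and length; supervised operations
  require both class labels present.
- The topological feature only sees the *ordering and depths of extrema*:
  any phase distortion in filtering would move extrema, hence all filters
  are applied forward–backward (zero phase).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `band_low`, `band_high` | 1, 70 | Hz | conventional EEG band of interest |
| `notch_freq` | 50 | Hz | European power-line frequency; configurable for 60 Hz grids |
| `notch_q` | 30 | – | narrow stop-band (≈1.7 Hz at 50 Hz) so physiological content is spared |
| `decimation_factor` | 10 | – | one order of magnitude fewer simplices; an 8th-order Chebyshev-I anti-alias low-pass at 0.8 of the post-decimation Nyquist precedes subsampling |
| Sample Entropy `m`, `r` | 2, 0.2·SD | – , µV | the standard conventions in the SampEn literature |
| VR `r_max` | max distance | – | the filtration runs to completion |
| VR `max_dim` | 2 | – | loops and voids are the objects of interest; simplices are generated one dimension higher so deaths are witnessed |

On the notch: descriptions of this pipeline sometimes pair "power-line
removal" with a wide 8–52 Hz interval, which would excise most of the EEG
band and cannot be what a power-line filter does. The package's default is
a narrow second-order IIR notch at a configurable centre frequency; a
literal Butterworth band-stop over 8–52 Hz is available behind
`wide_notch = TRUE` for anyone who wants that variant verbatim.

On decimation: the output length is defined as `floor(N / df)` (subsampling
from the first sample), and the anti-alias filter is applied
forward–backward. The Chebyshev passband ripple (0.05 dB per pass) means
amplitudes carry a deterministic ≈1% bias after two passes; the tests
account for this and it cancels in the entropy ratio to first order. A
shape-preservation diagnostic (`check_shape = TRUE`) warns when decimation
moves a channel's normalized persistent entropy by more than a tolerance —
the operational meaning of "downsampling must preserve the signal's shape".

## Numerical choices

- **Simplex order.** The reduction orders simplices by (filter value,
  dimension, lexicographic vertex tuple). Any face-respecting order gives
  the same barcode; the tie rule only fixes which representative cycles
  are reported, and makes them deterministic.
- **Coefficients.** Boundary-matrix reduction is over GF(2).
- **Zero-length bars.** Retained in barcodes (they keep the
  one-interval-per-vertex invariant) but contribute zero weight to entropy
  and are excluded from $\ell_{\max}$, matching the $0 \log 0 := 0$ limit.
- **Elder-rule ties.** When two components born at the same filter value
  merge, the one whose birth vertex has the larger id dies; this matches
  the pairing the lexicographic reduction produces, so the union-find and
  matrix-reduction routes agree interval-for-interval.
- **Entropy domain.** $\mathcal{H}$ requires $\ell_{\max} > 1$ (in µV
  units); violations raise a classed error rather than clipping, since a
  silently clipped feature would poison a classifier.
- **Infinite-bar replacement.** $m = \max F + 1$ exactly; the +1 is in
  amplitude units.
- **Degenerate metric positions.** If every channel agrees at some sample
  position, the standardized Euclidean metric is undefined there; the
  error names the offending positions.
- **EDF sampling rates.** EDF stores fs as samples-per-record over an
  8-character record duration; rates within 0.1% of an integer are snapped
  to it on read.

## Design decisions that were genuinely open

- **Threshold rule.** The threshold maximises Youden's J (midpointed
  between adjacent feature values, the ROC convention). The full ROC is
  part of every report so any other operating point can be audited.
- **Split × cross-validation.** The data are split stratified 70/30 once
  (seeded); 10-fold CV runs *inside* the training portion to gauge
  threshold stability; the final model is refitted on the whole training
  portion and evaluated once on the untouched 30%. Test labels are never
  visible to fitting.
- **Entropy dimensions.** For the per-channel feature, only the
  $H_0$ barcode exists (a path graph has no loops), so `dims = 0` is
  forced in practice; the argument stays general for VR barcodes.
- **$\ell_{\max}$ scope.** Taken per-channel barcode, not globally over a
  recording's 23 barcodes.
- **Generators → sensors.** A persistent hole is attributed to the set of
  distinct vertices of its representative cycle. Representatives are not
  unique; the fixed simplex order makes the choice deterministic, and the
  analysis report says so. Only positive-length intervals count (an
  optional `min_length` can suppress near-zero bars from noisy clouds).
- **VR input.** Sensor clouds are built from preprocessed channels (the
  same $\tilde{S}$ the classifier sees); the distance is computed in
  whatever $\mathbb{R}^N$ the preprocessing leaves.

## The synthetic generator

The generator emulates only what the feature measures. Each channel is a
sum of 2–8 Hz sinusoids with random phases (~15 µV), Gaussian noise
(3 µV), and downward Gaussian spike events (width 50 ms) — downward
because $H_0$ bars of a sublevel filtration are born at local minima, so
spike depth is the lever that shapes the barcode.

The two classes share the spike count (20 per 16 s channel) and the mean
depth (40 µV) and differ *only in depth dispersion*: sd 3 µV
("epileptic-like" — near-equal bars, higher $\mathcal{H}$) versus sd 35 µV
("healthy-like" — skewed bar lengths and a longer $\ell_{\max}$, lower
$\mathcal{H}$). Matching count and mean keeps the classes nearly
indistinguishable to amplitude- and regularity-based summaries, which is
what makes the Sample Entropy baseline an honest comparator: in the
package's tests the entropy classifier separates the classes essentially
perfectly while Sample Entropy does distinctly worse — the ordering, not
the exact margins, is the reproducible claim. An `overlapping` preset
narrows the dispersion gap (sd 15 vs 25 µV) for experiments that need
imperfect separation.

What the generator does **not** emulate: 1/f spectra, inter-channel
correlation (channels are independent draws), artifacts (eye blinks, EMG),
non-stationarity, and real seizure morphology. Passing tests therefore
show that the pipeline recovers a planted dispersion difference through
preprocessing, filtration, persistence and classification — they do not
show that real epileptic EEG is separable at any particular AUC.

## Problem sizes used by the test suite

Synthetic recordings default to 23 channels × 4,096 samples (16 s at
256 Hz); the classification check runs 33 + 33 recordings through the full
default pipeline. Oracle-equivalence checks use 200 random signals of
length ≤ 50 (persistence), 100 random feature sets of size ≤ 20 (AUC),
series of length ≤ 30 (Sample Entropy), and point clouds of ≤ 8 points
(Vietoris–Rips/Euler). The full clinical recording length the package
targets (921,600 samples, i.e. one hour at 256 Hz) is exercised once,
through the decimation length contract.

## Known limitations

- The boundary-matrix reduction is a dense-column GF(2) implementation in
  R: fine for sensor clouds of a few dozen points, not for large complexes.
  The union-find route handles long signals (it is linear-ish in N) and is
  the one the classifier uses.
- `read_edf` targets continuous EDF; EDF+ annotations, event markers and
  discontinuous records are out of scope.
- The 16-bit EDF writer quantises to the per-channel amplitude range
  (≈ range/65,000 absolute error).
- $\mathcal{H}$ is not scale-invariant (H is, $\ell_{\max}$ is not):
  recordings must be in consistent units for thresholds to transfer.
- Betti-number counting rules for "a recording has $\beta_0$" style
  summaries are not built in; `betti_at()` exposes the curve and leaves
  aggregation to the analyst.
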