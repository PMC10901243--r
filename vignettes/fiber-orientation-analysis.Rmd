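---
title: "Separating intrinsic and form birefringence from Mueller matrix images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating intrinsic and form birefringence from Mueller matrix images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polaxis)
```

## The measurement model

`polaxis` simulates and analyses transmission Mueller matrix imaging of
fibrous samples. The simulated instrument is a dual-rotating
quarter-wave-plate polarimeter: unpolarized light passes a fixed polarizer
and a quarter-wave plate stepping 6° per frame (the polarization state
generator), traverses the sample, and is analysed by a second quarter-wave
plate stepping 30° per frame in front of a fixed polarizer. Thirty frames
give intensities

$$I_k = a_k^\top \, M \, s_k,$$

a linear system in the 16 elements of the per-pixel Mueller matrix $M$,
with rank 16 (asserted at reconstruction time; a rank-deficient protocol is
a configuration error, not a numerical surprise). We invert it per pixel by
least squares through the singular value decomposition of the 30×16 design
matrix. On an evenly stepped protocol this is algebraically the same
estimate as the classical Fourier-coefficient reconstruction for this
instrument family; we prefer the linear-algebra formulation because it is
protocol-agnostic and its identifiability check (the rank) is explicit.

Angle conventions are global and fixed: degrees everywhere; orientation
angles are axial, reduced to [0°, 180°); the zero direction is the
horizontal image x-axis with positive angles counterclockwise; Stokes
vectors are (I, Q, U, V) with Q > 0 horizontal. The quarter-wave-plate
matrix under these conventions has fourth row
$(0, \sin 2\theta, -\cos 2\theta, 0)$, which pins down the sign convention
of every retarder in the package. Whether this frame mirrors the original
instrument's camera frame is unknowable from the measurement geometry
alone; all quantities we compare are either convention-invariant (axial
distances, peak separations, shares) or internally consistent.

## Decomposition and the orientation parameters

Each pixel's matrix is factored by the Lu–Chipman polar decomposition
$M = M_\Delta M_R M_D$ (depolarizer · retarder · diattenuator). The
diattenuator is built from the first row; the depolarizer submatrix is the
signed symmetric square root of $m' m'^\top$ (the sign following
$\det m'$); the retarder is the remaining rotation, re-orthogonalized by
nearest-rotation projection (SVD) whenever numerical inversion leaves an
orthogonality defect above $10^{-9}$. From the factors:

- $\theta = \tfrac12\,\mathrm{atan2}(r_2, r_1)$ with
  $r_i \propto \sum_{jk}\varepsilon_{ijk}\,m_R(j,k)$ — the retarder's
  fast-axis orientation. The printed normalization of the retardance vector
  cancels in this ratio, so we use the standard unnormalized contraction.
- linear retardance
  $\delta = \arccos\!\big(\sqrt{(m_{22}+m_{33})^2+(m_{32}-m_{23})^2}-1\big)$,
  with the arccos argument clamped when within $10^{-9}$ of the boundary
  and an error beyond that.
- depolarization power $\Delta = 1 - |\mathrm{tr}(m_\Delta)|/3$ over the
  3×3 submatrix. (A matrix-inverse reading of the inner term would break
  the [0, 1] range; the trace reading is the standard one.)
- the element-ratio azimuths $\alpha_P = \tfrac12\mathrm{atan2}(m_{31},
  m_{21})$ (first-column convention, which our Stokes-product tests pin to
  the transmission-maximum azimuth) and
  $\alpha_q = \tfrac12\mathrm{atan2}(m_{42}, -m_{43})$.

All half-angle ratios use the two-argument arctangent and are reduced
modulo 180°, avoiding the quadrant ambiguity a single-argument arctan
leaves open.

**Degenerate pixels are masked, not dropped or NaN-propagated.** θ is
undefined when the total retardance is 0 or 180° ($|\sin\delta| <
10^{-9}$); $\alpha_P$/$\alpha_q$ are undefined when their element pair is
below a relative floor (default $10^{-6}$, configurable — no threshold
policy is inherent in the method, so the floor is explicit and recorded);
the decomposition itself fails only for a diattenuation magnitude at 1
(singular $M_D$) or a singular depolarizer (retarder unattributable).
`decompose_image()` records a bitwise reason code per pixel so that
downstream histograms can report coverage.

**Why θ rather than $\alpha_q$.** For a pure linear retarder the two agree
exactly (a property test asserts this over a retardance × axis grid). But
$m_{42}$ and $m_{43}$ couple scattering and birefringence: an anisotropic
depolarizer encountered before the retarder rescales them unequally,
biasing $\alpha_q$ while the decomposition still isolates the true retarder
— and when $m_{43}$ sits near zero the ratio amplifies noise. Both effects
are reproduced and tested. $\alpha_P$, by contrast, rides on $m_{21}$,
which stays far from zero whenever cylinder-scattering diattenuation is
present at all; that robustness is what the peak classifier relies on.

## Axial histograms and the bimodal statistics

Orientation angles live on a 180°-periodic domain, so all histogram
operations are circular. The FDH uses 1° bins by default (any divisor of
180° is accepted); 1° resolves the narrowest peak widths we generate while
keeping ~50+ counts in a mode bin at the default image sizes. Peaks are
wraparound-aware local maxima, greedily accepted in order of decreasing
mass subject to a minimum axial separation (default 20°) and a minimum
circular topographic prominence (default 10% of the maximum mass — a flat
histogram therefore has no peaks, and plateau runs contribute one
candidate). `peak()` is read as the probability mass of the peak's bin; an
"area under the peak" reading would change the absolute numbers but not
the share γ, since the two mixture components share their angular spread.

The width β is the angular FWHM: from the peak bin, walk circularly to the
first crossings of half the peak mass on either side, interpolating
linearly between bins (sub-bin precision), and report the spanned angle; a
crossing not found within 90° on a side flags the width undefined.

Classification: the fiber axis is the $\alpha_P$ peak + 90°. With two θ
peaks, the one axially closer to the fiber axis is the form-birefringence
peak $\theta_c$ and the other the intrinsic peak $\theta_b$, and
$\gamma = \mathrm{peak}(\theta_b) / [\mathrm{peak}(\theta_b) +
\mathrm{peak}(\theta_c)]$. A single θ peak is assigned by a 45° axial
threshold (γ is then 0 or 1); exact equidistance is refused rather than
tie-broken arbitrarily. A multimodal $\alpha_P$ FDH or more than two θ
peaks — the serial and serial-parallel stacking regimes, where no single
fiber axis exists — refuses classification and reports the modality
instead of guessing.

## The phantom generator: what it emulates, and what it does not

The generator replaces both the instrument and the physical samples. The
real coupling of anisotropic scattering and lattice birefringence inside
one fiber is a radiative-transfer problem; we model its *observable
signature* phenomenologically. Each pixel of a layer draws a retarder axis:

- nonbirefringent cylinders (glass fiber): axis = fiber axis + wrapped
  Gaussian noise, retardance `delta_form`;
- pure birefringent material (air-dried tendon): axis = fiber axis + 90° +
  noise, retardance `delta_intrinsic`, no diattenuation or depolarization;
- birefringent cylinders (silk, muscle): a Bernoulli mixture — with
  probability `mixture_w` the intrinsic branch (axis ⊥ fiber), otherwise
  the form branch (axis ∥ fiber).

The pixel matrix is `depolarizer · retarder · diattenuator`, the
diattenuation axis fixed perpendicular to the fiber. That element order
matches the decomposition's factor order, so noise-free single-layer
phantoms decompose exactly — deliberate, because it lets recovery tests
separate statistical error from model mismatch. `mixture_w` is the
generative twin of the observable γ.

Defaults (free parameters of the phantom, chosen once as representative of
thin fibrous layers and documented here rather than derived from refractive
indices, for which no mapping to retardance magnitudes is available):
retardances 30° for both components (40° for the pure-birefringent tendon
spec), diattenuation D = 0.1, depolarizer diag coefficients (0.9, 0.9, 0.8)
for silk and (0.95, 0.95, 0.9) for glass, angular noise SD 8° (silk) / 5°
(glass). Layer-series phantoms raise the depolarization coefficients to the
L-th power (depolarization accumulates with thickness) and decay the
intrinsic share geometrically, $w_L = w_1\rho^{L-1}$ with ρ = 0.8;
stretch-series phantoms move `mixture_w` by ±0.12 per stretching step,
transverse down, longitudinal up. Both schedules are explicit arguments
recorded in the truth objects, so the trend tests are self-describing.

What the phantoms do **not** contain: real tissue texture and its spatial
correlations, wavelength dependence, multiple-scattering angular spread,
genuinely coupled (non-separable) scattering-birefringence within a pixel,
and registration error between frames (simulated frames are co-registered
by construction). Passing recovery tests therefore demonstrates that the
*analysis* is correct and well-calibrated on data obeying its own model
assumptions — not that those assumptions hold in any particular tissue.

The noise model for acquisition is multiplicative Gaussian on each frame
intensity, clipped at zero. Under it, reconstruction error grows linearly
in the noise level (tested by regression over three levels), and the
noise-free acquisition → reconstruction round trip is the identity to
better than $10^{-9}$ per element for arbitrary physical matrices.

## Problem sizes and determinism

Test and acceptance runs use image sizes the statistics actually need:
unit tests 24–64 px squares, trend sweeps and truth recovery 96×96
(≈ 9.2·10³ pixels, which keeps mode-bin counts in the hundreds so that
peak-mass ratios resolve the scheduled share differences), pure
angle-domain Monte Carlo properties 10⁵ draws, and the air-calibration
simulation 100×100. Every stochastic path takes an explicit seed; equal
seeds give bit-identical images, stacks and summaries, and equal run
configurations give byte-identical summary JSON.

## Known limitations

- The Lu–Chipman factor order is an assumption; samples whose physical
  element order differs (e.g. diattenuation after depolarization) decompose
  to *equivalent*, not literal, factors. Only the differential
  (logarithmic) decomposition would treat orders symmetrically, and it is
  out of scope.
- Peak angles are reported at bin-center resolution (no sub-bin peak
  interpolation); with 1° bins that bounds the orientation readout at
  ±0.5° plus sampling noise of the mode bin.
- `peak()` as bin mass makes γ mildly bin-width dependent when the two
  components' angular spreads differ; the phantoms share one spread, and
  real-data use should fix one bin width per comparison.
- The per-pixel maximum deviation of a reconstructed air image is
  noise-amplification-limited: the least-squares inversion of the 30-frame
  protocol amplifies intensity noise into the worst Mueller elements by
  roughly a factor of two relative SD, so the extreme over 10⁴ pixels × 16
  elements sits well above the per-element RMSE. Criterion-style bounds on
  that extreme are statements about the noise level as much as about the
  algorithm.
- Physicality checking is element-bound only (|m_ij| ≤ m11); no Cloude
  eigenvalue filtering, since the pipeline consumes its own simulated
  matrices, which are physical by construction.
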