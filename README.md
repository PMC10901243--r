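# polaxis

Transmission Mueller matrix polarimetry separates two physically distinct
sources of optical anisotropy in fibrous biological samples:

- **intrinsic birefringence** from ordered molecular structure — for a
  positive uniaxial fiber its fast axis lies *perpendicular* to the fiber
  long axis;
- **form birefringence** from anisotropic scattering by aligned cylinders —
  its fast axis lies *parallel* to the fiber long axis.

In samples where both coexist (silk, skeletal muscle, tendon), the per-pixel
fast-axis orientation does not cluster around one angle: its frequency
distribution histogram (FDH) over the axial domain [0°, 180°) is *bimodal*,
with two peaks perpendicular to each other. `polaxis` implements the full
desk-scale pipeline that produces and analyses these distributions, with a
synthetic phantom generator standing in for the instrument and the tissue.

## The model

A dual-rotating quarter-wave-plate polarimeter (30 frames; generator
retarder stepping 6°/frame, analyzer retarder 30°/frame, fixed polarizers)
measures intensities `I_k = a_k^T M s_k` per pixel; the 16 Mueller elements
are recovered by per-pixel least squares on this rank-16 linear system. Each
pixel's matrix is then factored by the Lu–Chipman polar decomposition

    M = M_Δ · M_R · M_D

into a depolarizer, a pure retarder and a diattenuator, giving the maps

- `θ = ½·atan2(r₂, r₁)` — fast-axis orientation from the retardance vector
  `rᵢ ∝ Σ ε_ijk m_R(j,k)` of the retarder factor;
- `δ` — linear retardance magnitude;
- `Δ = 1 − |tr(m_Δ)|/3` — depolarization power;
- `α_P = ½·atan2(m31, m21)` — diattenuation azimuth (element-ratio);
- `α_q = ½·atan2(m42, −m43)` — birefringence azimuth (element-ratio;
  equals θ for a pure retarder but unstable under coupled scattering);
- `D` — diattenuation magnitude.

Because the diattenuation of cylinder scattering always peaks perpendicular
to the fiber axis, the unimodal `α_P` FDH anchors the geometry: the fiber
axis is the `α_P` peak + 90°. The θ peak parallel to the fiber axis is the
form-birefringence peak `θ_c`; the perpendicular one is the intrinsic peak
`θ_b`. Each peak carries its probability mass `peak(·)` and angular FWHM
`β`; the share

    γ = peak(θ_b) / [peak(θ_b) + peak(θ_c)]

tracks how much of the anisotropy is intrinsic — it falls as scattering
thickens (more layers) and moves with mechanical stretch.

## Worked example

```r
library(polaxis)

# a two-component silk-like phantom: fiber axis 20 deg, 60% intrinsic share
ph <- generate_phantom(list(silk_spec(fiber_axis = 20, mixture_w = 0.6)),
                       shape = c(96, 96), seed = 42)

# simulate the 30-frame acquisition at 0.2% intensity noise and reconstruct
stack <- simulate_stack(ph$image, noise_sd = 0.002, seed = 42)
mm <- reconstruct_mueller(stack)

# per-pixel polar decomposition and axial histograms
maps <- decompose_image(mm)
theta_fdh  <- build_fdh(as.vector(maps$theta),  bin_width = 1)
alphaP_fdh <- build_fdh(as.vector(maps$alphaP), bin_width = 1)

classify_peaks(find_peaks(theta_fdh), alphaP_fdh)
```

```
<bimodal_summary>
  fiber axis        19.5 deg (from alphaP peak + 90)
  theta_c (form)    22.5 deg  peak 0.0216  beta 17.68
  theta_b (intr.)  110.5 deg  peak 0.0309  beta 17.14
  gamma            0.589
```

The classifier reads the fiber axis off the `α_P` peak (19.5° vs. the true
20°), finds the two θ peaks perpendicular to each other, assigns the one
along the fiber to form birefringence and the one across it to intrinsic
birefringence, and estimates the intrinsic share γ = 0.589 against the
generative truth of 0.6. The `β` values are the angular FWHMs of the two
peaks (the phantom draws axes with an 8° angular SD, so
β ≈ 2.355 × 8° ≈ 19°, shaved slightly by the retarder–diattenuator
coupling).

A command-line interface over the same pipeline (subcommands `phantom`,
`acquire`, `reconstruct`, `decompose`, `fdh`, `report`) is installed at
`system.file("cli", "polaxis.R", package = "polaxis")`.

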