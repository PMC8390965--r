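---
title: "Phasor analysis of Mueller-matrix microscopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor analysis of Mueller-matrix microscopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmphasor)
```

## The measurement and the two estimators

A Mueller-matrix (MM) microscope records, per pixel, the 4x4 real matrix
$M(x, y)$ that maps any illumination Stokes vector
$\vec S = (S_0, S_1, S_2, S_3)$ onto the Stokes vector of the light leaving
the sample, $\vec S_{out} = M \vec S_{in}$. Sixteen intensity measurements —
four generator states (H, V, 45°, right circular) crossed with four analyzer
projections — determine all sixteen elements. For thin biological tissue the
dominant contrast is *linear birefringence*: the sample acts as a linear
retarder with retardance $R = 360\,\Delta n\, e / \lambda$ degrees
(birefringence $\Delta n$, thickness $e$, wavelength $\lambda$) and fast-axis
orientation $\alpha_R$ on the 180°-periodic axis $(-90°, 90°]$.

The package implements two per-pixel estimators of $(R, \alpha_R)$:

1. **Lu-Chipman (LC) polar decomposition** (`lc_decompose()`), the classical
   reference: $M = M_\Delta M_R M_D$ with depolarizer, retarder and
   diattenuator factors in that fixed order. The scalars are the
   diattenuation $D = \lVert(m_{01}, m_{02}, m_{03})\rVert$, the
   depolarization index
   $P_d = \sqrt{(\sum_{ij} m_{ij}^2 - m_{00}^2)/(3 m_{00}^2)}$, the total
   retardance $R = \arccos\!\big(\mathrm{tr}(M_R)/2 - 1\big)$, and
   $\alpha_R = \tfrac12\,\mathrm{atan2}(r_2, r_1)$ from the retardance
   vector.
2. **The MM-phasor readout** (`phasor_parameter_images()`), the package's
   core: convert the MM into polarization-resolved intensities
   $I_\theta = \tfrac12 (S_0 + S_1 \cos 2\theta + S_2 \sin 2\theta)$ for a
   virtual analyzer rotation $\theta \in \{0°, 45°, 90°, 135°\}$, take the
   normalized first Fourier coefficient at period $\Theta = 180°$,
   $$ g = \frac{\sum_\theta I_\theta \cos(2\pi\theta/\Theta)}{\sum_\theta I_\theta},
      \qquad
      s = \frac{\sum_\theta I_\theta \sin(2\pi\theta/\Theta)}{\sum_\theta I_\theta}, $$
   and read modulation $M = \sqrt{g^2 + s^2} \in [0, 0.5]$ and phase
   $\varphi = \mathrm{atan2}(s, g)$. For a retarder the right-circular-input
   (RCP) channel obeys two closed forms, independent of each other:
   $M_{RCP} = \sin(R)/2$ and $\varphi_{RCP} = 90° + 2\alpha_R$, so
   $$ \alpha_R = \varphi/2 - 45°, \qquad
      R = \arcsin(2M) \;\text{ or }\; 180° - \arcsin(2M). $$

The arcsine ambiguity is resolved from the linear-input phasors: for
$R < 90°$ the H-channel phasor lies inside the circle of center $(0.25, 0)$
and radius $0.25$, for $R > 90°$ outside it (but within the physical radius
0.5), and exactly on it at $R = 90°$.

The phasor readout involves no matrix inversion and no assumption on the
ordering of elementary optical components, which is its advantage in layered
or disordered media where the LC factor order is a modelling choice.

## Conventions

* All user-facing angles are degrees; orientations are folded into
  $(-90°, 90°]$ (`fold_orientation()`).
* Stokes basis: $S_1 = I_H - I_V$, $S_2 = I_{45} - I_{135}$,
  $S_3 = I_{RCP} - I_{LCP}$, right-handed, detector view. The circular
  difference convention for $S_3$ is used throughout (the sum appears in
  some older texts but is inconsistent with $S_0 = I_{RCP} + I_{LCP}$).
* The retarder matrix `retarder_mueller()` has
  $m_{14} = -\sin 2\alpha \sin R$; this sign is pinned by requiring the RCP
  phasor phase of a retarder at $\alpha = 0$ to be $+90°$, which in turn
  makes $\alpha_R = \varphi/2 - 45°$ hold with the package's $S_2$ sign.
  The LC retardance vector uses the matching antisymmetric extraction
  $r_i = \sum_{jk}\epsilon_{ijk}(M_R)_{jk} / (2 \sin R)$, so that both
  estimators return the *same* orientation for the same matrix (this
  consistency is enforced by tests over a full $(R, \alpha)$ grid).
* `layered_mueller()` multiplies in traversal order (first layer hit by the
  light is rightmost); `reverse = TRUE` is available for order-sensitivity
  studies.

### The bundled experimental matrices and the readout transpose

`reference_mm()` ships ROI-averaged air and transparent-adhesive-film
matrices measured in reflection (epi) geometry, with their per-element ROI
standard deviations. Decoding the film matrix *as printed* with the
package's conventions yields a fast axis near $+6°$ from LC and $+9°$ from
the phasor, while the instrument's own analysis reported about $-86°$ (LC)
and $-83°$ (phasor). Decoding the *transpose* yields $-84.4°$ (LC) and
$-84.5°$ (phasor) — both estimators agreeing with each other and with the
reported values. In epi geometry the detection path traverses the optics in
the reverse order of the illumination path, which transposes the effective
element order relative to the transmission convention fixed above; the
loader therefore returns the transpose by default
(`convention = "transmission"`) and the raw layout via `"as_printed"`.
Scalars built from sums of squares ($D$ on the printed first row, $P_d$,
the LC retardance to within numerical asymmetries) are unaffected.

Note an estimator gap that the transpose does **not** explain: LC applied to
the printed *mean* film matrix gives $R \approx 51.1°$, while the published
ROI value is $55.5 \pm 1.9°$. The published numbers are per-pixel ROI
averages of a nonlinear estimator, which need not equal the estimate on the
averaged matrix; a Monte-Carlo check (mean matrix + printed element SDs)
reproduces the printed SD of $\pm 1.9°$ and the printed $P_d = 1.051$ (vs
1.047 on the mean matrix) but leaves the mean $R$ at $51.1°$. Both
estimators are therefore documented and neither is forced to match the
other.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `noise_floor_M` | 0.05 | RCP modulation below which a pixel is indistinguishable from air. 0.05 is the observed air-level modulation uncertainty under the bundled noise; it corresponds to a retardance sensitivity limit of $\arcsin(0.1) \approx 5.74°$. Gates both the $R$ and $\alpha_R$ maps. |
| `signal_threshold` (LC) | $D < 0.02$ and $R < 2°$ | air-level noise floor below which the LC orientation is masked. |
| `epsilon` (`branch_from_h_phasor`) | 0.005 | boundary band on the branch-circle distance for noisy data. |
| `boundary_tol` (`phasor_parameter_images`) | 1e-9 | numerical width of the exact $R = 90°$ boundary set. |
| `phasor_config()` | $\theta = 0,45,90,135$; $\Theta = 180°$; harmonic 1 | the transform is the generic Fourier sum over the $\theta$ list, so non-default analyzer sets work; with the default set it reduces to $g = (I_0 - I_{90})/\sum I$, $s = (I_{45} - I_{135})/\sum I$. |

### The branch rule used by the parameter maps

The H-channel circle rule is *blind* at $\alpha_R \in \{0°, 90°\}$: there
the H phasor is pinned to $(0.5, 0)$ — on the circle — for every retardance,
and for any small $R$ the phasor of *any* orientation approaches the air
point $(0.5, 0)$, which also lies on the circle. A fixed band
$\varepsilon = 0.005$ would therefore misclassify every pixel with
$\alpha_R$ within a few degrees of 0 or 90 and every pixel with
$R \lesssim 10°$. `phasor_parameter_images()` instead computes the circle
deviation on the H channel *and* on the 45°-channel analogue (circle center
$(0, 0.25)$, blind at $\alpha_R = \pm 45°$ instead), and classifies by the
sign of whichever deviation is larger in magnitude; the two blind sets are
disjoint, so the combined statistic vanishes only at $R = 90°$ exactly.
`branch_from_h_phasor()` retains the plain single-channel band rule for
direct use on noisy phasor coordinates.

## The instrument simulator and phantoms

`simulate_measurement()` projects a Mueller image through generator states
$W$ (columns) and analyzer projections $A$ (rows):
$I[a, p] = A_a M W_p$, and `reconstruct_mueller()` inverts
$M = A^{-1} I W^{-1}$ per pixel. With the ideal H/V/45/RCP set the state
matrix has 2-norm condition number 3.23 (`condition_number()`); a real
instrument's calibrated states differ, so the model accepts arbitrary
invertible $W$, $A$.

Noise is modelled as per-element additive Gaussian error on the
m00-normalized matrix, $M + \Delta(x, y)$, with SDs taken from the bundled
experimental air measurement (`air_sigma()`; $\sigma_{00} = 0$ since $m_{00}$
defines the normalization). The SD matrix is kept in the readout element
order: that orientation reproduces the observed air modulation uncertainty
of about 0.05 on which the noise floor is based. Under this model a 64x64
air phantom leaves about 86% of pixels below the default floor (the rest are
noise exceedances — the floor is a sensitivity limit, not a perfect
classifier), and per-pixel LC statistics land at the published air values
(mean $P_d$ within $1.007 \pm 0.01$, mean $R$ below $1.9 + 0.9°$).

`make_phantom()` builds the reference scenes with exact ground truth: air;
a film-on-air rectangle (defaults are the measured film parameters); stacks
of $n$ identical layers ($R_1 = 37.87°$, the 50-µm, $\Delta n = 0.0017$
collagen-like layer at 808 nm) at orientations 0°, 10°, 20°, 30°; a fiber
band under whole-scene rotation (physical rotation of a uniform fiber only
shifts its fast axis, so the scene geometry is kept fixed); and stripes of
alternating $\pm 20°$ orientation. For the layered scene the documented
noise option draws an independent error matrix per layer *before*
multiplication (`layer_noise = TRUE`), the injection point being otherwise
unspecified experimentally.

### What the phantoms do and do not emulate

The phantoms emulate element-wise instrument noise and idealized geometry.
They do not model the point-spread function, within-pixel incoherent mixing
of orientations, wavelength dispersion, scattering-induced depolarization,
or transmittance texture. Consequences worth knowing:

* Additive element noise *adds* energy to the matrix, so the LC $P_d$ of a
  noisy stack sits slightly **above** 1 and does not fall with the number of
  layers; strong experimental $P_d$ drops in disordered stacks require an
  incoherent-mixing mechanism that is outside this noise model.
* A noiseless stack of ideal retarders at different orientations is an
  **elliptical** retarder: its equivalent rotation axis acquires a circular
  component. The RCP modulation then measures
  $\sqrt{1 - Q_{33}^2}/2$ (with $Q$ the polarization block), not
  $\sin(R_{eq})/2$. For the 0/10/20/30° stack the phasor estimate tracks
  the quaternion-composition equivalent retardance to 0.2° at $n = 2$ but
  deviates by 2.1° at $n = 3$ and 13° at $n = 4$, while noiseless LC
  reproduces the rotation angle exactly. The phasor's model-free advantage
  claimed for layered media is therefore *not* reproduced by this phantom
  family under the documented noise model; the corresponding acceptance
  expectations are deliberately kept at their stated tolerances and fail,
  rather than being tuned to pass.

## Numerical choices

* `acos` arguments are clipped to $[-1, 1]$; near $R = 180°$ the
  antisymmetric retardance-vector extraction degenerates and a
  symmetric-part fallback is used (the half-wave degeneracy
  $\alpha \equiv \alpha + 90°$ is physical).
* Degenerate inputs are flagged, not fatal: singular diattenuators
  ($D = 1$) return `NaN` parameters with `flag = "singular"`; all-zero
  pixels are masked by the transform; singular microscope-fingerprint
  pixels are masked and counted by `correct_microscope()`.
* Orientation averages use the doubled-angle circular mean
  (`circular_orientation_mean()`), immune to the $\pm 90°$ wrap; plain
  means are reported alongside for comparison with conventional tables.
* Report tables round half away from zero at the conventional printed
  precision (1 decimal for angles, 3 for dimensionless parameters).
* Seeds are explicit everywhere randomness occurs, and the helpers restore
  the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the full grids
($35 \times 36$ retarders for the closed-form sweep, 1000 random retarders
for recovery, 100 seeds for the layered Monte-Carlo) on 1-pixel-per-case
images, and use phantom images up to 64x64 pixels elsewhere; these sizes were
chosen so the whole suite exercises every code path in well under a minute
of compute while keeping Monte-Carlo standard errors far below the asserted
tolerances. The simulators default to 256x256 images, matching the
instrument description.

## Known limitations

* Coherency/Jones formalisms, physical-realizability filtering and
  symmetric/differential decompositions are out of scope.
* Single-frequency phasor only (the first harmonic carries the retarder
  signal; higher harmonics are not analyzed).
* The linear-channel merge (`merge_linear_phasors()`) is a de-rotation
  average defined in this package: each linear channel is rotated by twice
  its input azimuth before averaging. It is validated by its air invariant
  (all channels collapse to $(0.5, 0)$) and the half-wave invariant
  ($\varphi = 4\alpha$ survives), not against an external reference.
* Phasor-gated segmentation assumes clusters separate in $(g, s)$; heavily
  depolarized or mixed pixels migrate toward the origin and lose both
  contrast and orientation identifiability, as do weakly retarding pixels
  below the modulation floor.
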