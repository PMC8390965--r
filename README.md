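# mmphasor

Phasor analysis for Mueller-matrix (MM) optical scanning microscopy.

## The problem

MM microscopy is a label-free imaging modality: sixteen polarization-resolved
intensities per pixel determine the 4x4 Mueller matrix `M(x, y)` that maps any
illumination Stokes vector onto the output Stokes vector. For thin biological
tissue (collagen, myosin and other fibrillar structures) the dominant contrast
is linear birefringence, described by a retardance
`R = 360 Δn e / λ` (degrees) and a fast-axis orientation `α_R ∈ (−90°, 90°]`.

The classical way to extract `(R, α_R)` is the **Lu-Chipman polar
decomposition** `M = M_Δ · M_R · M_D` (depolarizer × retarder ×
diattenuator), which requires matrix inversions and an a-priori ordering of
the elementary optical components. This package implements, alongside that
reference estimator, a **model-free phasor readout**: the matrix is converted
to polarization-resolved intensities
`I_θ = (S0 + S1 cos 2θ + S2 sin 2θ)/2` for a virtual analyzer rotation
`θ ∈ {0°, 45°, 90°, 135°}`, and the normalized first Fourier coefficients

```
g = Σ I_θ cos(2πθ/Θ) / Σ I_θ ,   s = Σ I_θ sin(2πθ/Θ) / Σ I_θ ,   Θ = 180°
```

give a per-pixel phasor with modulation `M = √(g² + s²) ∈ [0, 0.5]` and phase
`φ = atan2(s, g)`. For a retarder the right-circular-input channel obeys
`M = sin(R)/2` and `φ = 90° + 2 α_R`, so

```
α_R = φ/2 − 45°,    R = arcsin(2M)  or  180° − arcsin(2M),
```

with the branch decided by whether the linear-input phasor falls inside the
circle of center (0.25, 0) and radius 0.25. Phasor histograms double as a
segmentation tool: pixel populations cluster in `(g, s)` space and can be
gated back onto the image (`phasor_gate_segment()`).

The package also provides a forward instrument simulator (PSG/PSA
projections, 16-channel stacks, per-element Gaussian noise at a measured air
level), synthetic phantoms with exact ground truth (film-on-air, layered
fiber stacks, rotated and striped fibers), float32 TIFF I/O with JSON
sidecars, ROI summary tables with circular orientation statistics, and a
small command line (`inst/cli/mmphasor.R`).

## Worked example

Simulate a noisy film-on-air phantom, push it through the full measurement
chain, and compare the two estimators per region:

```r
library(mmphasor)

ph    <- make_phantom(phantom_spec("film_on_air", size = c(64, 64), seed = 7))
stack <- simulate_measurement(ph$mueller)                  # 16 intensities/px
img   <- reconstruct_mueller(stack)                        # back to Mueller
field <- phasor_transform(polarization_stack_from_mueller(img))
pmap  <- phasor_parameter_images(field)                    # phasor (R, alpha)
lcmap <- lc_image(img)                                     # Lu-Chipman maps

film <- ph$truth$region == "film"
roi_summarize(list(R_phasor = pmap$R, alpha_phasor = pmap$alpha_R,
                   R_lc = lcmap$R, alpha_lc = lcmap$alpha_R, P_d = lcmap$P_d),
              list(film = film, air = !film))
```

```
    roi    parameter    n     mean       sd circ_mean
1  film     R_phasor 1024  55.9218  5.01028        NA
2  film alpha_phasor 1024 -84.6131 13.48661   -85.668
3  film         R_lc 1024  55.4997  1.19284        NA
4  film     alpha_lc 1024 -85.6957  0.68954   -85.696
5  film          P_d 1024   1.0004  0.01500        NA
6   air     R_phasor  423  96.4982 82.86666        NA
7   air alpha_phasor  423   1.5197 48.72218     3.506
8   air         R_lc 3072   1.9206  0.83776        NA
9   air     alpha_lc 3072   0.3439 50.85219    24.410
```

Both estimators recover the film ground truth (`R = 55.5°`,
`α_R = −85.7°`); the phasor estimate is noisier (it is exposed to
transmittance fluctuations, LC is not), which mirrors what one sees on real
film data. Over air, only the 423 of 3072 pixels whose modulation exceeds
the 0.05 noise floor get a (meaningless) phasor value — `NA` elsewhere —
while LC reports the expected air-level residuals (`R ≈ 1.9°`, `P_d ≈ 1`).

Single matrices work everywhere images do. The bundled experimental film
matrix decodes as:

```r
lc_decompose(reference_mm("film")$mean)
#> <lc_result> Lu-Chipman polar decomposition
#>   D = 0.0269   R = 51.07 deg   alpha_R = -84.41 deg   P_d = 1.0472
```

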