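---
title: "Multiscale anisotropy of grayscale images with the 2D WTMM method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale anisotropy of grayscale images with the 2D WTMM method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtmmaniso)
```

## The problem

Fibrillar collagen reorganizes in disease: around pancreatic tumors the
extracellular matrix is remodeled at some spatial scales while larger-scale
bundle organization is disrupted. Second harmonic generation (SHG) microscopy
images collagen label-free, and the question this package addresses is how to
turn such a grayscale image into a *scale-resolved* measurement of directional
organization — not a single alignment score, but anisotropy as a continuous
function of the size scale being interrogated, so that effects confined to
small fibers and effects on large bundles can be separated.

## The method

### Wavelet-gradient field

For an image $f$ and a scale $a > 0$ (pixels), the package computes the
continuous 2D wavelet transform with the two first-order partial derivatives
of an isotropic Gaussian as analyzing wavelets:

$$
\mathbf{T}_\psi[f](\mathbf{b}, a) =
\nabla\, \{ T_\phi[f](\mathbf{b}, a) \},
$$

the spatial gradient of the Gaussian-smoothed image, with the Gaussian's
standard deviation equal to $a$ (the package's scale convention; nothing
downstream distinguishes a separate bandwidth parameter). From the two
components $T_{\psi_1}$ (along $x$) and $T_{\psi_2}$ (along $y$) follow the
modulus and argument rasters

$$
M_\psi = \sqrt{T_{\psi_1}^2 + T_{\psi_2}^2}, \qquad
A_\psi = \mathrm{Arg}(T_{\psi_1} + i\, T_{\psi_2}) \in [-\pi, \pi).
$$

Under the L1 wavelet normalization the response carries a factor $a$ relative
to the plain smoothed gradient ($\mathbf{T} = a \nabla (G_a * f)$). Every
statistic the package reports is invariant to per-scale rescaling of the
modulus, so this factor is a fidelity convention, not a tunable.

The convolution is evaluated in the Fourier domain with periodic boundary
handling. Two numerical details matter: the isotropic $|k|^2$ used in the
Gaussian keeps the true Nyquist frequency (otherwise the Nyquist band leaks
through the smoothing), while the odd derivative factors $ik_x$, $ik_y$ are
zeroed at the unpaired Nyquist frequency so the inverse transform is exactly
real. Periodic wrap-around contaminates a border of width comparable to $a$;
that contamination is exactly what the central-crop analysis below measures.

### Modulus maxima and chains

At each scale, the wavelet transform modulus maxima (WTMM) are the pixels
where $M_\psi$ is locally maximal *along the gradient direction*: the modulus
must be $\ge$ the bilinearly interpolated modulus one pixel away on both sides
along $\pm(\cos A_\psi, \sin A_\psi)$, with strict inequality on at least one
side. The probe distance (1 pixel) and bilinear interpolation are the standard
Canny/Mallat choices; the mixed $\ge/>$ rule keeps a single-pixel ridge on a
discrete plateau while discarding exactly flat regions, and zero-modulus
pixels can never qualify. Off-raster probes wrap periodically, consistent with
the transform.

The retained points are organized into *maxima chains*: 8-connected
components tracing intensity edges. Chains may wrap across the periodic
boundary; a minimum-chain-length filter exists but is off by default, and no
modulus threshold is applied. Within a chain, the reported point ordering is
breadth-first traversal order — it is exported for plotting and carries no
meaning downstream.

### Angle PDFs and the anisotropy factor

The gradient angles of all WTMM points at one scale are binned into a
probability density $P_a(A)$ over $[-\pi, \pi)$ (full gradient direction, not
orientation modulo $\pi$: the isotropic reference is the flat density
$1/2\pi$ on the whole circle). Two binning policies are provided:

* **fixed** — a constant bin count (conventionally 64) at every scale;
* **variable** (default) — the bin count adapts so each bin holds a target
  number of samples (default 100): $N_\text{bins} = \max(N_\text{min},
  \lfloor n / 100 \rfloor)$, with floor $N_\text{min} = 4$.

Small scales produce tens of thousands of maxima and large scales a few
hundred; with fixed binning the per-bin counting noise therefore varies by
orders of magnitude across the ladder, inflating the anisotropy factor
exactly where maxima are scarce. Variable binning pins the per-bin noise
level, which is what makes the statistic comparable across scales. The floor
of 4 bins prevents degenerate 1–2 bin densities at the largest scales; it is
configurable. The binned unit is one angle per WTMM *point* by default; a
per-chain mode (one circular-mean angle per maxima chain) is available behind
`binning_policy(unit = "chain")` for sensitivity analysis, since either unit
is defensible.

Each scale is then summarized by the anisotropy factor, the area between the
angle PDF and the flat isotropic density:

$$
F_a = \sum_{i=0}^{N_\text{bins}-1}
\left| P_a(A_i) - \tfrac{1}{2\pi} \right| \Delta A,
\qquad \Delta A = \tfrac{2\pi}{N_\text{bins}},\; A_i = -\pi + i\,\Delta A .
$$

The sum runs over one term per bin: the bins tile $2\pi$ exactly, and an
extra term at $A = \pi \equiv -\pi$ would double-count a bin. $F_a = 0$ is
pure isotropy; the supremum is 2, approached by a density concentrated in a
single bin, which gives exactly $2(1 - 1/N_\text{bins})$. These two analytic
values anchor the test suite.

### Isotropy calibration and normalization

A finite discrete image of an isotropic random field does *not* give
$F_a = 0$: counting noise and grid discretization leave a positive floor that
depends on scale. The package therefore calibrates against synthetic
isotropic references generated by Fourier filtering:

* **white noise** — i.i.d. standard normal pixels (flat spectrum);
* **Brownian surfaces** — white spectral noise shaped by $|k|^{-(H+1)}$
  (power spectrum $|k|^{-(2H+2)}$), DC zeroed, inverse-transformed. The
  roughness exponent defaults to $H = 0.5$, the standard Brownian surface; it
  is exposed as a parameter because any value in $(0,1)$ gives a legitimate
  isotropic scale-invariant surface.

White noise is the preferred reference: across the ladder its median $F_a$
stays below the Brownian surface's and its curve is flatter over a longer
scale range, because a Brownian surface's long-range undulations read as
weak large-scale directionality on any finite realization. Anisotropy curves
of study images are normalized by the per-scale *median* white-noise $F_a$ as
a **ratio** (normalized $F_a = 1$ marks the isotropic baseline). A
subtraction mode is provided, but the ratio is the default since it makes the
baseline scale-free.

The **central-crop analysis** quantifies periodic-boundary edge effects: the
transform and detection run on a large image (e.g. 1024²) and only maxima in
the central 512² window enter the PDFs. If edge contamination were material,
crop curves would differ systematically from native-512² curves; on white
noise they agree within the replicate scatter (the suite checks the crop
median against the native median ± 3 MAD per scale). The per-scale
**coefficient of variation** (sample SD / mean across replicate curves)
compares binning policies; variable binning improves the CV at small scales
where it changes the bin count the most.

### Group comparison

Groups of images are summarized by per-scale median curves; missing scales
(no maxima, e.g. constant images) are encoded explicitly and excluded from
medians with a warning, never imputed. Two groups are compared scale by scale
with a two-sided Wilcoxon rank-sum test on per-image $F_a$: exact p-values
when the combined sample size is ≤ 30 with no ties, else the normal
approximation with continuity correction. Raw per-scale p-values are the
primary output (plotted against the 0.05 line); Benjamini–Hochberg
adjustment is available behind a flag, off by default, since the per-scale
track is read as a profile rather than a family of independent claims. Each
image is treated as one observation — when several images come from one
slide or subject this overstates independence, and the caveat transfers to
any real study design.

The **crossover scale** of two median curves is reported as the geometric
mean of the two ladder scales bracketing the first sign change of their
difference (an exact zero counts as a crossover at that ladder scale). This
sign-change rule is a package convention for reading off the scale where
group ordering reverses; it is deliberately simple and resolution-limited to
one ladder step.

## The scale ladder

The default ladder has 50 geometrically spaced scales from 7 to 210 px. At
the reference pixel size of 180/512 ≈ 0.352 μm (a 512² image spanning a
180 μm field of view) the endpoints are ≈ 2.46 μm and ≈ 73.8 μm, the window
over which SHG collagen structure is usually interrogated; 50 scales gives
roughly 10 scales per octave. Both the ladder and the pixel size are fully
configurable (`scale_ladder()`), and the largest scale must stay below half
the image side so the Gaussian fits the raster.

## What the synthetic generator does and does not emulate

The generator produces the calibration conditions — isotropic fields with
controlled spectra, plus oriented sinusoidal gratings as known-anisotropic
positive controls (orientation, wavelength and phase are parameters, so
ensembles of gratings at varied orientations probe rotation behavior). It
does **not** emulate SHG optics: no point-spread function, no Poisson photon
noise, no intensity saturation, no tissue-shaped spatial heterogeneity.
Passing calibration tests therefore demonstrates that the *statistic* behaves
correctly — isotropy floors, binning stability, edge robustness, positive
controls separating from noise — not that any particular biological contrast
will be detected in real tissue.

## Problem sizes and determinism

The test suite runs the calibration comparisons at 30 images per reference
type (512², full 50-scale ladder) and 20 replicates for the edge-effect and
group-separation checks on a 12-scale sub-ladder spanning the same 7–210 px
range — ensemble sizes at which the medians and CVs are stable in replicate
reruns, chosen as the package's study conditions. Every generator call is
seeded through its `FieldSpec`, generation restores the caller's RNG state,
and the analysis pipeline itself contains no randomness, so identical
configurations yield byte-identical outputs (the pipeline writes its seed and
configuration into `manifest.json`, and re-running from that manifest
reproduces the run).

## Known limitations

* **Top-of-ladder degeneracy.** When $\sigma = a$ approaches a sizable
  fraction of the image side (beyond roughly $0.3\times$), the periodically
  smoothed field is dominated by its few lowest Fourier modes, so *any*
  finite realization — including isotropic references — shows strong apparent
  anisotropy ($F_a$ near or above 1), and the ordering between reference
  types is no longer controlled by their spectra. In the 30-image
  calibration ensembles the white-noise median sits below the Brownian
  median over the lower ~40 of the 50 default ladder scales but not at the
  largest ones. Conclusions drawn above ~30% of the image side should be
  treated as unreliable; analyze a larger field and crop if that range
  matters.
* **Fixtures are scale-bounded.** A monochromatic grating carries anisotropy
  only near its own wavelength: at $\sigma \gg \lambda$ its wavelet response
  is attenuated by $e^{-\sigma^2 k^2/2}$ into floating-point noise, so a
  positive control must be probed at scales commensurate with its structure
  (broadband anisotropic fixtures would be needed to exercise the whole
  ladder at once).
* Periodic (FFT-native) boundary handling is the only mode; for images whose
  opposite edges differ strongly, use the central-crop workflow or mirror-pad
  upstream.
* Square, single-channel rasters only; non-square inputs are rejected rather
  than padded.
* Angles use the full gradient direction; a texture symmetric under intensity
  inversion contributes mass at $A$ and $A + \pi$ separately, which is
  intended (the flat reference lives on the full circle) but differs from
  orientation-only (mod $\pi$) conventions in fiber-tracing tools.
* No scale-space linking of maxima across scales (no WTMM skeleton or
  multifractal partition functions): each scale is analyzed independently.
* TIFF/PNG output stores fields affinely rescaled to the unit interval
  (32-bit float for TIFF); the analysis is affine-invariant, but absolute
  intensities are not preserved on disk.
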