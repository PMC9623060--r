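# wtmmaniso

Multiscale anisotropy of grayscale images via the 2D Wavelet Transform
Modulus Maxima (WTMM) method.

## What this is for

Fibrillar structures — the motivating case is collagen in second harmonic
generation (SHG) microscopy of pancreatic tissue — can be organized at some
size scales and disorganized at others: disease may align small fibers while
disrupting large bundles. This package measures directional organization as a
*continuous function of size scale* rather than as a single alignment score,
so such scale-dependent effects (including crossovers, where the ordering of
two tissue groups reverses at a particular scale) are visible.

Users are image analysts working with square single-channel TIFF/PNG rasters
(the reference configuration is 512 × 512 pixels over a 180 μm field of view,
0.3516 μm/pixel); everything also runs dimensionless in pixel units.

## The method

At each scale `a` of a geometric ladder, the image is convolved with the two
first-order partial derivatives of an isotropic 2D Gaussian (standard
deviation `a` pixels), giving a wavelet-gradient field with modulus and
argument

```
M(b, a) = sqrt(T1^2 + T2^2),    A(b, a) = Arg(T1 + i T2) ∈ [-π, π).
```

The **WTMM** are the pixels where `M` is locally maximal along the gradient
direction `A` (bilinear probes one pixel away on both sides); they organize
into 8-connected **maxima chains** tracing intensity edges. The gradient
angles of all maxima at one scale are binned into a probability density
`P_a(A)` over `[-π, π)`, and each scale is summarized by the **anisotropy
factor**, the area between that density and the flat isotropic density:

```
Fa(a) = Σ_i |P_a(A_i) − 1/(2π)| ΔA,     ΔA = 2π / N_bins .
```

`Fa = 0` is pure isotropy; the supremum is 2 (a single-bin density gives
exactly `2(1 − 1/N_bins)`).

Two refinements make `Fa` comparable across scales and images:

* **Variable binning** (default): the bin count per scale adapts so each bin
  holds ~100 samples, pinning the per-bin counting noise that otherwise
  varies by orders of magnitude between maxima-rich small scales and sparse
  large scales.
* **White-noise normalization**: discrete isotropic fields have a positive,
  scale-dependent `Fa` floor. Curves are divided by the per-scale median
  `Fa` of a generated white-noise ensemble, so 1 marks the isotropic
  baseline. (Brownian surfaces, the other classical isotropic reference, are
  also provided; white noise sits lower and flatter over most of the ladder.)

Groups of images are compared per scale with two-sided Wilcoxon rank-sum
tests on per-image `Fa`.

## Worked example

Positive control: a sinusoidal grating at 30°, wavelength 16 px, analyzed
over six scales against a small white-noise reference ensemble.

```r
library(wtmmaniso)

grating <- generate_field(field_spec(512, "oriented_stripes",
                                     orientation_deg = 30, wavelength = 16,
                                     seed = 1, pixel_size_um = 180 / 512))
ladder <- scale_ladder(7, 42, 6, pixel_size_um = 180 / 512)
policy <- binning_policy("variable", samples_per_bin = 100)

curve <- multiscale_curve(grating, ladder, policy, image_id = "grating_30deg")
reference <- median_curve(lapply(1:5, function(s) multiscale_curve(
  generate_field(field_spec(512, "white_noise", seed = s)), ladder, policy)))
curve$fa_normalized <- normalize_by_reference(curve, reference)$fa
```

Output:

```
  scale scale_um    fa n_maxima n_bins fa_normalized
  7.000    2.461 1.874    36960    369          16.4
 10.017    3.522 1.821    35232    352          14.3
 14.334    5.039 1.787    31328    313          10.4
 20.511    7.211 1.642    25249    252           8.0
 29.351   10.319 1.502    18539    185           6.0
 42.000   14.766 0.890     8162     81           2.3
```

At small scales the grating's raw `Fa` approaches the supremum 2 (gradient
angles concentrate perpendicular to the stripes) and sits 6–16× above the
isotropic baseline; as the smoothing scale grows toward and past the
16-pixel wavelength the grating is progressively averaged away and both
columns fall. `n_bins` tracks `n_maxima`/100 — that is the variable binning.

For batch work, `run_pipeline(run_config(...))` (or the
`inst/cli/wtmm-aniso.R` script with a YAML config) analyzes labelled image
groups or synthetic ensembles end to end and writes per-image curves, group
medians, per-scale rank-sum p-value tracks, the white-noise reference table,
and a JSON manifest that reproduces the run.

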