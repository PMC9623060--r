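#' Histogram binning policy for gradient-angle PDFs
#'
#' Two conventions for binning WTMM angles into a probability density over
#' `[-pi, pi)`:
#'
#' * `fixed`: a constant number of bins (`n_bins`, conventionally 64) at every
#'   scale, regardless of how many maxima the scale produced.
#' * `variable`: the bin count adapts to the sample size so each bin holds a
#'   target number of samples (`samples_per_bin`, default 100):
#'   `n_bins = max(min_bins, floor(n / samples_per_bin))`. This stabilizes the
#'   per-bin counting noise that otherwise inflates the anisotropy factor at
#'   small scales, where maxima are plentiful, and deflates statistical power
#'   at large scales, where they are scarce.
#'
#' @param mode `"variable"` (default) or `"fixed"`.
#' @param n_bins Bin count in fixed mode (default 64).
#' @param samples_per_bin Target samples per bin in variable mode (default 100).
#' @param min_bins Lower clamp on the variable-mode bin count (default 4);
#'   prevents degenerate 1-2 bin densities at the largest scales.
#' @param unit What the binned sample is: `"point"` (one angle per WTMM point,
#'   default) or `"chain"` (the circular mean angle of each maxima chain).
#' @return An object of class `binning_policy`.
#' @export
binning_policy <- function(mode = c("variable", "fixed"), n_bins = 64L,
                           samples_per_bin = 100L, min_bins = 4L,
                           unit = c("point", "chain")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (n_bins < 2) stop("`n_bins` must be at least 2")
  if (samples_per_bin < 1) stop("`samples_per_bin` must be at least 1")
  if (min_bins < 2) stop("`min_bins` must be at least 2")
  structure(list(mode = mode, n_bins = as.integer(n_bins),
                 samples_per_bin = as.integer(samples_per_bin),
                 min_bins = as.integer(min_bins), unit = unit),
            class = "binning_policy")
}

resolve_n_bins <- function(n_samples, policy) {
  if (policy$mode == "fixed") policy$n_bins
  else max(policy$min_bins, as.integer(n_samples %/% policy$samples_per_bin))
}

#' Bin gradient angles into a probability density function
#'
#' Histograms the angles over `n_bins` equal bins tiling `[-pi, pi)` exactly
#' (each bin half-open on the right) and normalizes counts to a density:
#' `density_i = count_i / (n_samples * bin_width)`, so the densities integrate
#' to 1 over the circle.
#'
#' @param angles Numeric vector of angles in `[-pi, pi)`.
#' @param policy A [binning_policy()].
#' @param scale Optional scale annotation (pixels) carried on the result.
#' @return An object of class `angle_pdf`: list with `scale`, `n_bins`,
#'   `bin_width`, `left_edges`, `density`, `n_samples`.
#' @export
build_angle_pdf <- function(angles, policy = binning_policy(),
                            scale = NA_real_) {
  if (length(angles) == 0)
    stop(errorCondition("no maxima: cannot build an angle PDF from zero angles",
                        class = c("wtmm_no_maxima", "error")))
  if (any(!is.finite(angles)) || any(angles < -pi) || any(angles >= pi))
    stop("angles must be finite and lie in [-pi, pi)")
  nb <- resolve_n_bins(length(angles), policy)
  dA <- 2 * pi / nb
  idx <- pmin(as.integer(floor((angles + pi) / dA)) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(scale = scale, n_bins = nb, bin_width = dA,
                 left_edges = -pi + dA * (seq_len(nb) - 1),
                 density = counts / (length(angles) * dA),
                 n_samples = length(angles)),
            class = "angle_pdf")
}

#' Anisotropy factor of an angle PDF
#'
#' The area between the angle density and the flat isotropic density
#' `1/(2*pi)`:
#' `Fa = sum_i |P(A_i) - 1/(2*pi)| * bin_width`, one term per bin.
#' `Fa = 0` for a perfectly flat (isotropic) density; the supremum is 2,
#' approached by a density concentrated in a single bin, which gives exactly
#' `2 * (1 - 1/n_bins)`.
#'
#' @param pdf An [build_angle_pdf()] result.
#' @return Dimensionless anisotropy factor in `[0, 2)`.
#' @export
anisotropy_factor <- function(pdf) {
  stopifnot(inherits(pdf, "angle_pdf"))
  sum(abs(pdf$density - 1 / (2 * pi))) * pdf$bin_width
}

#' Per-scale WTMM angle sets of an image
#'
#' The shared engine behind [multiscale_curve()] and [central_crop_curve()]:
#' one forward FFT of the image, then for each ladder scale the
#' Gaussian-derivative transform, WTMM detection, optional restriction to a
#' centered crop window, and optional reduction of points to per-chain
#' circular mean angles. Exposed so that one expensive transform pass can be
#' re-binned under several policies.
#'
#' @param image A [scalar_field()].
#' @param ladder A [scale_ladder()]; its largest scale must not exceed half
#'   the image side.
#' @param crop Optional side (pixels) of a centered square window; only WTMM
#'   points inside the window are kept (chains straddling it are truncated).
#' @param unit `"point"` or `"chain"` (see [binning_policy()]).
#' @return List with one element per scale, each a list `(scale, angles,
#'   n_points)`.
#' @export
multiscale_angles <- function(image, ladder, crop = NULL,
                              unit = c("point", "chain")) {
  stopifnot(inherits(image, "scalar_field"), inherits(ladder, "scale_ladder"))
  unit <- match.arg(unit)
  n <- nrow(image$values)
  if (max(ladder$scales) > n / 2)
    stop("largest ladder scale exceeds half the image side")
  lo <- hi <- NULL
  if (!is.null(crop)) {
    if (crop >= n) stop("`crop` must be smaller than the image side")
    lo <- (n - crop) %/% 2 + 1L
    hi <- lo + as.integer(crop) - 1L
  }
  fhat <- stats::fft(image$values)
  lapply(ladder$scales, function(a) {
    field <- gaussian_derivative_transform(image, a, fhat = fhat)
    pts <- detect_wtmm(field)
    if (!is.null(crop))
      pts <- pts[pts$row >= lo & pts$row <= hi &
                 pts$col >= lo & pts$col <= hi, , drop = FALSE]
    angles <- if (unit == "chain" && nrow(pts) > 0) {
      attr(pts, "side") <- n
      attr(pts, "scale") <- a
      chain_mean_angles(chain_maxima(pts, side = n))
    } else {
      pts$angle
    }
    list(scale = a, angles = angles, n_points = nrow(pts))
  })
}

curve_row <- function(scale, scale_um, angles, policy) {
  if (length(angles) == 0) {
    data.frame(scale = scale, scale_um = scale_um, fa = NA_real_,
               n_samples = 0L, n_bins = NA_integer_)
  } else {
    pdf <- build_angle_pdf(angles, policy, scale = scale)
    data.frame(scale = scale, scale_um = scale_um,
               fa = anisotropy_factor(pdf),
               n_samples = pdf$n_samples, n_bins = pdf$n_bins)
  }
}

#' Build an anisotropy curve from precomputed angle sets
#'
#' Bins the output of [multiscale_angles()] under a policy. Lets one
#' expensive transform pass be re-binned under several policies, e.g. to
#' compare fixed and variable binning on the same maxima.
#'
#' @param angle_sets Result of [multiscale_angles()].
#' @param ladder The [scale_ladder()] the angle sets were computed on.
#' @param policy A [binning_policy()].
#' @param image_id Identifier recorded on the curve.
#' @return An `anisotropy_curve` (see [multiscale_curve()]).
#' @export
curve_from_angles <- function(angle_sets, ladder, policy, image_id = "image") {
  rows <- do.call(rbind, Map(function(s, su, a) curve_row(s, su, a$angles, policy),
                             ladder$scales, ladder$scales_um, angle_sets))
  if (anyNA(rows$fa))
    warning("no maxima at ", sum(is.na(rows$fa)), " scale(s) of '", image_id,
            "'; those scales carry fa = NA")
  structure(rows, image_id = image_id, policy = policy, ladder = ladder,
            class = c("anisotropy_curve", "data.frame"))
}

#' Multiscale anisotropy curve of an image
#'
#' Runs the full per-image pipeline: wavelet transform, WTMM detection and
#' angle binning at every ladder scale, yielding the anisotropy factor as a
#' function of scale. Scales at which no maxima exist (e.g. a constant image)
#' are reported with `fa = NA` and a warning, never dropped silently.
#'
#' @param image A [scalar_field()].
#' @param ladder A [scale_ladder()].
#' @param policy A [binning_policy()].
#' @param image_id Identifier recorded on the curve.
#' @return A data frame of class `anisotropy_curve` with columns `scale`,
#'   `scale_um`, `fa`, `n_samples`, `n_bins`; attributes `image_id`, `policy`,
#'   `ladder`.
#' @export
multiscale_curve <- function(image, ladder, policy = binning_policy(),
                             image_id = "image") {
  sets <- multiscale_angles(image, ladder, unit = policy$unit)
  curve_from_angles(sets, ladder, policy, image_id)
}

#' Edge-robust anisotropy curve from a central crop
#'
#' Computes the wavelet transform and WTMM detection on the full (large)
#' image, then keeps only the maxima falling in a centered `crop x crop`
#' window before building the angle PDFs. Because the periodic convolution
#' contaminates a border of width comparable to the scale, analyzing the
#' center of a larger field isolates the edge effect: curves from crops
#' should match curves from native images of the crop size.
#'
#' @param large_image A [scalar_field()] larger than `crop`.
#' @param ladder,policy As in [multiscale_curve()].
#' @param crop Window side in pixels, `< side(large_image)`.
#' @param image_id Identifier recorded on the curve.
#' @return An `anisotropy_curve`.
#' @export
central_crop_curve <- function(large_image, ladder, policy = binning_policy(),
                               crop, image_id = "image") {
  sets <- multiscale_angles(large_image, ladder, crop = crop,
                            unit = policy$unit)
  curve_from_angles(sets, ladder, policy, image_id)
}

common_ladder_scales <- function(curves) {
  s <- curves[[1]]$scale
  for (cv in curves[-1])
    if (length(cv$scale) != length(s) || any(abs(cv$scale - s) > 1e-9))
      stop("curves are not on a common scale ladder")
  s
}

#' Per-scale coefficient of variation across curves
#'
#' `CV = sd / mean` of the anisotropy factor across a set of curves on a
#' common ladder (sample standard deviation). Used to compare the stability of
#' binning policies on replicated isotropic reference images.
#'
#' @param curves List of `anisotropy_curve`s on one ladder (>= 3).
#' @return Data frame with columns `scale`, `scale_um`, `cv`, `n` (curves with
#'   a defined Fa at that scale).
#' @export
coefficient_of_variation <- function(curves) {
  if (length(curves) < 3) stop("need at least 3 curves")
  s <- common_ladder_scales(curves)
  fa <- matrix(sapply(curves, function(cv) cv$fa), nrow = length(s))
  data.frame(scale = s, scale_um = curves[[1]]$scale_um,
             cv = apply(fa, 1, function(v) {
               v <- v[!is.na(v)]
               if (length(v) < 2) NA_real_ else stats::sd(v) / mean(v)
             }),
             n = apply(fa, 1, function(v) sum(!is.na(v))))
}

#' Normalize an anisotropy curve by an isotropic reference
#'
#' Divides the curve's per-scale Fa by a reference Fa (typically the per-scale
#' median over a white-noise ensemble), so 1 marks the isotropic baseline.
#' A subtraction mode (`fa - reference`) is available; the ratio is the
#' default convention.
#'
#' @param curve An `anisotropy_curve`.
#' @param reference Numeric vector of reference Fa values, one per ladder
#'   scale, or a data frame with columns `scale` and `median_fa` (as returned
#'   by [median_curve()]).
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return An `anisotropy_curve` whose `fa` column holds the normalized
#'   values; attribute `normalized` records the mode.
#' @export
normalize_by_reference <- function(curve, reference,
                                   mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "anisotropy_curve"))
  if (is.data.frame(reference)) {
    if (length(reference$scale) != length(curve$scale) ||
        any(abs(reference$scale - curve$scale) > 1e-9))
      stop("reference is not on the curve's ladder")
    reference <- reference$median_fa
  }
  if (length(reference) != nrow(curve))
    stop("reference length does not match the number of ladder scales")
  if (mode == "ratio" && any(!is.na(reference) & reference == 0))
    stop("reference Fa is 0 at some scale; cannot normalize by ratio")
  out <- curve
  out$fa <- if (mode == "ratio") curve$fa / reference else curve$fa - reference
  attr(out, "normalized") <- mode
  out
}
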