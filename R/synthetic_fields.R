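#' Scalar field: a square grayscale intensity raster
#'
#' Light container for the images the anisotropy pipeline operates on: a
#' square matrix of finite intensities plus an optional physical pixel size.
#'
#' @param values Square numeric matrix of intensities. Rows index y (downward),
#'   columns index x (rightward).
#' @param pixel_size_um Physical pixel spacing in micrometers, or `NA` for
#'   dimensionless analysis.
#' @return An object of class `scalar_field` with elements `values` and
#'   `pixel_size_um`.
#' @export
scalar_field <- function(values, pixel_size_um = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("scalar fields must be square; got ", nrow(values), " x ", ncol(values))
  if (!all(is.finite(values)))
    stop("scalar field contains non-finite values")
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<scalar_field %d x %d, pixel size %s um>\n", n, n,
              ifelse(is.na(x$pixel_size_um), "unset",
                     format(x$pixel_size_um, digits = 4))))
  invisible(x)
}

#' Specification of a synthetic calibration field
#'
#' Describes a reproducible synthetic image: isotropic references (white
#' noise, fractional Brownian surfaces) used to calibrate the anisotropy
#' factor, or an oriented sinusoidal grating used as a known-anisotropic
#' positive control. An identical spec (including `seed`) always generates a
#' bit-identical field.
#'
#' @param side_length Image side in pixels; must be a power of two, at least 64.
#' @param kind One of `"white_noise"`, `"brownian_surface"`,
#'   `"oriented_stripes"`.
#' @param hurst Roughness (Hurst) exponent in (0, 1); Brownian surfaces only.
#'   Default 0.5, the standard Brownian surface.
#' @param orientation_deg Stripe orientation in degrees; oriented stripes only.
#'   0 degrees gives stripes constant along rows (wave vector along +y).
#' @param wavelength Stripe wavelength in pixels (>= 4); oriented stripes only.
#' @param seed Integer RNG seed.
#' @param pixel_size_um Optional physical pixel size recorded on the output.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(side_length, kind = c("white_noise", "brownian_surface",
                                             "oriented_stripes"),
                       hurst = 0.5, orientation_deg = 0, wavelength = 16,
                       seed = 1L, pixel_size_um = NA_real_) {
  kind <- match.arg(kind)
  side_length <- as.integer(side_length)
  if (side_length < 64 || bitwAnd(side_length, side_length - 1L) != 0L)
    stop("`side_length` must be a power of two >= 64")
  if (kind == "brownian_surface" && (!is.finite(hurst) || hurst <= 0 || hurst >= 1))
    stop("`hurst` must lie in (0, 1)")
  if (kind == "oriented_stripes" && wavelength < 4)
    stop("`wavelength` must be at least 4 pixels")
  structure(list(side_length = side_length, kind = kind, hurst = hurst,
                 orientation_deg = orientation_deg, wavelength = wavelength,
                 seed = as.integer(seed), pixel_size_um = pixel_size_um),
            class = "field_spec")
}

# Run expr under a local RNG seed, restoring the caller's RNG state.
with_field_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic field from its specification
#'
#' Dispatches on `spec$kind`. See [generate_white_noise()],
#' [generate_brownian_surface()] and [generate_oriented_stripes()].
#'
#' @param spec A [field_spec()].
#' @return A [scalar_field()].
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  switch(spec$kind,
         white_noise       = generate_white_noise(spec),
         brownian_surface  = generate_brownian_surface(spec),
         oriented_stripes  = generate_oriented_stripes(spec))
}

#' Generate a white-noise calibration image
#'
#' Pixels are independent standard normal draws, i.e. a flat-power-spectrum
#' field. White noise is the isotropic reference of choice for normalizing
#' anisotropy curves: its intensity gradients point in random directions at
#' every scale.
#'
#' @param spec A [field_spec()] with `kind = "white_noise"`.
#' @return A [scalar_field()].
#' @export
generate_white_noise <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  if (spec$kind != "white_noise")
    stop("spec kind is '", spec$kind, "', expected 'white_noise'")
  n <- spec$side_length
  values <- with_field_seed(spec$seed, matrix(stats::rnorm(n * n), n, n))
  scalar_field(values, spec$pixel_size_um)
}

#' Generate a fractional Brownian surface by Fourier filtering
#'
#' Shapes white spectral noise with a power-law amplitude `|k|^-(H+1)` (power
#' spectrum `|k|^-(2H+2)`), zeroes the DC coefficient, and inverse-transforms.
#' The spectral noise is the Fourier transform of a real Gaussian field, hence
#' Hermitian-symmetric, and the inverse transform is exactly real. The result
#' is an isotropic, scale-invariant rough surface; `hurst = 0.5` gives the
#' standard Brownian surface.
#'
#' @param spec A [field_spec()] with `kind = "brownian_surface"` and
#'   `hurst` in (0, 1).
#' @return A [scalar_field()].
#' @export
generate_brownian_surface <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  if (spec$kind != "brownian_surface")
    stop("spec kind is '", spec$kind, "', expected 'brownian_surface'")
  if (!is.finite(spec$hurst) || spec$hurst <= 0 || spec$hurst >= 1)
    stop("`hurst` must lie in (0, 1)")
  n <- spec$side_length
  w <- with_field_seed(spec$seed, matrix(stats::rnorm(n * n), n, n))
  what <- stats::fft(w)
  k <- fft_freq(n)                      # angular frequency per axis
  kmag <- sqrt(outer(k^2, k^2, `+`))
  amp <- matrix(0, n, n)
  nz <- kmag > 0
  amp[nz] <- kmag[nz]^(-(spec$hurst + 1))   # DC stays zero: no mean divergence
  values <- Re(stats::fft(what * amp, inverse = TRUE)) / (n * n)
  scalar_field(values, spec$pixel_size_um)
}

#' Generate an oriented sinusoidal grating
#'
#' A known-anisotropic positive-control fixture: a sinusoid whose wave vector
#' makes angle `orientation_deg` with the +y (row) axis, so 0 degrees gives
#' stripes constant along each row and periodic down the columns. The phase is
#' drawn from `seed`, so replicates with different seeds are shifted copies.
#'
#' @param spec A [field_spec()] with `kind = "oriented_stripes"` and
#'   `wavelength >= 4`.
#' @return A [scalar_field()].
#' @export
generate_oriented_stripes <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  if (spec$kind != "oriented_stripes")
    stop("spec kind is '", spec$kind, "', expected 'oriented_stripes'")
  if (spec$wavelength < 4)
    stop("`wavelength` must be at least 4 pixels")
  n <- spec$side_length
  phase <- with_field_seed(spec$seed, stats::runif(1, 0, 2 * pi))
  theta <- spec$orientation_deg * pi / 180
  x <- matrix(rep(0:(n - 1), each = n), n, n)   # column index
  y <- matrix(rep(0:(n - 1), times = n), n, n)  # row index
  u <- x * sin(theta) + y * cos(theta)
  values <- sin(2 * pi * u / spec$wavelength + phase)
  scalar_field(values, spec$pixel_size_um)
}
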