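#' Geometric ladder of wavelet scales
#'
#' Builds the discrete set of dilation scales `a` (in pixels) at which the
#' wavelet transform is evaluated, log-uniformly spaced from `min_scale` to
#' `max_scale` inclusive. When a physical pixel size is supplied the ladder
#' also carries scales in micrometers for reporting.
#'
#' @param min_scale,max_scale Scale range in pixels; `1 <= min_scale <
#'   max_scale`.
#' @param n_scales Number of scales (>= 2), endpoints included.
#' @param pixel_size_um Optional micrometers per pixel.
#' @return An object of class `scale_ladder` with elements `scales` (pixels),
#'   `scales_um` (or `NA`) and `pixel_size_um`.
#' @examples
#' scale_ladder(2, 8, 3)$scales  # 2 4 8
#' @export
scale_ladder <- function(min_scale, max_scale, n_scales,
                         pixel_size_um = NA_real_) {
  if (!is.finite(min_scale) || !is.finite(max_scale) ||
      min_scale < 1 || min_scale >= max_scale)
    stop("need 1 <= min_scale < max_scale")
  if (n_scales < 2) stop("`n_scales` must be at least 2")
  scales <- exp(seq(log(min_scale), log(max_scale), length.out = n_scales))
  scales[1] <- min_scale
  scales[n_scales] <- max_scale
  structure(list(scales = scales,
                 scales_um = scales * as.numeric(pixel_size_um),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "scale_ladder")
}

#' Default analysis ladder
#'
#' 50 geometric scales from 7 to 210 pixels. At the package's reference pixel
#' size of 180/512 um/px (a 512 x 512 image spanning a 180 um field of view)
#' the endpoints sit at about 2.46 um and 73.8 um, the window over which SHG
#' collagen images are typically analyzed with this method.
#'
#' @param pixel_size_um Micrometers per pixel; default `180/512`.
#' @param n_scales Number of scales; default 50.
#' @return A [scale_ladder()].
#' @export
default_ladder <- function(pixel_size_um = 180 / 512, n_scales = 50) {
  scale_ladder(7, 210, n_scales, pixel_size_um = pixel_size_um)
}

# Angular DFT frequencies for side n (even), in radians per pixel.
fft_freq <- function(n) {
  i <- 0:(n - 1)
  2 * pi * ifelse(i <= n / 2, i, i - n) / n
}

# Per-size cache of the spectral grids used by the transform.
spectral_grids <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- fft_freq(n)
    kx <- matrix(rep(k, each = n), n, n)   # x = column index
    ky <- matrix(rep(k, times = n), n, n)  # y = row index
    k2 <- kx^2 + ky^2
    if (n %% 2 == 0) {
      # zero the odd (derivative) filter at the unpaired Nyquist frequency so
      # the inverse transform of i*k*G is exactly real; the isotropic k2 used
      # for the Gaussian keeps the true Nyquist frequency
      kx[, n / 2 + 1] <- 0
      ky[n / 2 + 1, ] <- 0
    }
    g <- list(kx = kx, ky = ky, k2 = k2)
    cache[[key]] <- g
    g
  }
})

#' Gaussian-derivative wavelet transform at one scale
#'
#' Convolves the image with the two first-order partial derivatives of an
#' isotropic 2D Gaussian dilated to scale `a` (the Gaussian's standard
#' deviation equals `a` pixels), which equals the spatial gradient of the
#' Gaussian-smoothed image times `a` under the L1 wavelet normalization. The
#' convolution is computed in the Fourier domain with periodic boundary
#' handling; edge contamination from the wrap is what the central-crop
#' analysis ([central_crop_curve()]) quantifies.
#'
#' The modulus raster is `sqrt(tx^2 + ty^2)` and the argument raster is the
#' angle of `(tx, ty)` in `[-pi, pi)`, measured from the +x (column) axis
#' toward +y (downward rows).
#'
#' @param image A [scalar_field()].
#' @param scale Wavelet scale `a` in pixels; must not exceed `side/2`.
#' @param fhat Optional precomputed `stats::fft(image$values)`, so a scale
#'   ladder can reuse one forward transform.
#' @return An object of class `gradient_field`: list with `scale`, `tx`, `ty`,
#'   `modulus`, `argument`.
#' @export
gaussian_derivative_transform <- function(image, scale, fhat = NULL) {
  stopifnot(inherits(image, "scalar_field"))
  n <- nrow(image$values)
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be positive")
  if (scale > n / 2)
    stop("scale ", scale, " exceeds half the image side (", n, ")")
  if (is.null(fhat)) fhat <- stats::fft(image$values)
  g <- spectral_grids(n)
  smooth <- exp(-scale^2 * g$k2 / 2)
  nn <- n * n
  tx <- scale * Re(stats::fft(fhat * (1i * g$kx) * smooth, inverse = TRUE)) / nn
  ty <- scale * Re(stats::fft(fhat * (1i * g$ky) * smooth, inverse = TRUE)) / nn
  modulus <- sqrt(tx^2 + ty^2)
  argument <- atan2(ty, tx)
  argument[argument >= pi] <- -pi
  structure(list(scale = scale, tx = tx, ty = ty,
                 modulus = modulus, argument = argument),
            class = "gradient_field")
}
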