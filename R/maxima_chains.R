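#' Detect wavelet transform modulus maxima (WTMM)
#'
#' A pixel is a WTMM point at scale `a` when its modulus is positive and
#' locally maximal along the gradient direction: it must be `>=` the
#' bilinearly interpolated modulus one pixel away on both sides along the
#' argument direction, with strict inequality on at least one side. Probes
#' that fall off the raster wrap periodically, matching the transform's
#' boundary handling.
#'
#' @param field A `gradient_field` from [gaussian_derivative_transform()].
#' @return A data frame of class `wtmm_points` with columns `row`, `col`
#'   (1-based pixel coordinates), `modulus` and `angle` (radians in
#'   `[-pi, pi)`), carrying attributes `scale` and `side`. An empty frame
#'   (e.g. for a constant image) is a valid result.
#' @export
detect_wtmm <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  keep <- wtmm_detect_cpp(field$modulus, field$argument)
  idx <- which(keep)
  n <- nrow(field$modulus)
  pts <- data.frame(row = ((idx - 1L) %% n) + 1L,
                    col = ((idx - 1L) %/% n) + 1L,
                    modulus = field$modulus[idx],
                    angle = field$argument[idx])
  structure(pts, scale = field$scale, side = n,
            class = c("wtmm_points", "data.frame"))
}

#' Organize WTMM points into edge-detection maxima chains
#'
#' Partitions the detected points of one scale into 8-connected components,
#' the "maxima chains" tracing intensity edges. Within a chain, points are
#' ordered by breadth-first traversal; the ordering is reported for export
#' and plotting but carries no meaning downstream. By default chains may wrap
#' across the periodic image boundary, consistent with the transform.
#'
#' @param points A `wtmm_points` frame from [detect_wtmm()].
#' @param side Raster side in pixels; defaults to the frame's `side` attribute.
#' @param wrap Join chains across the periodic boundary (default `TRUE`).
#' @param min_length Drop chains with fewer points than this (default 1, i.e.
#'   no filtering).
#' @return A data frame of class `maxima_chains` with columns `chain_id`,
#'   `order`, `row`, `col`, `modulus`, `angle`; attribute `n_chains`.
#' @export
chain_maxima <- function(points, side = attr(points, "side"), wrap = TRUE,
                         min_length = 1L) {
  stopifnot(is.data.frame(points))
  scale <- attr(points, "scale")
  if (nrow(points) == 0) {
    out <- data.frame(chain_id = integer(), order = integer(),
                      row = integer(), col = integer(),
                      modulus = numeric(), angle = numeric())
    return(structure(out, scale = scale, n_chains = 0L,
                     class = c("maxima_chains", "data.frame")))
  }
  if (is.null(side)) side <- max(points$row, points$col)
  mask <- matrix(FALSE, side, side)
  mask[cbind(points$row, points$col)] <- TRUE
  lab <- label_chains_cpp(mask, wrap)
  ord_row <- ((lab$idx - 1L) %% side) + 1L
  ord_col <- ((lab$idx - 1L) %/% side) + 1L
  # map each visited pixel back to its point record
  key_pts <- paste(points$row, points$col)
  key_ord <- paste(ord_row, ord_col)
  m <- match(key_ord, key_pts)
  out <- data.frame(chain_id = lab$chain,
                    order = stats::ave(lab$chain, lab$chain,
                                       FUN = seq_along),
                    row = ord_row, col = ord_col,
                    modulus = points$modulus[m], angle = points$angle[m])
  if (min_length > 1L) {
    sizes <- table(out$chain_id)
    keep_ids <- as.integer(names(sizes)[sizes >= min_length])
    out <- out[out$chain_id %in% keep_ids, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, scale = scale,
            n_chains = length(unique(out$chain_id)),
            class = c("maxima_chains", "data.frame"))
}

# Circular mean angle of each chain (used by the per-chain binning mode).
chain_mean_angles <- function(chains) {
  if (nrow(chains) == 0) return(numeric())
  s <- tapply(sin(chains$angle), chains$chain_id, mean)
  c_ <- tapply(cos(chains$angle), chains$chain_id, mean)
  a <- atan2(as.numeric(s), as.numeric(c_))
  a[a >= pi] <- -pi
  a
}
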