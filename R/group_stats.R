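#' Bundle anisotropy curves into a labelled group
#'
#' @param label Group label (e.g. `"cancer"`, `"white_noise"`).
#' @param curves Non-empty list of `anisotropy_curve`s on a common ladder.
#' @return An object of class `group_curves`.
#' @export
group_curves <- function(label, curves) {
  if (length(curves) < 1) stop("a group needs at least one curve")
  lapply(curves, function(cv) stopifnot(inherits(cv, "anisotropy_curve")))
  common_ladder_scales(curves)
  structure(list(label = label, curves = curves), class = "group_curves")
}

#' Per-scale median anisotropy curve of a group
#'
#' The median Fa over the group's curves at each scale, computed over curves
#' that have a defined Fa there; scales where every curve is missing are
#' reported as `NA`.
#'
#' @param group A [group_curves()] or a plain list of `anisotropy_curve`s.
#' @return Data frame with columns `scale`, `scale_um`, `median_fa`, `n`.
#' @export
median_curve <- function(group) {
  curves <- if (inherits(group, "group_curves")) group$curves else group
  s <- common_ladder_scales(curves)
  fa <- sapply(curves, function(cv) cv$fa)
  fa <- matrix(fa, nrow = length(s))
  data.frame(scale = s, scale_um = curves[[1]]$scale_um,
             median_fa = apply(fa, 1, function(v)
               if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)),
             n = apply(fa, 1, function(v) sum(!is.na(v))))
}

#' Per-scale Wilcoxon rank-sum comparison of two groups
#'
#' At each ladder scale, a two-sided Wilcoxon rank-sum (Mann-Whitney) test on
#' the per-image anisotropy factors of the two groups. Exact p-values are used
#' when the combined sample size is at most 30 and there are no ties;
#' otherwise the normal approximation with continuity correction. Raw p-values
#' are the primary output; Benjamini-Hochberg adjusted values can be added.
#'
#' @param a,b [group_curves()] with at least 3 curves each, on one ladder.
#' @param adjust Add a `p_bh` column of Benjamini-Hochberg adjusted p-values
#'   (default `FALSE`).
#' @return Data frame with columns `scale`, `scale_um`, `n_a`, `n_b`, `p`
#'   (and `p_bh` if requested).
#' @export
pairwise_scale_test <- function(a, b, adjust = FALSE) {
  stopifnot(inherits(a, "group_curves"), inherits(b, "group_curves"))
  if (length(a$curves) < 3 || length(b$curves) < 3)
    stop("each group needs at least 3 curves")
  s <- common_ladder_scales(c(a$curves, b$curves))
  fa_a <- matrix(sapply(a$curves, function(cv) cv$fa), nrow = length(s))
  fa_b <- matrix(sapply(b$curves, function(cv) cv$fa), nrow = length(s))
  p <- vapply(seq_along(s), function(i) {
    x <- fa_a[i, ]; x <- x[!is.na(x)]
    y <- fa_b[i, ]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) return(NA_real_)
    exact <- (length(x) + length(y) <= 30) && !anyDuplicated(c(x, y))
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  }, numeric(1))
  out <- data.frame(scale = s, scale_um = a$curves[[1]]$scale_um,
                    n_a = length(a$curves), n_b = length(b$curves), p = p)
  if (adjust) out$p_bh <- stats::p.adjust(p, method = "BH")
  out
}

#' Crossover scale of two median curves
#'
#' The smallest scale at which the sign of `median_a - median_b` changes
#' between consecutive ladder scales, reported as the geometric mean of the
#' bracketing scales. A difference of exactly zero at a ladder scale counts as
#' a crossover at that scale itself. Scales are reported in micrometers when
#' the ladder carries a pixel size, otherwise in pixels.
#'
#' @param median_a,median_b [median_curve()] outputs on one ladder.
#' @return The crossover scale (um if available, else px), or `NA` if the
#'   curves never cross.
#' @export
crossover_scale <- function(median_a, median_b) {
  if (length(median_a$scale) != length(median_b$scale) ||
      any(abs(median_a$scale - median_b$scale) > 1e-9))
    stop("median curves are not on a common ladder")
  s <- if (all(is.na(median_a$scale_um))) median_a$scale else median_a$scale_um
  d <- median_a$median_fa - median_b$median_fa
  ok <- which(!is.na(d))
  for (k in seq_along(ok)) {
    i <- ok[k]
    if (d[i] == 0) return(s[i])
    if (k < length(ok)) {
      j <- ok[k + 1]
      if (d[i] * d[j] < 0) return(sqrt(s[i] * s[j]))
    }
  }
  NA_real_
}
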