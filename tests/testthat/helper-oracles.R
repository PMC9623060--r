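# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: explicit loops and textbook formulas only.

# Least-squares slope of the radially averaged log-log power spectrum.
oracle_spectral_slope <- function(values, fmin = 0.02, fmax = 0.25) {
  n <- nrow(values)
  P <- Mod(stats::fft(values))^2 / n^2
  f1 <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / n
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  sel <- fr > fmin & fr < fmax
  lf <- log(fr[sel]); lp <- log(P[sel])
  br <- seq(min(lf), max(lf), length.out = 20)
  grp <- cut(lf, br, include.lowest = TRUE)
  m <- tapply(lp, grp, mean); x <- tapply(lf, grp, mean)
  ok <- !is.na(m)
  unname(stats::coef(stats::lm(m[ok] ~ x[ok]))[2])
}

# Fraction of spectral power in the lowest `frac` of radial frequencies.
oracle_low_freq_power <- function(values, frac = 0.1) {
  n <- nrow(values)
  P <- Mod(stats::fft(values))^2
  f1 <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / n
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  P[1, 1] <- 0
  sum(P[fr <= 0.5 * frac & fr > 0]) / sum(P[fr > 0])
}

# Direct-space periodic convolution with the sampled, truncation-free
# Gaussian-derivative kernels (the kernel spans the whole raster, wrapped).
oracle_gaussian_derivative <- function(values, a) {
  n <- nrow(values)
  d <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n)
  DX <- matrix(rep(d, each = n), n, n)   # x = column offset
  DY <- matrix(rep(d, times = n), n, n)  # y = row offset
  G <- exp(-(DX^2 + DY^2) / (2 * a^2)) / (2 * pi * a^2)
  k1 <- a * (-DX / a^2) * G
  k2 <- a * (-DY / a^2) * G
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  for (br in 1:n) {
    rr <- ((br - 1) - (0:(n - 1))) %% n + 1
    for (bc in 1:n) {
      cc <- ((bc - 1) - (0:(n - 1))) %% n + 1
      tx[br, bc] <- sum(k1[rr, cc] * values)
      ty[br, bc] <- sum(k2[rr, cc] * values)
    }
  }
  list(tx = tx, ty = ty)
}

# Loop-based anisotropy factor: explicit histogram, explicit sum.
oracle_fa <- function(angles, n_bins) {
  dA <- 2 * pi / n_bins
  counts <- rep(0, n_bins)
  for (a in angles) {
    i <- floor((a + pi) / dA) + 1
    if (i > n_bins) i <- n_bins
    counts[i] <- counts[i] + 1
  }
  total <- 0
  for (i in 1:n_bins)
    total <- total + abs(counts[i] / (length(angles) * dA) - 1 / (2 * pi)) * dA
  total
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(length(all_v), length(x))
  w_all <- apply(combos, 2, function(id)
    sum(r[id]) - length(x) * (length(x) + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# 90-degree grid rotation used by the equivariance tests.
rot90ccw <- function(m) t(m)[nrow(m):1, ]
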