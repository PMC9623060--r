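test_that("binning policies resolve bin counts as specified", {
  pol_var <- binning_policy("variable", samples_per_bin = 100, min_bins = 4)
  # 6400 angles at 100 per bin -> 64 bins
  set.seed(1)
  a6400 <- runif(6400, -pi, pi - 1e-9)
  expect_equal(build_angle_pdf(a6400, pol_var)$n_bins, 64L)
  # 250 angles -> floor(2.5) = 2, clamped up to min_bins = 4
  expect_equal(build_angle_pdf(a6400[1:250], pol_var)$n_bins, 4L)
  pol_fix <- binning_policy("fixed", n_bins = 64)
  expect_equal(build_angle_pdf(a6400[1:250], pol_fix)$n_bins, 64L)
  expect_error(binning_policy("fixed", n_bins = 1), "n_bins")
  expect_error(binning_policy(min_bins = 1), "min_bins")
})

test_that("angle PDFs are normalized densities tiling the circle", {
  set.seed(2)
  for (pol in list(binning_policy("fixed", n_bins = 37),
                   binning_policy("variable"))) {
    a <- runif(5000, -pi, pi - 1e-9)
    pdf <- build_angle_pdf(a, pol)
    expect_equal(sum(pdf$density) * pdf$bin_width, 1, tolerance = 1e-9)
    expect_true(all(pdf$density >= 0))
    expect_equal(pdf$left_edges[1], -pi)
    expect_equal(pdf$bin_width, 2 * pi / pdf$n_bins)
    expect_equal(pdf$n_samples, 5000L)
  }
})

test_that("uniform angles give near-flat densities", {
  set.seed(3)
  a <- runif(6400, -pi, pi - 1e-9)
  for (pol in list(binning_policy("fixed", n_bins = 64), binning_policy())) {
    pdf <- build_angle_pdf(a, pol)
    rel <- abs(pdf$density - 1 / (2 * pi)) * 2 * pi
    expect_lt(max(rel), 5 * sqrt(100) / 100)
  }
})

test_that("an empty angle set raises the no-maxima condition", {
  expect_error(build_angle_pdf(numeric(0), binning_policy()),
               class = "wtmm_no_maxima")
  expect_error(build_angle_pdf(c(0, pi), binning_policy("fixed")), "\\[-pi, pi\\)")
})

test_that("the anisotropy factor has its analytic values and bounds", {
  # exactly uniform density -> Fa = 0 (pure isotropy)
  flat <- structure(list(scale = NA_real_, n_bins = 64L,
                         bin_width = 2 * pi / 64,
                         left_edges = -pi + 2 * pi / 64 * (0:63),
                         density = rep(1 / (2 * pi), 64), n_samples = 6400L),
                    class = "angle_pdf")
  expect_identical(anisotropy_factor(flat), 0)
  # all mass in one bin -> Fa = 2 (1 - 1/n_bins), approaching the supremum 2
  for (nb in c(64L, 1024L, 65536L)) {
    pdf <- build_angle_pdf(rep(-pi + pi / nb, 500),
                           binning_policy("fixed", n_bins = nb))
    expect_equal(anisotropy_factor(pdf), 2 * (1 - 1 / nb), tolerance = 1e-12)
  }
  # half the circle at 1/pi, the other half empty -> Fa = 1
  set.seed(4)
  half <- runif(4000, -pi, 0 - 1e-12)
  expect_equal(anisotropy_factor(build_angle_pdf(half,
                 binning_policy("fixed", n_bins = 64))), 1, tolerance = 5e-3)
  exact_half <- structure(list(scale = NA_real_, n_bins = 8L,
                               bin_width = 2 * pi / 8,
                               left_edges = -pi + 2 * pi / 8 * (0:7),
                               density = c(rep(1 / pi, 4), rep(0, 4)),
                               n_samples = 100L),
                          class = "angle_pdf")
  expect_equal(anisotropy_factor(exact_half), 1, tolerance = 1e-15)
})

test_that("Fa matches a loop-based brute-force oracle on random angle sets", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(200:5000, 1)
    a <- runif(n, -pi, pi - 1e-9)
    # mix in concentration so Fa spans a range
    if (rep %% 2 == 0) a[1:(n %/% 2)] <- rnorm(n %/% 2, sd = 0.3)
    a <- a[a >= -pi & a < pi]
    for (nb in c(16L, 64L)) {
      pdf <- build_angle_pdf(a, binning_policy("fixed", n_bins = nb))
      expect_equal(anisotropy_factor(pdf), oracle_fa(a, nb), tolerance = 1e-12)
      expect_gte(anisotropy_factor(pdf), 0)
      expect_lte(anisotropy_factor(pdf), 2 * (1 - 1 / nb))
    }
  }
})

test_that("multiscale curves rank a grating above white noise at every scale", {
  # probe scales up to ~1.5x the grating wavelength: far above its wavelength a
  # monochromatic fixture is smoothed to nothing and carries no anisotropy
  lad <- scale_ladder(4, 24, 8, pixel_size_um = 180 / 512)
  wn <- multiscale_curve(generate_field(field_spec(256, "white_noise", seed = 1)),
                         lad, image_id = "wn")
  st <- multiscale_curve(generate_field(field_spec(256, "oriented_stripes",
                                                   wavelength = 16, seed = 1)),
                         lad, image_id = "st")
  expect_true(all(st$fa > wn$fa))
  expect_equal(wn$scale, lad$scales)
  expect_equal(wn$scale_um, lad$scales_um)
})

test_that("curves are deterministic and flag no-maxima scales explicitly", {
  lad <- scale_ladder(4, 32, 5)
  f <- generate_field(field_spec(128, "white_noise", seed = 2))
  c1 <- multiscale_curve(f, lad)
  c2 <- multiscale_curve(f, lad)
  expect_identical(c1$fa, c2$fa)
  const <- scalar_field(matrix(2, 128, 128))
  expect_warning(cc <- multiscale_curve(const, lad), "no maxima")
  expect_true(all(is.na(cc$fa)))
  expect_true(all(cc$n_samples == 0))
})

test_that("Fa is invariant under 90-degree image rotation when 4 | n_bins", {
  f <- generate_field(field_spec(128, "white_noise", seed = 9))
  fr <- scalar_field(rot90ccw(f$values))
  lad <- scale_ladder(4, 16, 3)
  pol <- binning_policy("fixed", n_bins = 64)
  c1 <- multiscale_curve(f, lad, pol)
  c2 <- multiscale_curve(fr, lad, pol)
  expect_equal(c1$fa, c2$fa, tolerance = 1e-12)
})

test_that("central crops keep only maxima inside the window", {
  f <- generate_field(field_spec(256, "white_noise", seed = 10))
  lad <- scale_ladder(4, 32, 4)
  full <- multiscale_curve(f, lad)
  crop <- central_crop_curve(f, lad, crop = 128)
  expect_true(all(crop$n_samples < full$n_samples))
  expect_error(central_crop_curve(f, lad, crop = 256), "smaller than")
  sets <- multiscale_angles(f, lad, crop = 128)
  pts_lo <- (256 - 128) %/% 2 + 1
  expect_true(all(vapply(sets, function(s) length(s$angles) > 0, logical(1))))
})

test_that("per-chain binning uses one circular mean angle per chain", {
  f <- generate_field(field_spec(128, "white_noise", seed = 12))
  lad <- scale_ladder(4, 16, 3)
  pt <- multiscale_angles(f, lad, unit = "point")
  ch <- multiscale_angles(f, lad, unit = "chain")
  for (i in seq_along(lad$scales))
    expect_lt(length(ch[[i]]$angles), length(pt[[i]]$angles))
})

test_that("the coefficient of variation follows the sample-SD convention", {
  lad <- scale_ladder(4, 16, 3)
  f <- generate_field(field_spec(128, "white_noise", seed = 2))
  cv0 <- coefficient_of_variation(list(multiscale_curve(f, lad),
                                       multiscale_curve(f, lad),
                                       multiscale_curve(f, lad)))
  expect_equal(cv0$cv, rep(0, 3))
  # hand case: Fa = {1, 3} -> sd = sqrt(2), mean = 2, CV = sqrt(2)/2
  mk <- function(fa) structure(data.frame(scale = 4, scale_um = NA_real_,
                                          fa = fa, n_samples = 100L,
                                          n_bins = 4L),
                               class = c("anisotropy_curve", "data.frame"))
  cv <- coefficient_of_variation(list(mk(1), mk(3), mk(1), mk(3)))
  expect_equal(cv$cv, sd(c(1, 3, 1, 3)) / 2)
  two <- stats::sd(c(1, 3)) / mean(c(1, 3))
  expect_equal(two, sqrt(2) / 2)
  expect_error(coefficient_of_variation(list(mk(1), mk(2))), "at least 3")
})

test_that("reference normalization divides (or subtracts) per scale", {
  lad <- scale_ladder(4, 16, 3)
  f <- generate_field(field_spec(128, "white_noise", seed = 2))
  cv <- multiscale_curve(f, lad)
  ref <- data.frame(scale = cv$scale, median_fa = cv$fa)
  self <- normalize_by_reference(cv, ref)
  expect_equal(self$fa, rep(1, 3))
  doubled <- cv; doubled$fa <- 2 * cv$fa
  expect_equal(normalize_by_reference(doubled, ref)$fa, rep(2, 3))
  diffed <- normalize_by_reference(doubled, ref, mode = "difference")
  expect_equal(diffed$fa, cv$fa)
  bad <- ref; bad$median_fa[2] <- 0
  expect_error(normalize_by_reference(cv, bad), "cannot normalize")
})
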