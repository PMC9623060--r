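mk_curve <- function(fa, scales = seq_along(fa), scales_um = NA_real_) {
  structure(data.frame(scale = scales,
                       scale_um = if (all(is.na(scales_um))) NA_real_ else scales_um,
                       fa = fa, n_samples = 100L, n_bins = 8L),
            class = c("anisotropy_curve", "data.frame"))
}

test_that("median curves follow the median definition", {
  g1 <- group_curves("a", list(mk_curve(c(1, 2))))
  expect_equal(median_curve(g1)$median_fa, c(1, 2))
  g3 <- group_curves("a", list(mk_curve(c(1, 1)), mk_curve(c(2, 9)),
                               mk_curve(c(9, 2))))
  m <- median_curve(g3)
  expect_equal(m$median_fa, c(2, 2))
  expect_equal(m$n, c(3L, 3L))
})

test_that("median curves are invariant to duplicating the curve set", {
  curves <- list(mk_curve(c(1, 4)), mk_curve(c(2, 5)), mk_curve(c(3, 6)))
  m1 <- median_curve(group_curves("a", curves))
  m2 <- median_curve(group_curves("a", c(curves, curves)))
  expect_equal(m1$median_fa, m2$median_fa)
})

test_that("missing scales are excluded from medians, all-missing flagged", {
  curves <- list(mk_curve(c(1, NA)), mk_curve(c(3, NA)), mk_curve(c(5, NA)))
  m <- median_curve(group_curves("a", curves))
  expect_equal(m$median_fa, c(3, NA))
  expect_equal(m$n, c(3L, 0L))
})

test_that("rank-sum p-values match exact enumeration on small groups", {
  a <- group_curves("a", list(mk_curve(1), mk_curve(2), mk_curve(3)))
  b <- group_curves("b", list(mk_curve(4), mk_curve(5), mk_curve(6)))
  t <- pairwise_scale_test(a, b)
  expect_equal(t$p, 0.1)
  expect_equal(t$p, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  # a second configuration against the enumeration oracle
  x <- c(1.2, 0.4, 2.2, 0.9); y <- c(1.5, 2.8, 3.1)
  a2 <- group_curves("a", lapply(x, mk_curve))
  b2 <- group_curves("b", lapply(y, mk_curve))
  expect_equal(pairwise_scale_test(a2, b2)$p, oracle_ranksum_p(x, y))
})

test_that("identical groups give p = 1 and the test is symmetric", {
  curves <- list(mk_curve(c(1, 9)), mk_curve(c(2, 8)), mk_curve(c(3, 7)))
  a <- group_curves("a", curves)
  b <- group_curves("b", curves)
  expect_equal(pairwise_scale_test(a, b)$p, c(1, 1))
  c1 <- group_curves("a", list(mk_curve(c(1, 2)), mk_curve(c(2, 3)),
                               mk_curve(c(3, 4)), mk_curve(c(7, 1))))
  c2 <- group_curves("b", list(mk_curve(c(4, 2)), mk_curve(c(5, 6)),
                               mk_curve(c(6, 9))))
  expect_equal(pairwise_scale_test(c1, c2)$p, pairwise_scale_test(c2, c1)$p)
  expect_error(pairwise_scale_test(a, group_curves("b", curves[1:2])),
               "at least 3")
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  a <- group_curves("a", lapply(c(1, 2, 3, 4), mk_curve))
  b <- group_curves("b", lapply(c(5, 6, 7, 8), mk_curve))
  t0 <- pairwise_scale_test(a, b)
  expect_false("p_bh" %in% names(t0))
  t1 <- pairwise_scale_test(a, b, adjust = TRUE)
  expect_equal(t1$p_bh, p.adjust(t1$p, method = "BH"))
})

test_that("crossover scales follow the sign-change rule", {
  mk_med <- function(fa, scales, um = scales) data.frame(
    scale = scales, scale_um = um, median_fa = fa, n = 5L)
  # parallel curves never cross
  a <- mk_med(c(2, 3, 4), c(8, 16, 32))
  b <- mk_med(c(1, 2, 3), c(8, 16, 32))
  expect_true(is.na(crossover_scale(a, b)))
  # +0.2 +0.1 -0.1 at scales 8 16 32 -> sqrt(16 * 32)
  a2 <- mk_med(c(1.2, 1.1, 0.9), c(8, 16, 32))
  b2 <- mk_med(c(1, 1, 1), c(8, 16, 32))
  expect_equal(crossover_scale(a2, b2), sqrt(16 * 32))
  # an exact zero counts as a crossover at that ladder scale
  a3 <- mk_med(c(1.2, 1.0, 0.9), c(8, 16, 32))
  expect_equal(crossover_scale(a3, b2), 16)
})

test_that("a planted crossover is recovered within one ladder step", {
  lad <- scale_ladder(4, 64, 9)
  s_star <- 20
  fa_a <- 1 + 0.3 * log(s_star / lad$scales)   # decreasing, crosses 1 at s*
  fa_b <- rep(1, 9)
  m_a <- data.frame(scale = lad$scales, scale_um = lad$scales,
                    median_fa = fa_a, n = 5L)
  m_b <- data.frame(scale = lad$scales, scale_um = lad$scales,
                    median_fa = fa_b, n = 5L)
  found <- crossover_scale(m_a, m_b)
  step <- lad$scales[2] / lad$scales[1]
  expect_gt(found, s_star / step)
  expect_lt(found, s_star * step)
})
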