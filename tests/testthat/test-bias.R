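two_county_estimates <- function(a_mean, b_mean, years, sex = "male") {
  ids <- c("S01-C01", "S01-C02")
  m <- matrix(rep(a_mean, length(years)), 2, length(years),
              dimnames = list(ids, years))
  fx_estimates(m, years, sex = sex)
}

test_that("ramp weights anchor at zero in 2000 and one in 2011", {
  expect_equal(ramp_weight(1996:2000), rep(0, 5))
  expect_equal(ramp_weight(2011), 1)      # 11/11 of the measured bias
  expect_equal(ramp_weight(2006), 6 / 11)
  expect_equal(ramp_weight(2012), 1)
})

test_that("identical model estimates measure zero bias", {
  a <- two_county_estimates(c(20, 25), NULL, 2011)
  bias <- measure_bias(a, a)
  expect_true(all(bias$bias_2011 == 0))
})

test_that("the 2011 bias is the combined-minus-landline difference in points", {
  a <- fx_estimates(matrix(20.0, 1, 1, dimnames = list("X", NULL)), 2011)
  b <- fx_estimates(matrix(21.21, 1, 1, dimnames = list("X", NULL)), 2011)
  bias <- measure_bias(b, a)
  expect_equal(bias$bias_2011, 1.21)
  # mismatched county sets cannot be compared
  b2 <- fx_estimates(matrix(21, 1, 1, dimnames = list("Y", NULL)), 2011)
  expect_error(measure_bias(b2, a), "county sets")
})

test_that("ramp correction interpolates linearly and respects the window", {
  expect_equal(apply_ramp(20, 1.1, 2006) - 20, 1.1 * 6 / 11)
  expect_equal(apply_ramp(20, 5, 2000), 20)
  expect_equal(apply_ramp(20, 5, 1998), 20)
  expect_equal(apply_ramp(20, 5, 2011), 25)
  expect_error(apply_ramp(20, 1, 1990), "window")
  # corrections cannot push the series outside [0, 100]
  expect_equal(apply_ramp(99.5, 10, 2011), 100)
  expect_equal(apply_ramp(0.2, -10, 2011), 0)
})

test_that("the composed series follows the A / ramped-A / B rule", {
  years_a <- 1996:2010
  ids <- c("S01-C01", "S01-C02")
  ma <- matrix(20, 2, length(years_a), dimnames = list(ids, years_a))
  mb <- matrix(30, 2, 2, dimnames = list(ids, 2011:2012))
  a <- fx_estimates(ma, years_a)
  a11 <- fx_estimates(matrix(20, 2, 1, dimnames = list(ids, 2011)), 2011)
  b <- fx_estimates(mb, 2011:2012)
  bias <- measure_bias(b, a11)   # +10 everywhere
  expect_true(all(bias$bias_2011 == 10))
  final <- correct_series(a, b, bias)
  got <- final[final$county_id == ids[1], ]
  got <- got[order(got$year), ]
  expect_equal(got$mean[got$year <= 2000], rep(20, 5))
  expect_equal(got$mean[got$year %in% 2001:2010],
               20 + 10 * (1:10) / 11)
  expect_equal(got$mean[got$year >= 2011], c(30, 30))
  expect_equal(got$model, c(rep("A", 15), "B", "B"))
  expect_equal(got$corrected, got$year >= 2001 & got$year <= 2010)
})

test_that("constant-sign bias keeps the corrected series ordered against the raw one", {
  years_a <- 1996:2010
  ids <- c("S01-C01", "S01-C02")
  set.seed(8)
  ma <- matrix(20 + rnorm(2 * 15, 0, 2), 2, 15, dimnames = list(ids, years_a))
  a <- fx_estimates(ma, years_a)
  a11 <- fx_estimates(matrix(c(20, 22), 2, 1, dimnames = list(ids, 2011)), 2011)
  b <- fx_estimates(matrix(c(21.5, 23.8), 2, 1, dimnames = list(ids, 2011)), 2011)
  bias <- measure_bias(b, a11)
  final <- correct_series(a, b, bias)
  aa <- as.data.frame(a)
  m <- merge(as.data.frame(final), aa, by = c("county_id", "year"))
  m <- m[m$year %in% 2001:2010, ]
  expect_true(all(m$mean.x >= m$mean.y))
  # and the applied correction grows with the year
  diffs <- m$mean.x - m$mean.y
  for (cid in ids) {
    d <- diffs[m$county_id == cid][order(m$year[m$county_id == cid])]
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("empirical-Bayes smoothing recovers a common bias from noisy county measurements", {
  # truth: every county shares a 1.5 pp bias; measurements add 2 pp noise
  n_c <- 60; nsim <- 300
  ids <- sprintf("C%03d", seq_len(n_c))
  set.seed(12)
  base <- runif(n_c, 18, 30)
  noise_a <- rnorm(n_c, 0, 1.4); noise_b <- rnorm(n_c, 0, 1.4)
  da <- array(rnorm(n_c * nsim, base + noise_a, 1.4), c(n_c, 1, nsim),
              dimnames = list(ids, 2011, NULL))
  db <- array(rnorm(n_c * nsim, base + 1.5 + noise_b, 1.4), c(n_c, 1, nsim),
              dimnames = list(ids, 2011, NULL))
  a <- fx_estimates(matrix(apply(da, 1, mean), n_c, 1,
                           dimnames = list(ids, 2011)), 2011, draws = da)
  b <- fx_estimates(matrix(apply(db, 1, mean), n_c, 1,
                           dimnames = list(ids, 2011)), 2011, draws = db)
  raw <- measure_bias(b, a)
  eb <- measure_bias(b, a, smooth = "eb")
  expect_lt(rmse(eb$bias_2011, rep(1.5, n_c)),
            rmse(raw$bias_2011, rep(1.5, n_c)))
  # the cross-county center is preserved
  expect_equal(mean(eb$bias_2011), mean(raw$bias_2011))
  # smoothing without draws is refused
  a0 <- fx_estimates(matrix(base, n_c, 1, dimnames = list(ids, 2011)), 2011)
  expect_error(measure_bias(b, a0, smooth = "eb"), "draws")
})

test_that("draw-wise correction propagates bias uncertainty into the intervals", {
  years_a <- 2009:2010
  ids <- c("S01-C01", "S01-C02")
  nsim <- 400
  set.seed(10)
  base <- c(20, 24)
  da <- array(rnorm(2 * 2 * nsim, base, 0.3), c(2, 2, nsim),
              dimnames = list(ids, years_a, NULL))
  a <- fx_estimates(matrix(base, 2, 2, dimnames = list(ids, years_a)),
                    years_a, draws = da)
  da11 <- array(rnorm(2 * 1 * nsim, base, 0.3), c(2, 1, nsim),
                dimnames = list(ids, 2011, NULL))
  a11 <- fx_estimates(matrix(base, 2, 1, dimnames = list(ids, 2011)), 2011,
                      draws = da11)
  db <- array(rnorm(2 * 1 * nsim, base + 2, 0.3), c(2, 1, nsim),
              dimnames = list(ids, 2011, NULL))
  b <- fx_estimates(matrix(base + 2, 2, 1, dimnames = list(ids, 2011)), 2011,
                    draws = db)
  bias <- measure_bias(b, a11)
  expect_false(is.null(attr(bias, "bias_draws")))
  final <- correct_series(a, b, bias)
  f10 <- final[final$year == 2010, ]
  # interval width in 2010 exceeds the uncorrected width: bias noise adds in
  width_a <- apply(da[, 2, ], 1, function(x) diff(quantile(x, c(.025, .975))))
  width_f <- f10$upper - f10$lower
  expect_true(all(width_f > width_a))
  expect_equal(f10$mean, base + 2 * 10 / 11, tolerance = 0.1)
})
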