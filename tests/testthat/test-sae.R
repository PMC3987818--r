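# oracle: pooled logistic MLE with variance components pinned to zero
test_that("intercept-only fit with zero variance recovers the closed-form MLE", {
  md <- fx_flat_microdata(100, 30)
  spec <- sae_spec("total", "male", covariates = character(0),
                   year_term = FALSE, random_slopes = FALSE)
  fit <- sae_fit(md, spec, re_zero = TRUE)
  expect_equal(unname(coef(fit)[1]), log(30 / 70), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("a constant outcome or singular design is rejected with a clear error", {
  md <- fx_flat_microdata(50, 0)
  spec <- sae_spec("total", "male", covariates = character(0),
                   year_term = FALSE, random_slopes = FALSE)
  expect_error(sae_fit(md, spec, re_zero = TRUE), "constant")
  # education never varies in the flat fixture -> collinear with intercept
  md2 <- fx_flat_microdata(60, 20)
  spec2 <- sae_spec("total", "male", covariates = "education",
                    year_term = FALSE, random_slopes = FALSE)
  expect_error(sae_fit(md2, spec2, re_zero = TRUE), "singular|collinear")
})

test_that("cell predictions are inverse-logit linear in the fitted effects", {
  study <- fx_study_small()
  spec <- sae_spec("total", "male", random_slopes = FALSE)
  fit <- fx("fit_small", function() sae_fit(study$md, spec))
  # all-zero coefficients push every cell probability to exactly 1/2
  fit0 <- fit
  fit0$beta[] <- 0
  fit0$re_state$u0[] <- 0; fit0$re_state$u1[] <- 0
  fit0$re_county$u0[] <- 0; fit0$re_county$u1[] <- 0
  p <- predict(fit0, study$registry, years = 2005)
  expect_true(all(p$p == 0.5))
  # raising a county random intercept strictly raises every cell probability
  fit1 <- fit
  i <- match(study$registry$counties$county_id[1], fit1$re_county$id)
  fit1$re_county$u0[i] <- fit1$re_county$u0[i] + 0.3
  p0 <- predict(fit, study$registry, years = 2005)
  p1 <- predict(fit1, study$registry, years = 2005)
  cid <- study$registry$counties$county_id[1]
  expect_true(all(p1$p[p1$county_id == cid] > p0$p[p0$county_id == cid]))
  expect_equal(p1$p[p1$county_id != cid], p0$p[p0$county_id != cid])
})

test_that("a county with no data inherits its state-level prediction", {
  study <- fx_study_small()
  reg <- study$registry
  held_out <- reg$counties$county_id[1]
  md <- study$md[study$md$county_id != held_out, , drop = FALSE]
  spec <- sae_spec("total", "male", random_slopes = FALSE)
  fit <- sae_fit(md, spec)
  expect_false(held_out %in% fit$re_county$id)
  p <- predict(fit, reg, years = 2005)
  # state-only prediction: clone the fit, zero the county effects
  fit_state <- fit
  fit_state$re_county$u0[] <- 0; fit_state$re_county$u1[] <- 0
  ps <- predict(fit_state, reg, years = 2005)
  sibling <- reg$counties$county_id[reg$counties$state_id ==
    reg$counties$state_id[1]][2]
  expect_equal(p$p[p$county_id == held_out],
               ps$p[ps$county_id == sibling])
})

test_that("prediction outside the fitted years requires explicit extrapolation", {
  study <- fx_study_small()
  spec <- sae_spec("total", "male", random_slopes = FALSE)
  fit <- fx("fit_small", function() sae_fit(study$md, spec))
  expect_error(predict(fit, study$registry, years = 2020), "outside")
  p <- predict(fit, study$registry, years = 2020, allow_extrapolation = TRUE)
  expect_true(all(p$p > 0 & p$p < 1))
})

test_that("simulation draws are seeded, centered, and collapse when variance is zero", {
  study <- fx_study_small()
  spec <- sae_spec("total", "male", random_slopes = FALSE)
  fit <- fx("fit_small", function() sae_fit(study$md, spec))
  reg <- study$registry
  d1 <- simulate(fit, nsim = 50, seed = 5, registry = reg, years = 2010)
  d2 <- simulate(fit, nsim = 50, seed = 5, registry = reg, years = 2010)
  expect_identical(d1$draws, d2$draws)
  d3 <- simulate(fit, nsim = 50, seed = 6, registry = reg, years = 2010)
  expect_false(identical(d1$draws, d3$draws))

  # zero covariance and zero conditional variance: draws == point prediction
  # (exercises the marginal fallback used when no joint factor is stored)
  fit0 <- fit
  fit0$joint <- NULL
  fit0$vcov[] <- 0
  fit0$re_state$u0_var[] <- 0; fit0$re_state$u1_var[] <- 0
  fit0$re_county$u0_var[] <- 0; fit0$re_county$u1_var[] <- 0
  fit0$vc$sd[] <- 0
  d0 <- simulate(fit0, nsim = 20, seed = 1, registry = reg, years = 2010)
  point <- sae_point_estimates(fit0, reg, 2010)
  for (k in 2:20) expect_equal(d0$draws[, , k], d0$draws[, , 1])
  expect_equal(unname(d0$draws[, 1, 1]),
               point$mean[match(reg$counties$county_id, point$county_id)],
               tolerance = 1e-10)

  # draw means converge to the point summary within Monte-Carlo error
  big <- simulate(fit, nsim = 2000, seed = 7, registry = reg, years = 2010)
  mc_mean <- apply(big$draws[, 1, ], 1, mean)
  mc_se <- apply(big$draws[, 1, ], 1, sd) / sqrt(2000)
  pt <- sae_point_estimates(fit, reg, 2010)
  pt <- pt$mean[match(rownames(big$draws), pt$county_id)]
  expect_true(all(abs(mc_mean - pt) < 3 * mc_se + 0.05))
})

test_that("estimates lie in (0,100) with ordered interval bounds", {
  study <- fx_study_small()
  spec <- sae_spec("total", "male", random_slopes = FALSE)
  fit <- fx("fit_small", function() sae_fit(study$md, spec))
  est <- sae_estimates(fit, study$registry, c(1996, 2005, 2012),
                       n_draws = 200, seed = 3)
  expect_true(all(est$mean > 0 & est$mean < 100))
  expect_true(all(est$lower <= est$mean & est$mean <= est$upper))
})

test_that("variance components shrink toward zero when the truth has none", {
  reg <- build_registry(8, 5, seed = 51)
  p <- truth_params(sd_state = 0, sd_county = 0, sd_state_slope = 0,
                    sd_county_slope = 0, income_level_effect = 0,
                    income_trend_effect = 0, wireless_2012 = 0,
                    phone = c(0, 0, 0), mean_n = 250)
  surf <- true_prevalence_surface(p, reg, seed = 52)
  md <- classify_smoking(sample_respondents(surf, seed = 53,
                                            years = seq(1996, 2012, 4)))
  md <- md[md$sex == "male", ]
  fit <- sae_fit(md, sae_spec("total", "male", random_slopes = TRUE))
  expect_true(all(fit$vc$sd <= 0.05))
})

test_that("sparse-county estimates are pooled between raw data and state level", {
  # no-covariate spec so county, state and raw proportions are comparable
  study <- fx_study_small()
  md <- study$md[study$md$sex == "male" & study$md$year == 2005, ]
  spec <- sae_spec("total", "male", covariates = character(0),
                   year_term = FALSE, random_slopes = FALSE)
  fit <- sae_fit(md, spec)
  pr <- predict(fit, study$registry, years = 2005)
  fit_state <- fit
  fit_state$re_county$u0[] <- 0
  ps <- predict(fit_state, study$registry, years = 2005)
  checked <- 0
  for (cid in unique(md$county_id)) {
    raw <- mean(md$total_smoker[md$county_id == cid])
    if (raw %in% c(0, 1)) next
    pc <- pr$p[pr$county_id == cid][1]
    pstate <- ps$p[ps$county_id == cid][1]
    lo <- min(raw, pstate) - 1e-8; hi <- max(raw, pstate) + 1e-8
    expect_gte(pc, lo); expect_lte(pc, hi)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})
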