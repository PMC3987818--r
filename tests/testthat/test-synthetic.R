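test_that("generated registries have the declared size and valid shares", {
  reg <- build_registry(2, 3, seed = 1)
  expect_equal(nrow(reg$counties), 6)
  sums <- tapply(reg$cell_shares$share, reg$cell_shares$county_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(build_registry(1, 3), "at least 2")
})

test_that("the registry is deterministic given the seed", {
  r1 <- build_registry(3, 3, seed = 42)
  r2 <- build_registry(3, 3, seed = 42)
  expect_identical(r1, r2)
  r3 <- build_registry(3, 3, seed = 43)
  expect_false(identical(r1$counties$income_1996, r3$counties$income_1996))
})

test_that("generated incomes give nonempty quintiles", {
  reg <- build_registry(4, 5, seed = 7)
  q <- assign_income_quintiles(reg)
  expect_setequal(unique(q), 1:5)
})

test_that("a degenerate surface collapses to one national logistic trend", {
  reg <- fx_registry_uniform(2, 2)
  p <- truth_params(sd_state = 0, sd_county = 0, sd_state_slope = 0,
                    sd_county_slope = 0, income_level_effect = 0,
                    income_trend_effect = 0,
                    age = rep(0, 6), race = rep(0, 3), marital = rep(0, 2),
                    education = rep(0, 3),
                    phone = c(0, 0, 0), sex_effect = c(male = 0, female = 0))
  surf <- true_prevalence_surface(p, reg, seed = 1)
  tot <- surf$truth[surf$truth$outcome == "total", ]
  # all counties and sexes share one curve; the curve follows the fixed trend
  spread <- tapply(tot$prevalence, tot$year, function(x) diff(range(x)))
  expect_true(all(spread < 1e-9))
  expected <- 100 * plogis(p$intercept + p$year_slope * (1996:2012 - 2004))
  expect_equal(as.vector(tapply(tot$prevalence, tot$year, mean)),
               expected, tolerance = 1e-9)
})

test_that("with all effects zero the surface equals the inverse-logit intercept", {
  reg <- fx_registry_uniform(2, 2)
  p <- truth_params(intercept = qlogis(0.25), year_slope = 0,
                    sd_state = 0, sd_county = 0, sd_state_slope = 0,
                    sd_county_slope = 0, income_level_effect = 0,
                    income_trend_effect = 0, age = rep(0, 6), race = rep(0, 3),
                    marital = rep(0, 2), education = rep(0, 3),
                    phone = c(0, 0, 0), sex_effect = c(male = 0, female = 0))
  surf <- true_prevalence_surface(p, reg, seed = 1)
  tot <- surf$truth[surf$truth$outcome == "total", ]
  expect_true(all(abs(tot$prevalence - 25) < 1e-9))
  # zero year slope: constant over time county by county
  v <- tapply(tot$prevalence, tot$county_id, function(x) diff(range(x)))
  expect_true(all(v < 1e-9))
})

test_that("landline-frame years exclude wireless-only respondents", {
  md <- fx_study_small()$md
  pre <- md[md$year <= 2010, ]
  post <- md[md$year >= 2011, ]
  expect_equal(sum(pre$phone_usage == "wireless_only"), 0)
  expect_setequal(as.character(unique(post$phone_usage)),
                  c("landline_only", "dual", "wireless_only"))
  # inverse-inclusion weights exceed 1 exactly when a stratum is excluded
  expect_true(all(pre$design_weight >= 1))
  expect_true(all(post$design_weight == 1))
})

test_that("sampling is reproducible and respects the year schedule", {
  surf <- fx_study_small()$surface
  m1 <- sample_respondents(surf, seed = 9, years = 2010:2012)
  m2 <- sample_respondents(surf, seed = 9, years = 2010:2012)
  expect_identical(m1, m2)
  expect_error(sample_respondents(surf, seed = 1, years = 1990:1995),
               "outside")
})

test_that("frame exclusion biases prevalence by the closed-form mixture", {
  # wireless-only 30% with prevalence 0.35 vs 0.20 for the reachable:
  # full population 0.7*0.20 + 0.3*0.35 = 0.245, landline frame 0.20
  reg <- fx_registry_uniform(2, 2)
  delta <- qlogis(0.35) - qlogis(0.20)
  p <- truth_params(intercept = qlogis(0.20), year_slope = 0,
                    sd_state = 0, sd_county = 0, sd_state_slope = 0,
                    sd_county_slope = 0, income_level_effect = 0,
                    income_trend_effect = 0, age = rep(0, 6), race = rep(0, 3),
                    marital = rep(0, 2), education = rep(0, 3),
                    phone = c(0, 0, delta), sex_effect = c(male = 0, female = 0),
                    wireless_2012 = 0.36, wireless_age_tilt = rep(1, 6),
                    mean_n = 5000)
  surf <- true_prevalence_surface(p, reg, seed = 2)
  # 2010 has wireless share 0.30 under the linear trajectory
  truth10 <- surf$truth[surf$truth$year == 2010 &
                          surf$truth$outcome == "total", "prevalence"]
  expect_equal(unique(round(truth10, 9)), 24.5, tolerance = 1e-6)
  md <- classify_smoking(sample_respondents(surf, seed = 3, years = 2010))
  n <- nrow(md)
  frame_prev <- mean(md$total_smoker)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frame_prev - 0.20), 3 * se)
  # the weighted estimate targets the frame, not the full population
  expect_equal(sum(md$phone_usage == "wireless_only"), 0)
})

test_that("empirical county-year prevalence converges to the stored truth", {
  reg <- build_registry(2, 2, seed = 31)
  p <- truth_params(wireless_2012 = 0, mean_n = 5000)
  surf <- true_prevalence_surface(p, reg, seed = 32)
  md <- classify_smoking(sample_respondents(surf, seed = 33, years = 2012))
  w <- std_pop_us2000()$weight
  for (cid in reg$counties$county_id) {
    sub <- md[md$county_id == cid & md$sex == "male", ]
    # age-standardized empirical prevalence vs the stored standardized truth
    grp <- split(sub$total_smoker, sub$age_group)
    emp <- vapply(grp, mean, numeric(1))
    n_a <- vapply(grp, length, numeric(1))
    emp_std <- 100 * sum(w * emp)
    se <- 100 * sqrt(sum(w^2 * pmax(emp * (1 - emp), 0.05) / pmax(n_a, 1)))
    tr <- surf$truth[surf$truth$county_id == cid & surf$truth$year == 2012 &
                       surf$truth$sex == "male" &
                       surf$truth$outcome == "total", "prevalence"]
    expect_lt(abs(emp_std - tr), 3 * se)
  }
})
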