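test_that("annualized rates follow the geometric formula", {
  # the published national male endpoints: 27.3% to 22.2% over 1996-2012
  r <- annualized_rate(27.3, 22.2, 1996, 2012)
  expect_equal(round(r, 1), -1.3)
  expect_equal(annualized_rate(18, 18, 2000, 2010), 0)
  expect_equal(annualized_rate(20, 10, 1996, 2012),
               100 * (0.5^(1 / 16) - 1))
  expect_equal(round(annualized_rate(20, 10, 1996, 2012), 2), -4.24)
  expect_error(annualized_rate(0, 10, 2000, 2005), "positive")
  expect_error(annualized_rate(10, 20, 2005, 2005), "exceed")
})

test_that("rate is antisymmetric under path reversal", {
  set.seed(21)
  for (i in 1:20) {
    p0 <- runif(1, 5, 40); p1 <- runif(1, 5, 40)
    r01 <- annualized_rate(p0, p1, 1996, 2012)
    r10 <- annualized_rate(p1, p0, 1996, 2012)
    expect_equal((1 + r01 / 100) * (1 + r10 / 100), 1)
  }
})

test_that("trend significance follows the 95% draw-interval rule", {
  expect_true(classify_trend(seq(-3, -0.5, length.out = 200))$significant_decline)
  sym <- c(seq(-1, 1, length.out = 200))
  ct <- classify_trend(sym)
  expect_false(ct$significant_decline); expect_false(ct$significant_increase)
  set.seed(22)
  draws <- rnorm(1000, -1, 0.4)
  ct2 <- classify_trend(draws)
  expect_true(ct2$significant_decline)
  expect_lt(ct2$rate_upper, 0)
  expect_error(classify_trend(rnorm(50)), "at least 100")
})

test_that("county trends carry draw intervals containing the point rate", {
  ids <- c("A", "B", "C")
  years <- c(1996, 2012)
  set.seed(23)
  means <- matrix(c(30, 25, 20, 24, 25, 21), 3, 2, dimnames = list(ids, years))
  draws <- array(NA_real_, c(3, 2, 500), dimnames = list(ids, years, NULL))
  for (i in 1:3) for (j in 1:2)
    draws[i, j, ] <- rnorm(500, means[i, j], 0.8)
  est <- fx_estimates(means, years, draws = draws)
  tr <- county_trends(est, 1996, 2012)
  expect_equal(tr$county_id, ids)
  expect_true(all(tr$rate >= tr$rate_lower & tr$rate <= tr$rate_upper))
  expect_false(any(tr$significant_decline & tr$significant_increase))
  # A declines sharply, B is flat
  expect_true(tr$significant_decline[1])
  expect_false(tr$significant_decline[2] || tr$significant_increase[2])
})

test_that("within-state gaps reproduce printed worked examples", {
  reg <- fx_registry_uniform(2, 2)
  ids <- reg$counties$county_id
  # VA male 2012: Sussex 33.5 vs Falls Church 9.9 -> 23.6 pp
  # AK female 2012: Northwest Arctic 40.8 vs Haines 15.4 -> 25.4 pp
  m <- matrix(c(33.5, 9.9, 40.8, 15.4), 4, 1, dimnames = list(ids, 2012))
  est <- fx_estimates(m, 2012)
  ws <- within_state_range(est, reg, 2012)
  expect_equal(ws$states$gap, c(23.6, 25.4))
  expect_equal(ws$median_gap, (23.6 + 25.4) / 2)
  expect_equal(ws$states$county_max, ids[c(1, 3)])
  # equal counties: zero gap
  est0 <- fx_estimates(matrix(20, 4, 1, dimnames = list(ids, 2012)), 2012)
  expect_equal(within_state_range(est0, reg, 2012)$states$gap, c(0, 0))
})

test_that("single-county states are skipped with a note", {
  reg <- fx_registry_uniform(2, 2)
  ids <- reg$counties$county_id
  m <- matrix(c(30, 20, 25), 3, 1, dimnames = list(ids[1:3], 2012))
  est <- fx_estimates(m, 2012)
  expect_message(ws <- within_state_range(est, reg, 2012), "skipping")
  expect_equal(ws$skipped, "S02")
  expect_equal(nrow(ws$states), 1)
})

test_that("sex gaps count strict male excess and track pairing", {
  ids <- sprintf("C%02d", 1:20)
  set.seed(24)
  pm <- matrix(runif(20, 15, 35), 20, 1, dimnames = list(ids, 2012))
  em <- fx_estimates(pm, 2012, sex = "male")
  ef_same <- fx_estimates(pm, 2012, sex = "female")
  gs <- sex_gap_summary(em, ef_same, 2012)
  expect_equal(gs$share_male_higher, 0)  # ties are not "higher"
  expect_equal(gs$median_gap, 0)

  ef5 <- fx_estimates(pm - 5, 2012, sex = "female")
  gs5 <- sex_gap_summary(em, ef5, 2012)
  expect_equal(gs5$share_male_higher, 100)
  expect_equal(gs5$median_gap, 5)
  expect_equal(gs5$correlation, 1)

  # shuffling the pairing destroys the correlation
  pf <- pm[sample(20), , drop = FALSE]
  rownames(pf) <- ids
  gs_sh <- sex_gap_summary(em, fx_estimates(pf, 2012, sex = "female"), 2012)
  expect_lt(abs(gs_sh$correlation), 0.5)
})

test_that("quintile summaries aggregate rates and significance shares", {
  ids <- sprintf("C%02d", 1:10)
  q <- setNames(rep(1:5, each = 2), ids)
  years <- c(1996, 2012)
  m <- matrix(c(rep(30, 10), rep(24, 10)), 10, 2, dimnames = list(ids, years))
  est <- fx_estimates(m, years)
  tr <- data.frame(county_id = ids, y_start = 1996, y_end = 2012,
                   rate = annualized_rate(30, 24, 1996, 2012),
                   significant_decline = rep(c(TRUE, FALSE), 5),
                   significant_increase = FALSE)
  qt <- quintile_table(est, q, tr)
  expect_equal(nrow(qt), 5)
  expect_true(all(qt$median_prev_start == 30))
  expect_true(all(qt$median_prev_end == 24))
  expect_equal(length(unique(round(qt$median_rate, 10))), 1)
  expect_true(all(qt$pct_significant_decline >= 0 &
                    qt$pct_significant_decline <= 100))
  expect_equal(qt$pct_significant_decline, rep(50, 5))
})

test_that("rank tables give exact ranks with draw-based intervals", {
  ids <- c("lo", "mid", "hi")
  m <- matrix(c(10, 20, 30), 3, 1, dimnames = list(ids, 2012))
  # zero-variance draws: the interval collapses onto the point rank
  d0 <- array(rep(c(10, 20, 30), 100), c(3, 1, 100),
              dimnames = list(ids, 2012, NULL))
  rt0 <- rank_counties(fx_estimates(m, 2012, draws = d0), 2012)
  expect_equal(rt0$rank, 1:3)
  expect_equal(rt0$rank_lower, rt0$rank)
  expect_equal(rt0$rank_upper, rt0$rank)
  # well-separated draw distributions exclude each other's ranks
  set.seed(25)
  d1 <- array(NA_real_, c(3, 1, 500), dimnames = list(ids, 2012, NULL))
  d1[1, 1, ] <- rnorm(500, 10, 0.5)
  d1[2, 1, ] <- rnorm(500, 20, 0.5)
  d1[3, 1, ] <- rnorm(500, 30, 0.5)
  rt1 <- rank_counties(fx_estimates(m, 2012, draws = d1), 2012)
  expect_equal(rt1$rank_lower, 1:3)
  expect_equal(rt1$rank_upper, 1:3)
  # point ranks are always a permutation
  expect_setequal(rt1$rank, seq_len(nrow(rt1)))
})

test_that("total-daily gaps and correlation behave under exact relations", {
  ids <- sprintf("C%02d", 1:8)
  years <- c(2000, 2010)
  set.seed(26)
  mt <- matrix(runif(16, 20, 35), 8, 2, dimnames = list(ids, years))
  et <- fx_estimates(mt, years, outcome = "total")
  ed_same <- fx_estimates(mt, years, outcome = "daily")
  og <- outcome_gap(et, ed_same)
  expect_true(all(og$by_county_year$gap == 0))
  expect_equal(og$correlation, 1)
  ed_half <- fx_estimates(mt / 2, years, outcome = "daily")
  og2 <- outcome_gap(et, ed_half)
  expect_equal(og2$correlation, 1)
  expect_equal(og2$by_county_year$gap, og2$by_county_year$total / 2)
})
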