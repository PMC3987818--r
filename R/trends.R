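#' Annualized rate of change between two prevalence levels
#'
#' The constant per-year proportional change connecting two levels:
#' `100 * ((p_end / p_start)^(1 / (y_end - y_start)) - 1)`, in percent per
#' year (negative for declines). Geometric, so reversing the path inverts
#' the growth factor exactly.
#'
#' @param p_start,p_end Prevalence at the endpoints (any common positive
#'   scale).
#' @param y_start,y_end Endpoint years, `y_end > y_start`.
#' @return Rate(s) in percent per year.
#' @examples
#' annualized_rate(27.3, 22.2, 1996, 2012)  # about -1.3% per year
#' @export
annualized_rate <- function(p_start, p_end, y_start, y_end) {
  if (any(y_end <= y_start)) .stopf("y_end must exceed y_start")
  if (any(p_start <= 0) || any(p_end <= 0))
    .stopf("prevalence endpoints must be positive")
  100 * ((p_end / p_start)^(1 / (y_end - y_start)) - 1)
}

#' Classify trend significance from rate draws
#'
#' A county's decline (increase) is statistically significant when the 95%
#' draw interval of its annualized rate lies entirely below (above) zero:
#' significant decline iff the 97.5th percentile of the draws is negative,
#' significant increase iff the 2.5th percentile is positive. The flags are
#' mutually exclusive by construction.
#'
#' @param rate_draws Numeric vector of rate draws for one unit, or a matrix
#'   with one row per unit and one column per draw.
#' @param min_draws Minimum draws required.
#' @return data.frame: `rate_lower`, `rate_upper` (2.5/97.5 percentiles),
#'   `significant_decline`, `significant_increase`.
#' @export
classify_trend <- function(rate_draws, min_draws = 100L) {
  if (is.vector(rate_draws)) rate_draws <- matrix(rate_draws, nrow = 1)
  if (ncol(rate_draws) < min_draws)
    .stopf("need at least %d draws to classify significance", min_draws)
  qs <- t(apply(rate_draws, 1, stats::quantile, probs = c(.025, .975),
                names = FALSE))
  data.frame(rate_lower = qs[, 1], rate_upper = qs[, 2],
             significant_decline = qs[, 2] < 0,
             significant_increase = qs[, 1] > 0)
}

#' Per-county annualized trends with uncertainty
#'
#' Computes each county's annualized rate of change between two years from
#' an estimate table, draw-wise when draws are attached (rates are computed
#' within each draw, then summarized), so the significance flags follow the
#' draw-interval rule of [classify_trend()].
#'
#' @param estimates `sae_estimates` covering both years, with draws for
#'   significance.
#' @param y_start,y_end Endpoint years.
#' @return data.frame (`trend_result`): `county_id`, `sex`, `outcome`,
#'   `y_start`, `y_end`, `rate`, `rate_lower`, `rate_upper`,
#'   `significant_decline`, `significant_increase`.
#' @export
county_trends <- function(estimates, y_start, y_end) {
  e0 <- estimates[estimates$year == y_start, , drop = FALSE]
  e1 <- estimates[estimates$year == y_end, , drop = FALSE]
  if (!nrow(e0) || !nrow(e1)) .stopf("estimates do not cover both endpoint years")
  e1 <- e1[match(e0$county_id, e1$county_id), , drop = FALSE]
  out <- data.frame(county_id = e0$county_id, sex = e0$sex,
                    outcome = e0$outcome, y_start = y_start, y_end = y_end,
                    rate = annualized_rate(e0$mean, e1$mean, y_start, y_end),
                    stringsAsFactors = FALSE)
  dr <- attr(estimates, "draws")
  if (!is.null(dr)) {
    i <- match(out$county_id, dr$county_id)
    d0 <- dr$draws[i, match(y_start, dr$years), , drop = TRUE]
    d1 <- dr$draws[i, match(y_end, dr$years), , drop = TRUE]
    if (is.null(dim(d0))) { d0 <- matrix(d0, nrow = 1); d1 <- matrix(d1, nrow = 1) }
    rates <- annualized_rate(d0, d1, y_start, y_end)
    out <- cbind(out, classify_trend(rates))
    # keep the point rate inside its draw interval for pathological skew
    out$rate <- .clamp(out$rate, out$rate_lower, out$rate_upper)
  }
  out
}

#' Within-state prevalence gaps
#'
#' For a given year, the gap between the highest- and lowest-prevalence
#' county within each state, with the counties attaining them, and the
#' median gap across states. States with a single estimated county are
#' skipped with a note.
#'
#' @param estimates `sae_estimates` (or any table with `county_id`, `year`,
#'   `mean`).
#' @param registry A `county_registry` supplying the county-state nesting.
#' @param year Year to evaluate.
#' @return List: `states` (per-state gap table), `median_gap`, `skipped`
#'   (single-county states).
#' @export
within_state_range <- function(estimates, registry, year) {
  e <- estimates[estimates$year == year, , drop = FALSE]
  if (!nrow(e)) .stopf("no estimates for year %d", year)
  st <- .registry_states(registry)
  e$state_id <- unname(st[e$county_id])
  sizes <- table(e$state_id)
  skipped <- names(sizes)[sizes < 2]
  e <- e[!(e$state_id %in% skipped), , drop = FALSE]
  if (length(skipped))
    message(sprintf("within_state_range: skipping %d single-county state(s)",
                    length(skipped)))
  sp <- split(e, e$state_id)
  states <- do.call(rbind, lapply(sp, function(g) {
    hi <- which.max(g$mean); lo <- which.min(g$mean)
    data.frame(state_id = g$state_id[1], gap = g$mean[hi] - g$mean[lo],
               county_max = g$county_id[hi], p_max = g$mean[hi],
               county_min = g$county_id[lo], p_min = g$mean[lo],
               stringsAsFactors = FALSE)
  }))
  rownames(states) <- NULL
  list(states = states, median_gap = stats::median(states$gap),
       skipped = skipped)
}

#' Male-female prevalence gap summary
#'
#' Per-county male minus female prevalence in a year, the share of counties
#' where males smoke more (strict inequality; ties do not count), the
#' median gap, and the Pearson correlation of male and female prevalence
#' across counties.
#'
#' @param est_male,est_female Estimate tables for the two sexes over the
#'   same counties.
#' @param year Year to evaluate.
#' @return List: `by_county` (gap table), `share_male_higher` (percent),
#'   `median_gap` (percentage points), `correlation`.
#' @export
sex_gap_summary <- function(est_male, est_female, year) {
  m <- est_male[est_male$year == year, , drop = FALSE]
  f <- est_female[est_female$year == year, , drop = FALSE]
  if (!setequal(m$county_id, f$county_id))
    .stopf("male and female estimates cover different counties")
  f <- f[match(m$county_id, f$county_id), , drop = FALSE]
  gap <- m$mean - f$mean
  list(by_county = data.frame(county_id = m$county_id, male = m$mean,
                              female = f$mean, gap = gap,
                              stringsAsFactors = FALSE),
       share_male_higher = 100 * mean(gap > 0),
       median_gap = stats::median(gap),
       correlation = stats::cor(m$mean, f$mean))
}

#' Prevalence and trend summaries by county income quintile
#'
#' Reproduces the income-disparity table: per quintile of base-year county
#' income, the median prevalence at the start and end years, the median
#' annualized rate of change, and the percentage of counties with
#' statistically significant declines.
#'
#' @param estimates `sae_estimates` covering the endpoint years.
#' @param quintiles Named vector from [assign_income_quintiles()].
#' @param trends Per-county trend table from [county_trends()].
#' @return data.frame with one row per quintile (1 = lowest income).
#' @export
quintile_table <- function(estimates, quintiles, trends) {
  y0 <- trends$y_start[1]; y1 <- trends$y_end[1]
  e0 <- estimates[estimates$year == y0, , drop = FALSE]
  e1 <- estimates[estimates$year == y1, , drop = FALSE]
  q <- quintiles[trends$county_id]
  if (anyNA(q)) .stopf("quintile mapping does not cover every county")
  p0 <- e0$mean[match(trends$county_id, e0$county_id)]
  p1 <- e1$mean[match(trends$county_id, e1$county_id)]
  out <- do.call(rbind, lapply(1:5, function(k) {
    i <- which(q == k)
    data.frame(quintile = k, n_counties = length(i),
               median_rate = stats::median(trends$rate[i]),
               median_prev_start = stats::median(p0[i]),
               median_prev_end = stats::median(p1[i]),
               pct_significant_decline =
                 if (length(i)) 100 * mean(trends$significant_decline[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Rank counties with rank uncertainty
#'
#' Point ranks order counties by point estimate, rank 1 = lowest
#' prevalence. The rank interval re-ranks counties within each simulation
#' draw and takes the 2.5th/97.5th percentiles of each county's rank
#' distribution (widened, if needed, to contain the point rank).
#'
#' @param estimates `sae_estimates` with draws.
#' @param year Year to rank.
#' @return data.frame (`rank_table`): `county_id`, `mean`, `rank`,
#'   `rank_lower`, `rank_upper`, sorted by rank.
#' @export
rank_counties <- function(estimates, year) {
  e <- estimates[estimates$year == year, , drop = FALSE]
  if (!nrow(e)) .stopf("no estimates for year %d", year)
  dr <- attr(estimates, "draws")
  if (is.null(dr)) .stopf("rank intervals need estimates carrying draws")
  i <- match(e$county_id, dr$county_id)
  d <- dr$draws[i, match(year, dr$years), , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, nrow = length(i))
  point_rank <- rank(e$mean, ties.method = "first")
  rk <- apply(d, 2, rank, ties.method = "first")
  lo <- apply(rk, 1, stats::quantile, probs = .025, type = 1, names = FALSE)
  hi <- apply(rk, 1, stats::quantile, probs = .975, type = 1, names = FALSE)
  out <- data.frame(county_id = e$county_id, mean = e$mean,
                    rank = as.integer(point_rank),
                    rank_lower = as.integer(pmin(lo, point_rank)),
                    rank_upper = as.integer(pmax(hi, point_rank)),
                    stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

#' Gap and correlation between total and daily smoking estimates
#'
#' Per county-year difference (total minus daily, percentage points) and
#' the Pearson correlation of the two series across county-years.
#'
#' @param total_est,daily_est Estimate tables over the same county-years.
#' @return List: `by_county_year`, `median_gap`, `correlation`.
#' @export
outcome_gap <- function(total_est, daily_est) {
  kt <- paste(total_est$county_id, total_est$year)
  kd <- paste(daily_est$county_id, daily_est$year)
  if (!setequal(kt, kd)) .stopf("total and daily estimates cover different county-years")
  daily <- daily_est$mean[match(kt, kd)]
  gap <- total_est$mean - daily
  list(by_county_year = data.frame(county_id = total_est$county_id,
                                   year = total_est$year,
                                   total = total_est$mean, daily = daily,
                                   gap = gap, stringsAsFactors = FALSE),
       median_gap = stats::median(gap),
       correlation = stats::cor(total_est$mean, daily))
}
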