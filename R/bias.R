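#' Linear ramp weight for the wireless-frame bias correction
#'
#' The landline-frame bias is assumed to have grown linearly from none in
#' `zero_year` (2000, when very few adults were wireless-only) to the level
#' measured in `full_year` (2011, the first combined-frame year): weight 0
#' at or before 2000, `(year - 2000) / 11` between, and 1 from 2011 on.
#'
#' @param year Calendar year(s).
#' @param zero_year,full_year Ramp anchors.
#' @return Numeric weight(s) in `[0, 1]`.
#' @export
ramp_weight <- function(year, zero_year = 2000, full_year = 2011) {
  .clamp((year - zero_year) / (full_year - zero_year), 0, 1)
}

#' Measure landline-frame bias from the overlap year
#'
#' Compares, county by county, the combined-frame model's standardized
#' estimates with the landline-frame model's for the overlap year (2011):
#' `bias = combined - landline`, in percentage points. When both estimate
#' sets carry draws the difference is taken draw-wise (paired by draw
#' index) so the bias has its own uncertainty.
#'
#' The raw per-county difference mixes the real coverage bias with the
#' sampling noise of two model fits, and the combined-frame model sees only
#' two years of data, so the noise can rival the bias itself. With
#' `smooth = "eb"` the county biases are shrunk toward their cross-county
#' mean by an empirical-Bayes factor estimated from the draws: each
#' county's measurement variance comes from its bias draws, the
#' between-county signal variance is the method-of-moments excess of the
#' observed spread over the measurement noise, and the shrinkage is applied
#' draw-wise so corrected intervals stay honest. Counties with noisy
#' measurements are pulled strongly to the common bias; genuine
#' between-county bias variation, when present, survives.
#'
#' @param est_combined `sae_estimates` from the combined-frame model
#'   (model B).
#' @param est_landline `sae_estimates` from the landline-frame model
#'   (model A), covering the same counties.
#' @param year Overlap year measured (2011).
#' @param smooth `"none"` for the raw per-county difference, `"eb"` for
#'   empirical-Bayes shrinkage across counties (needs draws on both inputs
#'   and at least 3 counties).
#' @return data.frame of class `bias_profile`: `county_id`, `sex`,
#'   `outcome`, `bias_2011` (percentage points), with draw matrix attribute
#'   `bias_draws` when available.
#' @export
measure_bias <- function(est_combined, est_landline, year = 2011,
                         smooth = c("none", "eb")) {
  smooth <- match.arg(smooth)
  a <- est_landline[est_landline$year == year, , drop = FALSE]
  b <- est_combined[est_combined$year == year, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) .stopf("estimates do not cover year %d", year)
  if (!setequal(a$county_id, b$county_id))
    .stopf("county sets differ between the two estimate sets")
  b <- b[match(a$county_id, b$county_id), , drop = FALSE]
  out <- data.frame(county_id = a$county_id, sex = a$sex, outcome = a$outcome,
                    bias_2011 = b$mean - a$mean, stringsAsFactors = FALSE)
  class(out) <- c("bias_profile", "data.frame")
  attr(out, "zero_year") <- 2000
  attr(out, "full_year") <- year
  da <- attr(est_landline, "draws"); db <- attr(est_combined, "draws")
  if (!is.null(da) && !is.null(db) && da$nsim == db$nsim) {
    ya <- match(year, da$years); yb <- match(year, db$years)
    ia <- match(out$county_id, da$county_id)
    ib <- match(out$county_id, db$county_id)
    attr(out, "bias_draws") <- db$draws[ib, yb, ] - da$draws[ia, ya, ]
  }
  if (smooth == "eb") {
    bd <- attr(out, "bias_draws")
    if (is.null(bd))
      .stopf("empirical-Bayes smoothing needs draws on both estimate sets")
    if (nrow(out) < 3)
      .stopf("empirical-Bayes smoothing needs at least 3 counties")
    se2 <- apply(bd, 1, stats::var)              # measurement variance
    tau2 <- max(0, stats::var(out$bias_2011) - mean(se2))
    lambda <- tau2 / (tau2 + se2)
    gbar <- mean(out$bias_2011)
    out$bias_2011 <- gbar + lambda * (out$bias_2011 - gbar)
    gdraw <- colMeans(bd)                         # global bias per draw
    attr(out, "bias_draws") <- t(gdraw + t(lambda * sweep(bd, 2, gdraw)))
    attr(out, "smooth") <- c(tau = sqrt(tau2), lambda_mean = mean(lambda))
  }
  out
}

#' Apply the linear ramp correction to landline-frame estimates
#'
#' Adds the ramped 2011 bias to a landline-frame estimate: no correction
#' through 2000, `bias * (year - 2000) / 11` for 2001-2010, the full bias
#' at 2011. Results are clamped to `[0, 100]` since the correction is
#' additive on the percentage scale.
#'
#' @param value Landline-frame standardized prevalence (percent).
#' @param bias_2011 Measured 2011 bias (percentage points).
#' @param year Calendar year(s), within the study window.
#' @param window Permitted year window.
#' @return Corrected prevalence (percent).
#' @export
apply_ramp <- function(value, bias_2011, year, window = c(1996, 2012)) {
  if (any(year < window[1] | year > window[2]))
    .stopf("year outside the study window %d-%d", window[1], window[2])
  .clamp(value + bias_2011 * ramp_weight(year), 0, 100)
}

#' Compose the final bias-corrected estimate series
#'
#' Assembles the published series from the two models per the composition
#' rule: 1996-2000 from the landline-frame model unchanged, 2001-2010 from
#' the landline-frame model plus the ramped bias, and 2011-2012 from the
#' combined-frame model. The ramp is applied draw-wise whenever the inputs
#' carry draws, so corrected intervals reflect bias uncertainty; summaries
#' (mean/lower/upper) are then recomputed from the corrected draws.
#'
#' @param est_landline `sae_estimates` from model A covering 1996-2010 (at
#'   least).
#' @param est_combined `sae_estimates` from model B covering 2011-2012.
#' @param bias A `bias_profile` from [measure_bias()].
#' @return `sae_estimates` covering the union of years, with a
#'   `corrected` logical column.
#' @export
correct_series <- function(est_landline, est_combined, bias) {
  stopifnot(inherits(bias, "bias_profile"))
  da <- attr(est_landline, "draws"); db <- attr(est_combined, "draws")
  bd <- attr(bias, "bias_draws")
  use_draws <- !is.null(da) && !is.null(db) && !is.null(bd) &&
    da$nsim == db$nsim
  years_a <- sort(unique(est_landline$year))
  years_a <- years_a[years_a <= 2010]
  years_b <- sort(unique(est_combined$year))
  years_b <- years_b[years_b >= 2011]
  ids <- sort(unique(est_landline$county_id))
  if (!setequal(ids, bias$county_id))
    .stopf("bias profile does not cover the estimate counties")

  if (use_draws) {
    years <- c(years_a, years_b)
    n_c <- length(ids)
    draws <- array(NA_real_, c(n_c, length(years), da$nsim),
                   dimnames = list(ids, years, NULL))
    ia <- match(ids, da$county_id); ibz <- match(ids, db$county_id)
    ibias <- match(ids, bias$county_id)
    for (yi in seq_along(years)) {
      y <- years[yi]
      if (y <= 2010) {
        base <- da$draws[ia, match(y, da$years), ]
        draws[, yi, ] <- .clamp(base + ramp_weight(y) * bd[ibias, , drop = FALSE],
                                0, 100)
      } else {
        draws[, yi, ] <- db$draws[ibz, match(y, db$years), ]
      }
    }
    dr <- structure(list(draws = draws, county_id = ids, years = years,
                         sex = est_landline$sex[1],
                         outcome = est_landline$outcome[1], nsim = da$nsim),
                    class = "sae_draws")
    out <- .summarize_draws(dr)
  } else {
    a <- est_landline[est_landline$year %in% years_a, , drop = FALSE]
    bmap <- stats::setNames(bias$bias_2011, bias$county_id)
    w <- ramp_weight(a$year)
    for (col in intersect(c("mean", "lower", "upper"), names(a)))
      a[[col]] <- .clamp(a[[col]] + w * bmap[a$county_id], 0, 100)
    out <- rbind(a, est_combined[est_combined$year %in% years_b,
                                 names(a), drop = FALSE])
    out <- out[order(out$county_id, out$year), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("sae_estimates", "data.frame")
  }
  out$corrected <- out$year >= 2001 & out$year <= 2010
  out$model <- ifelse(out$year >= 2011, "B", "A")
  out
}
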