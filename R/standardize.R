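#' Post-stratify cell probabilities to age-group prevalence
#'
#' Collapses cell-level probabilities to age-group prevalence per
#' county(-year) as the share-weighted mean over race, marital status and
#' education (and phone usage when present in both tables). Shares are
#' renormalized within each age group, so they need only be proportional
#' within a group.
#'
#' @param cell_probs data.frame with `county_id`, demographic cell columns
#'   and probability column `p` (optionally a `year` column, carried
#'   through). Output of [predict.sae_fit()].
#' @param cell_shares data.frame with `county_id`, cell columns and
#'   `share`, e.g. the `cell_shares` element of a `county_registry`.
#' @return data.frame: `county_id` (, `year`), `age_group`, `prevalence`
#'   (on the probability scale of `p`).
#' @export
poststratify <- function(cell_probs, cell_shares) {
  .check_cols(cell_probs, c("county_id", .cell_vars, "p"), "cell_probs")
  .check_cols(cell_shares, c("county_id", .cell_vars, "share"), "cell_shares")
  by_cols <- intersect(c("county_id", .cell_vars, "phone_usage"),
                       intersect(names(cell_probs), names(cell_shares)))
  merged <- merge(cell_probs, cell_shares, by = by_cols, sort = FALSE)
  if (nrow(merged) < nrow(cell_probs)) {
    anti <- !do.call(paste, cell_probs[by_cols]) %in%
      do.call(paste, cell_shares[by_cols])
    .stopf("no share available for %d cell(s), e.g.: %s",
           sum(anti),
           paste(utils::head(do.call(paste, cell_probs[anti, by_cols]), 3),
                 collapse = "; "))
  }
  grp_cols <- intersect(c("county_id", "year", "age_group"), names(merged))
  key <- do.call(paste, c(merged[grp_cols], sep = "\r"))
  num <- rowsum(merged$p * merged$share, key)
  den <- rowsum(merged$share, key)
  first <- merged[!duplicated(key), grp_cols, drop = FALSE]
  first <- first[match(rownames(num), key[!duplicated(key)]), , drop = FALSE]
  out <- data.frame(first, prevalence = as.vector(num / den),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[do.call(order, out[grp_cols]), , drop = FALSE]
}

#' Directly age-standardize age-group prevalence
#'
#' Weighted mean of age-specific prevalence with fixed standard-population
#' age weights, making counties and years comparable despite differing age
#' structures. Accepts either a long data.frame (grouped by any identifier
#' columns present) or a matrix of draws with one row per age group, in
#' which case standardization is applied draw-wise (column-wise).
#'
#' @param age_prev data.frame with `age_group` and `prevalence` columns
#'   (plus optional grouping columns such as `county_id`, `year`), or a
#'   numeric matrix with `rownames` in the age groups.
#' @param std_pop Standard population (`age_group`, `weight`).
#' @return For a data.frame input: a data.frame with one standardized
#'   `prevalence` per group. For a matrix: a numeric vector, one value per
#'   column (draw).
#' @export
age_standardize <- function(age_prev, std_pop = std_pop_us2000()) {
  .check_std_pop(std_pop)
  wts <- stats::setNames(std_pop$weight, as.character(std_pop$age_group))
  if (is.matrix(age_prev)) {
    if (is.null(rownames(age_prev)) ||
        !setequal(rownames(age_prev), names(wts)))
      .stopf("matrix rownames must be exactly the standard population's age groups")
    w <- wts[rownames(age_prev)]
    return(drop(crossprod(w, age_prev))[if (ncol(age_prev) > 1) TRUE else 1])
  }
  .check_cols(age_prev, c("age_group", "prevalence"), "age_prev")
  if (!all(as.character(age_prev$age_group) %in% names(wts)))
    .stopf("age groups in age_prev do not match the standard population")
  grp_cols <- setdiff(names(age_prev), c("age_group", "prevalence"))
  if (!length(grp_cols)) {
    if (!setequal(as.character(age_prev$age_group), names(wts)))
      .stopf("age_prev must cover every standard-population age group")
    return(sum(wts[as.character(age_prev$age_group)] * age_prev$prevalence))
  }
  key <- do.call(paste, c(age_prev[grp_cols], sep = "\r"))
  cover <- tapply(as.character(age_prev$age_group), key,
                  function(a) setequal(a, names(wts)))
  if (!all(cover))
    .stopf("some groups do not cover every age group of the standard population")
  val <- rowsum(wts[as.character(age_prev$age_group)] * age_prev$prevalence, key)
  first <- age_prev[!duplicated(key), grp_cols, drop = FALSE]
  first <- first[match(rownames(val), key[!duplicated(key)]), , drop = FALSE]
  data.frame(first, prevalence = as.vector(val), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cap daily draws at their paired total draws
#'
#' Separately fitted total and daily models do not guarantee daily <= total
#' estimate-wise. This optional post-hoc consistency step caps each daily
#' draw at the paired total draw (matched by county, year and draw index)
#' and re-summarizes.
#'
#' @param daily_est,total_est `sae_estimates` for the same counties, years
#'   and sex, both carrying draws.
#' @return The capped daily `sae_estimates`.
#' @export
cap_daily_at_total <- function(daily_est, total_est) {
  dd <- attr(daily_est, "draws"); dt <- attr(total_est, "draws")
  if (is.null(dd) || is.null(dt))
    .stopf("both estimate sets must carry draws")
  if (!identical(dd$county_id, dt$county_id) ||
      !identical(dd$years, dt$years) || dd$nsim != dt$nsim)
    .stopf("daily and total draws are not aligned")
  dd$draws <- pmin(dd$draws, dt$draws)
  .summarize_draws(dd)
}
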