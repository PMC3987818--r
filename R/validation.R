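#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements around the 45-degree line,
#' penalizing both dispersion and location shifts:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments. Unlike Pearson correlation, adding a constant
#' offset to one series lowers the CCC.
#'
#' @param x,y Paired numeric vectors of length >= 2.
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 2) .stopf("need at least 2 paired observations")
  if (anyNA(x) || anyNA(y)) .stopf("missing values in paired vectors")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0)
    .stopf("concordance undefined: both vectors are constant")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Root mean squared error of predictions
#'
#' `sqrt(mean((pred - obs)^2))`; with prevalence inputs in percent the
#' result is in percentage points.
#'
#' @param pred,obs Paired numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) .stopf("pred and obs must have equal length")
  sqrt(mean((pred - obs)^2))
}

#' Gold-standard direct county estimates from data-rich counties
#'
#' Selects counties whose pooled respondent count over the window reaches
#' `min_n` (the validation set) and computes for each a design-weighted,
#' age-standardized direct prevalence from the pooled microdata: weighted
#' prevalence within each age group, standardized with the same standard
#' population as the model pipeline so that model and gold standard are
#' compared like with like. An age group with no respondents in a county
#' inherits that county's overall weighted prevalence.
#'
#' @param md Microdata.
#' @param sex,outcome Stratum to evaluate.
#' @param window Pooling window (inclusive years).
#' @param min_n Minimum pooled respondents for inclusion; 900 pooled
#'   respondents is the default data-richness threshold.
#' @param std_pop Standard population.
#' @return data.frame: `county_id`, `n` (pooled respondents), `gold`
#'   (percent).
#' @export
build_gold_standard <- function(md, sex = "male", outcome = "total",
                                window = c(2006, 2010), min_n = 900,
                                std_pop = std_pop_us2000()) {
  .check_std_pop(std_pop)
  md <- .ensure_outcomes(md)
  md <- md[md$sex == sex & md$year >= window[1] & md$year <= window[2], ,
           drop = FALSE]
  counts <- table(md$county_id)
  keep <- names(counts)[counts >= min_n]
  if (!length(keep))
    .stopf("no county reaches %d pooled respondents in %d-%d; generate larger samples",
           min_n, window[1], window[2])
  md <- md[md$county_id %in% keep, , drop = FALSE]
  y <- md[[paste0(outcome, "_smoker")]]
  w <- md$design_weight
  key <- paste(md$county_id, md$age_group, sep = "\r")
  num <- rowsum(w * y, key); den <- rowsum(w, key)
  parts <- do.call(rbind, strsplit(rownames(num), "\r", fixed = TRUE))
  age_tab <- data.frame(county_id = parts[, 1], age_group = parts[, 2],
                        prevalence = as.vector(100 * num / den),
                        stringsAsFactors = FALSE)
  overall <- 100 * rowsum(w * y, md$county_id) / rowsum(w, md$county_id)
  full <- expand.grid(county_id = keep, age_group = .age_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- match(paste(full$county_id, full$age_group, sep = "\r"),
             paste(age_tab$county_id, age_tab$age_group, sep = "\r"))
  full$prevalence <- ifelse(is.na(m), overall[full$county_id, 1],
                            age_tab$prevalence[m])
  std <- age_standardize(full, std_pop)
  out <- data.frame(county_id = std$county_id,
                    n = as.integer(counts[std$county_id]),
                    gold = std$prevalence, stringsAsFactors = FALSE)
  out[order(out$county_id), , drop = FALSE]
}

#' Thin microdata to a fixed number of respondents per county-year
#'
#' Builds a "sampled-down" dataset: within each county-year of the
#' validation set, a simple random sample without replacement of
#' `n_per_year` respondents (all respondents are kept when fewer are
#' available). Counties outside the validation set are dropped.
#'
#' @param md Microdata.
#' @param n_per_year Target respondents per county-year.
#' @param counties Validation-set county ids.
#' @param seed Integer seed; the reduced dataset is reproducible.
#' @return Reduced microdata data.frame.
#' @export
sample_down <- function(md, n_per_year, counties, seed = 1L) {
  md <- md[md$county_id %in% counties, , drop = FALSE]
  .with_seed(seed, {
    key <- paste(md$county_id, md$year, sep = "\r")
    idx <- unlist(lapply(split(seq_len(nrow(md)), key), function(i) {
      if (length(i) <= n_per_year) i else sample(i, n_per_year)
    }), use.names = FALSE)
    out <- md[sort(idx), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Sample-down validation of candidate models
#'
#' The model-selection framework: compute gold-standard direct estimates
#' from data-rich counties, repeatedly thin the data to a handful of
#' respondents per county-year, refit every candidate model on each thinned
#' dataset, and score the model predictions against the gold standard with
#' Lin's CCC and RMSE. An `in_sample` row per model scores the fit on the
#' full data. The best model is the one with the highest mean CCC, with
#' mean RMSE breaking ties.
#'
#' Model predictions are compared to the gold standard as the mean of the
#' standardized point estimates over the pooling window. A failed fit is
#' recorded in the report (NA scores, note) rather than aborting the run.
#'
#' @param specs Named list of `sae_spec` objects (all for the same sex and
#'   outcome).
#' @param md Microdata.
#' @param registry A `county_registry`.
#' @param sizes Sample sizes (respondents per county-year) to evaluate.
#' @param n_replicates Thinning replicates per size (>= 1).
#' @param seed Integer seed driving all thinning.
#' @param window,min_n Gold-standard settings, see
#'   [build_gold_standard()].
#' @param std_pop Standard population.
#' @return List of class `validation_report`: `report` (one row per model x
#'   size x replicate), `summary` (per-model, per-size means), `gold`, and
#'   `selected` (the chosen model id).
#' @export
run_validation <- function(specs, md, registry, sizes = c(10, 50, 100),
                           n_replicates = 3L, seed = 1L,
                           window = c(2006, 2010), min_n = 900,
                           std_pop = std_pop_us2000()) {
  if (!length(specs)) .stopf("need at least one model spec")
  if (is.null(names(specs)) || any(names(specs) == ""))
    .stopf("specs must be a named list")
  if (n_replicates < 1) .stopf("n_replicates must be at least 1")
  if (!length(sizes)) .stopf("need at least one sample size")
  sexes <- unique(vapply(specs, `[[`, "", "sex"))
  outcomes <- unique(vapply(specs, `[[`, "", "outcome"))
  if (length(sexes) > 1 || length(outcomes) > 1)
    .stopf("all specs must share one sex and one outcome")
  md <- .ensure_outcomes(md)
  gold <- build_gold_standard(md, sex = sexes, outcome = outcomes,
                              window = window, min_n = min_n,
                              std_pop = std_pop)
  vr <- registry$counties$county_id %in% gold$county_id
  vreg <- county_registry(registry$counties[vr, , drop = FALSE],
                          registry$cell_shares[
                            registry$cell_shares$county_id %in%
                              gold$county_id, , drop = FALSE])
  years <- window[1]:window[2]

  score_fit <- function(spec, data) {
    fit <- sae_fit(data, spec)
    pe <- sae_point_estimates(fit, vreg, years, std_pop = std_pop)
    pred <- tapply(pe$mean, pe$county_id, mean)[gold$county_id]
    c(ccc = lin_ccc(pred, gold$gold), rmse = rmse(pred, gold$gold))
  }

  rows <- list()
  for (sz in sizes) for (r in seq_len(n_replicates)) {
    s <- .child_seed(seed, sz, r)
    thin <- sample_down(md[md$year %in% years, , drop = FALSE], sz,
                        gold$county_id, seed = s)
    for (mid in names(specs)) {
      sc <- tryCatch(score_fit(specs[[mid]], thin), error = function(e)
        c(ccc = NA_real_, rmse = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = mid, sample_size = as.character(sz), replicate = r,
        seed = s, ccc = sc[["ccc"]], rmse = sc[["rmse"]],
        n_counties = nrow(gold),
        note = if (anyNA(sc)) "fit failed" else "",
        stringsAsFactors = FALSE)
    }
  }
  full <- md[md$year %in% years & md$county_id %in% gold$county_id, ,
             drop = FALSE]
  for (mid in names(specs)) {
    sc <- tryCatch(score_fit(specs[[mid]], full), error = function(e)
      c(ccc = NA_real_, rmse = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = mid, sample_size = "in_sample", replicate = 1L,
      seed = NA_integer_, ccc = sc[["ccc"]], rmse = sc[["rmse"]],
      n_counties = nrow(gold),
      note = if (anyNA(sc)) "fit failed" else "", stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  smry <- stats::aggregate(report[c("ccc", "rmse")],
                           by = report[c("model_id", "sample_size")],
                           FUN = mean, na.rm = TRUE)
  by_model <- stats::aggregate(report[c("ccc", "rmse")],
                               by = report["model_id"], FUN = mean,
                               na.rm = TRUE)
  ord <- order(-by_model$ccc, by_model$rmse)
  structure(list(report = report, summary = smry, gold = gold,
                 by_model = by_model[ord, , drop = FALSE],
                 selected = by_model$model_id[ord][1]),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Sample-down validation over %d counties\n",
              x$report$n_counties[1]))
  s <- x$summary
  s$ccc <- round(s$ccc, 3); s$rmse <- round(s$rmse, 2)
  print(s, row.names = FALSE)
  cat(sprintf("Selected model: %s (highest mean CCC, RMSE tie-break)\n",
              x$selected))
  invisible(x)
}
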