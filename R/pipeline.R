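#' Configuration for an end-to-end estimation run
#'
#' Bundles the inputs, model specifications, and reproducibility settings
#' of a full run. Model A is the landline-frame model fit to landline and
#' dual respondents in all years; model B is the combined-frame model fit
#' to all respondents in 2011-2012 with a phone-usage term, as the frame
#' bias correction requires.
#'
#' @param md Microdata (or a CSV path read through [read_microdata()]).
#' @param registry A `county_registry` (or a directory for
#'   [read_registry()]).
#' @param phone_comp Year-by-age phone composition table for
#'   post-stratifying model B.
#' @param sexes,outcomes Strata to run.
#' @param years Estimation years.
#' @param n_draws Simulation draws per fit.
#' @param seed Master seed; all stage seeds derive from it.
#' @param std_pop Standard population.
#' @param random_slopes Random year slopes in model A.
#' @param method Fitting method for both models.
#' @param cap_daily Apply the post-hoc daily-at-total consistency cap
#'   (off by default; separately fitted models do not guarantee it).
#' @param out_dir Optional directory; when set, estimate tables, the bias
#'   profile, trend reports and a run manifest are written as CSV/JSON.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(md, registry, phone_comp,
                            sexes = "male", outcomes = "total",
                            years = 1996:2012, n_draws = 300L, seed = 1L,
                            std_pop = std_pop_us2000(),
                            random_slopes = TRUE,
                            method = "agq0",
                            cap_daily = FALSE, out_dir = NULL) {
  structure(list(md = md, registry = registry, phone_comp = phone_comp,
                 sexes = sexes, outcomes = outcomes, years = years,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 std_pop = std_pop, random_slopes = random_slopes,
                 method = method, cap_daily = cap_daily, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full small-area estimation pipeline
#'
#' Executes the end-to-end flow for each requested sex and outcome:
#' classify smoking status; fit the landline-frame model A (all years,
#' wireless-only respondents excluded) and the combined-frame model B
#' (2011-2012, all respondents, phone-usage term); simulate draws and
#' age-standardize both; measure the 2011 frame bias per county; compose
#' the final series (model A through 2000, ramp-corrected A for 2001-2010,
#' model B from 2011); and derive the trend reports. Every stage is seeded
#' from the master seed, so rerunning an identical configuration
#' reproduces every output bit-for-bit.
#'
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_result` with one entry per sex-outcome
#'   stratum (`fit_a`, `fit_b`, `estimates_a`, `estimates_b`, `bias`,
#'   `final`, `trends`, `within_state`, `quintile_table`, `ranks`) plus a
#'   run `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  md <- config$md
  registry <- config$registry
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(md)) md <- read_microdata(md, registry)
  md <- .ensure_outcomes(md)
  years <- config$years
  years_b <- years[years >= 2011]
  quintiles <- assign_income_quintiles(registry)
  t_start <- Sys.time()

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  strata <- list()
  for (sx in config$sexes) for (oc in config$outcomes) {
    key <- paste(sx, oc, sep = "_")
    spec_a <- sae_spec(outcome = oc, sex = sx, phone_usage = FALSE,
                       random_slopes = config$random_slopes,
                       method = config$method)
    spec_b <- sae_spec(outcome = oc, sex = sx, phone_usage = TRUE,
                       random_slopes = FALSE, years = years_b,
                       method = config$method)
    md_a <- md[md$phone_usage != "wireless_only", , drop = FALSE]
    fit_a <- run_stage(paste0("fit_A_", key), sae_fit(md_a, spec_a))
    fit_b <- run_stage(paste0("fit_B_", key),
                       sae_fit(md[md$year %in% years_b, , drop = FALSE],
                               spec_b))
    est_a <- run_stage(paste0("standardize_A_", key),
      sae_estimates(fit_a, registry, years, std_pop = config$std_pop,
                    n_draws = config$n_draws,
                    seed = .child_seed(config$seed, "A", sx, oc)))
    est_b <- run_stage(paste0("standardize_B_", key),
      sae_estimates(fit_b, registry, years_b, std_pop = config$std_pop,
                    n_draws = config$n_draws,
                    seed = .child_seed(config$seed, "B", sx, oc),
                    phone_comp = config$phone_comp))
    bias <- run_stage(paste0("bias_", key),
                      measure_bias(est_b, est_a, smooth = "eb"))
    final <- run_stage(paste0("compose_", key),
                       correct_series(est_a, est_b, bias))
    trends <- run_stage(paste0("trends_", key),
                        county_trends(final, min(years), max(years)))
    strata[[key]] <- list(
      fit_a = fit_a, fit_b = fit_b, estimates_a = est_a, estimates_b = est_b,
      bias = bias, final = final, trends = trends,
      within_state = within_state_range(final, registry, max(years)),
      quintile_table = quintile_table(final, quintiles, trends),
      ranks = rank_counties(final, max(years)))
  }

  if (config$cap_daily && all(c("total", "daily") %in% config$outcomes)) {
    for (sx in config$sexes) {
      kt <- paste(sx, "total", sep = "_"); kd <- paste(sx, "daily", sep = "_")
      strata[[kd]]$final <- cap_daily_at_total(strata[[kd]]$final,
                                               strata[[kt]]$final)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("smokesae")),
    seed = config$seed, n_draws = config$n_draws,
    years = range(years), sexes = config$sexes, outcomes = config$outcomes,
    n_counties = nrow(registry$counties),
    n_respondents = nrow(md),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t_start,
                                          units = "secs")), 1))
  out <- structure(list(strata = strata, manifest = manifest,
                        registry = registry),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline(out, config$out_dir)
  out
}

.write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (key in names(result$strata)) {
    s <- result$strata[[key]]
    utils::write.csv(as.data.frame(s$final),
                     file.path(dir, sprintf("estimates_%s.csv", key)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(s$bias),
                     file.path(dir, sprintf("bias_%s.csv", key)),
                     row.names = FALSE)
    utils::write.csv(s$trends, file.path(dir, sprintf("trends_%s.csv", key)),
                     row.names = FALSE)
    utils::write.csv(s$quintile_table,
                     file.path(dir, sprintf("quintiles_%s.csv", key)),
                     row.names = FALSE)
    utils::write.csv(s$ranks, file.path(dir, sprintf("ranks_%s.csv", key)),
                     row.names = FALSE)
  }
  writeLines(.to_json(result$manifest[c("package_version", "seed", "n_draws",
                                        "n_counties", "n_respondents")]),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("SAE pipeline run: %d counties, %s respondents, years %d-%d\n",
              m$n_counties, format(m$n_respondents, big.mark = ","),
              m$years[1], m$years[2]))
  for (key in names(x$strata)) {
    f <- x$strata[[key]]$final
    last <- f[f$year == max(f$year), ]
    cat(sprintf("  %s: median %d prevalence %.1f%% (IQR %.1f-%.1f); median 2011 bias %.2f pp\n",
                key, max(f$year), stats::median(last$mean),
                stats::quantile(last$mean, .25), stats::quantile(last$mean, .75),
                stats::median(x$strata[[key]]$bias$bias_2011)))
  }
  invisible(x)
}
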