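# Shared fixtures, built in code and cached across test files.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# tiny registry: 2 states x 3 counties, deterministic
fx_registry_small <- function() fx("registry_small", function()
  build_registry(2, 3, seed = 11))

# hand-built registry with uniform cell shares, for exact arithmetic
fx_registry_uniform <- function(n_states = 2, counties_per_state = 2) {
  grid <- smokesae:::.cell_grid()
  state_id <- sprintf("S%02d", seq_len(n_states))
  ids <- as.vector(outer(sprintf("C%02d", seq_len(counties_per_state)),
                         state_id, function(c, s) paste(s, c, sep = "-")))
  counties <- data.frame(county_id = ids,
                         state_id = rep(state_id, each = counties_per_state),
                         adult_population = 1000L,
                         income_1996 = seq(30000, by = 1000,
                                           length.out = length(ids)))
  shares <- do.call(rbind, lapply(ids, function(id)
    data.frame(county_id = id, grid, share = 1 / nrow(grid))))
  county_registry(counties, shares)
}

# small generated study shared by several files
fx_study_small <- function() fx("study_small", function() {
  reg <- build_registry(3, 4, seed = 21)
  surf <- true_prevalence_surface(truth_params(mean_n = 60), reg, seed = 22)
  md <- classify_smoking(sample_respondents(surf, seed = 23))
  list(registry = reg, surface = surf, md = md)
})

# microdata frame with given outcome pattern, single county/cell, for oracles
fx_flat_microdata <- function(n, n_smokers, county = "S01-C01",
                              state = "S01", year = 2004, sex = "male") {
  smoker <- seq_len(n) <= n_smokers
  data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    year = year, county_id = county, state_id = state, sex = sex,
    age_group = factor("35-44", levels = smokesae:::.age_levels),
    race = factor("white", levels = smokesae:::.race_levels),
    marital = factor("married", levels = smokesae:::.marital_levels),
    education = factor("hs_grad", levels = smokesae:::.edu_levels),
    phone_usage = factor("landline_only", levels = smokesae:::.phone_levels),
    design_weight = 1,
    ever_100 = factor(ifelse(smoker, "yes", "no"),
                      levels = smokesae:::.ever_levels),
    smoke_now = factor(ifelse(smoker, "every_day", "not_asked"),
                       levels = smokesae:::.now_levels),
    stringsAsFactors = FALSE)
}

# minimal sae_estimates object from a county x year matrix of means,
# optionally with synthetic draws (county x year x n)
fx_estimates <- function(means, years, sex = "male", outcome = "total",
                         draws = NULL) {
  ids <- rownames(means)
  out <- data.frame(county_id = rep(ids, times = length(years)),
                    year = rep(years, each = length(ids)),
                    sex = sex, outcome = outcome,
                    mean = as.vector(means),
                    lower = as.vector(means), upper = as.vector(means),
                    stringsAsFactors = FALSE)
  class(out) <- c("sae_estimates", "data.frame")
  if (!is.null(draws)) {
    attr(out, "draws") <- structure(
      list(draws = draws, county_id = ids, years = years, sex = sex,
           outcome = outcome, nsim = dim(draws)[3]),
      class = "sae_draws")
  }
  out
}
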