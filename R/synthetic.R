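#' Ground-truth parameters for the synthetic survey generator
#'
#' Defines the generative model behind the synthetic BRFSS-like microdata:
#' a logistic model for current total smoking with fixed demographic and
#' calendar-time effects, nested state and county random intercepts and
#' year slopes, direct phone-usage logit shifts (the uncaptured channel of
#' landline-frame bias), a conditional logistic model for daily smoking
#' given current smoking (which guarantees daily <= total in truth), a
#' phone-usage composition trajectory by year with an age tilt, and the
#' sampling-frame schedule (landline-only before 2011, combined landline +
#' cell from 2011 onward).
#'
#' Defaults emulate the 1996-2012 US study conditions: population-level
#' male total smoking in the mid-20s percent declining slowly
#' (logit-linear), strong education and
#' marital-status gradients, a wireless-only population share growing from
#' zero in 2000 to about one-third by 2012 concentrated among younger
#' adults, and a positive wireless-only smoking shift so that excluding the
#' wireless-only stratum biases landline-frame prevalence downward by
#' roughly one to two percentage points by 2011.
#'
#' @param years Study window.
#' @param intercept Logit of total-smoking prevalence in the reference cell
#'   (male, 18-24, white, married, less than high school, landline-only) at
#'   the centering year.
#' @param sex_effect,age,race,marital,education,phone Fixed-effect logit
#'   shifts; first level of each factor is the reference (effect 0).
#' @param year_slope Logit change per calendar year.
#' @param year_center Centering year for the time trend.
#' @param sd_state,sd_county,sd_state_slope,sd_county_slope Random-effect
#'   standard deviations (logit scale; slopes per year).
#' @param income_level_effect,income_trend_effect County intercept / year
#'   slope shift per standard deviation of log county income (negative:
#'   richer counties smoke less and decline faster). Set to 0 for a purely
#'   exchangeable county distribution.
#' @param daily Parameters of the daily-given-total logistic model.
#' @param wireless_2012 Wireless-only population share reached in 2012
#'   (linear from 0 in 2000).
#' @param wireless_age_tilt Odds multipliers on the wireless-only share by
#'   age group (young adults skew wireless-only).
#' @param mean_n Mean respondents per county-year (Poisson), emulating
#'   very uneven county samples.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(years = 1996:2012,
                         intercept = stats::qlogis(0.32),
                         sex_effect = c(male = 0, female = -0.30),
                         year_slope = -0.025,
                         year_center = 2004,
                         age = c(0, 0.10, 0.05, -0.05, -0.30, -0.90),
                         race = c(0, -0.05, 0.10),
                         marital = c(0, 0.40),
                         education = c(0, -0.35, -0.90),
                         phone = c(landline_only = 0, dual = 0.05,
                                   wireless_only = 0.25),
                         sd_state = 0.22, sd_county = 0.18,
                         sd_state_slope = 0.012, sd_county_slope = 0.008,
                         income_level_effect = -0.10,
                         income_trend_effect = -0.004,
                         daily = list(intercept = stats::qlogis(0.72),
                                      year_slope = -0.035,
                                      marital = c(0, 0.10),
                                      education = c(0, -0.15, -0.30)),
                         wireless_2012 = 0.34,
                         wireless_age_tilt = c(2.2, 1.8, 1.2, 0.8, 0.5, 0.3),
                         mean_n = 50) {
  sds <- c(sd_state, sd_county, sd_state_slope, sd_county_slope)
  if (any(sds < 0)) .stopf("random-effect SDs must be nonnegative")
  if (wireless_2012 < 0 || wireless_2012 > 1)
    .stopf("wireless_2012 must lie in [0, 1]")
  stopifnot(length(age) == 6, length(race) == 3, length(marital) == 2,
            length(education) == 3, length(phone) == 3)
  p <- list(years = years, intercept = intercept, sex_effect = sex_effect,
            year_slope = year_slope, year_center = year_center,
            age = stats::setNames(age, .age_levels),
            race = stats::setNames(race, .race_levels),
            marital = stats::setNames(marital, .marital_levels),
            education = stats::setNames(education, .edu_levels),
            phone = stats::setNames(as.numeric(phone), .phone_levels),
            sd_state = sd_state, sd_county = sd_county,
            sd_state_slope = sd_state_slope, sd_county_slope = sd_county_slope,
            income_level_effect = income_level_effect,
            income_trend_effect = income_trend_effect,
            daily = daily, wireless_2012 = wireless_2012,
            wireless_age_tilt = wireless_age_tilt, mean_n = mean_n)
  class(p) <- "truth_params"
  p
}

#' Phone-usage schedule implied by truth parameters
#'
#' National phone-usage composition by year: the wireless-only share is 0
#' through 2000 and grows linearly to `wireless_2012` in 2012 (nondecreasing
#' by construction); the dual landline+cell share grows linearly over the
#' window; landline-only is the remainder.
#'
#' @param params A `truth_params`.
#' @return data.frame with columns `year`, `landline_only`, `dual`,
#'   `wireless_only`, and the sampling `frame` for the year.
#' @export
phone_schedule <- function(params) {
  y <- params$years
  w <- ifelse(y <= 2000, 0, params$wireless_2012 * (y - 2000) / 12)
  w <- .clamp(w, 0, params$wireless_2012)
  d <- .clamp(0.05 + 0.40 * (y - min(y)) / max(1, diff(range(y))), 0, 1 - w)
  data.frame(year = y, landline_only = 1 - w - d, dual = d, wireless_only = w,
             frame = ifelse(y >= 2011, "combined", "landline"),
             stringsAsFactors = FALSE)
}

#' Phone-usage composition by year and age group
#'
#' Applies the age tilt to the national wireless-only share (odds
#' multipliers, young adults more likely wireless-only), renormalizing the
#' landline-only and dual shares proportionally. This is the composition
#' table used both by the generator and to post-stratify combined-frame
#' model predictions.
#'
#' @param params A `truth_params`.
#' @return data.frame: `year`, `age_group`, `landline_only`, `dual`,
#'   `wireless_only` (rows sum to 1).
#' @export
phone_composition <- function(params) {
  sched <- phone_schedule(params)
  out <- expand.grid(year = sched$year, age_group = .age_levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(out$year, sched$year)
  a <- match(out$age_group, .age_levels)
  w <- sched$wireless_only[i]
  odds <- ifelse(w >= 1, Inf, w / (1 - w)) * params$wireless_age_tilt[a]
  wa <- .clamp(odds / (1 + odds), 0, 0.95)
  scale <- ifelse(sched$wireless_only[i] < 1,
                  (1 - wa) / (1 - sched$wireless_only[i]), 0)
  out$landline_only <- sched$landline_only[i] * scale
  out$dual <- sched$dual[i] * scale
  out$wireless_only <- wa
  out$age_group <- factor(out$age_group, levels = .age_levels)
  out
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic county registry
#'
#' Builds a registry of `n_states * counties_per_state` counties with
#' log-normal adult populations and 1996 incomes (so income quintiles are
#' nondegenerate) and demographic cell shares formed as the product of
#' county-specific age, race, marital and education margins drawn from
#' Dirichlet distributions around national margins. The education margin is
#' given the widest between-county variation, mirroring the strong
#' county-composition differences that post-stratification exploits.
#'
#' @param n_states Number of states (>= 2).
#' @param counties_per_state Counties per state (>= 2).
#' @param seed Integer seed; the registry is deterministic given the seed.
#' @return A `county_registry`.
#' @export
build_registry <- function(n_states, counties_per_state, seed = 1L) {
  if (n_states < 2 || counties_per_state < 2)
    .stopf("need at least 2 states and 2 counties per state")
  .with_seed(seed, {
    state_id <- sprintf("S%02d", seq_len(n_states))
    counties <- expand.grid(j = seq_len(counties_per_state), state = state_id,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    county_id <- sprintf("%s-C%03d", counties$state, counties$j)
    n <- length(county_id)
    pop <- round(exp(stats::rnorm(n, log(5e4), 1.0)))
    income <- round(exp(stats::rnorm(n, log(40000), 0.35)))
    base <- list(age = c(.13, .19, .21, .18, .12, .17),
                 race = c(.75, .12, .13),
                 marital = c(.55, .45),
                 education = c(.15, .55, .30))
    conc <- list(age = 60, race = 25, marital = 40, education = 15)
    grid <- .cell_grid()
    shares <- vector("list", n)
    for (i in seq_len(n)) {
      m <- lapply(names(base), function(v) .rdirichlet1(base[[v]] * conc[[v]]))
      names(m) <- names(base)
      s <- m$age[as.integer(grid$age_group)] *
        m$race[as.integer(grid$race)] *
        m$marital[as.integer(grid$marital)] *
        m$education[as.integer(grid$education)]
      shares[[i]] <- data.frame(county_id = county_id[i], grid,
                                share = s / sum(s),
                                stringsAsFactors = FALSE)
    }
    county_registry(
      counties = data.frame(county_id = county_id, state_id = counties$state,
                            adult_population = pop, income_1996 = income,
                            stringsAsFactors = FALSE),
      cell_shares = do.call(rbind, shares))
  })
}

# fixed-effect linear predictor for total smoking on the demographic grid,
# excluding phone and random effects
.truth_eta_cells <- function(params, grid, sex, yc) {
  params$intercept + params$sex_effect[[sex]] + params$year_slope * yc +
    params$age[as.integer(grid$age_group)] +
    params$race[as.integer(grid$race)] +
    params$marital[as.integer(grid$marital)] +
    params$education[as.integer(grid$education)]
}

.truth_eta_daily <- function(params, grid, yc) {
  d <- params$daily
  d$intercept + d$year_slope * yc +
    d$marital[as.integer(grid$marital)] +
    d$education[as.integer(grid$education)]
}

#' Realize the true prevalence surface
#'
#' Draws the state and county random effects once (seeded) and computes the
#' true age-standardized county-year prevalence for both sexes and both
#' outcomes, marginalizing phone usage over the full-population composition
#' of [phone_composition()]. The stored surface is the gold truth that
#' parameter-recovery and bias-correction experiments compare against.
#'
#' @param params A `truth_params`.
#' @param registry A `county_registry`.
#' @param years Years to realize (default: the params window).
#' @param seed Integer seed for the random-effect realization.
#' @param std_pop Standard population for the true standardized series.
#' @return Object of class `truth_surface`: realized random effects, the
#'   standardized truth table (`county_id`, `year`, `sex`, `outcome`,
#'   `prevalence` in percent), and the generative inputs.
#' @export
true_prevalence_surface <- function(params, registry, years = params$years,
                                    seed = 1L, std_pop = std_pop_us2000()) {
  if (!all(years %in% params$years))
    .stopf("requested years outside the parameter schedule")
  .check_std_pop(std_pop)
  counties <- registry$counties
  states <- unique(counties$state_id)
  .with_seed(seed, {
    zinc <- as.numeric(scale(log(counties$income_1996)))
    if (anyNA(zinc)) zinc <- rep(0, nrow(counties))
    re_state <- data.frame(
      state_id = states,
      u0 = stats::rnorm(length(states), 0, params$sd_state),
      u1 = stats::rnorm(length(states), 0, params$sd_state_slope),
      stringsAsFactors = FALSE)
    re_county <- data.frame(
      county_id = counties$county_id,
      state_id = counties$state_id,
      u0 = stats::rnorm(nrow(counties), 0, params$sd_county) +
        params$income_level_effect * zinc,
      u1 = stats::rnorm(nrow(counties), 0, params$sd_county_slope) +
        params$income_trend_effect * zinc,
      stringsAsFactors = FALSE)
  })
  pc <- phone_composition(params)
  grid <- .cell_grid()
  w_list <- .county_cell_weights(registry, std_pop, grid)
  u0 <- re_county$u0 + re_state$u0[match(re_county$state_id, re_state$state_id)]
  u1 <- re_county$u1 + re_state$u1[match(re_county$state_id, re_state$state_id)]

  out <- vector("list", length(years) * 2L)
  k <- 0L
  for (sx in .sex_levels) for (yi in seq_along(years)) {
    y <- years[yi]; yc <- y - params$year_center
    eta0 <- .truth_eta_cells(params, grid, sx, yc)
    etad <- .truth_eta_daily(params, grid, yc)
    pmix <- pc[pc$year == y, ]
    pi_ph <- as.matrix(pmix[match(grid$age_group, pmix$age_group),
                            .phone_levels])
    # cell prob marginal over phone usage, per county offset
    p_tot <- matrix(0, nrow(grid), length(u0))
    for (ph in seq_along(.phone_levels)) {
      eta_ph <- eta0 + params$phone[ph]
      p_tot <- p_tot + pi_ph[, ph] * stats::plogis(outer(eta_ph, u0 + u1 * yc, "+"))
    }
    p_day <- p_tot * stats::plogis(etad)  # daily = total * Pr(daily | total)
    tot <- vapply(seq_along(u0), function(ci) sum(w_list[[ci]] * p_tot[, ci]),
                  numeric(1))
    day <- vapply(seq_along(u0), function(ci) sum(w_list[[ci]] * p_day[, ci]),
                  numeric(1))
    k <- k + 1L
    out[[k]] <- data.frame(county_id = re_county$county_id, year = y, sex = sx,
                           outcome = rep(c("total", "daily"),
                                         each = length(u0)),
                           prevalence = 100 * c(tot, day),
                           stringsAsFactors = FALSE)
  }
  structure(list(params = params, registry = registry, years = years,
                 re_state = re_state, re_county = re_county,
                 truth = do.call(rbind, out), phone_composition = pc,
                 std_pop = std_pop, seed = seed),
            class = "truth_surface")
}

#' @export
print.truth_surface <- function(x, ...) {
  cat(sprintf("True prevalence surface: %d counties x %d years\n",
              nrow(x$re_county), length(x$years)))
  m <- x$truth[x$truth$outcome == "total" & x$truth$sex == "male", "prevalence"]
  cat(sprintf("  male total smoking truth: median %.1f%% (range %.1f-%.1f)\n",
              stats::median(m), min(m), max(m)))
  invisible(x)
}

#' Sample synthetic survey respondents from a realized surface
#'
#' Draws respondents county-year by county-year: counts are Poisson around
#' `mean_n`, demographics follow the county's cell shares, and phone usage
#' follows the year/age composition. In landline-frame years (before 2011)
#' wireless-only adults cannot be sampled: phone usage is drawn conditional
#' on reachability and the design weight is the inverse inclusion
#' probability `1 / (1 - P(wireless-only | age, year))`. From 2011 onward
#' all three phone groups are sampled with weight 1. Smoking responses are
#' Bernoulli draws from the cell's true probability, with daily vs nondaily
#' resolved by the conditional daily-given-total model; nonsmokers split
#' between never (`ever_100 = no`) and former (`not_at_all`) responders.
#'
#' @param surface A `truth_surface`.
#' @param n_per_county_year Mean respondents per county-year (defaults to
#'   the generator parameter `mean_n`).
#' @param seed Integer seed; the sample is reproducible bit-for-bit.
#' @param years Years to sample (must be covered by the surface).
#' @return Microdata data.frame in the layout of [read_microdata()], with
#'   `state_id` attached and outcome columns from [classify_smoking()]
#'   available downstream.
#' @export
sample_respondents <- function(surface, n_per_county_year = NULL, seed = 1L,
                               years = surface$years) {
  if (!inherits(surface, "truth_surface")) .stopf("surface must be a truth_surface")
  if (!all(years %in% surface$years))
    .stopf("requested years are outside the realized surface")
  params <- surface$params
  if (is.null(n_per_county_year)) n_per_county_year <- params$mean_n
  registry <- surface$registry
  grid <- .cell_grid()
  ncell <- nrow(grid)
  pc <- surface$phone_composition
  sched <- phone_schedule(params)
  re_c <- surface$re_county
  re_s <- surface$re_state
  u0 <- re_c$u0 + re_s$u0[match(re_c$state_id, re_s$state_id)]
  u1 <- re_c$u1 + re_s$u1[match(re_c$state_id, re_s$state_id)]
  share_mat <- .county_share_matrix(registry, grid)  # ncell x ncounty

  .with_seed(seed, {
    pieces <- vector("list", nrow(re_c) * length(years))
    k <- 0L; idbase <- 0L
    for (yi in seq_along(years)) {
      y <- years[yi]; yc <- y - params$year_center
      landline_frame <- sched$frame[sched$year == y] == "landline"
      pmix <- pc[pc$year == y, ]
      pi_age <- as.matrix(pmix[match(.age_levels, pmix$age_group), .phone_levels])
      eta_by_sex <- lapply(.sex_levels, function(sx)
        .truth_eta_cells(params, grid, sx, yc))
      etad <- .truth_eta_daily(params, grid, yc)
      for (ci in seq_len(nrow(re_c))) {
        n <- stats::rpois(1L, n_per_county_year)
        if (n == 0L) next
        cell <- sample.int(ncell, n, replace = TRUE, prob = share_mat[, ci])
        sex <- sample(.sex_levels, n, replace = TRUE)
        agei <- as.integer(grid$age_group[cell])
        # phone usage given age/year, restricted to the frame
        pph <- pi_age[agei, , drop = FALSE]
        wt <- rep(1, n)
        if (landline_frame) {
          incl <- 1 - pph[, 3L]
          wt <- 1 / incl
          pph <- cbind(pph[, 1L] / incl, pph[, 2L] / incl, 0)
        }
        u <- stats::runif(n)
        phone <- ifelse(u < pph[, 1L], 1L,
                        ifelse(u < pph[, 1L] + pph[, 2L], 2L, 3L))
        eta <- ifelse(sex == "male", eta_by_sex[[1L]][cell],
                      eta_by_sex[[2L]][cell]) +
          params$phone[phone] + u0[ci] + u1[ci] * yc
        total <- stats::rbinom(n, 1L, stats::plogis(eta))
        daily <- total * stats::rbinom(n, 1L, stats::plogis(etad[cell]))
        ever_tried <- stats::runif(n) < 0.4  # former/experimenter share
        ever <- ifelse(total == 1L | ever_tried, "yes", "no")
        now <- ifelse(daily == 1L, "every_day",
                      ifelse(total == 1L, "some_days",
                             ifelse(ever == "yes", "not_at_all", "not_asked")))
        k <- k + 1L
        pieces[[k]] <- data.frame(
          respondent_id = sprintf("R%08d", idbase + seq_len(n)),
          year = y,
          county_id = re_c$county_id[ci],
          state_id = re_c$state_id[ci],
          sex = sex,
          age_group = as.character(grid$age_group[cell]),
          race = as.character(grid$race[cell]),
          marital = as.character(grid$marital[cell]),
          education = as.character(grid$education[cell]),
          phone_usage = .phone_levels[phone],
          design_weight = wt,
          ever_100 = ever,
          smoke_now = now,
          stringsAsFactors = FALSE)
        idbase <- idbase + n
      }
    }
    md <- do.call(rbind, pieces[seq_len(k)])
    lv <- smoke_levels()
    for (v in c("sex", "age_group", "race", "marital", "education",
                "phone_usage", "ever_100", "smoke_now"))
      md[[v]] <- .as_level_factor(md[[v]], lv[[v]])
    rownames(md) <- NULL
    md
  })
}

# ncell x ncounty matrix of demographic cell shares, rows ordered as grid
.county_share_matrix <- function(registry, grid = .cell_grid()) {
  cs <- registry$cell_shares
  key <- interaction(cs$age_group, cs$race, cs$marital, cs$education,
                     drop = FALSE)
  gkey <- interaction(grid$age_group, grid$race, grid$marital, grid$education,
                      drop = FALSE)
  ids <- registry$counties$county_id
  m <- matrix(0, nrow(grid), length(ids), dimnames = list(NULL, ids))
  idx <- cbind(match(key, gkey), match(cs$county_id, ids))
  m[idx] <- cs$share
  m
}

# per-county post-stratification weights on the demographic grid combining
# county cell shares with standard-population age weights:
# w_cell = std_w[age] * share_cell / share_age
.county_cell_weights <- function(registry, std_pop, grid = .cell_grid()) {
  sm <- .county_share_matrix(registry, grid)
  wstd <- std_pop$weight[match(grid$age_group, std_pop$age_group)]
  agei <- as.integer(grid$age_group)
  lapply(stats::setNames(seq_len(ncol(sm)), colnames(sm)), function(ci) {
    s <- sm[, ci]
    age_tot <- tapply(s, agei, sum)[agei]
    w <- ifelse(age_tot > 0, wstd * s / age_tot, 0)
    w
  })
}

#' Write a synthetic study to disk
#'
#' Persists the three artifacts of a generated study: the microdata CSV,
#' the standardized truth CSV, and a JSON dump of the generator parameters.
#'
#' @param surface A `truth_surface`.
#' @param md Microdata from [sample_respondents()].
#' @param dir Output directory.
#' @export
write_synthetic_study <- function(surface, md, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_microdata(md, file.path(dir, "microdata.csv"))
  utils::write.csv(surface$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_registry(surface$registry, file.path(dir, "registry"))
  p <- surface$params
  dump <- c(list(years = range(p$years)), p[c("intercept", "year_slope",
           "year_center", "sd_state", "sd_county", "sd_state_slope",
           "sd_county_slope", "wireless_2012", "mean_n")],
           list(seed = surface$seed))
  writeLines(.to_json(dump), file.path(dir, "params.json"))
  invisible(dir)
}

# minimal JSON writer for flat named lists (avoids a hard dependency)
.to_json <- function(x) {
  item <- function(v) {
    if (length(v) > 1) paste0("[", paste(unname(v), collapse = ", "), "]")
    else if (is.character(v)) paste0('"', v, '"')
    else format(v, digits = 12)
  }
  paste0("{\n", paste(sprintf('  "%s": %s', names(x),
                              vapply(x, item, character(1))),
                      collapse = ",\n"), "\n}")
}
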