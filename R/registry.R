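#' Construct a consistent-county registry
#'
#' The registry defines the county universe used throughout an analysis: the
#' county-to-state nesting, adult population sizes, per-county demographic
#' cell shares used for post-stratification, mean income in the base year
#' (used for quintile assignment), and a merge map resolving raw geography
#' codes to consistent county ids. Counties whose boundaries changed over a
#' study period are handled upstream by mapping all raw codes of a merged
#' unit to one consistent id.
#'
#' @param counties data.frame with columns `county_id`, `state_id`,
#'   `adult_population`, `income_1996`.
#' @param cell_shares data.frame with columns `county_id`, `age_group`,
#'   `race`, `marital`, `education`, `share`; shares must sum to 1 within
#'   each county (tolerance 1e-9).
#' @param merge_map data.frame with columns `raw_code`, `county_id` mapping
#'   raw geography codes to consistent county ids. Defaults to the identity
#'   map over `counties$county_id`.
#' @return An object of class `county_registry`.
#' @export
county_registry <- function(counties, cell_shares, merge_map = NULL) {
  .check_cols(counties, c("county_id", "state_id", "adult_population",
                          "income_1996"), "counties")
  .check_cols(cell_shares, c("county_id", .cell_vars, "share"), "cell_shares")
  counties$county_id <- as.character(counties$county_id)
  counties$state_id <- as.character(counties$state_id)
  if (anyDuplicated(counties$county_id))
    .stopf("duplicate county_id in counties table")
  cell_shares$county_id <- as.character(cell_shares$county_id)
  for (v in .cell_vars)
    cell_shares[[v]] <- .as_level_factor(cell_shares[[v]], smoke_levels()[[v]])
  if (anyNA(cell_shares[.cell_vars]))
    .stopf("cell_shares contains unrecognized demographic categories")
  tot <- tapply(cell_shares$share, cell_shares$county_id, sum)
  bad <- names(tot)[abs(tot - 1) > 1e-9]
  if (length(bad))
    .stopf("cell shares do not sum to 1 for county(s): %s",
           paste(utils::head(bad, 5), collapse = ", "))
  if (!setequal(unique(cell_shares$county_id), counties$county_id))
    .stopf("cell_shares counties do not match the counties table")
  if (is.null(merge_map))
    merge_map <- data.frame(raw_code = counties$county_id,
                            county_id = counties$county_id,
                            stringsAsFactors = FALSE)
  .check_cols(merge_map, c("raw_code", "county_id"), "merge_map")
  merge_map$raw_code <- as.character(merge_map$raw_code)
  merge_map$county_id <- as.character(merge_map$county_id)
  if (anyDuplicated(merge_map$raw_code))
    .stopf("merge_map maps some raw code to more than one county")
  if (!all(merge_map$county_id %in% counties$county_id))
    .stopf("merge_map refers to county ids absent from the registry")
  structure(list(counties = counties, cell_shares = cell_shares,
                 merge_map = merge_map),
            class = "county_registry")
}

#' @export
print.county_registry <- function(x, ...) {
  cat(sprintf("County registry: %d counties in %d states\n",
              nrow(x$counties), length(unique(x$counties$state_id))))
  cat(sprintf("  adult population: %s; mean 1996 income: %s\n",
              format(sum(x$counties$adult_population), big.mark = ","),
              format(round(mean(x$counties$income_1996)), big.mark = ",")))
  invisible(x)
}

.registry_states <- function(registry) {
  stats::setNames(registry$counties$state_id, registry$counties$county_id)
}

#' Assign counties to income quintiles
#'
#' Quintile cut points are the 20/40/60/80 percentiles of county mean income
#' in the base year; quintile 1 is the lowest-income fifth. A county whose
#' income ties a cut point is assigned to the lower quintile, which makes
#' the assignment deterministic and invariant to row order.
#'
#' @param registry A `county_registry`.
#' @return Named integer vector (county_id -> quintile 1..5).
#' @export
assign_income_quintiles <- function(registry) {
  inc <- registry$counties$income_1996
  id <- registry$counties$county_id
  if (anyNA(inc))
    .stopf("income_1996 missing for county(s): %s",
           paste(utils::head(id[is.na(inc)], 10), collapse = ", "))
  cuts <- stats::quantile(inc, probs = c(.2, .4, .6, .8), names = FALSE)
  q <- 1L + findInterval(inc, cuts, left.open = TRUE)
  stats::setNames(as.integer(q), id)
}

#' Standard population age weights (US 2000 census, adults)
#'
#' Adult (18+) age distribution of the 2000 US census over the six age
#' groups used in this package, for direct age standardization. Override by
#' supplying any table with the same shape to the standardization functions.
#'
#' @return data.frame with columns `age_group`, `weight` (weights sum to 1).
#' @export
std_pop_us2000 <- function() {
  pop <- c(27143454, 39891724, 45148527, 37677952, 24274684, 34991753)
  data.frame(age_group = factor(.age_levels, levels = .age_levels),
             weight = pop / sum(pop))
}

.check_std_pop <- function(std_pop) {
  .check_cols(std_pop, c("age_group", "weight"), "standard population")
  if (any(std_pop$weight < 0)) .stopf("standard population weights must be nonnegative")
  if (abs(sum(std_pop$weight) - 1) > 1e-9)
    .stopf("standard population weights must sum to 1")
  invisible(TRUE)
}

# ---- file interfaces ------------------------------------------------------
# All tables are comma-delimited UTF-8 with a header row; missing values are
# empty fields.

#' Read survey microdata with row-level validation
#'
#' Reads a respondent-per-row CSV, resolves raw geography codes through the
#' registry merge map, and validates every row against the record
#' invariants: recognized category levels, positive design weight, year
#' inside the study window, and consistency of the two smoking questions
#' (the follow-up question is `not_asked` exactly when the lifetime question
#' is `no`). Rows failing validation are dropped and reported via the
#' `rejects` attribute; a missing required column is a hard error.
#'
#' @param path CSV file path. Expected columns: `respondent_id`, `year`,
#'   `county_id` (raw geography code), `sex`, `age_group`, `race`,
#'   `marital`, `education`, `phone_usage`, `design_weight`, `ever_100`,
#'   `smoke_now`.
#' @param registry A `county_registry` used to resolve codes and attach
#'   `state_id`.
#' @param years Permitted calendar-year window.
#' @return data.frame of validated respondent records with attribute
#'   `rejects` (a data.frame of row numbers and reasons).
#' @export
read_microdata <- function(path, registry, years = 1996:2012) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("respondent_id", "year", "county_id", "sex", "age_group", "race",
           "marital", "education", "phone_usage", "design_weight",
           "ever_100", "smoke_now")
  .check_cols(raw, req, basename(path))
  validate_microdata(raw, registry, years = years)
}

#' Validate in-memory microdata against record invariants
#'
#' Same validation and merge-map resolution as [read_microdata()], applied
#' to a data.frame.
#'
#' @inheritParams read_microdata
#' @param md data.frame of raw respondent rows.
#' @return Validated data.frame with a `rejects` attribute.
#' @export
validate_microdata <- function(md, registry, years = 1996:2012) {
  n <- nrow(md)
  reason <- character(n)
  lv <- smoke_levels()
  mm <- stats::setNames(registry$merge_map$county_id, registry$merge_map$raw_code)
  st <- .registry_states(registry)

  county <- unname(mm[as.character(md$county_id)])
  year <- suppressWarnings(as.integer(md$year))
  wt <- suppressWarnings(as.numeric(md$design_weight))
  flag <- function(bad, msg) reason[bad & reason == ""] <<- msg
  flag(is.na(county), "unresolvable county code")
  flag(is.na(year) | !(year %in% years), "year outside study window")
  flag(is.na(wt) | wt <= 0, "nonpositive design weight")
  for (v in c("sex", "age_group", "race", "marital", "education",
              "phone_usage", "ever_100", "smoke_now"))
    flag(!(as.character(md[[v]]) %in% lv[[v]]), sprintf("invalid %s", v))
  ever <- as.character(md$ever_100); now <- as.character(md$smoke_now)
  flag(reason == "" & ((ever == "no") != (now == "not_asked")),
       "inconsistent smoking responses")

  keep <- reason == ""
  out <- data.frame(
    respondent_id = as.character(md$respondent_id)[keep],
    year = year[keep],
    county_id = county[keep],
    state_id = unname(st[county[keep]]),
    sex = .as_level_factor(md$sex[keep], lv$sex),
    age_group = .as_level_factor(md$age_group[keep], lv$age_group),
    race = .as_level_factor(md$race[keep], lv$race),
    marital = .as_level_factor(md$marital[keep], lv$marital),
    education = .as_level_factor(md$education[keep], lv$education),
    phone_usage = .as_level_factor(md$phone_usage[keep], lv$phone_usage),
    design_weight = wt[keep],
    ever_100 = .as_level_factor(ever[keep], lv$ever_100),
    smoke_now = .as_level_factor(now[keep], lv$smoke_now),
    stringsAsFactors = FALSE)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(rejects))
    message(sprintf("validate_microdata: rejected %d of %d row(s)",
                    nrow(rejects), n))
  attr(out, "rejects") <- rejects
  out
}

#' Write survey microdata to CSV
#'
#' Writes with full floating-point precision on `design_weight` so that a
#' write/read round trip reproduces records exactly.
#'
#' @param md Microdata data.frame.
#' @param path Output CSV path.
#' @export
write_microdata <- function(md, path) {
  out <- md
  out$state_id <- NULL  # derived through the registry on read
  out$design_weight <- sprintf("%.17g", md$design_weight)
  for (v in names(out)) if (is.factor(out[[v]])) out[[v]] <- as.character(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a county registry to a directory of CSV files
#' @param registry A `county_registry`.
#' @param dir Output directory (created if needed).
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cs <- registry$cell_shares
  cs$share <- sprintf("%.17g", cs$share)
  co <- registry$counties
  co$income_1996 <- sprintf("%.17g", co$income_1996)
  utils::write.csv(co, file.path(dir, "counties.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cs, file.path(dir, "cell_shares.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(registry$merge_map, file.path(dir, "merge_map.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a county registry written by [write_registry()]
#' @param dir Directory containing `counties.csv`, `cell_shares.csv`,
#'   `merge_map.csv`.
#' @return A `county_registry`.
#' @export
read_registry <- function(dir) {
  county_registry(
    counties = utils::read.csv(file.path(dir, "counties.csv"),
                               stringsAsFactors = FALSE),
    cell_shares = utils::read.csv(file.path(dir, "cell_shares.csv"),
                                  stringsAsFactors = FALSE),
    merge_map = utils::read.csv(file.path(dir, "merge_map.csv"),
                                colClasses = "character"))
}

#' Read a standard-population age-weight table
#' @param path CSV with columns `age_group`, `weight`.
#' @return data.frame with validated weights.
#' @export
read_standard_pop <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_std_pop(sp)
  sp$age_group <- .as_level_factor(sp$age_group, .age_levels)
  if (anyNA(sp$age_group)) .stopf("unrecognized age groups in %s", path)
  sp
}
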