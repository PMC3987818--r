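# Internal helpers shared across modules.

.sex_levels   <- c("male", "female")
.age_levels   <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65+")
.race_levels  <- c("white", "black", "other")
.marital_levels <- c("married", "not_married")
.edu_levels   <- c("less_hs", "hs_grad", "college")
.phone_levels <- c("landline_only", "dual", "wireless_only")
.ever_levels  <- c("yes", "no")
.now_levels   <- c("every_day", "some_days", "not_at_all", "not_asked")
.outcome_levels <- c("total", "daily")

#' Canonical category levels used throughout the package
#'
#' Returns the factor levels assumed for survey microdata columns: sex, the
#' six adult age groups, race, marital status, education, phone usage, the
#' two smoking questions, and the modelled outcomes.
#'
#' @return Named list of character vectors.
#' @export
smoke_levels <- function() {
  list(sex = .sex_levels, age_group = .age_levels, race = .race_levels,
       marital = .marital_levels, education = .edu_levels,
       phone_usage = .phone_levels, ever_100 = .ever_levels,
       smoke_now = .now_levels, outcome = .outcome_levels)
}

# demographic post-stratification cell grid (age x race x marital x education)
.cell_grid <- function() {
  g <- expand.grid(age_group = .age_levels, race = .race_levels,
                   marital = .marital_levels, education = .edu_levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in names(g)) g[[v]] <- factor(g[[v]], levels = smoke_levels()[[v]])
  g
}

.cell_vars <- c("age_group", "race", "marital", "education")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  invisible(TRUE)
}

.as_level_factor <- function(x, levels) factor(as.character(x), levels = levels)

# draws from N(mu, Sigma); tolerant of a semi-definite Sigma
.mvn_draws <- function(n, mu, Sigma) {
  p <- length(mu)
  if (p == 1L) return(matrix(mu + sqrt(max(Sigma[1], 0)) * stats::rnorm(n), 1L, n))
  L <- tryCatch(t(chol(Sigma)), error = function(e) {
    ee <- eigen(Sigma, symmetric = TRUE)
    ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), p)
  })
  mu + L %*% matrix(stats::rnorm(p * n), p, n)
}

# seeded evaluation that restores the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stopf("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed below 2^31 from a base seed and a stage label
.child_seed <- function(seed, ...) {
  ints <- vapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x)) else as.integer(x)
  }, integer(1))
  as.integer((as.numeric(seed) + sum(ints * seq_along(ints) * 10007)) %% 2147483647)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
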