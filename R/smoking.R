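#' Classify smoking status from the two survey questions
#'
#' Respondents are asked whether they have smoked at least 100 cigarettes in
#' their life and, if so, whether they now smoke every day, some days, or
#' not at all. This maps each valid response pattern to one of three
#' categories and derives the two binary outcomes modelled by the package:
#' current total smoking (nondaily or daily) and current daily smoking.
#'
#' * `no` to the lifetime question, or `not_at_all` now -> `nonsmoker`
#' * `some_days` now -> `nondaily` (total = 1, daily = 0)
#' * `every_day` now -> `daily` (total = 1, daily = 1)
#'
#' An inconsistent pattern (`not_asked` paired with `yes`, or a follow-up
#' answer paired with `no`) is an error; such rows should have been rejected
#' upstream by [validate_microdata()].
#'
#' @param x Either a microdata data.frame containing `ever_100` and
#'   `smoke_now` columns, or a vector of lifetime-question responses.
#' @param smoke_now Follow-up question responses, when `x` is a vector.
#' @return If `x` is a data.frame: `x` with `category`, `total_smoker` and
#'   `daily_smoker` columns appended. Otherwise a data.frame with those
#'   three columns.
#' @examples
#' classify_smoking("yes", "some_days")
#' @export
classify_smoking <- function(x, smoke_now = NULL) {
  if (is.data.frame(x)) {
    .check_cols(x, c("ever_100", "smoke_now"), "microdata")
    st <- classify_smoking(x$ever_100, x$smoke_now)
    x$category <- st$category
    x$total_smoker <- st$total_smoker
    x$daily_smoker <- st$daily_smoker
    return(x)
  }
  ever <- as.character(x); now <- as.character(smoke_now)
  if (length(ever) != length(now))
    .stopf("ever_100 and smoke_now must have equal length")
  if (!all(ever %in% .ever_levels) || !all(now %in% .now_levels))
    .stopf("unrecognized smoking response values")
  if (any((ever == "no") != (now == "not_asked")))
    .stopf("inconsistent response pattern: smoke_now must be 'not_asked' iff ever_100 is 'no'")
  category <- ifelse(now == "every_day", "daily",
              ifelse(now == "some_days", "nondaily", "nonsmoker"))
  data.frame(
    category = factor(category, levels = c("nonsmoker", "nondaily", "daily")),
    total_smoker = as.integer(category != "nonsmoker"),
    daily_smoker = as.integer(category == "daily"))
}

# ensure outcome columns exist on a microdata frame
.ensure_outcomes <- function(md) {
  if (!all(c("total_smoker", "daily_smoker") %in% names(md)))
    md <- classify_smoking(md)
  md
}
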