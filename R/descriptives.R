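#' Percentages from stratum counts
#'
#' `100 * count / total`, rounded half-up to one decimal — the rounding rule
#' that reproduces published Table-1-style percentages from their printed
#' counts.
#'
#' @param counts numeric vector of stratum counts (names preserved).
#' @return numeric vector of percentages to one decimal.
#' @export
stratum_percents <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  round_half_up(100 * counts / total, 1)
}

SEX_LEVELS <- c("female", "male", "unknown")
AGE_LEVELS <- c("<18", "18-65", ">=65", "unknown")
REPORTER_LEVELS <- c("health_professional", "non_health_professional",
                     "unknown")
REGION_LEVELS <- c("Europe", "NorthAmerica", "Asia", "Oceania",
                   "SouthAmerica", "Africa", "unknown")

# banding convention: <18 is age < 18; 18-65 is 18 <= age < 65; >=65 is
# age >= 65; missing age is its own stratum
age_band <- function(age_years) {
  out <- rep("unknown", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "<18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 65] <- "18-65"
  out[!is.na(age_years) & age_years >= 65] <- ">=65"
  out
}

#' Demographic summary of event cases
#'
#' Counts and percentages by one demographic dimension, including an
#' explicit `"unknown"` stratum. The caller restricts the case set to the
#' reports of interest first (typically those with [case_has_event()] true
#' for the seizure set).
#'
#' @param cs a `case_set` of the reports to summarize.
#' @param dimension one of `"sex"`, `"age_band"`, `"reporter"`, `"region"`.
#' @return tibble with columns `stratum`, `count`, `percent`; attributes
#'   `total` and `dimension`.
#' @export
summarize_cases <- function(cs, dimension = c("sex", "age_band", "reporter",
                                              "region")) {
  stopifnot(inherits(cs, "case_set"))
  dimension <- match.arg(dimension)
  if (!n_cases(cs)) stop("cannot summarize zero cases")
  values <- switch(dimension,
                   sex = cs$cases$sex,
                   age_band = age_band(cs$cases$age_years),
                   reporter = cs$cases$reporter,
                   region = cs$cases$region)
  levels <- switch(dimension,
                   sex = SEX_LEVELS, age_band = AGE_LEVELS,
                   reporter = REPORTER_LEVELS, region = REGION_LEVELS)
  counts <- table(factor(values, levels = levels))
  out <- tibble::tibble(
    stratum = names(counts),
    count = as.integer(counts),
    percent = stratum_percents(as.integer(counts))
  )
  attr(out, "total") <- n_cases(cs)
  attr(out, "dimension") <- dimension
  out
}

#' Constituent ratio of event reports within a drug's reports
#'
#' The percentage of one drug's reports that are the event of interest,
#' `100 * n_event / n_all`, rounded half-up to two decimals.
#'
#' @param n_event_reports event report count for the drug.
#' @param n_all_reports_for_drug all report count for the drug (> 0).
#' @return percentage to two decimals.
#' @export
constituent_ratio <- function(n_event_reports, n_all_reports_for_drug) {
  if (any(n_all_reports_for_drug <= 0)) stop("total report count must be > 0")
  if (any(n_event_reports < 0 | n_event_reports > n_all_reports_for_drug)) {
    stop("event count must lie in [0, total]")
  }
  round_half_up(100 * n_event_reports / n_all_reports_for_drug, 2)
}

#' Female-to-male reporting ratio
#'
#' @param n_female,n_male stratum counts; `n_male` must be positive.
#' @return ratio rounded half-up to two decimals.
#' @export
sex_ratio <- function(n_female, n_male) {
  if (any(n_male <= 0)) stop("male count must be positive")
  round_half_up(n_female / n_male, 2)
}

#' Render demographic summaries as Markdown
#'
#' @param summaries list of tibbles from [summarize_cases()].
#' @return character vector of Markdown lines.
#' @export
render_descriptives <- function(summaries) {
  lines <- character()
  for (s in summaries) {
    lines <- c(lines,
               paste0("## ", attr(s, "dimension"),
                      " (n = ", attr(s, "total"), ")"), "",
               "| stratum | count | percent |",
               "|---|---:|---:|",
               sprintf("| %s | %d | %.1f |", s$stratum, s$count, s$percent),
               "")
  }
  lines
}
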