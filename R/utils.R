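#' Round half away from zero
#'
#' Deterministic decimal rounding in which exact halves round up (away from
#' zero), as opposed to the IEEE round-half-even rule used by [base::round()].
#' All percentages and ratios reported by the descriptives functions use this
#' rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) is 2
#' round_half_up(8.7512, 1)  # 8.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# canonical form used for drug-name lookup: case-fold, strip punctuation,
# collapse runs of whitespace
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a file shipped with the package
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
pv_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pvscreen")))
  }
  path <- system.file("extdata", file, package = "pvscreen")
  if (!nzchar(path)) stop("no packaged data file called '", file, "'")
  path
}
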