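#' Which reports carry a drug
#'
#' A report carries the index drug when some drug entry has the given ATC
#' code in one of the accepted role codes. The default role filter is
#' `"PS"` (primary suspect only); widen to `c("PS","SS","C","I")` to count
#' any mention.
#'
#' @param cs a `case_set`.
#' @param drug a single ATC code.
#' @param roles accepted FAERS role codes.
#' @return logical vector aligned with `cs$cases` rows.
#' @export
case_has_drug <- function(cs, drug, roles = "PS") {
  stopifnot(inherits(cs, "case_set"), length(drug) == 1L)
  dr <- cs$drugs
  hit <- !is.na(dr$atc_code) & dr$atc_code == drug & dr$role %in% roles
  cs$cases$primary_id %in% dr$primary_id[hit]
}

#' Which reports carry an event from a term set
#'
#' A report has the event when its reported event PTs intersect the term
#' set's included PTs. Indication PTs are deliberately not consulted here:
#' an indication is why the drug was given, not an adverse event.
#'
#' @param cs a `case_set`.
#' @param term_set a [term_set()].
#' @return logical vector aligned with `cs$cases` rows.
#' @export
case_has_event <- function(cs, term_set) {
  stopifnot(inherits(cs, "case_set"), inherits(term_set, "term_set"))
  ev <- cs$events
  cs$cases$primary_id %in% ev$primary_id[ev$pt %in% term_set$included_pts]
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Counts deduplicated reports, classifying every report into exactly one
#' cell against the whole-database background: `a` drug and event, `b` drug
#' without event, `c` event without drug, `d` neither. The unit of counting
#' is the report, so a report with several qualifying event PTs still counts
#' once.
#'
#' @param cs a deduplicated `case_set`.
#' @param drug ATC code of the index drug.
#' @param term_set the event [term_set()].
#' @param roles accepted drug role codes (default primary suspect only).
#' @return an object of class `contingency_table` with fields `drug`,
#'   `term_set`, `a`, `b`, `c`, `d`, `n_total`.
#' @export
build_table <- function(cs, drug, term_set, roles = "PS") {
  if (!n_cases(cs)) stop("cannot build a contingency table from zero cases")
  hd <- case_has_drug(cs, drug, roles)
  he <- case_has_event(cs, term_set)
  t <- contingency_table(drug, term_set$name,
                         a = sum(hd & he), b = sum(hd & !he),
                         c = sum(!hd & he), d = sum(!hd & !he))
  stopifnot(t$n_total == n_cases(cs))
  t
}

#' Construct a contingency table from known cells
#'
#' @param drug ATC code.
#' @param term_set_name event set name.
#' @param a,b,c,d non-negative report counts.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(drug, term_set_name, a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be non-negative counts")
  }
  structure(list(drug = drug, term_set = term_set_name,
                 a = a, b = b, c = c, d = d, n_total = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> ", x$drug, " x ", x$term_set,
      ": a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      " (n=", x$n_total, ")\n", sep = "")
  invisible(x)
}
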