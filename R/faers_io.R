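#' File dialect for quarterly report tables
#'
#' FAERS-style quarterly ASCII tables are `$`-separated with a header line and
#' no quoting. The dialect object carries the separator so that test fixtures
#' can use tabs.
#'
#' @param sep single-character field separator.
#' @return an object of class `faers_dialect`.
#' @export
faers_dialect <- function(sep = "$") {
  stopifnot(is.character(sep), nchar(sep) == 1L)
  structure(list(sep = sep), class = "faers_dialect")
}

TABLE_KEYS <- c("primaryid", "caseid")

parse_delim_table <- function(path, table_name, dialect) {
  if (!file.exists(path)) stop(table_name, " file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(table_name, " file is empty: ", path)
  header <- tolower(strsplit(lines[1L], dialect$sep, fixed = TRUE)[[1L]])
  if (!all(TABLE_KEYS %in% header)) {
    stop(table_name, " header lacks required key field(s): ",
         paste(setdiff(TABLE_KEYS, header), collapse = ", "))
  }
  k <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, dialect$sep, fixed = TRUE)
  # trailing empty field is dropped by strsplit; pad rows one short whose
  # raw line ends with the separator
  short1 <- lengths(parts) == k - 1L & endsWith(body, dialect$sep)
  parts[short1] <- lapply(parts[short1], function(p) c(p, ""))
  ok <- lengths(parts) == k
  rejects <- tibble::tibble(
    table_name = rep(table_name, sum(!ok)),
    line = which(!ok) + 1L,
    n_fields = lengths(parts)[!ok],
    n_expected = rep(k, sum(!ok)),
    text = body[!ok]
  )
  m <- matrix(unlist(parts[ok], use.names = FALSE), ncol = k, byrow = TRUE)
  tab <- tibble::as_tibble(stats::setNames(
    lapply(seq_len(k), function(j) if (nrow(m)) m[, j] else character()),
    header
  ), .name_repair = "minimal")
  list(table = tab, rejects = rejects)
}

#' Read one quarter of report tables
#'
#' Parses the four delimited tables (DEMO, DRUG, REAC, INDI), one row per
#' record, first line a separated header. Rows whose field count differs from
#' the header are collected in a rejects table, never silently dropped; a
#' missing file or a header lacking the `primaryid`/`caseid` keys is fatal.
#'
#' @param demo_path,drug_path,reac_path,indi_path file paths.
#' @param dialect a [faers_dialect()].
#' @return an object of class `faers_quarter`: list with `tables` (named list
#'   of tibbles `DEMO`, `DRUG`, `REAC`, `INDI`, all columns character, names
#'   lower-cased) and `rejects` (one row per malformed line).
#' @export
read_quarter <- function(demo_path, drug_path, reac_path, indi_path,
                         dialect = faers_dialect()) {
  paths <- c(DEMO = demo_path, DRUG = drug_path, REAC = reac_path,
             INDI = indi_path)
  parsed <- lapply(names(paths), function(nm) {
    parse_delim_table(paths[[nm]], nm, dialect)
  })
  names(parsed) <- names(paths)
  structure(list(
    tables = lapply(parsed, `[[`, "table"),
    rejects = do.call(rbind, lapply(parsed, `[[`, "rejects"))
  ), class = "faers_quarter")
}

#' Build a quarter object from in-memory tables
#'
#' Used by the synthetic generator and by tests to exercise the assembly path
#' without touching disk. Column names are lower-cased and values coerced to
#' character; the key columns must be present.
#'
#' @param demo,drug,reac,indi data frames with at least `primaryid` and
#'   `caseid` columns.
#' @return a `faers_quarter` (with an empty rejects table).
#' @export
quarter_from_tables <- function(demo, drug, reac, indi) {
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, INDI = indi)
  tabs <- lapply(tabs, function(t) {
    t <- tibble::as_tibble(lapply(t, as.character))
    names(t) <- tolower(names(t))
    if (!all(TABLE_KEYS %in% names(t))) {
      stop("table lacks required key field(s)")
    }
    t
  })
  structure(list(tables = tabs,
                 rejects = tibble::tibble(table_name = character(),
                                          line = integer(),
                                          n_fields = integer(),
                                          n_expected = integer(),
                                          text = character())),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter>\n")
  for (nm in names(x$tables)) {
    cat("  ", nm, ": ", nrow(x$tables[[nm]]), " records\n", sep = "")
  }
  if (nrow(x$rejects)) cat("  rejects: ", nrow(x$rejects), " rows\n", sep = "")
  invisible(x)
}

#' Write a quarter to delimited files
#'
#' @param quarter a `faers_quarter` (or the `tables` list from one).
#' @param dir output directory (created if needed).
#' @param dialect a [faers_dialect()].
#' @return named character vector of the four file paths, invisibly.
#' @export
write_quarter <- function(quarter, dir, dialect = faers_dialect()) {
  tabs <- if (inherits(quarter, "faers_quarter")) quarter$tables else quarter
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, paste0(names(tabs), ".txt")),
                           names(tabs))
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    lines <- c(paste(names(t), collapse = dialect$sep),
               do.call(paste, c(unname(as.list(t)), sep = dialect$sep)))
    writeLines(lines, paths[[nm]])
  }
  invisible(paths)
}

## -- demographic decoding ---------------------------------------------------

decode_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x == "F"] <- "female"
  out[x == "M"] <- "male"
  out
}

decode_reporter <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("MD", "PH", "OT", "HP")] <- "health_professional"
  out[x %in% c("CN", "LW")] <- "non_health_professional"
  out
}

decode_region <- function(country, lookup) {
  country <- toupper(trimws(country))
  out <- unname(lookup[country])
  out[is.na(out)] <- "unknown"
  out
}

# age units: YR years, DEC decades, MON months, WK weeks, DY days
decode_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(age_cod))
  f <- rep(NA_real_, length(v))
  f[u == "YR" | u == ""] <- 1
  f[u == "DEC"] <- 10
  f[u == "MON"] <- 1 / 12
  f[u == "WK"] <- 1 / 52
  f[u == "DY"] <- 1 / 365.25
  out <- v * f
  out[!is.finite(out) | out < 0 | out >= 150] <- NA_real_
  out
}

#' Packaged country-to-region lookup
#'
#' Maps ISO-2 reporter country codes to the seven region strata used in the
#' demographic summaries (Europe, NorthAmerica, Asia, Oceania, SouthAmerica,
#' Africa, unknown). Countries absent from the lookup decode to `"unknown"`.
#'
#' @return named character vector, country code -> region.
#' @export
default_region_lookup <- function() {
  tab <- utils::read.delim(pv_extdata("country_region.tsv"),
                           colClasses = "character")
  stats::setNames(tab$region, toupper(tab$country))
}

## -- case assembly ----------------------------------------------------------

DRUG_ROLES <- c("PS", "SS", "C", "I")

new_case_set <- function(cases, drugs, events, indications, log = list()) {
  structure(list(cases = cases, drugs = drugs, events = events,
                 indications = indications, log = log),
            class = "case_set")
}

#' Construct a case set directly
#'
#' The canonical in-memory container for assembled safety reports: a
#' case-level table plus long tables of drug entries, event PTs and
#' indication PTs keyed by `primary_id`. Mostly useful for building small
#' fixtures; real data flows through [read_quarter()] and
#' [assemble_cases()].
#'
#' @param cases tibble with columns `primary_id`, `case_id`,
#'   `receipt_sequence`, `sex`, `age_years`, `reporter`, `region`.
#' @param drugs tibble with columns `primary_id`, `raw_name`, `role`,
#'   `atc_code`.
#' @param events tibble with columns `primary_id`, `pt`.
#' @param indications tibble with columns `primary_id`, `pt`; may be empty.
#' @return an object of class `case_set`.
#' @export
case_set <- function(cases, drugs, events,
                     indications = tibble::tibble(primary_id = character(),
                                                  pt = character())) {
  cases <- tibble::as_tibble(cases)
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  indications <- tibble::as_tibble(indications)
  stopifnot(
    all(c("primary_id", "case_id", "receipt_sequence") %in% names(cases)),
    all(c("primary_id", "raw_name", "role") %in% names(drugs)),
    all(c("primary_id", "pt") %in% names(events)),
    all(c("primary_id", "pt") %in% names(indications)),
    !anyDuplicated(cases$primary_id)
  )
  if (!"atc_code" %in% names(drugs)) drugs$atc_code <- NA_character_
  for (col in c("sex", "reporter", "region")) {
    if (!col %in% names(cases)) cases[[col]] <- "unknown"
  }
  if (!"age_years" %in% names(cases)) cases$age_years <- NA_real_
  new_case_set(cases, drugs, events, indications)
}

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set> ", nrow(x$cases), " reports (",
      length(unique(x$cases$case_id)), " distinct cases); ",
      nrow(x$drugs), " drug rows, ", nrow(x$events), " event rows, ",
      nrow(x$indications), " indication rows\n", sep = "")
  invisible(x)
}

#' Number of reports in a case set
#' @param cs a `case_set`.
#' @return integer count of report rows.
#' @export
n_cases <- function(cs) nrow(cs$cases)

#' Assemble per-report case records from a parsed quarter
#'
#' Joins DRUG/REAC/INDI rows onto DEMO by `primaryid`, decoding demographics:
#' sex F/M, reporter occupation codes (MD/PH/OT/HP professional, CN/LW
#' consumer/lawyer), country to region via the lookup, and age to years from
#' its unit code. Reports with no adverse-event row or no drug row are
#' excluded (counted in the log, not silently dropped); DRUG/REAC/INDI rows
#' whose `primaryid` has no DEMO row are orphans, likewise counted.
#'
#' @param quarter a `faers_quarter` from [read_quarter()] or
#'   [quarter_from_tables()].
#' @param dict optional [drug_dictionary()]; when given, drug rows get an
#'   `atc_code` via [normalize_drug()].
#' @param region_lookup named country-to-region vector; see
#'   [default_region_lookup()].
#' @return a `case_set`; `$log` holds the exclusion bookkeeping
#'   (`n_demo_rows`, `n_excluded_no_event`, `n_excluded_no_drug`,
#'   `n_orphan_rows`, `n_invalid_role_rows`, `n_rejected_lines`).
#' @export
assemble_cases <- function(quarter, dict = NULL,
                           region_lookup = default_region_lookup()) {
  stopifnot(inherits(quarter, "faers_quarter"))
  demo <- quarter$tables$DEMO
  if (!nrow(demo)) stop("DEMO table has no records")
  dup_demo <- duplicated(demo$primaryid)
  demo <- demo[!dup_demo, , drop = FALSE]

  col <- function(t, nm) if (nm %in% names(t)) t[[nm]] else rep("", nrow(t))
  cases <- tibble::tibble(
    primary_id = demo$primaryid,
    case_id = demo$caseid,
    receipt_sequence = {
      v <- suppressWarnings(as.integer(col(demo, "caseversion")))
      v[is.na(v)] <- 1L
      v
    },
    sex = decode_sex(col(demo, "sex")),
    age_years = decode_age(col(demo, "age"), col(demo, "age_cod")),
    reporter = decode_reporter(col(demo, "occp_cod")),
    region = decode_region(col(demo, "reporter_country"), region_lookup)
  )

  dr <- quarter$tables$DRUG
  drugs <- tibble::tibble(
    primary_id = dr$primaryid,
    raw_name = col(dr, "drugname"),
    role = toupper(trimws(col(dr, "role_cod")))
  )
  bad_role <- !drugs$role %in% DRUG_ROLES
  drugs <- drugs[!bad_role, , drop = FALSE]
  drugs$atc_code <- if (is.null(dict)) NA_character_ else
    normalize_drug(drugs$raw_name, dict)

  re <- quarter$tables$REAC
  events <- tibble::tibble(primary_id = re$primaryid, pt = col(re, "pt"))
  ind <- quarter$tables$INDI
  indications <- tibble::tibble(primary_id = ind$primaryid,
                                pt = col(ind, "indi_pt"))

  known <- cases$primary_id
  orphan <- sum(!drugs$primary_id %in% known) +
    sum(!events$primary_id %in% known) +
    sum(!indications$primary_id %in% known)
  drugs <- drugs[drugs$primary_id %in% known, , drop = FALSE]
  events <- events[events$primary_id %in% known, , drop = FALSE]
  indications <- indications[indications$primary_id %in% known, , drop = FALSE]

  has_event <- cases$primary_id %in% events$primary_id
  has_drug <- cases$primary_id %in% drugs$primary_id
  n_no_event <- sum(!has_event)
  n_no_drug <- sum(has_event & !has_drug)
  keep <- has_event & has_drug
  cases <- cases[keep, , drop = FALSE]
  drugs <- drugs[drugs$primary_id %in% cases$primary_id, , drop = FALSE]
  events <- events[events$primary_id %in% cases$primary_id, , drop = FALSE]
  indications <- indications[indications$primary_id %in% cases$primary_id, ,
                             drop = FALSE]

  new_case_set(cases, drugs, events, indications, log = list(
    n_demo_rows = nrow(quarter$tables$DEMO),
    n_duplicate_demo_rows = sum(dup_demo),
    n_excluded_no_event = n_no_event,
    n_excluded_no_drug = n_no_drug,
    n_orphan_rows = orphan,
    n_invalid_role_rows = sum(bad_role),
    n_rejected_lines = nrow(quarter$rejects)
  ))
}

#' Deduplicate reports to one per case
#'
#' Spontaneous-report streams carry multiple versions of the same case; the
#' analysis must count each case once. Per distinct `case_id` the report with
#' the highest `receipt_sequence` is kept (ties broken by the
#' lexicographically highest `primary_id`, so the rule is deterministic).
#' Output is sorted by `case_id`. Idempotent.
#'
#' @param cs a `case_set`.
#' @return a `case_set` with one report per case; `$log$n_duplicates_removed`
#'   records the removal count.
#' @export
deduplicate <- function(cs) {
  stopifnot(inherits(cs, "case_set"))
  d <- cs$cases
  if (!nrow(d)) return(cs)
  ord <- order(d$case_id, d$receipt_sequence, d$primary_id)
  keep_last <- !duplicated(d$case_id[ord], fromLast = TRUE)
  rows <- ord[keep_last]
  out <- subset_cases(cs, d$primary_id[rows])
  out$log <- c(cs$log,
               list(n_duplicates_removed = nrow(d) - length(rows)))
  out
}

#' Subset a case set
#'
#' @param cs a `case_set`.
#' @param keep either a logical vector over report rows or a character vector
#'   of `primary_id`s to retain.
#' @return the filtered `case_set` (log preserved).
#' @export
subset_cases <- function(cs, keep) {
  stopifnot(inherits(cs, "case_set"))
  ids <- if (is.logical(keep)) cs$cases$primary_id[keep] else as.character(keep)
  cases <- cs$cases[match(ids, cs$cases$primary_id), , drop = FALSE]
  new_case_set(
    cases,
    cs$drugs[cs$drugs$primary_id %in% ids, , drop = FALSE],
    cs$events[cs$events$primary_id %in% ids, , drop = FALSE],
    cs$indications[cs$indications$primary_id %in% ids, , drop = FALSE],
    log = cs$log
  )
}

## -- canonical case TSV -----------------------------------------------------

#' Write a case set to a one-row-per-report TSV
#'
#' List-valued fields (drug names/roles/ATC codes, event and indication PTs)
#' are `;`-joined in report order.
#'
#' @param cs a `case_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cases_tsv <- function(cs, path) {
  join <- function(tab, val, ids) {
    s <- split(tab[[val]], factor(tab$primary_id, levels = ids))
    vapply(s, function(z) paste(ifelse(is.na(z), "", z), collapse = ";"),
           character(1))
  }
  ids <- cs$cases$primary_id
  out <- cs$cases
  out$drug_names <- join(cs$drugs, "raw_name", ids)
  out$drug_roles <- join(cs$drugs, "role", ids)
  out$drug_atcs <- join(cs$drugs, "atc_code", ids)
  out$event_pts <- join(cs$events, "pt", ids)
  out$indication_pts <- join(cs$indications, "pt", ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a case set back from its TSV serialization
#'
#' @param path file written by [write_cases_tsv()].
#' @return a `case_set`.
#' @export
read_cases_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  unjoin <- function(col) {
    parts <- strsplit(col, ";", fixed = TRUE)
    parts <- lapply(parts, function(z) z[nzchar(z)])
    tibble::tibble(primary_id = rep(tab$primary_id, lengths(parts)),
                   pt = unlist(parts, use.names = FALSE) %||% character())
  }
  drugs <- tibble::tibble(
    primary_id = rep(tab$primary_id,
                     lengths(strsplit(tab$drug_names, ";", fixed = TRUE))),
    raw_name = unlist(strsplit(tab$drug_names, ";", fixed = TRUE)),
    role = unlist(strsplit(tab$drug_roles, ";", fixed = TRUE)),
    atc_code = {
      z <- unlist(strsplit(tab$drug_atcs, ";", fixed = TRUE))
      z[z == ""] <- NA_character_
      z
    }
  )
  case_set(
    cases = tibble::tibble(
      primary_id = tab$primary_id,
      case_id = tab$case_id,
      receipt_sequence = as.integer(tab$receipt_sequence),
      sex = tab$sex,
      age_years = suppressWarnings(as.numeric(tab$age_years)),
      reporter = tab$reporter,
      region = tab$region
    ),
    drugs = drugs,
    events = unjoin(tab$event_pts),
    indications = unjoin(tab$indication_pts)
  )
}
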