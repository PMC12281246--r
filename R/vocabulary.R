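#' Construct a drug dictionary
#'
#' A drug dictionary maps raw report drug names (after case-folding,
#' punctuation stripping and whitespace collapsing) to ATC codes within one
#' ATC class, plus a display label per code. Matching downstream is exact
#' after normalization; there is deliberately no fuzzy matching, so the
#' mapping is reproducible.
#'
#' @param raw_name character vector of verbatim drug names.
#' @param atc_code character vector of 7-character ATC codes, parallel to
#'   `raw_name`.
#' @param display_name display label per entry (the label of the first entry
#'   seen for each ATC code is kept).
#' @param atc_class_prefix required ATC prefix; entries outside the class are
#'   rejected (kept in the `rejected` attribute, not silently dropped).
#' @return an object of class `drug_dictionary` with fields `entries`
#'   (named character vector, normalized raw name -> ATC code),
#'   `atc_class_prefix`, and `drug_labels` (named by ATC code).
#' @export
drug_dictionary <- function(raw_name, atc_code, display_name = raw_name,
                            atc_class_prefix = "N06A") {
  stopifnot(length(raw_name) == length(atc_code),
            length(display_name) == length(raw_name))
  raw_name <- as.character(raw_name)
  atc_code <- toupper(trimws(as.character(atc_code)))
  display_name <- as.character(display_name)

  ok_atc <- nchar(atc_code) == 7L & startsWith(atc_code, atc_class_prefix)
  rejected <- tibble::tibble(raw_name = raw_name[!ok_atc],
                             atc_code = atc_code[!ok_atc])
  raw_name <- raw_name[ok_atc]; atc_code <- atc_code[ok_atc]
  display_name <- display_name[ok_atc]

  key <- normalize_name(raw_name)
  # the same raw name may legitimately repeat with the same code; conflicting
  # codes for one name make the mapping ambiguous and are fatal
  conflict <- tapply(atc_code, key, function(z) length(unique(z)) > 1L)
  if (any(conflict)) {
    stop("conflicting ATC codes for raw name(s): ",
         paste(names(conflict)[conflict], collapse = ", "))
  }
  first <- !duplicated(key)
  entries <- stats::setNames(atc_code[first], key[first])
  lab_first <- !duplicated(atc_code)
  labels <- stats::setNames(display_name[lab_first], atc_code[lab_first])

  structure(list(entries = entries,
                 atc_class_prefix = atc_class_prefix,
                 drug_labels = labels,
                 rejected = rejected),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("<drug_dictionary> class ", x$atc_class_prefix, ": ",
      length(unique(x$entries)), " ATC codes, ",
      length(x$entries), " name entries",
      if (nrow(x$rejected)) paste0(" (", nrow(x$rejected), " rejected)"),
      "\n", sep = "")
  invisible(x)
}

#' Load a drug dictionary from a TSV file
#'
#' The file must have columns `raw_name`, `atc_code`, `display_name`.
#' Rows whose ATC code falls outside `atc_class_prefix` are collected in the
#' `rejected` attribute of the result; duplicate raw names mapped to
#' conflicting codes are a fatal error.
#'
#' @param path TSV path.
#' @inheritParams drug_dictionary
#' @return a [drug_dictionary()].
#' @export
load_drug_dictionary <- function(path, atc_class_prefix = "N06A") {
  if (!file.exists(path)) stop("drug dictionary file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("raw_name", "atc_code", "display_name")
  if (!all(need %in% names(tab))) {
    stop("drug dictionary must have columns ", paste(need, collapse = ", "))
  }
  drug_dictionary(tab$raw_name, tab$atc_code, tab$display_name,
                  atc_class_prefix = atc_class_prefix)
}

#' Resolve raw drug names to ATC codes
#'
#' Exact lookup after name normalization (case, whitespace, punctuation).
#' Unmapped names give `NA`; no fuzzy matching is attempted.
#'
#' @param raw_name character vector of verbatim names.
#' @param dict a [drug_dictionary()].
#' @return character vector of ATC codes (`NA` where unmapped).
#' @export
normalize_drug <- function(raw_name, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  unname(dict$entries[normalize_name(raw_name)])
}

#' ATC codes covered by a dictionary
#' @param dict a [drug_dictionary()].
#' @return sorted character vector of distinct ATC codes.
#' @export
atc_codes <- function(dict) sort(unique(unname(dict$entries)))

#' Construct a preferred-term set
#'
#' A term set is a named set of MedDRA-style preferred-term (PT) codes with
#' explicit inclusion and exclusion lists, the shape of an SMQ after manual
#' curation (e.g. a seizure query narrowed by dropping terms that cannot be
#' drug-induced).
#'
#' @param name set name.
#' @param included_pts character vector of included PT codes (non-empty).
#' @param excluded_pts character vector of excluded PT codes; must be disjoint
#'   from `included_pts`.
#' @param smq_code optional source SMQ code.
#' @param pt_labels optional named character vector of display labels.
#' @return an object of class `term_set`.
#' @export
term_set <- function(name, included_pts, excluded_pts = character(),
                     smq_code = NULL, pt_labels = NULL) {
  included_pts <- unique(as.character(included_pts))
  excluded_pts <- unique(as.character(excluded_pts))
  if (!length(included_pts)) stop("term set '", name, "' has no included PTs")
  if (length(intersect(included_pts, excluded_pts))) {
    stop("term set '", name, "': inclusion and exclusion lists overlap")
  }
  structure(list(name = name, smq_code = smq_code,
                 included_pts = included_pts, excluded_pts = excluded_pts,
                 pt_labels = pt_labels),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", x$name,
      if (!is.null(x$smq_code)) paste0(" (SMQ ", x$smq_code, ")"),
      ": ", length(x$included_pts), " included / ",
      length(x$excluded_pts), " excluded PTs\n", sep = "")
  invisible(x)
}

#' Build a term set from a candidate list and exclusions
#'
#' Included PTs are the candidates minus the exclusions; exclusions not in the
#' candidate list are ignored for the inclusion arithmetic but retained in the
#' exclusion record.
#'
#' @param name set name.
#' @param candidate_pts candidate PT codes (e.g. the full SMQ).
#' @param exclusions PT codes to strike from the candidates.
#' @inheritParams term_set
#' @return a [term_set()]; attributes `n_candidates` and `n_excluded` record
#'   the arithmetic.
#' @export
build_term_set <- function(name, candidate_pts, exclusions = character(),
                           smq_code = NULL, pt_labels = NULL) {
  candidate_pts <- unique(as.character(candidate_pts))
  exclusions <- unique(as.character(exclusions))
  included <- setdiff(candidate_pts, exclusions)
  if (!length(included)) {
    stop("term set '", name, "': every candidate PT was excluded")
  }
  out <- term_set(name, included, intersect(exclusions, candidate_pts),
                  smq_code = smq_code, pt_labels = pt_labels)
  attr(out, "n_candidates") <- length(candidate_pts)
  attr(out, "n_excluded") <- length(intersect(exclusions, candidate_pts))
  out
}

#' Load term sets from a TSV file
#'
#' The file must have columns `set_name`, `pt_code`, `pt_label`, `status`
#' (`include`/`exclude`). All rows of a set are its candidate PTs; rows with
#' status `exclude` are struck.
#'
#' @param path TSV path.
#' @param set_name which set to load; default when the file holds exactly one.
#' @param smq_code optional source SMQ code to attach.
#' @return a [term_set()].
#' @export
load_term_set <- function(path, set_name = NULL, smq_code = NULL) {
  tab <- read_term_table(path)
  if (is.null(set_name)) {
    nm <- unique(tab$set_name)
    if (length(nm) != 1L) {
      stop("file defines ", length(nm), " sets; give set_name")
    }
    set_name <- nm
  }
  tab <- tab[tab$set_name == set_name, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for set '", set_name, "' in ", path)
  build_term_set(set_name,
                 candidate_pts = tab$pt_code,
                 exclusions = tab$pt_code[tab$status == "exclude"],
                 smq_code = smq_code,
                 pt_labels = stats::setNames(tab$pt_label, tab$pt_code))
}

read_term_table <- function(path) {
  if (!file.exists(path)) stop("term-set file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("set_name", "pt_code", "pt_label", "status")
  if (!all(need %in% names(tab))) {
    stop("term-set file must have columns ", paste(need, collapse = ", "))
  }
  bad <- !tab$status %in% c("include", "exclude")
  if (any(bad)) stop("invalid status values: ", paste(unique(tab$status[bad]), collapse = ", "))
  tab
}

#' Construct a confounder catalog
#'
#' A catalog is a named list of [term_set()]s, each describing one category of
#' co-existing conditions that can produce the event of interest regardless of
#' drug exposure (for seizures: prior seizure disorders, cerebral injuries,
#' CNS vascular disorders, brain tumours, CNS infections/inflammations).
#'
#' @param sets list of `term_set` objects.
#' @return an object of class `confounder_catalog`.
#' @export
confounder_catalog <- function(sets) {
  if (!length(sets) || !all(vapply(sets, inherits, logical(1), "term_set"))) {
    stop("catalog must be a non-empty list of term_set objects")
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  structure(sets, class = "confounder_catalog")
}

#' @export
print.confounder_catalog <- function(x, ...) {
  cat("<confounder_catalog> ", length(x), " categories:\n", sep = "")
  for (s in x) {
    cat("  ", s$name, ": ", length(s$included_pts), " PTs\n", sep = "")
  }
  invisible(x)
}

#' Load a confounder catalog from a TSV file
#'
#' Same column layout as [load_term_set()]; every distinct `set_name` becomes
#' one category.
#'
#' @param path TSV path.
#' @return a [confounder_catalog()].
#' @export
load_confounder_catalog <- function(path) {
  tab <- read_term_table(path)
  sets <- lapply(unique(tab$set_name), function(nm) {
    sub <- tab[tab$set_name == nm, , drop = FALSE]
    build_term_set(nm, sub$pt_code, sub$pt_code[sub$status == "exclude"],
                   pt_labels = stats::setNames(sub$pt_label, sub$pt_code))
  })
  confounder_catalog(sets)
}

#' Packaged antidepressant (ATC N06A) drug dictionary
#'
#' A 65-drug dictionary covering the WHO ATC N06A class, with a handful of
#' brand-name synonyms. Shipped as plain TSV under `extdata`.
#'
#' @return a [drug_dictionary()].
#' @export
antidepressant_dictionary <- function() {
  load_drug_dictionary(pv_extdata("antidepressants_n06a.tsv"))
}

#' Packaged seizure term-set skeleton
#'
#' MedDRA PT lists are licensed and cannot be redistributed, so the packaged
#' seizure query is a synthetic skeleton with the documented set sizes: 84
#' candidate PTs of which 43 are excluded as unequivocally not drug-induced,
#' leaving 41 included PTs. Placeholder codes are used except for the two
#' publicly documented exclusions, post-stroke seizure (10076981) and
#' post-traumatic epilepsy (10036312). Users with a MedDRA licence load their
#' own export through [load_term_set()].
#'
#' @return a [term_set()] named `"seizures"`.
#' @export
seizure_smq_skeleton <- function() {
  load_term_set(pv_extdata("seizure_smq_skeleton.tsv"), "seizures",
                smq_code = "10039911")
}

#' Packaged confounder catalog skeleton
#'
#' Five synthetic categories of seizure-prone co-existing conditions with the
#' documented sizes: prior seizure disorders (81 PTs), cerebral injuries (30),
#' CNS vascular disorders (215), brain tumours (115), CNS infections and
#' inflammations (181). Placeholder codes; see [seizure_smq_skeleton()].
#'
#' @return a [confounder_catalog()].
#' @export
confounder_catalog_skeleton <- function() {
  load_confounder_catalog(pv_extdata("confounder_catalog_skeleton.tsv"))
}
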