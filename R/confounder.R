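#' Flag reports carrying confounding co-existing conditions
#'
#' A report is flagged when any of its PTs — reported events or drug
#' indications — falls in any catalog category. Indications are consulted
#' because confounding-by-indication manifests exactly there: the drug was
#' prescribed for a condition that itself produces the event.
#'
#' @param cs a `case_set`.
#' @param catalog a [confounder_catalog()].
#' @return logical vector aligned with `cs$cases` rows.
#' @export
flag_confounded <- function(cs, catalog) {
  stopifnot(inherits(cs, "case_set"), inherits(catalog, "confounder_catalog"))
  pts <- unique(unlist(lapply(catalog, `[[`, "included_pts"),
                       use.names = FALSE))
  hit_ids <- unique(c(cs$events$primary_id[cs$events$pt %in% pts],
                      cs$indications$primary_id[cs$indications$pt %in% pts]))
  cs$cases$primary_id %in% hit_ids
}

#' Confounder-exclusion sensitivity reanalysis
#'
#' Re-runs the screen after removing every flagged report from the entire
#' analysis (all four cells, not only `a`: removing flagged reports from the
#' exposed cells alone would bias the background). A drug whose primary
#' signal disappears in the adjusted screen is demoted to `false_signal`;
#' one that keeps its signal is `robust_signal`; drugs that never signalled
#' are `no_primary_signal`.
#'
#' @param cs a deduplicated `case_set`.
#' @param dict a [drug_dictionary()].
#' @param term_set the event [term_set()].
#' @param catalog a [confounder_catalog()].
#' @inheritParams run_screen
#' @return tibble with one row per drug screened in the primary analysis
#'   (`a >= 1`): primary columns as in [run_screen()], companion
#'   `*_adjusted` columns, `excluded_cases` (flagged reports carrying the
#'   drug) and `verdict`. Attributes: `n_flagged`, `n_total_primary`,
#'   `n_total_adjusted`.
#' @export
reanalyze <- function(cs, dict, term_set, catalog, roles = "PS",
                      min_cases = 3, continuity = FALSE) {
  flagged <- flag_confounded(cs, catalog)
  if (all(flagged)) {
    stop("every report is flagged as confounded; nothing left to analyse ",
         "(catalog too broad for this stream?)")
  }
  primary <- run_screen(cs, dict, term_set, roles, min_cases, continuity)
  cs_adj <- subset_cases(cs, !flagged)
  adjusted <- run_screen(cs_adj, dict, term_set, roles, min_cases, continuity)

  idx <- match(primary$atc, adjusted$atc)
  pick <- function(col, default) {
    v <- adjusted[[col]][idx]
    v[is.na(idx)] <- default
    v
  }
  out <- primary
  out$a_adjusted <- pick("a", 0L)
  out$b_adjusted <- pick("b", NA_integer_)
  out$c_adjusted <- pick("c", NA_integer_)
  out$d_adjusted <- pick("d", NA_integer_)
  out$ror_adjusted <- pick("ror", NA_real_)
  out$ror_low_adjusted <- pick("ror_low", NA_real_)
  out$ror_high_adjusted <- pick("ror_high", NA_real_)
  out$ic_adjusted <- pick("ic", NA_real_)
  out$ic_low_adjusted <- pick("ic_low", NA_real_)
  out$ic_high_adjusted <- pick("ic_high", NA_real_)
  adj_signal <- pick("signal", FALSE)
  adj_signal[is.na(adj_signal)] <- FALSE
  out$signal_adjusted <- adj_signal

  # flagged reports carrying each drug in an accepted role
  dr <- cs$drugs
  dr <- dr[dr$role %in% roles & !is.na(dr$atc_code), , drop = FALSE]
  flagged_ids <- cs$cases$primary_id[flagged]
  dr_f <- dr[dr$primary_id %in% flagged_ids, , drop = FALSE]
  cnt <- table(dr_f$atc_code[!duplicated(paste(dr_f$atc_code,
                                               dr_f$primary_id))])
  out$excluded_cases <- as.integer(ifelse(is.na(cnt[out$atc]), 0L,
                                          cnt[out$atc]))

  out$verdict <- ifelse(!out$signal, "no_primary_signal",
                        ifelse(out$signal_adjusted, "robust_signal",
                               "false_signal"))
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "n_total_primary") <- n_cases(cs)
  attr(out, "n_total_adjusted") <- n_cases(cs_adj)
  attr(out, "zero_case_drugs") <- attr(primary, "zero_case_drugs")
  out
}

#' Write an adjusted-signal table to TSV
#'
#' @param adj result of [reanalyze()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjusted_signals <- function(adj, path) {
  out <- as.data.frame(adj)
  num <- grep("^(ror|ic)", names(out), value = TRUE)
  for (col in num) {
    out[[paste0(col, "_full")]] <- out[[col]]
    out[[col]] <- sprintf("%.2f", round_half_up(out[[col]], 2))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
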