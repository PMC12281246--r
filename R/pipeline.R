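#' Pipeline configuration
#'
#' One validated object drives the whole analysis: ingest, deduplication,
#' screening, confounder reanalysis and descriptives. Either the four
#' quarterly files or a previously written case TSV serve as input. All
#' referenced paths must exist at validation time, before any compute.
#'
#' @param out_dir output directory (created on run).
#' @param demo,drug,reac,indi quarterly file paths (all four, or none if
#'   `cases_tsv` is given).
#' @param cases_tsv optional pre-assembled case TSV from
#'   [write_cases_tsv()].
#' @param dictionary_path drug dictionary TSV.
#' @param term_set_path term-set TSV; `term_set_name` selects the set.
#' @param term_set_name name of the event term set.
#' @param confounder_path confounder catalog TSV.
#' @param sep field separator for the quarterly files.
#' @param roles accepted drug role codes.
#' @param min_cases minimum case count for the signal criterion (>= 1).
#' @param continuity continuity-correction flag.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            demo = NULL, drug = NULL, reac = NULL,
                            indi = NULL, cases_tsv = NULL,
                            dictionary_path = pv_extdata("antidepressants_n06a.tsv"),
                            term_set_path = pv_extdata("seizure_smq_skeleton.tsv"),
                            term_set_name = "seizures",
                            confounder_path = pv_extdata("confounder_catalog_skeleton.tsv"),
                            sep = "$", roles = "PS", min_cases = 3,
                            continuity = FALSE) {
  quarter_paths <- c(demo, drug, reac, indi)
  if (is.null(cases_tsv)) {
    if (length(quarter_paths) != 4L) {
      stop("give either all four quarterly files or cases_tsv")
    }
  }
  if (min_cases < 1) stop("min_cases must be >= 1")
  for (p in c(quarter_paths, cases_tsv, dictionary_path, term_set_path,
              confounder_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(out_dir = out_dir, demo = demo, drug = drug, reac = reac,
                 indi = indi, cases_tsv = cases_tsv,
                 dictionary_path = dictionary_path,
                 term_set_path = term_set_path,
                 term_set_name = term_set_name,
                 confounder_path = confounder_path,
                 sep = sep, roles = roles, min_cases = min_cases,
                 continuity = continuity),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full screening pipeline
#'
#' Ingest, assemble, deduplicate, screen, reanalyse for confounding, and
#' summarize — writing `cases.tsv`, `signals.tsv`, `signals_adjusted.tsv`,
#' `descriptives.md` and `run_log.json` (stage counts) to the output
#' directory. Identical inputs and configuration give identical outputs.
#'
#' @param config a `pipeline_config`, or the path to a YAML file for
#'   [load_pipeline_config()].
#' @return the run log (named list of stage counts), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  dict <- load_drug_dictionary(config$dictionary_path)
  set <- load_term_set(config$term_set_path, config$term_set_name)
  catalog <- load_confounder_catalog(config$confounder_path)

  if (!is.null(config$cases_tsv)) {
    cases <- read_cases_tsv(config$cases_tsv)
    ingest_log <- list(source = "cases_tsv")
  } else {
    quarter <- read_quarter(config$demo, config$drug, config$reac,
                            config$indi, faers_dialect(config$sep))
    assembled <- assemble_cases(quarter, dict = dict)
    cases <- deduplicate(assembled)
    ingest_log <- cases$log
  }
  write_cases_tsv(cases, file.path(config$out_dir, "cases.tsv"))

  screen <- run_screen(cases, dict, set, roles = config$roles,
                       min_cases = config$min_cases,
                       continuity = config$continuity)
  write_signals(screen, file.path(config$out_dir, "signals.tsv"))

  adjusted <- reanalyze(cases, dict, set, catalog, roles = config$roles,
                        min_cases = config$min_cases,
                        continuity = config$continuity)
  write_adjusted_signals(adjusted,
                         file.path(config$out_dir, "signals_adjusted.tsv"))

  event_cases <- subset_cases(cases, case_has_event(cases, set))
  summaries <- lapply(c("sex", "age_band", "reporter", "region"),
                      function(d) summarize_cases(event_cases, d))
  writeLines(render_descriptives(summaries),
             file.path(config$out_dir, "descriptives.md"))

  log <- c(ingest_log, list(
    n_cases_analyzed = n_cases(cases),
    n_event_cases = n_cases(event_cases),
    n_flagged_confounded = attr(adjusted, "n_flagged"),
    n_cases_adjusted = attr(adjusted, "n_total_adjusted"),
    n_drugs_screened = nrow(screen),
    n_signals = sum(screen$signal),
    n_robust_signals = sum(adjusted$verdict == "robust_signal"),
    n_false_signals = sum(adjusted$verdict == "false_signal")
  ))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}
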