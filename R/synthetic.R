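## Synthetic spontaneous-report generator with known ground truth.
##
## Every pipeline stage is testable against this generator: demographics are
## drawn from configurable strata, each report carries one primary-suspect
## drug from a background frequency table, the index event fires with
## probability p * lambda(drug), duplicate report versions share a case id,
## and a confounding-by-indication mechanism can inject a confounder
## indication PT together with an index event PT. The implied odds ratio per
## drug is available in closed form for recovery tests.

# Table-1-like stratum frequencies used as the default demographic mix
DEFAULT_SEX_PROBS <- c(female = 4028, male = 2263, unknown = 1102) / 7393
DEFAULT_AGE_PROBS <- c("<18" = 853, "18-65" = 3662, ">=65" = 799,
                       unknown = 2079) / 7393
DEFAULT_REPORTER_PROBS <- c(health_professional = 5172,
                            non_health_professional = 1933,
                            unknown = 288) / 7393
DEFAULT_REGION_PROBS <- c(Europe = 1583, NorthAmerica = 647, Asia = 169,
                          Oceania = 24, SouthAmerica = 8, Africa = 2,
                          unknown = 4960) / 7393

# default background reporting weights over the antidepressant class
# (normalized internally) and relative seizure reporting rates that emulate
# a landscape with one strong signal drug, several moderate ones and nulls
DEFAULT_DRUG_BACKGROUND <- c(
  N06AX12 = 0.055, N06AX21 = 0.110, N06AX16 = 0.080, N06AX11 = 0.035,
  N06AB10 = 0.060, N06AB03 = 0.050, N06AB04 = 0.050, N06AB06 = 0.100,
  N06AB05 = 0.050, N06AB08 = 0.020, N06AX26 = 0.025, N06AA09 = 0.030,
  N06AA10 = 0.020, N06AA04 = 0.010, N06AA02 = 0.010, N06AX05 = 0.060,
  N06AX22 = 0.030, N06AX23 = 0.040, N06AX24 = 0.020, N06AG02 = 0.010
)
DEFAULT_PLANTED_LAMBDA <- c(
  N06AX12 = 8.6, N06AA09 = 4.7, N06AA02 = 3.4, N06AX16 = 3.0,
  N06AX11 = 3.0, N06AA10 = 2.9, N06AA04 = 2.9, N06AB10 = 2.7,
  N06AB03 = 2.6, N06AB04 = 2.5, N06AX21 = 2.4, N06AB06 = 2.0,
  N06AX26 = 1.6, N06AB05 = 1.3
)

REGION_COUNTRIES <- list(
  Europe = c("DE", "FR", "GB", "IT", "ES"),
  NorthAmerica = c("US", "CA"),
  Asia = c("JP", "CN", "IN"),
  Oceania = c("AU", "NZ"),
  SouthAmerica = c("BR", "AR"),
  Africa = c("ZA", "NG"),
  unknown = ""
)

check_probs <- function(p, levels, what) {
  if (is.null(names(p)) || !all(names(p) %in% levels)) {
    stop(what, " must be named with strata among: ",
         paste(levels, collapse = ", "))
  }
  if (abs(sum(p) - 1) > 1e-9) stop(what, " must sum to 1")
  if (any(p < 0)) stop(what, " must be non-negative")
  p
}

#' Configuration for the synthetic report generator
#'
#' The defaults describe the reference simulation conditions: demographic
#' strata matching the Table-1-like mix, a 20-drug antidepressant background,
#' a 2% base probability that a report is an index (seizure) event, planted
#' relative reporting rates emulating one strong signal drug plus moderate
#' and null drugs, and a 10% duplicate-version rate.
#'
#' @param n_cases number of distinct cases to generate.
#' @param seed integer root seed; every draw derives from it.
#' @param sex_probs,age_band_probs,reporter_probs,region_probs named
#'   probability vectors over the demographic strata (must sum to 1).
#' @param drug_background named non-negative weights, ATC code ->
#'   background reporting frequency (normalized internally).
#' @param seizure_prob base probability `p` that a report is an index event;
#'   the per-drug probability is `p * lambda(drug)`.
#' @param planted_lambda named relative reporting rates per ATC code; drugs
#'   not named have `lambda = 1`. `p * lambda > 1` for any background drug
#'   is a configuration error.
#' @param duplicate_rate probability in `[0, 1)` that a case also emits an
#'   earlier report version sharing its case id.
#' @param confounded_pairs `NULL`, or a data frame with columns `atc`,
#'   `category`, `prob`: with probability `prob`, a report of that drug
#'   carries an indication PT from the named confounder category together
#'   with an index event PT.
#' @param term_set index-event [term_set()] whose included PTs are emitted.
#' @param catalog [confounder_catalog()] supplying confounder indication PTs.
#' @param dictionary [drug_dictionary()] supplying emitted drug names.
#' @param extra_event_prob probability of a second background (filler)
#'   event PT on a report; one filler PT is always present so every report
#'   has at least one adverse event.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 10000,
                             seed = 1,
                             sex_probs = DEFAULT_SEX_PROBS,
                             age_band_probs = DEFAULT_AGE_PROBS,
                             reporter_probs = DEFAULT_REPORTER_PROBS,
                             region_probs = DEFAULT_REGION_PROBS,
                             drug_background = DEFAULT_DRUG_BACKGROUND,
                             seizure_prob = 0.02,
                             planted_lambda = DEFAULT_PLANTED_LAMBDA,
                             duplicate_rate = 0.1,
                             confounded_pairs = NULL,
                             term_set = seizure_smq_skeleton(),
                             catalog = confounder_catalog_skeleton(),
                             dictionary = antidepressant_dictionary(),
                             extra_event_prob = 0.3) {
  stopifnot(n_cases >= 1, is.numeric(seed))
  check_probs(sex_probs, SEX_LEVELS, "sex_probs")
  check_probs(age_band_probs, AGE_LEVELS, "age_band_probs")
  check_probs(reporter_probs, REPORTER_LEVELS, "reporter_probs")
  check_probs(region_probs, REGION_LEVELS, "region_probs")
  if (is.null(names(drug_background)) || any(drug_background < 0) ||
      sum(drug_background) <= 0) {
    stop("drug_background must be named non-negative weights")
  }
  if (!all(names(drug_background) %in% atc_codes(dictionary))) {
    stop("drug_background names must be ATC codes in the dictionary")
  }
  if (any(!is.finite(planted_lambda)) || any(planted_lambda < 0)) {
    stop("planted lambda values must be finite and >= 0")
  }
  lam <- lambda_for(planted_lambda, names(drug_background))
  over <- seizure_prob * lam > 1
  if (any(over)) {
    stop("p * lambda exceeds 1 for: ",
         paste(names(drug_background)[over], collapse = ", "))
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("duplicate_rate must be in [0, 1)")
  }
  if (!is.null(confounded_pairs)) {
    confounded_pairs <- as.data.frame(confounded_pairs)
    need <- c("atc", "category", "prob")
    stopifnot(all(need %in% names(confounded_pairs)))
    if (!all(confounded_pairs$category %in% names(catalog))) {
      stop("unknown confounder category in confounded_pairs")
    }
    if (!all(confounded_pairs$atc %in% names(drug_background))) {
      stop("confounded_pairs atc must appear in drug_background")
    }
    stopifnot(all(confounded_pairs$prob >= 0 & confounded_pairs$prob < 1))
  }
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    sex_probs = sex_probs, age_band_probs = age_band_probs,
    reporter_probs = reporter_probs, region_probs = region_probs,
    drug_background = drug_background / sum(drug_background),
    seizure_prob = seizure_prob, planted_lambda = planted_lambda,
    duplicate_rate = duplicate_rate, confounded_pairs = confounded_pairs,
    term_set = term_set, catalog = catalog, dictionary = dictionary,
    extra_event_prob = extra_event_prob
  ), class = "synthetic_config")
}

lambda_for <- function(planted_lambda, atc) {
  lam <- rep(1, length(atc))
  names(lam) <- atc
  hit <- intersect(names(planted_lambda), atc)
  lam[hit] <- planted_lambda[hit]
  lam
}

# P(index event | drug), combining the planted rate with any
# confounding-by-indication mechanism attached to the drug
event_prob_given_drug <- function(config, atc) {
  lam <- lambda_for(config$planted_lambda, names(config$drug_background))
  p <- pmin(config$seizure_prob * lam[atc], 1)
  q_keep <- rep(1, length(atc))
  cp <- config$confounded_pairs
  if (!is.null(cp) && nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      hit <- atc == cp$atc[i]
      q_keep[hit] <- q_keep[hit] * (1 - cp$prob[i])
    }
  }
  unname(1 - (1 - p) * q_keep)
}

#' Expected 2x2 cell proportions implied by a configuration
#'
#' Closed-form cell probabilities for one drug against the background: each
#' case carries one primary-suspect drug `D` with the normalized background
#' weight, and is an index-event case with probability
#' `1 - (1 - min(p*lambda_D, 1)) * prod(1 - q_Dk)` over the drug's
#' confounded pairs.
#'
#' @param config a [synthetic_config()].
#' @param drug ATC code.
#' @return list with elements `a`, `b`, `c`, `d` (probabilities summing
#'   to 1) and `n` (`n_cases`).
#' @export
expected_cells <- function(config, drug) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$drug_background
  if (!drug %in% names(w)) stop("drug not in background: ", drug)
  s <- event_prob_given_drug(config, names(w))
  i <- match(drug, names(w))
  pa <- w[[i]] * s[i]
  pb <- w[[i]] * (1 - s[i])
  pc <- sum(w[-i] * s[-i])
  pd <- sum(w[-i] * (1 - s[-i]))
  list(a = pa, b = pb, c = pc, d = pd, n = config$n_cases)
}

#' Analytic expected reporting odds ratio
#'
#' The population odds ratio implied by the generative probabilities; the
#' estimand the screened ROR converges to. `lambda = 1` with no confounding
#' gives exactly 1; `lambda = 0` gives 0.
#'
#' @inheritParams expected_cells
#' @return a positive number (0 when the drug can never co-report the
#'   event).
#' @export
expected_ror <- function(config, drug) {
  p <- expected_cells(config, drug)
  if (p$a == 0) return(0)
  (p$a * p$d) / (p$b * p$c)
}

#' Generate a synthetic report stream
#'
#' Draws the full stream described by the configuration and returns the four
#' raw quarterly tables plus per-case ground truth. Fully reproducible: the
#' same configuration (including seed) yields identical tables.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `pv_simulation`: list with `tables` (DEMO,
#'   DRUG, REAC, INDI tibbles in the quarterly layout), `truth` (per-case
#'   tibble: `case_id`, `primary_id`, `atc`, `has_event`, `confounded`,
#'   `duplicate`), `expected` (per-drug analytic cells and odds ratio), and
#'   `config`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cases
  w <- config$drug_background
  atc <- sample(names(w), n, replace = TRUE, prob = w)
  lam <- lambda_for(config$planted_lambda, names(w))
  base_event <- unname(stats::runif(n) < pmin(config$seizure_prob * lam[atc], 1))

  conf_case <- integer(0)
  conf_pt <- character(0)
  confounded <- rep(FALSE, n)
  cp <- config$confounded_pairs
  if (!is.null(cp) && nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      hit <- which(atc == cp$atc[i] & stats::runif(n) < cp$prob[i])
      if (length(hit)) {
        cat_pts <- config$catalog[[cp$category[i]]]$included_pts
        conf_case <- c(conf_case, hit)
        conf_pt <- c(conf_pt, sample(cat_pts, length(hit), replace = TRUE))
        confounded[hit] <- TRUE
      }
    }
  }
  has_event <- base_event | confounded

  seiz_pts <- config$term_set$included_pts
  event_pt <- sample(seiz_pts, n, replace = TRUE)
  filler_pool <- filler_pts()
  filler1 <- sample(filler_pool, n, replace = TRUE)
  extra <- stats::runif(n) < config$extra_event_prob
  filler2 <- sample(filler_pool, n, replace = TRUE)
  indi_pool <- benign_indication_pts()
  indi1 <- sample(indi_pool, n, replace = TRUE)

  sex_b <- sample(SEX_LEVELS, n, replace = TRUE, prob = config$sex_probs)
  age_b <- sample(AGE_LEVELS, n, replace = TRUE,
                  prob = config$age_band_probs)
  rep_b <- sample(REPORTER_LEVELS, n, replace = TRUE,
                  prob = config$reporter_probs)
  reg_b <- sample(REGION_LEVELS, n, replace = TRUE,
                  prob = config$region_probs)

  age_val <- rep("", n)
  age_val[age_b == "<18"] <- sample(1:17, sum(age_b == "<18"), TRUE)
  age_val[age_b == "18-65"] <- sample(18:64, sum(age_b == "18-65"), TRUE)
  age_val[age_b == ">=65"] <- sample(65:90, sum(age_b == ">=65"), TRUE)
  age_cod <- ifelse(age_b == "unknown", "", "YR")
  sex_code <- c(female = "F", male = "M", unknown = "")[sex_b]
  occp <- c(health_professional = "MD", non_health_professional = "CN",
            unknown = "")[rep_b]
  country <- rep("", n)
  for (r in REGION_LEVELS) {
    idx <- which(reg_b == r)
    pool <- REGION_COUNTRIES[[r]]
    if (length(idx)) {
      country[idx] <- if (length(pool) == 1L) pool else
        sample(pool, length(idx), replace = TRUE)
    }
  }

  dup <- stats::runif(n) < config$duplicate_rate
  version <- ifelse(dup, 2L, 1L)
  case_id <- as.character(90000000L + seq_len(n))
  primary <- paste0(case_id, version)
  drug_label <- unname(config$dictionary$drug_labels[atc])

  demo <- tibble::tibble(
    primaryid = primary, caseid = case_id,
    caseversion = as.character(version), sex = unname(sex_code),
    age = age_val, age_cod = age_cod, occp_cod = unname(occp),
    reporter_country = unname(country)
  )
  drug <- tibble::tibble(primaryid = primary, caseid = case_id,
                         role_cod = "PS", drugname = drug_label)
  reac <- tibble::tibble(
    primaryid = c(primary, primary[extra], primary[has_event]),
    caseid = c(case_id, case_id[extra], case_id[has_event]),
    pt = c(filler1, filler2[extra], event_pt[has_event])
  )
  indi <- tibble::tibble(
    primaryid = c(primary, primary[conf_case]),
    caseid = c(case_id, case_id[conf_case]),
    indi_pt = c(indi1, conf_pt)
  )

  # earlier report versions: same case and drug, filler event only — a
  # stale draft that deduplication must discard in favour of the final one
  if (any(dup)) {
    early <- paste0(case_id[dup], "1")
    demo <- rbind(demo, tibble::tibble(
      primaryid = early, caseid = case_id[dup], caseversion = "1",
      sex = unname(sex_code[dup]), age = age_val[dup],
      age_cod = age_cod[dup], occp_cod = unname(occp[dup]),
      reporter_country = unname(country[dup])
    ))
    drug <- rbind(drug, tibble::tibble(primaryid = early,
                                       caseid = case_id[dup],
                                       role_cod = "PS",
                                       drugname = drug_label[dup]))
    reac <- rbind(reac, tibble::tibble(primaryid = early,
                                       caseid = case_id[dup],
                                       pt = filler1[dup]))
    indi <- rbind(indi, tibble::tibble(primaryid = early,
                                       caseid = case_id[dup],
                                       indi_pt = indi1[dup]))
  }

  truth <- tibble::tibble(
    case_id = case_id, primary_id = primary, atc = atc,
    has_event = has_event, confounded = confounded, duplicate = dup
  )
  expected <- tibble::tibble(
    atc = names(w),
    weight = unname(w),
    p_event_given_drug = event_prob_given_drug(config, names(w)),
    expected_ror = vapply(names(w), function(d) expected_ror(config, d),
                          numeric(1))
  )
  structure(list(tables = list(DEMO = demo, DRUG = drug, REAC = reac,
                               INDI = indi),
                 truth = truth, expected = expected, config = config),
            class = "pv_simulation")
}

#' @export
print.pv_simulation <- function(x, ...) {
  cat("<pv_simulation> ", x$config$n_cases, " cases (seed ",
      x$config$seed, "); ", sum(x$truth$has_event), " index-event cases, ",
      sum(x$truth$duplicate), " duplicated\n", sep = "")
  invisible(x)
}

# background (non-index) event PTs and benign indication PTs emitted by the
# generator; synthetic placeholder codes
filler_pts <- function() sprintf("9%07d", 9000001:9000020)
benign_indication_pts <- function() sprintf("9%07d", 9100001:9100010)

#' Write a simulated quarter to disk
#'
#' Emits the four quarterly files in the given dialect plus
#' `ground_truth.json` with the generator's bookkeeping (per-drug expected
#' cells and odds ratios, case counts).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @param dialect a [faers_dialect()].
#' @return list with `paths` (named file paths) and `sim` (the
#'   `pv_simulation`), invisibly.
#' @export
generate_quarter <- function(config, dir, dialect = faers_dialect()) {
  sim <- simulate_reports(config)
  paths <- write_quarter(sim$tables, dir, dialect)
  gt <- list(
    n_cases = config$n_cases,
    n_reports = nrow(sim$tables$DEMO),
    n_duplicates = sum(sim$truth$duplicate),
    n_event_cases = sum(sim$truth$has_event),
    n_confounded_cases = sum(sim$truth$confounded),
    expected = sim$expected
  )
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = c(paths, ground_truth = gt_path), sim = sim))
}

#' Assemble a simulation through the production ingest path
#'
#' Convenience wrapper: converts the simulated raw tables into a parsed
#' quarter, assembles cases with the simulation's own dictionary, and
#' deduplicates — exactly what [read_quarter()] plus [assemble_cases()] plus
#' [deduplicate()] do for files on disk, minus the round trip through text.
#'
#' @param sim a `pv_simulation`.
#' @return a deduplicated `case_set`.
#' @export
assemble_simulation <- function(sim) {
  stopifnot(inherits(sim, "pv_simulation"))
  q <- quarter_from_tables(sim$tables$DEMO, sim$tables$DRUG,
                           sim$tables$REAC, sim$tables$INDI)
  deduplicate(assemble_cases(q, dict = sim$config$dictionary))
}
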