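#' Reporting odds ratio with Wald confidence interval
#'
#' Vectorized workhorse for the ROR. The point estimate is the sample odds
#' ratio `(a/b)/(c/d)`; the interval is the Woolf/Wald interval on the log
#' scale, `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z = 1.96`
#' for a two-sided 95% interval. When any cell is zero the point estimate
#' follows the arithmetic (0 or Inf) and the interval bounds are `NA`; apply
#' a continuity correction upstream if finite bounds are needed.
#'
#' @param a,b,c,d numeric vectors of cell counts (recycled).
#' @param z normal quantile for the interval half-width.
#' @return data frame with columns `ror`, `ror_low`, `ror_high`.
#' @export
ror_wald <- function(a, b, c, d, z = 1.96) {
  ror <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  low <- exp(log(ror) - z * se)
  high <- exp(log(ror) + z * se)
  zero <- !(a > 0 & b > 0 & c > 0 & d > 0)
  low[zero] <- NA_real_
  high[zero] <- NA_real_
  data.frame(ror = ror, ror_low = low, ror_high = high)
}

#' Shrinkage information component
#'
#' The IC is a shrunk log2 observed/expected measure of drug-event
#' dependence: `IC = log2((a + 0.5) / (E + 0.5))` where `E` is the expected
#' count under independence. The 95% credibility bounds use the closed-form
#' approximations
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}` and
#' `IC975 = IC + 2.4 (a+0.5)^{-1/2} - 0.5 (a+0.5)^{-3/2}`.
#' The +0.5 shrinkage pulls small-count estimates toward zero; as `a` grows
#' at fixed observed/expected ratio the IC converges to `log2(O/E)`.
#'
#' @param a observed report count(s).
#' @param expected expected count(s) under independence.
#' @return data frame with columns `ic`, `ic_low`, `ic_high` (bits).
#' @export
ic_shrinkage <- function(a, expected) {
  s <- a + 0.5
  ic <- log2(s / (expected + 0.5))
  data.frame(ic = ic,
             ic_low = ic - 3.3 * s^-0.5 - 2 * s^-1.5,
             ic_high = ic + 2.4 * s^-0.5 - 0.5 * s^-1.5)
}

#' ROR for one contingency table
#'
#' @param t a `contingency_table`.
#' @param continuity apply the Haldane-Anscombe correction (+0.5 to every
#'   cell) when any cell is zero. Off by default: the signal criterion
#'   requires at least 3 cases anyway, so zero-cell pairs can never signal.
#' @return list with `ror`, `ror_low`, `ror_high`.
#' @export
compute_ror <- function(t, continuity = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (all(cells[2:4] == 0)) stop("malformed table: b, c and d are all zero")
  if (continuity && any(cells == 0)) cells <- cells + 0.5
  out <- ror_wald(cells[1], cells[2], cells[3], cells[4])
  list(ror = out$ror, ror_low = out$ror_low, ror_high = out$ror_high)
}

#' IC for one contingency table
#'
#' The expected count is `E = (a+b)(a+c)/n`, the product of the drug and
#' event report margins under independence.
#'
#' @param t a `contingency_table`.
#' @return list with `ic`, `ic_low`, `ic_high` (bits).
#' @export
compute_ic <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n_total <= 0) stop("malformed table: empty database")
  e <- (t$a + t$b) * (t$a + t$c) / t$n_total
  out <- ic_shrinkage(t$a, e)
  list(ic = out$ic, ic_low = out$ic_low, ic_high = out$ic_high)
}

#' Joint signal criterion
#'
#' A drug-event pair is a signal only when every component criterion holds
#' strictly: case count `a >= min_cases`, ROR 95% lower bound `> 1`, `IC > 0`
#' and IC 95% lower bound `> 0`. Missing values (e.g. undefined interval
#' bounds from zero cells) fail the criterion.
#'
#' @param a case count(s).
#' @param ror_low ROR lower bound(s).
#' @param ic IC point estimate(s).
#' @param ic_low IC lower bound(s).
#' @param min_cases minimum case count (default 3).
#' @return logical vector.
#' @export
evaluate_signal <- function(a, ror_low, ic, ic_low, min_cases = 3) {
  out <- a >= min_cases & ror_low > 1 & ic > 0 & ic_low > 0
  out[is.na(out)] <- FALSE
  out
}

#' Screen every drug in a dictionary against one event set
#'
#' Builds the 2x2 table for each ATC code in the dictionary against the
#' whole-database background, computes ROR and IC, and applies the joint
#' signal criterion. Drugs with at least one co-reported case are returned
#' ranked by descending ROR (ties broken by ascending drug label); drugs
#' with zero co-reported cases are kept apart in the `zero_case_drugs`
#' attribute.
#'
#' @param cs a deduplicated `case_set`.
#' @param dict a [drug_dictionary()].
#' @param term_set the event [term_set()].
#' @param roles accepted drug role codes.
#' @param min_cases minimum case count for the signal criterion.
#' @param continuity continuity-correction flag passed to the ROR.
#' @return tibble with columns `atc`, `label`, `a`, `b`, `c`, `d`, `ror`,
#'   `ror_low`, `ror_high`, `ic`, `ic_low`, `ic_high`, `signal`.
#' @export
run_screen <- function(cs, dict, term_set, roles = "PS", min_cases = 3,
                       continuity = FALSE) {
  stopifnot(inherits(cs, "case_set"), inherits(dict, "drug_dictionary"))
  if (!n_cases(cs)) stop("cannot screen zero cases")
  codes <- atc_codes(dict)
  n <- n_cases(cs)
  he <- case_has_event(cs, term_set)
  n_event <- sum(he)

  dr <- cs$drugs
  dr <- dr[dr$role %in% roles & !is.na(dr$atc_code) &
             dr$atc_code %in% codes, , drop = FALSE]
  ids_by_drug <- split(dr$primary_id, dr$atc_code)

  a <- b <- integer(length(codes))
  for (i in seq_along(codes)) {
    hd <- cs$cases$primary_id %in% ids_by_drug[[codes[i]]]
    a[i] <- sum(hd & he)
    b[i] <- sum(hd) - a[i]
  }
  cc <- n_event - a
  dd <- n - a - b - cc

  cells <- data.frame(a = a, b = b, c = cc, d = dd)
  if (continuity) {
    zero <- pmin(cells$a, cells$b, cells$c, cells$d) == 0
    cells[zero, ] <- cells[zero, ] + 0.5
  }
  rr <- ror_wald(cells$a, cells$b, cells$c, cells$d)
  e <- (cells$a + cells$b) * (cells$a + cells$c) / n
  ii <- ic_shrinkage(cells$a, e)

  out <- tibble::tibble(
    atc = codes,
    label = unname(dict$drug_labels[codes]),
    a = a, b = b, c = cc, d = dd,
    ror = rr$ror, ror_low = rr$ror_low, ror_high = rr$ror_high,
    ic = ii$ic, ic_low = ii$ic_low, ic_high = ii$ic_high,
    signal = evaluate_signal(a, rr$ror_low, ii$ic, ii$ic_low, min_cases)
  )
  zero_case <- out[out$a == 0, , drop = FALSE]
  out <- out[out$a >= 1, , drop = FALSE]
  out <- out[order(-out$ror, out$label), , drop = FALSE]
  attr(out, "zero_case_drugs") <- zero_case
  attr(out, "n_total") <- n
  out
}

#' Write a screen result to TSV
#'
#' ROR and IC columns are rendered to two decimals for display alongside
#' full-precision companion columns.
#'
#' @param screen result of [run_screen()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signals <- function(screen, path) {
  out <- as.data.frame(screen)
  for (col in c("ror", "ror_low", "ror_high", "ic", "ic_low", "ic_high")) {
    out[[paste0(col, "_full")]] <- out[[col]]
    out[[col]] <- sprintf("%.2f", round_half_up(out[[col]], 2))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
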