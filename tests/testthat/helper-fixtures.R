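# Shared in-code fixtures for the unit tests.

# a tiny two-PT event set and a one-category confounder catalog
tiny_term_set <- function() {
  term_set("seizures_tiny", included_pts = c("PT_SEIZ1", "PT_SEIZ2"),
           excluded_pts = "PT_EXCL")
}

tiny_catalog <- function() {
  confounder_catalog(list(
    term_set("history_tiny", included_pts = c("PT_HIST1", "PT_HIST2"))
  ))
}

tiny_dict <- function() {
  drug_dictionary(
    raw_name = c("bupropion", "sertraline", "duloxetine"),
    atc_code = c("N06AX12", "N06AB06", "N06AX21"),
    display_name = c("Bupropion", "Sertraline", "Duloxetine")
  )
}

# build a case_set from a compact spec: one row per report
# drugs: "atc/role" strings separated by "+"; events/indis: "pt+pt"
make_cases <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (is.null(df$primary_id)) df$primary_id <- sprintf("p%03d", seq_len(n))
  if (is.null(df$case_id)) df$case_id <- df$primary_id
  if (is.null(df$receipt_sequence)) df$receipt_sequence <- 1L
  split_col <- function(x) strsplit(ifelse(is.na(x) | x == "", NA, x), "+",
                                    fixed = TRUE)
  dparts <- split_col(df$drugs)
  drugs <- do.call(rbind, lapply(seq_len(n), function(i) {
    entries <- strsplit(dparts[[i]], "/", fixed = TRUE)
    data.frame(primary_id = df$primary_id[i],
               raw_name = vapply(entries, `[`, "", 1),
               role = vapply(entries, function(e) e[2] %||% "PS", ""),
               atc_code = vapply(entries, `[`, "", 1))
  }))
  eparts <- split_col(df$events)
  events <- data.frame(primary_id = rep(df$primary_id, lengths(eparts)),
                       pt = unlist(eparts))
  iparts <- if (is.null(df$indis)) rep(list(character()), n) else
    lapply(split_col(df$indis), function(z) z[!is.na(z)])
  indis <- data.frame(primary_id = rep(df$primary_id, lengths(iparts)),
                      pt = unlist(iparts) %||% character())
  cs <- case_set(
    cases = data.frame(primary_id = df$primary_id, case_id = df$case_id,
                       receipt_sequence = df$receipt_sequence),
    drugs = drugs, events = events, indications = indis
  )
  cs
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

# write a tiny quarter of delimited files; each table is a data.frame
write_tiny_quarter <- function(dir, demo, drug, reac, indi, sep = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(t, f) {
    lines <- c(paste(names(t), collapse = sep),
               do.call(paste, c(unname(as.list(t)), sep = sep)))
    writeLines(lines, file.path(dir, f))
  }
  w(demo, "DEMO.txt"); w(drug, "DRUG.txt"); w(reac, "REAC.txt")
  w(indi, "INDI.txt")
  file.path(dir, c("DEMO.txt", "DRUG.txt", "REAC.txt", "INDI.txt"))
}
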