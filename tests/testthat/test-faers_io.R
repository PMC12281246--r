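test_that("read_quarter parses rows, routes malformed rows to rejects", {
  dir <- withr::local_tempdir()
  demo <- data.frame(primaryid = c("p11", "p21", "p31"),
                     caseid = c("c1", "c2", "c3"),
                     sex = c("F", "M", ""), age = c("34", "61", ""),
                     occp_cod = c("MD", "CN", ""),
                     reporter_country = c("US", "DE", ""))
  drug <- data.frame(primaryid = c("p11", "p21", "p31"),
                     caseid = c("c1", "c2", "c3"),
                     role_cod = "PS", drugname = "bupropion")
  reac <- data.frame(primaryid = c("p11", "p21", "p31"),
                     caseid = c("c1", "c2", "c3"),
                     pt = c("PT_A", "PT_B", "PT_C"))
  indi <- data.frame(primaryid = "p11", caseid = "c1", indi_pt = "PT_I")
  paths <- write_tiny_quarter(dir, demo, drug, reac, indi)
  # corrupt one DRUG line: 3 fields under the 4-field header
  lines <- readLines(paths[2])
  lines[3] <- "p21$c2$PS"
  writeLines(lines, paths[2])

  q <- read_quarter(paths[1], paths[2], paths[3], paths[4])
  expect_equal(nrow(q$tables$DEMO), 3)
  expect_equal(nrow(q$tables$DRUG), 2)   # bad row removed from the table...
  expect_equal(nrow(q$rejects), 1)       # ...and reported, not dropped
  expect_equal(q$rejects$table_name, "DRUG")

  expect_error(read_quarter("nope.txt", paths[2], paths[3], paths[4]),
               "not found")

  # header without the case key is unusable
  writeLines(c("primaryid$sex", "p11$F"), paths[1])
  expect_error(read_quarter(paths[1], paths[2], paths[3], paths[4]),
               "key field")
})

test_that("assemble_cases joins tables, decodes demographics, logs exclusions", {
  dir <- withr::local_tempdir()
  demo <- data.frame(primaryid = c("p11", "p21", "p31"),
                     caseid = c("c1", "c2", "c3"),
                     caseversion = "1",
                     sex = c("F", "M", "x"), age = c("34", "480", "61"),
                     age_cod = c("YR", "MON", "YR"),
                     occp_cod = c("MD", "CN", "zz"),
                     reporter_country = c("US", "DE", "QQ"))
  drug <- data.frame(primaryid = c("p11", "p21", "p99"),
                     caseid = c("c1", "c2", "c9"),
                     role_cod = c("PS", "C", "PS"),
                     drugname = c("Bupropion", "sertraline", "ghost"))
  reac <- data.frame(primaryid = c("p11", "p21"),
                     caseid = c("c1", "c2"), pt = c("PT_A", "PT_B"))
  indi <- data.frame(primaryid = "p11", caseid = "c1", indi_pt = "PT_I")
  paths <- write_tiny_quarter(dir, demo, drug, reac, indi)
  q <- read_quarter(paths[1], paths[2], paths[3], paths[4])
  cs <- assemble_cases(q, dict = tiny_dict())

  # p31 has no REAC row -> excluded; p99 rows are orphans
  expect_equal(n_cases(cs), 2)
  expect_equal(cs$log$n_excluded_no_event, 1)
  expect_equal(cs$log$n_orphan_rows, 1)

  expect_equal(cs$cases$sex, c("female", "male"))
  expect_equal(cs$cases$age_years, c(34, 40))   # 480 months = 40 years
  expect_equal(cs$cases$reporter,
               c("health_professional", "non_health_professional"))
  expect_equal(cs$cases$region, c("NorthAmerica", "Europe"))
  expect_equal(sort(cs$drugs$atc_code), c("N06AB06", "N06AX12"))
})

test_that("age decoding converts all unit codes and rejects impossible ages", {
  ages <- pvscreen:::decode_age(
    age = c("34", "4", "480", "104", "3652.5", "-3", "200", "abc"),
    age_cod = c("YR", "DEC", "MON", "WK", "DY", "YR", "YR", "YR"))
  expect_equal(ages, c(34, 40, 40, 2, 10, NA, NA, NA))
})

test_that("deduplicate keeps the final report version per case", {
  cs <- make_cases(data.frame(
    primary_id = c("p1a", "p1b", "p1c", "p2a"),
    case_id = c("C1", "C1", "C1", "C2"),
    receipt_sequence = c(1L, 3L, 2L, 1L),
    drugs = "N06AX12/PS",
    events = c("PT_X", "PT_SEIZ1", "PT_X", "PT_X")
  ))
  out <- deduplicate(cs)
  expect_equal(out$cases$primary_id, c("p1b", "p2a"))
  expect_equal(out$log$n_duplicates_removed, 2)
  # the retained version's events came along, the stale ones did not
  expect_setequal(out$events$pt[out$events$primary_id == "p1b"], "PT_SEIZ1")

  # receipt tie broken by highest primary_id, deterministically
  tie <- make_cases(data.frame(
    primary_id = c("p1a", "p1z"), case_id = "C1",
    receipt_sequence = 2L, drugs = "N06AX12/PS", events = "PT_X"
  ))
  expect_equal(deduplicate(tie)$cases$primary_id, "p1z")
})

test_that("deduplicate is idempotent and identity on duplicate-free input", {
  cs <- make_cases(data.frame(
    primary_id = sprintf("p%d", 1:5), case_id = sprintf("C%d", 5:1),
    drugs = "N06AB06/PS", events = "PT_X"
  ))
  once <- deduplicate(cs)
  twice <- deduplicate(once)
  expect_equal(twice$cases, once$cases)
  expect_equal(once$log$n_duplicates_removed, 0)
  expect_setequal(once$cases$primary_id, cs$cases$primary_id)
  expect_equal(once$cases$case_id, sort(cs$cases$case_id))
})

test_that("synthetic quarter round-trips through files to the generator truth", {
  cfg <- synthetic_config(n_cases = 500, seed = 11, duplicate_rate = 0.2)
  dir <- withr::local_tempdir()
  gen <- generate_quarter(cfg, dir)
  sim <- gen$sim

  q <- read_quarter(file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
                    file.path(dir, "REAC.txt"), file.path(dir, "INDI.txt"))
  expect_equal(nrow(q$rejects), 0)
  for (nm in names(q$tables)) {
    expect_equal(nrow(q$tables[[nm]]), nrow(sim$tables[[nm]]))
  }

  cs <- deduplicate(assemble_cases(q, dict = cfg$dictionary))
  expect_equal(n_cases(cs), 500)
  expect_setequal(cs$cases$case_id, sim$truth$case_id)
  expect_equal(cs$log$n_duplicates_removed, sum(sim$truth$duplicate))

  # retained report is the latest version, with the truth's drug and event
  expect_equal(cs$cases$primary_id,
               sim$truth$primary_id[match(cs$cases$case_id,
                                          sim$truth$case_id)])
  truth_atc <- sim$truth$atc[match(cs$cases$case_id, sim$truth$case_id)]
  expect_equal(unname(cs$drugs$atc_code[match(cs$cases$primary_id,
                                              cs$drugs$primary_id)]),
               truth_atc)
  he <- case_has_event(cs, cfg$term_set)
  truth_ev <- sim$truth$has_event[match(cs$cases$case_id,
                                        sim$truth$case_id)]
  expect_equal(he, truth_ev)
})

test_that("case TSV serialization round-trips", {
  cfg <- synthetic_config(n_cases = 120, seed = 3)
  cs <- assemble_simulation(simulate_reports(cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cases_tsv(cs, path)
  back <- read_cases_tsv(path)
  expect_equal(back$cases$case_id, cs$cases$case_id)
  expect_equal(back$cases$sex, cs$cases$sex)
  expect_equal(back$cases$age_years, cs$cases$age_years)
  expect_equal(back$drugs$atc_code, cs$drugs$atc_code)
  expect_setequal(paste(back$events$primary_id, back$events$pt),
                  paste(cs$events$primary_id, cs$events$pt))
})
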