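test_that("generation is byte-reproducible from the seed", {
  cfg <- synthetic_config(n_cases = 300, seed = 47)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_quarter(cfg, d1)
  generate_quarter(cfg, d2)
  for (f in c("DEMO.txt", "DRUG.txt", "REAC.txt", "INDI.txt",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the stream
  generate_quarter(synthetic_config(n_cases = 300, seed = 48), d2)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d2, "DEMO.txt"))))
})

test_that("case identifiers respect the duplicate-rate contract", {
  cfg0 <- synthetic_config(n_cases = 100, seed = 53, duplicate_rate = 0)
  sim0 <- simulate_reports(cfg0)
  expect_equal(nrow(sim0$tables$DEMO), 100)
  expect_equal(length(unique(sim0$tables$DEMO$caseid)), 100)

  cfg <- synthetic_config(n_cases = 1000, seed = 53, duplicate_rate = 0.2)
  sim <- simulate_reports(cfg)
  n_dup <- sum(sim$truth$duplicate)
  expect_equal(nrow(sim$tables$DEMO), 1000 + n_dup)
  expect_equal(length(unique(sim$tables$DEMO$caseid)), 1000)
  # after deduplication the retained count is the distinct-case count
  cs <- assemble_simulation(sim)
  expect_equal(n_cases(cs), 1000)
  expect_equal(cs$log$n_duplicates_removed, n_dup)
})

test_that("demographic strata converge to the configured probabilities", {
  cfg <- synthetic_config(n_cases = 50000, seed = 59)
  cs <- assemble_simulation(simulate_reports(cfg))
  for (dim in c("sex", "region")) {
    s <- summarize_cases(cs, dim)
    probs <- switch(dim, sex = cfg$sex_probs, region = cfg$region_probs)
    gof <- suppressWarnings(
      chisq.test(s$count[match(names(probs), s$stratum)], p = probs)
    )
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("expected odds ratio has the right fixed points", {
  flat <- synthetic_config(n_cases = 100, seed = 1,
                           planted_lambda = c(N06AX12 = 1))
  for (d in names(flat$drug_background)) {
    expect_equal(expected_ror(flat, d), 1.0, tolerance = 1e-12)
  }
  none <- synthetic_config(n_cases = 100, seed = 1,
                           planted_lambda = c(N06AX12 = 0))
  expect_equal(expected_ror(none, "N06AX12"), 0)
  cells <- expected_cells(none, "N06AX12")
  expect_equal(cells$a + cells$b + cells$c + cells$d, 1, tolerance = 1e-12)
})

test_that("analytic expected ROR matches a Monte-Carlo estimate", {
  toy <- synthetic_config(
    n_cases = 200000, seed = 61,
    drug_background = c(N06AX12 = 0.3, N06AB06 = 0.7),
    planted_lambda = c(N06AX12 = 4),
    seizure_prob = 0.02, duplicate_rate = 0
  )
  want <- expected_ror(toy, "N06AX12")
  cs <- assemble_simulation(simulate_reports(toy))
  t <- build_table(cs, "N06AX12", toy$term_set)
  est <- compute_ror(t)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  expect_lt(abs(log(est$ror) - log(want)), 3 * se)
})

test_that("ground-truth expectations match brute-force stream counts", {
  cfg <- synthetic_config(n_cases = 20000, seed = 67)
  sim <- simulate_reports(cfg)
  for (drug in c("N06AX12", "N06AB06")) {
    p <- expected_cells(cfg, drug)
    in_drug <- sim$truth$atc == drug
    a_obs <- sum(in_drug & sim$truth$has_event)
    # binomial sampling slack: 4 standard deviations
    tol <- 4 * sqrt(cfg$n_cases * p$a * (1 - p$a))
    expect_lt(abs(a_obs - cfg$n_cases * p$a), tol)
  }
})

test_that("impossible event probabilities are rejected at configuration", {
  expect_error(
    synthetic_config(n_cases = 10, seed = 1, seizure_prob = 0.2,
                     planted_lambda = c(N06AX12 = 8)),
    "p \\* lambda"
  )
  expect_error(synthetic_config(n_cases = 10, seed = 1,
                                duplicate_rate = 1),
               "duplicate_rate")
  expect_error(synthetic_config(n_cases = 10, seed = 1,
                                sex_probs = c(female = 0.5, male = 0.4)),
               "sum to 1")
})
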