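test_that("ROR point estimate and Wald interval match direct arithmetic", {
  # frozen oracle values, computed by hand from the defining formulas:
  # ror = (20*9800)/(80*100) = 24.5
  # se  = sqrt(1/20 + 1/80 + 1/100 + 1/9800) = sqrt(0.07260204...)
  t <- contingency_table("N06AX12", "seizures", a = 20, b = 80,
                         c = 100, d = 9800)
  r <- compute_ror(t)
  expect_equal(r$ror, 24.5, tolerance = 1e-12)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 9800)
  expect_equal(r$ror_low, 24.5 * exp(-1.96 * se), tolerance = 1e-12)
  expect_equal(r$ror_high, 24.5 * exp(1.96 * se), tolerance = 1e-12)

  # balanced table: ad = bc
  sym <- contingency_table("x", "y", 10, 10, 10, 10)
  expect_equal(compute_ror(sym)$ror, 1.0)

  # zero cell: bounds undefined without correction, finite with it
  z <- contingency_table("x", "y", 0, 50, 30, 900)
  expect_equal(compute_ror(z)$ror, 0)
  expect_true(is.na(compute_ror(z)$ror_low))
  rc <- compute_ror(z, continuity = TRUE)
  expect_equal(rc$ror, (0.5 * 900.5) / (50.5 * 30.5), tolerance = 1e-12)
  expect_true(rc$ror_low > 0 && is.finite(rc$ror_high))

  expect_error(compute_ror(contingency_table("x", "y", 5, 0, 0, 0)),
               "malformed")
})

test_that("log-odds agrees with an independent logistic regression fit", {
  tabs <- list(c(20, 80, 100, 9800), c(7, 3, 12, 40), c(33, 67, 190, 7000))
  for (cells in tabs) {
    t <- contingency_table("x", "y", cells[1], cells[2], cells[3], cells[4])
    r <- compute_ror(t)
    df <- data.frame(event = c(1, 0, 1, 0), drug = c(1, 1, 0, 0), w = cells)
    fit <- stats::glm(event ~ drug, family = binomial(), data = df,
                      weights = w)
    expect_equal(log(r$ror), unname(coef(fit)["drug"]), tolerance = 1e-6)
  }
})

test_that("IC equals the shrunk log2 observed/expected with its bounds", {
  # a = E exactly: the +0.5 terms cancel, IC is exactly zero
  t0 <- contingency_table("x", "y", a = 25, b = 75, c = 225, d = 675)
  expect_equal((25 + 75) * (25 + 225) / 1000, 25)  # E = a
  expect_equal(compute_ic(t0)$ic, 0)

  # frozen oracle: a=20, margins 100 and 120, n=10000 -> E = 1.2,
  # ic = log2(20.5/1.7)
  t <- contingency_table("x", "y", a = 20, b = 80, c = 100, d = 9800)
  ic <- compute_ic(t)
  expect_equal(ic$ic, log2(20.5 / 1.7), tolerance = 1e-12)
  s <- 20.5
  expect_equal(ic$ic_low, ic$ic - 3.3 / sqrt(s) - 2 * s^-1.5,
               tolerance = 1e-12)
  expect_equal(ic$ic_high, ic$ic + 2.4 / sqrt(s) - 0.5 * s^-1.5,
               tolerance = 1e-12)
})

test_that("shrinkage vanishes asymptotically at fixed observed/expected", {
  # tables built with E = a/2, so IC -> log2(2) = 1 as a grows
  for (a in c(10, 100, 1000)) {
    n <- 100 * a
    t <- contingency_table("x", "y", a = a, b = a, c = 24 * a, d = 74 * a)
    expect_equal((2 * a) * (25 * a) / n, a / 2)
    dev <- abs(compute_ic(t)$ic - 1)
    if (a >= 100) expect_lt(dev, 0.01)
  }
})

test_that("increasing a at fixed margins raises both ROR and IC", {
  n <- 1000; m1 <- 100; m2 <- 80
  prev_ror <- -Inf; prev_ic <- -Inf
  for (a in 5:40) {
    t <- contingency_table("x", "y", a, m1 - a, m2 - a, n - m1 - m2 + a)
    r <- compute_ror(t); ic <- compute_ic(t)
    expect_gt(r$ror, prev_ror)
    expect_gt(ic$ic, prev_ic)
    prev_ror <- r$ror; prev_ic <- ic$ic
  }
})

test_that("Wald lower bound exceeds 1 in at most ~2.5% of null tables", {
  # multinomial resampling of an independent (odds ratio 1) table
  set.seed(2024)
  n <- 10000
  p_drug <- 0.05; p_event <- 0.05
  probs <- c(p_drug * p_event, p_drug * (1 - p_event),
             (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
  draws <- stats::rmultinom(2000, n, probs)
  r <- ror_wald(draws[1, ], draws[2, ], draws[3, ], draws[4, ])
  frac <- mean(r$ror_low > 1, na.rm = TRUE)
  expect_lte(frac, 0.05 + 0.02)
})

test_that("the joint criterion is a strict conjunction", {
  expect_false(evaluate_signal(2, ror_low = 5, ic = 2, ic_low = 2))
  expect_true(evaluate_signal(100, ror_low = 1.2, ic = 0.8, ic_low = 0.1))
  expect_false(evaluate_signal(50, ror_low = 0.99, ic = 0.8, ic_low = 0.1))
  expect_false(evaluate_signal(50, ror_low = 1.2, ic = 0, ic_low = 0.1))
  expect_false(evaluate_signal(50, ror_low = NA, ic = 0.8, ic_low = 0.1))

  set.seed(5)
  a <- sample(0:10, 200, TRUE)
  rl <- runif(200, 0.5, 2); ic <- runif(200, -1, 1)
  il <- ic - runif(200, 0, 1)
  got <- evaluate_signal(a, rl, ic, il)
  want <- a >= 3 & rl > 1 & ic > 0 & il > 0
  expect_equal(got, want)
})

test_that("screen ranks a strongly planted drug first and flags it", {
  lam <- c(N06AX12 = 8)
  cfg <- synthetic_config(n_cases = 30000, seed = 17,
                          planted_lambda = lam)
  cs <- assemble_simulation(simulate_reports(cfg))
  sc <- run_screen(cs, cfg$dictionary, cfg$term_set)
  expect_equal(sc$atc[1], "N06AX12")
  expect_true(sc$signal[1])
  # ranking is by descending ROR with deterministic tie-break
  expect_true(all(diff(sc$ror) <= 0))

  sc2 <- run_screen(cs, cfg$dictionary, cfg$term_set)
  expect_identical(sc, sc2)

  # background partition holds for every screened drug
  expect_true(all(sc$a + sc$b + sc$c + sc$d == n_cases(cs)))
})

test_that("screen output and TSV rendering are deterministic", {
  cfg <- synthetic_config(n_cases = 2000, seed = 23)
  cs <- assemble_simulation(simulate_reports(cfg))
  sc <- run_screen(cs, cfg$dictionary, cfg$term_set)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_signals(sc, f1)
  write_signals(run_screen(cs, cfg$dictionary, cfg$term_set), f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- strsplit(readLines(f1)[1], "\t")[[1]]
  expect_true(all(c("ror", "ror_full", "ic", "ic_low") %in% header))
})
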