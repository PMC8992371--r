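test_that("2x2 construction puts each case in exactly one cell", {
  cases <- tibble::tibble(
    exposed_d = c(TRUE, TRUE, FALSE, FALSE),
    event_e = c(TRUE, FALSE, TRUE, FALSE)
  )
  t <- build_contingency(cases, "exposed_d", "event_e")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  # no exposure -> a = c = 0
  cases$exposed_d <- FALSE
  t0 <- build_contingency(cases, "exposed_d", "event_e")
  expect_equal(c(t0$a, t0$c), c(0, 0))
  # empty case list -> all-zero table
  te <- build_contingency(cases[0, ], "exposed_d", "event_e")
  expect_equal(te$a + te$b + te$c + te$d, 0)
})

test_that("contingency table equals brute-force recount of generator truth", {
  gen <- small_synth(n = 3000, seed = 13, dup = 0.05, miss = 0)
  db <- link_reports(dedup_reports(gen$db))
  at <- build_analysis_table(db, drug_set("nivolumab", "nivolumab"),
                             pmr_pt_set())
  t <- build_contingency(at, "exposed_nivolumab",
                         "event_polymyalgia_rheumatica")
  tc <- gen$truth$cases
  e <- tc$exposed_nivolumab
  v <- tc$`event_Polymyalgia rheumatica`
  expect_equal(c(t$a, t$b, t$c, t$d),
               c(sum(e & v), sum(!e & v), sum(e & !v), sum(!e & !v)))
})

test_that("ROR point estimate and Woolf interval match published tables", {
  # nivolumab PMR by age: published as 15.11 (4.642-49.149); the exact
  # cross-product ratio is 171150/11331 = 15.1046, which the source table
  # displays as 15.11 (double rounding via 15.105)
  s <- ror_stats(35, 3, 3777, 4890)
  expect_equal(s$ror, 171150 / 11331)
  expect_lt(abs(s$ror - 15.11), 0.01)
  expect_equal(round(s$ci_low, 3), 4.642)
  expect_equal(round(s$ci_high, 3), 49.149)
  expect_true(s$significant)
  # pembrolizumab PMR by sex: 0.216 (0.082-0.569)
  s2 <- ror_stats(7, 10, 3962, 1223)
  expect_equal(round(s2$ror, 3), 0.216)
  expect_equal(round(s2$ci_low, 3), 0.082)
  expect_equal(round(s2$ci_high, 3), 0.569)
  # balanced table
  expect_equal(ror_stats(10, 10, 10, 10)$ror, 1)
  expect_false(ror_stats(10, 10, 10, 10)$significant) # ROR = 1 is not > 1
  # zero cell -> undefined, not corrected
  s0 <- ror_stats(0, 5, 100, 1000)
  expect_true(is.na(s0$ror) && is.na(s0$ci_low) && is.na(s0$significant))
})

test_that("interval is log-symmetric for an all-equal table", {
  s <- ror_stats(8, 8, 8, 8)
  expect_equal(log(s$ci_low) + log(s$ci_high), 0, tolerance = 1e-12)
})

test_that("ROR invariances and CI-width monotonicity hold", {
  set.seed(1)
  for (i in 1:25) {
    cells <- sample(1:60, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    base <- ror_stats(a, b, c, d)
    # inflating the comparator population leaves the ROR unchanged
    k <- sample(2:7, 1)
    expect_equal(ror_stats(a, k * b, c, k * d)$ror, base$ror)
    # swapping drug and event roles leaves the ROR unchanged
    expect_equal(ror_stats(a, c, b, d)$ror, base$ror)
    # CI width (log scale) strictly decreases as any one cell grows
    w <- function(a, b, c, d) {
      s <- ror_stats(a, b, c, d); log(s$ci_high) - log(s$ci_low)
    }
    expect_lt(w(a + 1, b, c, d), w(a, b, c, d))
    expect_lt(w(a, b + 1, c, d), w(a, b, c, d))
    expect_lt(w(a, b, c + 1, d), w(a, b, c, d))
    expect_lt(w(a, b, c, d + 1), w(a, b, c, d))
  }
})

test_that("ROR equals exp(slope) of the equivalent logistic regression", {
  set.seed(2)
  cells <- c(a = 17, b = 9, c = 240, d = 410)
  dat <- tibble::tibble(
    exposed = rep(c(TRUE, FALSE, TRUE, FALSE),
                  times = c(cells["a"], cells["b"], cells["c"], cells["d"])),
    outcome = rep(c(TRUE, TRUE, FALSE, FALSE),
                  times = c(cells["a"], cells["b"], cells["c"], cells["d"]))
  )
  fit <- fit_event_predictors(dat, "outcome", "exposed", tol = 1e-12)
  or_glm <- tidy(fit)$odds_ratio[2]
  or_closed <- unname(ror_stats(cells["a"], cells["b"], cells["c"],
                                cells["d"])$ror)
  expect_equal(or_glm, or_closed, tolerance = 1e-6)
  # and the Wald SE equals the Woolf SE sqrt(1/a+1/b+1/c+1/d)
  expect_equal(tidy(fit)$std.error[2], sqrt(sum(1 / cells)),
               tolerance = 1e-6)
})

test_that("Woolf interval covers a planted ROR at the nominal rate", {
  set.seed(101)
  for (theta in c(0.5, 1, 5, 30)) {
    tabs <- simulate_ror_tables(2000, n_cases = 20000, exposure_prob = 0.3,
                                baseline_prob = 0.01, log_ror = log(theta))
    s <- ror_stats(tabs$a, tabs$b, tabs$c, tabs$d)
    ok <- !is.na(s$ror)
    cover <- mean(s$ci_low[ok] <= theta & theta <= s$ci_high[ok])
    expect_gte(cover, 0.93)
    expect_lte(cover, 0.97)
  }
})

test_that("screen enumerates every drug-event pair deterministically", {
  gen <- small_synth(n = 1500, seed = 21, dup = 0, miss = 0)
  db <- link_reports(dedup_reports(gen$db))
  vasc <- vasculitides_pt_set()
  singles <- lapply(1:10, function(i) {
    pt_set(vasc$terms$pt_name[i], vasc$terms[i, c("pt_code", "pt_name")])
  })
  names(singles) <- vasc$terms$pt_name[1:10]
  sc <- screen_signals(db, icpi_drug_sets(), singles)
  expect_equal(nrow(sc), 60)
  sc2 <- screen_signals(db, icpi_drug_sets(), singles)
  expect_equal(as.data.frame(sc), as.data.frame(sc2))
  # drugs never reported: whole column is N.A.
  expect_true(all(is.na(sc$ror[sc$drug == "avelumab"])))
  # screen agrees with a per-pair brute-force recount
  at <- build_analysis_table(db, icpi_drug_sets()["nivolumab"],
                             singles["Aortitis"])
  t <- build_contingency(at, "exposed_nivolumab", "event_Aortitis")
  row <- sc[sc$drug == "nivolumab" & sc$event == "Aortitis", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(t$a, t$b, t$c, t$d))
})

test_that("detect_signal applies the strict lower-bound rule", {
  s <- detect_signal(contingency_table(35, 3, 3777, 4890))
  expect_true(s$significant)
  expect_true(is.na(detect_signal(contingency_table(0, 3, 10, 10))$significant))
  td <- tidy(s)
  expect_equal(td$ror, s$ror)
})

test_that("screen CSV renders undefined statistics as N.A.", {
  sc <- ror_stats(c(3, 0), c(5, 5), c(10, 10), c(20, 20))
  sc$drug <- c("d1", "d2"); sc$event <- "e"
  sc$n_event <- sc$a; sc$n_other <- sc$c
  class(sc) <- c("ror_screen", class(sc))
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(sc, path)
  txt <- readLines(path)
  expect_true(any(grepl("N.A.", txt, fixed = TRUE)))
})
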