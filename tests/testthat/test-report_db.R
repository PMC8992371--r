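test_that("CSV round-trip preserves every record", {
  gen <- small_synth(n = 500, seed = 7)
  dir <- withr::local_tempdir()
  write_report_db(gen$db, dir)
  back <- read_report_db(list(demo = file.path(dir, "demo.csv"),
                              drug = file.path(dir, "drug.csv"),
                              reac = file.path(dir, "reac.csv"),
                              hist = file.path(dir, "hist.csv")))
  for (tb in c("demo", "drug", "reac", "hist")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(gen$db[[tb]]),
                 ignore_attr = TRUE)
  }
  expect_equal(nrow(back$demo), 500)
})

test_that("reader passes blank sex through as unknown and logs bad enum rows", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id,sex,age_decade,report_year,report_quarter",
               "a,male,40,2010,1", "b,,50,2011,2", "c,female,60,2012,3"),
             file.path(dir, "demo.csv"))
  writeLines(c("case_id,drug_name,role,first_admin_day",
               "a,nivolumab,suspected,10",
               "b,nivolumab,frobnicated,20"),
             file.path(dir, "drug.csv"))
  writeLines("case_id,pt_name,pt_code,onset_day,outcome",
             file.path(dir, "reac.csv"))
  writeLines("case_id,primary_disease_pt", file.path(dir, "hist.csv"))
  db <- read_report_db(list(demo = file.path(dir, "demo.csv"),
                            drug = file.path(dir, "drug.csv"),
                            reac = file.path(dir, "reac.csv"),
                            hist = file.path(dir, "hist.csv")))
  expect_equal(nrow(db$demo), 3)
  expect_equal(db$demo$sex, c("male", "unknown", "female"))
  # bad role row dropped and reported with its row number
  expect_equal(nrow(db$drug), 1)
  lr <- load_report(db)
  expect_equal(lr$table, "drug")
  expect_equal(lr$row, 2L)
  expect_equal(lr$field, "role")
  # ISO dates in day columns are converted to day indices
  writeLines(c("case_id,drug_name,role,first_admin_day",
               "a,nivolumab,suspected,1970-01-11"),
             file.path(dir, "drug.csv"))
  db2 <- read_report_db(list(demo = file.path(dir, "demo.csv"),
                             drug = file.path(dir, "drug.csv"),
                             reac = file.path(dir, "reac.csv"),
                             hist = file.path(dir, "hist.csv")))
  expect_equal(db2$drug$first_admin_day, 10L)
  expect_error(read_report_db(list(demo = file.path(dir, "nope.csv"),
                                   drug = file.path(dir, "drug.csv"),
                                   reac = file.path(dir, "reac.csv"),
                                   hist = file.path(dir, "hist.csv"))),
               "not found")
})

test_that("deduplication removes exact-key duplicates only and is idempotent", {
  db <- report_db(
    demo = data.frame(case_id = "c1", sex = "male", age_decade = 60,
                      report_year = 2018),
    drug = data.frame(case_id = "c1", drug_name = "nivolumab",
                      role = "suspected", first_admin_day = 1),
    reac = data.frame(case_id = c("c1", "c1", "c1"),
                      pt_name = "Polymyalgia rheumatica",
                      pt_code = 10036099L,
                      onset_day = c(5L, 5L, 9L), outcome = "recovery"),
    hist = data.frame(case_id = character(), primary_disease_pt = character())
  )
  d1 <- dedup_reports(db)
  expect_equal(nrow(d1$reac), 2)            # same onset kept once, other onset kept
  expect_equal(dedup_counts(d1)$reac, 1)
  d2 <- dedup_reports(d1)
  expect_equal(as.data.frame(d2$reac), as.data.frame(d1$reac))
  expect_equal(dedup_counts(d2)$reac, 0)
})

test_that("generator duplicate bookkeeping matches removal counts exactly", {
  gen <- small_synth(n = 2000, seed = 11, dup = 0.05)
  dd <- dedup_reports(gen$db)
  expect_equal(dedup_counts(dd)$drug, gen$truth$n_duplicates$drug)
  expect_equal(dedup_counts(dd)$reac, gen$truth$n_duplicates$reac)
})

test_that("linkage drops and counts orphans; counts reconcile", {
  db <- tiny_db()
  db$drug <- dplyr::bind_rows(db$drug,
                              tibble::tibble(case_id = "ghost",
                                             drug_name = "nivolumab",
                                             role = "suspected",
                                             first_admin_day = 1L))
  n_drug <- nrow(db$drug)
  db <- link_reports(db)
  expect_equal(orphan_counts(db)$drug, 1)
  expect_equal(nrow(db$drug) + orphan_counts(db)$drug, n_drug)
  expect_false("ghost" %in% db$drug$case_id)
})

test_that("exclusions drop missing sex/age, never alter survivors", {
  db <- link_reports(dedup_reports(tiny_db()))
  before <- db$demo
  out <- filter_complete_demo(db)
  fr <- filter_report(out)
  expect_equal(fr$n_input, 5)
  expect_equal(fr$n_excluded_missing_sex, 1)  # c4, unknown sex
  expect_equal(fr$n_excluded_missing_age, 1)  # c5, missing age
  expect_equal(fr$n_retained, 3)
  expect_equal(fr$n_retained, fr$n_input - fr$n_excluded_missing_sex -
                 fr$n_excluded_missing_age)
  expect_setequal(out$demo$case_id, c("c1", "c2", "c3"))
  expect_equal(as.data.frame(out$demo),
               as.data.frame(before[before$case_id %in% out$demo$case_id, ]))
})

test_that("exclusion counts agree with generator ground truth", {
  gen <- small_synth(n = 5000, seed = 3, miss = 0.1)
  db <- filter_complete_demo(link_reports(dedup_reports(gen$db)))
  expect_equal(nrow(db$demo), sum(gen$truth$cases$complete_demo))
  expect_setequal(db$demo$case_id,
                  gen$truth$cases$case_id[gen$truth$cases$complete_demo])
})

test_that("older-adult boundary is age decade 70 and errors on missing age", {
  expect_true(older_adult(70L))
  expect_true(older_adult(100L))
  expect_false(older_adult(60L))
  expect_equal(older_adult(c(0L, 60L, 70L, 90L)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_error(older_adult(c(70L, NA)), "missing")
})
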