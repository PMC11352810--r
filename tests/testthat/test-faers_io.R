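test_that("header-name-driven parsing absorbs column drift", {
  f <- tempfile(fileext = ".txt")
  # reordered columns, an unknown extra column, and a missing optional one
  writeLines(c(
    "caseid$primaryid$extra_col$fda_dt$caseversion$age$age_cod$sex$occp_cod$occr_country",
    "10001$100001$x$20150105$1$65$YR$F$MD$US",
    "10002$100002$y$20150106$1$$$M$CN$FR"), f)
  d <- read_faers_table(f, "demo")
  expect_equal(d$primaryid, c("100001", "100002"))
  expect_equal(d$caseid, c("10001", "10002"))
  expect_equal(d$event_dt, c("", ""))  # absent column -> empty fields
  expect_false("extra_col" %in% names(d))

  # header-only file -> empty table with the canonical columns
  writeLines("primaryid$caseid$caseversion$fda_dt", f)
  expect_equal(nrow(read_faers_table(f, "demo")), 0L)

  # header lacking the key column -> format error
  writeLines(c("caseid$fda_dt", "1$20150101"), f)
  expect_error(read_faers_table(f, "demo"), "primaryid")
  expect_error(read_faers_table(tempfile(), "demo"), "cannot read")
})

test_that("dialect round trip reproduces every field", {
  corpus <- small_corpus(n = 200, seed = 5)
  dir <- file.path(tempdir(), "rt_corpus")
  write_corpus(corpus$tables, corpus$deleted, dir,
               quarter = corpus$config$quarter)
  raw <- read_faers_quarter(dir)
  for (kind in c("demo", "drug", "reac", "outc", "ther")) {
    expect_equal(as.data.frame(raw[[kind]]),
                 as.data.frame(corpus$tables[[kind]]),
                 info = kind)
  }
  expect_setequal(raw$deleted, corpus$deleted)
  unlink(dir, recursive = TRUE)
})

test_that("assemble_cases joins on primaryid with DEMO as the spine", {
  demo <- data.table(primaryid = "1", caseid = "10", caseversion = "1",
                     fda_dt = "20200101", event_dt = "", age = "65",
                     age_cod = "YR", sex = "F", occp_cod = "MD",
                     occr_country = "US")
  drug <- data.table(primaryid = c("1", "1", "99"),
                     drug_seq = c("1", "2", "1"),
                     role_cod = c("PS", "C", "PS"),
                     drugname = c("IBRANCE", "LETROZOLE", "ORPHAN"),
                     prod_ai = "")
  reac <- data.table(primaryid = c("1", "1", "1", "99"),
                     pt = c("Nausea", "Nausea", " Cardiac  failure ", "Rash"))
  outc <- data.table(primaryid = "1", outc_cod = "HO")
  cases <- assemble_cases(demo, drug, reac, outc)
  expect_equal(nrow(cases), 1L)
  expect_equal(nrow(cases$drugs[[1]]), 2L)
  # set semantics and whitespace normalization on PTs
  expect_setequal(cases$pts[[1]], c("Nausea", "Cardiac failure"))
  expect_equal(cases$outcomes[[1]], "HO")
  expect_equal(attr(cases, "dropped"), c(drug = 1, reac = 1, outc = 0))
})

test_that("THER start dates are joined onto drug rows", {
  demo <- data.table(primaryid = "1", caseid = "10", caseversion = "1",
                     fda_dt = "20200101", event_dt = "", age = "",
                     age_cod = "", sex = "", occp_cod = "",
                     occr_country = "")
  drug <- data.table(primaryid = "1", drug_seq = "1", role_cod = "PS",
                     drugname = "KISQALI", prod_ai = "")
  ther <- data.table(primaryid = "1", dsg_drug_seq = "1",
                     start_dt = "20190105")
  cases <- assemble_cases(demo, drug,
                          data.table(primaryid = character(0),
                                     pt = character(0)),
                          data.table(primaryid = character(0),
                                     outc_cod = character(0)), ther)
  expect_equal(cases$drugs[[1]]$start_dt, "20190105")
})

test_that("assemble_cases conserves counts on a generated corpus", {
  corpus <- small_corpus(n = 500, seed = 17)
  cases <- corpus_cases(corpus)
  expect_equal(nrow(cases), nrow(corpus$tables$demo))
  # every drug row is attached exactly once
  expect_equal(sum(vapply(cases$drugs, nrow, integer(1))),
               nrow(corpus$tables$drug))
  expect_equal(sort(drug_long(cases)$primaryid),
               sort(corpus$tables$drug$primaryid))
})

test_that("write_results round-trips values losslessly", {
  set.seed(1)
  x <- data.table(drug = sample(letters, 100, TRUE),
                  n = sample(1e6L, 100),
                  prr = rlnorm(100), ror = rlnorm(100) * 1e-8,
                  signal = sample(c(TRUE, FALSE), 100, TRUE))
  x$prr[3] <- NA_real_
  f <- tempfile(fileext = ".csv")
  write_results(x, f)
  y <- data.table::fread(f)
  expect_identical(y$drug, x$drug)
  expect_identical(y$n, x$n)
  expect_identical(y$prr, x$prr)
  expect_identical(y$ror, x$ror)
  expect_identical(y$signal, x$signal)

  write_results(x[0], f)
  expect_equal(length(readLines(f)), 1L)  # header-only
  expect_error(write_results(NULL, f), "NULL")
})
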