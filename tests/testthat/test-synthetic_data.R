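test_that("configuration is validated", {
  expect_error(sim_config(followup_rate = 1.5), "rates")
  expect_error(sim_config(drug_mix = c(foo = 1, other = 0)), "drug_mix")
  expect_error(sim_config(anchor_pts = "Hypertension"), "disjoint")
  expect_error(
    sim_config(planted_rr = data.frame(drug_id = "ribociclib",
                                       query = "Hypertension", rho = 500)),
    "exceeds 1")
  expect_error(
    sim_config(planted_rr = data.frame(drug_id = "x", query = "nope",
                                       rho = 2)),
    "unknown quer")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_reports = 250, seed = 77)
  d1 <- file.path(tempdir(), "detA"); d2 <- file.path(tempdir(), "detB")
  generate_corpus(cfg, dir = d1)
  generate_corpus(cfg, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the ledger accounts for every generated report version", {
  corpus <- small_corpus(n = 1000, seed = 83)
  led <- corpus$ledger
  expect_equal(nrow(led), nrow(corpus$tables$demo))
  expect_false(anyDuplicated(led$primaryid) > 0)
  expect_setequal(led$primaryid, corpus$tables$demo$primaryid)
  # duplicate clusters reference their source case
  dups <- led[kind == "crossdup"]
  expect_true(all(dups$cluster_id %in% led[kind == "original", caseid]))
  # planted deletions are original caseids
  expect_true(all(corpus$deleted %in% led$caseid))
})

test_that("a null corpus (all rho = 1) yields PRR near 1 and no signal", {
  cfg <- sim_config(n_reports = 12000, seed = 7, planted_rr = NULL,
                    drug_mix = c(palbociclib = 0.45, ribociclib = 0.05,
                                 abemaciclib = 0.05, other = 0.45))
  corpus <- generate_corpus(cfg)
  cases <- clean_cases(corpus_cases(corpus), corpus$deleted)
  subs <- select_primary_suspect(cases)
  sig <- signal_table(subs, cases, cfg$queries,
                      ic_method = "log2_oe_shrunk")
  # restrict to pairs with expected cell count >= 50
  qp <- vapply(cfg$queries, function(q) {
    1 - prod(1 - cfg$background_pt_rates[intersect(q$pts,
      names(cfg$background_pt_rates))])
  }, numeric(1))
  expected_a <- outer(vapply(subs, nrow, integer(1)), qp)
  big <- data.table::as.data.table(which(expected_a >= 50, arr.ind = TRUE))
  expect_gt(nrow(big), 0)
  for (i in seq_len(nrow(big))) {
    row <- sig[drug == names(subs)[big$row[i]] &
                 query == names(cfg$queries)[big$col[i]]]
    expect_false(row$signal)
    expect_lt(abs(log(row$prr)), log(2))
  }
})

test_that("planted reporting-rate ratios are recovered across a rho grid", {
  rr <- data.frame(
    drug_id = "ribociclib",
    query = c("Hypertension", "Cardiac failure", "Myocardial infarction",
              "Torsade de pointes/QT prolongation", "Cardiomyopathy"),
    rho = c(0.5, 1, 2, 4, 8))
  cfg <- sim_config(n_reports = 20000, seed = 29, planted_rr = rr,
                    drug_mix = c(palbociclib = 0.2, ribociclib = 0.25,
                                 abemaciclib = 0.05, other = 0.5))
  corpus <- generate_corpus(cfg)
  cases <- clean_cases(corpus_cases(corpus), corpus$deleted)
  subs <- select_primary_suspect(cases)
  est <- vapply(seq_len(nrow(rr)), function(i) {
    q <- cfg$queries[[rr$query[i]]]
    tab <- contingency(subs$ribociclib, flag_reports(cases, q), nrow(cases))
    prr(tab)
  }, numeric(1))
  fit <- lm(log(est) ~ log(rr$rho))
  expect_lt(abs(unname(coef(fit)[2]) - 1), 0.25)
})

test_that("hand-built fixtures encode their constructed truth", {
  fx <- make_fixture_suite()

  with(fx$dup_cluster_3, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    out <- clean_cases(cases, deleted)
    expect_equal(nrow(out), truth$n_retained)
    expect_equal(out$primaryid, truth$retained_primaryid)
  })

  with(fx$followup_chain, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    expect_equal(clean_cases(cases, deleted)$primaryid,
                 truth$retained_primaryid)
  })

  with(fx$deleted_cases, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    expect_setequal(clean_cases(cases, deleted)$caseid,
                    truth$retained_caseids)
  })

  with(fx$unit_codes, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    out <- filter_valid_age(cases)
    keep <- !is.na(truth$expected_years)
    expect_equal(out$age_years, truth$expected_years[keep])
  })

  with(fx$all_invalid_dates, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    subs <- select_primary_suspect(clean_cases(cases, deleted))
    rec <- tte_records(subs)
    expect_equal(sort(rec$status), sort(truth$statuses))
    expect_equal(nrow(summarize_tte(rec)), 0L)  # n_valid = 0
  })

  with(fx$multi_drug_ps, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    subs <- select_primary_suspect(clean_cases(cases, deleted))
    expect_equal(subs$palbociclib$primaryid, truth$palbociclib)
    expect_equal(subs$ribociclib$primaryid, truth$ribociclib)
    expect_false(truth$not_in_any %in%
                   unlist(lapply(subs, `[[`, "primaryid")))
  })

  with(fx$multi_pt, {
    cases <- assemble_cases(tables$demo, tables$drug, tables$reac,
                            tables$outc, tables$ther)
    expect_setequal(cases$pts[[1]], truth$pts)
  })
})
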