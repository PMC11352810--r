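test_that("contingency builds the 2x2 from subsets and conserves totals", {
  tab <- contingency(as.character(1:100), as.character(91:110), 1000)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 10, b = 90, c = 10, d = 890))
  tab0 <- contingency(as.character(1:50), character(0), 100)
  expect_equal(c(tab0$a, tab0$b), c(0, 50))
  expect_error(contingency(as.character(1:80), as.character(81:160), 100),
               "consistency")

  corpus <- small_corpus(n = 800, seed = 13)
  cases <- clean_cases(corpus_cases(corpus), corpus$deleted)
  subs <- select_primary_suspect(cases)
  for (q in corpus$config$queries[1:3]) {
    flagged <- flag_reports(cases, q)
    for (d in names(subs)) {
      tab <- contingency(subs[[d]], flagged, nrow(cases))
      expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(cases))
      expect_equal(tab$a + tab$b, nrow(subs[[d]]))
    }
  }
})

test_that("PRR, ROR and chi-square match hand and reference values", {
  tb <- contingency_table(10, 90, 10, 890)
  expect_equal(prr(tb), (10 / 100) / (10 / 900))       # = 9
  expect_equal(ror(tb), 10 * 890 / (90 * 10))          # = 9.888...
  # chi-square equals an independent Pearson implementation, no correction
  for (cells in list(c(10, 90, 10, 890), c(5, 5, 5, 5), c(1, 99, 50, 850),
                     c(0, 100, 30, 870))) {
    m <- matrix(cells, 2, 2, byrow = TRUE)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE)$statistic)
    expect_equal(chi_square(contingency_table(cells[1], cells[2], cells[3],
                                              cells[4])),
                 unname(ref), tolerance = 1e-12)
  }
  # independence
  ind <- contingency_table(10, 90, 100, 900)
  expect_equal(prr(ind), 1)
  expect_equal(ror(ind), 1)
  expect_equal(chi_square(ind), 0)
  expect_equal(ic(ind, "log2_oe"), 0)
  # undefined cells print as NA
  z <- contingency_table(0, 57636, 100, 6541735)
  expect_true(is.na(prr(z)) && is.na(ror(z)))
  expect_false(is.na(chi_square(z)))  # chi-square still computable at a = 0
})

test_that("IC variants behave at the edges", {
  tb <- contingency_table(10, 90, 10, 890)
  expect_equal(ic(tb, "log2_oe"), log2(10 * 1000 / (100 * 20)))  # log2(5)
  z <- contingency_table(0, 100, 50, 850)
  E <- 100 * 50 / 1000
  expect_equal(ic(z, "log2_oe_shrunk"), log2(0.5 / (E + 0.5)))
  expect_lt(ic(z, "log2_oe_shrunk"), 0)
  expect_true(is.na(ic(z, "log2_oe")))
  expect_error(ic(tb, "no_such_method"))
})

test_that("ic025 sits below ic and tightens with information", {
  set.seed(8)
  tabs <- random_tables(30, seed = 8)
  for (i in seq_len(nrow(tabs))) {
    tb <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    for (m in c("bcpnn_bate1998", "log2_oe", "log2_oe_shrunk")) {
      expect_lt(ic025(tb, m), ic(tb, m))
    }
  }
  # widths shrink monotonically as counts grow with proportions held
  widths <- vapply(c(1, 10, 100), function(k) {
    tb <- contingency_table(5 * k, 95 * k, 100 * k, 1900 * k)
    ic(tb, "bcpnn_bate1998") - ic025(tb, "bcpnn_bate1998")
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("bcpnn ic025 agrees with a Monte-Carlo posterior oracle", {
  for (cells in list(c(5, 20, 30, 945), c(1, 10, 5, 984),
                     c(25, 100, 50, 2000))) {
    tb <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(ic025(tb, "bcpnn_bate1998") -
                    mc_bcpnn_ic025(cells[1], cells[2], cells[3], cells[4],
                                   ndraw = 5e5)),
              0.05)
  }
})

test_that("algebraic identities hold over random tables", {
  tabs <- random_tables(1000, seed = 21)
  for (i in seq_len(nrow(tabs))) {
    tb <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    p <- prr(tb); r <- ror(tb)
    if (!is.na(p) && p > 1) expect_gt(r, p)
    if (!is.na(p) && p < 1) expect_lt(r, p)
    # swapping the rows inverts PRR/ROR and keeps chi-square
    sw <- contingency_table(tb$c, tb$d, tb$a, tb$b)
    expect_equal(prr(sw), 1 / p)
    expect_equal(ror(sw), 1 / r)
    expect_equal(chi_square(sw), chi_square(tb))
  }
})

test_that("evaluate_signal is the five-way conjunction with NA => FALSE", {
  expect_true(evaluate_signal(190, 8.43, 8.65, 1237.99, 2.86))
  expect_false(evaluate_signal(2, 10, 10, 50, 1))       # n < 3
  expect_false(evaluate_signal(166, 1.8, 1.82, 60.04, 0.64))  # PRR < 2
  expect_false(evaluate_signal(0, NA, NA, 11.54, -6.35))
  expect_equal(evaluate_signal(c(3, 3), c(2, 2), c(2, 2), c(4, 3.9),
                               c(0, 0)),
               c(TRUE, FALSE))
})

test_that("signal_table emits one labelled row per drug-query pair", {
  corpus <- small_corpus(n = 600, seed = 3)
  cases <- clean_cases(corpus_cases(corpus), corpus$deleted)
  subs <- select_primary_suspect(cases)
  queries <- corpus$config$queries
  sig <- signal_table(subs, cases, queries, ic_method = "log2_oe_shrunk")
  expect_equal(nrow(sig), length(subs) * length(queries))
  expect_setequal(unique(sig$drug), names(subs))
  expect_equal(unique(sig$ic_method), "log2_oe_shrunk")
  expect_equal(names(sig), c("drug", "query", "n", "prr", "ror", "chi2",
                             "ic", "ic025", "signal", "ic_method"))
  fmt <- format_signal_table(sig)
  expect_true(all(fmt$prr[sig$n == 0] == "-"))
})
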