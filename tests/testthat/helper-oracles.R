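library(data.table)

# --- independent Monte-Carlo oracle for the BCPNN posterior ---------------
# Samples the three Beta posteriors of the BCPNN model directly and takes
# the empirical quantile of IC = log2(p11 / (p1. p.1)); independent of the
# package's deterministic quadrature.
mc_bcpnn_ic025 <- function(a, b, c, d, ndraw = 1e5, seed = 11) {
  set.seed(seed)
  N <- a + b + c + d; r <- a + b; s <- a + c
  gamma <- (N + 2) * (N + 2) / ((r + 1) * (s + 1))
  p11 <- rbeta(ndraw, 1 + a, gamma - 1 + N - a)
  p1 <- rbeta(ndraw, 1 + r, 1 + N - r)
  p2 <- rbeta(ndraw, 1 + s, 1 + N - s)
  quantile(log2(p11 / (p1 * p2)), 0.025, names = FALSE)
}

# --- in-memory case construction ------------------------------------------
empty_drug_rows <- function() {
  data.table(drug_seq = character(0), role_cod = character(0),
             drugname = character(0), prod_ai = character(0),
             start_dt = character(0))
}

make_drugs <- function(names, roles = "PS", starts = "", ais = "") {
  k <- length(names)
  data.table(drug_seq = as.character(seq_len(k)),
             role_cod = rep_len(roles, k), drugname = names,
             prod_ai = rep_len(ais, k), start_dt = rep_len(starts, k))
}

make_case <- function(primaryid, caseid = primaryid, caseversion = "1",
                      fda_dt = "20200101", event_dt = "", age = "65",
                      age_cod = "YR", sex = "F", occp_cod = "MD",
                      occr_country = "US", pts = "Nausea",
                      drugs = make_drugs("IBRANCE"),
                      outcomes = character(0)) {
  data.table(primaryid = primaryid, caseid = caseid,
             caseversion = caseversion, fda_dt = fda_dt,
             event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
             occp_cod = occp_cod, occr_country = occr_country,
             age_years = NA_real_, pts = list(pts), drugs = list(drugs),
             outcomes = list(outcomes))
}

make_cases <- function(...) rbindlist(list(...))

# a small default-world corpus shared by several test files
small_corpus <- function(n = 500, seed = 99, ...) {
  generate_corpus(sim_config(n_reports = n, seed = seed, ...))
}

corpus_cases <- function(corpus) {
  assemble_cases(corpus$tables$demo, corpus$tables$drug,
                 corpus$tables$reac, corpus$tables$outc,
                 corpus$tables$ther)
}

random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  data.table(a = sample(max_cell, n, TRUE), b = sample(max_cell, n, TRUE),
             c = sample(max_cell, n, TRUE), d = sample(max_cell, n, TRUE))
}
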