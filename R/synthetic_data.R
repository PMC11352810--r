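# Synthetic FAERS corpus generator.  Emits DEMO/DRUG/REAC/OUTC/THER files
# in the quarterly ASCII dialect plus a ground-truth ledger (one row per
# generated report version) so that every pipeline stage can be checked
# against planted truth: deletions, follow-up versions, cross-caseid
# duplicate clusters, age validity, date-rejection categories, per-drug
# cohorts, query flags and planted drug--event reporting-rate ratios.
#
# The default parameters emulate the reporting structure of the CDK4/6
# inhibitor cohort: a strongly female, elderly population, palbociclib
# dominating the class (conditional mix 0.60/0.25/0.15), right-skewed
# log-normal onset times with per-drug medians of roughly 83/63/33 days,
# and a ribociclib--QT-prolongation pair planted as the only true signal.

# verbatim-name pools used to fill drugname/prod_ai
.drug_name_pool <- list(
  palbociclib = list(ai = "PALBOCICLIB",
                     names = c("IBRANCE", "Ibrance (palbociclib)",
                               "PALBOCICLIB", "IBRANCE 125MG")),
  ribociclib  = list(ai = "RIBOCICLIB",
                     names = c("KISQALI", "KISQALI FEMARA CO-PACK",
                               "RIBOCICLIB", "Kisqali 200 mg")),
  abemaciclib = list(ai = "ABEMACICLIB",
                     names = c("VERZENIO", "VERZENIOS", "ABEMACICLIB",
                               "Verzenio 150 mg")),
  other       = list(ai = "",
                     names = c("LETROZOLE", "ANASTROZOLE", "FULVESTRANT",
                               "TAMOXIFEN CITRATE", "EXEMESTANE",
                               "CAPECITABINE", "METFORMIN HCL",
                               "ATORVASTATIN", "LISINOPRIL", "OMEPRAZOLE"))
)

#' Default per-report Preferred-Term rates of the toy vocabulary
#'
#' Independent per-report inclusion probabilities for the synthetic PT
#' vocabulary (a toy stand-in, not MedDRA).  Cardiovascular terms carry
#' realistic low background rates; common non-cardiac terms provide bulk.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_pt_rates <- function() {
  c(
    # toy "Cardiac disorders" SOC members
    "Atrial fibrillation" = 0.004, "Arrhythmia" = 0.002,
    "Bradycardia" = 0.002, "Cardiac disorder" = 0.004,
    "Cardiac failure" = 0.006, "Cardiac failure congestive" = 0.002,
    "Cardiogenic shock" = 0.0004, "Cardiomyopathy" = 0.001,
    "Congestive cardiomyopathy" = 0.0003, "Myocardial infarction" = 0.004,
    "Acute myocardial infarction" = 0.001, "Myocarditis" = 0.0005,
    "Palpitations" = 0.005, "Pericarditis" = 0.0008,
    "Tachycardia" = 0.004, "Torsade de pointes" = 0.0005,
    "Ventricular tachycardia" = 0.001, "Long QT syndrome" = 0.0003,
    # cardiovascular terms outside the toy cardiac SOC
    "Electrocardiogram QT prolonged" = 0.003, "Pulmonary oedema" = 0.001,
    "Hypertension" = 0.008, "Hypertensive crisis" = 0.0005,
    "Blood pressure increased" = 0.003, "Acute coronary syndrome" = 0.0005,
    "Heart rate increased" = 0.002, "Heart rate irregular" = 0.001,
    "Electrocardiogram abnormal" = 0.001,
    # common non-cardiac terms
    "Dizziness" = 0.06, "Rash" = 0.05, "Pyrexia" = 0.04,
    "Arthralgia" = 0.04, "Decreased appetite" = 0.03, "Cough" = 0.03,
    "Insomnia" = 0.02, "Pain" = 0.05
  )
}

#' Default planted reporting-rate ratios
#'
#' The ribociclib pairs the analysis world treats as true signals: torsade
#' de pointes/QT prolongation and arrhythmia-related investigations, at
#' the reported disproportionality levels; every unlisted pair has
#' `rho = 1` (no association).
#'
#' @return A `data.frame` with columns `drug_id`, `query`, `rho`.
#' @export
default_planted_rr <- function() {
  data.frame(
    drug_id = c("ribociclib", "ribociclib"),
    query = c("Torsade de pointes/QT prolongation",
              "Arrhythmia-related investigations, signs, and symptoms"),
    rho = c(8.43, 8.19),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Builds (and validates) the parameter set of the synthetic corpus
#' generator.  Defaults encode the statistical structure of the CDK4/6
#' cohort: conditional drug mix 0.60/0.25/0.15 over a 30% class share,
#' 96.6/2.5/0.9 percent sex mix, age centred at 65, log-normal onset with
#' per-drug median 83/63/33 days and log-sd 2 (matching the heavy
#' reported IQRs), roughly a third of reports carrying computable dates,
#' and the two ribociclib pairs planted as signals.
#'
#' @param n_reports Number of original cases (before follow-up and
#'   duplicate versions are added).
#' @param seed Integer seed; a fixed seed gives byte-identical files.
#' @param drug_mix Named probabilities of the primary-suspect drug
#'   (must include `other` for the non-study background).
#' @param background_pt_rates Named per-report PT probabilities.
#' @param anchor_pts Pool of guaranteed one-per-report terms (disjoint
#'   from every query's term set so planted rates stay exact).
#' @param planted_rr `data.frame(drug_id, query, rho)` of planted
#'   reporting-rate ratios; unlisted pairs are at `rho = 1`.
#' @param queries Named list of `smq_definition`s the ratios refer to.
#' @param followup_rate Fraction of cases receiving a follow-up version.
#' @param cross_dup_rate Fraction of cases duplicated under a fresh caseid.
#' @param deleted_rate Fraction of caseids listed as FDA-deleted.
#' @param missing_age_rate Fraction with unclear age (mostly blank, some
#'   implausible values).
#' @param invalid_date_rate Fraction with corrupted start/event dates.
#' @param sex_probs,occupation_probs,countries Categorical mixes.
#' @param age_mean,age_sd Normal age model (years), truncated to 18--99.
#' @param onset_meanlog Named per-drug log-normal location of onset days.
#' @param onset_sdlog Log-normal scale of onset days.
#' @param quarter Label used in generated file names (e.g. `"24Q1"`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 5000, seed = 1L,
                       drug_mix = c(palbociclib = 0.18, ribociclib = 0.075,
                                    abemaciclib = 0.045, other = 0.70),
                       background_pt_rates = default_pt_rates(),
                       anchor_pts = c("Nausea", "Fatigue", "Headache",
                                      "Diarrhoea", "Vomiting", "Neutropenia",
                                      "Anaemia", "Alopecia"),
                       planted_rr = default_planted_rr(),
                       queries = load_bundled_queries(include_soc = FALSE),
                       followup_rate = 0.2, cross_dup_rate = 0.03,
                       deleted_rate = 0.02, missing_age_rate = 0.08,
                       invalid_date_rate = 0.7,
                       sex_probs = c(F = 0.966, M = 0.025, U = 0.009),
                       occupation_probs = c(MD = 0.20, PH = 0.12, RN = 0.05,
                                            HP = 0.049, CN = 0.446,
                                            OT = 0.10, LW = 0.035),
                       countries = c(US = 0.70, FR = 0.06, DE = 0.05,
                                     JP = 0.05, GB = 0.05, IT = 0.03,
                                     CA = 0.03, KR = 0.02, ES = 0.01),
                       age_mean = 65, age_sd = 12,
                       onset_meanlog = c(palbociclib = log(83),
                                         ribociclib = log(63),
                                         abemaciclib = log(33),
                                         other = log(69)),
                       onset_sdlog = 2.0,
                       quarter = "24Q1") {
  stopifnot(n_reports >= 1, all(drug_mix >= 0), "other" %in% names(drug_mix))
  if (!all(names(drug_mix) %in% names(.drug_name_pool))) {
    stop("drug_mix names must be among: ",
         paste(names(.drug_name_pool), collapse = ", "))
  }
  rates <- c(followup_rate, cross_dup_rate, deleted_rate,
             missing_age_rate, invalid_date_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(background_pt_rates < 0 | background_pt_rates > 1)) {
    stop("PT rates must lie in [0, 1]")
  }
  qpts <- unique(unlist(lapply(queries, `[[`, "pts")))
  if (any(anchor_pts %in% qpts)) {
    stop("anchor PTs must be disjoint from all query term sets")
  }
  if (!is.null(planted_rr) && nrow(planted_rr)) {
    bad <- setdiff(planted_rr$query, names(queries))
    if (length(bad)) {
      stop("planted_rr refers to unknown queries: ",
           paste(bad, collapse = ", "))
    }
    for (i in seq_len(nrow(planted_rr))) {
      q <- queries[[planted_rr$query[i]]]
      vocab_pts <- intersect(q$pts, names(background_pt_rates))
      if (any(planted_rr$rho[i] * background_pt_rates[vocab_pts] > 1)) {
        stop("configuration error: rho * background rate exceeds 1 for ",
             planted_rr$drug_id[i], " / ", planted_rr$query[i])
      }
    }
  }
  missing_onset <- setdiff(names(drug_mix), names(onset_meanlog))
  if (length(missing_onset)) {
    stop("onset_meanlog lacks entries for: ",
         paste(missing_onset, collapse = ", "))
  }
  cfg <- list(n_reports = as.integer(n_reports), seed = as.integer(seed),
              drug_mix = drug_mix / sum(drug_mix),
              background_pt_rates = background_pt_rates,
              anchor_pts = anchor_pts, planted_rr = planted_rr,
              queries = queries, followup_rate = followup_rate,
              cross_dup_rate = cross_dup_rate, deleted_rate = deleted_rate,
              missing_age_rate = missing_age_rate,
              invalid_date_rate = invalid_date_rate,
              sex_probs = sex_probs / sum(sex_probs),
              occupation_probs = occupation_probs / sum(occupation_probs),
              countries = countries / sum(countries),
              age_mean = age_mean, age_sd = age_sd,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              quarter = quarter)
  class(cfg) <- "sim_config"
  cfg
}

# generator-side date validity (mirrors the documented rules on purpose:
# an independent code path used to write the ledger truth)
.expected_date_status <- function(s, e, start_min_year = 1980,
                                  event_max_year = 2024) {
  n <- length(s)
  status <- rep("accepted", n)
  ok8 <- grepl("^[0-9]{8}$", s) & grepl("^[0-9]{8}$", e)
  status[!ok8] <- "non-8-digit"
  sd <- suppressWarnings(as.Date(ifelse(ok8, s, NA), format = "%Y%m%d"))
  ed <- suppressWarnings(as.Date(ifelse(ok8, e, NA), format = "%Y%m%d"))
  bad_parse <- ok8 & (is.na(sd) | is.na(ed))
  status[bad_parse] <- "unparseable"
  parsed <- ok8 & !bad_parse
  sy <- as.integer(substr(s, 1, 4)); ey <- as.integer(substr(e, 1, 4))
  bad_year <- parsed & (sy < start_min_year | sy > event_max_year |
                          ey > event_max_year)
  status[bad_year] <- "year-bound"
  status[parsed & !bad_year & ed < sd] <- "negative-interval"
  status
}

# generator-side resolution of what the cleaning cascade must retain
.expected_retained <- function(ledger, deleted_caseids) {
  x <- copy(ledger)
  x[, .ver := as.integer(caseversion)]
  x[, .pid := as.numeric(primaryid)]
  # latest version per caseid among non-deleted reports
  alive <- x[!caseid %in% deleted_caseids]
  setorder(alive, caseid, -fda_dt, -.ver, -.pid)
  keep1 <- alive[!duplicated(caseid), primaryid]
  # cross-caseid dedup on the content key among the latest versions
  lat <- x[primaryid %in% keep1]
  lat[, .key := paste(
    ifelse(is.na(age_key), "NA", formatC(age_key, digits = 8, format = "g")),
    event_dt, country,
    vapply(pts, function(p) paste(sort(p), collapse = "|"), character(1)),
    vapply(drugnames, function(d) {
      paste(sort(unique(normalize_name(d))), collapse = "|")
    }, character(1)),
    sep = "\r")]
  setorder(lat, .key, -fda_dt, -.ver, -.pid)
  keep2 <- lat[!duplicated(.key), primaryid]
  ledger$dedup_survivor <- ledger$primaryid %in% keep2
  ledger$expected_retained <- ledger$dedup_survivor & ledger$age_valid
  ledger
}

.fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS corpus
#'
#' Draws a corpus under `config`, optionally writes it as FAERS-dialect
#' quarterly files (`DEMO<q>.txt`, `DRUG<q>.txt`, `REAC<q>.txt`,
#' `OUTC<q>.txt`, `THER<q>.txt`, `DELETED<q>.txt`), and returns the
#' in-memory tables together with the ground-truth ledger.
#'
#' For a drug--query pair planted at ratio `rho`, every query term's
#' inclusion probability is multiplied by `rho` for reports of that drug,
#' so the true reporting-rate ratio against the background is `rho`.
#' Follow-ups duplicate an original under a later FDA receipt date and an
#' incremented caseversion; cross-caseid duplicates copy all content
#' fields of the deduplication key under a fresh caseid.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for the dialect files.
#' @return List with `tables` (demo/drug/reac/outc/ther data.tables),
#'   `deleted` (caseids), `ledger` (one row per report version, with
#'   per-query flag columns `flag_<name>` and `expected_retained`),
#'   `config` and `dir`.
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  vocab <- names(config$background_pt_rates)

  caseid <- as.character(1000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  drug_id <- sample(names(config$drug_mix), n, TRUE, prob = config$drug_mix)

  sex <- sample(names(config$sex_probs), n, TRUE, prob = config$sex_probs)
  sex[sex == "U"] <- ""
  occp <- sample(names(config$occupation_probs), n, TRUE,
                 prob = config$occupation_probs)
  country <- sample(names(config$countries), n, TRUE,
                    prob = config$countries)

  # --- age ---------------------------------------------------------------
  age_true <- round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                              18), 99))
  cod <- sample(c("YR", "", "MON", "DEC"), n, TRUE,
                prob = c(0.88, 0.05, 0.04, 0.03))
  age_val <- as.character(age_true)
  age_val[cod == "MON"] <- as.character(age_true[cod == "MON"] * 12)
  age_val[cod == "DEC"] <- as.character(round(age_true[cod == "DEC"] / 10))
  age_years <- age_true
  age_years[cod == "DEC"] <- round(age_true[cod == "DEC"] / 10) * 10
  u <- runif(n)
  unclear <- u < config$missing_age_rate
  implaus <- unclear & runif(n) < 0.2
  age_val[unclear] <- ""
  cod[unclear] <- ""
  age_val[implaus] <- "999"
  cod[implaus] <- "YR"
  age_valid <- !unclear
  age_years_out <- ifelse(age_valid, age_years, NA_real_)

  # --- dates -------------------------------------------------------------
  onset <- pmax(0, round(rlnorm(n, config$onset_meanlog[drug_id],
                                config$onset_sdlog)))
  start_date <- as.Date("2015-01-01") + sample(0:2921, n, TRUE)
  event_date <- start_date + onset
  fda_date <- pmin(event_date + sample(10:400, n, TRUE),
                   as.Date("2024-03-31"))
  fda_date <- pmax(fda_date, start_date)  # receipt never precedes start
  start_s <- .fmt_date(start_date)
  event_s <- .fmt_date(event_date)
  corrupt <- runif(n) < config$invalid_date_rate
  ctype <- sample(c("start6", "start4", "start_empty", "event6",
                    "event_empty", "start_pre1980", "event_post2024",
                    "event_bad_day", "event_before_start"),
                  n, TRUE)
  i <- which(corrupt & ctype == "start6")
  start_s[i] <- substr(start_s[i], 1, 6)
  i <- which(corrupt & ctype == "start4")
  start_s[i] <- substr(start_s[i], 1, 4)
  i <- which(corrupt & ctype == "start_empty"); start_s[i] <- ""
  i <- which(corrupt & ctype == "event6")
  event_s[i] <- substr(event_s[i], 1, 6)
  i <- which(corrupt & ctype == "event_empty"); event_s[i] <- ""
  i <- which(corrupt & ctype == "start_pre1980")
  start_s[i] <- paste0("1979", substr(start_s[i], 5, 8))
  i <- which(corrupt & ctype == "event_post2024")
  event_s[i] <- paste0("2025", substr(event_s[i], 5, 8))
  i <- which(corrupt & ctype == "event_bad_day")
  event_s[i] <- paste0(substr(event_s[i], 1, 6), "99")
  i <- which(corrupt & ctype == "event_before_start")
  event_s[i] <- .fmt_date(start_date[i] - sample(5:100, length(i), TRUE))
  date_status <- .expected_date_status(start_s, event_s)

  # --- reactions ---------------------------------------------------------
  P <- matrix(rep(config$background_pt_rates, each = n), nrow = n,
              dimnames = list(NULL, vocab))
  pr <- config$planted_rr
  if (!is.null(pr) && nrow(pr)) {
    for (k in seq_len(nrow(pr))) {
      qpts <- intersect(config$queries[[pr$query[k]]]$pts, vocab)
      rows <- drug_id == pr$drug_id[k]
      if (any(rows) && length(qpts)) {
        P[rows, qpts] <- pmin(1, pr$rho[k] * P[rows, qpts, drop = FALSE])
      }
    }
  }
  hit <- matrix(runif(n * length(vocab)), n) < P
  anchor <- sample(config$anchor_pts, n, TRUE)
  w <- which(hit, arr.ind = TRUE)
  extra <- split(vocab[w[, 2]], factor(w[, 1], levels = seq_len(n)))
  pts_list <- Map(function(a, e) unique(c(a, e)), anchor, extra)
  names(pts_list) <- NULL
  flags <- lapply(config$queries, function(q) {
    qi <- vocab %in% q$pts
    if (any(qi)) rowSums(hit[, qi, drop = FALSE]) > 0 else rep(FALSE, n)
  })

  # --- outcomes ----------------------------------------------------------
  outcome_probs <- c(DE = 0.131, LT = 0.011, HO = 0.17, DS = 0.005,
                     RI = 0.002, OT = 0.25)
  ohit <- matrix(runif(n * length(outcome_probs)), n) <
    matrix(rep(outcome_probs, each = n), nrow = n)
  colnames(ohit) <- names(outcome_probs)
  outcomes_list <- apply(ohit, 1, function(r) names(outcome_probs)[r],
                         simplify = FALSE)

  # --- drug rows ---------------------------------------------------------
  ps_name <- character(n)
  for (d in unique(drug_id)) {
    idx <- which(drug_id == d)
    ps_name[idx] <- sample(.drug_name_pool[[d]]$names, length(idx), TRUE)
  }
  ai_map <- vapply(.drug_name_pool, `[[`, character(1), "ai")
  ps_ai <- unname(ai_map[drug_id])
  ps_ai[ps_ai == ""] <- normalize_name(ps_name[ps_ai == ""])
  n_con <- sample(0:3, n, TRUE, prob = c(0.30, 0.35, 0.25, 0.10))
  con_pool <- .drug_name_pool$other$names
  rep_idx <- rep(seq_len(n), n_con)
  con_names <- sample(con_pool, length(rep_idx), TRUE)
  con_roles <- sample(c("C", "SS"), length(rep_idx), TRUE,
                      prob = c(0.8, 0.2))
  drug_dt <- rbind(
    data.table(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
               drugname = ps_name, prod_ai = ps_ai),
    data.table(primaryid = primaryid[rep_idx],
               drug_seq = as.character(sequence(n_con) + 1L),
               role_cod = con_roles, drugname = con_names, prod_ai = ""))
  setorder(drug_dt, primaryid, drug_seq)
  con_split <- split(con_names, factor(rep_idx, levels = seq_len(n)))
  drugnames_list <- Map(c, ps_name, con_split)
  names(drugnames_list) <- NULL

  reac_dt <- data.table(
    primaryid = rep(primaryid, lengths(pts_list)),
    pt = unlist(pts_list))
  # occasional duplicate PT line (exercises set semantics downstream)
  dup_pt <- which(runif(n) < 0.02)
  if (length(dup_pt)) {
    reac_dt <- rbind(reac_dt, data.table(primaryid = primaryid[dup_pt],
                                         pt = anchor[dup_pt]))
  }
  outc_dt <- data.table(
    primaryid = rep(primaryid, lengths(outcomes_list)),
    outc_cod = unlist(outcomes_list))
  ther_dt <- data.table(primaryid = primaryid, dsg_drug_seq = "1",
                        start_dt = start_s)

  demo_dt <- data.table(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    fda_dt = .fmt_date(fda_date), event_dt = event_s, age = age_val,
    age_cod = cod, sex = sex, occp_cod = occp, occr_country = country)

  ledger <- data.table(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    kind = "original", cluster_id = caseid, drug_id = drug_id,
    fda_dt = demo_dt$fda_dt, event_dt = event_s, start_dt = start_s,
    age = age_val, age_cod = cod, age_years = age_years_out,
    age_key = age_in_years(age_val, cod),
    age_valid = age_valid, date_status = date_status, onset_days = onset,
    sex = sex, occp_cod = occp, country = country,
    pts = pts_list, drugnames = drugnames_list,
    outcomes = outcomes_list)
  for (qn in names(flags)) ledger[, (paste0("flag_", qn)) := flags[[qn]]]

  # --- follow-up versions ------------------------------------------------
  idx_f <- which(runif(n) < config$followup_rate)
  if (length(idx_f)) {
    f_pid <- paste0(caseid[idx_f], "2")
    f_fda <- .fmt_date(fda_date[idx_f] + sample(30:300, length(idx_f), TRUE))
    fd <- copy(demo_dt[idx_f])
    fd[, `:=`(primaryid = f_pid, caseversion = "2", fda_dt = f_fda)]
    demo_dt <- rbind(demo_dt, fd)
    for (tab in c("drug_dt", "reac_dt", "outc_dt", "ther_dt")) {
      src <- get(tab)
      cp <- copy(src[primaryid %chin% paste0(caseid[idx_f], "1")])
      map <- setNames(f_pid, paste0(caseid[idx_f], "1"))
      cp[, primaryid := unname(map[primaryid])]
      assign(tab, rbind(src, cp))
    }
    fl <- copy(ledger[idx_f])
    fl[, `:=`(primaryid = f_pid, caseversion = "2", kind = "followup",
              fda_dt = f_fda)]
    ledger <- rbind(ledger, fl)
  }

  # --- deleted cases -----------------------------------------------------
  idx_del <- which(runif(n) < config$deleted_rate)
  deleted_caseids <- caseid[idx_del]

  # --- cross-caseid duplicates -------------------------------------------
  cand <- setdiff(seq_len(n), idx_del)
  idx_d <- cand[runif(length(cand)) < config$cross_dup_rate]
  if (length(idx_d)) {
    d_case <- as.character(3000000 + seq_along(idx_d))
    d_pid <- paste0(d_case, "1")
    latest_by_case <- ledger[, .(fda = max(fda_dt)), by = caseid]
    latest_fda <- latest_by_case$fda[match(caseid[idx_d],
                                           latest_by_case$caseid)]
    d_fda <- .fmt_date(as.Date(latest_fda, format = "%Y%m%d") +
                         sample(1:30, length(idx_d), TRUE))
    dd <- copy(demo_dt[match(paste0(caseid[idx_d], "1"), primaryid)])
    dd[, `:=`(primaryid = d_pid, caseid = d_case, caseversion = "1",
              fda_dt = d_fda)]
    demo_dt <- rbind(demo_dt, dd)
    for (tab in c("drug_dt", "reac_dt", "outc_dt", "ther_dt")) {
      src <- get(tab)
      cp <- copy(src[primaryid %chin% paste0(caseid[idx_d], "1")])
      map <- setNames(d_pid, paste0(caseid[idx_d], "1"))
      cp[, primaryid := unname(map[primaryid])]
      assign(tab, rbind(src, cp))
    }
    src_case <- caseid[idx_d]
    dl <- copy(ledger[idx_d])
    dl[, `:=`(primaryid = d_pid, caseid = d_case, caseversion = "1",
              kind = "crossdup", cluster_id = src_case, fda_dt = d_fda)]
    ledger <- rbind(ledger, dl)
  }

  ledger[, deleted := caseid %in% deleted_caseids]
  ledger <- .expected_retained(ledger, deleted_caseids)

  tables <- list(demo = demo_dt, drug = drug_dt, reac = reac_dt,
                 outc = outc_dt, ther = ther_dt)
  if (!is.null(dir)) {
    write_corpus(tables, deleted_caseids, dir, quarter = config$quarter)
  }
  list(tables = tables, deleted = deleted_caseids, ledger = ledger,
       config = config, dir = dir)
}

#' Write corpus tables as FAERS-dialect quarterly files
#'
#' @param tables Named list with `demo`, `drug`, `reac`, `outc`, `ther`.
#' @param deleted Character vector of deleted caseids.
#' @param dir Output directory (created if missing).
#' @param quarter Quarter label used in the file names.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(tables, deleted, dir, quarter = "24Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(dt, name) {
    data.table::fwrite(dt, file.path(dir, paste0(name, quarter, ".txt")),
                       sep = "$", quote = FALSE)
  }
  wr(tables$demo, "DEMO"); wr(tables$drug, "DRUG")
  wr(tables$reac, "REAC"); wr(tables$outc, "OUTC")
  wr(tables$ther, "THER")
  wr(data.table(caseid = deleted), "DELETED")
  invisible(dir)
}

#' Hand-built deterministic fixture corpora
#'
#' Small corpora with constructed truth covering the cleaning and
#' validation edge cases: a 3-report cross-caseid duplicate cluster, a
#' follow-up chain, deleted cases, every age unit code, every
#' date-rejection category, duplicate PT lines, and a report with two
#' primary-suspect study drugs.
#'
#' @return Named list of fixtures; each has `tables`, `deleted` and a
#'   `truth` list describing the expected behaviour.
#' @export
make_fixture_suite <- function() {
  demo_cols <- .faers_columns$demo
  mk_demo <- function(...) {
    rows <- list(...)
    rbindlist(lapply(rows, function(r) {
      d <- as.list(setNames(rep("", length(demo_cols)), demo_cols))
      d[names(r)] <- r
      as.data.table(d)
    }))
  }
  mk_drug <- function(...) {
    rbindlist(lapply(list(...), function(r) {
      d <- list(primaryid = r[[1]], drug_seq = r[[2]], role_cod = r[[3]],
                drugname = r[[4]], prod_ai = if (length(r) > 4) r[[5]] else "")
      as.data.table(d)
    }))
  }
  mk_reac <- function(...) {
    rbindlist(lapply(list(...), function(r) {
      data.table(primaryid = r[[1]], pt = r[[2]])
    }))
  }
  empty_outc <- data.table(primaryid = character(0), outc_cod = character(0))
  empty_ther <- data.table(primaryid = character(0),
                           dsg_drug_seq = character(0),
                           start_dt = character(0))
  base_demo <- function(pid, cid, ver = "1", fda = "20200101", ...) {
    c(list(primaryid = pid, caseid = cid, caseversion = ver, fda_dt = fda,
           age = "65", age_cod = "YR", sex = "F", occp_cod = "MD",
           occr_country = "US", event_dt = "20190601"), list(...))
  }

  fixtures <- list()

  # three caseids, identical dedup key -> cleaning keeps 1, removes 2
  fixtures$dup_cluster_3 <- {
    demo <- mk_demo(base_demo("11", "1", fda = "20200101"),
                    base_demo("21", "2", fda = "20200301"),
                    base_demo("31", "3", fda = "20200201"))
    drug <- mk_drug(list("11", "1", "PS", "IBRANCE"),
                    list("21", "1", "PS", "ibrance"),
                    list("31", "1", "PS", "IBRANCE."))
    reac <- mk_reac(list("11", "Nausea"), list("21", "Nausea"),
                    list("31", "Nausea"))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = empty_ther),
         deleted = character(0),
         truth = list(n_retained = 1L, retained_primaryid = "21",
                      n_removed_crossdup = 2L))
  }

  # one caseid with three versions -> keep version 3
  fixtures$followup_chain <- {
    demo <- mk_demo(base_demo("101", "10", "1", "20180101"),
                    base_demo("102", "10", "2", "20190101"),
                    base_demo("103", "10", "3", "20200101"))
    drug <- mk_drug(list("101", "1", "PS", "KISQALI"),
                    list("102", "1", "PS", "KISQALI"),
                    list("103", "1", "PS", "KISQALI"))
    reac <- mk_reac(list("101", "Rash"), list("102", "Rash"),
                    list("103", "Rash"))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = empty_ther),
         deleted = character(0),
         truth = list(retained_primaryid = "103"))
  }

  # deleted caseid removed before anything else
  fixtures$deleted_cases <- {
    demo <- mk_demo(base_demo("201", "20", event_dt = "20190601"),
                    base_demo("211", "21", event_dt = "20190702"),
                    base_demo("221", "22", event_dt = "20190803"))
    drug <- mk_drug(list("201", "1", "PS", "VERZENIO"),
                    list("211", "1", "PS", "VERZENIO"),
                    list("221", "1", "PS", "VERZENIO"))
    reac <- mk_reac(list("201", "Pain"), list("211", "Pain"),
                    list("221", "Pain"))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = empty_ther),
         deleted = "21",
         truth = list(retained_caseids = c("20", "22")))
  }

  # one report per age unit code, including invalid entries
  fixtures$unit_codes <- {
    spec <- list(
      list(age = "7", cod = "DEC", years = 70),
      list(age = "65", cod = "YR", years = 65),
      list(age = "6", cod = "MON", years = 0.5),
      list(age = "26", cod = "WK", years = 26 / 52.143),
      list(age = "730.5", cod = "DY", years = 2),
      list(age = "8766", cod = "HR", years = 1),
      list(age = "65", cod = "", years = 65),
      list(age = "", cod = "", years = NA_real_),
      list(age = "999", cod = "YR", years = NA_real_))
    rows <- lapply(seq_along(spec), function(i) {
      base_demo(paste0("30", i), paste0("3", i),
                event_dt = sprintf("201906%02d", i),
                age = spec[[i]]$age, age_cod = spec[[i]]$cod)
    })
    demo <- do.call(mk_demo, rows)
    drug <- rbindlist(lapply(seq_along(spec), function(i) {
      mk_drug(list(paste0("30", i), "1", "PS", "IBRANCE"))
    }))
    reac <- rbindlist(lapply(seq_along(spec), function(i) {
      mk_reac(list(paste0("30", i), "Nausea"))
    }))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = empty_ther),
         deleted = character(0),
         truth = list(expected_years = vapply(spec, `[[`, numeric(1),
                                              "years")))
  }

  # every date-rejection category; no record survives time-to-event
  fixtures$all_invalid_dates <- {
    # distinct event dates so the reports are not cross-caseid duplicates
    dates <- list(
      list(start = "201912", event = "20200102", status = "non-8-digit"),
      list(start = "", event = "20200103", status = "non-8-digit"),
      list(start = "20200199", event = "20200301", status = "unparseable"),
      list(start = "19791231", event = "20200104", status = "year-bound"),
      list(start = "20200101", event = "20250101", status = "year-bound"),
      list(start = "20200301", event = "20200105",
           status = "negative-interval"))
    rows <- lapply(seq_along(dates), function(i) {
      base_demo(paste0("40", i), paste0("4", i),
                event_dt = dates[[i]]$event)
    })
    demo <- do.call(mk_demo, rows)
    drug <- rbindlist(lapply(seq_along(dates), function(i) {
      mk_drug(list(paste0("40", i), "1", "PS", "KISQALI"))
    }))
    ther <- rbindlist(lapply(seq_along(dates), function(i) {
      data.table(primaryid = paste0("40", i), dsg_drug_seq = "1",
                 start_dt = dates[[i]]$start)
    }))
    reac <- rbindlist(lapply(seq_along(dates), function(i) {
      mk_reac(list(paste0("40", i), "Dizziness"))
    }))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = ther),
         deleted = character(0),
         truth = list(statuses = vapply(dates, `[[`, character(1),
                                        "status"),
                      n_valid = 0L))
  }

  # duplicate PT lines collapse to a set
  fixtures$multi_pt <- {
    demo <- mk_demo(base_demo("501", "50"))
    drug <- mk_drug(list("501", "1", "PS", "IBRANCE"))
    reac <- mk_reac(list("501", "Nausea"), list("501", "Nausea"),
                    list("501", "Cardiac failure"))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = empty_ther),
         deleted = character(0),
         truth = list(pts = c("Cardiac failure", "Nausea")))
  }

  # two PS rows matching two study drugs -> both cohorts, once each
  fixtures$multi_drug_ps <- {
    demo <- mk_demo(base_demo("601", "60"),
                    base_demo("611", "61", event_dt = "20190704"))
    drug <- mk_drug(list("601", "1", "PS", "IBRANCE"),
                    list("601", "2", "PS", "KISQALI"),
                    list("611", "1", "C", "IBRANCE"),
                    list("611", "2", "PS", "LETROZOLE"))
    reac <- mk_reac(list("601", "Hypertension"), list("611", "Rash"))
    list(tables = list(demo = demo, drug = drug, reac = reac,
                       outc = empty_outc, ther = empty_ther),
         deleted = character(0),
         truth = list(palbociclib = "601", ribociclib = "601",
                      not_in_any = "611"))
  }

  fixtures
}
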