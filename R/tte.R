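# Time-to-event: days from the (earliest) primary-suspect drug start date
# to the report's adverse-event date, under strict date-validity rules.
# Rejections are data, not errors: each rejected pair gets exactly one
# category so that category counts partition the rejected set.

#' Validate a start/event date pair
#'
#' A pair is accepted iff both strings are 8 digits (`YYYYMMDD`), parse as
#' real calendar dates, the years are plausible (start year at or after
#' `start_min_year`, no year past `event_max_year`) and the event does not
#' precede the start.  Otherwise it is assigned one rejection category, in
#' this order of precedence: `non-8-digit`, `unparseable`, `year-bound`,
#' `negative-interval`.
#'
#' @param start_raw,event_raw Character vectors of raw date strings
#'   (recycled to common length).
#' @param start_min_year Earliest plausible start year (default 1980).
#' @param event_max_year Latest plausible year (default 2024).
#' @return A `data.table` with columns `start_raw`, `event_raw`, `status`
#'   (`"accepted"` or a rejection category), `start_date`, `event_date`
#'   (`Date`, `NA` unless accepted) and `days` (integer, `NA` unless
#'   accepted).
#' @export
validate_dates <- function(start_raw, event_raw,
                           start_min_year = 1980, event_max_year = 2024) {
  n <- max(length(start_raw), length(event_raw))
  s <- rep_len(as.character(start_raw), n)
  e <- rep_len(as.character(event_raw), n)
  s[is.na(s)] <- ""
  e[is.na(e)] <- ""
  status <- rep("accepted", n)

  ok8 <- grepl("^[0-9]{8}$", s) & grepl("^[0-9]{8}$", e)
  status[!ok8] <- "non-8-digit"

  sd <- ed <- as.Date(rep(NA, n))
  sd[ok8] <- as.Date(s[ok8], format = "%Y%m%d")
  ed[ok8] <- as.Date(e[ok8], format = "%Y%m%d")
  bad_parse <- ok8 & (is.na(sd) | is.na(ed))
  status[bad_parse] <- "unparseable"

  parsed <- ok8 & !bad_parse
  sy <- suppressWarnings(as.integer(substr(s, 1, 4)))
  ey <- suppressWarnings(as.integer(substr(e, 1, 4)))
  bad_year <- parsed &
    (sy < start_min_year | sy > event_max_year | ey > event_max_year)
  status[bad_year] <- "year-bound"

  neg <- parsed & !bad_year & (ed < sd)
  status[neg] <- "negative-interval"

  acc <- status == "accepted"
  days <- rep(NA_integer_, n)
  days[acc] <- as.integer(ed[acc] - sd[acc])
  sd[!acc] <- NA
  ed[!acc] <- NA
  data.table(start_raw = s, event_raw = e, status = status,
             start_date = sd, event_date = ed, days = days)
}

#' Earliest primary-suspect start date for a drug
#'
#' Among a report's drug rows with role code `PS` that match `drug_id` in
#' the dictionary, returns the minimum 8-digit-format start date, or
#' `NA` when no matching PS row carries one.
#'
#' @param drugs A report's drug rows (data.table with `role_cod`,
#'   `drugname`, `prod_ai`, `start_dt`).
#' @param drug_id Dictionary drug id.
#' @param dictionary A `drug_dictionary`.
#' @return Character scalar (`YYYYMMDD`) or `NA_character_`.
#' @export
earliest_suspect_start <- function(drugs, drug_id, dictionary) {
  ps <- drugs[drugs$role_cod == "PS", , drop = FALSE]
  if (!nrow(ps)) return(NA_character_)
  hits <- .match_many(normalize_name(ps$drugname), normalize_name(ps$prod_ai),
                      dictionary)
  starts <- ps$start_dt[vapply(hits, function(h) drug_id %in% h, logical(1))]
  starts <- starts[grepl("^[0-9]{8}$", starts)]
  if (!length(starts)) NA_character_ else min(starts)
}

#' Time-to-event records for per-drug cohorts
#'
#' For every report in each primary-suspect subset, takes the report-level
#' event date and the earliest matching PS start date, validates the pair
#' with [validate_dates()] and computes the onset in days for the accepted
#' ones.  A report without any 8-digit PS start is rejected as
#' `non-8-digit`.
#'
#' @param drug_subsets Named list of case subsets
#'   (see [select_primary_suspect()]).
#' @param dictionary The `drug_dictionary` used to build the subsets.
#' @param start_min_year,event_max_year Passed to [validate_dates()].
#' @return A `data.table` with columns `drug_id`, `caseid`, `primaryid`,
#'   `status`, `start_date`, `event_date`, `days`.  Attribute
#'   `rejections` tabulates status by drug.
#' @export
tte_records <- function(drug_subsets, dictionary = default_drug_dictionary(),
                        start_min_year = 1980, event_max_year = 2024) {
  rows <- lapply(names(drug_subsets), function(id) {
    sub <- drug_subsets[[id]]
    if (!nrow(sub)) return(NULL)
    starts <- vapply(sub$drugs, earliest_suspect_start, character(1),
                     drug_id = id, dictionary = dictionary)
    starts[is.na(starts)] <- ""
    v <- validate_dates(starts, sub$event_dt,
                        start_min_year = start_min_year,
                        event_max_year = event_max_year)
    data.table(drug_id = id, caseid = sub$caseid, primaryid = sub$primaryid,
               status = v$status, start_date = v$start_date,
               event_date = v$event_date, days = v$days)
  })
  out <- rbindlist(rows)
  if (!nrow(out)) {
    out <- data.table(drug_id = character(0), caseid = character(0),
                      primaryid = character(0), status = character(0),
                      start_date = as.Date(character(0)),
                      event_date = as.Date(character(0)),
                      days = integer(0))
  }
  setattr(out, "rejections",
          if (nrow(out)) table(out$drug_id, out$status) else NULL)
  out[]
}

#' Summarize time-to-event by group
#'
#' Median and quartiles over the accepted records, using the
#' linear-interpolation quantile convention (R type 7).  Groups with no
#' valid record are omitted.  When `group_sizes` is supplied (named
#' vector of cohort sizes), the share of the cohort with a computable
#' time-to-event is reported as `pct_valid`.
#'
#' @param records Output of [tte_records()] (or any table with `days` and
#'   the grouping column); only rows with `status == "accepted"` are used
#'   when a `status` column is present.
#' @param by Grouping column name (default `"drug_id"`).
#' @param group_sizes Optional named numeric vector of group sizes.
#' @return A `data.table` with columns `by`, `n_valid`, `median`, `q1`,
#'   `q3` and optionally `pct_valid` (one decimal).
#' @export
summarize_tte <- function(records, by = "drug_id", group_sizes = NULL) {
  x <- as.data.table(records)
  if ("status" %in% names(x)) x <- x[status == "accepted"]
  x <- x[!is.na(days)]
  out <- x[, {
    q <- quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    .(n_valid = .N, median = q[2], q1 = q[1], q3 = q[3])
  }, by = by]
  if (!is.null(group_sizes) && nrow(out)) {
    out[, pct_valid := round(100 * n_valid /
                               as.numeric(group_sizes[get(by)]), 1)]
  }
  setorderv(out, by)
  out[]
}
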