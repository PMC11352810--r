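# Report-cleaning cascade: FDA-deleted case removal, two-stage
# deduplication (latest version per caseid, then cross-caseid content
# duplicates), and age validation.

# conversion from FAERS age unit codes to years
.age_unit_factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143,
                       DY = 1 / 365.25, HR = 1 / 8766)

#' Convert FAERS age fields to years
#'
#' Applies the unit-code conversion (DEC x10, YR x1, MON /12, WK /52.143,
#' DY /365.25, HR /8766).  A blank unit code with a numeric age is treated
#' as years, the dominant FAERS convention; non-numeric ages and unknown
#' unit codes give `NA`.
#'
#' @param age Character vector of raw age values.
#' @param age_cod Character vector of unit codes.
#' @return Numeric vector of ages in years (`NA` where unconvertible).
#' @export
age_in_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  cod[cod == "" & !is.na(v)] <- "YR"
  unname(v * .age_unit_factors[cod])
}

# sort helper columns: "most recent" = max (fda_dt, caseversion, primaryid)
.add_order_cols <- function(x) {
  x[, .ver := suppressWarnings(as.integer(caseversion))]
  x[is.na(.ver), .ver := 0L]
  x[, .pid := suppressWarnings(as.numeric(primaryid))]
  x[is.na(.pid), .pid := 0]
  x
}

#' Remove FDA-deleted cases
#'
#' Drops every report whose `caseid` appears in the quarterly deleted-case
#' lists.  The number of removals is stored in the `n_removed` attribute.
#'
#' @param cases A case table.
#' @param deleted_caseids Character vector of caseids flagged as erroneous.
#' @return The retained case table.
#' @export
drop_deleted <- function(cases, deleted_caseids) {
  keep <- !cases$caseid %in% deleted_caseids
  out <- cases[keep]
  setattr(out, "n_removed", sum(!keep))
  out
}

#' Keep the most recent report version per caseid
#'
#' FAERS distributes initial and follow-up versions of the same case.  The
#' retained version maximizes `(fda_dt, caseversion, primaryid)`
#' lexicographically: FDA receipt date is the clock, caseversion breaks
#' same-day follow-ups, and primaryid (unique) breaks anything left.
#'
#' @param cases A case table.
#' @return One report per caseid; attribute `n_removed` counts drops.
#' @export
keep_latest_per_caseid <- function(cases) {
  x <- .add_order_cols(copy(cases))
  setorder(x, caseid, -fda_dt, -.ver, -.pid)
  out <- x[!duplicated(caseid)]
  out[, c(".ver", ".pid") := NULL]
  setattr(out, "n_removed", nrow(cases) - nrow(out))
  out[]
}

#' Deduplication key for cross-caseid duplicate detection
#'
#' A report's key is the tuple (age in years, event date, reporter country,
#' sorted Preferred-Term set, sorted normalized drug-name set).  Missing
#' fields compare equal to missing.  Equal report content gives an equal
#' key.
#'
#' @param cases A case table.
#' @return Character vector, one key per report.
#' @export
dedup_key <- function(cases) {
  yrs <- age_in_years(cases$age, cases$age_cod)
  agek <- ifelse(is.na(yrs), "NA", formatC(yrs, digits = 8, format = "g"))
  ptk <- vapply(cases$pts,
                function(p) paste(sort(p), collapse = "|"), character(1))
  drk <- vapply(cases$drugs, function(d) {
    paste(sort(unique(normalize_name(d$drugname))), collapse = "|")
  }, character(1))
  paste(agek, cases$event_dt, cases$occr_country, ptk, drk, sep = "\r")
}

#' Remove duplicate reports filed under different caseids
#'
#' Reports with identical age, event date, reporter country, adverse-event
#' set and (normalized) drug-name set are regarded as the same event even
#' when their caseids differ; one representative, the most recent by
#' `(fda_dt, caseversion, primaryid)`, is retained per key.
#'
#' @param cases A case table, already unique per caseid.
#' @return The retained case table; attribute `n_removed` counts drops.
#' @export
dedup_cross_caseid <- function(cases) {
  x <- .add_order_cols(copy(cases))
  x[, .key := dedup_key(x)]
  setorder(x, .key, -fda_dt, -.ver, -.pid)
  out <- x[!duplicated(.key)]
  out[, c(".ver", ".pid", ".key") := NULL]
  setattr(out, "n_removed", nrow(cases) - nrow(out))
  out[]
}

#' Exclude reports with unclear age information
#'
#' Retains reports whose age converts to years via [age_in_years()] and
#' falls inside `bounds` (default 0--120 years, excluding unit-coding
#' errors without discarding valid elderly patients), and populates the
#' `age_years` column on the retained reports.
#'
#' @param cases A case table.
#' @param bounds Length-2 numeric, inclusive plausibility bounds in years.
#' @return The retained case table; attributes `n_removed` and
#'   `n_blank_unit` (numeric age with blank unit code, treated as years).
#' @export
filter_valid_age <- function(cases, bounds = c(0, 120)) {
  yrs <- age_in_years(cases$age, cases$age_cod)
  keep <- !is.na(yrs) & yrs >= bounds[1] & yrs <= bounds[2]
  out <- copy(cases[keep])
  if (nrow(out)) out[, age_years := yrs[keep]]
  setattr(out, "n_removed", sum(!keep))
  setattr(out, "n_blank_unit",
          sum(keep & trimws(cases$age_cod) == "" & !is.na(yrs)))
  out
}

#' Run the full report-cleaning cascade
#'
#' Applies, in order: [drop_deleted()], [keep_latest_per_caseid()],
#' [dedup_cross_caseid()], [filter_valid_age()].  The cascade is idempotent
#' and each stage can only shrink the corpus.
#'
#' @param cases A case table from [assemble_cases()].
#' @param deleted_caseids Character vector of FDA-deleted caseids.
#' @param age_bounds Passed to [filter_valid_age()].
#' @return The cleaned case table.  Attribute `manifest` is a named integer
#'   vector of stage counts (`n_raw`, `n_after_deleted`,
#'   `n_after_version_dedup`, `n_after_crosscase_dedup`, `n_after_age`).
#' @export
clean_cases <- function(cases, deleted_caseids = character(0),
                        age_bounds = c(0, 120)) {
  s1 <- drop_deleted(cases, deleted_caseids)
  s2 <- keep_latest_per_caseid(s1)
  s3 <- dedup_cross_caseid(s2)
  s4 <- filter_valid_age(s3, bounds = age_bounds)
  manifest <- c(n_raw = nrow(cases),
                n_after_deleted = nrow(s1),
                n_after_version_dedup = nrow(s2),
                n_after_crosscase_dedup = nrow(s3),
                n_after_age = nrow(s4))
  setattr(s4, "manifest", manifest)
  s4
}
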