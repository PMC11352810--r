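# Table-1 style cohort characteristics: age, sex, reporter occupation
# classes, serious outcomes.  Percents always use the group size as
# denominator and round to one decimal at the presentation boundary.

#' Default reporter-occupation mapping
#'
#' Maps FAERS `occp_cod` codes to three reporting classes: `MD`, `PH`,
#' `RN`, `HP` are healthcare professionals, `CN` is consumer; any other
#' non-empty code is "other"; empty or `UNK` is unknown.  The mapping is
#' configuration, not a hard-coded rule: supply your own named list to
#' [classify_occupation()] to change it.
#'
#' @return Named list of code vectors.
#' @export
default_occupation_mapping <- function() {
  list(healthcare_professional = c("MD", "PH", "RN", "HP"),
       consumer = "CN")
}

#' Classify reporter occupation codes
#'
#' @param occp_cod Character vector of FAERS occupation codes.
#' @param mapping Named list of code vectors
#'   (default [default_occupation_mapping()]); codes not covered map to
#'   `"other"`, empty/`UNK` to `"unknown"`.
#' @return Character vector of classes.
#' @export
classify_occupation <- function(occp_cod, mapping = default_occupation_mapping()) {
  code <- toupper(trimws(occp_cod))
  out <- rep("other", length(code))
  out[code == "" | code == "UNK"] <- "unknown"
  for (cls in names(mapping)) out[code %in% mapping[[cls]]] <- cls
  out
}

.pct <- function(k, n) round(100 * k / n, 1)

#' Cohort characteristics summary
#'
#' For each group of reports produces long-format rows covering the group
#' size, median age with quartiles, sex counts, reporter occupation
#' classes, and serious-outcome counts (non-exclusive: a report may carry
#' several outcome codes, so outcome percents need not sum to 100).
#'
#' @param groups Named list of case tables (e.g. the full cohort plus the
#'   per-drug subsets); a single case table is treated as one group
#'   named `"all"`.
#' @param occupation_mapping Passed to [classify_occupation()].
#' @return A `data.table` with columns `group`, `section`, `item`, `n`,
#'   `pct`, `median`, `q1`, `q3` (the last three populated only for the
#'   age section).
#' @export
summarize_cohort <- function(groups, occupation_mapping = default_occupation_mapping()) {
  if (is.data.frame(groups)) groups <- list(all = groups)
  outcome_labels <- c(DE = "Death", LT = "Life-threatening",
                      HO = "Hospitalization", DS = "Disability",
                      RI = "Required intervention")
  rows <- lapply(names(groups), function(g) {
    cases <- groups[[g]]
    N <- nrow(cases)
    out <- list(data.table(group = g, section = "total", item = "reports",
                           n = N, pct = NA_real_, median = NA_real_,
                           q1 = NA_real_, q3 = NA_real_))
    if (N == 0L) return(rbindlist(out))

    ages <- cases$age_years
    ages <- ages[!is.na(ages)]
    if (length(ages)) {
      q <- quantile(ages, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out <- c(out, list(data.table(
        group = g, section = "age", item = "years", n = length(ages),
        pct = NA_real_, median = q[2], q1 = q[1], q3 = q[3])))
    }

    sexcode <- toupper(trimws(cases$sex))
    sexcls <- ifelse(sexcode == "F", "Female",
                     ifelse(sexcode == "M", "Male", "Unknown"))
    sextab <- table(factor(sexcls, levels = c("Female", "Male", "Unknown")))
    out <- c(out, list(data.table(
      group = g, section = "sex", item = names(sextab),
      n = as.integer(sextab), pct = .pct(as.integer(sextab), N),
      median = NA_real_, q1 = NA_real_, q3 = NA_real_)))

    occ <- classify_occupation(cases$occp_cod, occupation_mapping)
    lev <- c(names(occupation_mapping), "other", "unknown")
    occtab <- table(factor(occ, levels = unique(lev)))
    out <- c(out, list(data.table(
      group = g, section = "occupation", item = names(occtab),
      n = as.integer(occtab), pct = .pct(as.integer(occtab), N),
      median = NA_real_, q1 = NA_real_, q3 = NA_real_)))

    counts <- vapply(names(outcome_labels), function(code) {
      sum(vapply(cases$outcomes, function(o) code %in% o, logical(1)))
    }, integer(1))
    out <- c(out, list(data.table(
      group = g, section = "outcome", item = unname(outcome_labels),
      n = unname(counts), pct = .pct(unname(counts), N),
      median = NA_real_, q1 = NA_real_, q3 = NA_real_)))
    rbindlist(out)
  })
  rbindlist(rows)
}
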