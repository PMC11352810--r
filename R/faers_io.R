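# Reading and writing the FAERS quarterly ASCII dialect and joining the
# tables into per-report case records.  All values are kept as opaque
# strings here; typing (ages, dates) happens in the cleaning stage so that
# malformed entries survive ingestion and can be counted as exclusions.

# canonical column sets per table kind; unknown columns are ignored and
# missing ones are filled with "" to absorb schema drift across quarters
.faers_columns <- list(
  demo    = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
              "age", "age_cod", "sex", "occp_cod", "occr_country"),
  drug    = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac    = c("primaryid", "pt"),
  outc    = c("primaryid", "outc_cod"),
  ther    = c("primaryid", "dsg_drug_seq", "start_dt"),
  deleted = c("caseid")
)

#' Read one FAERS ASCII table
#'
#' Parses a "$"-delimited FAERS quarterly file (first row is the header)
#' into a `data.table` of character columns.  Parsing is header-name driven,
#' so column order and extra columns added by the FDA in later quarters are
#' tolerated; canonical columns absent from the file come back as `""`.
#'
#' @param path Path to the file.
#' @param kind Table kind: `"demo"`, `"drug"`, `"reac"`, `"outc"`,
#'   `"ther"` or `"deleted"`.
#' @return A `data.table` with the canonical columns for `kind`, one row per
#'   data line, all columns character.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country",
#'              "100001$10001$1$20150105$20150101$65$YR$F$MD$US"), f)
#' read_faers_table(f, "demo")
#' @export
read_faers_table <- function(path, kind = names(.faers_columns)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read FAERS table: ", path)
  dt <- data.table::fread(
    path, sep = "$", quote = "", header = TRUE, colClasses = "character",
    fill = TRUE, encoding = "UTF-8", na.strings = NULL, showProgress = FALSE,
    blank.lines.skip = TRUE
  )
  setnames(dt, tolower(names(dt)))
  key_col <- if (kind == "deleted") "caseid" else "primaryid"
  if (!key_col %in% names(dt)) {
    stop("format error: header of ", basename(path),
         " lacks required column '", key_col, "'")
  }
  want <- .faers_columns[[kind]]
  for (col in setdiff(want, names(dt))) dt[, (col) := ""]
  dt <- dt[, want, with = FALSE]
  for (j in seq_along(dt)) {
    nas <- which(is.na(dt[[j]]))
    if (length(nas)) set(dt, nas, j, "")
  }
  dt[]
}

#' Read all FAERS tables found in a directory
#'
#' Collects every `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`, `OUTC*.txt`,
#' `THER*.txt` and `DELETED*.txt` file under `dir` (the FAERS quarterly
#' naming scheme, e.g. `DEMO24Q1.txt`) and row-binds the quarters per kind.
#'
#' @param dir Directory containing the quarterly files.
#' @return A list with elements `demo`, `drug`, `reac`, `outc`, `ther`
#'   (data.tables, possibly zero-row) and `deleted` (character vector of
#'   deleted caseids).
#' @export
read_faers_quarter <- function(dir) {
  if (!dir.exists(dir)) stop("input directory not found: ", dir)
  read_kind <- function(prefix, kind) {
    files <- list.files(dir, pattern = paste0("^", prefix, ".*\\.(txt|TXT)$"),
                        full.names = TRUE)
    if (!length(files)) {
      return(setnames(data.table(matrix(character(0), 0,
                                        length(.faers_columns[[kind]]))),
                      .faers_columns[[kind]]))
    }
    rbindlist(lapply(sort(files), read_faers_table, kind = kind))
  }
  list(
    demo    = read_kind("DEMO", "demo"),
    drug    = read_kind("DRUG", "drug"),
    reac    = read_kind("REAC", "reac"),
    outc    = read_kind("OUTC", "outc"),
    ther    = read_kind("THER", "ther"),
    deleted = unique(read_kind("DELETED", "deleted")$caseid)
  )
}

#' Assemble per-report case records
#'
#' Joins the DEMO, DRUG, REAC and OUTC tables on `primaryid` into one row
#' per report version.  DEMO is the spine: drug/reaction/outcome rows whose
#' `primaryid` has no DEMO row are dropped, and their counts recorded in the
#' `"dropped"` attribute.  Reaction Preferred Terms are whitespace-normalized
#' and de-duplicated per report (set semantics).  If a THER table is given,
#' therapy start dates are joined onto the drug rows by
#' `(primaryid, drug_seq)`.
#'
#' @param demo,drug,reac,outc data.tables as returned by
#'   [read_faers_table()].
#' @param ther Optional THER data.table carrying `start_dt`.
#' @return A `data.table` with one row per DEMO row: the DEMO columns plus
#'   `age_years` (`NA`, filled by [filter_valid_age()]), and list columns
#'   `pts` (unique Preferred Terms), `drugs` (a data.table of drug rows with
#'   `drug_seq`, `role_cod`, `drugname`, `prod_ai`, `start_dt`) and
#'   `outcomes` (unique outcome codes).  Attribute `dropped` holds counts of
#'   orphan drug/reac/outc rows.
#' @export
assemble_cases <- function(demo, drug, reac, outc, ther = NULL) {
  stopifnot(is.data.frame(demo))
  demo <- as.data.table(demo)
  ids <- demo$primaryid
  if (anyDuplicated(ids)) {
    stop("format error: duplicated primaryid in DEMO table")
  }

  drug <- copy(as.data.table(drug))
  if (!"start_dt" %in% names(drug)) drug[, start_dt := ""]
  if (!is.null(ther) && nrow(ther)) {
    th <- as.data.table(ther)[start_dt != "",
                              .(primaryid, drug_seq = dsg_drug_seq,
                                ther_start = start_dt)]
    th <- th[!duplicated(th[, .(primaryid, drug_seq)])]
    drug[th, on = c("primaryid", "drug_seq"),
         start_dt := ifelse(start_dt == "", i.ther_start, start_dt)]
  }

  reac <- copy(as.data.table(reac))
  reac[, pt := trimws(gsub("[[:space:]]+", " ", pt))]
  reac <- reac[pt != ""]
  outc <- as.data.table(outc)

  dropped <- c(
    drug = sum(!drug$primaryid %in% ids),
    reac = sum(!reac$primaryid %in% ids),
    outc = sum(!outc$primaryid %in% ids)
  )

  cases <- copy(demo)
  cases[, age_years := NA_real_]

  ptl <- reac[primaryid %chin% ids, .(pts = list(unique(pt))), by = primaryid]
  empty_drugs <- data.table(drug_seq = character(0), role_cod = character(0),
                            drugname = character(0), prod_ai = character(0),
                            start_dt = character(0))
  dl <- drug[primaryid %chin% ids][
    order(primaryid, suppressWarnings(as.integer(drug_seq)))][
    , .(drugs = list(data.table(drug_seq, role_cod, drugname, prod_ai,
                                start_dt))), by = primaryid]
  ol <- outc[primaryid %chin% ids, .(outcomes = list(unique(outc_cod))),
             by = primaryid]

  # attach list columns by position; rows without records get typed empties
  list_col <- function(keys, values, default) {
    out <- rep(list(default), length(ids))
    out[match(keys, ids)] <- values
    out
  }
  pts_col <- list_col(ptl$primaryid, ptl$pts, character(0))
  drugs_col <- list_col(dl$primaryid, dl$drugs, empty_drugs)
  outc_col <- list_col(ol$primaryid, ol$outcomes, character(0))
  if (nrow(cases)) {
    cases[, `:=`(pts = pts_col, drugs = drugs_col, outcomes = outc_col)]
  } else {
    cases <- cases[, c(.SD, list(pts = list(), drugs = list(),
                                 outcomes = list()))]
  }
  setattr(cases, "dropped", dropped)
  cases[]
}

#' Flatten the drug list column of a case table
#'
#' @param cases A case table from [assemble_cases()].
#' @return A long `data.table` of drug rows with a `primaryid` column.
#' @export
drug_long <- function(cases) {
  keep <- vapply(cases$drugs, nrow, integer(1)) > 0L
  if (!any(keep)) {
    return(data.table(primaryid = character(0), drug_seq = character(0),
                      role_cod = character(0), drugname = character(0),
                      prod_ai = character(0), start_dt = character(0)))
  }
  rbindlist(setNames(cases$drugs[keep], cases$primaryid[keep]),
            idcol = "primaryid")
}

#' Write a result table as CSV
#'
#' UTF-8 CSV with a header row and stable column order.  Numeric columns are
#' serialized with 17 significant digits so that a write-then-read round trip
#' reproduces the doubles exactly.
#'
#' @param records A data.frame of results (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (is.null(records)) stop("records must not be NULL")
  out <- as.data.table(records)
  out <- copy(out)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- out[[col]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- ""
      set(out, j = col, value = s)
    }
  }
  data.table::fwrite(out, path, quote = "auto", bom = FALSE)
  invisible(path)
}
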