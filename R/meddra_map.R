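# Mapping report Preferred Terms to SOC/SMQ term lists.  MedDRA itself is
# licensed and is not bundled: term lists are user-supplied configuration
# files, and the package ships a small synthetic toy vocabulary (see
# inst/extdata) for tests and simulations.

#' Load an SMQ/SOC query definition
#'
#' A query file is a CSV with columns `name`, `code`, `scope` and `pt`,
#' one row per Preferred Term (name/code/scope repeated).  Only
#' narrow-scope term lists are accepted, PTs are whitespace-trimmed and
#' duplicates collapsed.
#'
#' @param path CSV path.
#' @return An object of class `smq_definition`: a list with `name`,
#'   `code`, `scope` and the character set `pts`.
#' @export
load_query <- function(path) {
  d <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  need <- c("name", "code", "scope", "pt")
  if (!all(need %in% names(d))) {
    stop("configuration error: query file needs columns ",
         paste(need, collapse = ", "), ": ", path)
  }
  name <- unique(d$name); code <- unique(d$code); scope <- unique(d$scope)
  if (length(name) != 1L || length(code) != 1L || length(scope) != 1L) {
    stop("configuration error: query file must define a single query: ", path)
  }
  if (scope != "narrow") {
    stop("configuration error: only narrow-scope queries are supported ",
         "(got '", scope, "'): ", path)
  }
  pts <- unique(trimws(gsub("[[:space:]]+", " ", d$pt)))
  pts <- pts[pts != ""]
  if (!length(pts)) {
    stop("configuration error: query has an empty Preferred-Term list: ", path)
  }
  structure(list(name = name, code = code, scope = scope, pts = pts),
            class = "smq_definition")
}

#' Serialize a query definition back to CSV
#'
#' @param query An `smq_definition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_query <- function(query, path) {
  data.table::fwrite(
    data.table(name = query$name, code = query$code, scope = query$scope,
               pt = sort(query$pts)),
    path)
  invisible(path)
}

#' @export
print.smq_definition <- function(x, ...) {
  cat("<smq_definition> ", x$name, " (code ", x$code, ", ", x$scope,
      "): ", length(x$pts), " PTs\n", sep = "")
  invisible(x)
}

#' Paths of the bundled toy query files
#'
#' Synthetic stand-ins for the cardiac-disorders SOC and the seven
#' cardiovascular SMQs; the PT lists are small toy sets, not MedDRA.
#'
#' @return Named character vector of file paths.
#' @export
bundled_query_files <- function() {
  dir <- system.file("extdata", package = "faersignal", mustWork = TRUE)
  files <- list.files(dir, pattern = "^(smq|soc)_.*\\.csv$", full.names = TRUE)
  setNames(files, sub("\\.csv$", "", basename(files)))
}

#' Load all bundled toy queries
#'
#' @param include_soc Include the SOC-level query (default `TRUE`).
#' @return Named list of `smq_definition` objects (names are query names).
#' @export
load_bundled_queries <- function(include_soc = TRUE) {
  files <- bundled_query_files()
  if (!include_soc) files <- files[!startsWith(names(files), "soc_")]
  qs <- lapply(files, load_query)
  setNames(qs, vapply(qs, `[[`, character(1), "name"))
}

#' Logical flags: does each report hit the query?
#'
#' @param cases A case table with `pts` populated.
#' @param query An `smq_definition`.
#' @return Logical vector, one element per report.
#' @export
report_flags <- function(cases, query) {
  vapply(cases$pts, function(p) any(p %in% query$pts), logical(1))
}

#' Flag reports matched by an SMQ/SOC query
#'
#' A report is flagged iff its Preferred-Term set intersects the query's
#' term set; each report counts once per query no matter how many of its
#' PTs match.
#'
#' @param cases A case table.
#' @param query An `smq_definition`.
#' @return The flagged subset of `cases`; attribute `n_flagged`.
#' @export
flag_reports <- function(cases, query) {
  hit <- report_flags(cases, query)
  out <- cases[hit]
  setattr(out, "n_flagged", sum(hit))
  out
}

#' Report-level Preferred-Term frequency table
#'
#' Restricts `cases` to reports carrying at least one query member PT and
#' counts, per member PT, the number of reports containing it.  Percents
#' use the restricted subset size as denominator and are rounded to one
#' decimal; because reports can carry several member PTs the percents may
#' sum past 100.  Rows are ordered by descending count, ties alphabetical.
#'
#' @param cases A case table.
#' @param query An `smq_definition` (e.g. the SOC-level cardiac query).
#' @return A `data.table` with columns `pt`, `n`, `pct`; attribute
#'   `n_reports` is the restricted subset size (the percent denominator).
#' @export
pt_frequency <- function(cases, query) {
  subset <- flag_reports(cases, query)
  denom <- nrow(subset)
  per_report <- lapply(subset$pts, function(p) unique(p[p %in% query$pts]))
  tab <- table(unlist(per_report))
  out <- data.table(pt = names(tab), n = as.integer(tab))
  if (nrow(out)) {
    out[, pct := round(100 * n / denom, 1)]
    setorder(out, -n, pt)
  } else {
    out[, pct := numeric(0)]
  }
  setattr(out, "n_reports", denom)
  out[]
}
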