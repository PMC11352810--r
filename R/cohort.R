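# Primary-suspect cohort selection: drug name normalization, a
# name/variant dictionary, and substring matching against the verbatim
# drugname / prod_ai fields.

#' Normalize a verbatim drug name
#'
#' Uppercases, collapses punctuation and runs of whitespace to single
#' spaces, and trims.  Idempotent.
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @examples
#' normalize_name("Ibrance (palbociclib)")  # "IBRANCE PALBOCICLIB"
#' @export
normalize_name <- function(text) {
  x <- toupper(as.character(text))
  x[is.na(x)] <- ""
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(x)
}

#' Read a drug name/variant dictionary
#'
#' The dictionary is a CSV with columns `drug_id`, `type`
#' (`ingredient` or `brand`) and `variant`.  Variants are stored
#' normalized (uppercase, punctuation-stripped).  Every drug must have at
#' least one ingredient and one brand variant.
#'
#' @param path CSV path.
#' @return A `data.table` with columns `drug_id`, `type`, `variant`, of
#'   class `drug_dictionary`.
#' @export
read_drug_dictionary <- function(path) {
  d <- data.table::fread(path, colClasses = "character",
                         showProgress = FALSE)
  need <- c("drug_id", "type", "variant")
  if (!all(need %in% names(d))) {
    stop("configuration error: drug dictionary needs columns ",
         paste(need, collapse = ", "))
  }
  d <- d[, need, with = FALSE]
  d[, variant := normalize_name(variant)]
  d <- d[variant != ""]
  if (!nrow(d)) stop("configuration error: drug dictionary has zero drugs")
  bad <- d[, .(ok = all(c("ingredient", "brand") %in% type)), by = drug_id][
    ok == FALSE, drug_id]
  if (length(bad)) {
    stop("configuration error: drug(s) without both ingredient and brand ",
         "variants: ", paste(bad, collapse = ", "))
  }
  setattr(d, "class", c("drug_dictionary", class(d)))
  d
}

#' Bundled dictionary for the three CDK4/6 inhibitors
#'
#' Ingredient and brand-name variants for palbociclib, ribociclib and
#' abemaciclib; extend or replace via [read_drug_dictionary()].
#'
#' @return A `drug_dictionary`.
#' @export
default_drug_dictionary <- function() {
  read_drug_dictionary(system.file("extdata", "drug_dictionary.csv",
                                   package = "faersignal", mustWork = TRUE))
}

#' Match one drug record against the dictionary
#'
#' A drug matches `drug_id` iff any dictionary variant occurs as a
#' substring of the normalized `drugname` or the normalized `prod_ai`.
#' Matching is therefore invariant to case and punctuation.
#'
#' @param drugname Verbatim drug name.
#' @param prod_ai Active-ingredient text (may be empty).
#' @param dictionary A `drug_dictionary`.
#' @return Character vector of matched drug ids (length 0 if none).
#' @examples
#' \dontrun{match_drug("KISQALI FEMARA CO-PACK", "", default_drug_dictionary())}
#' @export
match_drug <- function(drugname, prod_ai = "", dictionary) {
  hits <- .match_many(normalize_name(drugname), normalize_name(prod_ai),
                      dictionary)
  ids <- unlist(hits)
  if (is.null(ids)) character(0) else sort(unique(ids))
}

# vectorized matcher: dn, ai are normalized character vectors; returns a
# list of matched drug_id vectors per element
.match_many <- function(dn, ai, dictionary) {
  n <- length(dn)
  out <- vector("list", n)
  for (id in unique(dictionary$drug_id)) {
    variants <- unique(dictionary$variant[dictionary$drug_id == id])
    hit <- rep(FALSE, n)
    for (v in variants) {
      hit <- hit | grepl(v, dn, fixed = TRUE) | grepl(v, ai, fixed = TRUE)
    }
    idx <- which(hit)
    for (i in idx) out[[i]] <- c(out[[i]], id)
  }
  out
}

#' Select primary-suspect cohorts per drug
#'
#' A report enters drug `D`'s subset iff some drug row with role code
#' `PS` matches `D` in the dictionary.  A report with distinct PS rows
#' matching distinct drugs counts once in each subset.
#'
#' @param cases A cleaned case table.
#' @param dictionary A `drug_dictionary`
#'   (default [default_drug_dictionary()]).
#' @return Named list of case-table subsets, one per dictionary drug (the
#'   full dictionary order); attribute `sizes` holds the subset sizes.
#' @export
select_primary_suspect <- function(cases, dictionary = default_drug_dictionary()) {
  drug_ids <- unique(dictionary$drug_id)
  if (!length(drug_ids)) {
    stop("configuration error: drug dictionary has zero drugs")
  }
  long <- drug_long(cases)
  ps <- long[role_cod == "PS"]
  hits <- .match_many(normalize_name(ps$drugname), normalize_name(ps$prod_ai),
                      dictionary)
  subsets <- setNames(vector("list", length(drug_ids)), drug_ids)
  for (id in drug_ids) {
    matched <- vapply(hits, function(h) id %in% h, logical(1))
    pids <- unique(ps$primaryid[matched])
    subsets[[id]] <- cases[primaryid %chin% pids]
  }
  setattr(subsets, "sizes",
          vapply(subsets, nrow, integer(1)))
  subsets
}
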