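# Disproportionality statistics on the drug-by-event 2x2 table
#
#             event   no event
#   drug        a        b        (a+b = drug subset size)
#   all other   c        d        (a+b+c+d = cleaned corpus size)
#
# PRR = (a/(a+b)) / (c/(c+d));  ROR = ad/bc;  Pearson chi-square without
# continuity correction; IC = a Bayesian log2 observed-to-expected measure
# with three selectable variants.  The comparator population is all other
# reports in the cleaned corpus.

#' Construct a 2x2 contingency table from counts
#'
#' @param a Reports with the target drug and the target query.
#' @param b Target drug without the query.
#' @param c Query without the target drug.
#' @param d Neither.
#' @return An object of class `contingency_table` (list with `a`, `b`,
#'   `c`, `d`, `n`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative numbers")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one drug--query pair
#'
#' `a` is the overlap between the drug's primary-suspect subset and the
#' query-flagged subset of the full cleaned corpus; the comparator is all
#' other reports in the corpus.
#'
#' @param drug_subset Case table (or vector of primaryids) of the drug's
#'   primary-suspect reports.
#' @param flagged_overall Case table (or vector of primaryids) of reports
#'   flagged by the query over the whole cleaned corpus.
#' @param corpus_size Number of reports in the cleaned corpus.
#' @return A `contingency_table`.
#' @export
contingency <- function(drug_subset, flagged_overall, corpus_size) {
  pid <- function(x) {
    if (is.data.frame(x)) as.character(x$primaryid) else as.character(x)
  }
  did <- unique(pid(drug_subset))
  qid <- unique(pid(flagged_overall))
  a <- length(intersect(did, qid))
  b <- length(did) - a
  c <- length(qid) - a
  d <- corpus_size - a - b - c
  if (d < 0) {
    stop("consistency error: corpus_size smaller than |drug| + |query| - a")
  }
  contingency_table(a, b, c, d)
}

#' Proportional reporting ratio
#'
#' `(a/(a+b)) / (c/(c+d))`.  Undefined (`NA`, printed "-") when the drug
#' row is empty, when `a = 0`, or when `c = 0`.
#'
#' @param table A `contingency_table`.
#' @return Numeric scalar or `NA`.
#' @export
prr <- function(table) {
  with(table, {
    if (a == 0 || c == 0 || (a + b) == 0) return(NA_real_)
    (a / (a + b)) / (c / (c + d))
  })
}

#' Reporting odds ratio
#'
#' `ad/bc`.  Undefined (`NA`) when `a = 0`, `b = 0` or `c = 0`.
#'
#' @param table A `contingency_table`.
#' @return Numeric scalar or `NA`.
#' @export
ror <- function(table) {
  with(table, {
    if (a == 0 || b == 0 || c == 0) return(NA_real_)
    (a * d) / (b * c)
  })
}

#' Pearson chi-square of the 2x2 table
#'
#' Without continuity correction: `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#' Computable whenever all four margins are positive (including `a = 0`);
#' `NA` if any margin is zero.
#'
#' @param table A `contingency_table`.
#' @return Numeric scalar or `NA`.
#' @export
chi_square <- function(table) {
  with(table, {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(NA_real_)
    n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  })
}

.ic_methods <- c("bcpnn_bate1998", "log2_oe", "log2_oe_shrunk")

# BCPNN hyperparameters (Bate et al. 1998): uniform priors on the
# marginal probabilities, and the joint prior calibrated so that the
# prior expectation of IC is 0.
.bcpnn_params <- function(table) {
  with(table, {
    N <- n; r <- a + b; s <- a + c
    alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2; gamma11 <- 1
    gamma <- gamma11 * (N + alpha) * (N + beta) /
      ((r + alpha1) * (s + beta1))
    list(N = N, c11 = a, r = r, s = s, alpha1 = alpha1, beta1 = beta1,
         alpha = alpha, beta = beta, gamma11 = gamma11, gamma = gamma)
  })
}

.bcpnn_eic <- function(table) {
  p <- .bcpnn_params(table)
  log2((p$c11 + p$gamma11) * (p$N + p$alpha) * (p$N + p$beta) /
         ((p$N + p$gamma) * (p$r + p$alpha1) * (p$s + p$beta1)))
}

.bcpnn_vic <- function(table) {
  p <- .bcpnn_params(table)
  (1 / log(2)^2) * (
    (p$N - p$c11 + p$gamma - p$gamma11) /
      ((p$c11 + p$gamma11) * (1 + p$N + p$gamma)) +
    (p$N - p$r + p$alpha - p$alpha1) /
      ((p$r + p$alpha1) * (1 + p$N + p$alpha)) +
    (p$N - p$s + p$beta - p$beta1) /
      ((p$s + p$beta1) * (1 + p$N + p$beta)))
}

# Posterior quantile of IC = log2(p11 / (p1. p.1)) under the BCPNN model,
# computed deterministically: the posteriors of p1., p.1 and p11 are Beta;
# the CDF of IC is an expectation of a Beta CDF over (p1., p.1), evaluated
# by midpoint quadrature in probability space, then inverted by uniroot.
.bcpnn_ic_quantile <- function(table, prob = 0.025, nodes = 160L) {
  p <- .bcpnn_params(table)
  u <- (seq_len(nodes) - 0.5) / nodes
  y <- qbeta(u, p$alpha1 + p$r, p$alpha - p$alpha1 + p$N - p$r)
  z <- qbeta(u, p$beta1 + p$s, p$beta - p$beta1 + p$N - p$s)
  yz <- outer(y, z)
  sh1 <- p$gamma11 + p$c11
  sh2 <- p$gamma - p$gamma11 + p$N - p$c11
  cdf <- function(t) mean(pbeta(pmin(1, 2^t * yz), sh1, sh2))
  mid <- .bcpnn_eic(table)
  sdv <- sqrt(.bcpnn_vic(table))
  lo <- mid - 6 * sdv - 1
  hi <- mid + 6 * sdv + 1
  while (cdf(lo) > prob) lo <- lo - 4
  while (cdf(hi) < prob) hi <- hi + 4
  uniroot(function(t) cdf(t) - prob, c(lo, hi), tol = 1e-7)$root
}

#' Information component
#'
#' Three variants of the log2 observed-to-expected measure:
#' \describe{
#'   \item{`bcpnn_bate1998`}{(default) the closed-form posterior
#'     expectation of the Bayesian Confidence Propagation Neural Network
#'     IC with the standard priors; finite at `a = 0`.}
#'   \item{`log2_oe`}{`log2(aN / ((a+b)(a+c)))`, undefined at `a = 0`.}
#'   \item{`log2_oe_shrunk`}{`log2((a + 0.5) / (E + 0.5))` with
#'     `E = (a+b)(a+c)/N`; the +0.5 shrinkage keeps it finite (and
#'     negative) at `a = 0`.}
#' }
#'
#' @param table A `contingency_table`.
#' @param method One of `"bcpnn_bate1998"`, `"log2_oe"`,
#'   `"log2_oe_shrunk"`.
#' @return Numeric scalar (possibly `NA` for `log2_oe` at `a = 0`).
#' @export
ic <- function(table, method = .ic_methods) {
  method <- match.arg(method)
  with(table, {
    expected <- (a + b) * (a + c) / n
    switch(method,
      log2_oe = if (a == 0) NA_real_ else log2(a / expected),
      log2_oe_shrunk = log2((a + 0.5) / (expected + 0.5)),
      bcpnn_bate1998 = .bcpnn_eic(table))
  })
}

#' Lower 95% bound of the information component (IC025)
#'
#' For `bcpnn_bate1998` this is the 2.5th percentile of the posterior IC
#' distribution, computed by deterministic numerical quadrature (not Monte
#' Carlo).  For `log2_oe` a delta-method normal approximation treating the
#' observed count as Poisson (`IC - 1.96 / (ln 2 * sqrt(a))`); for
#' `log2_oe_shrunk` the standard credibility-interval approximation
#' `IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2`.
#'
#' @inheritParams ic
#' @return Numeric scalar (`NA` for `log2_oe` at `a = 0`).
#' @export
ic025 <- function(table, method = .ic_methods) {
  method <- match.arg(method)
  a <- table$a
  switch(method,
    log2_oe = {
      if (a == 0) NA_real_
      else ic(table, "log2_oe") - qnorm(0.975) / (log(2) * sqrt(a))
    },
    log2_oe_shrunk = {
      ic(table, "log2_oe_shrunk") -
        3.3 * (a + 0.5)^-0.5 - 2 * (a + 0.5)^-1.5
    },
    bcpnn_bate1998 = .bcpnn_ic_quantile(table, prob = 0.025))
}

#' Evaluate the signal-detection criteria
#'
#' A potential signal requires all of: number of events `n >= 3`,
#' `PRR >= 2`, `ROR >= 2`, chi-square `>= 4`, and `IC025 >= 0`.  Any
#' undefined (`NA`) metric makes the decision `FALSE`.
#'
#' @param n,prr,ror,chi2,ic025 Numeric vectors of metric values (recycled).
#' @return Logical vector.
#' @export
evaluate_signal <- function(n, prr, ror, chi2, ic025) {
  ok <- !is.na(n) & !is.na(prr) & !is.na(ror) & !is.na(chi2) & !is.na(ic025)
  out <- ok
  out[ok] <- n[ok] >= 3 & prr[ok] >= 2 & ror[ok] >= 2 &
    chi2[ok] >= 4 & ic025[ok] >= 0
  out
}

#' Disproportionality table over drug--query pairs
#'
#' Builds the 2x2 table of every (drug subset, query) pair against the
#' full cleaned corpus and computes all metrics at full precision; use
#' [format_signal_table()] for Table-3 style rounding.
#'
#' @param drug_subsets Named list of per-drug case subsets, as returned by
#'   [select_primary_suspect()].
#' @param cases The full cleaned case table (the comparator population).
#' @param queries List of `smq_definition` objects.
#' @param ic_method IC variant, see [ic()].
#' @return A `data.table` with columns `drug`, `query`, `n`, `prr`,
#'   `ror`, `chi2`, `ic`, `ic025`, `signal`, `ic_method`.
#' @export
signal_table <- function(drug_subsets, cases, queries,
                         ic_method = .ic_methods) {
  ic_method <- match.arg(ic_method)
  corpus_size <- nrow(cases)
  rows <- list()
  for (q in queries) {
    flagged <- cases$primaryid[report_flags(cases, q)]
    for (dname in names(drug_subsets)) {
      tab <- contingency(drug_subsets[[dname]], flagged, corpus_size)
      r <- data.table(
        drug = dname, query = q$name, n = as.integer(tab$a),
        prr = prr(tab), ror = ror(tab), chi2 = chi_square(tab),
        ic = ic(tab, ic_method), ic025 = ic025(tab, ic_method),
        ic_method = ic_method)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- rbindlist(rows)
  out[, signal := evaluate_signal(n, prr, ror, chi2, ic025)]
  setcolorder(out, c("drug", "query", "n", "prr", "ror", "chi2",
                     "ic", "ic025", "signal", "ic_method"))
  out[]
}

#' Round a signal table for presentation
#'
#' Rounds the metrics to two decimals and prints undefined values as
#' `"-"`, mirroring the usual published layout.  Rounding happens only at
#' this presentation boundary.
#'
#' @param x A table from [signal_table()].
#' @return A `data.table` of characters.
#' @export
format_signal_table <- function(x) {
  fmt <- function(v) ifelse(is.na(v), "-", formatC(round(v, 2), format = "fg"))
  out <- as.data.table(x)[, .(
    drug, query, n,
    prr = fmt(prr), ror = fmt(ror), chi2 = fmt(chi2),
    ic = fmt(ic), ic025 = fmt(ic025), signal, ic_method)]
  out[]
}
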