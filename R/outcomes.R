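#' Hospitalization and mortality rates of the case cohort
#'
#' Counts, per drug, the case reports carrying a hospitalization (`HO`) or
#' death (`DE`) outcome. A case with several outcome rows counts once per
#' outcome kind; a case with both HO and DE enters both numerators. The
#' denominator is the drug's case count.
#'
#' @param flags a `case_flags` object.
#' @param reports the matching `safety_reports` (needs `outc`).
#' @return object of class `outcome_summary`: data.frame with one row per
#'   drug: `drug`, `n_cases`, `n_hospitalized`, `n_died`,
#'   `hospitalization_rate`, `mortality_rate` (proportions in `[0, 1]`).
#' @export
outcome_rates <- function(flags, reports) {
  cases <- flags[flags$is_case, , drop = FALSE]
  outc <- reports$outc
  if (is.null(outc))
    outc <- data.frame(primaryid = character(0), outcome_code = character(0))
  ho <- unique(outc$primaryid[outc$outcome_code == "HO"])
  de <- unique(outc$primaryid[outc$outcome_code == "DE"])
  drugs <- sort(unique(cases$drug))
  rows <- lapply(drugs, function(dg) {
    pid <- unique(cases$primaryid[cases$drug == dg])
    n <- length(pid)
    nh <- sum(pid %in% ho)
    nd <- sum(pid %in% de)
    data.frame(drug = dg, n_cases = n, n_hospitalized = nh, n_died = nd,
               hospitalization_rate = if (n) nh / n else NA_real_,
               mortality_rate = if (n) nd / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    rows <- list(data.frame(drug = character(0), n_cases = integer(0),
                            n_hospitalized = integer(0), n_died = integer(0),
                            hospitalization_rate = numeric(0),
                            mortality_rate = numeric(0),
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("outcome_summary", "data.frame")
  out
}

#' @export
print.outcome_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$hospitalization_rate <- sprintf("%.1f%%", 100 * y$hospitalization_rate)
  y$mortality_rate <- sprintf("%.1f%%", 100 * y$mortality_rate)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Pairwise chi-squared contrasts of outcome rates
#'
#' Pearson chi-squared test (no Yates correction by default, consistent with
#' the PRR convention used elsewhere in the package) on the 2x2 table of each
#' drug pair for the chosen outcome. Tests whose smallest expected cell is
#' below 1 are flagged `unreliable` rather than suppressed. Raw p-values are
#' reported by default; Bonferroni correction is available.
#'
#' @param summary an `outcome_summary` from [outcome_rates()].
#' @param outcome `"hospitalization"` or `"mortality"`.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param yates apply Yates continuity correction.
#' @return data.frame with one row per unordered drug pair: `drug1`, `drug2`,
#'   counts, `chi2`, `df`, `p`, `significant` (p < 0.05), `unreliable`.
#' @export
pairwise_chi2 <- function(summary, outcome = c("hospitalization", "mortality"),
                          correction = c("none", "bonferroni"),
                          yates = FALSE) {
  outcome <- match.arg(outcome)
  correction <- match.arg(correction)
  x <- as.data.frame(summary)
  cnt <- if (outcome == "hospitalization") x$n_hospitalized else x$n_died
  if (any(x$n_cases == 0L)) stop("empty group: ",
                                 x$drug[x$n_cases == 0L][1L])
  pairs <- utils::combn(seq_len(nrow(x)), 2L)
  rows <- apply(pairs, 2L, function(idx) {
    i <- idx[1L]; j <- idx[2L]
    m <- matrix(c(cnt[i], x$n_cases[i] - cnt[i],
                  cnt[j], x$n_cases[j] - cnt[j]), 2L, byrow = TRUE)
    expct <- outer(rowSums(m), colSums(m)) / sum(m)
    ts <- suppressWarnings(stats::chisq.test(m, correct = yates))
    data.frame(drug1 = x$drug[i], drug2 = x$drug[j],
               x1 = cnt[i], n1 = x$n_cases[i],
               x2 = cnt[j], n2 = x$n_cases[j],
               chi2 = unname(ts$statistic), df = unname(ts$parameter),
               p = unname(ts$p.value),
               unreliable = min(expct) < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correction == "bonferroni")
    out$p <- pmin(1, out$p * nrow(out))
  out$significant <- out$p < 0.05
  attr(out, "outcome") <- outcome
  attr(out, "correction") <- correction
  rownames(out) <- NULL
  out
}
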