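#' Contingency table for a drug-event pair
#'
#' The case/non-case design compares how often an event set is reported with
#' the target drug against its reporting with all other drugs in the same
#' database:
#' \preformatted{
#'                     event   other events
#'   target drug         a         b
#'   all other drugs     c         d
#' }
#'
#' @param a,b,c,d non-negative integer counts; `N = a+b+c+d` must be > 0.
#' @return object of class `contingency_table` (named list `a`, `b`, `c`,
#'   `d`, `N`).
#' @export
contingency_table <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("cells must be non-negative integers")
  if (sum(v) <= 0) stop("empty contingency table")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), N = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

# accept a contingency_table, a data.frame of cells, or a named vector
as_cells <- function(tab) {
  if (inherits(tab, "contingency_table"))
    return(data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d))
  tab <- as.data.frame(as.list(tab))
  stopifnot(all(c("a", "b", "c", "d") %in% names(tab)))
  tab <- tab[c("a", "b", "c", "d")]
  tab[] <- lapply(tab, as.numeric)  # avoid integer overflow in products
  tab
}

#' Build a 2x2 contingency table from the report universe
#'
#' Counting is either at the event level — the unit is a distinct
#' (report, PT) pair, so a report listing two SMQ terms contributes 2 to
#' `a` — or at the case level, where the unit is the report. Event-level is
#' the default (it is what reconciles per-term "AE numbers" exceeding case
#' counts).
#'
#' @param reports a `safety_reports` universe (all deduplicated reports,
#'   cases and non-cases).
#' @param target_pids `primaryid`s attributed to the target drug (e.g. from
#'   a [flag_cases()] subset).
#' @param event_pts character vector of preferred terms defining the event.
#' @param counting `"event"` or `"case"`.
#' @param correction Haldane continuity correction: `"none"` (default; zero
#'   cells make ROR/PRR incomputable rather than corrected) or `"haldane"`
#'   (adds 0.5 to every cell downstream; stored as an attribute).
#' @return a `contingency_table`.
#' @export
build_table <- function(reports, target_pids, event_pts,
                        counting = c("event", "case"),
                        correction = c("none", "haldane")) {
  counting <- match.arg(counting)
  correction <- match.arg(correction)
  stopifnot(inherits(reports, "safety_reports"))
  if (nrow(reports$demo) == 0L) stop("empty report universe")
  reac <- reports$reac
  units <- unique(reac[!is.na(reac$pt), c("primaryid", "pt")])
  in_target <- units$primaryid %in% target_pids
  in_event <- units$pt %in% event_pts
  if (counting == "event") {
    a <- sum(in_target & in_event)
    b <- sum(in_target & !in_event)
    c_ <- sum(!in_target & in_event)
    d <- sum(!in_target & !in_event)
  } else {
    pid_evt <- unique(units$primaryid[in_event])
    all_pid <- unique(reports$demo$primaryid)
    tgt <- all_pid %in% target_pids
    evt <- all_pid %in% pid_evt
    a <- sum(tgt & evt); b <- sum(tgt & !evt)
    c_ <- sum(!tgt & evt); d <- sum(!tgt & !evt)
  }
  tab <- contingency_table(a, b, c_, d)
  attr(tab, "counting") <- counting
  attr(tab, "correction") <- correction
  tab
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d)/(b c)`; the two-sided CI is computed on the log scale,
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell the
#' statistic is incomputable and returned as `NA` (no continuity correction
#' by default; pass tables built with `correction = "haldane"` to add 0.5 to
#' every cell).
#'
#' @param tab a `contingency_table`, or a data.frame with columns
#'   `a`,`b`,`c`,`d` (vectorized over rows).
#' @param conf_level confidence level for the interval.
#' @return data.frame with columns `ror`, `ror_ci_low`, `ror_ci_high`.
#' @export
#' @examples
#' ror(contingency_table(20, 10, 10, 20))
ror <- function(tab, conf_level = 0.95) {
  cells <- haldane(as_cells(tab), tab)
  a <- cells$a; b <- cells$b; c_ <- cells$c; d <- cells$d
  ok <- a > 0 & b > 0 & c_ > 0 & d > 0
  est <- lo <- hi <- rep(NA_real_, length(a))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c_[ok] + 1 / d[ok])
  est[ok] <- (a[ok] * d[ok]) / (b[ok] * c_[ok])
  lo[ok] <- exp(log(est[ok]) - z * se)
  hi[ok] <- exp(log(est[ok]) + z * se)
  data.frame(ror = est, ror_ci_low = lo, ror_ci_high = hi)
}

haldane <- function(cells, tab) {
  if (identical(attr(tab, "correction"), "haldane")) cells + 0.5 else cells
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the companion statistic is the Pearson
#' chi-squared of the 2x2 table without Yates continuity correction,
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`. Degenerate margins give `NA`.
#'
#' @inheritParams ror
#' @return data.frame with columns `prr`, `chi2`.
#' @export
#' @examples
#' prr_chi2(contingency_table(20, 10, 10, 20))
prr_chi2 <- function(tab) {
  cells <- haldane(as_cells(tab), tab)
  a <- cells$a; b <- cells$b; c_ <- cells$c; d <- cells$d
  N <- a + b + c_ + d
  prr <- rep(NA_real_, length(a))
  okp <- (a + b) > 0 & (c_ + d) > 0 & c_ > 0
  prr[okp] <- (a[okp] / (a[okp] + b[okp])) / (c_[okp] / (c_[okp] + d[okp]))
  chi2 <- rep(NA_real_, length(a))
  okc <- (a + b) > 0 & (c_ + d) > 0 & (a + c_) > 0 & (b + d) > 0
  chi2[okc] <- N[okc] * (a[okc] * d[okc] - b[okc] * c_[okc])^2 /
    ((a + b)[okc] * (c_ + d)[okc] * (a + c_)[okc] * (b + d)[okc])
  data.frame(prr = prr, chi2 = chi2)
}

#' BCPNN information component with closed-form posterior moments
#'
#' The information component is `IC = log2 p11 / (p1. p.1)`, the
#' log-observed-to-expected of the joint reporting probability under a
#' Bayesian model with Beta priors on the joint and marginal probabilities.
#' With the standard prior choice (`gamma11 = 1`, `alpha1 = beta1 = 1`,
#' `alpha = beta = 2`, and the joint prior weight `gamma` tuned so the prior
#' IC is centred at zero), the posterior moments have the closed form
#' \preformatted{
#'   gamma  = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))
#'   E(IC)  = log2[ (a+gamma11)(N+alpha)(N+beta) /
#'                  ((N+gamma)(a+b+alpha1)(a+c+beta1)) ]
#'   V(IC)  = (1/ln 2)^2 [ (N-a+gamma-gamma11)/((a+gamma11)(1+N+gamma))
#'          + (N-a-b+alpha-alpha1)/((a+b+alpha1)(1+N+alpha))
#'          + (N-a-c+beta-beta1)/((a+c+beta1)(1+N+beta)) ]
#' }
#' and `IC025 = E(IC) - 2 sqrt(V(IC))`. The priors regularize zero cells, so
#' the IC is always computable.
#'
#' @inheritParams ror
#' @param priors named vector of prior parameters
#'   (`gamma11`, `alpha1`, `beta1`, `alpha`, `beta`).
#' @return data.frame with columns `ic`, `ic025`.
#' @export
#' @examples
#' bcpnn_ic(contingency_table(20, 10, 10, 20))
bcpnn_ic <- function(tab, priors = c(gamma11 = 1, alpha1 = 1, beta1 = 1,
                                     alpha = 2, beta = 2)) {
  cells <- as_cells(tab)
  a <- cells$a; N <- cells$a + cells$b + cells$c + cells$d
  n1. <- cells$a + cells$b
  n.1 <- cells$a + cells$c
  g11 <- priors[["gamma11"]]; a1 <- priors[["alpha1"]]
  b1 <- priors[["beta1"]]; al <- priors[["alpha"]]; be <- priors[["beta"]]
  gam <- g11 * (N + al) * (N + be) / ((n1. + a1) * (n.1 + b1))
  ic <- log2((a + g11) * (N + al) * (N + be) /
               ((N + gam) * (n1. + a1) * (n.1 + b1)))
  vic <- ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
            (N - n1. + al - a1) / ((n1. + a1) * (1 + N + al)) +
            (N - n.1 + be - b1) / ((n.1 + b1) * (1 + N + be))) / log(2)^2
  data.frame(ic = ic, ic025 = ic - 2 * sqrt(vic))
}

#' Signal criteria for the four algorithms
#'
#' Default thresholds used to flag a drug-event pair, applied per algorithm;
#' a pair is a joint signal only when all four flags hold simultaneously:
#' ROR: `a >= min_count` and lower CI bound > `ror_ci_low`;
#' PRR: `a >= min_count`, `prr >= prr_min` and `chi2 >= chi2_min`;
#' BCPNN: `ic025 > ic025_min`; MGPS: `ebgm05 > ebgm05_min`.
#'
#' @param min_count minimum observed count `a` for ROR/PRR.
#' @param ror_ci_low threshold the ROR lower CI bound must exceed.
#' @param prr_min,chi2_min PRR thresholds.
#' @param ic025_min BCPNN threshold.
#' @param ebgm05_min MGPS threshold.
#' @return named list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_count = 3, ror_ci_low = 1, prr_min = 2,
                            chi2_min = 4, ic025_min = 0, ebgm05_min = 2) {
  structure(list(min_count = min_count, ror_ci_low = ror_ci_low,
                 prr_min = prr_min, chi2_min = chi2_min,
                 ic025_min = ic025_min, ebgm05_min = ebgm05_min),
            class = "signal_criteria")
}

#' Score a set of contingency tables with all four algorithms
#'
#' Computes ROR (Woolf CI), PRR with Pearson chi-squared, BCPNN IC with
#' IC025, and MGPS EBGM with EBGM05 for each table, then applies
#' [signal_criteria()] to obtain per-algorithm flags and the joint flag
#' (their conjunction).
#'
#' @param cells data.frame with columns `a`, `b`, `c`, `d` (one row per
#'   drug-event pair), or a list of `contingency_table`s.
#' @param prior an `mgps_prior` from [fit_mgps()]; if `NULL`, fitted here on
#'   the supplied tables.
#' @param criteria a [signal_criteria()] list.
#' @return data.frame: the cells, expected count `E = (a+b)(a+c)/N`, all
#'   statistics, per-algorithm logical flags (`sig_ror`, `sig_prr`,
#'   `sig_bcpnn`, `sig_mgps`) and `joint_significant`.
#' @export
evaluate_signals <- function(cells, prior = NULL,
                             criteria = signal_criteria()) {
  if (is.list(cells) && !is.data.frame(cells) &&
      all(vapply(cells, inherits, TRUE, "contingency_table")))
    cells <- do.call(rbind, lapply(cells, as_cells))
  cells <- as.data.frame(cells)
  a <- cells$a; N <- with(cells, a + b + c + d)
  E <- with(cells, (a + b) * (a + c) / N)
  if (is.null(prior)) prior <- fit_mgps(a, E)
  out <- cbind(cells[c("a", "b", "c", "d")], E = E,
               ror(cells), prr_chi2(cells), bcpnn_ic(cells),
               ebgm(cells, prior))
  cr <- criteria
  out$sig_ror <- !is.na(out$ror_ci_low) & a >= cr$min_count &
    out$ror_ci_low > cr$ror_ci_low
  out$sig_prr <- !is.na(out$prr) & !is.na(out$chi2) & a >= cr$min_count &
    out$prr >= cr$prr_min & out$chi2 >= cr$chi2_min
  out$sig_bcpnn <- out$ic025 > cr$ic025_min
  out$sig_mgps <- out$ebgm05 > cr$ebgm05_min
  out$joint_significant <- out$sig_ror & out$sig_prr & out$sig_bcpnn &
    out$sig_mgps
  out
}
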