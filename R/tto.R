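#' Extract time-to-onset records for case reports
#'
#' Time-to-onset (TTO) is the interval in days from the initiation of therapy
#' with the matched drug (earliest day-precision `start_dt` among the drug's
#' THER rows) to the onset of the event (`event_dt`). The analysis is
#' confined to reports carrying usable data: both dates must have day
#' precision and the interval must be non-negative; every exclusion is
#' logged with its reason. Same-day onset (`tto = 0`) is retained.
#'
#' @param flags a `case_flags` object; only rows with `is_case` are used.
#' @param reports the matching `safety_reports` (needs `ther` and `demo`).
#' @return list of class `tto_records`: `tto` (data.frame `primaryid`,
#'   `drug`, `tto_days`), `exclusions` (data.frame `primaryid`, `drug`,
#'   `reason`), and `included` (named per-drug inclusion counts).
#' @export
extract_tto <- function(flags, reports) {
  cases <- flags[flags$is_case, , drop = FALSE]
  demo <- reports$demo
  ther <- reports$ther
  if (is.null(ther)) stop("reports have no THER table")
  evt <- parse_faers_date(demo$event_dt[match(cases$primaryid,
                                              demo$primaryid)])
  # earliest day-precision start date among the matched drug's THER rows
  ther_day <- ther[ther$start_precision == "day", , drop = FALSE]
  start_by <- split(as.numeric(ther_day$start_date),
                    paste(ther_day$primaryid, ther_day$drug_seq, sep = "\r"))
  has_any_ther <- cases$primaryid %in% ther$primaryid

  n <- nrow(cases)
  tto_days <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    seqs <- strsplit(cases$drug_seq[i], ";", fixed = TRUE)[[1L]]
    keys <- paste(cases$primaryid[i], seqs, sep = "\r")
    starts <- unlist(start_by[keys], use.names = FALSE)
    if (length(starts) == 0L) {
      reason[i] <- if (has_any_ther[i]) "partial or missing start date" else
        "no therapy record"
      next
    }
    if (evt$precision[i] != "day") {
      reason[i] <- "partial or missing event date"
      next
    }
    delta <- as.numeric(evt$date[i]) - min(starts)
    if (delta < 0) {
      reason[i] <- "negative interval"
      next
    }
    tto_days[i] <- delta
  }
  ok <- is.na(reason)
  tto <- data.frame(primaryid = cases$primaryid[ok], drug = cases$drug[ok],
                    tto_days = tto_days[ok], stringsAsFactors = FALSE)
  excl <- data.frame(primaryid = cases$primaryid[!ok],
                     drug = cases$drug[!ok], reason = reason[!ok],
                     stringsAsFactors = FALSE)
  rownames(tto) <- rownames(excl) <- NULL
  included <- table(factor(tto$drug, levels = sort(unique(cases$drug))))
  structure(list(tto = tto, exclusions = excl,
                 included = as.integer(included),
                 drugs = names(included)),
            class = "tto_records")
}

#' @export
print.tto_records <- function(x, ...) {
  cat(sprintf("time-to-onset: %d usable records, %d excluded\n",
              nrow(x$tto), nrow(x$exclusions)))
  if (length(x$drugs))
    cat("  included per drug:",
        paste(sprintf("%s=%d", x$drugs, x$included), collapse = ", "), "\n")
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded '%s': %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Kaplan-Meier cumulative incidence of onset
#'
#' Fits product-limit curves of time-to-onset per drug. Every record is an
#' event (spontaneous reports contain the event by construction, so there is
#' no censoring), hence each curve equals the empirical distribution of onset
#' times and the cumulative incidence is `1 - S(t)`. The median is the
#' smallest time at which cumulative incidence reaches 0.5.
#'
#' @param tto a `tto_records` object, or a data.frame with columns `drug`
#'   and `tto_days`.
#' @return object of class `tto_km`: list with `fit` (the underlying
#'   [survival::survfit] object), `curves` (data.frame `drug`, `time`,
#'   `survival`, `cum_incidence`), `median` (named per-drug medians) and `n`
#'   (named per-drug record counts).
#' @export
km_onset <- function(tto) {
  df <- if (inherits(tto, "tto_records")) tto$tto else as.data.frame(tto)
  if (nrow(df) == 0L) stop("no time-to-onset records")
  df$drug <- as.character(df$drug)
  fit <- survival::survfit(
    survival::Surv(df$tto_days, rep(1, nrow(df))) ~ drug, data = df)
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) rep(unique(df$drug), length(sm$time)) else
    sub("^drug=", "", as.character(sm$strata))
  curves <- data.frame(drug = strata, time = sm$time, survival = sm$surv,
                       cum_incidence = 1 - sm$surv, stringsAsFactors = FALSE)
  med <- vapply(split(curves, curves$drug), function(cv) {
    # tolerance: the product-limit estimator can land on 0.5 - eps
    hit <- cv$time[cv$cum_incidence >= 0.5 - 1e-9]
    if (length(hit)) min(hit) else NA_real_
  }, 0.0)
  n <- vapply(split(df$tto_days, df$drug), length, 0L)
  structure(list(fit = fit, curves = curves, median = med, n = n),
            class = "tto_km")
}

#' @export
print.tto_km <- function(x, ...) {
  cat("Kaplan-Meier time-to-onset\n")
  out <- data.frame(drug = names(x$n), n = as.integer(x$n),
                    median_days = as.numeric(x$median[names(x$n)]))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tto_km <- function(x, xlab = "days since therapy start",
                        ylab = "cumulative incidence", ...) {
  drugs <- sort(unique(x$curves$drug))
  cols <- grDevices::hcl.colors(max(3L, length(drugs)), "Dark 3")
  graphics::plot(NA, xlim = c(0, max(x$curves$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(drugs)) {
    cv <- x$curves[x$curves$drug == drugs[i], , drop = FALSE]
    graphics::lines(stats::stepfun(cv$time, c(0, cv$cum_incidence)),
                    do.points = FALSE, col = cols[i])
  }
  graphics::legend("bottomright", legend = drugs, col = cols[seq_along(drugs)],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank comparison of onset distributions
#'
#' Standard k-sample log-rank test of the time-to-onset distributions across
#' drugs (all records events, no censoring), with `df = k - 1`.
#'
#' @param tto a `tto_records` object or data.frame (`drug`, `tto_days`) with
#'   at least two non-empty groups.
#' @return list of class `tto_logrank` with `chisq`, `df`, `p`, `n` (named
#'   group sizes).
#' @export
logrank_test <- function(tto) {
  df <- if (inherits(tto, "tto_records")) tto$tto else as.data.frame(tto)
  n <- table(as.character(df$drug))
  if (length(n) < 2L) stop("log-rank needs at least two groups")
  if (any(n == 0L)) stop("empty group: ", names(n)[n == 0L][1L])
  sd <- survival::survdiff(
    survival::Surv(tto_days, rep(1, nrow(df))) ~ drug, data = df)
  k <- length(sd$n)
  out <- list(chisq = unname(sd$chisq), df = k - 1L,
              p = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE),
              n = stats::setNames(as.integer(n), names(n)))
  class(out) <- "tto_logrank"
  out
}

#' @export
print.tto_logrank <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
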