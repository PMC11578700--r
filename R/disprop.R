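#' Disproportionality scan of target drugs against an event terminology
#'
#' The package's central fit: for each dictionary drug and each term at the
#' requested level (whole SMQ, system organ class, or individual preferred
#' term) it builds the case/non-case 2x2 table against the full deduplicated
#' report universe and scores it with all four algorithms (ROR, PRR/chi2,
#' BCPNN IC, MGPS EBGM), flagging joint signals per [signal_criteria()].
#'
#' The MGPS prior is, by default, estimated once from the whole universe —
#' every (primary-suspect drug, PT) pair with at least one report — so the
#' empirical Bayes shrinkage reflects the database, not just the scanned
#' terms.
#'
#' @param reports a `safety_reports` universe.
#' @param flags a `case_flags` object for the target drugs.
#' @param level `"smq"` (one row per drug), `"soc"` or `"pt"`.
#' @param smq an `smq_definition`; required for levels `"smq"` and `"pt"`.
#' @param pt_soc_map data.frame (`pt`, `soc`) from [read_pt_soc_map()];
#'   required for level `"soc"`. PTs absent from the map are scanned under
#'   the bucket `"UNMAPPED"` and reported in the `unmapped_pts` attribute.
#' @param counting `"event"` (distinct report-PT pairs; default) or `"case"`.
#' @param criteria a [signal_criteria()] list.
#' @param prior an `mgps_prior`, or `NULL` to fit from the universe.
#' @param conf_level confidence level for the ROR interval.
#' @return object of class `disprop`: list with `scores` (data.frame `drug`,
#'   `level`, `term`, cells, statistics, flags; within drug ordered by `a`
#'   descending, ties alphabetical), `prior`, `criteria`, `level`,
#'   `counting`, `n_reports`.
#' @seealso [top_signals()], [evaluate_signals()], [fit_mgps()]
#' @export
disprop <- function(reports, flags, level = c("smq", "soc", "pt"),
                    smq = NULL, pt_soc_map = NULL,
                    counting = c("event", "case"),
                    criteria = signal_criteria(), prior = NULL,
                    conf_level = 0.95) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  stopifnot(inherits(reports, "safety_reports"))
  if (level %in% c("smq", "pt") && is.null(smq))
    stop("level '", level, "' needs an smq definition")
  if (level == "soc" && is.null(pt_soc_map))
    stop("level 'soc' needs a pt_soc_map")
  if (is.null(prior)) prior <- fit_mgps_universe(reports, counting = counting)

  units <- unique(reports$reac[!is.na(reports$reac$pt),
                               c("primaryid", "pt")])
  unmapped <- character(0)
  if (level == "soc") {
    soc <- pt_soc_map$soc[match(units$pt, pt_soc_map$pt)]
    unmapped <- sort(unique(units$pt[is.na(soc)]))
    soc[is.na(soc)] <- "UNMAPPED"
    units$group <- soc
  } else if (level == "pt") {
    units$group <- ifelse(units$pt %in% smq$pts, units$pt, NA_character_)
  } else {
    units$group <- ifelse(units$pt %in% smq$pts, smq$name, NA_character_)
  }

  drugs <- sort(unique(flags$drug))
  rows <- NULL
  for (dg in drugs) {
    tpid <- unique(flags$primaryid[flags$drug == dg])
    if (counting == "event") {
      tgt <- units$primaryid %in% tpid
      n_t <- sum(tgt); n_all <- nrow(units)
      grp <- units$group
      a <- table(grp[tgt])
      tot <- table(grp)
    } else {
      # case level: a report counts once per group it mentions
      u <- unique(units[!is.na(units$group), c("primaryid", "group")])
      all_pid <- unique(reports$demo$primaryid)
      n_t <- sum(all_pid %in% tpid); n_all <- length(all_pid)
      tgt <- u$primaryid %in% tpid
      grp <- u$group
      a <- table(grp[tgt])
      tot <- table(grp)
    }
    terms <- names(tot)
    if (length(terms) == 0L) next
    av <- as.integer(a[terms]); av[is.na(av)] <- 0L
    cv <- as.integer(tot) - av
    df <- data.frame(drug = dg, level = level, term = terms,
                     a = av, b = n_t - av,
                     c = cv, d = (n_all - n_t) - cv,
                     stringsAsFactors = FALSE)
    rows <- rbind(rows, df)
  }
  if (is.null(rows) || nrow(rows) == 0L)
    rows <- data.frame(drug = character(0), level = character(0),
                       term = character(0), a = integer(0), b = integer(0),
                       c = integer(0), d = integer(0))
  if (nrow(rows)) {
    scored <- evaluate_signals(rows[c("a", "b", "c", "d")], prior = prior,
                               criteria = criteria)
    scores <- cbind(rows[c("drug", "level", "term")], scored)
    scores <- scores[order(scores$drug, -scores$a, scores$term), ,
                     drop = FALSE]
    rownames(scores) <- NULL
  } else scores <- rows
  structure(list(scores = scores, prior = prior, criteria = criteria,
                 level = level, counting = counting,
                 n_reports = nrow(reports$demo),
                 unmapped_pts = unmapped),
            class = "disprop")
}

#' Fit the MGPS prior from the whole report universe
#'
#' Computes observed and expected counts for every (primary-suspect drug
#' name, preferred term) pair in the universe with at least `min_count`
#' reports and fits the gamma-mixture prior on them with [fit_mgps()].
#'
#' @param reports a `safety_reports` universe.
#' @param counting `"event"` or `"case"` (margins follow the counting level).
#' @param min_count smallest observed count entering the fit.
#' @return an `mgps_prior`.
#' @export
fit_mgps_universe <- function(reports, counting = c("event", "case"),
                              min_count = 1L) {
  counting <- match.arg(counting)
  units <- unique(reports$reac[!is.na(reports$reac$pt),
                               c("primaryid", "pt")])
  ps <- reports$drug[reports$drug$role_code == "PS" &
                       !is.na(reports$drug$drugname),
                     c("primaryid", "drugname")]
  ps <- unique(ps)
  joined <- merge(units, ps, by = "primaryid")
  if (counting == "case") {
    joined <- unique(joined[c("primaryid", "pt", "drugname")])
    N <- length(unique(reports$demo$primaryid))
    row_tot <- tapply(ps$primaryid, ps$drugname,
                      function(p) length(unique(p)))
    col_tot <- tapply(units$primaryid, units$pt,
                      function(p) length(unique(p)))
  } else {
    N <- nrow(units)
    # row margin: units among the drug's reports; col margin: units per PT
    drug_pids <- split(ps$primaryid, ps$drugname)
    row_tot <- vapply(drug_pids,
                      function(p) sum(units$primaryid %in% p), 0)
    col_tot <- table(units$pt)
  }
  pair <- paste(joined$drugname, joined$pt, sep = "\r")
  a_tab <- table(pair)
  keep <- a_tab >= min_count
  a_tab <- a_tab[keep]
  parts <- strsplit(names(a_tab), "\r", fixed = TRUE)
  dnm <- vapply(parts, `[[`, "", 1L)
  pnm <- vapply(parts, `[[`, "", 2L)
  E <- as.numeric(row_tot[dnm]) * as.numeric(col_tot[pnm]) / N
  fit_mgps(as.integer(a_tab), E)
}

#' @export
print.disprop <- function(x, ...) {
  cat(sprintf("Disproportionality scan (%s level, %s counting) over %d reports\n",
              x$level, x$counting, x$n_reports))
  cat(sprintf("  %d drug-term pairs, %d joint signals\n",
              nrow(x$scores), sum(x$scores$joint_significant)))
  if (nrow(x$scores)) {
    show <- x$scores[, c("drug", "term", "a", "ror", "ror_ci_low",
                         "ror_ci_high", "prr", "chi2", "ic", "ic025",
                         "ebgm", "ebgm05", "joint_significant")]
    show[4:12] <- lapply(show[4:12], function(v) round(v, 2))
    print(utils::head(show, 15), row.names = FALSE)
    if (nrow(show) > 15) cat("  ...", nrow(show) - 15, "more rows\n")
  }
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  s <- object$scores
  out <- data.frame(
    drug = sort(unique(s$drug)),
    n_terms = as.integer(tapply(s$term, s$drug, length)[sort(unique(s$drug))]),
    n_joint = as.integer(tapply(s$joint_significant, s$drug,
                                sum)[sort(unique(s$drug))]))
  cat(sprintf("Disproportionality scan summary (%s level):\n", object$level))
  print(out, row.names = FALSE)
  cat("criteria: a >=", object$criteria$min_count,
      "| ROR CI low >", object$criteria$ror_ci_low,
      "| PRR >=", object$criteria$prr_min,
      "& chi2 >=", object$criteria$chi2_min,
      "| IC025 >", object$criteria$ic025_min,
      "| EBGM05 >", object$criteria$ebgm05_min, "\n")
  invisible(out)
}

#' @export
as.data.frame.disprop <- function(x, ...) x$scores

#' @export
plot.disprop <- function(x, drug = NULL, n = 10, ...) {
  s <- x$scores
  if (!is.null(drug)) s <- s[s$drug %in% drug, , drop = FALSE]
  s <- s[!is.na(s$ror), , drop = FALSE]
  s <- utils::head(s[order(-s$a), , drop = FALSE], n)
  if (nrow(s) == 0L) {
    warning("nothing to plot")
    return(invisible(NULL))
  }
  s <- s[order(s$ror), , drop = FALSE]
  lab <- paste0(substr(s$term, 1, 28), " (", s$drug, ")")
  xr <- range(c(s$ror_ci_low, s$ror_ci_high, 1), finite = TRUE)
  graphics::dotchart(s$ror, labels = lab, xlim = xr, log = "x",
                     xlab = "ROR (95% CI, log scale)", pch = 19, ...)
  graphics::segments(s$ror_ci_low, seq_len(nrow(s)), s$ror_ci_high,
                     seq_len(nrow(s)))
  graphics::abline(v = 1, lty = 2, col = "grey40")
  invisible(s)
}

#' Top signals per drug ranked by report count
#'
#' Selects, per drug, the `n` terms with the largest observed count `a`
#' (ties broken alphabetically) — the "top terms by AE numbers" view of a
#' PT-level scan.
#'
#' @param x a `disprop` object.
#' @param n terms per drug.
#' @return data.frame subset of `x$scores`.
#' @export
top_signals <- function(x, n = 10) {
  stopifnot(inherits(x, "disprop"))
  s <- x$scores
  out <- NULL
  for (dg in sort(unique(s$drug))) {
    sd <- s[s$drug == dg, , drop = FALSE]
    sd <- sd[order(-sd$a, sd$term), , drop = FALSE]
    out <- rbind(out, utils::head(sd, n))
  }
  rownames(out) <- NULL
  out
}
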