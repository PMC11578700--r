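#' Assemble deduplicated safety reports
#'
#' Joins the five FAERS tables into one per-report structure restricted to the
#' deduplication survivors. Child rows (DRUG/REAC/THER/OUTC) belonging to
#' superseded report versions are removed; child rows whose `primaryid` never
#' appears in DEMO are orphans and are logged, not silently dropped.
#'
#' @param tables a `faers_tables` list (from [read_faers_tables()]) or a list
#'   of data.frames `demo`, `drug`, `reac`, `ther`, `outc`.
#' @param dedup a `faers_dedup` from [dedup_reports()]. If `NULL`,
#'   deduplication is run here.
#' @param verbose log stage counts.
#' @return object of class `safety_reports`: list of data.frames `demo`,
#'   `drug`, `reac`, `ther`, `outc` (all filtered to kept `primaryid`s),
#'   plus `orphans` (data.frame `table`, `primaryid`, `n`) and `dedup`.
#' @export
assemble_reports <- function(tables, dedup = NULL, verbose = TRUE) {
  get_rec <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "faers_table")) x$records else as.data.frame(x)
  }
  demo <- get_rec(tables$demo)
  if (is.null(demo)) stop("tables must contain a demo element")
  if (is.null(dedup)) dedup <- dedup_reports(demo)
  all_pids <- as.character(demo$primaryid)
  kept <- dedup$kept
  out <- list(demo = dedup$demo)
  orphans <- NULL
  for (kind in c("drug", "reac", "ther", "outc")) {
    child <- get_rec(tables[[kind]])
    if (is.null(child)) {
      out[[kind]] <- NULL
      next
    }
    cpid <- as.character(child$primaryid)
    orphan <- !cpid %in% all_pids
    if (any(orphan)) {
      orphans <- rbind(orphans, data.frame(
        table = toupper(kind),
        primaryid = unique(cpid[orphan]),
        stringsAsFactors = FALSE))
    }
    keep <- cpid %in% kept
    kd <- child[keep, , drop = FALSE]
    rownames(kd) <- NULL
    out[[kind]] <- kd
    log_stage("%s: %d rows kept, %d superseded, %d orphan", toupper(kind),
              sum(keep), sum(!keep & !orphan), sum(orphan), verbose = verbose)
  }
  out$orphans <- if (is.null(orphans))
    data.frame(table = character(0), primaryid = character(0),
               stringsAsFactors = FALSE) else orphans
  out$dedup <- dedup
  class(out) <- "safety_reports"
  out
}

#' @export
print.safety_reports <- function(x, ...) {
  cat(sprintf("safety_reports: %d deduplicated reports\n", nrow(x$demo)))
  for (kind in c("drug", "reac", "ther", "outc"))
    if (!is.null(x[[kind]]))
      cat(sprintf("  %s rows: %d\n", toupper(kind), nrow(x[[kind]])))
  if (nrow(x$orphans)) cat(sprintf("  orphan child ids: %d\n", nrow(x$orphans)))
  invisible(x)
}

#' Flag target-drug reports and SMQ cases
#'
#' A report is attributed to a dictionary drug when one of its
#' primary-suspect (PS) DRUG rows contains the dictionary pattern as a
#' substring of the normalized drug name. A flagged report is a case when at
#' least one of its reaction PTs belongs to the SMQ term set. Reports naming
#' two different target drugs as PS contribute one flag per drug (the overlap
#' count is recorded in the `overlap_reports` attribute).
#'
#' @param reports a `safety_reports` object.
#' @param drug_dict data.frame (`pattern`, `label`) from
#'   [read_drug_dictionary()].
#' @param smq an `smq_definition` from [read_smq()].
#' @param route optional route restriction (e.g. `"ORAL"`): only PS rows
#'   whose normalized route matches are eligible. Off by default because
#'   FAERS route text is unreliable; product-name dictionaries are the usual
#'   way oral formulations are selected.
#' @return object of class `case_flags`: data.frame with one row per
#'   (report, matched drug): `primaryid`, `drug`, `drug_seq` (matching PS
#'   rows, `;`-separated), `n_smq_pts`, `matched_pts` (`|`-separated),
#'   `is_case`.
#' @export
flag_cases <- function(reports, drug_dict, smq, route = NULL) {
  stopifnot(inherits(reports, "safety_reports"))
  if (nrow(drug_dict) == 0L) stop("drug dictionary is empty")
  drug <- reports$drug
  ps <- drug[drug$role_code == "PS" & !is.na(drug$drugname), , drop = FALSE]
  if (!is.null(route))
    ps <- ps[!is.na(ps$route) & ps$route == norm_term(route), , drop = FALSE]
  hits <- NULL
  for (i in seq_len(nrow(drug_dict))) {
    m <- grepl(drug_dict$pattern[i], ps$drugname, fixed = TRUE)
    if (any(m)) {
      h <- ps[m, c("primaryid", "drug_seq"), drop = FALSE]
      h$drug <- drug_dict$label[i]
      hits <- rbind(hits, h)
    }
  }
  if (is.null(hits)) {
    flags <- data.frame(primaryid = character(0), drug = character(0),
                        drug_seq = character(0), n_smq_pts = integer(0),
                        matched_pts = character(0), is_case = logical(0),
                        stringsAsFactors = FALSE)
    class(flags) <- c("case_flags", "data.frame")
    attr(flags, "overlap_reports") <- character(0)
    return(flags)
  }
  # one flag per (report, drug); keep all matching PS drug_seq for THER lookup
  key <- paste(hits$primaryid, hits$drug, sep = "\r")
  seqs <- vapply(split(hits$drug_seq, key),
                 function(s) paste(unique(s), collapse = ";"), "")
  first <- !duplicated(key)
  flags <- hits[first, c("primaryid", "drug"), drop = FALSE]
  flags$drug_seq <- as.character(seqs[paste(flags$primaryid, flags$drug,
                                            sep = "\r")])

  reac <- reports$reac
  in_smq <- reac[!is.na(reac$pt) & reac$pt %in% smq$pts, , drop = FALSE]
  pts_by_pid <- split(in_smq$pt, in_smq$primaryid)
  ml <- pts_by_pid[flags$primaryid]
  flags$n_smq_pts <- vapply(ml, function(p) length(unique(p)), 0L)
  flags$matched_pts <- vapply(ml, function(p) {
    if (is.null(p)) "" else paste(sort(unique(p)), collapse = "|")
  }, "")
  flags$is_case <- flags$n_smq_pts > 0L
  rownames(flags) <- NULL
  overlap <- flags$primaryid[duplicated(flags$primaryid)]
  class(flags) <- c("case_flags", "data.frame")
  attr(flags, "overlap_reports") <- unique(overlap)
  flags
}

# reporter occupation and country display lookups (FAERS codes)
reporter_labels <- c(CN = "Consumer", HP = "Health Professional",
                     LW = "Lawyer", MD = "Medical doctor",
                     OT = "Other", PH = "Pharmacists")
country_labels <- c(US = "United States", GB = "United Kingdom",
                    CA = "Canada", AU = "Australia", JP = "Japan")

#' Descriptive summary of the case cohort
#'
#' Builds the per-drug characteristics table of the case cohort: sex, age
#' strata (`<18`, `18-64.9`, `65-85`, `>85`, missing; the boundary age 85
#' falls in `65-85`), age mean and sample SD over known ages, reporter type
#' and reporting country. Percentages are computed over the drug's full case
#' count (missing categories included in the denominator) and rounded to one
#' decimal. Reports matching several target drugs appear under each; the
#' `Total` column counts distinct reports.
#'
#' @param flags a `case_flags` object.
#' @param reports the `safety_reports` the flags came from.
#' @return object of class `cohort_descriptives`: list with `table` (long
#'   data.frame `drug`, `block`, `category`, `count`, `pct`), `age_stats`
#'   (`drug`, `mean`, `sd`, `n_known`) and `n_cases` (named vector).
#' @export
describe_cohort <- function(flags, reports) {
  cases <- flags[flags$is_case, , drop = FALSE]
  demo <- reports$demo
  demo_i <- demo[match(cases$primaryid, demo$primaryid), , drop = FALSE]

  strat_age <- function(a) {
    out <- rep("Missing", length(a))
    out[!is.na(a) & a < 18] <- "<18"
    out[!is.na(a) & a >= 18 & a < 65] <- "18-64.9"
    out[!is.na(a) & a >= 65 & a <= 85] <- "65-85"
    out[!is.na(a) & a > 85] <- ">85"
    out
  }
  one_drug <- function(idx, label) {
    d <- demo_i[idx, , drop = FALSE]
    # distinct reports only (a report can match one drug through several rows)
    d <- d[!duplicated(d$primaryid), , drop = FALSE]
    n <- nrow(d)
    blk <- function(block, values, levels) {
      cnt <- vapply(levels, function(l) sum(values == l), 0L)
      data.frame(drug = label, block = block, category = levels,
                 count = as.integer(cnt),
                 pct = if (n > 0) round(100 * cnt / n, 1) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    sex <- ifelse(is.na(d$sex), "Missing",
                  ifelse(d$sex == "F", "Female",
                         ifelse(d$sex == "M", "Male", "Missing")))
    occ <- reporter_labels[d$occp_cod]
    occ[is.na(occ) & nzchar(d$occp_cod)] <- "Other"
    occ[is.na(occ)] <- "Missing"
    ctry <- country_labels[d$reporter_country]
    ctry[is.na(ctry)] <- "Other"
    age <- d$age_years
    tab <- rbind(
      blk("sex", sex, c("Female", "Male", "Missing")),
      blk("age", strat_age(age),
          c("<18", "18-64.9", "65-85", ">85", "Missing")),
      blk("reporter", occ, c("Consumer", "Health Professional", "Lawyer",
                             "Medical doctor", "Other", "Pharmacists",
                             "Missing")),
      blk("country", ctry, c("United States", "United Kingdom", "Canada",
                             "Australia", "Japan", "Other")))
    known <- age[!is.na(age)]
    stats <- data.frame(drug = label,
                        mean = if (length(known)) mean(known) else NA_real_,
                        sd = if (length(known) > 1) stats::sd(known) else NA_real_,
                        n_known = length(known), stringsAsFactors = FALSE)
    list(tab = tab, stats = stats, n = n)
  }

  drugs <- sort(unique(cases$drug))
  parts <- lapply(drugs, function(dg) one_drug(which(cases$drug == dg), dg))
  total <- one_drug(which(!duplicated(cases$primaryid)), "Total")
  tab <- do.call(rbind, c(lapply(parts, `[[`, "tab"), list(total$tab)))
  age_stats <- do.call(rbind, c(lapply(parts, `[[`, "stats"),
                                list(total$stats)))
  n_cases <- c(vapply(parts, `[[`, 0L, "n"), Total = total$n)
  names(n_cases) <- c(drugs, "Total")
  rownames(tab) <- rownames(age_stats) <- NULL
  structure(list(table = tab, age_stats = age_stats, n_cases = n_cases),
            class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat("Case cohort characteristics\n")
  cat("  cases:", paste(sprintf("%s=%d", names(x$n_cases), x$n_cases),
                        collapse = ", "), "\n")
  wide <- stats::reshape(
    x$table, direction = "wide", idvar = c("block", "category"),
    timevar = "drug", v.names = c("count", "pct"))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Yearly case-report counts
#'
#' Counts case reports per calendar year (the temporal reporting profile),
#' using the FDA receipt date by default; the event onset date is available
#' as an alternative. Reports whose chosen date is missing are excluded and
#' the exclusion count is recorded in the `n_undated` attribute.
#'
#' @param flags a `case_flags` object.
#' @param reports the matching `safety_reports`.
#' @param year_field `"fda_dt"` (default) or `"event_dt"`.
#' @return data.frame (`drug`, `year`, `n`); the sum of `n` per drug equals
#'   that drug's case reports with a usable date.
#' @export
yearly_counts <- function(flags, reports, year_field = c("fda_dt", "event_dt")) {
  year_field <- match.arg(year_field)
  cases <- flags[flags$is_case, , drop = FALSE]
  demo <- reports$demo
  d <- demo[match(cases$primaryid, demo$primaryid), , drop = FALSE]
  yr <- if (year_field == "fda_dt") d$fda_year else
    parse_faers_date(d$event_dt)$year
  ok <- !is.na(yr)
  if (!any(ok)) {
    out <- data.frame(drug = character(0), year = integer(0), n = integer(0))
  } else {
    agg <- stats::aggregate(list(n = rep(1L, sum(ok))),
                            by = list(drug = cases$drug[ok], year = yr[ok]),
                            FUN = sum)
    out <- agg[order(agg$drug, agg$year), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_undated") <- sum(!ok)
  out
}
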