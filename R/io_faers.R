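#' Read one FAERS-style quarterly ASCII table
#'
#' FAERS quarterly data are distributed as `"$"`-delimited text files with a
#' header row (DEMO, DRUG, REAC, THER, OUTC, ...). This reader ingests that
#' dialect unchanged, validates every row against the table's vocabulary, and
#' never drops a line silently: each input line becomes either a record or a
#' logged reject with a reason, and the two counts always reconcile with the
#' line count.
#'
#' Validation rules per table kind:
#' \describe{
#'   \item{DEMO}{`primaryid` must be non-empty and unique within the file;
#'     `fda_dt`/`event_dt` are parsed with [parse_faers_date()] (partial dates
#'     kept with a precision flag); age is normalized to years via
#'     [age_in_years()]. A missing `primaryid`/`caseid` column is a hard error.}
#'   \item{DRUG}{`role_cod` restricted to `PS`, `SS`, `C`, `I`; empty drug
#'     names rejected. Names are normalized with [norm_term()].}
#'   \item{REAC}{`pt` must be non-empty; normalized with [norm_term()].}
#'   \item{THER}{`start_dt` parsed with precision; `dsg_drug_seq` kept as the
#'     link to the DRUG table.}
#'   \item{OUTC}{`outc_cod` restricted to `DE`, `HO`, `LT`, `DS`, `CA`, `RI`,
#'     `OT`.}
#' }
#'
#' @param path path to a `"$"`-delimited text file with a header row.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`
#'   (case-insensitive).
#' @return an object of class `faers_table`: a list with elements
#'   `kind`, `records` (data.frame of validated records), and `rejects`
#'   (data.frame with columns `line` and `reason`; `line` counts data lines,
#'   header excluded). `nrow(records) + nrow(rejects)` equals the number of
#'   data lines.
#' @seealso [read_faers_tables()] to load a directory of all five tables,
#'   [write_faers_tables()] for the inverse.
#' @export
read_faers_table <- function(path, table_kind) {
  kind <- toupper(match.arg(tolower(table_kind),
                            c("demo", "drug", "reac", "ther", "outc")))
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "$", header = TRUE, quote = "",
                           comment.char = "", colClasses = "character",
                           stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = character(0))
  validate_faers_table(raw, kind, source = path)
}

# validation core shared by the file reader and in-memory generator output
validate_faers_table <- function(raw, kind, source = "<memory>") {
  path <- source
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  raw[] <- lapply(raw, as.character)
  names(raw) <- tolower(names(raw))
  n <- nrow(raw)

  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    rep("", n)
  }
  need <- function(...) {
    nms <- c(...)
    if (!any(nms %in% names(raw)))
      stop("missing mandatory column ", nms[1L], " in ", kind, " file ", path)
  }

  reasons <- rep(NA_character_, n)
  mark <- function(cond, why) {
    hit <- cond & is.na(reasons)
    reasons[hit] <<- why
    invisible(NULL)
  }

  if (kind == "DEMO") {
    need("primaryid"); need("caseid")
    pid <- trimws(pick("primaryid"))
    caseid <- trimws(pick("caseid"))
    mark(!nzchar(pid), "missing primaryid")
    mark(duplicated(pid) & nzchar(pid), "duplicate primaryid")
    fda <- parse_faers_date(pick("fda_dt"))
    evt <- parse_faers_date(pick("event_dt"))
    sex <- toupper(trimws(pick("sex", "gndr_cod")))
    sex[!sex %in% c("F", "M")] <- NA_character_
    age_raw <- trimws(pick("age"))
    age_cod <- toupper(trimws(pick("age_cod")))
    rec <- data.frame(
      primaryid = pid, caseid = caseid,
      fda_dt = fda$raw, fda_key = fda$key, fda_precision = fda$precision,
      fda_year = fda$year,
      event_dt = evt$raw, event_precision = evt$precision,
      sex = sex, age = age_raw, age_cod = age_cod,
      age_years = age_in_years(age_raw, age_cod),
      occp_cod = toupper(trimws(pick("occp_cod"))),
      reporter_country = toupper(trimws(pick("reporter_country",
                                             "occr_country"))),
      stringsAsFactors = FALSE)
  } else if (kind == "DRUG") {
    need("primaryid")
    pid <- trimws(pick("primaryid"))
    role <- toupper(trimws(pick("role_cod", "role_code")))
    dname <- norm_term(pick("drugname"))
    mark(!nzchar(pid), "missing primaryid")
    mark(!role %in% c("PS", "SS", "C", "I"), "invalid role_code")
    mark(is.na(dname), "missing drugname")
    rec <- data.frame(
      primaryid = pid,
      drug_seq = trimws(pick("drug_seq", "dsg_drug_seq")),
      drugname = dname, role_code = role,
      route = norm_term(pick("route")),
      stringsAsFactors = FALSE)
  } else if (kind == "REAC") {
    need("primaryid")
    pid <- trimws(pick("primaryid"))
    pt <- norm_term(pick("pt"))
    mark(!nzchar(pid), "missing primaryid")
    mark(is.na(pt), "missing pt")
    rec <- data.frame(primaryid = pid, pt = pt, stringsAsFactors = FALSE)
  } else if (kind == "THER") {
    need("primaryid")
    pid <- trimws(pick("primaryid"))
    mark(!nzchar(pid), "missing primaryid")
    start <- parse_faers_date(pick("start_dt"))
    rec <- data.frame(
      primaryid = pid,
      drug_seq = trimws(pick("dsg_drug_seq", "drug_seq")),
      start_dt = start$raw, start_precision = start$precision,
      start_date = start$date,
      stringsAsFactors = FALSE)
  } else { # OUTC
    need("primaryid")
    pid <- trimws(pick("primaryid"))
    code <- toupper(trimws(pick("outc_cod", "outc_code", "outcome_code")))
    mark(!nzchar(pid), "missing primaryid")
    mark(!code %in% c("DE", "HO", "LT", "DS", "CA", "RI", "OT"),
         "invalid outcome_code")
    rec <- data.frame(primaryid = pid, outcome_code = code,
                      stringsAsFactors = FALSE)
  }

  keep <- is.na(reasons)
  out <- list(kind = kind,
              records = rec[keep, , drop = FALSE],
              rejects = data.frame(line = which(!keep),
                                   reason = reasons[!keep],
                                   stringsAsFactors = FALSE))
  rownames(out$records) <- NULL
  class(out) <- "faers_table"
  out
}

#' @export
print.faers_table <- function(x, ...) {
  cat(sprintf("FAERS %s table: %d records, %d rejects\n",
              x$kind, nrow(x$records), nrow(x$rejects)))
  if (nrow(x$rejects)) {
    tab <- table(x$rejects$reason)
    for (r in names(tab)) cat(sprintf("  reject '%s': %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Read a directory of FAERS-style tables
#'
#' Looks for files whose names start with `demo`, `drug`, `reac`, `ther`,
#' `outc` (case-insensitive, any extension) and reads each with
#' [read_faers_table()].
#'
#' @param dir directory containing the five tables.
#' @param verbose log per-table record/reject counts.
#' @return named list of class `faers_tables` with elements `demo`, `drug`,
#'   `reac`, `ther`, `outc`, each a `faers_table` (missing files yield `NULL`
#'   for THER/OUTC; DEMO, DRUG and REAC are mandatory).
#' @export
read_faers_tables <- function(dir, verbose = TRUE) {
  files <- list.files(dir, full.names = TRUE)
  out <- list()
  for (kind in c("demo", "drug", "reac", "ther", "outc")) {
    hit <- files[grepl(paste0("^", kind), tolower(basename(files)))]
    if (length(hit) == 0L) {
      if (kind %in% c("demo", "drug", "reac"))
        stop("no ", toupper(kind), " file found in ", dir)
      out[[kind]] <- NULL
      next
    }
    tab <- read_faers_table(hit[1L], kind)
    log_stage("%s: %d records, %d rejects", toupper(kind),
              nrow(tab$records), nrow(tab$rejects), verbose = verbose)
    out[[kind]] <- tab
  }
  class(out) <- "faers_tables"
  out
}

#' Write FAERS-style tables in the quarterly ASCII dialect
#'
#' Inverse of [read_faers_tables()]: writes each table as a `"$"`-delimited
#' text file with a FAERS header row, so generator output can be re-read by
#' the package (or by any FAERS tooling) unchanged.
#'
#' @param tables a list with data.frame elements `demo`, `drug`, `reac`,
#'   and optionally `ther`, `outc` (raw-column layout as produced by
#'   [synth_generate()], or the `records` element of read tables).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_faers_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- list(
    demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
             "age_cod", "occp_cod", "reporter_country"),
    drug = c("primaryid", "drug_seq", "drugname", "role_cod", "route"),
    reac = c("primaryid", "pt"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt"),
    outc = c("primaryid", "outc_cod"))
  alias <- c(role_code = "role_cod", drug_seq = "dsg_drug_seq",
             outcome_code = "outc_cod")
  paths <- character(0)
  for (kind in names(cols)) {
    df <- tables[[kind]]
    if (is.null(df)) next
    if (inherits(df, "faers_table")) df <- df$records
    for (nm in names(alias)) {
      if (nm %in% names(df) && !alias[[nm]] %in% names(df) &&
          !(kind == "drug" && nm == "drug_seq"))
        names(df)[names(df) == nm] <- alias[[nm]]
    }
    for (cl in cols[[kind]]) if (!cl %in% names(df)) df[[cl]] <- ""
    df <- df[cols[[kind]]]
    df[] <- lapply(df, function(v) {
      v <- as.character(v); v[is.na(v)] <- ""; v
    })
    path <- file.path(dir, paste0(kind, ".txt"))
    utils::write.table(df, path, sep = "$", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a Standardized MedDRA Query (SMQ) definition
#'
#' An SMQ is a curated set of preferred terms (PTs) delineating one medical
#' condition of interest. The file is delimited text with a `pt` column and
#' optionally an `smq` / `smq_name` column. Terms are case-normalized and
#' deduplicated.
#'
#' @param path path to the definition file (CSV).
#' @param name optional SMQ name overriding the file's.
#' @return object of class `smq_definition`: list with `name` and `pts`
#'   (character vector of distinct normalized PTs).
#' @export
read_smq <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"pt" %in% names(df)) stop("SMQ file needs a 'pt' column: ", path)
  pts <- unique(norm_term(df$pt))
  pts <- pts[!is.na(pts)]
  if (length(pts) == 0L) stop("SMQ definition is empty: ", path)
  if (is.null(name)) {
    nm_col <- intersect(c("smq", "smq_name"), names(df))
    name <- if (length(nm_col)) norm_term(df[[nm_col[1L]]][1L]) else "SMQ"
  }
  structure(list(name = name, pts = sort(pts)), class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("SMQ '%s': %d preferred terms\n", x$name, length(x$pts)))
  invisible(x)
}

#' Read a preferred-term to system-organ-class map
#'
#' Two-column delimited text (`pt`, `soc`). Every PT must map to exactly one
#' SOC; a PT listed twice with conflicting SOCs is a hard error, identical
#' repeats are deduplicated.
#'
#' @param path path to the mapping file (CSV).
#' @return data.frame with normalized columns `pt` and `soc`, one row per PT.
#' @export
read_pt_soc_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("pt", "soc") %in% names(df)))
    stop("PT->SOC map needs 'pt' and 'soc' columns: ", path)
  df$pt <- norm_term(df$pt)
  df$soc <- norm_term(df$soc)
  df <- unique(df[!is.na(df$pt), c("pt", "soc")])
  dup <- unique(df$pt[duplicated(df$pt)])
  if (length(dup))
    stop("PT mapped to multiple SOCs: ", paste(dup, collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Read a drug dictionary
#'
#' The dictionary drives case-insensitive substring matching of FAERS free-text
#' drug names: a row `(pattern, label)` means any normalized `drugname`
#' containing `pattern` is attributed to drug `label` (so
#' `"ALENDRONATE SODIUM"` matches pattern `"ALENDRONATE"`).
#'
#' @param path CSV with columns `pattern` and `label` (a single-column file is
#'   read as both).
#' @return data.frame with normalized `pattern` and `label`.
#' @export
read_drug_dictionary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"pattern" %in% names(df)) {
    if (ncol(df) >= 1L) names(df)[1L] <- "pattern" else
      stop("empty drug dictionary: ", path)
  }
  if (!"label" %in% names(df)) df$label <- df$pattern
  df$pattern <- norm_term(df$pattern)
  df$label <- norm_term(df$label)
  df <- unique(df[!is.na(df$pattern), c("pattern", "label")])
  if (nrow(df) == 0L) stop("empty drug dictionary: ", path)
  rownames(df) <- NULL
  df
}

#' Write (and read back) a result table as CSV or JSON
#'
#' Round-trips result tables (signal tables, descriptives, KM curves)
#' losslessly through either format.
#'
#' @param rows data.frame to write.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `write_report_table()`: invisibly, `path`;
#'   `read_report_table()`: the data.frame.
#' @export
write_report_table <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(rows, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
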