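#' Deduplicate FAERS reports by the FDA rule
#'
#' FAERS cases appear as multiple report versions sharing one `caseid`. The
#' FDA deduplication rule keeps, per `caseid`, the version with the highest
#' `fda_dt` (FDA receipt date); among ties on `fda_dt`, the highest
#' `primaryid`. The result is deterministic regardless of input row order.
#'
#' Details: `fda_dt` is compared on its zero-padded 8-digit key so partial
#' dates (`"201705"`) order consistently; a missing `fda_dt` sorts lowest and
#' so loses to any dated version. `primaryid` is compared numerically when
#' possible. Records with a missing `caseid` cannot be grouped; they are kept
#' as singletons and logged.
#'
#' @param demo a `faers_table` of kind DEMO, or its `records` data.frame
#'   (columns `primaryid`, `caseid`, and `fda_key` or `fda_dt`).
#' @return object of class `faers_dedup`: list with
#'   \describe{
#'     \item{kept}{character vector of retained `primaryid`s.}
#'     \item{dropped}{data.frame (`primaryid`, `caseid`, `reason`,
#'       `winner_primaryid`) for superseded versions.}
#'     \item{singletons}{`primaryid`s kept despite missing `caseid`.}
#'     \item{demo}{the retained DEMO records.}
#'   }
#'   `kept` and `dropped$primaryid` partition the input.
#' @export
#' @examples
#' demo <- data.frame(primaryid = c("100", "200", "300"),
#'                    caseid = c("1", "1", "2"),
#'                    fda_dt = c("20200101", "20210101", "20190501"))
#' dedup_reports(demo)$kept
dedup_reports <- function(demo) {
  if (inherits(demo, "faers_table")) demo <- demo$records
  demo <- as.data.frame(demo)
  if (nrow(demo) == 0L) {
    out <- list(kept = character(0),
                dropped = data.frame(primaryid = character(0),
                                     caseid = character(0),
                                     reason = character(0),
                                     winner_primaryid = character(0),
                                     stringsAsFactors = FALSE),
                singletons = character(0), demo = demo)
    class(out) <- "faers_dedup"
    return(out)
  }
  if (!"fda_key" %in% names(demo))
    demo$fda_key <- parse_faers_date(demo$fda_dt)$key
  pid <- as.character(demo$primaryid)
  caseid <- trimws(as.character(demo$caseid))
  pid_num <- suppressWarnings(as.numeric(pid))
  # numeric primaryid comparison; non-numeric ids fall back to string order
  pid_rank <- if (anyNA(pid_num)) rank(pid, ties.method = "first") else pid_num

  missing_case <- is.na(caseid) | !nzchar(caseid)
  grouped <- which(!missing_case)
  kept_idx <- integer(0)
  dropped <- NULL
  if (length(grouped)) {
    g <- caseid[grouped]
    ord <- order(g, demo$fda_key[grouped], pid_rank[grouped])
    gi <- grouped[ord]
    last_in_group <- c(g[ord][-1L] != g[ord][-length(ord)], TRUE)
    kept_idx <- gi[last_in_group]
    winner <- rep(pid[kept_idx], times = rle(g[ord])$lengths)
    lose <- !last_in_group
    if (any(lose)) {
      dropped <- data.frame(primaryid = pid[gi[lose]],
                            caseid = g[ord][lose],
                            reason = "superseded by later version",
                            winner_primaryid = winner[lose],
                            stringsAsFactors = FALSE)
    }
  }
  if (is.null(dropped))
    dropped <- data.frame(primaryid = character(0), caseid = character(0),
                          reason = character(0),
                          winner_primaryid = character(0),
                          stringsAsFactors = FALSE)
  kept_idx <- sort(c(kept_idx, which(missing_case)))
  out <- list(kept = pid[kept_idx], dropped = dropped,
              singletons = pid[missing_case],
              demo = {
                d <- demo[kept_idx, , drop = FALSE]
                rownames(d) <- NULL
                d
              })
  class(out) <- "faers_dedup"
  out
}

#' @export
print.faers_dedup <- function(x, ...) {
  cat(sprintf("FAERS deduplication: %d kept, %d dropped (%d missing-caseid singletons)\n",
              length(x$kept), nrow(x$dropped), length(x$singletons)))
  invisible(x)
}
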