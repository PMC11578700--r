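# Background catalogs shared by the stochastic generator and the fixture.
bg_drug_catalog <- sprintf("BACKGROUND DRUG %02d", 1:20)
bg_pt_catalog <- c("HEADACHE", "NAUSEA", "DIZZINESS", "FATIGUE", "RASH",
                   "ARTHRALGIA", "MYALGIA", "PYREXIA", "PRURITUS", "VOMITING",
                   "INSOMNIA", "DIARRHOEA", "COUGH", "DYSPNOEA", "ANAEMIA",
                   "HYPERTENSION", "RENAL IMPAIRMENT", "DEPRESSION",
                   "TREMOR", "CONSTIPATION")

# largest-remainder apportionment of `total` over weights w (exact fixture
# cells and deterministic category cycling both rely on it)
apportion <- function(w, total) {
  if (total == 0L || sum(w) == 0) return(integer(length(w)))
  q <- w / sum(w) * total
  f <- floor(q)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(q - f, decreasing = TRUE)
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

#' Configuration of the synthetic FAERS generator
#'
#' Parameterizes a FAERS-like universe with known ground truth: per-drug
#' report counts, baseline per-PT reporting probabilities, a multiplicative
#' signal matrix of reporting-rate ratios, duplicate report-version clusters,
#' missingness, per-drug time-to-onset distributions, and per-report outcome
#' probabilities. The defaults emulate, at desk scale (a 50,000-report
#' background universe, one tenth of the full fixture's), the structure of
#' the oral-bisphosphonate oesophageal-toxicity cohort: three target drugs
#' with report volumes proportional to 30,735 / 6,189 / 4,666, an injected
#' oesophageal signal of strength 6, lognormal onset distributions with
#' medians 346 / 126 / 28 days, and hospitalization/death probabilities
#' 0.376/0.022, 0.315/0.022, 0.148/0.011.
#'
#' @param seed integer RNG seed; the same config yields byte-identical output.
#' @param n_background number of non-target background reports.
#' @param drugs data.frame with columns `label`, `drugname`, `n_reports`.
#' @param smq_pts data.frame (`pt`, `base_p`): per-PT baseline inclusion
#'   probability for a background report (independent Bernoulli per PT).
#' @param rr signal matrix of reporting-rate ratios, drugs x SMQ PTs
#'   (rownames = drug labels, colnames = PTs); a scalar is recycled. RR = 1
#'   is the null.
#' @param bg_pt_lambda mean number of additional background PTs per report
#'   beyond the first.
#' @param duplicate_rate fraction of cases receiving extra report versions.
#' @param dup_extra_lambda extra versions per duplicated case are
#'   `1 + Poisson(dup_extra_lambda)`.
#' @param missing named list of missingness rates: `sex`, `age`, `country`;
#'   `event_day` / `start_day` are the probabilities that the event/therapy
#'   start dates are recorded at day precision (otherwise partial/missing).
#' @param sex_f probability that a non-missing sex is female.
#' @param age_mean,age_sd age distribution (years, truncated at 18 and 100).
#' @param tto data.frame (`label`, `median`, `sigma`): lognormal
#'   time-to-onset per target drug.
#' @param outcomes data.frame (`label`, `p_ho`, `p_de`): per-report outcome
#'   probabilities for target drugs.
#' @param bg_p_ho,bg_p_de outcome probabilities for background reports.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1L,
    n_background = 50000L,
    drugs = data.frame(
      label = c("ALENDRONATE", "RISEDRONATE", "IBANDRONATE"),
      drugname = c("ALENDRONATE SODIUM", "RISEDRONATE SODIUM",
                   "IBANDRONATE SODIUM"),
      n_reports = c(3074L, 619L, 467L),
      stringsAsFactors = FALSE),
    smq_pts = NULL,
    rr = 6,
    bg_pt_lambda = 1,
    duplicate_rate = 0.1,
    dup_extra_lambda = 0.3,
    missing = list(sex = 0.09, age = 0.52, country = 0.05,
                   event_day = 0.5, start_day = 0.55),
    sex_f = 0.925,
    age_mean = 68, age_sd = 12.5,
    tto = data.frame(label = c("ALENDRONATE", "RISEDRONATE", "IBANDRONATE"),
                     median = c(346, 126, 28), sigma = c(1, 1, 1),
                     stringsAsFactors = FALSE),
    outcomes = data.frame(label = c("ALENDRONATE", "RISEDRONATE",
                                    "IBANDRONATE"),
                          p_ho = c(0.376, 0.315, 0.148),
                          p_de = c(0.022, 0.022, 0.011),
                          stringsAsFactors = FALSE),
    bg_p_ho = 0.2, bg_p_de = 0.03) {
  if (is.null(smq_pts)) {
    pts <- fixture_smq_pts()
    smq_pts <- data.frame(pt = pts$pt, base_p = 0.013 * pts$weight,
                          stringsAsFactors = FALSE)
  }
  if (!is.matrix(rr)) {
    rr <- matrix(rr, nrow(drugs), nrow(smq_pts),
                 dimnames = list(drugs$label, smq_pts$pt))
  }
  stopifnot(all(smq_pts$base_p >= 0), all(smq_pts$base_p <= 1), all(rr > 0),
            duplicate_rate >= 0, duplicate_rate <= 1)
  structure(list(seed = as.integer(seed), n_background = n_background,
                 drugs = drugs, smq_pts = smq_pts, rr = rr,
                 bg_pt_lambda = bg_pt_lambda,
                 duplicate_rate = duplicate_rate,
                 dup_extra_lambda = dup_extra_lambda,
                 missing = missing, sex_f = sex_f,
                 age_mean = age_mean, age_sd = age_sd,
                 tto = tto, outcomes = outcomes,
                 bg_p_ho = bg_p_ho, bg_p_de = bg_p_de),
            class = "synth_config")
}

#' Generate a synthetic FAERS-like universe with ground truth
#'
#' Samples a complete five-table FAERS-style dataset from a [synth_config()]
#' and records, per case, the generating truth (drug, SMQ PTs, duplicate
#' cluster size, intended deduplication survivor, true onset interval,
#' outcomes), enabling exact scoring of every pipeline stage.
#'
#' @param config a `synth_config`.
#' @return object of class `synth_faers`: list with `tables` (raw data.frames
#'   `demo`, `drug`, `reac`, `ther`, `outc` in the quarterly-dialect column
#'   layout; see [write_faers_tables()]) and `truth` (one row per case:
#'   `caseid`, `primaryid` of the intended survivor, `drug`, `is_case`,
#'   `n_smq_pts`, `n_versions`, `tto_days`, `ho`, `de`).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  n_t <- sum(cf$drugs$n_reports)
  n <- cf$n_background + n_t
  drug_label <- c(rep(cf$drugs$label, cf$drugs$n_reports),
                  sample(bg_drug_catalog, cf$n_background, replace = TRUE))
  drugname <- c(rep(cf$drugs$drugname, cf$drugs$n_reports),
                drug_label[(n_t + 1L):n])
  caseid <- as.character(seq_len(n))

  # --- SMQ events: independent Bernoulli per PT, rate base_p * RR(drug, pt)
  n_pt <- nrow(cf$smq_pts)
  rr_row <- matrix(1, n, n_pt)
  for (i in seq_len(nrow(cf$drugs))) {
    idx <- which(drug_label == cf$drugs$label[i])
    rr_row[idx, ] <- matrix(cf$rr[cf$drugs$label[i], ], length(idx), n_pt,
                            byrow = TRUE)
  }
  p_mat <- sweep(rr_row, 2L, cf$smq_pts$base_p, `*`)
  p_mat[p_mat > 1] <- 1
  hit <- matrix(stats::runif(n * n_pt), n, n_pt) < p_mat
  smq_pairs <- which(hit, arr.ind = TRUE)
  n_smq <- tabulate(smq_pairs[, 1L], nbins = n)

  # --- background PTs (every report has at least one reaction)
  k_bg <- 1L + stats::rpois(n, cf$bg_pt_lambda)
  bg_pid_idx <- rep(seq_len(n), k_bg)
  bg_pt <- sample(bg_pt_catalog, length(bg_pid_idx), replace = TRUE)

  # --- demographics
  sex <- ifelse(stats::runif(n) < cf$missing$sex, "",
                ifelse(stats::runif(n) < cf$sex_f, "F", "M"))
  age <- round(pmin(100, pmax(18, stats::rnorm(n, cf$age_mean, cf$age_sd))))
  age <- ifelse(stats::runif(n) < cf$missing$age, "", as.character(age))
  occp <- sample(c("CN", "MD", "OT", "PH", "HP", "LW", ""), n, replace = TRUE,
                 prob = c(0.38, 0.37, 0.14, 0.03, 0.015, 0.023, 0.042))
  country <- ifelse(stats::runif(n) < cf$missing$country, "",
                    sample(c("US", "GB", "CA", "AU", "JP", "FR", "DE"), n,
                           replace = TRUE,
                           prob = c(0.78, 0.05, 0.04, 0.01, 0.01, 0.06,
                                    0.05)))

  # --- dates and time-to-onset
  start_date <- as.Date("2004-01-01") + floor(stats::runif(n) * 6900)
  tto_true <- rep(NA_real_, n)
  for (i in seq_len(nrow(cf$tto))) {
    idx <- which(drug_label == cf$tto$label[i])
    tto_true[idx] <- round(stats::rlnorm(length(idx),
                                         log(cf$tto$median[i]),
                                         cf$tto$sigma[i]))
  }
  tto_true[is.na(tto_true)] <- round(stats::rlnorm(sum(is.na(tto_true)),
                                                   log(120), 1))
  event_date <- start_date + tto_true
  start_day <- stats::runif(n) < cf$missing$start_day
  event_day <- stats::runif(n) < cf$missing$event_day
  fmt <- function(d) format(d, "%Y%m%d")
  start_dt <- ifelse(start_day, fmt(start_date),
                     ifelse(stats::runif(n) < 0.5,
                            format(start_date, "%Y%m"), ""))
  event_dt <- ifelse(event_day, fmt(event_date),
                     ifelse(stats::runif(n) < 0.5,
                            format(event_date, "%Y%m"), ""))
  fda_date <- event_date + stats::rpois(n, 30)
  fda_dt <- fmt(fda_date)

  # --- outcomes
  p_ho <- rep(cf$bg_p_ho, n)
  p_de <- rep(cf$bg_p_de, n)
  for (i in seq_len(nrow(cf$outcomes))) {
    idx <- which(drug_label == cf$outcomes$label[i])
    p_ho[idx] <- cf$outcomes$p_ho[i]
    p_de[idx] <- cf$outcomes$p_de[i]
  }
  ho <- stats::runif(n) < p_ho
  de <- stats::runif(n) < p_de

  # --- duplicate report versions: survivor has the highest fda_dt
  n_extra <- ifelse(stats::runif(n) < cf$duplicate_rate,
                    1L + stats::rpois(n, cf$dup_extra_lambda), 0L)
  survivor_pid <- as.character(as.integer(caseid) * 100L + n_extra)
  extra_idx <- rep(seq_len(n), n_extra)
  extra_ver <- sequence(n_extra) - 1L
  extra_pid <- as.character(as.integer(caseid[extra_idx]) * 100L + extra_ver)
  extra_fda <- fmt(fda_date[extra_idx] -
                     (n_extra[extra_idx] - extra_ver) * 10L)

  demo <- data.frame(
    primaryid = c(survivor_pid, extra_pid),
    caseid = c(caseid, caseid[extra_idx]),
    fda_dt = c(fda_dt, extra_fda),
    event_dt = c(event_dt, event_dt[extra_idx]),
    sex = c(sex, sex[extra_idx]),
    age = c(age, age[extra_idx]),
    age_cod = "YR",
    occp_cod = c(occp, occp[extra_idx]),
    reporter_country = c(country, country[extra_idx]),
    stringsAsFactors = FALSE)

  all_pid <- c(survivor_pid, extra_pid)
  all_idx <- c(seq_len(n), extra_idx)
  drug_tab <- data.frame(primaryid = all_pid, drug_seq = "1",
                         drugname = drugname[all_idx], role_cod = "PS",
                         route = "ORAL", stringsAsFactors = FALSE)
  reac <- rbind(
    data.frame(primaryid = survivor_pid[smq_pairs[, 1L]],
               pt = cf$smq_pts$pt[smq_pairs[, 2L]], stringsAsFactors = FALSE),
    data.frame(primaryid = survivor_pid[bg_pid_idx], pt = bg_pt,
               stringsAsFactors = FALSE))
  # duplicate versions repeat their case's reactions
  if (length(extra_idx)) {
    case_pts <- c(split(cf$smq_pts$pt[smq_pairs[, 2L]],
                        factor(smq_pairs[, 1L], levels = seq_len(n))),
                  recursive = FALSE)
    bg_split <- split(bg_pt, factor(bg_pid_idx, levels = seq_len(n)))
    pts_per_case <- mapply(c, case_pts, bg_split, SIMPLIFY = FALSE)
    npt <- lengths(pts_per_case)
    reac <- rbind(reac, data.frame(
      primaryid = rep(extra_pid, npt[extra_idx]),
      pt = unlist(pts_per_case[extra_idx], use.names = FALSE),
      stringsAsFactors = FALSE))
  }
  ther <- data.frame(primaryid = survivor_pid[nzchar(start_dt)],
                     dsg_drug_seq = "1",
                     start_dt = start_dt[nzchar(start_dt)],
                     stringsAsFactors = FALSE)
  outc <- rbind(
    data.frame(primaryid = survivor_pid[ho], outc_cod = "HO",
               stringsAsFactors = FALSE),
    data.frame(primaryid = survivor_pid[de], outc_cod = "DE",
               stringsAsFactors = FALSE))

  truth <- data.frame(
    caseid = caseid, primaryid = survivor_pid, drug = drug_label,
    is_case = n_smq > 0L, n_smq_pts = n_smq,
    n_versions = 1L + n_extra,
    tto_days = ifelse(start_day & event_day, tto_true, NA_real_),
    tto_true = tto_true, ho = ho, de = de, stringsAsFactors = FALSE)

  structure(list(tables = list(demo = demo, drug = drug_tab, reac = reac,
                               ther = ther, outc = outc),
                 truth = truth, config = cf),
            class = "synth_faers")
}

#' @export
print.synth_faers <- function(x, ...) {
  cat(sprintf("synthetic FAERS universe: %d cases (%d DEMO rows incl. duplicates)\n",
              nrow(x$truth), nrow(x$tables$demo)))
  tab <- table(x$truth$drug[x$truth$drug %in%
                              unique(x$truth$drug[x$truth$is_case])])
  cat(sprintf("  SMQ-positive reports: %d\n", sum(x$truth$is_case)))
  invisible(x)
}

#' Convert generator tables to assembled safety reports
#'
#' Convenience wrapper: runs in-memory raw tables through the same
#' validation, deduplication and assembly stages used for files on disk,
#' without touching the filesystem.
#'
#' @param x a `synth_faers` object (or list of raw data.frames).
#' @param verbose log stage counts.
#' @return a `safety_reports` object.
#' @export
as_safety_reports <- function(x, verbose = FALSE) {
  tabs <- if (inherits(x, "synth_faers")) x$tables else x
  tables <- list()
  for (kind in c("demo", "drug", "reac", "ther", "outc")) {
    if (is.null(tabs[[kind]])) next
    tab <- validate_faers_table(tabs[[kind]], toupper(kind))
    log_stage("%s: %d records, %d rejects", toupper(kind),
              nrow(tab$records), nrow(tab$rejects), verbose = verbose)
    tables[[kind]] <- tab
  }
  class(tables) <- "faers_tables"
  assemble_reports(tables, verbose = verbose)
}
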