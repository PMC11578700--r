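# Oesophageal PT sub-catalog used by the generator and the fixture: the
# terms actually assigned to synthetic cases, with their relative frequency
# (gastroesophageal reflux disease most frequent). All are members of the
# packaged synthetic 172-term SMQ.
fixture_smq_pts <- function() {
  data.frame(
    pt = c("GASTROOESOPHAGEAL REFLUX DISEASE", "DYSPHAGIA", "OESOPHAGITIS",
           "OESOPHAGEAL DISORDER", "OESOPHAGEAL PAIN", "OESOPHAGEAL ULCER",
           "BARRETT'S OESOPHAGUS", "OESOPHAGEAL STENOSIS",
           "OESOPHAGEAL DISCOMFORT", "OESOPHAGEAL HAEMORRHAGE",
           "ODYNOPHAGIA", "ACQUIRED OESOPHAGEAL WEB"),
    weight = c(0.28, 0.16, 0.13, 0.08, 0.07, 0.06, 0.05, 0.05, 0.04, 0.03,
               0.03, 0.02),
    stringsAsFactors = FALSE)
}

# Table-1-style per-drug cell counts of the case cohort (columns:
# alendronate, risedronate, ibandronate).
fixture_cells <- function() {
  list(
    totals = c(30735L, 6189L, 4666L),
    cases = c(3039L, 281L, 177L),
    extra_pts = c(582L, 80L, 19L),   # second SMQ PT => event units 3621/361/196
    sex = rbind(F_ = c(2527, 243, 168), M_ = c(210, 25, 4),
                miss = c(302, 13, 5)),
    age = rbind(u18 = c(2, 0, 0), a18 = c(635, 88, 59),
                a65 = c(618, 121, 53), o85 = c(73, 12, 4),
                miss = c(1711, 60, 61)),
    reporter = rbind(CN = c(1112, 100, 119), HP = c(42, 10, 2),
                     LW = c(72, 1, 6), MD = c(1178, 70, 33),
                     OT = c(435, 50, 8), PH = c(93, 21, 6),
                     miss = c(107, 29, 3)),
    country = rbind(US = c(2531, 139, 156), GB = c(128, 13, 1),
                    CA = c(85, 46, 1), AU = c(23, 12, 0),
                    JP = c(14, 20, 4), other = c(258, 51, 15)),
    tto_n = c(847L, 88L, 19L),
    tto_median = c(346, 126, 28),
    tto_sigma = c(1, 1, 1),
    ho = c(1143L, 89L, 26L),
    de = c(67L, 6L, 2L))
}

#' Deterministic FAERS-like reference dataset
#'
#' Builds, without any random number generation, a complete five-table
#' FAERS-style dataset whose deduplicated counts reproduce the headline
#' figures of the oral-bisphosphonate oesophageal-toxicity cohort exactly:
#' per-drug report totals 30,735 / 6,189 / 4,666 (alendronate, risedronate,
#' ibandronate), per-drug oesophageal case totals 3,039 / 281 / 177, every
#' sex/age-stratum/reporter/country cell of the characteristics table,
#' event-level term counts 3,621 / 361 / 196 (some cases carry a second SMQ
#' term), time-to-onset subsets of 847 / 88 / 19 records drawn as lognormal
#' quantile grids with medians 346 / 126 / 28 days, and hospitalization /
#' death outcome counts whose rates round to 37.6%/31.7%/14.7% and
#' 2.2%/2.1%/1.1%. A background universe of 500,000 non-target reports
#' (6,500 of them with an oesophageal term, a 1.3% background reporting
#' fraction) provides the comparator for disproportionality.
#'
#' Signal statistics computed on this fixture are positive for all three
#' drugs (ROR > 1 with the lower confidence bound above 1) but do not equal
#' the values obtained on the full multi-million-report corpus, whose
#' comparator margins are not reproducible from the printed counts; the
#' fixture's purpose is exact count arithmetic and end-to-end pipeline
#' validation, not reproduction of published signal magnitudes.
#'
#' @param scale scale factor; `0.1` builds a one-tenth universe (cells
#'   apportioned by largest remainder so every block still sums to its
#'   drug total) for fast checks.
#' @return a `synth_faers` object (see [synth_generate()]); `truth` carries
#'   the per-report drug, case status and onset interval.
#' @export
reference_fixture <- function(scale = 1) {
  fc <- fixture_cells()
  drugs <- c("ALENDRONATE", "RISEDRONATE", "IBANDRONATE")
  dnames <- c("ALENDRONATE SODIUM", "RISEDRONATE SODIUM",
              "IBANDRONATE SODIUM")
  sc_cases <- as.integer(round(fc$cases * scale))
  sc_tot <- as.integer(round(fc$totals * scale))
  n_bg <- as.integer(round(500000 * scale))
  n_bg_smq <- as.integer(round(6500 * scale))
  smq <- fixture_smq_pts()
  years <- 2004:2023
  yw <- list(
    ALENDRONATE = c(2, 3, 4, 5, rep(10, 9), 4, 3, 2, 2, 1, 1, 1),
    RISEDRONATE = rep(1, 20),
    IBANDRONATE = {
      w <- rep(3, 20); w[years == 2017] <- 120; w
    })

  expand_cat <- function(counts, labels) rep(labels, counts)
  demo <- drug_tab <- reac <- ther <- outc <- truth <- NULL
  next_id <- 1L

  for (k in seq_along(drugs)) {
    n_case <- sc_cases[k]
    n_all <- sc_tot[k]
    pid <- as.character(seq.int(next_id, length.out = n_all))
    next_id <- next_id + n_all
    is_case <- seq_len(n_all) <= n_case

    sexv <- rep("F", n_all)
    agev <- rep("", n_all)
    occv <- rep("CN", n_all)
    ctryv <- rep("US", n_all)
    evtv <- rep("", n_all)
    startv <- rep(NA_character_, n_all)
    ttov <- rep(NA_real_, n_all)
    if (n_case > 0) {
      sx <- apportion(fc$sex[, k], n_case)
      sexv[is_case] <- expand_cat(sx, c("F", "M", ""))
      ag <- apportion(fc$age[, k], n_case)
      age_val <- function(lo, hi, m) {
        if (m == 0) return(character(0))
        as.character(round(lo + (seq_len(m) - 0.5) / m * (hi - lo)))
      }
      agev[is_case] <- c(age_val(8, 17, ag[1L]), age_val(18, 64, ag[2L]),
                         age_val(65, 85, ag[3L]), age_val(86, 97, ag[4L]),
                         rep("", ag[5L]))
      rp <- apportion(fc$reporter[, k], n_case)
      occv[is_case] <- expand_cat(rp, c("CN", "HP", "LW", "MD", "OT", "PH",
                                        ""))
      ct <- apportion(fc$country[, k], n_case)
      ctryv[is_case] <- expand_cat(ct, c("US", "GB", "CA", "AU", "JP", "FR"))

      # onset subset: lognormal quantile grid => deterministic KM median
      n_tto <- min(as.integer(round(fc$tto_n[k] * scale)), n_case)
      if (n_tto > 0) {
        q <- (seq_len(n_tto) - 0.5) / n_tto
        tt <- round(stats::qlnorm(q, log(fc$tto_median[k]),
                                  fc$tto_sigma[k]))
        start <- as.Date("2008-01-01") + ((seq_len(n_tto) * 37L) %% 3000L)
        ttov[seq_len(n_tto)] <- tt
        startv[seq_len(n_tto)] <- format(start, "%Y%m%d")
        evtv[seq_len(n_tto)] <- format(start + tt, "%Y%m%d")
      }
      if (n_case > n_tto)
        evtv[(n_tto + 1L):n_case] <- rep(c("201202", ""),
                                         length.out = n_case - n_tto)
    }
    yr <- expand_cat(apportion(yw[[k]], n_all), years)
    fdav <- paste0(yr, "0615")

    demo <- rbind(demo, data.frame(
      primaryid = pid, caseid = pid, fda_dt = fdav, event_dt = evtv,
      sex = sexv, age = agev, age_cod = "YR", occp_cod = occv,
      reporter_country = ctryv, stringsAsFactors = FALSE))
    drug_tab <- rbind(drug_tab, data.frame(
      primaryid = pid, drug_seq = "1", drugname = dnames[k],
      role_cod = "PS", route = "ORAL", stringsAsFactors = FALSE))

    # reactions: each case one SMQ PT (weighted cycle); first `extra` cases a
    # second, distinct SMQ PT; non-cases one background PT
    pt1 <- expand_cat(apportion(smq$weight, n_case), smq$pt)
    n_extra <- min(as.integer(round(fc$extra_pts[k] * scale)), n_case)
    reac_k <- data.frame(primaryid = pid[is_case], pt = pt1,
                         stringsAsFactors = FALSE)
    if (n_extra > 0) {
      shift <- smq$pt[match(pt1[seq_len(n_extra)], smq$pt) %% nrow(smq) + 1L]
      reac_k <- rbind(reac_k, data.frame(primaryid = pid[seq_len(n_extra)],
                                         pt = shift,
                                         stringsAsFactors = FALSE))
    }
    if (n_all > n_case) {
      bg_n <- n_all - n_case
      reac_k <- rbind(reac_k, data.frame(
        primaryid = pid[!is_case],
        pt = expand_cat(apportion(rep(1, length(bg_pt_catalog)), bg_n),
                        bg_pt_catalog),
        stringsAsFactors = FALSE))
    }
    reac <- rbind(reac, reac_k)

    has_start <- !is.na(startv)
    if (any(has_start))
      ther <- rbind(ther, data.frame(primaryid = pid[has_start],
                                     dsg_drug_seq = "1",
                                     start_dt = startv[has_start],
                                     stringsAsFactors = FALSE))
    n_ho <- min(as.integer(round(fc$ho[k] * scale)), n_case)
    n_de <- min(as.integer(round(fc$de[k] * scale)), n_case)
    if (n_ho > 0)
      outc <- rbind(outc, data.frame(primaryid = pid[seq_len(n_ho)],
                                     outc_cod = "HO",
                                     stringsAsFactors = FALSE))
    if (n_de > 0)
      outc <- rbind(outc, data.frame(primaryid = pid[seq_len(n_de)],
                                     outc_cod = "DE",
                                     stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      caseid = pid, primaryid = pid, drug = drugs[k], is_case = is_case,
      n_smq_pts = as.integer(is_case) +
        (seq_len(n_all) <= n_extra),
      n_versions = 1L, tto_days = ttov, tto_true = ttov,
      ho = seq_len(n_all) <= n_ho, de = seq_len(n_all) <= n_de,
      stringsAsFactors = FALSE))
  }

  # background universe: one PT per report, a fixed fraction oesophageal
  if (n_bg > 0) {
    pid <- as.character(seq.int(next_id, length.out = n_bg))
    next_id <- next_id + n_bg
    bg_smq_pt <- expand_cat(apportion(smq$weight, n_bg_smq), smq$pt)
    bg_other <- expand_cat(
      apportion(rep(1, length(bg_pt_catalog)), n_bg - n_bg_smq),
      bg_pt_catalog)
    demo <- rbind(demo, data.frame(
      primaryid = pid, caseid = pid,
      fda_dt = paste0(expand_cat(apportion(rep(1, 20), n_bg), years),
                      "0615"),
      event_dt = "", sex = "F", age = "", age_cod = "YR", occp_cod = "CN",
      reporter_country = "US", stringsAsFactors = FALSE))
    drug_tab <- rbind(drug_tab, data.frame(
      primaryid = pid, drug_seq = "1",
      drugname = expand_cat(apportion(rep(1, length(bg_drug_catalog)), n_bg),
                            bg_drug_catalog),
      role_cod = "PS", route = "ORAL", stringsAsFactors = FALSE))
    reac <- rbind(reac, data.frame(primaryid = pid,
                                   pt = c(bg_smq_pt, bg_other),
                                   stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      caseid = pid, primaryid = pid, drug = "BACKGROUND",
      is_case = c(rep(TRUE, n_bg_smq), rep(FALSE, n_bg - n_bg_smq)),
      n_smq_pts = c(rep(1L, n_bg_smq), rep(0L, n_bg - n_bg_smq)),
      n_versions = 1L, tto_days = NA_real_, tto_true = NA_real_,
      ho = FALSE, de = FALSE, stringsAsFactors = FALSE))
  }

  structure(list(tables = list(demo = demo, drug = drug_tab, reac = reac,
                               ther = ther, outc = outc),
                 truth = truth,
                 config = list(scale = scale, n_background = n_bg,
                               n_background_smq = n_bg_smq)),
            class = "synth_faers")
}
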