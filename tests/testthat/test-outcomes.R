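make_outcome_reports <- function(n_per_drug, ho, de) {
  drugs <- c("ALENDRONATE", "RISEDRONATE", "IBANDRONATE")[seq_along(n_per_drug)]
  demo <- drug <- reac <- outc <- NULL
  id0 <- 0L
  for (k in seq_along(n_per_drug)) {
    pid <- as.character(id0 + seq_len(n_per_drug[k])); id0 <- id0 +
      n_per_drug[k]
    demo <- rbind(demo, data.frame(
      primaryid = pid, caseid = pid, fda_dt = "20200101", event_dt = "",
      sex = "F", age = "", age_cod = "", occp_cod = "CN",
      reporter_country = "US", stringsAsFactors = FALSE))
    drug <- rbind(drug, data.frame(primaryid = pid, drug_seq = "1",
                                   drugname = drugs[k], role_cod = "PS",
                                   route = "ORAL", stringsAsFactors = FALSE))
    reac <- rbind(reac, data.frame(primaryid = pid, pt = "OESOPHAGITIS",
                                   stringsAsFactors = FALSE))
    if (ho[k] > 0)
      outc <- rbind(outc, data.frame(primaryid = pid[seq_len(ho[k])],
                                     outc_cod = "HO",
                                     stringsAsFactors = FALSE))
    if (de[k] > 0)
      outc <- rbind(outc, data.frame(primaryid = pid[seq_len(de[k])],
                                     outc_cod = "DE",
                                     stringsAsFactors = FALSE))
  }
  rep <- as_safety_reports(list(demo = demo, drug = drug, reac = reac,
                                outc = outc))
  list(reports = rep, flags = flag_cases(rep, mini_dict(), mini_smq()))
}

test_that("outcome rates count each case once per outcome kind", {
  x <- make_outcome_reports(10, ho = 3, de = 2)
  s <- outcome_rates(x$flags, x$reports)
  expect_equal(s$hospitalization_rate, 0.3)
  expect_equal(s$mortality_rate, 0.2)  # first 2 cases have both HO and DE
  expect_equal(s$n_cases, 10L)
})

test_that("rates equal a brute-force count on a random fixture", {
  gen <- synth_generate(synth_config(seed = 31, n_background = 100,
                                     duplicate_rate = 0))
  rep <- as_safety_reports(gen)
  flags <- flag_cases(rep, mini_dict(), mini_smq(synth_config()$smq_pts$pt))
  s <- outcome_rates(flags, rep)
  truth <- gen$truth
  for (i in seq_len(nrow(s))) {
    sub <- truth[truth$drug == s$drug[i] & truth$is_case, ]
    expect_equal(s$n_cases[i], nrow(sub))
    expect_equal(s$n_hospitalized[i], sum(sub$ho))
    expect_equal(s$n_died[i], sum(sub$de))
  }
})

test_that("pairwise contrasts match the generic chi-squared routine and are symmetric", {
  x <- make_outcome_reports(c(40, 40), ho = c(12, 12), de = c(2, 2))
  tests <- pairwise_chi2(outcome_rates(x$flags, x$reports),
                         "hospitalization")
  expect_equal(tests$chi2, 0, tolerance = 1e-12)
  expect_equal(tests$p, 1)

  y <- make_outcome_reports(c(60, 45, 30), ho = c(25, 10, 3),
                            de = c(3, 2, 1))
  s <- outcome_rates(y$flags, y$reports)
  th <- pairwise_chi2(s, "hospitalization")
  expect_equal(nrow(th), 3L)
  for (i in seq_len(nrow(th))) {
    m <- matrix(c(th$x1[i], th$n1[i] - th$x1[i],
                  th$x2[i], th$n2[i] - th$x2[i]), 2, byrow = TRUE)
    expect_equal(th$chi2[i],
                 unname(suppressWarnings(
                   chisq.test(m, correct = FALSE)$statistic)),
                 tolerance = 1e-12)
    # invariance under swapping outcome and non-outcome columns
    expect_equal(th$chi2[i],
                 unname(suppressWarnings(
                   chisq.test(m[, 2:1], correct = FALSE)$statistic)),
                 tolerance = 1e-12)
  }
  # order of the groups does not matter
  s_rev <- s[rev(seq_len(nrow(s))), ]
  class(s_rev) <- class(s)
  th_rev <- pairwise_chi2(s_rev, "hospitalization")
  expect_setequal(round(th$chi2, 10), round(th_rev$chi2, 10))
})

test_that("tiny expected cells are flagged unreliable and bonferroni inflates p", {
  x <- make_outcome_reports(c(30, 25), ho = c(5, 3), de = c(1, 0))
  s <- outcome_rates(x$flags, x$reports)
  tm <- pairwise_chi2(s, "mortality")
  expect_true(tm$unreliable)
  y <- make_outcome_reports(c(60, 45, 30), ho = c(25, 10, 3),
                            de = c(3, 2, 1))
  raw <- pairwise_chi2(outcome_rates(y$flags, y$reports), "hospitalization")
  bonf <- pairwise_chi2(outcome_rates(y$flags, y$reports), "hospitalization",
                        correction = "bonferroni")
  expect_equal(bonf$p, pmin(1, raw$p * 3))
})
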