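small_cfg <- function(...) {
  synth_config(n_background = 400,
               drugs = data.frame(label = c("ALENDRONATE", "RISEDRONATE"),
                                  drugname = c("ALENDRONATE SODIUM",
                                               "RISEDRONATE SODIUM"),
                                  n_reports = c(120L, 60L)),
               ...)
}

test_that("without duplication every case is one DEMO row and dedup keeps all", {
  gen <- synth_generate(small_cfg(seed = 8, duplicate_rate = 0))
  expect_equal(nrow(gen$tables$demo), nrow(gen$truth))
  dd <- dedup_reports(gen$tables$demo)
  expect_length(dd$kept, nrow(gen$truth))
})

test_that("deduplication recovers exactly the generator's intended survivor set", {
  gen <- synth_generate(small_cfg(seed = 9, duplicate_rate = 0.25,
                                  dup_extra_lambda = 1))
  expect_gt(nrow(gen$tables$demo), nrow(gen$truth))
  dd <- dedup_reports(gen$tables$demo)
  expect_setequal(dd$kept, gen$truth$primaryid)
})

test_that("the same seed reproduces the universe byte for byte", {
  g1 <- synth_generate(small_cfg(seed = 10))
  g2 <- synth_generate(small_cfg(seed = 10))
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$truth, g2$truth)
  g3 <- synth_generate(small_cfg(seed = 11))
  expect_false(identical(g1$tables$demo, g3$tables$demo))
})

test_that("realized SMQ event counts stay within 3 Monte-Carlo SDs of expectation", {
  cfg <- synth_config(seed = 12, n_background = 2000,
                      drugs = data.frame(label = "ALENDRONATE",
                                         drugname = "ALENDRONATE SODIUM",
                                         n_reports = 3000L),
                      rr = 6, duplicate_rate = 0)
  gen <- synth_generate(cfg)
  p <- pmin(1, 6 * cfg$smq_pts$base_p)
  expected <- 3000 * sum(p)
  sd_mc <- sqrt(3000 * sum(p * (1 - p)))
  observed <- sum(gen$truth$n_smq_pts[gen$truth$drug == "ALENDRONATE"])
  expect_lt(abs(observed - expected), 3 * sd_mc)
})

test_that("the scaled fixture preserves block sums and headline proportions", {
  fx <- reference_fixture(0.1)
  truth <- fx$truth
  tot <- table(truth$drug)
  expect_equal(as.vector(tot[c("ALENDRONATE", "RISEDRONATE",
                               "IBANDRONATE")]),
               c(3074L, 619L, 467L))
  cases <- truth[truth$is_case & truth$drug != "BACKGROUND", ]
  expect_equal(as.vector(table(cases$drug)[c("ALENDRONATE", "RISEDRONATE",
                                             "IBANDRONATE")]),
               c(304L, 28L, 18L))
  # every demographic block of the assembled cohort sums to the case total
  rep <- as_safety_reports(fx)
  flags <- flag_cases(rep, mini_dict(), mini_smq(fixture_pts()))
  desc <- describe_cohort(flags, rep)
  for (dg in c("ALENDRONATE", "Total")) {
    t_d <- desc$table[desc$table$drug == dg, ]
    for (blk in unique(t_d$block))
      expect_equal(sum(t_d$count[t_d$block == blk]),
                   unname(desc$n_cases[dg]))
  }
  # female share stays at the published 84% after scaling
  sex <- desc$table[desc$table$drug == "Total" & desc$table$block == "sex", ]
  expect_equal(sex$pct[sex$category == "Female"], 84.0)
})

test_that("fixture event units exceed case counts through second SMQ terms", {
  fx <- reference_fixture(0.1)
  rep <- as_safety_reports(fx)
  flags <- flag_cases(rep, mini_dict(), mini_smq(fixture_pts()))
  tpid <- unique(flags$primaryid[flags$drug == "ALENDRONATE"])
  tab <- build_table(rep, tpid, fixture_pts(), counting = "event")
  cas <- build_table(rep, tpid, fixture_pts(), counting = "case")
  expect_equal(tab$a, 362)   # 304 cases + 58 second terms at 1/10 scale
  expect_equal(cas$a, 304)
})
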