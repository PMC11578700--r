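test_that("assembly keeps only dedup survivors and logs orphans", {
  tabs <- mini_tables()
  tabs$demo <- rbind(tabs$demo, data.frame(
    primaryid = "5", caseid = "1", fda_dt = "20150101", event_dt = "",
    sex = "F", age = "", age_cod = "", occp_cod = "", reporter_country = "",
    stringsAsFactors = FALSE))  # older version of case 1
  tabs$reac <- rbind(tabs$reac,
                     data.frame(primaryid = c("5", "999"),
                                pt = c("OESOPHAGITIS", "HEADACHE")))
  rep <- as_safety_reports(tabs)
  expect_equal(nrow(rep$demo), 4L)
  expect_false("5" %in% rep$reac$primaryid)      # superseded version removed
  expect_equal(rep$orphans$primaryid, "999")     # unknown pid logged
})

test_that("assembly equals a brute-force nested scan on a random fixture", {
  gen <- synth_generate(synth_config(seed = 11, n_background = 80,
                                     drugs = data.frame(
                                       label = "ALENDRONATE",
                                       drugname = "ALENDRONATE SODIUM",
                                       n_reports = 20L),
                                     duplicate_rate = 0.3))
  rep <- as_safety_reports(gen)
  kept <- dedup_reports(gen$tables$demo)$kept
  # brute force: child rows whose pid is in the kept set
  for (kind in c("reac", "ther", "outc")) {
    brute <- gen$tables[[kind]][gen$tables[[kind]]$primaryid %in% kept, ]
    expect_equal(sort(rep[[kind]]$primaryid), sort(brute$primaryid))
  }
})

test_that("case flags need a PS role, match substrings, and split cases from non-cases", {
  rep <- as_safety_reports(mini_tables())
  flags <- flag_cases(rep, mini_dict(), mini_smq())
  # report 3 names alendronate only as concomitant: no flag
  expect_false("3" %in% flags$primaryid)
  # report 1: PS "ALENDRONATE SODIUM" matches by substring, two SMQ PTs
  f1 <- flags[flags$primaryid == "1", ]
  expect_equal(f1$drug, "ALENDRONATE")
  expect_true(f1$is_case)
  expect_equal(f1$n_smq_pts, 2L)
  # report 2: PS risedronate but no SMQ PT: flagged, not a case
  f2 <- flags[flags$primaryid == "2", ]
  expect_false(f2$is_case)
  # route filter drops the intravenous ibandronate report
  oral <- flag_cases(rep, mini_dict(), mini_smq(), route = "ORAL")
  expect_false("4" %in% oral$primaryid)
  expect_true("4" %in% flags$primaryid)
})

test_that("descriptive percentages use the full case denominator", {
  rep <- as_safety_reports(mini_tables())
  flags <- flag_cases(rep, mini_dict(), mini_smq())
  desc <- describe_cohort(flags, rep)
  tot <- desc$table[desc$table$drug == "Total", ]
  sex <- tot[tot$block == "sex", ]
  expect_equal(sum(sex$count), unname(desc$n_cases["Total"]))
  expect_equal(sex$pct[sex$category == "Female"], 100)
  cty <- tot[tot$block == "country", ]
  expect_equal(cty$count[cty$category == "Other"], 1L)  # FR falls in Other
})

test_that("age strata edges and moments follow the table conventions", {
  demo <- data.frame(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = "20200101", event_dt = "",
    sex = "F", age = c("17", "18", "64", "65", "85", "86"), age_cod = "YR",
    occp_cod = "CN", reporter_country = "US", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = as.character(1:6), drug_seq = "1",
                     drugname = "ALENDRONATE", role_cod = "PS",
                     route = "ORAL", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = as.character(1:6), pt = "OESOPHAGITIS",
                     stringsAsFactors = FALSE)
  rep <- as_safety_reports(list(demo = demo, drug = drug, reac = reac))
  desc <- describe_cohort(flag_cases(rep, mini_dict(), mini_smq()), rep)
  age <- desc$table[desc$table$drug == "ALENDRONATE" &
                      desc$table$block == "age", ]
  expect_equal(age$count[match(c("<18", "18-64.9", "65-85", ">85"),
                               age$category)], c(1L, 2L, 2L, 1L))

  # sample mean and SD over known ages only
  demo$age <- c("60", "70", "80", "", "", "")
  rep2 <- as_safety_reports(list(demo = demo, drug = drug, reac = reac))
  desc2 <- describe_cohort(flag_cases(rep2, mini_dict(), mini_smq()), rep2)
  st <- desc2$age_stats[desc2$age_stats$drug == "ALENDRONATE", ]
  expect_equal(st$mean, 70)
  expect_equal(st$sd, 10)
  expect_equal(st$n_known, 3L)
})

test_that("yearly counts equal a brute-force histogram of usable dates", {
  gen <- synth_generate(synth_config(seed = 3, n_background = 150))
  rep <- as_safety_reports(gen)
  flags <- flag_cases(rep, mini_dict(), mini_smq(synth_config()$smq_pts$pt))
  yr <- yearly_counts(flags, rep)
  cases <- flags[flags$is_case, ]
  d <- rep$demo[match(cases$primaryid, rep$demo$primaryid), ]
  brute <- table(cases$drug, substr(d$fda_dt, 1, 4))
  for (i in seq_len(nrow(yr)))
    expect_equal(yr$n[i],
                 unname(brute[yr$drug[i], as.character(yr$year[i])]))
  expect_equal(sum(yr$n) + attr(yr, "n_undated"), nrow(cases))
})
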