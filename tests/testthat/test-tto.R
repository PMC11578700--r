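make_tto_reports <- function(start, event) {
  n <- length(start)
  demo <- data.frame(primaryid = as.character(seq_len(n)),
                     caseid = as.character(seq_len(n)),
                     fda_dt = "20200101", event_dt = event, sex = "F",
                     age = "", age_cod = "", occp_cod = "CN",
                     reporter_country = "US", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = demo$primaryid, drug_seq = "1",
                     drugname = "ALENDRONATE", role_cod = "PS",
                     route = "ORAL", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = demo$primaryid, pt = "OESOPHAGITIS",
                     stringsAsFactors = FALSE)
  has <- nzchar(start)
  ther <- data.frame(primaryid = demo$primaryid[has],
                     dsg_drug_seq = rep("1", sum(has)),
                     start_dt = start[has], stringsAsFactors = FALSE)
  rep <- as_safety_reports(list(demo = demo, drug = drug, reac = reac,
                                ther = ther))
  flags <- flag_cases(rep, mini_dict(), mini_smq())
  list(reports = rep, flags = flags)
}

test_that("onset intervals are calendar differences and exclusions are reasoned", {
  x <- make_tto_reports(
    start = c("20200101", "20200301", "202003", "", "20200401"),
    event = c("20200131", "20200201", "20200401", "20200501", "202005"))
  tto <- extract_tto(x$flags, x$reports)
  expect_equal(tto$tto$tto_days, 30)
  expect_setequal(tto$exclusions$reason,
                  c("negative interval", "partial or missing start date",
                    "no therapy record", "partial or missing event date"))
})

test_that("every date-precision combination is excluded unless both dates are day-precision", {
  starts <- c(day = "20200101", month = "202001", missing = "")
  events <- c(day = "20200301", month = "202003", missing = "")
  for (sp in names(starts)) for (ep in names(events)) {
    x <- make_tto_reports(starts[[sp]], events[[ep]])
    tto <- extract_tto(x$flags, x$reports)
    if (sp == "day" && ep == "day") {
      expect_equal(nrow(tto$tto), 1L)
    } else {
      expect_equal(nrow(tto$tto), 0L)
      expect_equal(nrow(tto$exclusions), 1L)
    }
  }
  # same-day onset is a valid zero interval
  x0 <- make_tto_reports("20200101", "20200101")
  expect_equal(extract_tto(x0$flags, x0$reports)$tto$tto_days, 0)
})

test_that("the KM median follows the first-time-cumulative-incidence>=0.5 rule", {
  km_odd <- km_onset(data.frame(drug = "A", tto_days = c(10, 20, 30)))
  expect_equal(unname(km_odd$median["A"]), 20)
  km_even <- km_onset(data.frame(drug = "A", tto_days = c(10, 20)))
  expect_equal(unname(km_even$median["A"]), 10)
})

test_that("with no censoring the KM curve is the empirical distribution", {
  set.seed(4)
  tt <- round(rlnorm(500, log(120), 1))
  km <- km_onset(data.frame(drug = "A", tto_days = tt))
  cv <- km$curves
  for (i in sample(nrow(cv), 20))
    expect_equal(cv$survival[i], mean(tt > cv$time[i]), tolerance = 1e-12)
  # median agrees with the empirical CDF median rule
  srt <- sort(tt)
  emp <- srt[which(seq_along(srt) / length(srt) >= 0.5)[1]]
  expect_equal(unname(km$median["A"]), emp)
})

test_that("log-rank is null on identical groups and matches the O-E oracle on two groups", {
  tt <- c(5, 10, 20, 40, 80)
  same <- data.frame(drug = rep(c("A", "B"), each = 5), tto_days = rep(tt, 2))
  lr <- logrank_test(same)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(5)
  t1 <- round(rlnorm(40, log(100), 0.8)); t2 <- round(rlnorm(35, log(60), 0.8))
  two <- data.frame(drug = rep(c("A", "B"), c(40, 35)),
                    tto_days = c(t1, t2))
  lr2 <- logrank_test(two)
  expect_equal(lr2$chisq, oracle_logrank2(t1, t2), tolerance = 1e-8)
  expect_equal(lr2$df, 1L)
  expect_error(logrank_test(data.frame(drug = "A", tto_days = 1)),
               "two groups")
})

test_that("well-separated onset scales give an overwhelming log-rank signal", {
  set.seed(6)
  d <- data.frame(
    drug = rep(c("A", "B", "C"), each = 300),
    tto_days = c(round(rlnorm(300, log(346), 1)),
                 round(rlnorm(300, log(126), 1)),
                 round(rlnorm(300, log(28), 1))))
  lr <- logrank_test(d)
  expect_equal(lr$df, 2L)
  expect_lt(lr$p, 1e-4)
})
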