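test_that("event-level counting counts report-PT pairs, case-level counts reports", {
  rep <- as_safety_reports(mini_tables())
  flags <- flag_cases(rep, mini_dict(), mini_smq())
  tpid <- flags$primaryid[flags$drug == "ALENDRONATE"]
  smq <- mini_smq()
  ev <- build_table(rep, tpid, smq$pts, counting = "event")
  ca <- build_table(rep, tpid, smq$pts, counting = "case")
  # report 1 carries two SMQ PTs: 2 event units but 1 case
  expect_equal(ev$a, 2)
  expect_equal(ca$a, 1)
  # absent target drug
  none <- build_table(rep, character(0), smq$pts)
  expect_equal(none$a + none$b, 0)
})

test_that("contingency cells equal a brute-force double loop over a random universe", {
  gen <- synth_generate(synth_config(seed = 21, n_background = 120,
                                     duplicate_rate = 0))
  rep <- as_safety_reports(gen)
  smq <- mini_smq(synth_config()$smq_pts$pt)
  flags <- flag_cases(rep, mini_dict(), smq)
  tpid <- unique(flags$primaryid[flags$drug == "RISEDRONATE"])
  tab <- build_table(rep, tpid, smq$pts, counting = "event")
  units <- unique(rep$reac[, c("primaryid", "pt")])
  a <- b <- c_ <- d <- 0
  for (i in seq_len(nrow(units))) {
    tgt <- units$primaryid[i] %in% tpid
    evt <- units$pt[i] %in% smq$pts
    if (tgt && evt) a <- a + 1 else if (tgt) b <- b + 1
    else if (evt) c_ <- c_ + 1 else d <- d + 1
  }
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(a, b, c_, d))
})

test_that("ROR matches its definition, inverts under table transposition, and is NA on zero cells", {
  sym <- ror(contingency_table(10, 10, 10, 10))
  expect_equal(sym$ror, 1)
  expect_lt(sym$ror_ci_low, 1)
  expect_gt(sym$ror_ci_high, 1)

  r <- ror(contingency_table(20, 10, 10, 20))
  o <- oracle_ror(20, 10, 10, 20)
  expect_equal(r$ror, 4)
  expect_equal(r$ror_ci_low, unname(o["lo"]), tolerance = 1e-12)
  expect_equal(r$ror_ci_high, unname(o["hi"]), tolerance = 1e-12)

  swapped <- ror(contingency_table(10, 20, 20, 10))
  expect_equal(swapped$ror, 1 / r$ror)

  expect_true(is.na(ror(contingency_table(0, 10, 10, 10))$ror))
})

test_that("PRR is 1 with chi2 0 at independence, and chi2 scales with the table", {
  ind <- prr_chi2(contingency_table(10, 20, 30, 60))
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)

  p <- prr_chi2(contingency_table(20, 10, 10, 20))
  expect_equal(p$prr, oracle_prr(20, 10, 10, 20))
  expect_equal(p$chi2, oracle_chi2(20, 10, 10, 20), tolerance = 1e-12)

  dbl <- prr_chi2(contingency_table(40, 20, 20, 40))
  expect_equal(dbl$prr, p$prr)
  expect_equal(dbl$chi2, 2 * p$chi2, tolerance = 1e-12)
})

test_that("IC is negative under depletion and approaches 0 at independence as N grows", {
  depleted <- bcpnn_ic(contingency_table(0, 500, 500, 10000))
  expect_lt(depleted$ic, 0)

  for (N in c(1e4, 1e6, 1e8)) {
    n1 <- N / 100
    tab <- contingency_table(n1 * n1 / N, n1 - n1 * n1 / N,
                             n1 - n1 * n1 / N, N - 2 * n1 + n1 * n1 / N)
    expect_lt(abs(bcpnn_ic(tab)$ic), 2 / sqrt(N^0.5))
  }
  big <- bcpnn_ic(contingency_table(100, 9900, 9900, 980100))
  expect_lt(abs(big$ic), 0.01)
})

test_that("interval orderings hold across random tables", {
  set.seed(99)
  cells <- random_tables(300)
  prior <- fit_mgps(cells$a, with(cells, (a + b) * (a + c) / (a + b + c + d)))
  sc <- evaluate_signals(cells, prior = prior)
  expect_true(all(sc$ror_ci_low < sc$ror & sc$ror < sc$ror_ci_high))
  expect_true(all(sc$ic025 < sc$ic))
  expect_true(all(sc$ebgm05 < sc$ebgm))
})

test_that("threshold rules gate significance as specified", {
  # huge ROR but a = 2: the minimum-count rule blocks ROR and PRR flags
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 2,
                          p = 0.5, loglik = 0, n = 2L),
                     class = "mgps_prior")
  sc <- evaluate_signals(data.frame(a = 2, b = 10, c = 2, d = 5000),
                         prior = prior)
  expect_gt(sc$ror, 100)
  expect_false(sc$sig_ror)
  expect_false(sc$joint_significant)

  ind <- evaluate_signals(data.frame(a = 10, b = 90, c = 100, d = 900),
                          prior = prior)
  expect_false(any(ind$sig_ror, ind$sig_prr, ind$sig_bcpnn, ind$sig_mgps))
})

test_that("ROR and PRR flags are monotone in a with fixed margins", {
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 2,
                          p = 0.5, loglik = 0, n = 2L),
                     class = "mgps_prior")
  n1 <- 60; m1 <- 80; N <- 2000
  a_grid <- 3:(min(n1, m1) - 5)  # keep all cells positive
  cells <- data.frame(a = a_grid, b = n1 - a_grid, c = m1 - a_grid,
                      d = N - n1 - m1 + a_grid)
  sc <- evaluate_signals(cells, prior = prior)
  # once a flag turns on it stays on as a increases
  expect_true(all(diff(sc$sig_ror) >= 0))
  expect_true(all(diff(sc$sig_prr) >= 0))
})

test_that("PT-level scan ranks by count, reconciles with build_table, and buckets unmapped SOCs", {
  gen <- synth_generate(synth_config(seed = 5, n_background = 400,
                                     duplicate_rate = 0))
  rep <- as_safety_reports(gen)
  smq <- mini_smq(synth_config()$smq_pts$pt)
  flags <- flag_cases(rep, mini_dict(), smq)
  prior <- fit_mgps_universe(rep)

  scan_pt <- disprop(rep, flags, level = "pt", smq = smq, prior = prior)
  s <- scan_pt$scores[scan_pt$scores$drug == "ALENDRONATE", ]
  expect_true(all(diff(s$a) <= 0))
  for (i in sample(nrow(s), min(5, nrow(s)))) {
    tpid <- unique(flags$primaryid[flags$drug == "ALENDRONATE"])
    tab <- build_table(rep, tpid, s$term[i], counting = "event")
    expect_equal(s$a[i], tab$a)
    expect_equal(s$c[i], tab$c)
  }
  top <- top_signals(scan_pt, n = 3)
  expect_true(all(table(top$drug) <= 3))

  # SOC level with a deliberately incomplete map
  map <- data.frame(pt = smq$pts, soc = "GASTROINTESTINAL DISORDERS",
                    stringsAsFactors = FALSE)
  scan_soc <- disprop(rep, flags, level = "soc", pt_soc_map = map,
                      prior = prior)
  expect_true("UNMAPPED" %in% scan_soc$scores$term)
  expect_true(all(bg_pts <- scan_soc$unmapped_pts %in%
                    rep$reac$pt))
})
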