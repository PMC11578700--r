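test_that("the fitted optimum is at least as likely as the starting point", {
  set.seed(1)
  E <- rlnorm(400, log(4), 1)
  lam <- ifelse(runif(400) < 0.4, rgamma(400, 0.3, rate = 0.2),
                rgamma(400, 3, rate = 2.5))
  a <- rpois(400, lam * E)
  start <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, p = 1 / 3)
  fit <- fit_mgps(a, E, start = start)
  ll_start <- sum(mgps_marginal_loglik(a, E, start[1], start[2], start[3],
                                       start[4], start[5]))
  expect_gte(fit$loglik, ll_start)
  expect_s3_class(fit, "mgps_prior")
})

test_that("null data concentrate the fitted prior near lambda = 1", {
  set.seed(2)
  E <- round(runif(300, 400, 600))
  a <- as.integer(E)  # observed exactly equal to expected, huge counts
  fit <- fit_mgps(a, E)
  mix_mean <- unname(fit$p * fit$alpha1 / fit$beta1 +
                       (1 - fit$p) * fit$alpha2 / fit$beta2)
  expect_equal(mix_mean, 1, tolerance = 0.05)
  # dominant component has small coefficient of variation around 1
  dom <- if (fit$p > 0.5) c(fit$alpha1, fit$beta1) else
    c(fit$alpha2, fit$beta2)
  expect_lt(sqrt(dom[1]) / dom[2] / (dom[1] / dom[2]), 0.25)
})

test_that("EBGM with a degenerate one-component prior matches quadrature", {
  prior <- structure(list(alpha1 = 1.4, beta1 = 0.9, alpha2 = 1.4,
                          beta2 = 0.9, p = 0.5, loglik = 0, n = 2L),
                     class = "mgps_prior")
  for (case in list(c(a = 0, E = 3), c(a = 4, E = 1.5), c(a = 25, E = 6))) {
    got <- ebgm(data.frame(a = case["a"], E = case["E"]), prior)
    # closed form through the digamma identity
    closed <- 2^((digamma(prior$alpha1 + case[["a"]]) -
                    log(prior$beta1 + case[["E"]])) / log(2))
    quad <- oracle_ebgm_quad(case[["a"]], case[["E"]], prior)
    expect_equal(got$ebgm, closed, tolerance = 1e-10)
    expect_equal(got$ebgm, quad, tolerance = 1e-6)
  }
})

test_that("EBGM05 is the exact 5th percentile of the posterior mixture", {
  prior <- structure(list(alpha1 = 0.3, beta1 = 0.2, alpha2 = 2.2,
                          beta2 = 3.8, p = 0.35, loglik = 0, n = 2L),
                     class = "mgps_prior")
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:80, 1)
    E <- runif(1, 0.5, 40)
    q <- ebgm(data.frame(a = a, E = E), prior)$ebgm05
    expect_equal(oracle_posterior_cdf(q, a, E, prior), 0.05,
                 tolerance = 1e-6)
  }
})

test_that("EBGM shrinks small observed/expected ratios toward 1 and tracks large ones", {
  prior <- structure(list(alpha1 = 0.3, beta1 = 0.3, alpha2 = 2, beta2 = 2,
                          p = 0.4, loglik = 0, n = 2L),
                     class = "mgps_prior")
  small <- ebgm(data.frame(a = 3, E = 0.5), prior)   # raw ratio 6, tiny a
  expect_lt(small$ebgm, 6)
  expect_gt(small$ebgm, 1)
  big <- ebgm(data.frame(a = 6000, E = 1000), prior) # raw ratio 6, huge a
  expect_equal(big$ebgm, 6, tolerance = 0.02)
  # depletion direction: a = 0 with large E shrinks below 1
  none <- ebgm(data.frame(a = 0, E = 50), prior)
  expect_lt(none$ebgm, 1)
})
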