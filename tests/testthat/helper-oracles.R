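# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately use different code paths (different
# arithmetic arrangements, generic routines, numerical integration,
# Monte-Carlo posterior sampling) from the implementations in R/.

oracle_ror <- function(a, b, c, d, z = qnorm(0.975)) {
  est <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = est, lo = est * exp(-z * se), hi = est * exp(z * se))
}

oracle_prr <- function(a, b, c, d) {
  (a * (c + d)) / ((a + b) * c)
}

oracle_chi2 <- function(a, b, c, d) {
  unname(suppressWarnings(
    chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
               correct = FALSE)$statistic))
}

# Monte-Carlo check of the BCPNN closed form: the posterior of
# (p11, p1., p.1) under the standard priors is a triple of Betas; the
# implementation's E(IC) is log2 of the ratio of posterior means and its
# V(IC) is the delta-method sum of relative variances. Both are estimated
# here from posterior draws.
oracle_ic_mc <- function(a, b, c, d, ndraw = 1e6,
                         priors = c(gamma11 = 1, alpha1 = 1, beta1 = 1,
                                    alpha = 2, beta = 2)) {
  N <- a + b + c + d
  g11 <- priors[["gamma11"]]; a1 <- priors[["alpha1"]]
  b1 <- priors[["beta1"]]; al <- priors[["alpha"]]; be <- priors[["beta"]]
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  p11 <- rbeta(ndraw, a + g11, N - a + gam - g11)
  px <- rbeta(ndraw, a + b + a1, N - (a + b) + al - a1)
  py <- rbeta(ndraw, a + c + b1, N - (a + c) + be - b1)
  ic <- log2(mean(p11) / (mean(px) * mean(py)))
  relvar <- function(x) var(x) / mean(x)^2
  vic <- (relvar(p11) + relvar(px) + relvar(py)) / log(2)^2
  c(ic = ic, ic025 = ic - 2 * sqrt(vic))
}

# EBGM by direct numerical integration of the unnormalized posterior
# density prior(lambda) * Poisson(a | lambda E); independent of the
# negative-binomial weight algebra used in the package.
oracle_ebgm_quad <- function(a, E, prior) {
  dens <- function(l)
    (prior$p * dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$p) * dgamma(l, prior$alpha2, rate = prior$beta2)) *
    dpois(a, l * E)
  norm <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  m <- integrate(function(l) log2(l) * dens(l), 0, Inf,
                 rel.tol = 1e-10)$value / norm
  2^m
}

oracle_posterior_cdf <- function(q, a, E, prior) {
  l1 <- log(prior$p) + dnbinom(a, size = prior$alpha1,
                               prob = prior$beta1 / (prior$beta1 + E),
                               log = TRUE)
  l2 <- log1p(-prior$p) + dnbinom(a, size = prior$alpha2,
                                  prob = prior$beta2 / (prior$beta2 + E),
                                  log = TRUE)
  q1 <- 1 / (1 + exp(l2 - l1))
  q1 * pgamma(q, prior$alpha1 + a, rate = prior$beta1 + E) +
    (1 - q1) * pgamma(q, prior$alpha2 + a, rate = prior$beta2 + E)
}

# random small contingency tables with all cells positive
random_tables <- function(n, max_cell = 200) {
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE),
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(10 * max_cell, n, replace = TRUE))
}

# two-sample log-rank statistic as the squared standardized O-E score
oracle_logrank2 <- function(t1, t2) {
  times <- sort(unique(c(t1, t2)))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); nj <- n1 + n2
    d1 <- sum(t1 == tt); dj <- d1 + sum(t2 == tt)
    if (nj < 2) next
    O1 <- O1 + d1
    E1 <- E1 + n1 * dj / nj
    V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  (O1 - E1)^2 / V
}

# in-memory mini FAERS raw tables for cohort tests
mini_tables <- function() {
  demo <- data.frame(
    primaryid = c("1", "2", "3", "4"),
    caseid = c("1", "2", "3", "4"),
    fda_dt = c("20170315", "20180601", "20180915", "20190101"),
    event_dt = c("20170101", "2018", "", "20181220"),
    sex = c("F", "M", "", "F"),
    age = c("65", "70", "", "80"),
    age_cod = c("YR", "YR", "", "YR"),
    occp_cod = c("CN", "MD", "", "LW"),
    reporter_country = c("US", "GB", "US", "FR"),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("1", "1", "2", "3", "4"),
    drug_seq = c("1", "2", "1", "1", "1"),
    drugname = c("ALENDRONATE SODIUM", "ASPIRIN", "RISEDRONATE",
                 "ALENDRONATE", "IBANDRONATE SODIUM"),
    role_cod = c("PS", "C", "PS", "C", "PS"),
    route = c("ORAL", "ORAL", "ORAL", "ORAL", "INTRAVENOUS"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("1", "1", "2", "3", "4"),
    pt = c("OESOPHAGITIS", "DYSPHAGIA", "HEADACHE", "OESOPHAGITIS",
           "OESOPHAGEAL PAIN"),
    stringsAsFactors = FALSE)
  ther <- data.frame(
    primaryid = c("1", "4"), dsg_drug_seq = c("1", "1"),
    start_dt = c("20161201", "20181201"), stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = c("1", "1", "4"),
                     outc_cod = c("HO", "DE", "HO"),
                     stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc)
}

mini_smq <- function(pts = c("OESOPHAGITIS", "DYSPHAGIA",
                             "OESOPHAGEAL PAIN")) {
  structure(list(name = "OESOPHAGEAL TOXICITY (TEST)", pts = sort(pts)),
            class = "smq_definition")
}

fixture_pts <- function() synth_config()$smq_pts$pt

mini_dict <- function() {
  data.frame(pattern = c("ALENDRONATE", "RISEDRONATE", "IBANDRONATE"),
             label = c("ALENDRONATE", "RISEDRONATE", "IBANDRONATE"),
             stringsAsFactors = FALSE)
}
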