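#' Fit the MGPS two-component gamma mixture prior
#'
#' The multi-item gamma Poisson shrinker models the observed count `a` of each
#' drug-event pair as Poisson with mean `lambda * E`, where `E` is the count
#' expected under independence and the reporting-rate ratio `lambda` follows a
#' two-component gamma mixture prior
#' `p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2)` (shape/rate).
#' Marginally each count is then a mixture of negative binomials,
#' `NB(size = alpha_j, prob = beta_j/(beta_j + E))`, and the five
#' hyperparameters are estimated by maximizing the marginal log-likelihood
#' over all pairs.
#'
#' Optimization is deterministic: Nelder-Mead from a fixed starting point in
#' unconstrained space (`log` for shapes/rates, `logit` for the mixing
#' weight).
#'
#' @param a integer vector of observed counts, one per drug-event pair.
#' @param E numeric vector of expected counts under independence
#'   (`(a+b)(a+c)/N`), strictly positive.
#' @param start numeric start `c(alpha1, beta1, alpha2, beta2, p)`.
#' @param maxit maximum Nelder-Mead iterations. Null-like data make the
#'   mixture weakly identified (both components can describe the same
#'   unimodal prior), so the simplex is allowed many iterations.
#' @return object of class `mgps_prior`: list with the five hyperparameters,
#'   `loglik`, `n` (number of pairs) and `optim` diagnostics.
#' @references DuMouchel, W. (1999) Bayesian data mining in large frequency
#'   tables, with an application to the FDA spontaneous reporting system.
#'   The American Statistician 53, 177-190.
#' @export
fit_mgps <- function(a, E, start = c(alpha1 = 0.2, beta1 = 0.1,
                                     alpha2 = 2, beta2 = 4, p = 1 / 3),
                     maxit = 20000) {
  stopifnot(length(a) == length(E), length(a) >= 2, all(E > 0), all(a >= 0))
  negll <- function(theta) {
    -sum(mgps_marginal_loglik(a, E,
                              alpha1 = exp(theta[1L]), beta1 = exp(theta[2L]),
                              alpha2 = exp(theta[3L]), beta2 = exp(theta[4L]),
                              p = stats::plogis(theta[5L])))
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5L]))
  opt <- stats::optim(theta0, negll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  # weakly identified mixtures (null-like data) can degenerate the simplex
  # on a likelihood ridge; restart once and polish with quasi-Newton
  if (opt$convergence != 0) {
    opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
  }
  if (opt$convergence != 0) {
    polish <- stats::optim(opt$par, negll, method = "BFGS",
                           control = list(maxit = 500))
    if (polish$value <= opt$value) opt <- polish
  }
  if (opt$convergence != 0)
    stop("MGPS prior fit did not converge (optim code ", opt$convergence,
         ", value ", format(opt$value), ")")
  th <- unname(opt$par)
  structure(list(alpha1 = exp(th[1L]), beta1 = exp(th[2L]),
                 alpha2 = exp(th[3L]), beta2 = exp(th[4L]),
                 p = stats::plogis(th[5L]),
                 loglik = -opt$value, n = length(a), optim = opt),
            class = "mgps_prior")
}

#' Marginal log-likelihood of counts under an MGPS prior
#'
#' @param a,E observed and expected counts.
#' @param alpha1,beta1,alpha2,beta2,p hyperparameters (shape/rate pairs and
#'   first-component weight).
#' @return numeric vector of per-pair log-likelihood contributions.
#' @export
mgps_marginal_loglik <- function(a, E, alpha1, beta1, alpha2, beta2, p) {
  l1 <- log(p) + stats::dnbinom(a, size = alpha1,
                                prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- log1p(-p) + stats::dnbinom(a, size = alpha2,
                                   prob = beta2 / (beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (shape/rate):\n")
  cat(sprintf("  component 1: Gamma(%.4g, %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$p))
  cat(sprintf("  component 2: Gamma(%.4g, %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$p))
  cat(sprintf("  marginal log-likelihood %.2f on %d pairs\n", x$loglik, x$n))
  invisible(x)
}

#' @export
logLik.mgps_prior <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n, class = "logLik")
}

#' Empirical Bayes geometric mean (EBGM) and its lower bound
#'
#' Given the fitted prior, the posterior of the reporting-rate ratio `lambda`
#' for a pair with observed `a` and expected `E` is again a two-component
#' gamma mixture, with shapes `alpha_j + a`, rates `beta_j + E`, and weights
#' proportional to the component negative-binomial likelihoods. The EBGM is
#' the posterior geometric mean `2^(E[log2 lambda | a])`, with the expectation
#' available in closed form through the digamma function; EBGM05 is the 5th
#' percentile of the posterior, obtained by root-finding on the mixture gamma
#' CDF.
#'
#' @param tab a `contingency_table`, or a data.frame with either cell columns
#'   `a`,`b`,`c`,`d` (then `E = (a+b)(a+c)/N`) or columns `a` and `E`.
#' @param prior an `mgps_prior`.
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
ebgm <- function(tab, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (inherits(tab, "contingency_table") ||
      (is.data.frame(tab) && all(c("a", "b", "c", "d") %in% names(tab)))) {
    cells <- as_cells(tab)
    a <- cells$a
    N <- cells$a + cells$b + cells$c + cells$d
    E <- (cells$a + cells$b) * (cells$a + cells$c) / N
  } else {
    tab <- as.data.frame(tab)
    a <- tab$a; E <- tab$E
  }
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  l1 <- log(prior$p) + stats::dnbinom(a, size = prior$alpha1,
                                      prob = prior$beta1 / (prior$beta1 + E),
                                      log = TRUE)
  l2 <- log1p(-prior$p) + stats::dnbinom(a, size = prior$alpha2,
                                         prob = prior$beta2 / (prior$beta2 + E),
                                         log = TRUE)
  q1 <- 1 / (1 + exp(l2 - l1))
  elog2 <- (q1 * (digamma(s1) - log(r1)) +
              (1 - q1) * (digamma(s2) - log(r2))) / log(2)
  eb <- 2^elog2
  eb05 <- vapply(seq_along(a), function(i) {
    mixture_gamma_quantile(0.05, q1[i], s1[i], r1[i], s2[i], r2[i])
  }, 0.0)
  data.frame(ebgm = eb, ebgm05 = eb05)
}

# quantile of q1*Gamma(s1,r1) + (1-q1)*Gamma(s2,r2) by root-finding on the CDF
mixture_gamma_quantile <- function(p, q1, s1, r1, s2, r2) {
  cdf <- function(x) q1 * stats::pgamma(x, s1, rate = r1) +
    (1 - q1) * stats::pgamma(x, s2, rate = r2)
  q1_ <- stats::qgamma(p, s1, rate = r1)
  q2_ <- stats::qgamma(p, s2, rate = r2)
  lo <- min(q1_, q2_) * (1 - 1e-9)
  hi <- max(q1_, q2_) * (1 + 1e-9)
  if (hi - lo < .Machine$double.eps) return(hi)
  stats::uniroot(function(x) cdf(x) - p, c(lo, hi), tol = 1e-12,
                 extendInt = "yes")$root
}
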