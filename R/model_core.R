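#' Model hyperparameters and prior settings
#'
#' Bundles the parameters of the hierarchical changepoint model. Regime
#' rates on the per-100,000 scale carry independent Gamma(a, b) priors
#' (shape/rate), chosen conjugate to the Poisson likelihood so indicator
#' updates can integrate rates out in closed form. The changepoint process
#' for each state-drug series is a centered autologistic chain with linear
#' predictor `beta0[d] + phi[r(s), d]` and autoregressive coefficient
#' `eta[d]`; regional effect vectors `phi[r, ]` are multivariate normal
#' across drugs with covariance `Sigma_phi`.
#'
#' @param drugs Drug-category labels (defines D).
#' @param n_regions Number of regions (defines R).
#' @param a,b Gamma shape and rate of the regime-rate prior, recycled over
#'   drugs. Defaults a = 0.5, b = 0.05: prior mean 10 per 100k, variance
#'   200 -- proper but diffuse on the scale of observed overdose rates.
#' @param beta0,eta Initial values, recycled over drugs.
#' @param phi R x D matrix of regional effects (default 0).
#' @param Sigma_phi D x D covariance of regional effect vectors (default
#'   identity).
#' @param prior_sd_beta0,prior_sd_eta Normal prior SDs (default 10).
#' @param iw_df,iw_scale Inverse-Wishart prior on `Sigma_phi`: degrees of
#'   freedom (default D + 2) and scale matrix (default identity).
#' @return A `model_hyperparams` list.
#' @export
model_hyperparams <- function(drugs = DRUG_LEVELS, n_regions = 10L,
                              a = 0.5, b = 0.05,
                              beta0 = -2, eta = 0,
                              phi = NULL, Sigma_phi = NULL,
                              prior_sd_beta0 = 10, prior_sd_eta = 10,
                              iw_df = NULL, iw_scale = NULL) {
  D <- length(drugs)
  if (is.null(phi)) phi <- matrix(0, n_regions, D)
  if (is.null(Sigma_phi)) Sigma_phi <- diag(D)
  if (is.null(iw_df)) iw_df <- D + 2
  if (is.null(iw_scale)) iw_scale <- diag(D)
  a <- rep_len(a, D); b <- rep_len(b, D)
  beta0 <- rep_len(beta0, D); eta <- rep_len(eta, D)
  stopifnot(all(a > 0), all(b > 0), nrow(phi) == n_regions,
            ncol(phi) == D, nrow(Sigma_phi) == D, ncol(Sigma_phi) == D)
  if (!isSymmetric(unname(Sigma_phi)) ||
      any(eigen(Sigma_phi, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("Sigma_phi must be symmetric positive definite")
  }
  structure(list(drugs = drugs, n_regions = as.integer(n_regions),
                 a = a, b = b, beta0 = beta0, eta = eta, phi = phi,
                 Sigma_phi = Sigma_phi,
                 prior_sd_beta0 = prior_sd_beta0, prior_sd_eta = prior_sd_eta,
                 iw_df = iw_df, iw_scale = iw_scale),
            class = "model_hyperparams")
}

#' Regime partition implied by changepoint indicators
#'
#' Indicator `z[t] = 1` marks year `t+1` (the t-th transition year) as the
#' start of a new regime; the first year always opens regime 1.
#'
#' @param z Binary vector of length T-1 (transition years 2..T).
#' @param years Integer vector of the T years.
#' @return List of integer vectors, each the years of one regime, in order.
#' @examples
#' partition_from_indicators(c(0, 0, 1, 0), 2001:2005)
#' @export
partition_from_indicators <- function(z, years) {
  stopifnot(length(z) == length(years) - 1L, all(z %in% c(0, 1)))
  starts <- c(1L, which(z == 1) + 1L)
  ends <- c(starts[-1L] - 1L, length(years))
  lapply(seq_along(starts), function(k) years[starts[k]:ends[k]])
}

#' Collapsed Poisson-Gamma log marginal likelihood of one segment
#'
#' Integrates the regime rate out of a segment's Poisson likelihood against
#' its Gamma(a, b) prior:
#' \deqn{\log \int \prod_t \mathrm{Pois}(y_t \mid E_t\theta)\,
#'   \mathrm{Ga}(\theta \mid a, b)\, d\theta
#'   = \sum_t [y_t \log E_t - \log y_t!] + a\log b - \log\Gamma(a)
#'     + \log\Gamma(a + Y) - (a + Y)\log(b + \textstyle\sum E_t)}
#' with \eqn{Y = \sum_t y_t}. Exposures `E` are population / 100,000 so the
#' rate is per 100k.
#'
#' @param y Non-negative integer counts of the segment's years.
#' @param E Positive exposures, same length.
#' @param a,b Gamma shape and rate, both > 0.
#' @return Log marginal likelihood (scalar).
#' @export
segment_log_marginal <- function(y, E, a, b) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  if (any(E <= 0)) stop("exposures must be positive")
  if (any(y < 0)) stop("counts must be non-negative")
  Y <- sum(y)
  sum(y * log(E) - lgamma(y + 1)) + a * log(b) - lgamma(a) +
    lgamma(a + Y) - (a + Y) * log(b + sum(E))
}

#' Conditional changepoint probability of the centered autologistic chain
#'
#' The independence-model mean is `mu = plogis(beta0 + phi)`. At the first
#' transition year (no predecessor) the probability is `mu` itself; at later
#' years it is `plogis(beta0 + phi + eta * (z_prev - mu))` -- centering the
#' autoregressive term by `mu` keeps `beta0 + phi` interpretable as the
#' marginal log odds of a change.
#'
#' @param beta0 Baseline log odds.
#' @param phi Regional effect.
#' @param eta Autoregressive coefficient.
#' @param z_prev Previous year's indicator (0/1), or `NULL` at the first
#'   transition year.
#' @return Probability of a changepoint.
#' @export
changepoint_prob <- function(beta0, phi, eta, z_prev = NULL) {
  mu <- stats::plogis(beta0 + phi)
  if (is.null(z_prev)) return(mu)
  stats::plogis(beta0 + phi + eta * (z_prev - mu))
}

#' Log density of a changepoint configuration under the autologistic prior
#'
#' Sums, over state-drug series, the Markov-chain factorization of the
#' centered autologistic process: a Bernoulli log-mass at every transition
#' year with probability from [changepoint_prob()] using that state's
#' regional effect.
#'
#' @param z S x (T-1) x D binary array of indicators.
#' @param hyper A [model_hyperparams()].
#' @param region_idx Integer vector, length S: region index of each state
#'   (row of `hyper$phi`).
#' @return Log prior density (scalar).
#' @export
changepoint_prior_logpdf <- function(z, hyper, region_idx) {
  dm <- dim(z)
  S <- dm[1]; Tm1 <- dm[2]; D <- dm[3]
  stopifnot(length(region_idx) == S, max(region_idx) <= nrow(hyper$phi))
  total <- 0
  for (d in seq_len(D)) {
    lin <- hyper$beta0[d] + hyper$phi[region_idx, d]     # length S
    mu <- stats::plogis(lin)
    zm <- matrix(z[, , d], S, Tm1)
    p <- matrix(NA_real_, S, Tm1)
    p[, 1] <- mu
    if (Tm1 > 1) {
      for (t in 2:Tm1) {
        p[, t] <- stats::plogis(lin + hyper$eta[d] * (zm[, t - 1] - mu))
      }
    }
    total <- total + sum(zm * log(p) + (1 - zm) * log1p(-p))
  }
  total
}

## log density of a multivariate normal via Cholesky
dmvnorm_log <- function(x, Sigma) {
  L <- chol(Sigma)
  k <- ncol(Sigma)
  u <- backsolve(L, x, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(u * u)
}

## log multivariate gamma function
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## log density of an inverse-Wishart(nu, Psi) at Sigma
dinvwishart_log <- function(Sigma, nu, Psi) {
  p <- ncol(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive definite")
  (nu / 2) * determinant(Psi, logarithm = TRUE)$modulus -
    (nu * p / 2) * log(2) - lmvgamma(nu / 2, p) -
    ((nu + p + 1) / 2) * determinant(Sigma, logarithm = TRUE)$modulus -
    0.5 * sum(diag(solve(Sigma, Psi)))
}

#' Log prior density of the hyperparameters
#'
#' `beta0[d] ~ N(0, prior_sd_beta0^2)`, `eta[d] ~ N(0, prior_sd_eta^2)`,
#' regional effect rows `phi[r, ] ~ MVN(0, Sigma_phi)`, and
#' `Sigma_phi ~ Inverse-Wishart(iw_df, iw_scale)`. The Gamma constants
#' (a, b) of the rate prior are fixed, not hyper-learned, by default.
#'
#' @param hyper A [model_hyperparams()].
#' @return Log prior density (scalar).
#' @export
hyper_log_prior <- function(hyper) {
  ev <- eigen(hyper$Sigma_phi, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma_phi must be symmetric positive definite")
  lp <- sum(stats::dnorm(hyper$beta0, 0, hyper$prior_sd_beta0, log = TRUE)) +
    sum(stats::dnorm(hyper$eta, 0, hyper$prior_sd_eta, log = TRUE))
  for (r in seq_len(nrow(hyper$phi))) {
    lp <- lp + dmvnorm_log(hyper$phi[r, ], hyper$Sigma_phi)
  }
  lp + as.numeric(dinvwishart_log(hyper$Sigma_phi, hyper$iw_df,
                                  hyper$iw_scale))
}

#' Joint log posterior of a full model state (up to a constant)
#'
#' Sums the Poisson log likelihood at the current rates, the Gamma log prior
#' of each regime rate, the autologistic prior of the indicators, and the
#' hyperparameter prior.
#'
#' @param state List with `z` (S x (T-1) x D), `rate` (S x T x D, constant
#'   within regimes), and `hyper`.
#' @param data A `counts_table`.
#' @param region_idx Region index per state.
#' @return Scalar log posterior density (unnormalized).
#' @export
joint_log_posterior <- function(state, data, region_idx) {
  S <- length(data$states); Tn <- length(data$years)
  D <- length(data$drugs)
  if (!all(dim(state$z) == c(S, Tn - 1L, D)) ||
      !all(dim(state$rate) == c(S, Tn, D))) {
    stop("state dimensions do not match data")
  }
  if (anyNA(state$rate) || any(state$rate <= 0)) return(-Inf)
  E <- exposures(data)
  lp <- 0
  for (d in seq_len(D)) {
    mu <- state$rate[, , d] * E
    lp <- lp + sum(stats::dpois(data$deaths[, , d], mu, log = TRUE))
    for (s in seq_len(S)) {
      segs <- partition_from_indicators(state$z[s, , d], data$years)
      th <- vapply(segs, function(yrs) state$rate[s, match(yrs[1], data$years), d], 0)
      lp <- lp + sum(stats::dgamma(th, shape = state$hyper$a[d],
                                   rate = state$hyper$b[d], log = TRUE))
    }
  }
  lp + changepoint_prior_logpdf(state$z, state$hyper, region_idx) +
    hyper_log_prior(state$hyper)
}
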