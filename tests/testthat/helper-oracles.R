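## Independent oracles and small fixtures used across the suite.

## Brute-force posterior over all changepoint configurations of a single
## state-drug series, with regime rates integrated out. Written directly
## from the Poisson-Gamma integral and the centered autologistic chain, not
## via the package's model functions.
enum_posterior <- function(y, E, a, b, beta0, eta, phi = 0) {
  Tn <- length(y); Tm1 <- Tn - 1L
  mu <- plogis(beta0 + phi)
  configs <- as.matrix(expand.grid(rep(list(0:1), Tm1)))
  lw <- apply(configs, 1, function(z) {
    lp <- 0
    for (t in seq_len(Tm1)) {
      p <- if (t == 1L) mu else plogis(beta0 + phi + eta * (z[t - 1] - mu))
      lp <- lp + if (z[t] == 1) log(p) else log(1 - p)
    }
    bounds <- c(1L, which(z == 1) + 1L, Tn + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      idx <- bounds[k]:(bounds[k + 1L] - 1L)
      Y <- sum(y[idx]); Es <- sum(E[idx])
      lp <- lp + a * log(b) - lgamma(a) + lgamma(a + Y) -
        (a + Y) * log(b + Es) + sum(y[idx] * log(E[idx]) - lgamma(y[idx] + 1))
    }
    lp
  })
  w <- exp(lw - max(lw)); w <- w / sum(w)
  list(pz = colSums(configs * w), probs = w, configs = configs)
}

## Quadrature oracle for the collapsed segment likelihood.
## Integrand scaled by its mode so the quadrature keeps precision even when
## the unnormalized posterior mass is far below double range.
quad_segment_marginal <- function(y, E, a, b) {
  logf <- function(t0) {
    sum(dpois(y, E * t0, log = TRUE)) + dgamma(t0, a, rate = b, log = TRUE)
  }
  opt <- optimize(function(t0) -logf(t0), c(1e-10, max((sum(y) + a) /
                                                         (sum(E) + b), 1) * 50))
  c0 <- -opt$objective
  ig <- integrate(function(th) sapply(th, function(t0) exp(logf(t0) - c0)),
                  0, Inf, rel.tol = 1e-11)
  c0 + log(ig$value)
}

## Forward simulation of one centered autologistic chain of length Tm1.
sim_autologistic_chain <- function(Tm1, beta0, eta, phi = 0) {
  mu <- plogis(beta0 + phi)
  z <- integer(Tm1)
  z[1] <- rbinom(1, 1, mu)
  for (t in seq_len(Tm1)[-1]) {
    z[t] <- rbinom(1, 1, plogis(beta0 + phi + eta * (z[t - 1] - mu)))
  }
  z
}

## A small valid counts table on an arbitrary lattice.
toy_counts <- function(S = 2L, Tn = 3L, D = 4L, seed = 42L) {
  set.seed(seed)
  drugs <- c("prescription", "heroin", "synthetic", "unspecified")[seq_len(D)]
  counts_table(states = paste0("S", LETTERS[seq_len(S)]),
               years = 2000L + seq_len(Tn) - 1L,
               drugs = drugs,
               deaths = array(rpois(S * Tn * D, 20), c(S, Tn, D)),
               population = matrix(1e6, S, Tn))
}

## Region map assigning every listed state to one region.
toy_regions <- function(states, region = 1L) {
  structure(setNames(rep(as.integer(region), length(states)), states),
            class = "region_map")
}

## One shared medium-scale recovery fit, computed lazily and cached so the
## changepoint-recovery, coverage and onset checks reuse the same run.
recovery_cache <- new.env(parent = emptyenv())
recovery_fit <- function() {
  if (!is.null(recovery_cache$fit)) return(recovery_cache$fit)
  cfg <- sim_config(
    n_states = 10L, n_regions = 2L, years = 1999:2021,
    drugs = c("heroin", "synthetic"),
    onset_window = list(heroin = c(2010L, 2014L),
                        synthetic = c(2014L, 2021L)),
    baseline_range = list(heroin = c(2, 8), synthetic = c(2, 8)),
    population_range = c(2e6, 2e7))
  truth <- simulate_truth(cfg, seed = 101L)
  counts <- simulate_counts(truth, seed = 102L)
  draws <- run_mcmc(counts, truth$region_map,
                    model_hyperparams(drugs = counts$drugs, n_regions = 2L),
                    mcmc_config(n_iter = 20000L, n_burn = 10000L, thin = 10L,
                                seed = 103L))
  recovery_cache$fit <- list(truth = truth, counts = counts, draws = draws)
  recovery_cache$fit
}
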