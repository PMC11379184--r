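test_that("retained-draw arithmetic matches the configuration", {
  expect_identical(n_retained(mcmc_config()), 5000L)
  expect_identical(n_retained(mcmc_config(2000, 500, 10)), 150L)
  expect_error(mcmc_config(n_iter = 100, n_burn = 100), "smaller")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(blocks = "frogs"), "unknown block")
})

test_that("conjugate rate updates reproduce Gamma moments", {
  # one state, one drug, single segment: theta | y ~ Gamma(a + Y, b + E)
  tab <- counts_table("SA", 2000L, "heroin", array(10L, c(1, 1, 1)),
                      matrix(1e5, 1, 1))   # E = 1
  hyper <- model_hyperparams(drugs = "heroin", n_regions = 1L, a = 1, b = 1)
  state <- list(z = array(0L, c(1, 0, 1)), rate = array(1, c(1, 1, 1)),
                hyper = hyper)
  set.seed(19)
  draws <- replicate(1e5, update_rates(state, tab)$rate[1, 1, 1])
  post_mean <- 11 / 2; post_var <- 11 / 4
  expect_lt(abs(mean(draws) - post_mean),
            3 * sqrt(post_var / length(draws)))
  # with huge exposure and no deaths the posterior mean collapses to 0
  tab0 <- counts_table("SA", 2000L, "heroin", array(0L, c(1, 1, 1)),
                       matrix(1e12, 1, 1))
  d0 <- replicate(200, update_rates(state, tab0)$rate[1, 1, 1])
  expect_lt(mean(d0), 1e-3)
  # fixed seed gives an identical draw sequence
  set.seed(7); a1 <- replicate(10, update_rates(state, tab)$rate[1, 1, 1])
  set.seed(7); a2 <- replicate(10, update_rates(state, tab)$rate[1, 1, 1])
  expect_identical(a1, a2)
})

test_that("indicator sweeps lock onto an overwhelming jump", {
  # rate jumps x20 mid-series with expected counts >> 500/yr
  years <- 2000:2009
  rate <- c(rep(5, 5), rep(100, 5))
  set.seed(12)
  deaths <- rpois(10, rate * 20)          # population 2e6, E = 20
  tab <- counts_table("SA", years, "heroin",
                      array(deaths, c(1, 10, 1)), matrix(2e6, 1, 10))
  hyper <- model_hyperparams(drugs = "heroin", n_regions = 1L)
  state <- list(z = array(0L, c(1, 9, 1)),
                rate = array(mean(deaths) / 20, c(1, 10, 1)), hyper = hyper)
  hits <- 0L
  set.seed(13)
  for (i in 1:200) {
    state <- update_indicators(state, tab, 1L)
    if (i > 10L) hits <- hits + state$z[1, 5, 1]   # transition into 2005
  }
  expect_gte(hits / 190, 0.99)

  # flat data with beta0 = -10: indicators stay off
  tab_flat <- counts_table("SA", years, "heroin",
                           array(rpois(10, 200), c(1, 10, 1)),
                           matrix(2e6, 1, 10))
  hyper_flat <- model_hyperparams(drugs = "heroin", n_regions = 1L,
                                  beta0 = -10)
  st <- list(z = array(0L, c(1, 9, 1)), rate = array(10, c(1, 10, 1)),
             hyper = hyper_flat)
  tot <- 0L
  for (i in 1:100) {
    st <- update_indicators(st, tab_flat, 1L)
    tot <- tot + sum(st$z)
  }
  expect_identical(tot, 0L)
})

test_that("indicator Gibbs targets the exact collapsed posterior", {
  # 1 state, T = 4 (8 configurations), moderate counts
  years <- 2000:2003
  y <- c(8, 30, 31, 6); E <- rep(1.5, 4)
  tab <- counts_table("SA", years, "heroin", array(y, c(1, 4, 1)),
                      matrix(1.5e5, 1, 4))
  beta0 <- -1; eta <- 0.8
  hyper <- model_hyperparams(drugs = "heroin", n_regions = 1L, a = 0.5,
                             b = 0.05, beta0 = beta0, eta = eta)
  oracle <- enum_posterior(y, E, 0.5, 0.05, beta0, eta)
  state <- list(z = array(0L, c(1, 3, 1)), rate = array(10, c(1, 4, 1)),
                hyper = hyper)
  set.seed(31)
  n_sweep <- 4e4
  freq <- numeric(8)
  for (i in seq_len(n_sweep)) {
    state$z[, , 1] <- opioidwaves:::cpp_sweep_indicators(
      matrix(state$z[, , 1], 1), matrix(y, 1), matrix(E, 1), 0.5, 0.05,
      beta0, eta)
    code <- sum(state$z[1, , 1] * c(1, 2, 4)) + 1
    freq[code] <- freq[code] + 1
  }
  emp <- freq / n_sweep
  exact <- numeric(8)
  for (k in seq_len(nrow(oracle$configs))) {
    code <- sum(oracle$configs[k, ] * c(1, 2, 4)) + 1
    exact[code] <- oracle$probs[k]
  }
  expect_lt(0.5 * sum(abs(emp - exact)), 0.01)   # total variation
})

test_that("autologistic Metropolis recovers generating parameters", {
  set.seed(41)
  S <- 30L; Tm1 <- 22L
  beta0_true <- -2; eta_true <- 1
  z <- t(replicate(S, sim_autologistic_chain(Tm1, beta0_true, eta_true)))
  tab <- counts_table(paste0("S", seq_len(S)), 1999:2021, "heroin",
                      array(rpois(S * 23, 50), c(S, 23, 1)),
                      matrix(1e6, S, 23))
  regions <- toy_regions(tab$states)
  draws <- run_mcmc(tab, regions,
                    model_hyperparams(drugs = "heroin", n_regions = 1L),
                    mcmc_config(n_iter = 12000L, n_burn = 4000L, thin = 4L,
                                seed = 42L, blocks = "autologistic"),
                    init = list(z = array(as.integer(z), c(S, Tm1, 1))))
  b0 <- draws$beta0[1, ]; et <- draws$eta[1, ]
  expect_lt(abs(mean(b0) - beta0_true), 3 * sd(b0))
  expect_lt(abs(mean(et) - eta_true), 3 * sd(et))
  expect_gt(mean(draws$acceptance$beta0), 0.05)
})

test_that("regional effect block preserves its prior and IW conditional", {
  # no data contribution: a 0-row indicator array leaves only the MVN prior
  D <- 2L
  hyper <- model_hyperparams(drugs = c("heroin", "synthetic"),
                             n_regions = 1L,
                             Sigma_phi = diag(c(0.5, 2)))
  state <- list(z = array(0L, c(0, 5, D)), rate = array(1, c(0, 6, D)),
                hyper = hyper)
  set.seed(51)
  ph <- matrix(NA_real_, 2e4, D)
  for (i in seq_len(nrow(ph))) {
    state <- update_regional_effects(state, integer(0), scale = 1.2)
    state$hyper$Sigma_phi <- diag(c(0.5, 2))  # hold covariance fixed
    ph[i, ] <- state$hyper$phi[1, ]
  }
  # MVN(0, diag(0.5, 2)) moments within Monte-Carlo error (correlated draws)
  expect_lt(abs(mean(ph[, 1])), 0.1)
  expect_lt(abs(var(ph[, 1]) - 0.5), 0.15)
  expect_lt(abs(var(ph[, 2]) - 2), 0.5)

  # conjugate inverse-Wishart conditional: posterior mean of Sigma given phi
  R <- 10L
  set.seed(52)
  phi_fix <- matrix(rnorm(R * D), R, D)
  hy2 <- model_hyperparams(drugs = c("heroin", "synthetic"), n_regions = R)
  st2 <- list(z = array(0L, c(0, 5, D)), rate = array(1, c(0, 6, D)),
              hyper = hy2)
  st2$hyper$phi <- phi_fix
  sig_draws <- array(NA_real_, c(D, D, 4000))
  for (i in 1:4000) {
    out <- update_regional_effects(st2, integer(0), scale = 0)
    sig_draws[, , i] <- out$hyper$Sigma_phi
  }
  # phi unchanged by a zero-scale proposal; Sigma redrawn each call
  expect_true(all(out$hyper$phi == phi_fix))
  nu_post <- hy2$iw_df + R
  Psi_post <- hy2$iw_scale + crossprod(phi_fix)
  iw_mean <- Psi_post / (nu_post - D - 1)
  got <- apply(sig_draws, c(1, 2), mean)
  expect_lt(max(abs(got - iw_mean)), 0.1)
})

test_that("full runs are reproducible and match the conjugate posterior", {
  tab <- toy_counts(S = 3L, Tn = 5L, D = 2L, seed = 60L)
  regions <- toy_regions(tab$states)
  cfg <- mcmc_config(n_iter = 800L, n_burn = 200L, thin = 3L, seed = 9L)
  d1 <- run_mcmc(tab, regions,
                 model_hyperparams(drugs = tab$drugs, n_regions = 1L), cfg)
  d2 <- run_mcmc(tab, regions,
                 model_hyperparams(drugs = tab$drugs, n_regions = 1L), cfg)
  expect_identical(d1$lambda, d2$lambda)
  expect_identical(d1$z, d2$z)
  expect_identical(d1$beta0, d2$beta0)
  expect_identical(dim(d1$lambda)[4], n_retained(cfg))

  # z fixed all-zero, rates only: lambda ~ Gamma(a + Y, b + E) exactly
  tabc <- counts_table("SA", 2000:2003, "heroin",
                       array(c(12L, 9L, 15L, 11L), c(1, 4, 1)),
                       matrix(1e6, 1, 4))
  a <- 0.5; b <- 0.05
  drc <- run_mcmc(tabc, toy_regions("SA"),
                  model_hyperparams(drugs = "heroin", n_regions = 1L,
                                    a = a, b = b),
                  mcmc_config(n_iter = 4000L, n_burn = 0L, thin = 1L,
                              seed = 3L, blocks = "rates"))
  lam <- drc$lambda[1, 1, 1, ]
  Y <- 47; E <- 40
  pm <- (a + Y) / (b + E); pv <- (a + Y) / (b + E)^2
  M <- length(lam)
  expect_lt(abs(mean(lam) - pm), 3 * sqrt(pv / M))
  # variance of a Gamma sample: SE via fourth-moment approximation
  se_var <- pv * sqrt(2 / (M - 1)) * sqrt(3)
  expect_lt(abs(var(lam) - pv), 3 * se_var)
  # lambda constant across the single regime in every draw
  expect_true(all(apply(drc$lambda[1, , 1, ], 2, function(x) all(x == x[1]))))
})

test_that("non-finite initialization is rejected with a diagnostic", {
  tab <- toy_counts(S = 2L, Tn = 3L, D = 2L)
  bad_init <- list(rate = array(-1, c(2, 3, 2)))
  expect_error(
    run_mcmc(tab, toy_regions(tab$states),
             model_hyperparams(drugs = tab$drugs, n_regions = 1L),
             mcmc_config(n_iter = 100L, n_burn = 10L, thin = 1L),
             init = bad_init),
    "non-finite|NaN")
})

test_that("diagnostics quantify mixing and flag failures", {
  make_draws <- function(vals, seed) {
    tab <- toy_counts(S = 2L, Tn = 3L, D = 1L)
    d <- run_mcmc(tab, toy_regions(tab$states),
                  model_hyperparams(drugs = tab$drugs, n_regions = 1L),
                  mcmc_config(n_iter = 2100L, n_burn = 100L, thin = 1L,
                              seed = seed))
    if (!is.null(vals)) d$beta0[1, ] <- vals
    d
  }
  set.seed(71)
  chains <- lapply(1:4, function(i) make_draws(rnorm(2000), seed = i))
  diag <- mcmc_diagnostics(chains)
  b0 <- diag[diag$parameter == "beta0[prescription]", ]
  expect_gt(b0$rhat, 0.99); expect_lt(b0$rhat, 1.01)
  expect_gt(b0$ess, 4000)   # iid injected draws: ess near 4 x 2000

  # two chains with different means are flagged
  c2 <- lapply(1:2, function(i) {
    make_draws(rnorm(2000, mean = c(0, 3)[i], sd = 0.3), seed = i + 4)
  })
  d2 <- mcmc_diagnostics(c2)
  expect_gt(d2$rhat[d2$parameter == "beta0[prescription]"], 1.1)

  # constant chains degrade gracefully
  c3 <- make_draws(rep(1.5, 2000), seed = 9)
  d3 <- mcmc_diagnostics(c3)
  row <- d3[d3$parameter == "beta0[prescription]", ]
  expect_true(row$degenerate)
  expect_true(is.na(row$ess))
  expect_error(mcmc_diagnostics(make_draws(NULL, 1)[c()]), "")
})
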