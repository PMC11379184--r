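#' MCMC sampler configuration
#'
#' Defaults mirror the full analysis profile (500,000 iterations, 250,000
#' burn-in, thinning by 50, giving 5,000 retained draws); reduced settings
#' are used throughout the tests and examples.
#'
#' @param n_iter Total iterations.
#' @param n_burn Burn-in iterations discarded (< `n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer RNG seed.
#' @param scale_beta0,scale_eta,scale_phi Random-walk proposal SDs.
#' @param adapt Adapt proposal scales during burn-in toward 30% acceptance
#'   (frozen afterwards, preserving detailed balance).
#' @param blocks Character subset of
#'   `c("indicators", "rates", "autologistic", "regional")`: which parameter
#'   blocks the sampler updates. Fixing a block at its initial value
#'   supports conditional runs (e.g. fixed indicators for hyperparameter
#'   recovery).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 500000L, n_burn = 250000L, thin = 50L,
                        seed = 1L,
                        scale_beta0 = 0.3, scale_eta = 0.3, scale_phi = 0.3,
                        adapt = TRUE,
                        blocks = c("indicators", "rates", "autologistic",
                                   "regional")) {
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  thin <- as.integer(thin)
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  unknown <- setdiff(blocks, c("indicators", "rates", "autologistic",
                               "regional"))
  if (length(unknown)) stop("unknown block(s): ", paste(unknown, collapse = ", "))
  structure(list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                 seed = as.integer(seed), scale_beta0 = scale_beta0,
                 scale_eta = scale_eta, scale_phi = scale_phi,
                 adapt = isTRUE(adapt), blocks = blocks),
            class = "mcmc_config")
}

#' Number of retained draws implied by an MCMC configuration
#'
#' @param config An [mcmc_config()].
#' @return `floor((n_iter - n_burn) / thin)`.
#' @export
n_retained <- function(config) {
  (config$n_iter - config$n_burn) %/% config$thin
}

## dense region indexing: map region ids of the data's states to 1..R
dense_regions <- function(regions, states) {
  ids <- region_of(regions, states)
  labels <- sort(unique(ids))
  list(idx = match(ids, labels), labels = labels, R = length(labels))
}

#' One collapsed Gibbs sweep over the changepoint indicators
#'
#' Visits every (state, transition year, drug) site and resamples its
#' indicator from the full conditional with the regime rates integrated out
#' (Poisson-Gamma conjugacy); the autologistic prior contributes the site's
#' own Bernoulli mass and its successor's (which depends on the site through
#' the centered autoregressive term). Regime rates are then redrawn from
#' their conjugate Gamma conditionals.
#'
#' @param state Model state (`z`, `rate`, `hyper`).
#' @param data A `counts_table`.
#' @param region_idx Dense region index per state.
#' @return Updated state.
#' @export
update_indicators <- function(state, data, region_idx) {
  E <- exposures(data)
  for (d in seq_along(data$drugs)) {
    lin <- state$hyper$beta0[d] + state$hyper$phi[region_idx, d]
    zmat <- matrix(as.integer(state$z[, , d]), nrow = dim(state$z)[1])
    ymat <- matrix(data$deaths[, , d], nrow = dim(state$z)[1])
    zmat <- cpp_sweep_indicators(zmat, ymat,
                                 E, state$hyper$a[d], state$hyper$b[d],
                                 lin, state$hyper$eta[d])
    state$z[, , d] <- zmat
  }
  update_rates(state, data)
}

#' Conjugate redraw of all regime rates
#'
#' Each regime rate is `Gamma(a + Y_seg, b + E_seg)` given the current
#' partition; the draw is replicated across the regime's years in the
#' expanded `rate` array.
#'
#' @inheritParams update_indicators
#' @return Updated state.
#' @export
update_rates <- function(state, data) {
  E <- exposures(data)
  for (d in seq_along(data$drugs)) {
    zmat <- matrix(as.integer(state$z[, , d]), nrow = dim(state$z)[1])
    ymat <- matrix(data$deaths[, , d], nrow = dim(state$z)[1])
    state$rate[, , d] <- cpp_draw_rates(zmat, ymat,
                                        E, state$hyper$a[d], state$hyper$b[d])
  }
  state
}

## autologistic log target for drug d given candidate beta0/eta/phi column
autologistic_target_d <- function(z_d, beta0_d, eta_d, phi_col, region_idx) {
  cpp_autologistic_logpdf(z_d, beta0_d + phi_col[region_idx], eta_d)
}

#' Random-walk Metropolis update of the autologistic parameters
#'
#' Updates `beta0[d]` and `eta[d]` for every drug against the autologistic
#' prior of the current indicators plus their normal priors; symmetric
#' Gaussian proposals.
#'
#' @inheritParams update_indicators
#' @param scales List with elements `beta0`, `eta` (proposal SDs, scalar or
#'   per drug).
#' @return Updated state; acceptance indicators in
#'   `attr(, "accept")` (matrix drug x parameter).
#' @export
update_autologistic_params <- function(state, region_idx,
                                       scales = list(beta0 = 0.3, eta = 0.3)) {
  D <- length(state$hyper$drugs)
  sb <- rep_len(scales$beta0, D); se <- rep_len(scales$eta, D)
  acc <- matrix(0L, D, 2L, dimnames = list(NULL, c("beta0", "eta")))
  for (d in seq_len(D)) {
    z_d <- matrix(as.integer(state$z[, , d]), nrow = dim(state$z)[1])
    phi_col <- state$hyper$phi[, d]
    b0 <- state$hyper$beta0[d]; et <- state$hyper$eta[d]
    cur <- autologistic_target_d(z_d, b0, et, phi_col, region_idx) +
      stats::dnorm(b0, 0, state$hyper$prior_sd_beta0, log = TRUE)
    prop <- b0 + stats::rnorm(1, 0, sb[d])
    new <- autologistic_target_d(z_d, prop, et, phi_col, region_idx) +
      stats::dnorm(prop, 0, state$hyper$prior_sd_beta0, log = TRUE)
    if (log(stats::runif(1)) < new - cur) {
      state$hyper$beta0[d] <- b0 <- prop
      acc[d, 1L] <- 1L
    }
    cur <- autologistic_target_d(z_d, b0, et, phi_col, region_idx) +
      stats::dnorm(et, 0, state$hyper$prior_sd_eta, log = TRUE)
    prop <- et + stats::rnorm(1, 0, se[d])
    new <- autologistic_target_d(z_d, b0, prop, phi_col, region_idx) +
      stats::dnorm(prop, 0, state$hyper$prior_sd_eta, log = TRUE)
    if (log(stats::runif(1)) < new - cur) {
      state$hyper$eta[d] <- prop
      acc[d, 2L] <- 1L
    }
  }
  attr(state, "accept") <- acc
  state
}

#' Metropolis update of regional effects and conjugate Sigma update
#'
#' Each region's effect vector (one entry per drug) is proposed jointly with
#' a spherical Gaussian step and accepted against the autologistic prior of
#' that region's states plus the MVN(0, Sigma_phi) prior. `Sigma_phi` is
#' then redrawn from its conjugate inverse-Wishart full conditional
#' IW(iw_df + R, iw_scale + sum_r phi_r phi_r').
#'
#' @inheritParams update_indicators
#' @param scale Proposal SD for the effect vectors.
#' @return Updated state; acceptance indicators per region in
#'   `attr(, "accept_phi")`.
#' @export
update_regional_effects <- function(state, region_idx, scale = 0.3) {
  R <- nrow(state$hyper$phi); D <- ncol(state$hyper$phi)
  acc <- integer(R)
  for (r in seq_len(R)) {
    rows <- which(region_idx == r)
    cur_phi <- state$hyper$phi[r, ]
    prop_phi <- cur_phi + stats::rnorm(D, 0, scale)
    cur <- dmvnorm_log(cur_phi, state$hyper$Sigma_phi)
    new <- dmvnorm_log(prop_phi, state$hyper$Sigma_phi)
    for (d in seq_len(D)) {
      z_rd <- matrix(as.integer(state$z[rows, , d]), nrow = length(rows))
      cur <- cur + cpp_autologistic_logpdf(
        z_rd, rep(state$hyper$beta0[d] + cur_phi[d], length(rows)),
        state$hyper$eta[d])
      new <- new + cpp_autologistic_logpdf(
        z_rd, rep(state$hyper$beta0[d] + prop_phi[d], length(rows)),
        state$hyper$eta[d])
    }
    if (log(stats::runif(1)) < new - cur) {
      state$hyper$phi[r, ] <- prop_phi
      acc[r] <- 1L
    }
  }
  ## conjugate inverse-Wishart draw for Sigma_phi
  Psi <- state$hyper$iw_scale + crossprod(state$hyper$phi)
  df <- state$hyper$iw_df + R
  W <- stats::rWishart(1L, df, solve(Psi))[, , 1L]
  Sigma <- solve(W)
  Sigma <- (Sigma + t(Sigma)) / 2
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("Sigma_phi update produced a non-positive-definite matrix")
  }
  state$hyper$Sigma_phi <- Sigma
  attr(state, "accept_phi") <- acc
  state
}

init_state <- function(data, hyper) {
  S <- length(data$states); Tn <- length(data$years)
  D <- length(data$drugs)
  E <- exposures(data)
  z <- array(0L, dim = c(S, Tn - 1L, D),
             dimnames = list(data$states, data$years[-1], data$drugs))
  rate <- array(NA_real_, dim = c(S, Tn, D),
                dimnames = list(data$states, data$years, data$drugs))
  for (d in seq_len(D)) {
    emp <- rowSums(matrix(data$deaths[, , d], nrow = S)) / rowSums(E)
    rate[, , d] <- pmax(emp, 0.5)  # empirical series rate with a 0.5/100k floor
  }
  list(z = z, rate = rate, hyper = hyper)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Cycles collapsed indicator sweeps, conjugate rate redraws, random-walk
#' Metropolis on the autologistic parameters, and regional-effect updates
#' with a conjugate inverse-Wishart step for their covariance. Retains every
#' `thin`-th post-burn-in state with regime rates expanded to a per-year
#' rate array `lambda[s, t, d]`.
#'
#' @param data A `counts_table`.
#' @param regions A `region_map` covering the data's states.
#' @param model A [model_hyperparams()] giving priors and initial
#'   hyperparameter values; drug labels must match the data.
#' @param config An [mcmc_config()].
#' @param init Optional initial state overrides: list with any of `z`
#'   (S x (T-1) x D), `rate`, `hyper` components to replace the defaults
#'   (z = 0 everywhere, empirical rates).
#' @param progress Print progress every `progress` iterations (0 = silent).
#' @return A `posterior_draws` object: arrays `lambda` (S x T x D x M),
#'   `z` (S x (T-1) x D x M), `beta0`, `eta` (D x M), `phi` (R x D x M),
#'   `Sigma_phi` (D x D x M), plus dimension metadata, the configuration,
#'   and per-block acceptance rates.
#' @export
run_mcmc <- function(data, regions, model = NULL, config = mcmc_config(),
                     init = NULL, progress = 0L) {
  validate_counts_table(data)
  dr <- dense_regions(regions, data$states)
  if (is.null(model)) {
    model <- model_hyperparams(drugs = data$drugs, n_regions = dr$R)
  }
  if (!identical(model$drugs, data$drugs)) {
    stop("model drug labels do not match the data")
  }
  if (nrow(model$phi) != dr$R) {
    stop("model has ", nrow(model$phi), " regions; data spans ", dr$R)
  }
  set.seed(config$seed)
  state <- init_state(data, model)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("z", "rate", "hyper"))) {
      state[[nm]] <- init[[nm]]
    }
  }
  lp0 <- joint_log_posterior(state, data, dr$idx)
  if (!is.finite(lp0)) {
    stop("non-finite log posterior at initialization (lp = ", lp0, ")")
  }

  S <- length(data$states); Tn <- length(data$years)
  D <- length(data$drugs); M <- n_retained(config)
  if (M < 1L) stop("configuration retains no draws")
  draws <- list(
    lambda = array(NA_real_, c(S, Tn, D, M)),
    z = array(NA_integer_, c(S, Tn - 1L, D, M)),
    beta0 = matrix(NA_real_, D, M), eta = matrix(NA_real_, D, M),
    phi = array(NA_real_, c(dr$R, D, M)),
    Sigma_phi = array(NA_real_, c(D, D, M)))

  scales <- list(beta0 = rep_len(config$scale_beta0, D),
                 eta = rep_len(config$scale_eta, D),
                 phi = config$scale_phi)
  acc_tot <- list(beta0 = numeric(D), eta = numeric(D), phi = 0)
  acc_batch <- list(beta0 = numeric(D), eta = numeric(D), phi = 0)
  n_post <- 0L
  batch <- 100L

  do_ind <- "indicators" %in% config$blocks
  do_rate <- "rates" %in% config$blocks
  do_auto <- "autologistic" %in% config$blocks
  do_reg <- "regional" %in% config$blocks

  m <- 0L
  for (i in seq_len(config$n_iter)) {
    if (do_ind) {
      state <- update_indicators(state, data, dr$idx)
    } else if (do_rate) {
      state <- update_rates(state, data)
    }
    if (do_auto) {
      state <- update_autologistic_params(
        state, dr$idx, scales = list(beta0 = scales$beta0, eta = scales$eta))
      a <- attr(state, "accept")
      acc_batch$beta0 <- acc_batch$beta0 + a[, 1L]
      acc_batch$eta <- acc_batch$eta + a[, 2L]
      if (i > config$n_burn) {
        acc_tot$beta0 <- acc_tot$beta0 + a[, 1L]
        acc_tot$eta <- acc_tot$eta + a[, 2L]
      }
    }
    if (do_reg) {
      state <- update_regional_effects(state, dr$idx, scale = scales$phi)
      aphi <- mean(attr(state, "accept_phi"))
      acc_batch$phi <- acc_batch$phi + aphi
      if (i > config$n_burn) acc_tot$phi <- acc_tot$phi + aphi
    }
    if (i > config$n_burn) n_post <- n_post + 1L

    ## burn-in adaptation toward 30% acceptance, frozen afterwards
    if (config$adapt && i <= config$n_burn && i %% batch == 0L) {
      step <- min(0.5, 5 / sqrt(i))
      scales$beta0 <- scales$beta0 * exp(step * (acc_batch$beta0 / batch - 0.3))
      scales$eta <- scales$eta * exp(step * (acc_batch$eta / batch - 0.3))
      scales$phi <- scales$phi * exp(step * (acc_batch$phi / batch - 0.3))
      acc_batch <- list(beta0 = numeric(D), eta = numeric(D), phi = 0)
    }

    if (i > config$n_burn && (i - config$n_burn) %% config$thin == 0L) {
      m <- m + 1L
      draws$lambda[, , , m] <- state$rate
      draws$z[, , , m] <- state$z
      draws$beta0[, m] <- state$hyper$beta0
      draws$eta[, m] <- state$hyper$eta
      draws$phi[, , m] <- state$hyper$phi
      draws$Sigma_phi[, , m] <- state$hyper$Sigma_phi
    }
    if (progress > 0L && i %% progress == 0L) {
      message("iteration ", i, "/", config$n_iter)
    }
  }

  acc_rates <- list(
    beta0 = if (do_auto && n_post > 0L) acc_tot$beta0 / n_post else NULL,
    eta = if (do_auto && n_post > 0L) acc_tot$eta / n_post else NULL,
    phi = if (do_reg && n_post > 0L) acc_tot$phi / n_post else NULL)

  structure(list(states = data$states, years = data$years,
                 drugs = data$drugs, region_labels = dr$labels,
                 region_idx = dr$idx,
                 lambda = draws$lambda, z = draws$z, beta0 = draws$beta0,
                 eta = draws$eta, phi = draws$phi,
                 Sigma_phi = draws$Sigma_phi,
                 config = config, acceptance = acc_rates),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", dim(x$lambda)[4], " retained draws; ",
      length(x$states), " states x ", length(x$years), " years x ",
      length(x$drugs), " drugs\n", sep = "")
  invisible(x)
}
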