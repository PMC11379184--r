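#' Posterior median rates and equal-tailed credible intervals
#'
#' @param draws A `posterior_draws`.
#' @param level Credible level (default 0.90, i.e. 5% and 95% quantiles).
#' @return Long `data.frame`: state, year, drug, median, lower, upper
#'   (all rates per 100,000 residents).
#' @export
rate_summaries <- function(draws, level = 0.90) {
  M <- dim(draws$lambda)[4]
  if (M < 10L) stop("need at least 10 retained draws")
  alpha <- (1 - level) / 2
  qs <- apply(draws$lambda, c(1, 2, 3), stats::quantile,
              probs = c(alpha, 0.5, 1 - alpha), names = FALSE, type = 7)
  grid <- expand.grid(state = draws$states, year = draws$years,
                      drug = draws$drugs, stringsAsFactors = FALSE)
  grid$median <- as.vector(qs[2, , , ])
  grid$lower <- as.vector(qs[1, , , ])
  grid$upper <- as.vector(qs[3, , , ])
  grid
}

#' Year-over-year relative risk with posterior direction flags
#'
#' For each draw, `RR[s, t, d] = lambda[s, t, d] / lambda[s, t-1, d]` for
#' every year after the first. A cell is flagged `increase` when the
#' posterior probability that the rate rose from the previous year reaches
#' `threshold` (default 0.90), `decrease` symmetrically, else `none`. Years
#' in the same regime within a draw contribute RR exactly 1, counted as
#' neither an increase nor a decrease.
#'
#' @param draws A `posterior_draws`.
#' @param threshold Posterior probability required to flag a direction.
#' @return Long `data.frame`: state, year, drug, median_log_rr, p_up,
#'   p_down, flag.
#' @export
relative_risk <- function(draws, threshold = 0.90) {
  dm <- dim(draws$lambda)
  S <- dm[1]; Tn <- dm[2]; D <- dm[3]; M <- dm[4]
  if (Tn < 2L) stop("need at least two years")
  stopifnot(all(draws$lambda > 0))
  cur <- draws$lambda[, -1L, , , drop = FALSE]
  prev <- draws$lambda[, -Tn, , , drop = FALSE]
  logrr <- log(cur) - log(prev)
  med <- apply(logrr, c(1, 2, 3), stats::median)
  p_up <- apply(logrr > 0, c(1, 2, 3), mean)
  p_down <- apply(logrr < 0, c(1, 2, 3), mean)
  grid <- expand.grid(state = draws$states, year = draws$years[-1L],
                      drug = draws$drugs, stringsAsFactors = FALSE)
  grid$median_log_rr <- as.vector(med)
  grid$p_up <- as.vector(p_up)
  grid$p_down <- as.vector(p_down)
  grid$flag <- ifelse(grid$p_up >= threshold, "increase",
                      ifelse(grid$p_down >= threshold, "decrease", "none"))
  grid
}

#' Posterior log odds of a regime change, by state and by region
#'
#' Per draw the autologistic linear predictor at each transition year is
#' `psi[s, t, d] = beta0[d] + phi[r(s), d] + eta[d] (z[s, t-1, d] - mu[s, d])`
#' with `mu = plogis(beta0 + phi)`; the first transition year has no lag
#' term. With `lag_term = FALSE` the realized autoregressive term is
#' dropped and the log odds reduce to the independence-model value
#' `beta0 + phi`. Region values average `psi` over the region's states
#' within each draw before summarizing.
#'
#' @param draws A `posterior_draws`.
#' @param lag_term Include the realized centered lag term (default TRUE).
#' @return List of two long data frames: `state` (state, year, drug,
#'   median_log_odds) and `region` (region, year, drug, median_log_odds).
#' @export
changepoint_logodds <- function(draws, lag_term = TRUE) {
  if (is.null(draws$beta0) || is.null(draws$phi)) {
    stop("draws do not carry hyperparameter samples")
  }
  dm <- dim(draws$z)
  S <- dm[1]; Tm1 <- dm[2]; D <- dm[3]; M <- dm[4]
  ridx <- draws$region_idx
  psi <- array(NA_real_, c(S, Tm1, D, M))
  for (d in seq_len(D)) {
    for (m in seq_len(M)) {
      lin <- draws$beta0[d, m] + draws$phi[ridx, d, m]
      pm <- matrix(lin, S, Tm1)
      if (lag_term && Tm1 > 1L) {
        mu <- stats::plogis(lin)
        zm <- matrix(draws$z[, , d, m], S, Tm1)
        pm[, 2:Tm1] <- pm[, 2:Tm1] +
          draws$eta[d, m] * (zm[, 1:(Tm1 - 1L), drop = FALSE] - mu)
      }
      psi[, , d, m] <- pm
    }
  }
  med_state <- apply(psi, c(1, 2, 3), stats::median)
  gs <- expand.grid(state = draws$states, year = draws$years[-1L],
                    drug = draws$drugs, stringsAsFactors = FALSE)
  gs$median_log_odds <- as.vector(med_state)

  R <- length(draws$region_labels)
  psi_reg <- array(NA_real_, c(R, Tm1, D, M))
  for (r in seq_len(R)) {
    rows <- which(ridx == r)
    psi_reg[r, , , ] <- apply(psi[rows, , , , drop = FALSE], c(2, 3, 4), mean)
  }
  med_reg <- apply(psi_reg, c(1, 2, 3), stats::median)
  gr <- expand.grid(region = draws$region_labels, year = draws$years[-1L],
                    drug = draws$drugs, stringsAsFactors = FALSE)
  gr$median_log_odds <- as.vector(med_reg)
  list(state = gs, region = gr)
}

#' Wave-onset year per state for one drug category
#'
#' The onset is the earliest transition year whose posterior probability of
#' an upward regime change -- a changepoint indicator of 1 together with a
#' rate higher than the previous year's -- reaches `prob_threshold`.
#' Returns `NA` for states with no qualifying year.
#'
#' @param draws A `posterior_draws`.
#' @param drug Drug-category label.
#' @param prob_threshold Posterior probability required (default 0.5).
#' @return `data.frame`: state, onset_year (integer or NA), prob (posterior
#'   probability at the onset year).
#' @export
wave_onset <- function(draws, drug, prob_threshold = 0.5) {
  d <- match(drug, draws$drugs)
  if (is.na(d)) stop("unknown drug label: ", drug)
  dm <- dim(draws$z)
  S <- dm[1]; Tm1 <- dm[2]; M <- dm[4]
  up <- (draws$z[, , d, , drop = FALSE] == 1L) &
    (draws$lambda[, -1L, d, , drop = FALSE] >
       draws$lambda[, -(Tm1 + 1L), d, , drop = FALSE])
  p_up <- apply(up, c(1, 2), mean)           # S x Tm1
  onset <- rep(NA_integer_, S)
  prob <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    hit <- which(p_up[s, ] >= prob_threshold)
    if (length(hit) > 0L) {
      onset[s] <- draws$years[-1L][hit[1L]]
      prob[s] <- p_up[s, hit[1L]]
    }
  }
  data.frame(state = draws$states, onset_year = onset, prob = prob,
             stringsAsFactors = FALSE)
}

#' Write the four standard summary CSVs
#'
#' @param draws A `posterior_draws`.
#' @param dir Output directory.
#' @param rr_threshold Direction-flag probability threshold.
#' @param onset_threshold Wave-onset probability threshold.
#' @return Named character vector of the files written, invisibly.
#' @export
write_summaries <- function(draws, dir, rr_threshold = 0.90,
                            onset_threshold = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(rates = file.path(dir, "rates.csv"),
             rr_flags = file.path(dir, "rr_flags.csv"),
             logodds = file.path(dir, "logodds.csv"),
             onsets = file.path(dir, "onsets.csv"))
  utils::write.csv(rate_summaries(draws), files["rates"], row.names = FALSE)
  utils::write.csv(relative_risk(draws, rr_threshold), files["rr_flags"],
                   row.names = FALSE)
  lo <- changepoint_logodds(draws)
  lo$state$region <- NA_integer_
  lo$region$state <- NA_character_
  lo_all <- rbind(
    data.frame(level = "state", state = lo$state$state,
               region = NA_integer_, year = lo$state$year,
               drug = lo$state$drug,
               median_log_odds = lo$state$median_log_odds),
    data.frame(level = "region", state = NA_character_,
               region = lo$region$region, year = lo$region$year,
               drug = lo$region$drug,
               median_log_odds = lo$region$median_log_odds))
  utils::write.csv(lo_all, files["logodds"], row.names = FALSE)
  onsets <- do.call(rbind, lapply(draws$drugs, function(dg) {
    o <- wave_onset(draws, dg, onset_threshold)
    o$drug <- dg
    o
  }))
  utils::write.csv(onsets, files["onsets"], row.names = FALSE)
  invisible(files)
}
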