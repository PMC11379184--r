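#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a lattice of states,
#' contiguous years, and drug categories; per-drug onset windows for the
#' first (upward) regime change; per-drug baseline-rate ranges on the
#' per-100,000 scale; a multiplicative log-normal jump-size distribution;
#' and a log-uniform population range. The default onset windows follow the
#' three recognised waves of the US opioid epidemic: prescription opioids
#' 1999-2005, heroin 2010-2014, synthetic opioids 2014-2021.
#'
#' @param n_states Number of states.
#' @param n_regions Number of regions (states assigned in contiguous blocks).
#' @param years Integer vector of contiguous years.
#' @param drugs Drug-category labels.
#' @param onset_window Named list, per drug, of `c(first, last)` years within
#'   which that drug's first upward change falls. Drugs without an entry may
#'   change at any transition year.
#' @param baseline_range Named list, per drug, of `c(lo, hi)` baseline rates
#'   per 100,000.
#' @param jump_meanlog,jump_sdlog Log-normal parameters of the multiplicative
#'   jump at the onset (median `exp(jump_meanlog)`, default x2.5 upward).
#' @param p_extra Probability, per post-onset transition year, of an
#'   additional regime change (up or down).
#' @param extra_sdlog Log-scale SD of post-onset change multipliers.
#' @param population_range `c(lo, hi)` bounds of the log-uniform state
#'   population draw; populations are held constant over years.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_states = 10L,
                       n_regions = 2L,
                       years = 1999:2021,
                       drugs = DRUG_LEVELS,
                       onset_window = list(prescription = c(1999L, 2005L),
                                           heroin = c(2010L, 2014L),
                                           synthetic = c(2014L, 2021L)),
                       baseline_range = list(prescription = c(2, 8),
                                             heroin = c(0.5, 3),
                                             synthetic = c(0.2, 1),
                                             unspecified = c(0.5, 5)),
                       jump_meanlog = log(2.5),
                       jump_sdlog = 0.2,
                       p_extra = 0.15,
                       extra_sdlog = 0.3,
                       population_range = c(5e5, 2e7)) {
  years <- as.integer(years)
  stopifnot(n_states >= 1L, n_regions >= 1L, n_regions <= n_states,
            length(years) >= 2L, all(diff(years) == 1L),
            p_extra >= 0, p_extra <= 1, all(population_range > 0))
  for (d in names(onset_window)) {
    w <- onset_window[[d]]
    if (w[1] > w[2] || w[1] < years[2] - 1L || w[2] > max(years)) {
      stop("onset window for '", d, "' outside the year range")
    }
  }
  for (d in drugs) {
    if (is.null(baseline_range[[d]])) {
      stop("no baseline rate range for drug '", d, "'")
    }
    if (any(baseline_range[[d]] <= 0)) stop("baseline rates must be positive")
  }
  structure(list(n_states = as.integer(n_states),
                 n_regions = as.integer(n_regions),
                 years = years, drugs = drugs,
                 onset_window = onset_window,
                 baseline_range = baseline_range,
                 jump_meanlog = jump_meanlog, jump_sdlog = jump_sdlog,
                 p_extra = p_extra, extra_sdlog = extra_sdlog,
                 population_range = population_range),
            class = "sim_config")
}

synthetic_state_names <- function(n) {
  if (n <= 26 * 26) {
    i <- seq_len(n) - 1L
    paste0("S", LETTERS[i %/% 26L + 1L], LETTERS[i %% 26L + 1L])
  } else {
    sprintf("S%04d", seq_len(n))
  }
}

#' Simulate ground truth: regimes, rates, and hyperparameters
#'
#' For each state-drug series, draws a baseline rate in the configured range
#' and one onset changepoint uniformly inside the drug's onset window with a
#' multiplicative upward jump (log-normal, truncated above 1 so the onset is
#' always a rise). After the onset, additional changes (up or down) occur
#' independently with probability `p_extra` per year. Regional effects are
#' drawn from a multivariate normal across drugs.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; the truth is a deterministic function of
#'   `(config, seed)`.
#' @return A `synthetic_truth` object: `states`, `years`, `drugs`,
#'   `region_map`, `population` (S x T), `z` (S x (T-1) x D planted
#'   indicators), `rate` (S x T x D true rate per 100k each year),
#'   `onset_year` (S x D), and `hyper` (nominal beta0, eta, phi, Sigma_phi).
#' @export
simulate_truth <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(as.integer(seed))
  S <- cfg$n_states; Tn <- length(cfg$years); D <- length(cfg$drugs)
  states <- synthetic_state_names(S)
  region <- stats::setNames(
    as.integer(ceiling(seq_len(S) * cfg$n_regions / S)),  # contiguous blocks
    states)
  class(region) <- "region_map"
  pop <- matrix(rep(round(exp(stats::runif(
    S, log(cfg$population_range[1]), log(cfg$population_range[2])))), Tn),
    nrow = S, ncol = Tn, dimnames = list(states, cfg$years))

  z <- array(0L, dim = c(S, Tn - 1L, D),
             dimnames = list(states, cfg$years[-1], cfg$drugs))
  rate <- array(NA_real_, dim = c(S, Tn, D),
                dimnames = list(states, cfg$years, cfg$drugs))
  onset <- matrix(NA_integer_, S, D, dimnames = list(states, cfg$drugs))

  for (d in seq_len(D)) {
    drug <- cfg$drugs[d]
    win <- cfg$onset_window[[drug]]
    if (is.null(win)) win <- c(cfg$years[2], max(cfg$years))
    br <- cfg$baseline_range[[drug]]
    for (s in seq_len(S)) {
      theta <- stats::runif(1, br[1], br[2])
      r <- rep(theta, Tn)
      oy <- as.integer(round(stats::runif(1, win[1] - 0.5, win[2] + 0.5)))
      oy <- min(max(oy, win[1]), win[2])
      jump <- exp(stats::rnorm(1, cfg$jump_meanlog, cfg$jump_sdlog))
      # a degenerate jump of exactly 1 plants no change at all; otherwise the
      # onset is forced upward. A window opening at the first year can place
      # the onset there, where no transition indicator exists.
      if (jump != 1 && oy >= cfg$years[2]) {
        onset[s, d] <- oy
        ot <- match(oy, cfg$years)
        jump <- max(jump, 1.1)
        r[ot:Tn] <- r[ot:Tn] * jump
        z[s, ot - 1L, d] <- 1L
        t <- ot + 1L
        while (t <= Tn) {
          if (stats::runif(1) < cfg$p_extra) {
            m <- exp(stats::rnorm(1, 0, cfg$extra_sdlog))
            # a negligible multiplier would not be a real regime change
            if (abs(log(m)) < 0.05) m <- exp(sign(log(m) + 1e-9) * 0.05)
            r[t:Tn] <- r[t:Tn] * m
            z[s, t - 1L, d] <- 1L
          }
          t <- t + 1L
        }
      }
      rate[s, , d] <- r
    }
  }

  R <- cfg$n_regions
  Sigma_phi <- diag(0.5, D)
  phi <- MASS::mvrnorm(R, mu = rep(0, D), Sigma = Sigma_phi)
  phi <- matrix(phi, nrow = R, ncol = D,
                dimnames = list(NULL, cfg$drugs))
  hyper <- list(beta0 = stats::setNames(rep(stats::qlogis(cfg$p_extra), D),
                                        cfg$drugs),
                eta = stats::setNames(rep(0.5, D), cfg$drugs),
                phi = phi, Sigma_phi = Sigma_phi)

  structure(list(states = states, years = cfg$years, drugs = cfg$drugs,
                 region_map = region, population = pop, z = z, rate = rate,
                 onset_year = onset, hyper = hyper, config = cfg),
            class = "synthetic_truth")
}

#' Simulate a counts table from a planted truth
#'
#' Death counts are Poisson with mean `population x rate / 100000`,
#' independent across cells given the truth.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Integer RNG seed.
#' @return A `counts_table` on the truth's lattice.
#' @export
simulate_counts <- function(truth, seed = 1L) {
  set.seed(as.integer(seed))
  S <- length(truth$states); Tn <- length(truth$years)
  D <- length(truth$drugs)
  mu <- truth$rate * as.vector(truth$population) / 1e5
  deaths <- array(stats::rpois(S * Tn * D, lambda = as.vector(mu)),
                  dim = c(S, Tn, D))
  counts_table(truth$states, truth$years, truth$drugs, deaths,
               truth$population)
}

#' Construct line-level records that re-aggregate to a counts table
#'
#' Inverse of [aggregate_records()]: builds death records whose
#' classification and aggregation reproduce the input table exactly,
#' including records carrying several drug flags (counted once in each
#' category) and unspecified records carrying only T50.9/T40.6.
#'
#' @param counts A `counts_table` with the four standard drug categories.
#' @param overlap Fraction (0-1) of the feasible pairwise overlap between
#'   named drug categories realised as multi-drug records. Each overlapping
#'   record consumes one count from both categories.
#' @param p_t406 Probability an unspecified record carries T40.6 rather than
#'   T50.9.
#' @param seed Integer RNG seed (underlying-cause draws, record order).
#' @return `data.frame` of records (columns `state`, `year`, `ucod`,
#'   list-column `mcod`).
#' @export
simulate_records <- function(counts, overlap = 0.2, p_t406 = 0.3, seed = 1L) {
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  if (p_t406 < 0 || p_t406 > 1) stop("p_t406 must lie in [0, 1]")
  need <- c("prescription", "heroin", "synthetic", "unspecified")
  if (!all(need %in% counts$drugs)) {
    stop("counts table must carry the four standard drug categories")
  }
  set.seed(as.integer(seed))
  tcode_for <- list(prescription = c("T402", "T403"), heroin = "T401",
                    synthetic = "T404")
  recs <- list()
  for (s in seq_along(counts$states)) {
    for (t in seq_along(counts$years)) {
      c_d <- stats::setNames(
        counts$deaths[s, t, match(need, counts$drugs)], need)
      pairs <- list(c("prescription", "heroin"),
                    c("heroin", "synthetic"),
                    c("prescription", "synthetic"))
      remaining <- c_d[1:3]
      n_pair <- integer(3)
      for (k in seq_along(pairs)) {
        cap <- min(remaining[pairs[[k]][1]], remaining[pairs[[k]][2]])
        n_pair[k] <- floor(overlap * cap)
        remaining[pairs[[k]][1]] <- remaining[pairs[[k]][1]] - n_pair[k]
        remaining[pairs[[k]][2]] <- remaining[pairs[[k]][2]] - n_pair[k]
      }
      if (any(remaining < 0)) {
        stop("infeasible overlap: requested multi-drug records exceed counts")
      }
      flag_sets <- c(
        rep(pairs, times = n_pair),
        lapply(rep(names(remaining), times = remaining), identity),
        rep(list("unspecified"), c_d["unspecified"]))
      for (fl in flag_sets) {
        if (identical(fl, "unspecified")) {
          mc <- if (stats::runif(1) < p_t406) "T406" else "T509"
        } else {
          mc <- unlist(lapply(fl, function(d) tcode_for[[d]][1]), use.names = FALSE)
        }
        recs[[length(recs) + 1L]] <- list(
          state = counts$states[s], year = counts$years[t],
          ucod = sample(UCOD_INCLUDE, 1L), mcod = mc)
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(state = character(), year = integer(),
                      ucod = character(),
                      mcod = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(state = vapply(recs, `[[`, "", "state"),
                   year = vapply(recs, `[[`, 0L, "year"),
                   ucod = vapply(recs, `[[`, "", "ucod"),
                   stringsAsFactors = FALSE)
  df$mcod <- lapply(recs, `[[`, "mcod")
  df[sample.int(nrow(df)), , drop = FALSE]
}
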