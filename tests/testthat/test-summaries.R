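## A small hand-built draws object lets every summary be checked against
## values computed directly from the raw arrays.
fake_draws <- function(lambda, z = NULL, beta0 = NULL, eta = NULL,
                       phi = NULL, region_idx = NULL) {
  dm <- dim(lambda)
  S <- dm[1]; Tn <- dm[2]; D <- dm[3]; M <- dm[4]
  if (is.null(z)) {
    z <- array(0L, c(S, Tn - 1L, D, M))
    for (m in seq_len(M)) {
      for (d in seq_len(D)) {
        for (s in seq_len(S)) {
          z[s, , d, m] <- as.integer(abs(diff(lambda[s, , d, m])) > 1e-12)
        }
      }
    }
  }
  if (is.null(beta0)) beta0 <- matrix(-2, D, M)
  if (is.null(eta)) eta <- matrix(0, D, M)
  if (is.null(region_idx)) region_idx <- rep(1L, S)
  R <- max(region_idx)
  if (is.null(phi)) phi <- array(0, c(R, D, M))
  structure(list(states = paste0("S", seq_len(S)),
                 years = 2000L + seq_len(Tn) - 1L,
                 drugs = c("prescription", "heroin", "synthetic",
                           "unspecified")[seq_len(D)],
                 region_labels = seq_len(R), region_idx = region_idx,
                 lambda = lambda, z = z, beta0 = beta0, eta = eta,
                 phi = phi, Sigma_phi = array(diag(D), c(D, D, M)),
                 config = mcmc_config(100, 10, 1, 1), acceptance = list()),
            class = "posterior_draws")
}

test_that("rate summaries are exact quantiles of the draws", {
  set.seed(90)
  lam <- array(rexp(2 * 3 * 1 * 51) + 0.1, c(2, 3, 1, 51))
  rs <- rate_summaries(fake_draws(lam))
  for (i in seq_len(nrow(rs))) {
    s <- match(rs$state[i], c("S1", "S2")); t <- rs$year[i] - 1999L
    v <- sort(lam[s, t, 1, ])
    expect_equal(rs$median[i], median(v))
    expect_equal(rs$lower[i], unname(quantile(v, 0.05)))
    expect_equal(rs$upper[i], unname(quantile(v, 0.95)))
    expect_true(rs$lower[i] <= rs$median[i] && rs$median[i] <= rs$upper[i])
  }
  # odd draw count: the median is the middle order statistic
  lam3 <- array(c(1, 2, 3), c(1, 1, 1, 3))
  lam3 <- array(rep(c(1, 2, 3), each = 1), c(1, 1, 1, 3))
  expect_error(rate_summaries(fake_draws(lam3)), "at least 10")
  lam11 <- array(rep(1:11, each = 2), c(1, 2, 1, 11))
  expect_equal(rate_summaries(fake_draws(lam11))$median, c(6, 6))
  # constant draws give a zero-width interval
  lamc <- array(2.5, c(1, 2, 1, 20))
  rsc <- rate_summaries(fake_draws(lamc))
  expect_true(all(rsc$lower == 2.5 & rsc$upper == 2.5))
})

test_that("relative-risk flags follow the posterior-probability rule", {
  # within-regime years: RR identically 1, no flag
  lam <- array(3, c(1, 3, 1, 20))
  rr <- relative_risk(fake_draws(lam))
  expect_true(all(rr$median_log_rr == 0))
  expect_true(all(rr$flag == "none"))

  # all draws rise year 2: certain increase
  lam2 <- array(3, c(1, 3, 1, 20)); lam2[1, 2:3, 1, ] <- 6
  rr2 <- relative_risk(fake_draws(lam2))
  expect_equal(rr2$flag, c("increase", "none"))
  expect_equal(rr2$p_up, c(1, 0))

  # p_up = 0.85 at threshold 0.9: no flag; at 0.8: flagged
  lam3 <- array(3, c(1, 2, 1, 100)); lam3[1, 2, 1, 1:85] <- 6
  rr3 <- relative_risk(fake_draws(lam3), threshold = 0.9)
  expect_equal(rr3$p_up, 0.85)
  expect_equal(rr3$flag, "none")
  expect_equal(relative_risk(fake_draws(lam3), threshold = 0.8)$flag,
               "increase")
})

test_that("flags are monotone in the threshold", {
  set.seed(91)
  lam <- array(rexp(3 * 4 * 2 * 40) + 0.05, c(3, 4, 2, 40))
  fd <- fake_draws(lam)
  for (th in c(0.5, 0.7, 0.9)) {
    lo <- relative_risk(fd, threshold = th)
    hi <- relative_risk(fd, threshold = th + 0.09)
    # raising the threshold never creates a flag that was absent
    expect_true(all(lo$flag[hi$flag == "increase"] == "increase"))
    expect_true(all(lo$flag[hi$flag == "decrease"] == "decrease"))
  }
})

test_that("changepoint log odds recompute from the raw draws", {
  S <- 4L; Tn <- 5L; D <- 1L; M <- 30L
  set.seed(92)
  lam <- array(rexp(S * Tn * D * M) + 0.1, c(S, Tn, D, M))
  z <- array(rbinom(S * (Tn - 1) * D * M, 1, 0.3), c(S, Tn - 1L, D, M))
  beta0 <- matrix(rnorm(M, -2, 0.3), D, M)
  eta <- matrix(rnorm(M, 1, 0.2), D, M)
  region_idx <- c(1L, 1L, 2L, 2L)
  phi <- array(rnorm(2 * D * M, 0, 0.5), c(2, D, M))
  fd <- fake_draws(lam, z = z, beta0 = beta0, eta = eta, phi = phi,
                   region_idx = region_idx)
  lo <- changepoint_logodds(fd)

  # direct recomputation for one state and year
  s <- 3L; t <- 3L   # third transition year
  psi <- sapply(seq_len(M), function(m) {
    lin <- beta0[1, m] + phi[region_idx[s], 1, m]
    lin + eta[1, m] * (z[s, t - 1L, 1, m] - plogis(lin))
  })
  got <- lo$state$median_log_odds[lo$state$state == "S3" &
                                    lo$state$year == fd$years[t + 1L]]
  expect_equal(got, median(psi), tolerance = 1e-12)

  # eta = 0 collapses psi to beta0 + phi, constant over years
  fd0 <- fake_draws(lam, z = z, beta0 = beta0,
                    eta = matrix(0, D, M), phi = phi,
                    region_idx = region_idx)
  lo0 <- changepoint_logodds(fd0)
  for (s in 1:S) {
    vals <- lo0$state$median_log_odds[lo0$state$state == paste0("S", s)]
    expect_true(all(abs(vals - vals[1]) < 1e-12))
  }

  # a single-state region's average equals the state value
  one <- changepoint_logodds(fake_draws(lam[1, , , , drop = FALSE],
                                        z = z[1, , , , drop = FALSE],
                                        beta0 = beta0, eta = eta,
                                        phi = phi[1, , , drop = FALSE],
                                        region_idx = 1L))
  expect_equal(one$region$median_log_odds, one$state$median_log_odds)
})

test_that("wave onset finds the earliest certain upward change", {
  # every draw: only upward change into year 3 (2002)
  lam <- array(2, c(1, 4, 1, 25)); lam[1, 3:4, 1, ] <- 5
  fd <- fake_draws(lam)
  on <- wave_onset(fd, "prescription")
  expect_equal(on$onset_year, 2002L)
  expect_equal(on$prob, 1)

  # flat series: no onset
  on0 <- wave_onset(fake_draws(array(2, c(1, 4, 1, 25))), "prescription")
  expect_true(is.na(on0$onset_year))

  # a certain *downward* change is not an onset
  lam_dn <- array(5, c(1, 4, 1, 25)); lam_dn[1, 3:4, 1, ] <- 2
  expect_true(is.na(wave_onset(fake_draws(lam_dn), "prescription")$onset_year))

  expect_error(wave_onset(fd, "ayahuasca"), "unknown drug")
})

test_that("summary CSVs are written and parse", {
  set.seed(93)
  lam <- array(rexp(2 * 3 * 2 * 20) + 0.1, c(2, 3, 2, 20))
  fd <- fake_draws(lam)
  d <- withr::local_tempdir()
  files <- write_summaries(fd, d)
  expect_true(all(file.exists(files)))
  rates <- read.csv(files["rates"])
  expect_equal(nrow(rates), 2 * 3 * 2)
  onsets <- read.csv(files["onsets"])
  expect_setequal(unique(onsets$drug), fd$drugs)
})
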