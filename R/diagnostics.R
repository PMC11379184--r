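## Quantitative convergence checks: split R-hat and an autocorrelation-based
## effective sample size (Geyer initial positive sequence).

ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(NA_real_)  # degenerate (constant) chain
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                   demean = TRUE)$acf[-1L]
  ## sum consecutive pairs while they stay positive (initial positive sequence)
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

split_rhat <- function(chains) {
  ## chains: list of numeric vectors, equal length
  half <- lapply(chains, function(x) {
    n2 <- length(x) %/% 2L
    list(x[seq_len(n2)], x[seq_len(n2) + n2])
  })
  xs <- unlist(half, recursive = FALSE)
  m <- length(xs); n <- length(xs[[1L]])
  means <- vapply(xs, mean, 0)
  vars <- vapply(xs, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for posterior draws
#'
#' Computes per-parameter effective sample size (autocorrelation-based) and,
#' when two or more chains are supplied, split R-hat. Scalar hyperparameters
#' (`beta0`, `eta`, per-region `phi`) and a subset of rate cells are
#' summarized. Constant chains are reported with `ess = NA` and flagged
#' `degenerate` rather than erroring.
#'
#' @param draws A `posterior_draws`, or a list of them (parallel chains with
#'   identical dimensions).
#' @param max_cells Maximum number of lambda cells to include.
#' @return `data.frame`: parameter, ess (summed over chains), rhat (NA for a
#'   single chain), degenerate flag.
#' @export
mcmc_diagnostics <- function(draws, max_cells = 25L) {
  chains <- if (inherits(draws, "posterior_draws")) list(draws) else draws
  stopifnot(length(chains) >= 1L)
  M <- dim(chains[[1L]]$lambda)[4]
  if (M < 10L) stop("too few draws for diagnostics (need >= 10)")

  extract <- function(ch) {
    out <- list()
    D <- length(ch$drugs)
    for (d in seq_len(D)) {
      out[[paste0("beta0[", ch$drugs[d], "]")]] <- ch$beta0[d, ]
      out[[paste0("eta[", ch$drugs[d], "]")]] <- ch$eta[d, ]
      for (r in seq_len(dim(ch$phi)[1])) {
        out[[paste0("phi[", r, ",", ch$drugs[d], "]")]] <- ch$phi[r, d, ]
      }
    }
    dm <- dim(ch$lambda)
    cells <- expand.grid(s = seq_len(dm[1]), t = seq_len(dm[2]),
                         d = seq_len(dm[3]))
    keep <- cells[seq(1L, nrow(cells),
                      length.out = min(max_cells, nrow(cells))), ]
    for (i in seq_len(nrow(keep))) {
      nm <- sprintf("lambda[%s,%d,%s]", ch$states[keep$s[i]],
                    ch$years[keep$t[i]], ch$drugs[keep$d[i]])
      out[[nm]] <- ch$lambda[keep$s[i], keep$t[i], keep$d[i], ]
    }
    out
  }
  per_chain <- lapply(chains, extract)
  params <- names(per_chain[[1L]])
  res <- lapply(params, function(p) {
    series <- lapply(per_chain, `[[`, p)
    ess <- sum(vapply(series, ess_one, 0), na.rm = FALSE)
    degenerate <- all(vapply(series, function(x) stats::var(x) == 0, TRUE))
    rhat <- if (length(series) >= 2L && !degenerate) split_rhat(series)
            else NA_real_
    data.frame(parameter = p,
               ess = if (degenerate) NA_real_ else ess,
               rhat = rhat, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Save trace plots for selected parameters
#'
#' @param draws A `posterior_draws` or list of chains.
#' @param parameters Character vector of hyperparameter names among
#'   `"beta0"`, `"eta"`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
trace_plot <- function(draws, parameters = c("beta0", "eta"), path) {
  chains <- if (inherits(draws, "posterior_draws")) list(draws) else draws
  D <- length(chains[[1L]]$drugs)
  df <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    do.call(rbind, lapply(parameters, function(p) {
      do.call(rbind, lapply(seq_len(D), function(d) {
        v <- ch[[p]][d, ]
        data.frame(chain = factor(ci), iter = seq_along(v), value = v,
                   parameter = paste0(p, "[", ch$drugs[d], "]"))
      }))
    }))
  }))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = iter, y = value,
                                        colour = chain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL)
  ggplot2::ggsave(path, g, width = 8, height = 5, dpi = 120)
  invisible(path)
}
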