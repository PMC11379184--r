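## Self-describing on-disk container for posterior draws: a directory with
## a JSON metadata block and one CSV per array. Doubles are serialized with
## "%.17g", which round-trips IEEE-754 binary64 exactly through strtod.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_array_csv <- function(x, path) {
  df <- data.frame(value = if (is.integer(x)) as.character(as.vector(x))
                   else fmt_num(as.vector(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_array_csv <- function(path, dim, integer = FALSE) {
  df <- utils::read.csv(path, colClasses = "character")
  v <- if (integer) as.integer(df$value) else as.numeric(df$value)
  if (length(v) != prod(dim)) {
    stop("corrupt draws container: ", basename(path), " has ", length(v),
         " values, expected ", prod(dim))
  }
  array(v, dim = dim)
}

#' Write posterior draws to a lossless text container
#'
#' Serializes a `posterior_draws` object to a directory holding a JSON
#' metadata block (dimensions, labels, sampler configuration, acceptance
#' rates) and one CSV per sampled array, with doubles written at full
#' precision so the round trip through [read_draws()] is exact.
#'
#' @param draws A `posterior_draws`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "opioidwaves-draws-1",
    states = draws$states, years = draws$years, drugs = draws$drugs,
    region_labels = draws$region_labels, region_idx = draws$region_idx,
    n_draws = dim(draws$lambda)[4],
    config = unclass(draws$config),
    acceptance = draws$acceptance)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in c("lambda", "z", "beta0", "eta", "phi", "Sigma_phi")) {
    write_array_csv(draws[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path Directory containing `meta.json` and the array CSVs.
#' @return A `posterior_draws` object equal to the one written.
#' @export
read_draws <- function(path) {
  mpath <- file.path(path, "meta.json")
  if (!file.exists(mpath)) stop("not a draws container (no meta.json): ", path)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(meta$format, "opioidwaves-draws-1")) {
    stop("unrecognized draws container format")
  }
  S <- length(meta$states); Tn <- length(meta$years)
  D <- length(meta$drugs); R <- length(meta$region_labels)
  M <- meta$n_draws
  arr <- function(nm, dim, integer = FALSE) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("corrupt draws container: missing ", nm, ".csv")
    read_array_csv(f, dim, integer)
  }
  cfg <- meta$config
  config <- mcmc_config(n_iter = cfg$n_iter, n_burn = cfg$n_burn,
                        thin = cfg$thin, seed = cfg$seed,
                        scale_beta0 = cfg$scale_beta0,
                        scale_eta = cfg$scale_eta, scale_phi = cfg$scale_phi,
                        adapt = cfg$adapt, blocks = cfg$blocks)
  acc <- meta$acceptance
  structure(list(states = meta$states, years = as.integer(meta$years),
                 drugs = meta$drugs,
                 region_labels = as.integer(meta$region_labels),
                 region_idx = as.integer(meta$region_idx),
                 lambda = arr("lambda", c(S, Tn, D, M)),
                 z = arr("z", c(S, Tn - 1L, D, M), integer = TRUE),
                 beta0 = arr("beta0", c(D, M)), eta = arr("eta", c(D, M)),
                 phi = arr("phi", c(R, D, M)),
                 Sigma_phi = arr("Sigma_phi", c(D, D, M)),
                 config = config, acceptance = acc),
            class = "posterior_draws")
}
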