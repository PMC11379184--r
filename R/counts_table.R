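#' Construct a state x year x drug counts table
#'
#' The central data container: a complete lattice of overdose death counts
#' `deaths[s, t, d]` with per state-year populations `P[s, t]`. Years must be
#' contiguous; every cell of the lattice must be present.
#'
#' @param states Character vector of state postal codes (defines row order).
#' @param years Integer vector of contiguous calendar years.
#' @param drugs Character vector of drug-category labels.
#' @param deaths Integer array `length(states) x length(years) x length(drugs)`.
#' @param population Integer matrix `length(states) x length(years)`, all > 0.
#' @return A `counts_table` object.
#' @export
counts_table <- function(states, years, drugs, deaths, population) {
  states <- as.character(states)
  years <- as.integer(years)
  drugs <- as.character(drugs)
  deaths <- array(as.numeric(deaths),
                  dim = c(length(states), length(years), length(drugs)),
                  dimnames = list(states, years, drugs))
  population <- matrix(as.numeric(population),
                       nrow = length(states), ncol = length(years),
                       dimnames = list(states, years))
  x <- structure(list(states = states, years = years, drugs = drugs,
                      deaths = deaths, population = population),
                 class = "counts_table")
  validate_counts_table(x)
  x
}

validate_counts_table <- function(x) {
  if (length(x$states) == 0L) stop("empty lattice: no states")
  if (length(x$years) == 0L) stop("empty lattice: no years")
  if (length(x$drugs) == 0L) stop("empty lattice: no drug categories")
  if (anyDuplicated(x$states)) stop("duplicate states")
  if (length(x$years) > 1L && !all(diff(x$years) == 1L)) {
    stop("years must be contiguous")
  }
  if (anyNA(x$deaths)) stop("missing death counts in lattice")
  if (any(x$deaths < 0)) stop("negative death counts")
  if (any(x$deaths != round(x$deaths))) stop("non-integer death counts")
  if (anyNA(x$population) || any(x$population <= 0)) {
    stop("populations must be positive for every state-year")
  }
  over <- x$deaths > as.vector(x$population)  # recycles over drugs
  if (any(over)) stop("death count exceeds population")
  invisible(x)
}

#' @export
print.counts_table <- function(x, ...) {
  cat("<counts_table> ", length(x$states), " states x ",
      length(x$years), " years (", min(x$years), "-", max(x$years), ") x ",
      length(x$drugs), " drug categories; total deaths ",
      format(sum(x$deaths), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
`==.counts_table` <- function(e1, e2) {
  identical(e1$states, e2$states) && identical(e1$years, e2$years) &&
    identical(e1$drugs, e2$drugs) &&
    isTRUE(all(e1$deaths == e2$deaths)) &&
    isTRUE(all(e1$population == e2$population))
}

#' Read a counts table from long-format CSV
#'
#' Expects columns `state, year, drug, deaths, population` (one row per
#' state-year-drug cell). The lattice must be complete: every combination of
#' the states, years and drugs present must appear exactly once, and the
#' population must be constant across drug rows within a state-year.
#'
#' @param path CSV file path.
#' @param drugs Expected drug labels; rows with other labels are an error.
#' @return A `counts_table`.
#' @export
read_counts <- function(path, drugs = DRUG_LEVELS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "year", "drug", "deaths", "population")
  if (!all(need %in% names(df))) {
    stop("counts CSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$drug), drugs)
  if (length(bad) > 0L) {
    stop("unknown drug label(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$deaths < 0)) stop("negative death counts in ", path)
  states <- unique(df$state)  # first-appearance order preserved
  years <- sort(unique(as.integer(df$year)))
  dr <- drugs[drugs %in% unique(df$drug)]
  key <- paste(df$state, df$year, df$drug, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate state-year-drug rows in ", path)
  full <- expand.grid(state = states, year = years, drug = dr,
                      stringsAsFactors = FALSE)
  fkey <- paste(full$state, full$year, full$drug, sep = "\r")
  idx <- match(fkey, key)
  if (anyNA(idx)) {
    miss <- full[is.na(idx), , drop = FALSE][1L, ]
    stop(sprintf("incomplete lattice: missing cell (%s, %d, %s)",
                 miss$state, miss$year, miss$drug))
  }
  deaths <- array(df$deaths[idx],
                  dim = c(length(states), length(years), length(dr)))
  pop <- matrix(df$population[idx[seq_len(length(states) * length(years))]],
                nrow = length(states), ncol = length(years))
  # population must not vary across drug rows of the same state-year
  pop_all <- array(df$population[idx],
                   dim = c(length(states), length(years), length(dr)))
  if (any(pop_all != as.vector(pop))) {
    stop("population differs across drug rows within a state-year")
  }
  counts_table(states, years, dr, deaths, pop)
}

#' Write a counts table to long-format CSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, p))` reproduces
#' `x` exactly.
#'
#' @param table A `counts_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  validate_counts_table(table)
  grid <- expand.grid(state = table$states, year = table$years,
                      drug = table$drugs, stringsAsFactors = FALSE)
  grid$deaths <- as.vector(table$deaths)
  grid$population <- rep(as.vector(table$population), times = length(table$drugs))
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a counts table to a long data frame
#'
#' @param x A `counts_table`.
#' @return `data.frame` with columns state, year, drug, deaths, population.
#' @export
as.data.frame.counts_table <- function(x, ...) {
  grid <- expand.grid(state = x$states, year = x$years, drug = x$drugs,
                      stringsAsFactors = FALSE)
  grid$deaths <- as.vector(x$deaths)
  grid$population <- rep(as.vector(x$population), times = length(x$drugs))
  grid
}

#' Exposures on the per-100,000 scale
#'
#' @param x A `counts_table`.
#' @return Matrix `E[s, t] = population / 1e5` so that rates are per 100,000.
#' @export
exposures <- function(x) x$population / 1e5
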