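## ICD-10 classification of overdose deaths into drug-involvement categories.
##
## Inclusion: underlying cause in X40-X44 (accidental poisoning), X60-X64
## (intentional self-poisoning), X85 (assault by drugs), or Y10-Y14
## (undetermined intent). Categories from multiple-cause T-codes:
##   prescription  T40.2 (other opioids), T40.3 (methadone)
##   heroin        T40.1
##   synthetic     T40.4
##   unspecified   T50.9, or T40.6 without any of T40.1-T40.4 -- and only
##                 when none of the three named categories applies.
## A death involving several named drugs counts in each category present;
## the unspecified category is exclusive of the other three.

UCOD_INCLUDE <- c(paste0("X4", 0:4), paste0("X6", 0:4), "X85",
                  paste0("Y1", 0:4))
TCODE_STEMS <- list(prescription = c("T402", "T403"),
                    heroin = "T401",
                    synthetic = "T404",
                    unspecified = c("T509", "T406"))

#' Canonicalize ICD-10 code strings
#'
#' Uppercases and strips dots, so `"T40.2"` and `"t402"` both become
#' `"T402"`. Mortality files differ in punctuation; all matching in this
#' package is on the canonical form.
#'
#' @param codes Character vector of ICD-10 codes.
#' @return Character vector of canonical codes.
#' @export
canonicalize_icd <- function(codes) {
  out <- toupper(gsub(".", "", codes, fixed = TRUE))
  bad <- !grepl("^[A-Z][0-9]{2,5}$", out) & nzchar(out)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ", paste(unique(codes[bad]), collapse = ", "))
  }
  out
}

#' Overdose inclusion test on the underlying cause of death
#'
#' @param underlying_cause Character vector of canonical ICD-10 codes.
#' @return Logical: `TRUE` iff the 3-character stem lies in X40-X44, X60-X64,
#'   X85, or Y10-Y14.
#' @export
is_overdose <- function(underlying_cause) {
  codes <- canonicalize_icd(underlying_cause)
  substr(codes, 1L, 3L) %in% UCOD_INCLUDE
}

tcode_match <- function(tcodes, stems) {
  # prefix match on 4-character stems: "T4021" matches stem "T402"
  any(substr(tcodes, 1L, 4L) %in% stems)
}

#' Classify one death record into drug-involvement categories
#'
#' @param underlying_cause Single ICD-10 code string.
#' @param tcodes Character vector of multiple-cause ICD-10 codes
#'   (T-codes; other codes are ignored).
#' @return List with `included` (logical) and `flags` (character subset of
#'   `prescription, heroin, synthetic, unspecified`). Excluded records carry
#'   empty flags. A record may carry several of the three named drug flags;
#'   `unspecified` is set only when none of the three is.
#' @examples
#' classify_record("X44", c("T401", "T402"))$flags  # heroin + prescription
#' @export
classify_record <- function(underlying_cause, tcodes = character()) {
  included <- is_overdose(underlying_cause)
  stopifnot(length(included) == 1L)
  if (!included) {
    return(list(included = FALSE, flags = character()))
  }
  tc <- canonicalize_icd(tcodes)
  flags <- character()
  for (d in c("prescription", "heroin", "synthetic")) {
    if (tcode_match(tc, TCODE_STEMS[[d]])) flags <- c(flags, d)
  }
  if (length(flags) == 0L && tcode_match(tc, TCODE_STEMS$unspecified)) {
    flags <- "unspecified"
  }
  list(included = TRUE, flags = flags)
}

#' Read line-level death records from CSV
#'
#' Columns `state, year, ucod, mcod`; `mcod` is a semicolon-delimited list of
#' multiple-cause codes.
#'
#' @param path CSV file path.
#' @return `data.frame` with columns state, year, ucod and list-column mcod.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mcod = "character"))
  need <- c("state", "year", "ucod", "mcod")
  if (!all(need %in% names(df))) {
    stop("records CSV must have columns ", paste(need, collapse = ", "))
  }
  df$year <- as.integer(df$year)
  df$mcod <- lapply(strsplit(df$mcod, ";", fixed = TRUE),
                    function(x) canonicalize_icd(x[nzchar(x)]))
  df
}

#' Write line-level death records to CSV
#'
#' @param records `data.frame` as from [read_records()] or
#'   [simulate_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- data.frame(state = records$state, year = records$year,
                    ucod = records$ucod,
                    mcod = vapply(records$mcod, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate death records to the state-year-drug lattice
#'
#' Counts each included record once in every drug category its codes flag
#' (so category totals can exceed the number of distinct deaths). Excluded
#' records are reported in an audit attribute with a reason code.
#'
#' @param records `data.frame` with columns `state`, `year`, `ucod`, and
#'   list-column `mcod` (canonical codes).
#' @param populations `data.frame` with columns `state`, `year`,
#'   `population`, covering every state-year in `records`; defines the
#'   output lattice.
#' @param drugs Drug-category labels of the output table.
#' @return A `counts_table`; attribute `"audit"` is a `data.frame` of
#'   excluded records with a `reason` column.
#' @export
aggregate_records <- function(records, populations, drugs = DRUG_LEVELS) {
  states <- unique(populations$state)
  years <- sort(unique(as.integer(populations$year)))
  pkey <- paste(populations$state, populations$year)
  if (nrow(records) > 0L) {
    rkey <- paste(records$state, records$year)
    out <- !(rkey %in% pkey)
    if (any(out)) {
      stop("records outside population coverage: ",
           paste(unique(rkey[out]), collapse = "; "))
    }
  }
  pop <- matrix(NA_real_, length(states), length(years),
                dimnames = list(states, years))
  pop[cbind(match(populations$state, states),
            match(as.integer(populations$year), years))] <- populations$population
  if (anyNA(pop)) stop("populations do not cover the full state-year lattice")

  deaths <- array(0, dim = c(length(states), length(years), length(drugs)),
                  dimnames = list(states, years, drugs))
  audit <- list()
  for (i in seq_len(nrow(records))) {
    cls <- classify_record(records$ucod[i], records$mcod[[i]])
    if (!cls$included) {
      audit[[length(audit) + 1L]] <- data.frame(
        state = records$state[i], year = records$year[i],
        ucod = records$ucod[i], reason = "underlying_cause_not_overdose",
        stringsAsFactors = FALSE)
      next
    }
    s <- match(records$state[i], states)
    t <- match(as.integer(records$year[i]), years)
    for (d in cls$flags) deaths[s, t, match(d, drugs)] <-
        deaths[s, t, match(d, drugs)] + 1
  }
  tab <- counts_table(states, years, drugs, deaths, pop)
  attr(tab, "audit") <- if (length(audit)) do.call(rbind, audit) else
    data.frame(state = character(), year = integer(), ucod = character(),
               reason = character(), stringsAsFactors = FALSE)
  tab
}
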