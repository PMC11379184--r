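#' CMS region map for the continental United States
#'
#' Returns the mapping from state postal codes to the ten administrative
#' regions of the Centers for Medicare and Medicaid Services (CMS), covering
#' the 48 contiguous states plus the District of Columbia (49 jurisdictions).
#' Alaska and Hawaii are excluded because the analysis scope is the
#' continental US. The map is shipped as a plain CSV under `extdata` so users
#' can supply their own via [read_region_map()].
#'
#' @return A `region_map` object: named integer vector of region ids (1-10),
#'   names are state postal codes.
#' @examples
#' rm <- default_region_map()
#' rm[["WV"]]   # 3
#' @export
default_region_map <- function() {
  path <- system.file("extdata", "cms_regions.csv", package = "opioidwaves",
                      mustWork = TRUE)
  read_region_map(path)
}

#' Read a state-to-region map from CSV
#'
#' @param path CSV file with columns `state` and `region`.
#' @return A `region_map` object (named integer vector, region ids 1-10).
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("state", "region") %in% names(df))) {
    stop("region map CSV must have columns 'state' and 'region'")
  }
  if (anyDuplicated(df$state)) {
    stop("region map assigns more than one region to a state: ",
         paste(unique(df$state[duplicated(df$state)]), collapse = ", "))
  }
  region <- as.integer(df$region)
  if (any(is.na(region)) || any(region < 1L) || any(region > 10L)) {
    stop("region ids must be integers in 1..10")
  }
  structure(stats::setNames(region, toupper(df$state)), class = "region_map")
}

#' Look up regions for a set of states
#'
#' @param map A `region_map`.
#' @param states Character vector of postal codes.
#' @return Integer vector of region ids.
#' @export
region_of <- function(map, states) {
  missing <- setdiff(states, names(map))
  if (length(missing) > 0L) {
    stop("states with no region assignment: ", paste(missing, collapse = ", "))
  }
  unname(unclass(map)[states])
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map> ", length(x), " states in ",
      length(unique(unclass(x))), " regions\n", sep = "")
  invisible(x)
}
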