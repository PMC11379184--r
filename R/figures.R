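#' Approximate-geography grid coordinates for states
#'
#' Grid (row, column) positions placing each jurisdiction roughly where it
#' sits on a US map, used for the small-multiple and tile-map figures.
#' States absent from the shipped grid (e.g. synthetic state labels) are
#' laid out automatically in a compact rectangle.
#'
#' @param states Character vector of state codes to cover.
#' @return `data.frame` with columns state, row, col.
#' @export
state_grid <- function(states) {
  path <- system.file("extdata", "state_grid.csv", package = "opioidwaves",
                      mustWork = TRUE)
  grid <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- grid[grid$state %in% states, , drop = FALSE]
  missing <- setdiff(states, grid$state)
  if (length(missing) > 0L) {
    ncol_auto <- ceiling(sqrt(length(missing)))
    auto <- data.frame(state = missing,
                       row = (seq_along(missing) - 1L) %/% ncol_auto + 1L,
                       col = (seq_along(missing) - 1L) %% ncol_auto + 1L)
    known <- if (nrow(known) > 0L) rbind(known, auto) else auto
  }
  known
}

#' Render the standard figure set from posterior summaries
#'
#' Produces three PNG files in `dir`:
#' \describe{
#'   \item{timeseries_grid.png}{small multiples of posterior median rate
#'     time series per state, placed on an approximate-geography grid, one
#'     line per drug category;}
#'   \item{heatmap.png}{state x year heatmap of median rates per drug, rows
#'     ordered by CMS region with the region id prefixed to the state
#'     label;}
#'   \item{map_panels.png}{per-year tile-map panels with each state's tile
#'     filled by its median rate and outlined red/blue where the posterior
#'     probability of a year-over-year increase/decrease reaches the
#'     direction-flag threshold.}
#' }
#'
#' @param rates Rate summary frame from [rate_summaries()].
#' @param rr Direction-flag frame from [relative_risk()].
#' @param regions A `region_map` covering the states.
#' @param dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
render_figures <- function(rates, rr, regions, dir) {
  need <- c("state", "year", "drug", "median")
  if (!all(need %in% names(rates))) {
    stop("rates summary lacks columns ", paste(need, collapse = ", "))
  }
  if (!all(c("state", "year", "drug", "flag") %in% names(rr))) {
    stop("relative-risk summary lacks required columns")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states <- unique(rates$state)
  grid <- state_grid(states)
  reg <- region_of(regions, states)

  ## 1. approximate-geography small multiples
  df <- merge(rates, grid, by = "state")
  g1 <- ggplot2::ggplot(df, ggplot2::aes(x = year, y = median,
                                         colour = drug)) +
    ggplot2::geom_line(linewidth = 0.35) +
    ggplot2::facet_grid(rows = ggplot2::vars(row),
                        cols = ggplot2::vars(col)) +
    ggplot2::geom_text(
      data = stats::aggregate(median ~ state + row + col, df, max),
      ggplot2::aes(label = state), x = mean(range(df$year)),
      y = Inf, vjust = 1.2, size = 2.4, inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "deaths per 100,000",
                  title = "Posterior median overdose death rates") +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(strip.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_blank())
  f1 <- file.path(dir, "timeseries_grid.png")
  ggplot2::ggsave(f1, g1, width = 11, height = 7, dpi = 120)

  ## 2. region-ordered heatmap
  ord <- order(reg, states)
  lab <- paste0(reg, "-", states)
  hm <- rates
  hm$state_lab <- factor(paste0(reg[match(hm$state, states)], "-", hm$state),
                         levels = rev(lab[ord]))
  g2 <- ggplot2::ggplot(hm, ggplot2::aes(x = year, y = state_lab,
                                         fill = median)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~drug, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = "rate per 100k") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Median death rates, states ordered by CMS region") +
    ggplot2::theme_minimal(base_size = 7)
  f2 <- file.path(dir, "heatmap.png")
  ggplot2::ggsave(f2, g2, width = 11, height = 7, dpi = 120)

  ## 3. per-year tile maps with direction outlines
  mp <- merge(rates, grid, by = "state")
  mp <- merge(mp, rr[, c("state", "year", "drug", "flag")],
              by = c("state", "year", "drug"), all.x = TRUE)
  mp$flag[is.na(mp$flag)] <- "none"
  g3 <- ggplot2::ggplot(mp, ggplot2::aes(x = col, y = -row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = median, colour = flag),
                       linewidth = 0.5, width = 0.9, height = 0.9) +
    ggplot2::scale_colour_manual(
      values = c(increase = "red", decrease = "blue", none = "grey80")) +
    ggplot2::scale_fill_viridis_c(name = "rate per 100k") +
    ggplot2::facet_grid(rows = ggplot2::vars(drug),
                        cols = ggplot2::vars(year)) +
    ggplot2::labs(title = paste("Median rates by year;",
                                "outline = 90% posterior direction"),
                  x = NULL, y = NULL) +
    ggplot2::theme_void(base_size = 6)
  f3 <- file.path(dir, "map_panels.png")
  ggplot2::ggsave(f3, g3, width = 14, height = 4, dpi = 120, limitsize = FALSE)

  invisible(c(f1, f2, f3))
}
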