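#' Rarity filter for the deer-browsing susceptibility index
#'
#' Rare species would skew DBSI values, so only species observed widely
#' enough are scored: a species passes when, in at least `year_threshold`
#' years, it had positive cover in at least `plot_threshold` distinct plots
#' (exclosures or controls counted together). The defaults (2 plots, 2
#' years) follow the stricter of the two published phrasings of the rule;
#' both thresholds are configurable so the looser reading (a single plot) is
#' also runnable.
#'
#' @param panel A [cover_panel].
#' @param plot_threshold Minimum number of plots with the species present in
#'   a qualifying year (default 2).
#' @param year_threshold Minimum number of qualifying years (default 2).
#' @return Character vector of species passing the filter.
#' @export
rarity_filter <- function(panel, plot_threshold = 2L, year_threshold = 2L) {
  stopifnot(inherits(panel, "cover_panel"))
  pres <- panel[panel$cover_pct > 0, c("species", "year", "plot_id")]
  if (!nrow(pres)) return(character(0))
  pres <- unique(pres)
  n_plots <- stats::aggregate(plot_id ~ species + year, data = pres,
                              FUN = function(p) length(unique(p)))
  ok_years <- n_plots[n_plots$plot_id >= plot_threshold, ]
  if (!nrow(ok_years)) return(character(0))
  yrs <- table(ok_years$species)
  sort(names(yrs)[yrs >= year_threshold])
}

#' Per-year deer-browsing susceptibility index
#'
#' For each species and year, DBSI is the fraction of the species' summed
#' percent cover found inside exclosures:
#' \deqn{DBSI = \sum C_e / (\sum C_e + \sum C_c),}
#' where \eqn{C_e} and \eqn{C_c} are the species' percent cover in each
#' exclosure and control plot of that year. DBSI is 1 when the species
#' occurs only inside exclosures (browse-susceptible), 0 when only outside,
#' and undefined (`NA`) when both sums are zero — an absent species carries
#' no information, so such species-years are excluded from across-year means
#' rather than scored 0 or 0.5.
#'
#' @param panel A [cover_panel].
#' @param species Optional character vector restricting output.
#' @return Data frame with columns `species`, `year`, `sum_ce`, `sum_cc`,
#'   `dbsi` (one row per species-year over all species/years in the panel).
#' @export
dbsi_per_year <- function(panel, species = NULL) {
  stopifnot(inherits(panel, "cover_panel"))
  spp <- sort(unique(panel$species))
  if (!is.null(species)) {
    unknown <- setdiff(species, spp)
    if (length(unknown))
      stopf("species not in panel: %s", paste(unknown, collapse = ", "))
    spp <- sort(species)
  }
  years <- sort(unique(panel$year))
  grid <- expand.grid(species = spp, year = years, stringsAsFactors = FALSE)
  key <- function(s, y, tr) paste(s, y, tr, sep = "\r")
  sums <- tapply(panel$cover_pct,
                 key(panel$species, panel$year, panel$treatment), sum)
  get <- function(s, y, tr) {
    v <- sums[key(s, y, tr)]
    ifelse(is.na(v), 0, v)
  }
  grid$sum_ce <- as.numeric(get(grid$species, grid$year, "exclosure"))
  grid$sum_cc <- as.numeric(get(grid$species, grid$year, "control"))
  tot <- grid$sum_ce + grid$sum_cc
  grid$dbsi <- ifelse(tot > 0, grid$sum_ce / tot, NA_real_)
  grid[order(grid$species, grid$year), , drop = FALSE]
}

#' Mean DBSI table across years
#'
#' Applies the [rarity_filter()], computes [dbsi_per_year()] for every
#' species, and reports the unweighted mean of the defined (non-`NA`)
#' per-year values, together with per-year columns and the inclusion flag.
#' Species are ordered from least to most browse-susceptible (ascending mean
#' DBSI). Species with no defined year at all are dropped with a warning.
#'
#' @param panel A [cover_panel].
#' @param plot_threshold,year_threshold Passed to [rarity_filter()].
#' @param include_all Keep species failing the rarity filter (flagged
#'   `included = FALSE`) instead of dropping them (default FALSE).
#' @return Data frame with columns `species`, `included`, `mean_dbsi`,
#'   `n_years_defined`, then one `dbsi_<year>` column per panel year.
#' @examples
#' pan <- cover_panel(data.frame(
#'   plot_id = rep(c("e1", "e2", "c1", "c2"), 2),
#'   site_id = rep(c("s1", "s2", "s1", "s2"), 2),
#'   treatment = rep(c("exclosure", "exclosure", "control", "control"), 2),
#'   year = rep(2006:2007, each = 4), species = "sp1",
#'   cover_pct = c(4, 2, 0, 0, 5, 1, 0, 0)))
#' mean_dbsi(pan) # exclosure-only species: mean DBSI 1
#' @export
mean_dbsi <- function(panel, plot_threshold = 2L, year_threshold = 2L,
                      include_all = FALSE) {
  stopifnot(inherits(panel, "cover_panel"))
  included <- rarity_filter(panel, plot_threshold, year_threshold)
  per_year <- dbsi_per_year(panel)
  years <- sort(unique(per_year$year))
  spp <- sort(unique(per_year$species))
  wide <- matrix(NA_real_, length(spp), length(years),
                 dimnames = list(spp, paste0("dbsi_", years)))
  wide[cbind(match(per_year$species, spp), match(per_year$year, years))] <-
    per_year$dbsi
  n_def <- rowSums(!is.na(wide))
  out <- data.frame(species = spp,
                    included = spp %in% included,
                    mean_dbsi = rowMeans(wide, na.rm = TRUE),
                    n_years_defined = as.integer(n_def),
                    row.names = NULL)
  out <- cbind(out, as.data.frame(wide, row.names = NULL))
  none <- out$species[out$n_years_defined == 0]
  if (length(none)) {
    warnf("species with no defined DBSI year dropped: %s",
          paste(none, collapse = ", "))
    out <- out[out$n_years_defined > 0, , drop = FALSE]
  }
  if (!include_all) out <- out[out$included, , drop = FALSE]
  out <- out[order(out$mean_dbsi, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
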