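#' Species richness of a cover vector
#'
#' Number of species encountered along a plot's transects, i.e. species with
#' strictly positive cover. Invariant to any positive rescaling of cover.
#'
#' @param cover Named numeric vector of percent cover for one plot-year.
#' @return Integer count of species with cover > 0.
#' @export
species_richness <- function(cover) {
  if (!length(cover)) return(0L)
  if (anyNA(cover) || any(cover < 0)) stopf("cover must be non-negative")
  sum(cover > 0)
}

#' Shannon-Wiener diversity of a cover vector
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} with \eqn{p_i} the share of species *i* in
#' the plot's total cover. Percent cover serves as the abundance measure;
#' zero-cover species are excluded. Natural logarithm (nats).
#'
#' @param cover Named numeric vector of percent cover for one plot-year with
#'   at least one positive entry.
#' @return Shannon-Wiener index \eqn{H'} in nats.
#' @examples
#' shannon_index(c(A = 5, B = 5)) # log(2)
#' @export
shannon_index <- function(cover) {
  if (anyNA(cover) || any(cover < 0)) stopf("cover must be non-negative")
  cover <- cover[cover > 0]
  if (!length(cover))
    stopf("Shannon index undefined for all-zero cover")
  p <- cover / sum(cover)
  -sum(p * log(p))
}

#' Per-plot diversity table
#'
#' Species richness, Shannon-Wiener \eqn{H'} and (optionally, when a tree is
#' supplied) mean pairwise phylogenetic distance for every plot-year of a
#' cover panel. Plot-years with fewer than two species present get `NA` MPD.
#'
#' @param panel A [cover_panel].
#' @param tree Optional `phylo` covering the panel's species.
#' @return Data frame with one row per plot-year: `plot_id`, `site_id`,
#'   `treatment`, `year`, `richness`, `shannon`, and `mpd` if `tree` given.
#' @export
diversity_by_plot <- function(panel, tree = NULL) {
  stopifnot(inherits(panel, "cover_panel"))
  dist <- NULL
  if (!is.null(tree)) {
    dist <- patristic_matrix(tree)
    absent <- setdiff(unique(panel$species), rownames(dist))
    if (length(absent))
      stopf("species in panel but not on tree: %s", paste(absent, collapse = ", "))
  }
  cells <- unique(panel[c("plot_id", "site_id", "treatment", "year")])
  cells <- cells[order(cells$year, cells$treatment, cells$plot_id), ]
  rownames(cells) <- NULL
  cells$richness <- NA_integer_
  cells$shannon <- NA_real_
  if (!is.null(dist)) cells$mpd <- NA_real_
  for (i in seq_len(nrow(cells))) {
    cov <- plot_cover(panel, cells$plot_id[i], cells$year[i])
    cov <- cov[cov > 0]
    cells$richness[i] <- species_richness(cov)
    cells$shannon[i] <- if (length(cov)) shannon_index(cov) else NA_real_
    if (!is.null(dist) && length(cov) >= 2)
      cells$mpd[i] <- mpd(names(cov), dist)
  }
  cells
}
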