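#' Construct a percent-cover panel
#'
#' A cover panel is the package's community container: a long-format
#' data frame with one row per (plot, year, species) combination holding
#' percent cover on the 0-100 scale, plus plot metadata (site and treatment).
#' Treatments follow the paired exclosure/control design: each site holds one
#' fenced plot (`"exclosure"`) and one adjacent unfenced plot (`"control"`).
#'
#' Per-species cover is capped at 100 %; because different species can
#' intercept the same transect segment at different heights, the *total*
#' cover of a plot may legitimately exceed 100 %.
#'
#' @param df Data frame with columns `plot_id`, `site_id`, `treatment`
#'   (`"exclosure"` or `"control"`), `year`, `species`, `cover_pct`.
#' @return The validated data frame with class `cover_panel`.
#' @seealso [compute_cover()] to build a panel from raw transect records.
#' @export
cover_panel <- function(df) {
  need <- c("plot_id", "site_id", "treatment", "year", "species", "cover_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("cover panel is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  bad <- setdiff(unique(df$treatment), c("exclosure", "control"))
  if (length(bad))
    stopf("unknown treatment value(s): %s", paste(bad, collapse = ", "))
  if (anyNA(df$cover_pct) || any(df$cover_pct < 0))
    stopf("cover values must be non-negative and non-missing")
  if (any(df$cover_pct > 100))
    stopf("per-species cover cannot exceed 100 %%")
  df$species <- trimws(df$species)
  # a plot must map to exactly one site/treatment
  meta <- unique(df[c("plot_id", "site_id", "treatment")])
  dup <- meta$plot_id[duplicated(meta$plot_id)]
  if (length(dup))
    stopf("plot(s) with inconsistent site/treatment metadata: %s",
          paste(unique(dup), collapse = ", "))
  key <- paste(df$plot_id, df$year, df$species, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicated (plot, year, species) entries in cover panel")
  class(df) <- c("cover_panel", "data.frame")
  df
}

#' Percent cover from line-intercept transect records
#'
#' Implements the line-intercept cover calculation: along each 5 m transect
#' the tape length (to the nearest cm) intercepted by each occurrence of a
#' species is recorded, and percent cover of species *i* in a plot-year is
#' \deqn{100 \cdot \sum n_i / 1500,}
#' where the sum runs over every occurrence of the species on the plot's
#' three transects and 1500 cm is the combined transect length. Multiple
#' occurrences of the same species on one transect are summed; overlap
#' between *different* species is allowed, so plot totals can exceed 100 %.
#'
#' @param records Data frame of transect records with columns `plot_id`,
#'   `site_id`, `treatment`, `year`, `transect_id`, `species`,
#'   `intercept_cm` (positive integers).
#' @param transect_total_cm Combined length of all transects in a plot
#'   (default 1500 = three 5 m transects).
#' @param n_transects Number of transects per plot (default 3).
#' @return A [cover_panel] covering every (plot, year) present in `records`.
#' @examples
#' rec <- data.frame(plot_id = "p1", site_id = "s1", treatment = "control",
#'                   year = 2006, transect_id = c(1, 1), species = "A",
#'                   intercept_cm = c(100, 50))
#' compute_cover(rec) # one species at 10 % cover
#' @export
compute_cover <- function(records, transect_total_cm = 1500L, n_transects = 3L) {
  need <- c("plot_id", "site_id", "treatment", "year", "transect_id",
            "species", "intercept_cm")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("transect records missing column(s): %s", paste(miss, collapse = ", "))
  records <- as.data.frame(records)
  records$species <- trimws(records$species)
  if (anyNA(records$intercept_cm) || any(records$intercept_cm < 1) ||
      any(records$intercept_cm != round(records$intercept_cm)))
    stopf("intercept_cm must be positive integers (lengths to the nearest cm)")
  if (any(!records$transect_id %in% seq_len(n_transects)))
    stopf("transect_id must be in 1..%d", n_transects)
  transect_cm <- transect_total_cm / n_transects
  # a single species cannot intercept more tape than one transect holds
  tkey <- paste(records$plot_id, records$year, records$transect_id,
                records$species, sep = "\r")
  tsum <- tapply(records$intercept_cm, tkey, sum)
  if (any(tsum > transect_cm)) {
    bad <- names(tsum)[tsum > transect_cm][1]
    f <- strsplit(bad, "\r", fixed = TRUE)[[1]]
    stopf(paste0("species '%s' intercepts %d cm on transect %s of plot %s ",
                 "(year %s), more than the %g cm transect length"),
          f[4], tsum[[bad]], f[3], f[1], f[2], transect_cm)
  }
  agg <- stats::aggregate(
    intercept_cm ~ plot_id + site_id + treatment + year + species,
    data = records, FUN = sum)
  agg$cover_pct <- 100 * agg$intercept_cm / transect_total_cm
  agg$intercept_cm <- NULL
  cover_panel(agg)
}

#' Treatment-pooled percent cover
#'
#' Percent cover of each species pooled over all plots of one treatment in
#' one year: the summed intercept lengths divided by the combined tape length
#' of all plots, i.e. \eqn{100 \cdot \sum n_i / 6000} for four plots of three
#' 5 m transects. This equals the mean of the per-plot covers, which is how
#' it is computed here (so it applies to panels built from cover values
#' directly, not only from raw records).
#'
#' @param panel A [cover_panel].
#' @param treatment `"exclosure"` or `"control"`.
#' @param year Year to pool.
#' @param expected_plots Plot ids that must be present; defaults to every
#'   plot id seen for that treatment anywhere in the panel. Missing plots
#'   raise an error naming them.
#' @return Named numeric vector of pooled percent cover, one entry per
#'   species observed in the treatment-year (zeros dropped).
#' @export
pooled_cover <- function(panel, treatment, year, expected_plots = NULL) {
  stopifnot(inherits(panel, "cover_panel"))
  treatment <- match.arg(treatment, c("exclosure", "control"))
  if (is.null(expected_plots))
    expected_plots <- unique(panel$plot_id[panel$treatment == treatment])
  sub <- panel[panel$treatment == treatment & panel$year == year, , drop = FALSE]
  absent <- setdiff(expected_plots, unique(sub$plot_id))
  if (length(absent))
    stopf("treatment '%s', year %s: plot(s) missing from panel: %s",
          treatment, year, paste(absent, collapse = ", "))
  n_plots <- length(expected_plots)
  pooled <- tapply(sub$cover_pct, sub$species, sum) / n_plots
  out <- as.numeric(pooled)
  names(out) <- names(pooled)
  out[out > 0]
}

#' Per-plot cover vector
#'
#' @param panel A [cover_panel].
#' @param plot_id,year Plot and year to extract.
#' @return Named numeric vector of percent cover for that plot-year.
#' @export
plot_cover <- function(panel, plot_id, year) {
  stopifnot(inherits(panel, "cover_panel"))
  sub <- panel[panel$plot_id == plot_id & panel$year == year, , drop = FALSE]
  stats::setNames(sub$cover_pct, sub$species)
}

#' Plot-by-species cover matrix
#'
#' @param panel A [cover_panel].
#' @param year Single year.
#' @return Numeric matrix, plots as rows, species as columns, percent cover.
#' @export
cover_matrix <- function(panel, year) {
  stopifnot(inherits(panel, "cover_panel"))
  sub <- panel[panel$year == year, , drop = FALSE]
  if (!nrow(sub)) stopf("no cover entries for year %s", year)
  plots <- sort(unique(sub$plot_id))
  spp <- sort(unique(sub$species))
  m <- matrix(0, length(plots), length(spp), dimnames = list(plots, spp))
  m[cbind(match(sub$plot_id, plots), match(sub$species, spp))] <- sub$cover_pct
  m
}

#' Read/write transect records and cover panels as CSV
#'
#' The delimited-text interchange formats: transect records with header
#' `plot_id,site_id,treatment,year,transect_id,species,intercept_cm`, and
#' long-format cover panels with header
#' `plot_id,site_id,treatment,year,species,cover_pct`.
#'
#' @param file Path to a CSV file.
#' @return `read_transect_records`: a validated records data frame;
#'   `read_cover_panel`: a [cover_panel].
#' @name cover-io
#' @export
read_transect_records <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("plot_id", "site_id", "treatment", "year", "transect_id",
            "species", "intercept_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("transect CSV missing column(s): %s", paste(miss, collapse = ", "))
  df
}

#' @rdname cover-io
#' @param records Transect records data frame.
#' @export
write_transect_records <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname cover-io
#' @export
read_cover_panel <- function(file) {
  cover_panel(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname cover-io
#' @param panel A [cover_panel].
#' @export
write_cover_panel <- function(panel, file) {
  stopifnot(inherits(panel, "cover_panel"))
  utils::write.csv(as.data.frame(panel), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
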