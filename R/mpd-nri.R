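#' Mean pairwise phylogenetic distance
#'
#' Mean patristic distance over all unordered pairs of community members.
#' Presence-based: every member counts once regardless of abundance. MPD is
#' the package's general phylogenetic-diversity metric because it is less
#' correlated with species richness than summed-branch-length measures and
#' more sensitive to deep (between-clade) turnover than nearest-taxon
#' distances.
#'
#' @param members Character vector of tip labels present in the community
#'   (duplicates ignored; at least 2 distinct members).
#' @param dist Patristic distance matrix from [patristic_matrix()].
#' @return MPD in the tree's branch-length units.
#' @export
mpd <- function(members, dist) {
  members <- unique(members)
  missing <- setdiff(members, rownames(dist))
  if (length(missing))
    stopf("community member(s) not in distance matrix: %s",
          paste(missing, collapse = ", "))
  k <- length(members)
  if (k < 2) stopf("MPD requires at least 2 community members")
  sum(dist[members, members]) / (k * (k - 1))
}

# Null MPD distribution for communities of size k drawn uniformly from the
# tip pool. For presence-based MPD this is equivalent to shuffling all tip
# labels of the phylogeny: a shuffled-label community is a uniform random
# k-subset of the pool. Vectorized: with V the n x n_perm 0/1 membership
# matrix, the pairwise sums are diag(V' D V) = colSums(V * (D %*% V)).
.mpd_null <- function(dist, k, n_perm) {
  n <- nrow(dist)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, k), integer(k))
  V <- matrix(0, n, n_perm)
  V[cbind(as.vector(idx), rep(seq_len(n_perm), each = k))] <- 1
  colSums(V * (dist %*% V)) / (k * (k - 1))
}

#' Net relatedness index with a tip-shuffle permutation null
#'
#' Compares observed community MPD with a null distribution obtained by
#' shuffling the phylogeny's tip labels (equivalently, drawing communities of
#' the same size uniformly at random from the tip pool), simulating a null
#' expectation of no effect of phylogeny. The index is
#' \deqn{NRI = -(MPD_{obs} - \overline{MPD}_{null}) / sd(MPD_{null}),}
#' so communities of close relatives (phylogenetic clustering) give positive
#' NRI. The clustering p-value is the permutation estimate
#' \eqn{(r+1)/(n_{perm}+1)} with \eqn{r} the number of null MPDs less than or
#' equal to the observed MPD; a two-tailed p is also reported.
#'
#' The species pool is all tips of the supplied tree (a site-specific
#' phylogeny of the species encountered at the study site). If the community
#' equals the whole pool every shuffle returns the same MPD; the result is
#' then flagged `degenerate`, NRI is `NA` and p-values are rank-based only.
#'
#' @param members Character vector of community member tip labels.
#' @param tree A `phylo` object (pool = its tips); ignored when `dist` given.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param dist Optional precomputed [patristic_matrix()] (its rownames define
#'   the pool), to avoid recomputation in loops.
#' @return An object of class `nri_result`: list with `mpd_obs`, `null_mean`,
#'   `null_sd`, `nri`, `p_clustering`, `p_two_tailed`, `n_species`, `n_perm`,
#'   `seed`, `degenerate`.
#' @examples
#' tr <- sim_yule_tree(20, seed = 1)
#' nri(tr$tip.label[1:8], tr, n_perm = 199, seed = 1)
#' @export
nri <- function(members, tree = NULL, n_perm = 999L, seed = NULL, dist = NULL) {
  if (is.null(dist)) {
    if (is.null(tree)) stopf("supply `tree` or a precomputed `dist`")
    dist <- patristic_matrix(tree)
  }
  if (n_perm < 99) stopf("n_perm must be at least 99")
  members <- unique(members)
  obs <- mpd(members, dist)
  k <- length(members)
  null_mpd <- with_seed(seed, .mpd_null(dist, k, n_perm))
  null_mean <- mean(null_mpd)
  null_sd <- stats::sd(null_mpd)
  r_le <- sum(null_mpd <= obs)
  r_ge <- sum(null_mpd >= obs)
  p_clust <- (r_le + 1) / (n_perm + 1)
  p_over <- (r_ge + 1) / (n_perm + 1)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  structure(list(
    mpd_obs = obs,
    null_mean = null_mean,
    null_sd = null_sd,
    nri = if (degenerate) NA_real_ else -(obs - null_mean) / null_sd,
    p_clustering = p_clust,
    p_two_tailed = min(1, 2 * min(p_clust, p_over)),
    n_species = k,
    n_perm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    degenerate = degenerate
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI (n = %d species, %d permutations)\n", x$n_species, x$n_perm))
  cat(sprintf("  MPD observed %.4f  null %.4f +/- %.4f\n",
              x$mpd_obs, x$null_mean, x$null_sd))
  cat(sprintf("  NRI = %s   P(clustering) = %.4g   P(two-tailed) = %.4g%s\n",
              ifelse(x$degenerate, "NA (degenerate null)",
                     sprintf("%.3f", x$nri)),
              x$p_clustering, x$p_two_tailed,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' NRI for treatment-pooled communities, by year
#'
#' Pools all plots of each treatment within a year (a species is a member of
#' the pooled community if its pooled cover is positive) and runs [nri()] on
#' each (treatment, year) cell, so that years in which browsing most shaped
#' community structure can be identified from the per-cell p-values.
#'
#' Cells that fail (e.g. fewer than two species present) are kept as `NA`
#' rows with a warning; remaining cells are still computed. Each cell uses a
#' seed derived from `seed` and the cell's label via [derive_seed()], so the
#' whole table is reproducible and cells are independent.
#'
#' @param panel A [cover_panel].
#' @param tree A `phylo` whose tips include all panel species.
#' @param n_perm Permutations per cell (default 999).
#' @param seed Master integer seed.
#' @return Data frame with one row per (treatment, year):
#'   `treatment`, `year`, `n_species`, `mpd_obs`, `null_mean`, `null_sd`,
#'   `nri`, `p_clustering`, `p_two_tailed`, `n_perm`, `seed`, `degenerate`.
#' @export
nri_by_treatment_year <- function(panel, tree, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(panel, "cover_panel"))
  dist <- patristic_matrix(tree)
  absent <- setdiff(unique(panel$species), rownames(dist))
  if (length(absent))
    stopf("species in panel but not on tree: %s", paste(absent, collapse = ", "))
  cells <- expand.grid(treatment = c("exclosure", "control"),
                       year = sort(unique(panel$year)),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$year, cells$treatment), ]
  rownames(cells) <- NULL
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tr <- cells$treatment[i]
    yr <- cells$year[i]
    sub <- panel[panel$treatment == tr & panel$year == yr & panel$cover_pct > 0, ]
    members <- unique(sub$species)
    cell_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, paste("nri", tr, yr, sep = "/"))
    res <- tryCatch(nri(members, dist = dist, n_perm = n_perm, seed = cell_seed),
                    error = function(e) {
                      warnf("NRI failed for %s/%s: %s", tr, yr, conditionMessage(e))
                      NULL
                    })
    out[[i]] <- if (is.null(res)) {
      data.frame(treatment = tr, year = yr, n_species = length(members),
                 mpd_obs = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
                 nri = NA_real_, p_clustering = NA_real_,
                 p_two_tailed = NA_real_, n_perm = as.integer(n_perm),
                 seed = if (is.null(cell_seed)) NA_integer_ else cell_seed,
                 degenerate = NA)
    } else {
      data.frame(treatment = tr, year = yr, n_species = res$n_species,
                 mpd_obs = res$mpd_obs, null_mean = res$null_mean,
                 null_sd = res$null_sd, nri = res$nri,
                 p_clustering = res$p_clustering,
                 p_two_tailed = res$p_two_tailed, n_perm = res$n_perm,
                 seed = res$seed, degenerate = res$degenerate)
    }
  }
  do.call(rbind, out)
}
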