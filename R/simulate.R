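#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation with exponential waiting times: starting from two crown
#' lineages, the time to the next speciation with `k` extant lineages is
#' exponential with rate `k * birth_rate`, and a uniformly chosen lineage
#' splits. After the pool reaches `n_species` lineages one further waiting
#' time elapses to the present, so all pendant branches are positive and the
#' tree is ultrametric by construction. Tips are labelled `sp0001`,
#' `sp0002`, ...
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Integer seed; fixed seed gives an identical tree.
#' @return An ultrametric `phylo` object.
#' @export
sim_yule_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 2, birth_rate > 0)
  with_seed(seed, {
    parent <- c(NA_integer_, 1L, 1L)
    btime <- c(0, 0, 0)
    active <- c(2L, 3L)
    t <- 0
    while (length(active) < n_species) {
      t <- t + stats::rexp(1, birth_rate * length(active))
      pick <- sample.int(length(active), 1L)
      i <- active[pick]
      ids <- length(parent) + c(1L, 2L)
      parent <- c(parent, i, i)
      btime <- c(btime, t, t)
      active <- c(active[-pick], ids)
    }
    t_present <- t + stats::rexp(1, birth_rate * n_species)
    n_nodes <- length(parent)
    is_tip <- rep(TRUE, n_nodes)
    is_tip[parent[-1]] <- FALSE
    tip_ids <- which(is_tip)
    int_ids <- which(!is_tip) # root (node 1) first, then in creation order
    newid <- integer(n_nodes)
    newid[tip_ids] <- seq_len(n_species)
    newid[int_ids] <- n_species + seq_along(int_ids)
    end_time <- rep(t_present, n_nodes)
    for (v in seq(2L, n_nodes)) end_time[parent[v]] <- btime[v]
    tree <- structure(list(
      edge = cbind(as.integer(newid[parent[-1]]), as.integer(newid[-1]),
                   deparse.level = 0),
      edge.length = end_time[-1] - btime[-1],
      Nnode = length(int_ids),
      tip.label = sprintf("sp%04d", seq_len(n_species))
    ), class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

# Tip-by-edge incidence matrix of root-to-tip paths: tip values of a
# Brownian walk are B %*% (per-edge increments).
.bm_path_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  edge <- tree$edge
  root <- nt + 1L
  eidx <- integer(nt + tree$Nnode)
  eidx[edge[, 2]] <- seq_len(nrow(edge))
  B <- matrix(0, nt, nrow(edge))
  for (i in seq_len(nt)) {
    v <- i
    while (v != root) {
      e <- eidx[v]
      B[i, e] <- 1
      v <- edge[e, 1]
    }
  }
  rownames(B) <- tree$tip.label
  B
}

# n_tip x n_sim matrix of independent Brownian-motion tip values
# (root value 0, increment variance sigma2 * branch length)
.bm_tip_matrix <- function(tree, sigma2, n_sim) {
  B <- .bm_path_matrix(tree)
  s <- sqrt(sigma2 * tree$edge.length)
  Z <- matrix(stats::rnorm(ncol(B) * n_sim), ncol = n_sim)
  B %*% (Z * s)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Continuous characters evolved by Brownian motion: the root value is 0 and
#' each child value is its parent's value plus a Normal(0, `sigma2` * branch
#' length) increment. `sim_brownian_trait()` returns one named tip vector;
#' `sim_brownian_traits()` returns a tips-by-replicates matrix of
#' independent simulations.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param n_sim Number of independent replicate traits.
#' @param seed Integer seed.
#' @return Named numeric vector (`sim_brownian_trait`) or matrix with
#'   rownames = tip labels (`sim_brownian_traits`).
#' @export
sim_brownian_traits <- function(tree, sigma2 = 1, n_sim = 1L, seed = NULL) {
  tree <- validate_tree(tree)
  stopifnot(sigma2 >= 0, n_sim >= 1)
  with_seed(seed, .bm_tip_matrix(tree, sigma2, n_sim))
}

#' @rdname sim_brownian_traits
#' @export
sim_brownian_trait <- function(tree, sigma2 = 1, seed = NULL) {
  m <- sim_brownian_traits(tree, sigma2 = sigma2, n_sim = 1L, seed = seed)
  stats::setNames(m[, 1], rownames(m))
}

#' Threshold a continuous trait into a binary trait at fixed prevalence
#'
#' The Brownian threshold model for binary characters: tips are ranked by a
#' continuous (liability) value and the top `k` receive state 1, the rest
#' state 0, so the prevalence is exactly `k`. Ties are broken by seeded
#' uniform jitter.
#'
#' @param values Named numeric vector of tip values.
#' @param k Number of tips assigned state 1 (0 < k < length(values)).
#' @param seed Integer seed (only affects tie-breaking).
#' @return Named integer 0/1 vector with `sum == k`.
#' @export
threshold_binarize <- function(values, k, seed = NULL) {
  if (is.null(names(values))) stopf("`values` must be a named vector")
  n <- length(values)
  if (!(k > 0 && k < n))
    stopf("prevalence k must satisfy 0 < k < %d", n)
  y <- with_seed(seed, .threshold_topk(values, as.integer(k)))
  stats::setNames(as.integer(y), names(values))
}

#' Simulate a multistate trait under an equal-rates Markov (Mk) model
#'
#' A categorical character evolves along each branch under a continuous-time
#' Markov chain with equal rates between all state pairs; `rate` is the
#' total rate of leaving the current state per unit branch length. The root
#' state is uniform. Transition probabilities use the closed form
#' \eqn{P(stay) = 1/S + (1 - 1/S) e^{-S \cdot rate \cdot t/(S-1)}}. With
#' `rate = 0` the trait is constant; as `rate` grows, tip states approach
#' independent uniform draws.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param n_states Number of states S (>= 2).
#' @param rate Total transition rate per unit branch length (>= 0).
#' @param seed Integer seed.
#' @return Named integer vector of tip states in `1..n_states`.
#' @export
sim_mk_trait <- function(tree, n_states = 6L, rate = 0.5, seed = NULL) {
  tree <- validate_tree(tree)
  stopifnot(n_states >= 2, rate >= 0)
  with_seed(seed, {
    nt <- length(tree$tip.label)
    ord <- ape::reorder.phylo(tree, "cladewise")
    edge <- ord$edge
    len <- ord$edge.length
    state <- integer(nt + tree$Nnode)
    state[nt + 1L] <- sample.int(n_states, 1L)
    p_stay <- 1 / n_states +
      (1 - 1 / n_states) * exp(-n_states * rate * len / (n_states - 1))
    for (e in seq_len(nrow(edge))) {
      par <- state[edge[e, 1]]
      state[edge[e, 2]] <- if (stats::runif(1) < p_stay[e]) par else {
        others <- setdiff(seq_len(n_states), par)
        others[sample.int(n_states - 1L, 1L)]
      }
    }
    stats::setNames(state[seq_len(nt)], tree$tip.label)
  })
}

# split an intercept length of L cm into 1..n_transects integer pieces,
# each within one transect's length
.split_intercept <- function(L, n_transects, transect_cm) {
  m_min <- as.integer(ceiling(L / transect_cm))
  m_max <- min(n_transects, L)
  m <- if (m_min >= m_max) m_min else
    m_min + sample.int(m_max - m_min + 1L, 1L) - 1L
  if (m == 1L) return(L)
  for (i in seq_len(100)) {
    cuts <- sort(sample.int(L - 1L, m - 1L))
    parts <- diff(c(0L, cuts, L))
    if (all(parts <= transect_cm)) return(parts)
  }
  base <- L %/% m
  extra <- L %% m
  rep(base, m) + c(rep(1L, extra), rep(0L, m - extra))
}

#' Simulate a browsed/unbrowsed community panel with transect records
#'
#' Emulates the paired-exclosure design: at each of `n_sites` sites, one
#' fenced exclosure plot and one adjacent control plot are surveyed by
#' `n_transects` line-intercept transects in each year. Every pool species
#' (tree tip) occurs in an exclosure plot with a common base probability
#' `occupancy`; in control (browsed) plots browsing acts as a biotic filter
#' that additionally thins presence by `retention[state]`, the retention
#' probability of the species' trait state (`browse_mode = "presence"`).
#' With `browse_mode = "cover"` presence is unthinned but control cover is
#' multiplied by the retention factor instead.
#'
#' Realized percent cover is log-normal (capped at 100 %); each species-plot
#' cover value is converted to an integer intercept length and split into
#' 1-3 integer-cm segments placed on distinct random transects, so
#' [compute_cover()] on the emitted records reproduces the target covers to
#' the 1 cm rounding bound (100/1500 of a percent). Overlap between
#' different species is allowed, as in the field protocol.
#'
#' @param tree A `phylo`; its tips are the species pool.
#' @param trait Named vector of trait states driving susceptibility.
#' @param retention Retention probabilities in browsed plots: either a
#'   single number for all states or a named vector/list keyed by state.
#' @param years Survey years.
#' @param n_sites Number of paired sites (default 4).
#' @param occupancy Base per-plot occupancy probability.
#' @param cover_meanlog,cover_sdlog Log-normal percent-cover parameters.
#' @param n_transects,transect_cm Transects per plot and length of each (cm).
#' @param browse_mode `"presence"` (default) or `"cover"`; see above.
#' @param seed Integer seed; identical seed and arguments give byte-identical
#'   output.
#' @return List with `records` (transect records data frame), `panel`
#'   (the [cover_panel] built from them via [compute_cover()]), and
#'   `targets` (data frame of the generating cover values, for round-trip
#'   checks).
#' @export
sim_browse_panel <- function(tree, trait, retention,
                             years = c(2006, 2008:2012), n_sites = 4L,
                             occupancy = 0.4, cover_meanlog = 0.5,
                             cover_sdlog = 0.8, n_transects = 3L,
                             transect_cm = 500L,
                             browse_mode = c("presence", "cover"),
                             seed = NULL) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  browse_mode <- match.arg(browse_mode)
  spp <- tree$tip.label
  if (is.null(names(trait))) stopf("`trait` must be a named vector")
  missing <- setdiff(spp, names(trait))
  if (length(missing))
    stopf("no trait state for species: %s", paste(missing, collapse = ", "))
  states <- as.character(unlist(trait[spp]))
  if (length(retention) == 1L && is.null(names(retention)))
    retention <- stats::setNames(rep(as.numeric(retention),
                                     length(unique(states))), unique(states))
  retention <- unlist(retention)
  no_ret <- setdiff(unique(states), names(retention))
  if (length(no_ret))
    stopf("no retention probability for state(s): %s",
          paste(no_ret, collapse = ", "))
  if (any(retention < 0 | retention > 1) || !(occupancy >= 0 && occupancy <= 1))
    stopf("occupancy and retention values must lie in [0, 1]")
  total_cm <- n_transects * transect_cm
  with_seed(seed, {
    rec <- vector("list", 0L)
    tgt <- vector("list", 0L)
    for (yr in years) for (s in seq_len(n_sites))
      for (tr in c("exclosure", "control")) {
        plot_id <- sprintf("site%d-%s", s, substr(tr, 1, 4))
        for (i in seq_along(spp)) {
          if (stats::runif(1) >= occupancy) next
          if (browse_mode == "presence" && tr == "control" &&
              stats::runif(1) >= retention[[states[i]]]) next
          cov <- min(100, stats::rlnorm(1, cover_meanlog, cover_sdlog))
          if (browse_mode == "cover" && tr == "control")
            cov <- cov * retention[[states[i]]]
          L <- as.integer(round(cov / 100 * total_cm))
          if (L < 1L) {
            if (browse_mode == "cover") next else L <- 1L
          }
          parts <- .split_intercept(L, n_transects, transect_cm)
          on_tr <- sample.int(n_transects, length(parts))
          rec[[length(rec) + 1L]] <- data.frame(
            plot_id = plot_id, site_id = sprintf("site%d", s), treatment = tr,
            year = yr, transect_id = on_tr, species = spp[i],
            intercept_cm = as.integer(parts))
          tgt[[length(tgt) + 1L]] <- data.frame(
            plot_id = plot_id, year = yr, species = spp[i], target_pct = cov)
        }
      }
    if (!length(rec))
      stopf("simulation produced no occurrences; raise `occupancy`")
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    targets <- do.call(rbind, tgt)
    rownames(targets) <- NULL
    list(records = records,
         panel = compute_cover(records, transect_total_cm = total_cm,
                               n_transects = n_transects),
         targets = targets)
  })
}
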