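# Matrix of tip weights behind ancestral node values: node value = equal-
# weight average of its daughters' values (branch lengths ignored), so every
# node value is a fixed linear combination of tip values. Row v of W holds
# the tip weights of node v.
.tip_weight_matrix <- function(tree) {
  topo <- .tree_topology(tree)
  W <- matrix(0, topo$n_tip + topo$n_node, topo$n_tip)
  W[cbind(seq_len(topo$n_tip), seq_len(topo$n_tip))] <- 1
  for (j in seq_along(topo$internal)) {
    kids <- topo$children[[j]]
    W[topo$internal[j], ] <- colMeans(W[kids, , drop = FALSE])
  }
  colnames(W) <- tree$tip.label
  W
}

# Linear operator M such that d(x) = sum(abs(M %*% x)): one row per
# unordered pair of daughters at each internal node, holding the difference
# of the daughters' tip-weight vectors. At a polytomy all daughter pairs
# contribute, generalizing the two-daughter case. Rows of M sum to zero, so
# d is exactly invariant to adding a constant to all tip values (hence to
# swapping a 0/1 coding).
.sister_diff_operator <- function(tree) {
  topo <- .tree_topology(tree)
  W <- .tip_weight_matrix(tree)
  rows <- list()
  for (j in seq_along(topo$internal)) {
    kids <- topo$children[[j]]
    for (a in seq_len(length(kids) - 1))
      for (b in seq((a + 1), length(kids)))
        rows[[length(rows) + 1L]] <- W[kids[a], ] - W[kids[b], ]
  }
  do.call(rbind, rows)
}

#' Sum of sister-clade differences
#'
#' The raw quantity behind the D statistic for binary traits: ancestral node
#' values are estimated tip-to-root by equal-weight averaging of daughter
#' values (branch lengths ignored), and d is the sum over internal nodes of
#' the absolute differences between all pairs of daughter values. A trait
#' concentrated in one clade yields a small d; a trait scattered over the
#' tips yields a large d.
#'
#' @param tree A `phylo` object.
#' @param values Named numeric vector of tip values.
#' @return The scalar sister-clade difference sum d.
#' @export
sister_diff_sum <- function(tree, values) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  if (is.null(names(values)))
    stopf("tip values must be a named vector (names = tip labels)")
  names(values) <- trimws(names(values))
  missing <- setdiff(tree$tip.label, names(values))
  if (length(missing))
    stopf("no value for tip(s): %s", paste(missing, collapse = ", "))
  x <- as.numeric(values[tree$tip.label])
  if (anyNA(x)) stopf("missing (NA) tip values are not allowed")
  M <- .sister_diff_operator(tree)
  sum(abs(M %*% x))
}

# top-k indicator with seeded-stream random tie-breaking
.threshold_topk <- function(z, k) {
  y <- numeric(length(z))
  y[order(z, stats::runif(length(z)), decreasing = TRUE)[seq_len(k)]] <- 1
  y
}

.as_binary_trait <- function(tree, trait) {
  if (is.null(names(trait)))
    stopf("binary trait must be a named vector (names = tip labels)")
  names(trait) <- trimws(names(trait))
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stopf("no trait state for tip(s): %s", paste(missing, collapse = ", "))
  x <- trait[tree$tip.label]
  if (anyNA(x)) stopf("missing (NA) trait states are not allowed")
  if (is.logical(x)) x <- as.integer(x)
  if (is.character(x) || is.factor(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) > 2)
      stopf("binary trait has %d states: %s", length(lev),
            paste(lev, collapse = ", "))
    x <- as.integer(as.character(x) == lev[length(lev)])
  }
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) stopf("binary trait must be coded 0/1")
  x
}

#' Fritz and Purvis' D statistic for binary traits
#'
#' Measures phylogenetic signal in a binary trait (e.g. pollination mode,
#' biotic vs abiotic) by scaling the observed sister-clade difference sum
#' \eqn{d_{obs}} (see [sister_diff_sum()]) between the means of two null
#' distributions:
#' \deqn{D = (d_{obs} - \bar d_{Brownian}) / (\bar d_{random} - \bar d_{Brownian}).}
#' D = 1 indicates a trait distributed randomly over the tips; D = 0 a trait
#' consistent with a Brownian threshold model. Values significantly below 0
#' indicate strong phylogenetic conservatism, values above 1 phylogenetic
#' overdispersion.
#'
#' The random null permutes the observed states across tips (prevalence
#' preserved). The Brownian null simulates Brownian motion along the tree's
#' branch lengths and thresholds each simulation so that the number of
#' 1-tips matches the observed prevalence (ties broken by seeded uniform
#' jitter). Significance against each null is the two-tailed permutation
#' p-value \eqn{2\min(p_{lower}, p_{upper})} with \eqn{(r+1)/(n+1)} tail
#' ranks.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named binary trait (0/1, logical, or two-level factor; for
#'   character input the alphabetically later level is coded 1). Both states
#'   must be present.
#' @param n_perm Permutations / simulations per null (default 1000).
#' @param seed Integer seed; fixed seed gives identical results.
#' @return Object of class `d_stat`: `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `p_random`, `p_brownian`, `prevalence`,
#'   `n_tips`, `n_perm`, `seed`, `degenerate`.
#' @examples
#' tr <- sim_yule_tree(20, seed = 7)
#' trait <- threshold_binarize(sim_brownian_trait(tr, seed = 8), k = 10)
#' d_statistic(tr, trait, n_perm = 199, seed = 9)
#' @export
d_statistic <- function(tree, trait, n_perm = 1000L, seed = NULL) {
  tree <- validate_tree(tree)
  if (n_perm < 99) stopf("n_perm must be at least 99")
  x <- .as_binary_trait(tree, trait)
  n <- length(x)
  k <- as.integer(sum(x))
  if (k == 0L || k == n)
    stopf("binary trait must have both states present (prevalence %d/%d)", k, n)
  M <- .sister_diff_operator(tree)
  d_obs <- sum(abs(M %*% x))
  nulls <- with_seed(seed, {
    Xr <- vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
    d_rand <- colSums(abs(M %*% Xr))
    Z <- .bm_tip_matrix(tree, sigma2 = 1, n_sim = n_perm)
    Xb <- apply(Z, 2, .threshold_topk, k = k)
    d_brown <- colSums(abs(M %*% Xb))
    list(rand = d_rand, brown = d_brown)
  })
  mean_r <- mean(nulls$rand)
  mean_b <- mean(nulls$brown)
  degenerate <- isTRUE(all.equal(mean_r, mean_b))
  two_tailed <- function(null) {
    p_lo <- (sum(null <= d_obs) + 1) / (n_perm + 1)
    p_hi <- (sum(null >= d_obs) + 1) / (n_perm + 1)
    min(1, 2 * min(p_lo, p_hi))
  }
  structure(list(
    d_obs = d_obs,
    mean_d_random = mean_r,
    mean_d_brownian = mean_b,
    D = if (degenerate) NA_real_ else (d_obs - mean_b) / (mean_r - mean_b),
    p_random = two_tailed(nulls$rand),
    p_brownian = two_tailed(nulls$brown),
    prevalence = k,
    n_tips = n,
    n_perm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    degenerate = degenerate
  ), class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("Fritz & Purvis' D (prevalence %d/%d, %d permutations)\n",
              x$prevalence, x$n_tips, x$n_perm))
  cat(sprintf("  d_obs %.4f; null means: random %.4f, Brownian %.4f\n",
              x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("  D = %s   P(random) = %.4g   P(Brownian) = %.4g%s\n",
              ifelse(x$degenerate, "NA", sprintf("%.3f", x$D)),
              x$p_random, x$p_brownian,
              if (x$degenerate) "  [degenerate nulls]" else ""))
  invisible(x)
}
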