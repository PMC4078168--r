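# Minimum-change parsimony scores for a matrix of tip-state columns.
# Hartigan's generalization of the Fitch down-pass: at each internal node,
# count for every state how many children admit it; with K the maximum count
# the node contributes (n_children - K) changes and keeps the argmax states.
# On binary trees this reduces to Fitch; at polytomies it preserves the true
# minimum. State sets are bitmasks so all columns advance in one vector op.
.parsimony_steps_matrix <- function(tree, smat, n_states) {
  topo <- .tree_topology(tree)
  m <- ncol(smat)
  masks <- matrix(0L, topo$n_tip + topo$n_node, m)
  masks[seq_len(topo$n_tip), ] <- bitwShiftL(1L, smat - 1L)
  bits <- bitwShiftL(1L, seq_len(n_states) - 1L)
  steps <- integer(m)
  for (j in seq_along(topo$internal)) {
    kids <- topo$children[[j]]
    cnt <- vector("list", n_states)
    K <- integer(m)
    for (s in seq_len(n_states)) {
      cs <- integer(m)
      for (k in kids) cs <- cs + as.integer(bitwAnd(masks[k, ], bits[s]) > 0L)
      cnt[[s]] <- cs
      K <- pmax(K, cs)
    }
    steps <- steps + (length(kids) - K)
    mv <- integer(m)
    for (s in seq_len(n_states))
      mv <- mv + bits[s] * as.integer(cnt[[s]] == K)
    masks[topo$internal[j], ] <- mv
  }
  steps
}

# Align a named tip-state vector to tree$tip.label and code as integers 1..S.
.align_states <- function(tree, states) {
  tips <- tree$tip.label
  if (is.null(names(states)))
    stopf("tip states must be a named vector (names = tip labels)")
  names(states) <- trimws(names(states))
  missing <- setdiff(tips, names(states))
  if (length(missing))
    stopf("no trait state for tip(s): %s", paste(missing, collapse = ", "))
  x <- states[tips]
  if (anyNA(x)) stopf("missing (NA) trait states are not allowed")
  f <- factor(as.character(unlist(x)))
  list(code = as.integer(f), levels = levels(f))
}

#' Minimum number of character-state transitions (parsimony score)
#'
#' The minimum number of state changes needed to explain the observed tip
#' states of an unordered categorical character on the given rooted tree.
#' Branch lengths are ignored. Computed by the Fitch down-pass, generalized
#' to multifurcating nodes via Hartigan's algorithm so the count remains the
#' true minimum at polytomies.
#'
#' @param tree A `phylo` object (branch lengths not required).
#' @param states Named vector (names = tip labels) of categorical states.
#' @return Integer minimum number of transitions; 0 iff the trait is constant.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' parsimony_steps(tr, c(A = "x", B = "x", C = "y", D = "y")) # 1
#' @export
parsimony_steps <- function(tree, states) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  al <- .align_states(tree, states)
  .parsimony_steps_matrix(tree, matrix(al$code, ncol = 1), length(al$levels))
}

#' Parsimony-score permutation test of phylogenetic signal
#'
#' Tests whether a multistate trait (e.g. browse type: woody, broadleaf forb,
#' fern, grass, sedge, lycopod) is phylogenetically conserved: the observed
#' parsimony score is compared with a null distribution of scores obtained by
#' permuting the tip states across all tips (the state multiset is
#' preserved). Following the permutation estimate of the Type I error rate,
#' \deqn{p = (\#\{null \le observed\} + 1) / (n_{perm} + 1),}
#' small p means fewer transitions than expected under no phylogenetic
#' effect, i.e. phylogenetic clustering of the trait.
#'
#' A constant trait is degenerate: the observed score and every permuted
#' score are 0, so p = 1 and the result is flagged.
#'
#' @param tree A `phylo` object.
#' @param states Named vector of categorical tip states.
#' @param n_perm Number of tip-state permutations (default 1000).
#' @param seed Integer seed; fixed seed gives identical results.
#' @return Object of class `parsimony_signal`: `observed_steps`, `null_mean`,
#'   `null_ci` (2.5 % and 97.5 % quantiles of the null scores), `p_value`,
#'   `n_perm`, `seed`, `degenerate`.
#' @export
parsimony_signal_test <- function(tree, states, n_perm = 1000L, seed = NULL) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  if (n_perm < 99) stopf("n_perm must be at least 99")
  al <- .align_states(tree, states)
  n <- length(al$code)
  obs <- .parsimony_steps_matrix(tree, matrix(al$code, ncol = 1),
                                 length(al$levels))
  null_scores <- with_seed(seed, {
    X <- vapply(seq_len(n_perm), function(i) al$code[sample.int(n)], integer(n))
    .parsimony_steps_matrix(tree, X, length(al$levels))
  })
  structure(list(
    observed_steps = obs,
    null_mean = mean(null_scores),
    null_ci = stats::quantile(null_scores, c(0.025, 0.975), type = 1,
                              names = FALSE),
    p_value = (sum(null_scores <= obs) + 1) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    degenerate = obs == 0L
  ), class = "parsimony_signal")
}

#' @export
print.parsimony_signal <- function(x, ...) {
  cat(sprintf("Parsimony signal test (%d permutations of tip states)\n",
              x$n_perm))
  cat(sprintf("  observed steps %d; null mean %.1f (95%% CI [%g, %g])\n",
              x$observed_steps, x$null_mean, x$null_ci[1], x$null_ci[2]))
  cat(sprintf("  P = %.4g%s\n", x$p_value,
              if (x$degenerate) "  [degenerate: constant trait]" else ""))
  invisible(x)
}
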