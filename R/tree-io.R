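#' Read and validate a rooted Newick tree
#'
#' Parses a single Newick tree (from a string or a file) into an [ape]
#' `phylo` object and validates it for downstream community-phylogenetic use:
#' the tree must be rooted, tip labels must be unique and non-empty (labels
#' are trimmed of surrounding whitespace; matching against community and trait
#' tables is exact and case-sensitive), and, unless `require_lengths = FALSE`,
#' every edge must carry a non-negative branch length.
#'
#' A light structural pre-scan reports the character offset of the first
#' unbalanced parenthesis before handing the text to the parser, and the text
#' must end with the customary semicolon.
#'
#' Ultrametricity is checked with relative tolerance `1e-6` and reported as a
#' warning only: the distance-based metrics do not require an ultrametric
#' tree, but chronogram inputs are expected to be ultrametric, so a failure
#' usually signals a data problem.
#'
#' @param text Newick string (exactly one tree, trailing `;`).
#' @param file Path to a Newick file; exactly one of `text`/`file`.
#' @param require_lengths Require branch lengths on every edge (default TRUE).
#' @param min_tips Minimum tip count accepted (default 2).
#' @return A validated `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' patristic_matrix(tr)
#' @seealso [write_newick()], [patristic_matrix()], [prune_tree()]
#' @export
read_newick <- function(text = NULL, file = NULL, require_lengths = TRUE,
                        min_tips = 2L) {
  if (is.null(text) == is.null(file))
    stopf("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stopf("Newick parse failed")
  if (inherits(tree, "multiPhylo"))
    stopf("expected a single Newick tree, found %d", length(tree))
  validate_tree(tree, require_lengths = require_lengths, min_tips = min_tips,
                warn_ultrametric = TRUE)
}

.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("malformed Newick: unmatched ')' at character %d", i)
    }
  }
  if (depth > 0L)
    stopf("malformed Newick: %d unclosed '(' at end of input", depth)
  if (!grepl(";\\s*$", text))
    stopf("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

#' Validate a phylogeny for community-phylogenetic analysis
#'
#' @param tree A `phylo` object.
#' @param require_lengths Require non-negative branch lengths on all edges.
#' @param min_tips Minimum number of tips.
#' @param warn_ultrametric Emit the ultrametricity warning (used at the I/O
#'   boundary; internal revalidation stays quiet).
#' @return The tree, invisibly usable, with whitespace-trimmed tip labels.
#' @export
validate_tree <- function(tree, require_lengths = TRUE, min_tips = 2L,
                          warn_ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stopf("`tree` must be a `phylo` object")
  tree$tip.label <- trimws(tree$tip.label)
  n <- length(tree$tip.label)
  if (n < min_tips) stopf("tree has %d tips; at least %d required", n, min_tips)
  if (any(!nzchar(tree$tip.label))) stopf("empty tip labels are not allowed")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stopf("duplicate tip label(s): %s", paste(dup, collapse = ", "))
  # the basal node is taken as the root as given; a basal polytomy is a
  # legitimate multifurcating root here, so we check structure (exactly one
  # parentless node) rather than ape's rooted/unrooted convention
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, tree$edge[, 2])
  if (length(roots) != 1L) stopf("tree must have exactly one root")
  if (require_lengths) {
    if (is.null(tree$edge.length))
      stopf("tree has no branch lengths; they are required here")
    if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
      stopf("branch lengths must all be non-negative and non-missing")
    if (warn_ultrametric && !ape::is.ultrametric(tree, tol = 1e-6, option = 2))
      warnf("tree is not ultrametric (relative tolerance 1e-6)")
  }
  tree
}

#' Write a tree as Newick
#'
#' Branch lengths are formatted with 12 significant digits, enough for
#' parse-write round trips to preserve path lengths to numerical identity.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(tree, file = NULL, digits = 12L) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Patristic (cophenetic) distance matrix
#'
#' Pairwise tip-to-tip distances, each the sum of branch lengths along the
#' path connecting two tips; the substrate for mean pairwise distance and the
#' net relatedness index. Rows and columns follow `tree$tip.label` order.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Prune a tree to a set of tips
#'
#' Returns the induced subtree on `keep`: dropped tips are removed, resulting
#' degree-two internal nodes are collapsed and their branch lengths summed,
#' so patristic distances among retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  tree <- validate_tree(tree, require_lengths = FALSE)
  keep <- unique(trimws(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stopf("tip label(s) not in tree: %s", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stopf("`keep` must contain at least 2 tips")
  ape::keep.tip(tree, keep)
}

# children-before-parents traversal bundle reused by the parsimony and
# sister-difference engines
.tree_topology <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")$edge
  internal <- unique(po[, 1]) # postorder: every child row precedes its parent's
  children <- split(po[, 2], factor(po[, 1], levels = internal))
  list(n_tip = length(tree$tip.label), n_node = tree$Nnode,
       internal = internal, children = unname(children))
}
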