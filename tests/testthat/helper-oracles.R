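# Independent brute-force oracles and fixture builders used across tests.
# Each oracle re-derives its quantity by a different route than the package
# implementation (explicit path walks, exhaustive enumeration, plain
# recursion), so agreement is evidence and not tautology.

# patristic distances by explicit node-to-root path walks
oracle_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  edge <- tree$edge
  eidx <- integer(nt + tree$Nnode)
  eidx[edge[, 2]] <- seq_len(nrow(edge))
  root_path <- function(v) { # vector of edge indices from v up to root
    p <- integer(0)
    while (v != root) {
      e <- eidx[v]
      p <- c(p, e)
      v <- edge[e, 1]
    }
    p
  }
  paths <- lapply(seq_len(nt), root_path)
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) for (j in seq((i + 1), nt)) {
    sym <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    d[i, j] <- d[j, i] <- sum(tree$edge.length[sym])
  }
  d
}

# MPD by a plain double loop over unordered pairs
oracle_mpd <- function(members, dist) {
  members <- unique(members)
  tot <- 0
  np <- 0
  for (i in seq_len(length(members) - 1))
    for (j in seq((i + 1), length(members))) {
      tot <- tot + dist[members[i], members[j]]
      np <- np + 1
    }
  tot / np
}

# minimum parsimony steps by exhaustive enumeration of internal-node states
oracle_parsimony <- function(tree, states_int, n_states) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)), nn)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    full <- c(states_int, grid[r, ])
    best <- min(best, sum(full[edge[, 1]] != full[edge[, 2]]))
  }
  as.integer(best)
}

# sister-clade difference sum by straightforward recursion
oracle_sister_diff <- function(tree, values) {
  nt <- length(tree$tip.label)
  kids <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  total <- 0
  nodeval <- function(v) {
    if (v <= nt) return(values[[tree$tip.label[v]]])
    vals <- vapply(kids[[v]], nodeval, numeric(1))
    for (a in seq_len(length(vals) - 1))
      for (b in seq((a + 1), length(vals)))
        total <<- total + abs(vals[a] - vals[b])
    mean(vals)
  }
  nodeval(nt + 1L)
  total
}

# balanced binary tree on 2^h tips with unit branch lengths
balanced_tree <- function(h) {
  build <- function(depth) {
    if (depth == 0) return("X")
    paste0("(", build(depth - 1), ":1,", build(depth - 1), ":1)")
  }
  txt <- paste0(build(h), ";")
  n <- 2^h
  for (i in seq_len(n)) txt <- sub("X", paste0("t", i), txt, fixed = TRUE)
  read_newick(txt)
}

# two deep clades of `m` tips each, joined by long stems: strong split
two_clade_tree <- function(m, stem = 10) {
  clade <- function(prefix) {
    tr <- sim_yule_tree(m, seed = NULL)
    txt <- write_newick(tr)
    gsub("sp", prefix, txt)
  }
  a <- sub(";$", "", clade("a"))
  b <- sub(";$", "", clade("b"))
  # the two clades have independent depths, so the fixture is deliberately
  # non-ultrametric; the reader's warning is expected
  suppressWarnings(read_newick(sprintf("(%s:%g,%s:%g);", a, stem, b, stem)))
}

# compact cover-panel builder: `entries` is a data.frame with plot, site,
# treatment, year, species, cover columns in that order
make_panel <- function(...) {
  df <- data.frame(...)
  names(df) <- c("plot_id", "site_id", "treatment", "year", "species",
                 "cover_pct")[seq_along(df)]
  cover_panel(df)
}

# the standard toy design: 4 paired sites, exclosure plots e1..e4 and
# control plots c1..c4
toy_design <- function(years) {
  expand.grid(plot = c(paste0("e", 1:4), paste0("c", 1:4)), year = years,
              stringsAsFactors = FALSE)
}
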