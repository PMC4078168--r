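test_that("Yule trees are ultrametric with the right shape", {
  tr2 <- sim_yule_tree(2, seed = 91)
  expect_equal(length(tr2$tip.label), 2)
  expect_true(ape::is.ultrametric(tr2, tol = 1e-10))
  expect_true(all(tr2$edge.length > 0))

  tr50 <- sim_yule_tree(50, seed = 92)
  expect_equal(length(tr50$tip.label), 50)
  expect_true(ape::is.ultrametric(tr50, tol = 1e-10))
  expect_identical(tr50$tip.label, sprintf("sp%04d", 1:50))
  expect_identical(write_newick(sim_yule_tree(50, seed = 92)),
                   write_newick(tr50))
})

test_that("Yule waiting times follow the analytic pure-birth expectation", {
  # with k lineages the next split waits Exp(k * birth_rate), so the time
  # from the 2-lineage crown to the (n-1)th split has mean
  # sum_{k=2}^{n-1} 1/(k * birth_rate)
  n <- 20
  rate <- 1.5
  set.seed(93)
  times <- replicate(500, {
    tr <- sim_yule_tree(n, birth_rate = rate, seed = sample.int(1e6, 1))
    depths <- ape::node.depth.edgelength(tr)
    total <- depths[1] # ultrametric: tip depth = crown-to-present time
    internal <- depths[(n + 1):(2 * n - 1)]
    max(internal) # time of the last split, measured from the crown
  })
  expected <- sum(1 / (rate * (2:(n - 1))))
  expect_lt(abs(mean(times) - expected), 2 * sd(times) / sqrt(length(times)))
})

test_that("Brownian traits have the closed-form moments", {
  cherry <- read_newick("(A:3,B:3);")
  expect_equal(unname(sim_brownian_trait(cherry, sigma2 = 0, seed = 94)),
               c(0, 0))

  m <- sim_brownian_traits(cherry, sigma2 = 2, n_sim = 10000, seed = 95)
  dif <- m["A", ] - m["B", ]
  expect_equal(var(dif), 2 * 2 * 3, tolerance = 0.05)

  # shared-path covariance: A and B share the 2-unit stem of their clade
  tr <- read_newick("((A:1,B:1):2,C:3);")
  m2 <- sim_brownian_traits(tr, sigma2 = 1, n_sim = 10000, seed = 96)
  expect_equal(cov(m2["A", ], m2["B", ]), 2, tolerance = 0.05)
  expect_equal(var(m2["A", ]), 3, tolerance = 0.05)
  expect_lt(abs(cov(m2["A", ], m2["C", ])), 0.1)
})

test_that("thresholding fixes prevalence exactly and jitters ties", {
  vals <- setNames(c(5, 4, 3, 2, 1), paste0("s", 1:5))
  expect_equal(sum(threshold_binarize(vals, 1)), 1)
  expect_equal(unname(threshold_binarize(vals, 2)), c(1, 1, 0, 0, 0))
  expect_error(threshold_binarize(vals, 5), "0 < k < 5")
  expect_error(threshold_binarize(vals, 0), "0 < k < 5")

  set.seed(110)
  ties <- setNames(rep(1, 6), paste0("s", 1:6))
  picks <- replicate(50, paste(which(threshold_binarize(ties, 3) == 1),
                               collapse = ","))
  expect_true(all(replicate(10, sum(threshold_binarize(ties, 3))) == 3))
  expect_gt(length(unique(picks)), 1) # ties broken at random, not by index
})

test_that("Mk traits are constant at rate 0 and near-uniform at high rate", {
  yt <- sim_yule_tree(40, seed = 97)
  const <- sim_mk_trait(yt, n_states = 4, rate = 0, seed = 98)
  expect_equal(length(unique(const)), 1)
  expect_equal(parsimony_steps(yt, const), 0)

  fast <- replicate(50, sim_mk_trait(yt, n_states = 3, rate = 50,
                                     seed = sample.int(1e6, 1)))
  freq <- table(factor(fast, levels = 1:3)) / length(fast)
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("low-rate Mk traits on a deep split carry detectable signal", {
  set.seed(99)
  hits <- 0
  for (i in 1:60) {
    tr <- two_clade_tree(8, stem = 20)
    trait <- sim_mk_trait(tr, n_states = 3, rate = 0.02,
                          seed = sample.int(1e6, 1))
    if (length(unique(trait)) < 2) next # constant draw carries no signal
    p <- parsimony_signal_test(tr, trait, n_perm = 199,
                               seed = sample.int(1e6, 1))$p_value
    hits <- hits + (p <= 0.05)
  }
  expect_gt(hits / 60, 0.5)
})

test_that("community simulation is deterministic and round-trips cover", {
  yt <- sim_yule_tree(25, seed = 100)
  trait <- threshold_binarize(sim_brownian_trait(yt, seed = 101), k = 12)
  ret <- c(`0` = 1, `1` = 0.2)
  s1 <- sim_browse_panel(yt, trait, ret, years = c(2006, 2008), seed = 102)
  s2 <- sim_browse_panel(yt, trait, ret, years = c(2006, 2008), seed = 102)
  expect_identical(s1, s2)

  # records -> cover -> target round trip within the 1 cm granularity bound
  got <- merge(as.data.frame(s1$panel), s1$targets,
               by = c("plot_id", "year", "species"))
  expect_equal(nrow(got), nrow(s1$targets))
  expect_true(all(abs(got$cover_pct - got$target_pct) <= 100 / 1500))

  # every record respects the transect geometry
  expect_true(all(s1$records$intercept_cm >= 1))
  expect_true(all(s1$records$intercept_cm <= 500))
  expect_true(all(s1$records$transect_id %in% 1:3))
})

test_that("a null filter leaves browsed and unbrowsed plots exchangeable", {
  yt <- sim_yule_tree(20, seed = 103)
  trait <- setNames(rep("x", 20), yt$tip.label)
  set.seed(104)
  diffs <- replicate(200, {
    sim <- sim_browse_panel(yt, trait, retention = 1, years = 2006,
                            occupancy = 0.5, seed = sample.int(1e6, 1))
    div <- diversity_by_plot(sim$panel)
    mean(div$richness[div$treatment == "exclosure"]) -
      mean(div$richness[div$treatment == "control"])
  })
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("lowering retention cannot raise browsed cover of that state", {
  yt <- sim_yule_tree(30, seed = 105)
  trait <- threshold_binarize(sim_brownian_trait(yt, seed = 106), k = 15)
  target <- names(trait)[trait == 1]
  pooled_state_cover <- function(retention, seed) {
    sim <- sim_browse_panel(yt, trait, c(`0` = 1, `1` = retention),
                            years = 2006, occupancy = 0.6, seed = seed)
    pc <- pooled_cover(sim$panel, "control", 2006,
                       expected_plots = paste0("site", 1:4, "-cont"))
    sum(pc[names(pc) %in% target])
  }
  set.seed(107)
  seeds <- sample.int(1e6, 30)
  grid <- vapply(c(1, 0.6, 0.2),
                 function(r) mean(vapply(seeds, function(s)
                   pooled_state_cover(r, s), numeric(1))), numeric(1))
  expect_true(all(diff(grid) < 0))
})

test_that("cover-reduction browsing mode shrinks control cover instead", {
  yt <- sim_yule_tree(15, seed = 108)
  trait <- setNames(rep("x", 15), yt$tip.label)
  sim <- sim_browse_panel(yt, trait, retention = 0.3, years = 2006,
                          occupancy = 0.9, browse_mode = "cover", seed = 109)
  pan <- sim$panel
  me <- mean(pan$cover_pct[pan$treatment == "exclosure"])
  mc <- mean(pan$cover_pct[pan$treatment == "control"])
  expect_lt(mc, me)
})
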