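# builds the standard 4-site paired design panel from a cover function
# cover_fn(plot, treatment, year, species) -> percent cover (0 = absent)
design_panel <- function(species, years, cover_fn) {
  rows <- list()
  for (y in years) for (s in 1:4) for (tr in c("exclosure", "control")) {
    plot <- paste0(ifelse(tr == "exclosure", "e", "c"), s)
    for (sp in species) {
      cv <- cover_fn(plot, tr, y, sp)
      if (cv > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          plot_id = plot, site_id = paste0("s", s), treatment = tr,
          year = y, species = sp, cover_pct = cv)
    }
  }
  cover_panel(do.call(rbind, rows))
}

test_that("DBSI hits its endpoints for exclosure-only and control-only species", {
  pan <- design_panel(c("inside", "outside", "both"), c(2006, 2008),
    function(plot, tr, y, sp) {
      if (sp == "inside") return(if (tr == "exclosure") 3 else 0)
      if (sp == "outside") return(if (tr == "control") 2 else 0)
      1.5
    })
  py <- dbsi_per_year(pan)
  expect_equal(py$dbsi[py$species == "inside"], c(1, 1))
  expect_equal(py$dbsi[py$species == "outside"], c(0, 0))
  expect_equal(py$dbsi[py$species == "both"], c(0.5, 0.5))

  tab <- mean_dbsi(pan)
  expect_equal(tab$mean_dbsi[tab$species == "inside"], 1)
  expect_equal(tab$mean_dbsi[tab$species == "outside"], 0)
  expect_true(all(tab$included))
  # ascending susceptibility ordering
  expect_equal(tab$species, c("outside", "both", "inside"))
})

test_that("per-year DBSI follows the cover-sum ratio", {
  pan <- design_panel("sp", 2006, function(plot, tr, y, sp)
    if (plot == "e1") 3 else if (plot == "c1") 1 else 0)
  py <- dbsi_per_year(pan)
  expect_equal(py$sum_ce, 3)
  expect_equal(py$sum_cc, 1)
  expect_equal(py$dbsi, 0.75)
})

test_that("species absent from both treatments in a year are undefined, not zero", {
  pan <- design_panel(c("sp", "filler"), c(2006, 2008),
    function(plot, tr, y, sp) {
      if (sp == "filler") return(1)
      if (y == 2006 && plot %in% c("e1", "e2")) return(2)
      0
    })
  py <- dbsi_per_year(pan)
  expect_equal(py$dbsi[py$species == "sp" & py$year == 2006], 1)
  expect_true(is.na(py$dbsi[py$species == "sp" & py$year == 2008]))
  tab <- mean_dbsi(pan, plot_threshold = 1, year_threshold = 1)
  expect_equal(tab$mean_dbsi[tab$species == "sp"], 1) # NA year excluded
  expect_equal(tab$n_years_defined[tab$species == "sp"], 1)
})

test_that("the rarity filter keeps widespread species only", {
  # in 3 exclosure plots in 2006 and 2008 -> included under the defaults
  pan <- design_panel(c("wide", "rare"), c(2006, 2008),
    function(plot, tr, y, sp) {
      if (sp == "wide" && plot %in% c("e1", "e2", "e3")) return(1)
      if (sp == "rare" && plot == "c1") return(1)
      0
    })
  expect_equal(rarity_filter(pan), "wide")
  # one plot every year is never enough at plot_threshold = 2
  expect_equal(rarity_filter(pan, plot_threshold = 1), c("rare", "wide"))
  # a widespread single year fails year_threshold = 2
  pan1 <- design_panel("once", 2006, function(plot, tr, y, sp) 1)
  expect_equal(rarity_filter(pan1), character(0))
  expect_equal(rarity_filter(pan1, year_threshold = 1), "once")
})

test_that("rarity filter matches an independent plot-year recount", {
  set.seed(81)
  for (rep in 1:10) {
    species <- paste0("sp", 1:12)
    years <- c(2006, 2008, 2009)
    occ <- array(runif(8 * length(species) * length(years)) < 0.3,
                 dim = c(8, length(species), length(years)))
    plots <- c(paste0("e", 1:4), paste0("c", 1:4))
    pan <- design_panel(species, years, function(plot, tr, y, sp)
      if (occ[match(plot, plots), match(sp, species), match(y, years)])
        round(runif(1, 0.5, 5), 1) else 0)
    got <- rarity_filter(pan)
    manual <- character(0)
    for (sp in species) {
      good_years <- 0
      for (y in years)
        if (sum(occ[, match(sp, species), match(y, years)]) >= 2)
          good_years <- good_years + 1
      if (good_years >= 2) manual <- c(manual, sp)
    }
    expect_setequal(got, manual)
  }
})

test_that("mean DBSI equals brute-force recomputation on random panels", {
  set.seed(82)
  for (rep in 1:5) {
    species <- paste0("sp", 1:8)
    years <- c(2006, 2008)
    cov <- array(round(runif(8 * 8 * 2, 0, 4), 2) *
                   (runif(8 * 8 * 2) < 0.5), dim = c(8, 8, 2))
    plots <- c(paste0("e", 1:4), paste0("c", 1:4))
    pan <- design_panel(species, years, function(plot, tr, y, sp)
      cov[match(plot, plots), match(sp, species), match(y, years)])
    tab <- mean_dbsi(pan, include_all = TRUE)
    for (i in seq_len(nrow(tab))) {
      sp <- tab$species[i]
      vals <- c()
      for (y in years) {
        ce <- sum(cov[1:4, match(sp, species), match(y, years)])
        cc <- sum(cov[5:8, match(sp, species), match(y, years)])
        if (ce + cc > 0) vals <- c(vals, ce / (ce + cc))
      }
      expect_equal(tab$mean_dbsi[i], mean(vals))
      expect_equal(tab$n_years_defined[i], length(vals))
    }
  }
})

test_that("DBSI is scale-invariant, bounded and complement-symmetric", {
  set.seed(83)
  species <- paste0("sp", 1:6)
  years <- c(2006, 2008)
  cov <- array(round(runif(8 * 6 * 2, 0, 4), 2) *
                 (runif(8 * 6 * 2) < 0.6), dim = c(8, 6, 2))
  plots <- c(paste0("e", 1:4), paste0("c", 1:4))
  pan <- design_panel(species, years, function(plot, tr, y, sp)
    cov[match(plot, plots), match(sp, species), match(y, years)])
  py <- dbsi_per_year(pan)
  expect_true(all(py$dbsi >= 0 & py$dbsi <= 1, na.rm = TRUE))
  expect_true(all((py$dbsi == 1) == (py$sum_cc == 0 & py$sum_ce > 0),
                  na.rm = TRUE))

  # multiplying every cover in a year by a constant changes nothing
  pan_scaled <- design_panel(species, years, function(plot, tr, y, sp) {
    k <- if (y == 2006) 7 else 0.1
    k * cov[match(plot, plots), match(sp, species), match(y, years)]
  })
  expect_equal(dbsi_per_year(pan_scaled)$dbsi, py$dbsi)

  # swapping treatment labels maps DBSI to 1 - DBSI
  pan_swap <- design_panel(species, years, function(plot, tr, y, sp) {
    mirror <- chartr("ec", "ce", plot)
    cov[match(mirror, plots), match(sp, species), match(y, years)]
  })
  expect_equal(dbsi_per_year(pan_swap)$dbsi, 1 - py$dbsi)
})
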