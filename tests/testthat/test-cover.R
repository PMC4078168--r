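rec_row <- function(plot, tr, year, transect, sp, cm,
                    site = sub("^[ec]", "s", plot)) {
  data.frame(plot_id = plot, site_id = site, treatment = tr, year = year,
             transect_id = transect, species = sp, intercept_cm = cm)
}

test_that("line-intercept cover follows the sum(n_i)/1500 rule", {
  rec <- rec_row("e1", "exclosure", 2006, c(1, 1), "A", c(100, 50))
  pan <- compute_cover(rec)
  expect_equal(pan$cover_pct[pan$species == "A"], 10)

  # a species with no records simply has no positive cover
  expect_equal(plot_cover(pan, "e1", 2006)[["A"]], 10)
  expect_false("B" %in% pan$species)

  # two species can each reach 100 %: plot total 200 % is legal
  rec2 <- rbind(rec_row("e1", "exclosure", 2006, 1:3, "A", rep(500, 3)),
                rec_row("e1", "exclosure", 2006, 1:3, "B", rep(500, 3)))
  pan2 <- compute_cover(rec2)
  expect_equal(sort(pan2$cover_pct), c(100, 100))
  expect_equal(sum(pan2$cover_pct), 200)
})

test_that("cover validation catches impossible records", {
  expect_error(compute_cover(rec_row("e1", "exclosure", 2006, 1, "A", 0)),
               "positive integers")
  expect_error(compute_cover(rec_row("e1", "exclosure", 2006, 1, "A", 2.5)),
               "positive integers")
  # one species cannot intercept more than one transect's 500 cm
  expect_error(
    compute_cover(rec_row("e1", "exclosure", 2006, c(1, 1), "A", c(400, 200))),
    "transect 1")
  expect_error(compute_cover(rec_row("e1", "exclosure", 2006, 4, "A", 10)),
               "transect_id")
})

test_that("cover is linear in intercept lengths", {
  set.seed(11)
  rec <- do.call(rbind, lapply(1:20, function(i)
    rec_row("e1", "exclosure", 2006, sample(3, 1), paste0("sp", sample(8, 1)),
            sample(50, 1))))
  rec <- rec[!duplicated(rec[c("transect_id", "species")]), ]
  p1 <- compute_cover(rec)
  rec2 <- rec
  rec2$intercept_cm <- 2L * rec2$intercept_cm
  p2 <- compute_cover(rec2)
  m <- merge(p1, p2, by = c("plot_id", "year", "species"))
  expect_equal(m$cover_pct.y, 2 * m$cover_pct.x)
})

test_that("treatment pooling equals sum(n_i)/6000 and the per-plot mean", {
  plots <- paste0("e", 1:4)
  rec <- rbind(rec_row("e1", "exclosure", 2006, 1, "A", 150),
               rec_row("e2", "exclosure", 2006, 1, "B", 30),
               rec_row("e3", "exclosure", 2006, 2, "B", 60),
               rec_row("e4", "exclosure", 2006, 3, "A", 300))
  pan <- compute_cover(rec)
  pooled <- pooled_cover(pan, "exclosure", 2006, expected_plots = plots)
  # independent re-summation straight from the raw lengths
  expect_equal(pooled[["A"]], 100 * (150 + 300) / 6000)
  expect_equal(pooled[["B"]], 100 * (30 + 60) / 6000)

  # per-plot covers 10, 0, 0, 0 pool to 2.5
  rec1 <- rec_row("e1", "exclosure", 2006, c(1, 1), "A", c(100, 50))
  empty <- do.call(rbind, lapply(paste0("e", 2:4), function(p)
    rec_row(p, "exclosure", 2006, 1, "Z", 1)))
  pan1 <- compute_cover(rbind(rec1, empty))
  expect_equal(pooled_cover(pan1, "exclosure", 2006)[["A"]], 2.5)

  expect_error(pooled_cover(pan1, "exclosure", 2007), "missing from panel")
  expect_error(
    pooled_cover(pan, "exclosure", 2006,
                 expected_plots = c(plots, "e5")), "e5")
})

test_that("pooled cover matches an independent summation on random panels", {
  set.seed(22)
  for (rep in 1:5) {
    rec <- do.call(rbind, lapply(paste0("c", 1:4), function(p) {
      n <- sample(3:8, 1)
      do.call(rbind, lapply(seq_len(n), function(i)
        rec_row(p, "control", 2006, sample(3, 1),
                paste0("sp", sample(10, 1)), sample(100, 1))))
    }))
    rec <- rec[!duplicated(rec[c("plot_id", "transect_id", "species")]), ]
    pan <- compute_cover(rec)
    pooled <- pooled_cover(pan, "control", 2006,
                           expected_plots = paste0("c", 1:4))
    tp <- tapply(rec$intercept_cm, rec$species, sum) * 100 / 6000
    direct <- setNames(as.numeric(tp), names(tp))
    expect_equal(pooled[sort(names(pooled))], direct[sort(names(pooled))])
  }
})

test_that("cover panel validation enforces metadata consistency and bounds", {
  expect_error(make_panel("p1", "s1", "grazed", 2006, "A", 5), "treatment")
  expect_error(make_panel("p1", "s1", "control", 2006, "A", -1),
               "non-negative")
  expect_error(make_panel("p1", "s1", "control", 2006, "A", 101), "100")
  expect_error(
    make_panel(c("p1", "p1"), c("s1", "s2"), "control", 2006, c("A", "B"),
               c(5, 5)), "inconsistent")
  expect_error(
    make_panel("p1", "s1", "control", 2006, c("A", "A"), c(5, 5)),
    "duplicated")
})

test_that("cover panels and transect records survive CSV round trips", {
  rec <- rbind(rec_row("e1", "exclosure", 2006, 1, "A", 150),
               rec_row("c1", "control", 2006, 2, "B", 75))
  f1 <- tempfile(fileext = ".csv")
  write_transect_records(rec, f1)
  expect_equal(read_transect_records(f1), rec)
  pan <- compute_cover(rec)
  f2 <- tempfile(fileext = ".csv")
  write_cover_panel(pan, f2)
  expect_equal(read_cover_panel(f2), pan)
  m <- cover_matrix(pan, 2006)
  expect_equal(m["e1", "A"], 10)
  expect_equal(m["c1", "A"], 0)
})
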