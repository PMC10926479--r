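stress_from_totals <- function(cold, heat = matrix(0, nrow(cold), ncol(cold))) {
  # build a stress_result directly from year totals (classification tests)
  structure(list(cold_total = cold, heat_total = heat,
                 cold_class = phenorisk:::.classify_stress(cold, 80, 160),
                 heat_class = phenorisk:::.classify_stress(heat, 75, 150),
                 combined_class = pmin(
                   phenorisk:::.classify_stress(cold, 80, 160),
                   phenorisk:::.classify_stress(heat, 75, 150)),
                 year = 2021, xmin = 0, ymax = nrow(cold), cellsize = 1,
                 crs = "synthetic"),
            class = "stress_result")
}

test_that("threshold boundary behavior is strict", {
  s <- stress_from_totals(matrix(c(80, 80.01, 160, 160.01), 2, 2))
  expect_identical(as.vector(s$cold_class), c(0L, -1L, -1L, -2L))
})

test_that("benign weather accumulates no stress", {
  g <- synth_weather(synthetic_weather_config(nrow = 3, ncol = 3, base = 10,
                                              amplitude = 14, noise_sd = 0))
  s <- accumulate_stress(g, species_params())
  expect_true(all(s$cold_total == 0) && all(s$heat_total == 0))
  expect_true(all(s$combined_class == 0L))
})

test_that("stress totals match a direct daily sum and classes follow", {
  # cold north via a strong latitudinal gradient; noise-free for exactness
  g <- synth_weather(synthetic_weather_config(nrow = 4, ncol = 2,
                                              base = -20, amplitude = 25,
                                              gradient = -6, noise_sd = 0,
                                              diurnal_range = 12))
  p <- species_params()
  s <- accumulate_stress(g, p)
  direct <- sum(cold_stress_units(g$tmin[, 1, 1], g$tmax[, 1, 1], -31))
  expect_equal(s$cold_total[1, 1], direct, tolerance = 1e-9)
  expect_identical(s$cold_class,
                   phenorisk:::.classify_stress(s$cold_total, 80, 160))
  expect_identical(s$combined_class, pmin(s$cold_class, s$heat_class))
})

test_that("combined class is the worse of cold and heat", {
  s <- stress_from_totals(matrix(200, 1, 1), matrix(0, 1, 1))
  expect_identical(s$cold_class[1, 1], -2L)
  expect_identical(s$combined_class[1, 1], -2L)
  s2 <- stress_from_totals(matrix(100, 1, 1), matrix(200, 1, 1))
  expect_identical(s2$combined_class[1, 1], -2L)
})

test_that("raising stress limits never worsens a class", {
  set.seed(5)
  totals <- matrix(runif(100, 0, 250), 10, 10)
  c1 <- phenorisk:::.classify_stress(totals, 80, 160)
  c2 <- phenorisk:::.classify_stress(totals, 120, 200)
  expect_true(all(c2 >= c1))
})

test_that("a uniformly warmer year moves stress monotonically", {
  g <- synth_weather(synthetic_weather_config(nrow = 4, ncol = 4,
                                              base = -12, amplitude = 28,
                                              noise_sd = 2, seed = 8))
  gw <- g; gw$tmin <- g$tmin + 2; gw$tmax <- g$tmax + 2
  p <- species_params()
  s <- accumulate_stress(g, p); sw <- accumulate_stress(gw, p)
  expect_true(all(sw$cold_total <= s$cold_total + 1e-9))
  expect_true(all(sw$heat_total >= s$heat_total - 1e-9))
})

test_that("integration applies the four-way legend", {
  g <- synth_weather(synthetic_weather_config(nrow = 2, ncol = 2,
                                              base = 18, noise_sd = 0))
  em <- run_all_cohorts(g, species_params())
  cls <- matrix(c(0, -1, -2, 0), 2, 2)
  s <- stress_from_totals(matrix(c(0, 100, 200, 0), 2, 2))
  integ <- integrate_phenology_suitability(em, s)
  e <- integ$adult_emergence
  expect_equal(e$doy[1, 1], em$first$adult_emergence[1, 1])
  expect_identical(e$status[2, 1], -1L)
  expect_identical(e$status[1, 2], -2L)
  expect_true(is.na(e$doy[2, 1]) && is.na(e$doy[1, 2]))
  # insufficient accumulation in a suitable cell
  cold <- synth_weather(synthetic_weather_config(nrow = 2, ncol = 2,
                                                 base = 11, amplitude = 3,
                                                 noise_sd = 0))
  emc <- run_all_cohorts(cold, species_params())
  sc <- accumulate_stress(cold, species_params())
  ic <- integrate_phenology_suitability(emc, sc)
  expect_true(all(ic$egg_hatch$status == 1L))
  # grid mismatch errors
  expect_error(integrate_phenology_suitability(emc,
    stress_from_totals(matrix(0, 3, 3))), "co-registered")
})

test_that("multi-year agreement counts inclusion years", {
  s0 <- stress_from_totals(matrix(0, 2, 2))
  s1 <- stress_from_totals(matrix(c(100, 0, 0, 0), 2, 2))
  s2 <- stress_from_totals(matrix(200, 2, 2))
  expect_true(all(multi_year_agreement(rep(list(s0), 20)) == 20L))
  agree <- multi_year_agreement(c(rep(list(s0), 19), list(s1)))
  expect_equal(agree[1, 1], 19L)
  expect_equal(agree[2, 2], 20L)
  expect_true(all(multi_year_agreement(rep(list(s2), 3)) == 0L))
})

test_that("presence sensitivity counts records by class and mode", {
  cls_totals <- matrix(0, 5, 5)
  cls_totals[1, 1] <- 200   # severe cell at row 1, col 1
  cls_totals[2, 2] <- 100   # moderate cell
  s <- stress_from_totals(cls_totals)
  # 50 records in class-0 cells -> sensitivity 1
  set.seed(2)
  lon <- runif(50, 2, 5); lat <- runif(50, 0, 3)
  ps <- presence_sensitivity(lon, lat, s)
  expect_equal(ps$sensitivity, 1)
  # 1 of 10 in the severe cell
  lon10 <- c(rep(3.5, 9), 0.5); lat10 <- c(rep(1.5, 9), 4.5)
  ps10 <- presence_sensitivity(lon10, lat10, s)
  expect_equal(ps10$sensitivity, 0.9)
  expect_false(ps10$records$included[10])
  # moderate cell: excluded under both-levels, included under severe-only
  pm <- presence_sensitivity(1.5, 3.5, s)
  expect_equal(pm$sensitivity, 0)
  pm2 <- presence_sensitivity(1.5, 3.5, s, mode = "severe-only")
  expect_equal(pm2$sensitivity, 1)
  # outside-extent records reported, empty list errors
  po <- presence_sensitivity(c(3.5, 99), c(1.5, 99), s)
  expect_equal(po$n_outside, 1)
  expect_equal(po$n_records, 1)
  expect_error(presence_sensitivity(numeric(0), numeric(0), s), "empty")
})

test_that("classification is invariant to day order", {
  g <- synth_weather(synthetic_weather_config(nrow = 2, ncol = 2,
                                              base = -15, amplitude = 25,
                                              noise_sd = 3, seed = 13))
  p <- species_params()
  s <- accumulate_stress(g, p)
  perm <- sample(dim(g$tmin)[1])
  g$tmin <- g$tmin[perm, , , drop = FALSE]
  g$tmax <- g$tmax[perm, , , drop = FALSE]
  s2 <- accumulate_stress(g, p)
  expect_equal(s2$cold_total, s$cold_total, tolerance = 1e-9)
  expect_identical(s2$combined_class, s$combined_class)
})

test_that("consecutive cold-day runs are counted", {
  tmin <- rep(0, 365); tmin[20:26] <- -35; tmin[100:102] <- -35
  g <- daily_temperature_grid(tmin, tmin + 10, year = 2021)
  expect_equal(consecutive_days_below(g, -31)[1, 1], 7L)
  expect_equal(consecutive_days_below(g, -31, days = 90:120)[1, 1], 3L)
  expect_equal(consecutive_days_below(g, -40)[1, 1], 0L)
})
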