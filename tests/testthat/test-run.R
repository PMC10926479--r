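cfg_small <- function(out_dir, seed = 1L)
  run_config(synthetic_weather_config(nrow = 6, ncol = 6, seed = seed,
                                      base = 12, noise_sd = 2),
             out_dir = out_dir, seed = seed)

test_that("a full run writes the contracted artifact set", {
  dir <- withr::local_tempdir()
  res <- run_model(cfg_small(dir))
  for (e in event_names()) {
    expect_true(file.exists(file.path(dir, paste0(e, "_first_doy.asc"))))
    expect_true(file.exists(file.path(dir, paste0(e, "_avg_doy.asc"))))
    expect_true(file.exists(file.path(dir, paste0(e, "_integrated.png"))))
  }
  for (f in c("cold_stress_units", "heat_stress_units", "cold_class",
              "heat_class", "combined_class"))
    expect_true(file.exists(file.path(dir, paste0(f, ".asc"))))
  prov <- jsonlite::fromJSON(file.path(dir, "provenance.json"))
  expect_equal(prov$params$distro_mean, 200)
  expect_equal(length(prov$cohorts$completion_dd), 7)
  expect_true(file.exists(file.path(dir, "run.log")))
  # grids reload to the in-memory results
  g <- read_ascii_grid(file.path(dir, "adult_emergence_first_doy.asc"))
  expect_equal(g$values, res$events$first$adult_emergence)
})

test_that("identical config and seed reproduce byte-identical rasters", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_model(cfg_small(d1, seed = 7L))
  run_model(cfg_small(d2, seed = 7L))
  for (f in c("adult_emergence_first_doy.asc", "combined_class.asc",
              "egg_hatch_integrated_doy.asc"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("unknown events are rejected and stage errors are labeled", {
  expect_error(run_config(synthetic_weather_config(),
                          events = "diapause_end"), "unknown event")
  dir <- withr::local_tempdir()
  cfg <- cfg_small(file.path(dir, "out"))
  cfg$weather <- "no/such/file.csv"
  expect_error(run_model(cfg), "stage 'weather'")
  expect_false(dir.exists(file.path(dir, "out")))  # partial outputs removed
})

test_that("validation reports MAE/bias per event and flags unmatched", {
  g <- synth_weather(synthetic_weather_config(nrow = 6, ncol = 6, seed = 3,
                                              base = 12, noise_sd = 2))
  em <- run_all_cohorts(g, species_params())
  pts <- expand.grid(lon = c(1.5, 3.5), lat = c(1.5, 4.5))
  mk_obs <- function(event, grid, shift = 0)
    data.frame(event = event, lon = pts$lon, lat = pts$lat,
               observed_doy = extract_at_points(grid, pts$lon, pts$lat,
                                                0, 6, 1)$value + shift)
  obs <- rbind(mk_obs("adult_emergence", em$first$adult_emergence),
               mk_obs("egg_hatch", em$first$egg_hatch))
  rep0 <- run_validation(em, obs)
  expect_true(all(rep0$table$mae == 0))
  # constant +5 day shift in observations -> bias -5 (model predicts early)
  obs5 <- rbind(mk_obs("adult_emergence", em$first$adult_emergence, 5),
                mk_obs("oviposition", em$first$oviposition, 5))
  rep5 <- run_validation(em, obs5)
  expect_true(all(abs(rep5$table$bias + 5) < 1e-9))
  expect_true("adult_emergence_delta14" %in% names(rep5$equivalence))
  # out-of-extent observation listed, not dropped
  obs_out <- rbind(obs, data.frame(event = "adult_emergence", lon = 99,
                                   lat = 99, observed_doy = 150))
  rep_out <- run_validation(em, obs_out)
  expect_equal(nrow(rep_out$unmatched), 1)
  # report files
  dir <- withr::local_tempdir()
  run_validation(em, obs, out_csv = file.path(dir, "v.csv"),
                 out_json = file.path(dir, "v.json"))
  expect_true(file.exists(file.path(dir, "v.csv")))
  expect_true(file.exists(file.path(dir, "v.json")))
})

test_that("peak adult activity validates against weighted-average oviposition", {
  g <- synth_weather(synthetic_weather_config(nrow = 4, ncol = 4, seed = 5,
                                              base = 12, noise_sd = 1))
  em <- run_all_cohorts(g, species_params())
  obs <- data.frame(event = "peak_adult_activity", lon = 1.5, lat = 1.5,
                    observed_doy = em$average$oviposition[3, 2])
  rep <- run_validation(em, obs)
  expect_equal(rep$table$mae, 0)
})

test_that("yearly trend orchestration finds imposed warming", {
  p <- species_params()
  co <- make_cohorts(p)
  years <- lapply(1:12, function(y)
    run_all_cohorts(synth_weather(synthetic_weather_config(
      nrow = 4, ncol = 4, base = 11 + 0.35 * y, seed = 100 + y,
      noise_sd = 1)), p, co))
  tm <- run_trends(years, "first_emergence_doy")
  ok <- !is.na(tm$tau)
  expect_true(any(ok))
  expect_lt(median(tm$tau[ok]), 0)   # warming -> earlier emergence
  # identical years -> no trend anywhere
  same <- rep(years[1], 3)
  tm0 <- run_trends(same, "first_emergence_doy")
  expect_true(all(tm0$no_trend[!is.na(tm0$no_trend)]))
  expect_error(run_trends(years[1:2], "first_emergence_doy"), "3 yearly")
})

test_that("plot helpers write PNG files", {
  g <- synth_weather(synthetic_weather_config(nrow = 4, ncol = 4, seed = 2,
                                              base = 12))
  p <- species_params()
  em <- run_all_cohorts(g, p)
  st <- accumulate_stress(g, p)
  integ <- integrate_phenology_suitability(em, st)
  f <- withr::local_tempfile(fileext = ".png")
  plot_integrated_map(integ$adult_emergence, "adult emergence", f)
  expect_gt(file.size(f), 0)
  stack <- lapply(1:5, function(y) matrix(rnorm(16, 150 - y, 2), 4, 4))
  f2 <- withr::local_tempfile(fileext = ".png")
  plot_trend_map(trend_map(stack), "trend", f2)
  expect_gt(file.size(f2), 0)
})
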