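# At a constant 22.2 degC every day contributes exactly 10 DD
# (22.2 - 12.2), so event days are hand-computable from the cumulative
# stage requirements 200 / 335 / 407 / 579 / 1279.

test_that("constant-temperature arithmetic reproduces hand-derived DOYs", {
  r <- run_cohort(const_grid(22.2), species_params(), 200)
  expect_identical(vapply(r$events, function(m) m[1, 1], numeric(1)),
                   c(pupation = 20, adult_emergence = 34, oviposition = 41,
                     egg_hatch = 58, jlarva_formation = 128))
  expect_equal(r$final_stage[1, 1], 6)  # diapause entered
})

test_that("no degree-days accumulate below the lower threshold", {
  r <- run_cohort(const_grid(10), species_params(), 200)
  expect_true(all(is.na(unlist(r$events))))
  expect_equal(r$annual_dd[1, 1], 0)
})

test_that("earlier-completing cohorts reach every event earlier", {
  p <- species_params()
  r60 <- run_cohort(const_grid(22.2), p, 60)
  r350 <- run_cohort(const_grid(22.2), p, 350)
  for (e in event_names())
    expect_lt(r60$events[[e]][1, 1], r350$events[[e]][1, 1])
})

test_that("completion_dd outside the truncation bounds errors", {
  expect_error(run_cohort(const_grid(22.2), species_params(), 30),
               "xdist")
})

test_that("general stage machine agrees with the shared-threshold shortcut", {
  g <- default_synth(17, nrow = 4, ncol = 4)
  p_shared <- species_params()
  fast <- run_cohort(g, p_shared, 200)
  # nudge one threshold so the slow path runs, then verify the slow path
  # under truly shared thresholds by reverting via a distinct params object
  p_forced <- species_params()
  slow <- phenorisk:::run_cohort_general(g, p_forced, 200)
  for (e in event_names())
    expect_identical(slow$events[[e]], fast$events[[e]])
})

test_that("stage-specific thresholds engage the general path coherently", {
  p <- species_params(egg_ldt = 13.7, pupae_ldt = 10, larvae_ldt = 10)
  r <- run_cohort(const_grid(22.2), p, 200)
  d <- vapply(r$events, function(m) m[1, 1], numeric(1))
  # OL/pupae develop at 12.2 DD/day, adults at 10, eggs at 8.5
  expect_identical(unname(d["pupation"]), ceiling(200 / 12.2))
  expect_true(all(diff(d) > 0))
})

test_that("combined maps follow the first/weighted-average contracts", {
  g <- default_synth(23, nrow = 5, ncol = 5)
  p <- species_params()
  co <- make_cohorts(p)
  em <- run_all_cohorts(g, p, co)
  # worked two-cohort combination
  co2 <- structure(list(completion_dd = c(100, 300), weight = c(0.25, 0.75),
                        n = 2L), class = "cohort_set")
  cg <- const_grid(22.2)
  em2 <- run_all_cohorts(cg, p, co2)
  d1 <- em2$per_cohort[[1]]$adult_emergence[1, 1]
  d2 <- em2$per_cohort[[2]]$adult_emergence[1, 1]
  expect_equal(em2$first$adult_emergence[1, 1], min(d1, d2))
  expect_equal(em2$average$adult_emergence[1, 1],
               0.25 * d1 + 0.75 * d2)
  # single cohort: first == average
  em1 <- run_all_cohorts(cg, p, make_cohorts(species_params(n_cohorts = 1)))
  expect_identical(em1$first$egg_hatch, em1$average$egg_hatch)
  # first <= average wherever both are defined
  for (e in event_names()) {
    both <- !is.na(em$first[[e]]) & !is.na(em$average[[e]])
    expect_true(all(em$first[[e]][both] <= em$average[[e]][both] + 1e-9))
  }
})

test_that("insufficient-accumulation mask complements defined values", {
  # positive gradient cools with row index: the last rows never
  # accumulate enough degree-days for the late events
  g <- synth_weather(synthetic_weather_config(nrow = 6, ncol = 3, base = 16,
                                              gradient = 2.5, noise_sd = 0,
                                              amplitude = 10))
  em <- run_all_cohorts(g, species_params())
  for (e in event_names())
    expect_identical(em$insufficient[[e]], is.na(em$first[[e]]))
  expect_true(any(em$insufficient$egg_hatch))
  expect_false(all(em$insufficient$pupation))
})

test_that("masked cells yield all-missing trajectories", {
  tmin <- array(15, c(365, 2, 2)); tmax <- array(25, c(365, 2, 2))
  tmin[50, 1, 2] <- NA
  g <- daily_temperature_grid(tmin, tmax, year = 2021)
  em <- run_all_cohorts(g, species_params())
  expect_true(all(is.na(vapply(em$first, function(m) m[1, 2], numeric(1)))))
  expect_false(em$insufficient$pupation[1, 2])  # missing, not insufficient
})

test_that("event ordering and monotonicity hold over seeded weather draws", {
  p <- species_params()
  co <- make_cohorts(p)
  for (seed in 1:100) {
    g <- default_synth(seed, nrow = 20, ncol = 20)
    em <- run_all_cohorts(g, p, co)
    # ordering within every cohort and cell
    for (k in seq_along(em$per_cohort)) {
      evs <- em$per_cohort[[k]]
      for (i in 1:4) {
        a <- evs[[i]]; b <- evs[[i + 1]]
        both <- !is.na(a) & !is.na(b)
        expect_true(all(a[both] <= b[both]))
        # a later event reached implies the earlier one was
        expect_false(any(is.na(a) & !is.na(b)))
      }
    }
    if (seed <= 10) {
      # warming by +1 degC never delays any event
      gw <- g
      gw$tmin <- g$tmin + 1; gw$tmax <- g$tmax + 1
      emw <- run_all_cohorts(gw, p, co)
      for (e in event_names()) {
        both <- !is.na(em$first[[e]]) & !is.na(emw$first[[e]])
        expect_true(all(emw$first[[e]][both] <= em$first[[e]][both]))
        expect_false(any(is.na(emw$first[[e]]) & !is.na(em$first[[e]])))
      }
      # cohort monotonicity on this weather
      for (e in event_names()) {
        mats <- lapply(em$per_cohort, `[[`, e)
        for (k in 1:(length(mats) - 1)) {
          both <- !is.na(mats[[k]]) & !is.na(mats[[k + 1]])
          expect_true(all(mats[[k]][both] <= mats[[k + 1]][both]))
        }
      }
    }
  }
})

test_that("degree-days are conserved across stage transitions", {
  # with one shared threshold pair, within-stage sums plus the unused
  # remainder equal the annual total
  g <- default_synth(3, nrow = 3, ncol = 3)
  p <- species_params()
  r <- run_cohort(g, p, 200)
  req <- c(200, p$pupae_event_dd, p$adult_event_dd, p$egg_event_dd,
           p$larvae_event_dd)
  for (i in 1:3) for (j in 1:3) {
    reached <- sum(!vapply(r$events, function(m) is.na(m[i, j]), TRUE))
    spent <- sum(req[seq_len(reached)])
    expect_lte(spent, r$annual_dd[i, j] + 1e-6)
    if (reached < 5 && reached > 0) {
      # remainder in the current stage is short of its requirement
      expect_lt(r$annual_dd[i, j] - spent, req[reached + 1])
    }
  }
})

test_that("stage snapshots track the event chain", {
  p <- species_params()
  co <- make_cohorts(species_params(n_cohorts = 1))
  co$completion_dd <- 200
  em <- run_all_cohorts(const_grid(22.2), p, co)
  s25 <- stage_snapshot(em, 25)
  expect_equal(s25$stages[1, 1, 1], 2)   # pupa on day 25
  expect_equal(s25$dominant[1, 1], 2)
  expect_equal(s25$generations[1, 1], 0)
  s1 <- stage_snapshot(em, 1)
  expect_equal(s1$stages[1, 1, 1], 1)    # overwintering J-larva on day 1
  s200 <- stage_snapshot(em, 200)
  expect_equal(s200$stages[1, 1, 1], 6)  # diapause after J-larval formation
  expect_equal(s200$generations[1, 1], 1)
  expect_error(stage_snapshot(em, 400), "outside")
  expect_error(stage_snapshot(em, as.Date("2020-06-01")), "outside")
})
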