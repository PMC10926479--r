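# Daily time-step life-cycle engine. Starting 1 January in the
# overwintered J-larva (OL) stage, each cohort advances through
# OL -> P -> A -> E -> L, recording one phenological event per stage:
#   pupation            OL completes its cohort-specific requirement
#   adult_emergence     pupal requirement (pupae_event_dd) met
#   oviposition         adult accrues adult_event_dd (egg laying starts the
#                       offspring egg stage; adult_dd is adult longevity,
#                       used only for stage presence)
#   egg_hatch           egg_event_dd met
#   jlarva_formation    larvae_event_dd met; with obligate diapause the
#                       trajectory then terminates (univoltine life cycle)

#' Names of the five mapped phenological events
#'
#' In life-cycle order: pupation, adult emergence, oviposition (egg
#' laying), egg hatch, J-larval formation.
#'
#' @return Character vector of length 5.
#' @export
event_names <- function() {
  c("pupation", "adult_emergence", "oviposition", "egg_hatch",
    "jlarva_formation")
}

# LDT/UDT per modeled stage, in stgorder position OL,P,A,E,L.
# The overwintered J-larva uses the larval thresholds.
.stage_thresholds <- function(params) {
  list(ldt = c(OL = params$larvae_ldt, P = params$pupae_ldt,
               A = params$adult_ldt, E = params$egg_ldt,
               L = params$larvae_ldt),
       udt = c(OL = params$larvae_udt, P = params$pupae_udt,
               A = params$adult_udt, E = params$egg_udt,
               L = params$larvae_udt))
}

.stage_requirements <- function(params, completion_dd) {
  c(OL = completion_dd, P = params$pupae_event_dd, A = params$adult_event_dd,
    E = params$egg_event_dd, L = params$larvae_event_dd)
}

#' Run the life-cycle engine for one cohort
#'
#' Simulates a single cohort over one calendar year on every grid cell.
#' Each day contributes [single_triangle_dd()] computed with the current
#' stage's thresholds; when the accumulated degree-days within the stage
#' meet its requirement the stage advances the same day, carrying any
#' excess into the next stage (several transitions may fall on one day).
#' Event days are the first calendar day (integer DOY, 1 Jan = 1) on which
#' the relevant cumulative requirement is met. After J-larval formation,
#' obligate diapause halts the trajectory (no second generation).
#'
#' When every stage shares one LDT/UDT pair — true for the emerald ash
#' borer defaults — the engine takes an exact closed-form shortcut: events
#' fall where the annual cumulative degree-day curve crosses the summed
#' stage requirements.
#'
#' @param temps a [daily_temperature_grid()].
#' @param params a [species_params()].
#' @param completion_dd this cohort's overwintering completion requirement
#'   (degree-days); must lie in `[xdist1, xdist2]`.
#' @return A `cohort_run`: list with `events` (named list of five
#'   `row x col` DOY matrices, `NA` where the event is never reached or the
#'   cell is masked), `final_stage` (integer matrix, 1..5 = OL,P,A,E,L,
#'   6 = diapause/DONE), and `annual_dd` (year-total degree-days of the
#'   OL-stage thresholds).
#' @export
run_cohort <- function(temps, params, completion_dd) {
  .check_cohort_inputs(temps, params, completion_dd)
  th <- .stage_thresholds(params)
  if (length(unique(th$ldt)) == 1 && length(unique(th$udt)) == 1)
    run_cohort_shared(temps, params, completion_dd)
  else
    run_cohort_general(temps, params, completion_dd)
}

.check_cohort_inputs <- function(temps, params, completion_dd) {
  stopifnot(inherits(temps, "daily_temperature_grid"),
            inherits(params, "species_params"))
  if (completion_dd < params$xdist1 || completion_dd > params$xdist2)
    stop("completion_dd must lie within [xdist1, xdist2]")
}

.cohort_result <- function(ev, final, annual, masked, nr, nc,
                           completion_dd) {
  ev[masked, ] <- NA_real_
  annual[masked] <- NA_real_
  events <- lapply(seq_len(5), function(e) matrix(ev[, e], nr, nc))
  names(events) <- event_names()
  structure(list(events = events,
                 final_stage = matrix(final, nr, nc),
                 annual_dd = matrix(annual, nr, nc),
                 completion_dd = completion_dd),
            class = "cohort_run")
}

# Closed-form shortcut for a single shared threshold pair: events fall
# where the annual cumulative DD curve crosses the summed requirements.
run_cohort_shared <- function(temps, params, completion_dd) {
  .check_cohort_inputs(temps, params, completion_dd)
  th <- .stage_thresholds(params)
  req <- .stage_requirements(params, completion_dd)
  ndays <- dim(temps$tmin)[1]
  nr <- dim(temps$tmin)[2]; nc <- dim(temps$tmin)[3]
  ncell <- nr * nc
  tmin <- matrix(temps$tmin, ndays, ncell)
  tmax <- matrix(temps$tmax, ndays, ncell)
  dd <- matrix(single_triangle_dd(tmin, tmax, th$ldt[1], th$udt[1]),
               ndays, ncell)
  cum <- matrix(apply(dd, 2, cumsum), ndays, ncell)
  thresholds <- cumsum(req)
  ev <- matrix(NA_real_, ncell, 5)
  for (e in 1:5) {
    idx <- colSums(cum < thresholds[e] - 1e-9) + 1L
    idx[idx > ndays] <- NA_integer_
    ev[, e] <- idx
  }
  final <- rowSums(!is.na(ev)) + 1L   # 1..6
  final[final == 6L & !params$obligate_diapause] <- 5L
  .cohort_result(ev, final, cum[ndays, ], as.vector(temps$missing_mask),
                 nr, nc, completion_dd)
}

# General daily stage machine: per-stage thresholds, same-day carryover,
# multiple transitions per day permitted.
run_cohort_general <- function(temps, params, completion_dd) {
  .check_cohort_inputs(temps, params, completion_dd)
  th <- .stage_thresholds(params)
  req <- .stage_requirements(params, completion_dd)
  ndays <- dim(temps$tmin)[1]
  nr <- dim(temps$tmin)[2]; nc <- dim(temps$tmin)[3]
  ncell <- nr * nc
  tmin <- matrix(temps$tmin, ndays, ncell)
  tmax <- matrix(temps$tmax, ndays, ncell)
  ev <- matrix(NA_real_, ncell, 5)
  stage <- rep(1L, ncell)
  acc <- numeric(ncell)
  annual <- numeric(ncell)
  for (d in seq_len(ndays)) {
    for (s in unique(stage[stage <= 5L])) {
      i <- which(stage == s)
      dd <- single_triangle_dd(tmin[d, i], tmax[d, i], th$ldt[s], th$udt[s])
      dd[is.na(dd)] <- 0
      acc[i] <- acc[i] + dd
      annual[i] <- annual[i] + dd
    }
    repeat {
      adv <- which(stage <= 5L & acc >= req[stage] - 1e-9)
      if (!length(adv)) break
      ev[cbind(adv, stage[adv])] <- d
      acc[adv] <- acc[adv] - req[stage[adv]]
      stage[adv] <- stage[adv] + 1L
    }
  }
  .cohort_result(ev, stage, annual, as.vector(temps$missing_mask),
                 nr, nc, completion_dd)
}

#' Run all cohorts and combine event maps
#'
#' Runs [run_cohort()] for every cohort and combines the per-cohort event
#' grids: the combined "first" grid is the earliest DOY across cohorts that
#' reached the event; the combined "average" grid is the cohort-weighted
#' mean DOY over reaching cohorts (weights renormalized over those
#' cohorts); cells where no cohort reached an event are flagged in the
#' insufficient-accumulation mask.
#'
#' @param temps a [daily_temperature_grid()].
#' @param params a [species_params()].
#' @param cohorts a [make_cohorts()] cohort set (built from `params` when
#'   omitted).
#' @return An `event_maps` object: `per_cohort` (list of `cohort_run`
#'   event lists), `first`, `average` (named lists of five DOY matrices),
#'   `insufficient` (named list of logical matrices), `weights`, and the
#'   grid georeference.
#' @examples
#' g <- synth_weather(synthetic_weather_config(nrow = 3, ncol = 3,
#'                                             noise_sd = 0))
#' em <- run_all_cohorts(g, species_params())
#' em$first$adult_emergence
#' @export
run_all_cohorts <- function(temps, params, cohorts = make_cohorts(params)) {
  stopifnot(inherits(cohorts, "cohort_set"))
  runs <- lapply(cohorts$completion_dd,
                 function(cdd) run_cohort(temps, params, cdd))
  nr <- dim(temps$tmin)[2]; nc <- dim(temps$tmin)[3]
  first <- average <- insufficient <- vector("list", 5)
  names(first) <- names(average) <- names(insufficient) <- event_names()
  for (e in event_names()) {
    stackm <- vapply(runs, function(r) r$events[[e]], matrix(0, nr, nc))
    stackm <- array(stackm, c(nr, nc, cohorts$n))
    wts <- array(rep(cohorts$weight, each = nr * nc), c(nr, nc, cohorts$n))
    wts[is.na(stackm)] <- NA
    wsum <- apply(wts, c(1, 2), sum, na.rm = TRUE)
    f <- suppressWarnings(apply(stackm, c(1, 2), min, na.rm = TRUE))
    f[!is.finite(f)] <- NA
    a <- apply(stackm * wts, c(1, 2), sum, na.rm = TRUE) / wsum
    a[wsum == 0] <- NA
    none <- apply(is.na(stackm), c(1, 2), all)
    a[none] <- f[none] <- NA
    first[[e]] <- f; average[[e]] <- a
    insufficient[[e]] <- none & !temps$missing_mask
  }
  structure(list(per_cohort = lapply(runs, `[[`, "events"),
                 runs = runs,
                 first = first, average = average,
                 insufficient = insufficient,
                 weights = cohorts$weight,
                 missing_mask = temps$missing_mask,
                 year = temps$year,
                 xmin = temps$xmin, ymax = temps$ymax,
                 cellsize = temps$cellsize, crs = temps$crs),
            class = "event_maps")
}

#' @export
print.event_maps <- function(x, ...) {
  cat("<event_maps> ", length(x$per_cohort), " cohorts, ",
      nrow(x$first[[1]]), " x ", ncol(x$first[[1]]), " cells, year ",
      x$year, "\n", sep = "")
  med <- vapply(x$first, function(m) stats::median(m, na.rm = TRUE),
                numeric(1))
  cat("  median first DOY:",
      paste(names(med), round(med), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Life stages present on a date
#'
#' Summarizes, for one calendar date, which stage each cohort occupies in
#' every cell (OL before pupation; P, A, E, L between successive events;
#' diapause/DONE after J-larval formation), the weight-dominant stage, and
#' the generation count (0 before J-larval formation of the new
#' generation, 1 after — the univoltine ceiling).
#'
#' @param maps an [run_all_cohorts()] result.
#' @param date a `Date` (or DOY integer) inside the modeled year.
#' @return List with `stages` (cohort x row x col integer array, 1..5 =
#'   OL,P,A,E,L, 6 = diapause), `dominant` (matrix of modal stage by
#'   weight), `generations` (0/1 matrix).
#' @export
stage_snapshot <- function(maps, date) {
  stopifnot(inherits(maps, "event_maps"))
  doy <- if (inherits(date, "Date")) {
    yr <- as.integer(format(date, "%Y"))
    if (yr != maps$year) stop("date outside modeled year ", maps$year)
    as.integer(date - as.Date(paste0(maps$year, "-01-01"))) + 1L
  } else as.integer(date)
  ndays <- as.integer(as.Date(paste0(maps$year, "-12-31")) -
                        as.Date(paste0(maps$year, "-01-01"))) + 1L
  if (doy < 1L || doy > ndays) stop("date outside modeled year ", maps$year)
  nr <- nrow(maps$first[[1]]); nc <- ncol(maps$first[[1]])
  ncoh <- length(maps$per_cohort)
  stages <- array(1L, c(ncoh, nr, nc))
  for (k in seq_len(ncoh)) {
    s <- matrix(1L, nr, nc)
    for (e in seq_along(event_names())) {
      d <- maps$per_cohort[[k]][[e]]
      s[!is.na(d) & d <= doy] <- e + 1L
    }
    s[maps$missing_mask] <- NA_integer_
    stages[k, , ] <- s
  }
  dominant <- matrix(NA_integer_, nr, nc)
  w <- maps$weights
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    sk <- stages[, i, j]
    if (all(is.na(sk))) next
    tw <- tapply(w[!is.na(sk)], sk[!is.na(sk)], sum)
    dominant[i, j] <- as.integer(names(tw)[which.max(tw)])
  }
  reached <- vapply(maps$per_cohort,
                    function(evl) !is.na(evl$jlarva_formation) &
                      evl$jlarva_formation <= doy,
                    matrix(TRUE, nr, nc))
  generations <- matrix(as.integer(apply(array(reached, c(nr, nc, ncoh)),
                                         c(1, 2), any)), nr, nc)
  generations[maps$missing_mask] <- NA_integer_
  list(stages = stages, dominant = dominant, generations = generations,
       stage_labels = c("OL", "P", "A", "E", "L", "diapause"))
}
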