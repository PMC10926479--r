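# End-to-end model orchestration: weather -> cohorts -> phenology ->
# stress -> integration, with all artifacts written to an output
# directory. These functions back the command-line interface shipped in
# inst/cli/phenorisk.

#' Full-run configuration
#'
#' @param weather either a [daily_temperature_grid()], a
#'   [synthetic_weather_config()], or a `c(tmin=, tmax=)` ASCII-stack path
#'   pair.
#' @param params_file optional parameter file for [load_params()]
#'   (packaged emerald ash borer defaults otherwise).
#' @param out_dir output directory (created if absent).
#' @param events which of the five events to export.
#' @param write_stress,write_integrated,write_png toggles for the
#'   respective artifact groups.
#' @param snapshot_dates optional dates for stage-presence snapshots.
#' @param year modeled year (synthetic weather only).
#' @param n_cohorts optional cohort-count override.
#' @param seed seed for synthetic weather.
#' @return A `run_config` list.
#' @export
run_config <- function(weather, params_file = NULL, out_dir = tempfile("run"),
                       events = event_names(), write_stress = TRUE,
                       write_integrated = TRUE, write_png = TRUE,
                       snapshot_dates = NULL, year = 2021,
                       n_cohorts = NULL, seed = 1L) {
  bad <- setdiff(events, event_names())
  if (length(bad))
    stop("unknown event(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(event_names(), collapse = ", "), ")")
  structure(list(weather = weather, params_file = params_file,
                 out_dir = out_dir, events = events,
                 write_stress = write_stress,
                 write_integrated = write_integrated,
                 write_png = write_png, snapshot_dates = snapshot_dates,
                 year = year, n_cohorts = n_cohorts, seed = as.integer(seed)),
            class = "run_config")
}

.resolve_weather <- function(cfg) {
  w <- cfg$weather
  if (inherits(w, "daily_temperature_grid")) return(w)
  if (inherits(w, "synthetic_weather_config")) return(synth_weather(w))
  if (is.character(w) && all(c("tmin", "tmax") %in% names(w)))
    return(read_daily_grids(w, "ascii-stack"))
  if (is.character(w) && length(w) == 1)
    return(read_daily_grids(w, "site-csv"))
  stop("run stage 'weather': unrecognized weather source")
}

.stage <- function(log, name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("run stage '", name, "': ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %-12s done in %.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Execute a full model run
#'
#' Runs the whole pipeline described by a [run_config()] and writes the
#' artifact set: per-event combined first/average DOY grids and stress
#' total/class grids as ASCII text rasters, integrated four-way maps, PNG
#' summary maps, a structured log, and a JSON provenance record
#' (parameter values, seed, input checksums) sufficient to reproduce the
#' run bit-identically. On error, partial outputs are removed.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory results (`weather`,
#'   `params`, `cohorts`, `events`, `stress`, `integrated`) and `files`,
#'   the written paths.
#' @export
run_model <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  created <- !dir.exists(cfg$out_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  logger <- function(msg)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), "INFO ", msg, "\n",
        sep = "", file = logfile, append = TRUE)
  files <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(if (created) cfg$out_dir else files,
                          recursive = TRUE))

  params <- .stage(logger, "params", {
    p <- if (is.null(cfg$params_file)) species_params()
         else load_params(cfg$params_file)
    if (!is.null(cfg$n_cohorts)) p <- species_params_update(p, n_cohorts = cfg$n_cohorts)
    p
  })
  wx <- .stage(logger, "weather", .resolve_weather(cfg))
  logger(sprintf("grid %d x %d cells, %d masked",
                 dim(wx$tmin)[2], dim(wx$tmin)[3], sum(wx$missing_mask)))
  cohorts <- .stage(logger, "cohorts", make_cohorts(params))
  ev <- .stage(logger, "phenology", run_all_cohorts(wx, params, cohorts))
  stress <- .stage(logger, "suitability", accumulate_stress(wx, params))
  integ <- .stage(logger, "integration",
                  integrate_phenology_suitability(ev, stress))

  wgrid <- function(mat, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".asc"))
    write_ascii_grid(mat, p, xmin = wx$xmin, ymax = wx$ymax,
                     cellsize = wx$cellsize)
    files <<- c(files, p)
    p
  }
  for (e in cfg$events) {
    wgrid(ev$first[[e]], paste0(e, "_first_doy"))
    wgrid(ev$average[[e]], paste0(e, "_avg_doy"))
  }
  if (cfg$write_stress) {
    wgrid(stress$cold_total, "cold_stress_units")
    wgrid(stress$heat_total, "heat_stress_units")
    wgrid(stress$cold_class + 0, "cold_class")
    wgrid(stress$heat_class + 0, "heat_class")
    wgrid(stress$combined_class + 0, "combined_class")
  }
  if (cfg$write_integrated)
    for (e in cfg$events) {
      wgrid(integ[[e]]$doy, paste0(e, "_integrated_doy"))
      wgrid(integ[[e]]$status + 0, paste0(e, "_integrated_status"))
    }
  if (!is.null(cfg$snapshot_dates))
    for (d in as.list(cfg$snapshot_dates)) {
      snap <- stage_snapshot(ev, d)
      wgrid(snap$dominant + 0, paste0("stages_", format(d)))
    }
  if (cfg$write_png) {
    for (e in cfg$events) {
      p <- file.path(cfg$out_dir, paste0(e, "_integrated.png"))
      plot_integrated_map(integ[[e]], title = e, file = p)
      files <- c(files, p)
    }
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("phenorisk")),
    params = unclass(params),
    cohorts = list(completion_dd = cohorts$completion_dd,
                   weight = cohorts$weight),
    seed = cfg$seed,
    year = wx$year,
    weather = if (is.character(cfg$weather))
      list(paths = as.list(cfg$weather),
           md5 = as.list(tools::md5sum(unname(cfg$weather))))
    else if (inherits(cfg$weather, "synthetic_weather_config"))
      unclass(cfg$weather)
    else "in-memory grid",
    events = cfg$events)
  provfile <- file.path(cfg$out_dir, "provenance.json")
  jsonlite::write_json(prov, provfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, provfile, logfile)
  logger(sprintf("wrote %d files", length(files)))
  ok <- TRUE
  invisible(list(weather = wx, params = params, cohorts = cohorts,
                 events = ev, stress = stress, integrated = integ,
                 files = files))
}

# re-validate a params object after field overrides
species_params_update <- function(params, ...) {
  p <- unclass(params)
  ov <- list(...)
  p[names(ov)] <- ov
  validate_params(p)
}

#' Validate predictions against observed event dates
#'
#' Builds a per-event report in the standard layout (N_obs, MAE, bias,
#' SD, range) plus TOST equivalence verdicts at 7 and 14 days for adult
#' events with n >= 2. Observations are matched to the prediction grids
#' by containing cell; out-of-extent observations are listed as
#' unmatched, not dropped.
#'
#' @param events an [run_all_cohorts()] result.
#' @param observations data.frame (or CSV path) with columns `event`
#'   (event name), `lon`, `lat`, `observed_doy`, and optionally `site`,
#'   `year`. Event names may also be `peak_adult_activity`, which is
#'   compared to the weighted-average oviposition grid.
#' @param out_csv,out_json optional report paths.
#' @return List with `table` (data.frame of summary rows), `equivalence`
#'   (list of [tost_equivalence()] results by event/delta), `pairs` (the
#'   matched predicted/observed pairs) and `unmatched`.
#' @export
run_validation <- function(events, observations, out_csv = NULL,
                           out_json = NULL) {
  stopifnot(inherits(events, "event_maps"))
  if (is.character(observations))
    observations <- utils::read.csv(observations, stringsAsFactors = FALSE)
  need <- c("event", "lon", "lat", "observed_doy")
  if (!all(need %in% names(observations)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  grid_for <- function(e) {
    if (e == "peak_adult_activity") events$average$oviposition
    else if (e %in% event_names()) events$first[[e]]
    else NULL
  }
  observations$predicted_doy <- NA_real_
  observations$unmatched <- FALSE
  for (e in unique(observations$event)) {
    g <- grid_for(e)
    i <- observations$event == e
    if (is.null(g)) { observations$unmatched[i] <- TRUE; next }
    ex <- extract_at_points(g, observations$lon[i], observations$lat[i],
                            xmin = events$xmin, ymax = events$ymax,
                            cellsize = events$cellsize)
    observations$predicted_doy[i] <- ex$value
    observations$unmatched[i] <- ex$outside
  }
  matched <- observations[!observations$unmatched &
                            !is.na(observations$predicted_doy), ]
  rows <- lapply(split(matched, matched$event), function(df) {
    s <- error_summary(df$predicted_doy, df$observed_doy)
    data.frame(event = df$event[1], n_obs = s$n_obs, mae = s$mae,
               bias = s$bias, sd = s$sd, range_low = s$range_low,
               range_high = s$range_high)
  })
  tab <- do.call(rbind, rows)
  adult_events <- intersect(unique(matched$event),
                            c("adult_emergence", "oviposition",
                              "peak_adult_activity"))
  equiv <- list()
  for (e in adult_events) {
    df <- matched[matched$event == e, ]
    if (nrow(df) < 2) next
    for (delta in c(7, 14))
      equiv[[paste0(e, "_delta", delta)]] <-
        tryCatch(tost_equivalence(df$predicted_doy, df$observed_doy, delta),
                 error = function(err) NULL)
  }
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(
      list(table = tab,
           equivalence = lapply(equiv, unclass),
           unmatched = observations[observations$unmatched, need]),
      out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(table = tab, equivalence = equiv,
       pairs = matched,
       unmatched = observations[observations$unmatched, , drop = FALSE])
}

#' Trend analysis over yearly model outputs
#'
#' Stacks a variable across yearly runs and calls [trend_map()].
#' Class variables are sign-flipped (absolute values) so that a negative
#' trend reads as decreasing stress.
#'
#' @param yearly list (>= 3) of yearly results: [run_all_cohorts()]
#'   results for `"first_emergence_doy"`, or [accumulate_stress()] results
#'   for `"cold_class"`/`"heat_class"`.
#' @param variable which yearly layer to test.
#' @param out_dir optional directory for tau/p/significance ASCII grids.
#' @return The [trend_map()] result.
#' @export
run_trends <- function(yearly,
                       variable = c("first_emergence_doy", "cold_class",
                                    "heat_class"),
                       out_dir = NULL) {
  variable <- match.arg(variable)
  if (length(yearly) < 3) stop("need at least 3 yearly outputs")
  layers <- lapply(yearly, function(y) {
    switch(variable,
           first_emergence_doy = {
             stopifnot(inherits(y, "event_maps"))
             y$first$adult_emergence
           },
           cold_class = { stopifnot(inherits(y, "stress_result"))
             y$cold_class + 0 },
           heat_class = { stopifnot(inherits(y, "stress_result"))
             y$heat_class + 0 })
  })
  tm <- trend_map(layers, flip_sign = variable != "first_emergence_doy")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    g <- yearly[[1]]
    write_ascii_grid(tm$tau, file.path(out_dir, paste0(variable, "_tau.asc")),
                     xmin = g$xmin, ymax = g$ymax, cellsize = g$cellsize)
    write_ascii_grid(tm$p, file.path(out_dir, paste0(variable, "_p.asc")),
                     xmin = g$xmin, ymax = g$ymax, cellsize = g$cellsize)
    write_ascii_grid((tm$significant + 0),
                     file.path(out_dir, paste0(variable, "_sig.asc")),
                     xmin = g$xmin, ymax = g$ymax, cellsize = g$cellsize)
  }
  tm
}
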