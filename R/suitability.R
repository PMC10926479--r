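# Climatic suitability: yearly cold/heat stress-unit totals classify each
# cell into 0 (no exclusion), -1 (moderate) or -2 (severe exclusion).
# Class-0 cells constitute the potential distribution.

# strict inequality: a total exactly at a limit is not excluded
.classify_stress <- function(total, max1, max2) {
  cls <- matrix(0L, nrow(total), ncol(total))
  cls[total > max1] <- -1L
  cls[total > max2] <- -2L
  cls[is.na(total)] <- NA_integer_
  cls
}

#' Accumulate climate stress and classify exclusion
#'
#' Sums daily [cold_stress_units()] and [heat_stress_units()] over the full
#' calendar year for every cell, then assigns three-level exclusion
#' classes: 0 where the total is at or below the moderate limit, -1
#' (moderate exclusion) above it, -2 (severe exclusion) above the severe
#' limit. The combined class is the worse (minimum) of the cold and heat
#' classes. Masked cells stay missing.
#'
#' @param temps a [daily_temperature_grid()].
#' @param params a [species_params()] supplying the stress thresholds and
#'   limits.
#' @return A `stress_result`: `cold_total`, `heat_total` (matrices,
#'   degree-days), `cold_class`, `heat_class`, `combined_class` (integer
#'   matrices in {0, -1, -2}), plus georeference fields.
#' @export
accumulate_stress <- function(temps, params) {
  stopifnot(inherits(temps, "daily_temperature_grid"),
            inherits(params, "species_params"))
  ndays <- dim(temps$tmin)[1]
  nr <- dim(temps$tmin)[2]; nc <- dim(temps$tmin)[3]
  tmin <- matrix(temps$tmin, ndays, nr * nc)
  tmax <- matrix(temps$tmax, ndays, nr * nc)
  cold <- matrix(colSums(matrix(cold_stress_units(
    tmin, tmax, params$coldstress_threshold), ndays)), nr, nc)
  heat <- matrix(colSums(matrix(heat_stress_units(
    tmin, tmax, params$heatstress_threshold), ndays)), nr, nc)
  cold[temps$missing_mask] <- NA
  heat[temps$missing_mask] <- NA
  cc <- .classify_stress(cold, params$coldstress_units_max1,
                         params$coldstress_units_max2)
  hc <- .classify_stress(heat, params$heatstress_units_max1,
                         params$heatstress_units_max2)
  structure(list(cold_total = cold, heat_total = heat,
                 cold_class = cc, heat_class = hc,
                 combined_class = pmin(cc, hc),
                 year = temps$year, xmin = temps$xmin, ymax = temps$ymax,
                 cellsize = temps$cellsize, crs = temps$crs),
            class = "stress_result")
}

#' @export
print.stress_result <- function(x, ...) {
  tab <- table(factor(x$combined_class, levels = c(0, -1, -2)),
               useNA = "ifany")
  cat("<stress_result> year ", x$year, ": ", sep = "")
  cat("class 0:", tab[1], " moderate(-1):", tab[2],
      " severe(-2):", tab[3], "\n")
  invisible(x)
}

#' Integrate phenology with climatic suitability
#'
#' Overlays the exclusion classification on an event-map set, producing
#' per-event maps with the four-way legend used for integrated risk maps:
#' the event DOY where the combined class is 0, and status labels
#' elsewhere (moderate exclusion, severe exclusion, or insufficient
#' degree-day accumulation where no cohort reached the event).
#'
#' @param events an [run_all_cohorts()] result.
#' @param stress an [accumulate_stress()] result on the same grid.
#' @param which_doy use the `"first"` or `"average"` combined event grids.
#' @return Named list (one entry per event) of lists with `doy` (matrix,
#'   `NA` outside class-0 cells) and `status` (integer matrix: 0 = event
#'   date shown, -1 = moderate exclusion, -2 = severe exclusion,
#'   1 = insufficient accumulation, `NA` = missing data).
#' @export
integrate_phenology_suitability <- function(events, stress,
                                            which_doy = c("first",
                                                          "average")) {
  which_doy <- match.arg(which_doy)
  stopifnot(inherits(events, "event_maps"),
            inherits(stress, "stress_result"))
  if (!identical(dim(events$first[[1]]), dim(stress$combined_class)))
    stop("event maps and stress grids are not co-registered")
  lapply(stats::setNames(nm = event_names()), function(e) {
    doy <- events[[which_doy]][[e]]
    status <- matrix(0L, nrow(doy), ncol(doy))
    status[stress$combined_class == -1L] <- -1L
    status[stress$combined_class == -2L] <- -2L
    status[events$insufficient[[e]] & status == 0L] <- 1L
    status[is.na(stress$combined_class)] <- NA_integer_
    doy[status != 0L | is.na(status)] <- NA
    list(doy = doy, status = status)
  })
}

#' Multi-year agreement of the potential distribution
#'
#' Counts, per cell, the years whose combined exclusion class is 0, i.e.
#' the years in which the cell is part of the potential distribution.
#'
#' @param stress_by_year list of co-registered [accumulate_stress()]
#'   results (>= 1).
#' @return Integer matrix of inclusion counts (`NA` where any year is
#'   missing).
#' @export
multi_year_agreement <- function(stress_by_year) {
  stopifnot(length(stress_by_year) >= 1)
  dims <- lapply(stress_by_year, function(s) dim(s$combined_class))
  if (length(unique(dims)) != 1) stop("stress grids are not co-registered")
  Reduce(`+`, lapply(stress_by_year,
                     function(s) (s$combined_class == 0L) + 0L))
}

#' Sensitivity of the classification to presence records
#'
#' The fraction of known presence locations that fall in cells counted as
#' part of the potential distribution. Mode `"both-levels"` counts only
#' class-0 cells as included (both moderate and severe stress exclude);
#' mode `"severe-only"` is the conservative option that excludes only
#' severely stressed cells (class >= -1 included). Records outside the
#' grid extent are reported separately, never silently dropped.
#'
#' @param lon,lat presence-record coordinates (equal length, >= 1).
#' @param stress an [accumulate_stress()] result.
#' @param mode `"both-levels"` or `"severe-only"`.
#' @return List with `sensitivity` (fraction of in-extent records
#'   included), `n_included`, `n_records`, `n_outside`, and `records` (the
#'   per-record data.frame with `class` and `included`).
#' @export
presence_sensitivity <- function(lon, lat, stress,
                                 mode = c("both-levels", "severe-only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stress, "stress_result"))
  if (!length(lon)) stop("empty presence-record list")
  ex <- extract_at_points(stress$combined_class + 0, lon, lat,
                          xmin = stress$xmin, ymax = stress$ymax,
                          cellsize = stress$cellsize)
  ex$class <- ex$value
  ex$included <- if (mode == "both-levels") ex$class == 0 else ex$class >= -1
  inex <- !ex$outside & !is.na(ex$class)
  list(sensitivity = if (any(inex)) mean(ex$included[inex]) else NA_real_,
       n_included = sum(ex$included[inex]),
       n_records = sum(inex),
       n_outside = sum(ex$outside),
       records = ex)
}

#' Longest run of days below a temperature threshold
#'
#' Diagnostic helper: the maximum number of consecutive days on which
#' daily Tmin falls below `threshold`, per cell, optionally restricted to
#' a set of days (e.g. winter months). Provided for exploring cold-stress
#' limits; it plays no part in the exclusion classification.
#'
#' @param temps a [daily_temperature_grid()].
#' @param threshold temperature, degC.
#' @param days optional integer DOYs to consider (default all).
#' @return Integer matrix of maximum run lengths.
#' @export
consecutive_days_below <- function(temps, threshold, days = NULL) {
  stopifnot(inherits(temps, "daily_temperature_grid"))
  ndays <- dim(temps$tmin)[1]
  if (is.null(days)) days <- seq_len(ndays)
  nr <- dim(temps$tmin)[2]; nc <- dim(temps$tmin)[3]
  tmin <- matrix(temps$tmin[days, , , drop = FALSE], length(days), nr * nc)
  below <- tmin < threshold
  maxrun <- apply(below, 2, function(b) {
    if (anyNA(b)) return(NA_integer_)
    r <- rle(b)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  })
  matrix(maxrun, nr, nc)
}
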