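# Daily thermal-unit kernels. The day's temperature course is idealized as
# a triangle rising from tmin to tmax and back; the area of that curve
# above (or below) a threshold, in degC * day, is the day's unit total.

# Area of the triangular diurnal curve above temperature x, per day.
# NA inputs yield NA.
.tri_area_above <- function(tmin, tmax, x) {
  na <- !is.finite(tmin) | !is.finite(tmax)
  if (any(na)) { tmin[na] <- 0; tmax[na] <- 0 }
  out <- numeric(length(tmin))
  flat <- tmax == tmin                      # degenerate constant-T day
  out[flat] <- pmax(tmin[flat] - x, 0)
  i <- !flat & tmin >= x
  out[i] <- (tmin[i] + tmax[i]) / 2 - x
  i <- !flat & tmin < x & x < tmax
  out[i] <- (tmax[i] - x)^2 / (2 * (tmax[i] - tmin[i]))
  out[na] <- NA_real_
  out
}

# Mirror image: area below temperature x.
.tri_area_below <- function(tmin, tmax, x) {
  na <- !is.finite(tmin) | !is.finite(tmax)
  if (any(na)) { tmin[na] <- 0; tmax[na] <- 0 }
  out <- numeric(length(tmin))
  flat <- tmax == tmin
  out[flat] <- pmax(x - tmin[flat], 0)
  i <- !flat & tmax <= x
  out[i] <- x - (tmin[i] + tmax[i]) / 2
  i <- !flat & tmin < x & x < tmax
  out[i] <- (x - tmin[i])^2 / (2 * (tmax[i] - tmin[i]))
  out[na] <- NA_real_
  out
}

.check_tmin_tmax <- function(tmin, tmax) {
  if (length(tmin) != length(tmax))
    stop("tmin and tmax must have equal length")
  bad <- which(is.finite(tmin) & is.finite(tmax) & tmin > tmax)
  if (length(bad))
    stop("tmin > tmax at position(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
}

#' Single-triangle degree-days with horizontal upper cutoff
#'
#' Computes one day's developmental degree-days from daily minimum and
#' maximum temperature by the single-triangle method: the diurnal
#' temperature course is a triangle from `tmin` up to `tmax` and back, and
#' degree-days are the area of that curve between the lower (`ldt`) and
#' upper (`udt`) developmental thresholds. Heat above `udt` is discarded
#' (horizontal cutoff), so the result lies in `[0, udt - ldt]`.
#'
#' With `A(x)` the area of the triangle above temperature `x`
#' (`0` if `tmax <= x`; `(tmax-x)^2 / (2(tmax-tmin))` if `tmin < x < tmax`;
#' `(tmin+tmax)/2 - x` if `tmin >= x`), the day's total is
#' `A(ldt) - A(udt)`. A degenerate day with `tmin == tmax == T` contributes
#' `clamp(T, ldt, udt) - ldt` when `T > ldt`, else 0.
#'
#' @param tmin,tmax daily minimum/maximum temperature, degC (vectorized;
#'   `tmin <= tmax` required elementwise).
#' @param ldt,udt lower and upper developmental thresholds, degC
#'   (`ldt < udt`).
#' @return Degree-days (degC), same length as `tmin`. `NA` where either
#'   input is `NA`.
#' @examples
#' single_triangle_dd(10, 20, 12.2, 36)   # 3.042
#' single_triangle_dd(40, 45, 12.2, 36)   # 23.8 = udt - ldt
#' @export
single_triangle_dd <- function(tmin, tmax, ldt, udt) {
  if (!(ldt < udt)) stop("ldt must be below udt")
  .check_tmin_tmax(tmin, tmax)
  na <- !is.finite(tmin) | !is.finite(tmax)
  dd <- .tri_area_above(tmin, tmax, ldt) - .tri_area_above(tmin, tmax, udt)
  dd <- pmin(pmax(dd, 0), udt - ldt)
  dd[na] <- NA_real_
  dd
}

#' Daily cold and heat stress units
#'
#' Cold stress units are the area of the day's triangular temperature curve
#' below the cold stress threshold (degree-days degC below threshold); heat
#' stress units are the area above the heat stress threshold, with no upper
#' cutoff. Stress accrues every day of the year regardless of life stage,
#' and yearly totals drive the establishment-risk exclusion classes (see
#' [accumulate_stress()]).
#'
#' @param tmin,tmax daily minimum/maximum temperature, degC (vectorized).
#' @param threshold stress threshold, degC (defaults: -31 cold, 38 heat,
#'   the emerald ash borer values).
#' @return Stress units (degree-days degC), same length as `tmin`.
#' @examples
#' cold_stress_units(-35, -20, -31)  # 0.533
#' heat_stress_units(25, 45, 38)     # 1.225
#' @export
cold_stress_units <- function(tmin, tmax, threshold = -31) {
  .check_tmin_tmax(tmin, tmax)
  na <- !is.finite(tmin) | !is.finite(tmax)
  out <- .tri_area_below(tmin, tmax, threshold)
  out[na] <- NA_real_
  out
}

#' @rdname cold_stress_units
#' @export
heat_stress_units <- function(tmin, tmax, threshold = 38) {
  .check_tmin_tmax(tmin, tmax)
  na <- !is.finite(tmin) | !is.finite(tmax)
  out <- .tri_area_above(tmin, tmax, threshold)
  out[na] <- NA_real_
  out
}
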