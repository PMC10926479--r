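# PNG summary maps with fixed, documented color classes so runs are
# visually comparable. Styling is deliberately plain: an event-date
# gradient plus three flat status colors.

.status_cols <- c(moderate = "grey55", severe = "grey25",
                  insufficient = "grey85", missing = "white")

#' Plot an integrated phenology/suitability map
#'
#' Renders one event's integrated map with the four-way legend: a color
#' gradient over event DOY where the cell is climatically suitable, and
#' flat grays for moderate exclusion (grey55), severe exclusion (grey25)
#' and insufficient degree-day accumulation (grey85).
#'
#' @param layer one element of [integrate_phenology_suitability()] output
#'   (list with `doy` and `status`).
#' @param title plot title.
#' @param file optional PNG path; when given the plot is written there.
#' @return `file` (or `NULL` when plotting to the active device),
#'   invisibly.
#' @export
plot_integrated_map <- function(layer, title = "", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 640)
    on.exit(grDevices::dev.off())
  }
  doy <- layer$doy; status <- layer$status
  nr <- nrow(doy); nc <- ncol(doy)
  img <- matrix(NA_integer_, nr, nc)
  ramp <- grDevices::hcl.colors(64, "Viridis")
  rng <- range(doy, na.rm = TRUE)
  if (all(is.finite(rng))) {
    span <- max(rng[2] - rng[1], 1)
    img[!is.na(doy)] <- 1L + as.integer(63 * (doy[!is.na(doy)] - rng[1]) / span)
  }
  img[status == -1L] <- 65L
  img[status == -2L] <- 66L
  img[status == 1L] <- 67L
  pal <- c(ramp, .status_cols[["moderate"]], .status_cols[["severe"]],
           .status_cols[["insufficient"]])
  # image() draws row 1 at the bottom; flip so north stays up
  graphics::image(t(img[nr:1, , drop = FALSE]), col = pal,
                  zlim = c(1, 67), axes = FALSE, main = title,
                  useRaster = TRUE)
  graphics::legend("bottomright", bty = "n", cex = 0.8,
                   fill = c(ramp[1], ramp[64], pal[65:67]),
                   legend = c(paste("DOY", round(rng[1])),
                              paste("DOY", round(rng[2])),
                              "moderate exclusion", "severe exclusion",
                              "insufficient accumulation"))
  invisible(file)
}

#' Plot a trend map
#'
#' Tau map in a blue-red diverging palette with non-significant pixels
#' (p > 0.1) and no-trend pixels (S = 0) drawn in light gray.
#'
#' @param tm a [trend_map()] result.
#' @param title plot title.
#' @param file optional PNG path.
#' @return `file`, invisibly.
#' @export
plot_trend_map <- function(tm, title = "", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 640)
    on.exit(grDevices::dev.off())
  }
  tau <- tm$tau
  nr <- nrow(tau)
  img <- matrix(NA_integer_, nr, ncol(tau))
  ramp <- grDevices::hcl.colors(64, "Blue-Red 3")
  ok <- !is.na(tau)
  img[ok] <- 1L + as.integer(63 * (tau[ok] + 1) / 2)
  img[tm$no_trend | (!is.na(tm$significant) & !tm$significant)] <- 65L
  graphics::image(t(img[nr:1, , drop = FALSE]), col = c(ramp, "grey85"),
                  zlim = c(1, 65), axes = FALSE, main = title,
                  useRaster = TRUE)
  graphics::legend("bottomright", bty = "n", cex = 0.8,
                   fill = c(ramp[1], ramp[64], "grey85"),
                   legend = c("tau = -1", "tau = +1",
                              "no / non-significant trend"))
  invisible(file)
}
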