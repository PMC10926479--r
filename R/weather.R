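#' Daily temperature grids
#'
#' A `daily_temperature_grid` stores one calendar year of gridded daily
#' minimum and maximum temperature: two `day x row x col` arrays (degC),
#' the vector of dates (1 Jan .. 31 Dec), a simple georeference (x of the
#' west edge, y of the north edge, square cell size, CRS label), and a
#' `missing_mask` marking every cell with at least one missing day. Masked
#' cells propagate as missing through all downstream model outputs. Row 1
#' is the northernmost row.
#'
#' @param tmin,tmax numeric arrays `day x row x col` (degC). A matrix or a
#'   vector is accepted for a 1 x 1 (site) grid.
#' @param year calendar year covered; `dim(tmin)[1]` must be 365 or 366 to
#'   match.
#' @param xmin,ymax coordinates of the grid's west and north edges.
#' @param cellsize square cell size in coordinate units.
#' @param crs free-text CRS label (not interpreted).
#' @return A `daily_temperature_grid` object.
#' @export
daily_temperature_grid <- function(tmin, tmax, year,
                                   xmin = 0, ymax = 0, cellsize = 1,
                                   crs = "unspecified") {
  if (is.null(dim(tmin))) tmin <- array(tmin, c(length(tmin), 1, 1))
  if (is.null(dim(tmax))) tmax <- array(tmax, c(length(tmax), 1, 1))
  if (length(dim(tmin)) == 2) tmin <- array(tmin, c(dim(tmin), 1))
  if (length(dim(tmax)) == 2) tmax <- array(tmax, c(dim(tmax), 1))
  if (!identical(dim(tmin), dim(tmax)))
    stop("tmin and tmax arrays must have identical dimensions")
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  if (dim(tmin)[1] != length(dates))
    stop("expected ", length(dates), " day layers for year ", year,
         ", got ", dim(tmin)[1])
  bad <- which(is.finite(tmin) & is.finite(tmax) & tmin > tmax)
  if (length(bad)) {
    idx <- arrayInd(utils::head(bad, 5), dim(tmin))
    stop("tmin > tmax at [day,row,col]: ",
         paste(apply(idx, 1, paste, collapse = ","), collapse = "; "),
         if (length(bad) > 5) " ..." else "")
  }
  miss <- apply(!is.finite(tmin) | !is.finite(tmax), c(2, 3), any)
  structure(list(tmin = tmin, tmax = tmax, dates = dates, year = year,
                 xmin = xmin, ymax = ymax, cellsize = cellsize, crs = crs,
                 missing_mask = miss),
            class = "daily_temperature_grid")
}

#' @export
print.daily_temperature_grid <- function(x, ...) {
  d <- dim(x$tmin)
  cat("<daily_temperature_grid> ", x$year, ": ", d[1], " days x ",
      d[2], " x ", d[3], " cells (", sum(x$missing_mask),
      " masked), origin (", x$xmin, ", ", x$ymax, "), cellsize ",
      x$cellsize, "\n", sep = "")
  invisible(x)
}

#' Synthetic daily weather configuration
#'
#' Describes a seeded synthetic year of gridded daily Tmin/Tmax used in
#' place of downloaded climate data: a sinusoidal annual cycle around a
#' base mean, a per-row latitudinal gradient, a fixed diurnal range, and
#' Gaussian day/cell noise. The daily mean at (row, col, day d) is
#' `base - gradient * (row - 1) + amplitude * cos(2*pi*(d - peak_day)/365)
#' + noise`, and `tmin/tmax = mean -/+ diurnal_range/2` (noise is applied
#' to the mean, so `tmin <= tmax` always holds). Rows are numbered from the
#' north, so a negative `gradient` makes the north colder.
#'
#' Defaults emulate a mid-latitude temperate year on a 20 x 20 grid:
#' annual mean 10 degC, seasonal amplitude 14 degC peaking on 20 July
#' (day 201), diurnal range 10 degC, day-to-day noise SD 3 degC.
#'
#' @param nrow,ncol grid dimensions.
#' @param base base annual-mean temperature, degC.
#' @param amplitude seasonal half-amplitude, degC (>= 0).
#' @param peak_day day of year of the warm peak.
#' @param diurnal_range tmax - tmin, degC (>= 0).
#' @param gradient per-row cooling, degC per row (applied as
#'   `-gradient * (row - 1)`).
#' @param noise_sd SD of Gaussian noise on the daily mean, degC (>= 0).
#' @param seed integer random seed; fixed seed gives identical output.
#' @param year calendar year (366 layers in leap years; the seasonal
#'   formula keeps period 365).
#' @param xmin,ymax,cellsize,crs georeference passed through to the grid.
#' @return A `synthetic_weather_config` object.
#' @export
synthetic_weather_config <- function(nrow = 20, ncol = 20, base = 10,
                                     amplitude = 14, peak_day = 201,
                                     diurnal_range = 10, gradient = 0,
                                     noise_sd = 3, seed = 1L, year = 2021,
                                     xmin = 0, ymax = nrow, cellsize = 1,
                                     crs = "synthetic") {
  stopifnot(nrow >= 1, ncol >= 1, amplitude >= 0, diurnal_range >= 0,
            noise_sd >= 0)
  structure(list(nrow = nrow, ncol = ncol, base = base,
                 amplitude = amplitude, peak_day = peak_day,
                 diurnal_range = diurnal_range, gradient = gradient,
                 noise_sd = noise_sd, seed = as.integer(seed), year = year,
                 xmin = xmin, ymax = ymax, cellsize = cellsize, crs = crs),
            class = "synthetic_weather_config")
}

#' Generate a synthetic year of daily weather
#'
#' Realizes the deterministic-plus-noise model described by
#' [synthetic_weather_config()] into a [daily_temperature_grid()].
#' Reproducible: the same config (including seed) always yields identical
#' arrays.
#'
#' @param cfg a [synthetic_weather_config()].
#' @return A [daily_temperature_grid()].
#' @examples
#' g <- synth_weather(synthetic_weather_config(nrow = 2, ncol = 2,
#'                                             noise_sd = 0))
#' dim(g$tmin)
#' @export
synth_weather <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_weather_config"))
  ndays <- length(seq(as.Date(paste0(cfg$year, "-01-01")),
                      as.Date(paste0(cfg$year, "-12-31")), by = "day"))
  d <- seq_len(ndays)
  seasonal <- cfg$base + cfg$amplitude * cos(2 * pi * (d - cfg$peak_day) / 365)
  rowterm <- -cfg$gradient * (seq_len(cfg$nrow) - 1)
  tmean <- array(0, c(ndays, cfg$nrow, cfg$ncol))
  tmean <- tmean + seasonal                       # recycles over day index
  tmean <- tmean + rep(rep(rowterm, each = ndays), cfg$ncol)
  if (cfg$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
    tmean <- tmean + array(stats::rnorm(length(tmean), 0, cfg$noise_sd),
                           dim(tmean))
  }
  daily_temperature_grid(tmean - cfg$diurnal_range / 2,
                         tmean + cfg$diurnal_range / 2,
                         year = cfg$year, xmin = cfg$xmin, ymax = cfg$ymax,
                         cellsize = cfg$cellsize, crs = cfg$crs)
}

# ---- plain-text raster I/O ------------------------------------------------
# Grids are exchanged as ESRI-style ASCII text: a 6-line header (ncols,
# nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of
# values, north row first. A "stack" file extends the header with nbands
# and band_dates and concatenates one block per day.

#' Read and write single-layer ASCII grids
#'
#' Plain-text raster exchange in the ESRI ASCII grid dialect (6-line
#' header, then `nrows` lines of `ncols` values, northernmost row first).
#'
#' @param x numeric matrix (row 1 = north).
#' @param path file path.
#' @param xmin,ymax west/north edge coordinates.
#' @param cellsize square cell size.
#' @param nodata value written for `NA` cells.
#' @return `read_ascii_grid`: a list with `values` (matrix), `xmin`,
#'   `ymax`, `cellsize`. `write_ascii_grid`: `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, xmin = 0, ymax = nrow(x),
                             cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(x))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", ncol(x)),
               paste("nrows", nrow(x)),
               paste("xllcorner", format(xmin, digits = 15)),
               paste("yllcorner", format(ymax - nrow(x) * cellsize,
                                         digits = 15)),
               paste("cellsize", format(cellsize, digits = 15)),
               paste("NODATA_value", nodata)), con)
  v <- x
  v[!is.finite(v)] <- nodata
  writeLines(apply(v, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  nr <- vals[["nrows"]]; nc <- vals[["ncols"]]
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  list(values = m, xmin = vals[["xllcorner"]],
       ymax = vals[["yllcorner"]] + nr * vals[["cellsize"]],
       cellsize = vals[["cellsize"]])
}

write_ascii_stack <- function(arr, path, xmin, ymax, cellsize,
                              dates = NULL, nodata = -9999) {
  stopifnot(length(dim(arr)) == 3)
  nb <- dim(arr)[1]; nr <- dim(arr)[2]; nc <- dim(arr)[3]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", nc), paste("nrows", nr),
               paste("xllcorner", format(xmin, digits = 15)),
               paste("yllcorner", format(ymax - nr * cellsize, digits = 15)),
               paste("cellsize", format(cellsize, digits = 15)),
               paste("NODATA_value", nodata),
               paste("nbands", nb),
               paste("band_dates",
                     if (is.null(dates)) "" else
                       paste(format(dates), collapse = ","))), con)
  for (b in seq_len(nb)) {
    v <- arr[b, , , drop = TRUE]
    v <- matrix(v, nr, nc)
    v[!is.finite(v)] <- nodata
    writeLines(apply(v, 1, function(r)
      paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = " ")), con)
  }
  invisible(path)
}

read_ascii_stack <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:8], "\\s+")
  keys <- tolower(vapply(hdr, `[[`, "", 1L))
  get <- function(k) hdr[[match(k, keys)]][2]
  nc <- as.integer(get("ncols")); nr <- as.integer(get("nrows"))
  nb <- as.integer(get("nbands"))
  cs <- as.numeric(get("cellsize"))
  nodata <- as.numeric(get("nodata_value"))
  dates <- if (length(hdr[[8]]) > 1)
    as.Date(strsplit(get("band_dates"), ",")[[1]]) else NULL
  body <- scan(text = lines[-(1:8)], quiet = TRUE)
  if (length(body) != nb * nr * nc)
    stop("ASCII stack body has ", length(body), " values, expected ",
         nb * nr * nc)
  arr <- array(NA_real_, c(nb, nr, nc))
  per <- nr * nc
  for (b in seq_len(nb))
    arr[b, , ] <- matrix(body[((b - 1) * per + 1):(b * per)], nr, nc,
                         byrow = TRUE)
  arr[arr == nodata] <- NA
  list(values = arr, xmin = as.numeric(get("xllcorner")),
       ymax = as.numeric(get("yllcorner")) + nr * cs,
       cellsize = cs, dates = dates)
}

#' Read one year of daily temperature grids
#'
#' Reads paired daily Tmin/Tmax data into a [daily_temperature_grid()].
#' Two plain-text routes are supported: `"ascii-stack"` (a pair of stacked
#' ASCII grid files, one band per day — the package's text stand-in for
#' multi-band GeoTIFF/NetCDF stacks) and `"site-csv"` (a single-site CSV
#' with columns `date,tmin,tmax`, yielding a 1 x 1 grid).
#'
#' @param source for `"ascii-stack"`, `c(tmin = path, tmax = path)`; for
#'   `"site-csv"`, one CSV path.
#' @param format `"ascii-stack"` or `"site-csv"`.
#' @param year calendar year; defaults to the year of the first date found.
#' @return A validated [daily_temperature_grid()]. Band/record count must
#'   match the year's length (365/366); `tmin > tmax` anywhere is an error.
#' @seealso [write_daily_grids()]
#' @export
read_daily_grids <- function(source, format = c("ascii-stack", "site-csv"),
                             year = NULL) {
  format <- match.arg(format)
  missing_src <- source[!file.exists(source)]
  if (length(missing_src))
    stop("input file not found: ", paste(missing_src, collapse = ", "))
  if (format == "site-csv") {
    df <- utils::read.csv(source, stringsAsFactors = FALSE)
    need <- c("date", "tmin", "tmax")
    if (!all(need %in% names(df)))
      stop("site CSV must have columns date,tmin,tmax")
    df$date <- as.Date(df$date)
    df <- df[order(df$date), ]
    if (is.null(year)) year <- as.integer(format(df$date[1], "%Y"))
    dates <- seq(as.Date(paste0(year, "-01-01")),
                 as.Date(paste0(year, "-12-31")), by = "day")
    if (!identical(df$date, dates))
      stop("site CSV must cover every day of ", year, " exactly once")
    return(daily_temperature_grid(df$tmin, df$tmax, year = year))
  }
  if (!all(c("tmin", "tmax") %in% names(source)))
    stop("source must be c(tmin = <path>, tmax = <path>)")
  a <- read_ascii_stack(source[["tmin"]])
  b <- read_ascii_stack(source[["tmax"]])
  if (!identical(dim(a$values), dim(b$values)))
    stop("tmin and tmax stacks have different shapes")
  if (is.null(year)) {
    if (is.null(a$dates)) stop("year not given and stack carries no dates")
    year <- as.integer(format(a$dates[1], "%Y"))
  }
  daily_temperature_grid(a$values, b$values, year = year, xmin = a$xmin,
                         ymax = a$ymax, cellsize = a$cellsize)
}

#' Write one year of daily temperature grids
#'
#' Inverse of [read_daily_grids()]: writes the `"ascii-stack"` pair or a
#' `"site-csv"` file. Round-trips exactly through `read_daily_grids()`.
#'
#' @param grid a [daily_temperature_grid()].
#' @param source output path(s), as in [read_daily_grids()].
#' @param format `"ascii-stack"` or `"site-csv"`.
#' @return `source`, invisibly.
#' @export
write_daily_grids <- function(grid, source,
                              format = c("ascii-stack", "site-csv")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "daily_temperature_grid"))
  if (format == "site-csv") {
    if (any(dim(grid$tmin)[2:3] != 1))
      stop("site-csv output requires a 1 x 1 grid")
    utils::write.csv(data.frame(date = format(grid$dates),
                                tmin = grid$tmin[, 1, 1],
                                tmax = grid$tmax[, 1, 1]),
                     source, row.names = FALSE, quote = FALSE)
    return(invisible(source))
  }
  write_ascii_stack(grid$tmin, source[["tmin"]], grid$xmin, grid$ymax,
                    grid$cellsize, grid$dates)
  write_ascii_stack(grid$tmax, source[["tmax"]], grid$xmin, grid$ymax,
                    grid$cellsize, grid$dates)
  invisible(source)
}

#' Extract grid values at points
#'
#' Nearest-cell (containing-cell) lookup of a single-layer grid at lon/lat
#' points. Cell extents are half-open: `[x, x + cellsize)` horizontally and
#' `(y - cellsize, y]` vertically, so a point on a shared vertical edge
#' belongs to the cell starting at that edge and a point on a shared
#' horizontal edge to the cell whose top it is. Points outside the extent
#' are returned as `NA` with `outside = TRUE`, never silently dropped.
#'
#' @param values numeric matrix (row 1 = north).
#' @param lon,lat point coordinates (equal length).
#' @param xmin,ymax,cellsize grid georeference.
#' @return A data.frame with `lon`, `lat`, `row`, `col`, `value`,
#'   `outside`.
#' @export
extract_at_points <- function(values, lon, lat, xmin = 0,
                              ymax = nrow(values), cellsize = 1) {
  stopifnot(is.matrix(values), length(lon) == length(lat))
  if (!length(lon))
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      row = integer(0), col = integer(0),
                      value = numeric(0), outside = logical(0)))
  # floor() realizes both half-open conventions: a vertical edge belongs to
  # the cell whose west edge it is, a horizontal edge to the cell whose top
  # it is (the grid's own top edge lands in row 1)
  col <- floor((lon - xmin) / cellsize) + 1L
  row <- floor((ymax - lat) / cellsize) + 1L
  out <- row < 1L | row > nrow(values) | col < 1L | col > ncol(values)
  val <- rep(NA_real_, length(lon))
  ok <- !out
  val[ok] <- values[cbind(row[ok], col[ok])]
  data.frame(lon = lon, lat = lat,
             row = ifelse(out, NA_integer_, row),
             col = ifelse(out, NA_integer_, col),
             value = val, outside = out)
}
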