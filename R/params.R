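#' Species parameter sets
#'
#' A `species_params` object holds every tunable constant of the model:
#' per-stage lower/upper developmental thresholds (LDT/UDT, degC), stage
#' durations and event offsets (degree-days degC), cold/heat stress
#' thresholds and moderate/severe stress-unit limits, and the settings of
#' the overwintering-cohort completion distribution (lognormal mean,
#' variance, truncation bounds, cohort count).
#'
#' The packaged defaults parameterize emerald ash borer (*Agrilus
#' planipennis*): all stages share LDT 12.2 degC and UDT 36 degC; stage
#' durations are egg 172, larvae 700, pupae 135, adult 145 DD; oviposition
#' occurs 72 DD into the adult stage; cold stress accrues below -31 degC
#' with moderate/severe limits 80/160 units; heat stress accrues above
#' 38 degC with limits 75/150.
#'
#' `ow_event_dd` (the overwintered J-larva completion requirement) is not a
#' user-settable scalar: it varies by cohort and is always derived from the
#' cohort set (see [make_cohorts()]).
#'
#' @param ... named overrides of default parameter values, e.g.
#'   `n_cohorts = 1`.
#' @return A validated `species_params` object (a named list).
#' @seealso [load_params()], [make_cohorts()]
#' @examples
#' p <- species_params()
#' p$egg_dd
#' species_params(n_cohorts = 1)$n_cohorts
#' @export
species_params <- function(...) {
  p <- eab_defaults()
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) {
      warning("unknown parameter key(s) ignored: ",
              paste(unknown, collapse = ", "))
      ov <- ov[setdiff(names(ov), unknown)]
    }
    p[names(ov)] <- ov
  }
  validate_params(p)
}

# Table of defaults for emerald ash borer. Temperatures degC, durations DD.
eab_defaults <- function() {
  list(
    egg_ldt = 12.2, larvae_ldt = 12.2, pupae_ldt = 12.2, adult_ldt = 12.2,
    egg_udt = 36.0, larvae_udt = 36.0, pupae_udt = 36.0, adult_udt = 36.0,
    egg_dd = 172, larvae_dd = 700, pup_dd = 135, adult_dd = 145,
    egg_event_dd = 172, larvae_event_dd = 700, pupae_event_dd = 135,
    adult_event_dd = 72,
    coldstress_threshold = -31,
    coldstress_units_max1 = 80, coldstress_units_max2 = 160,
    heatstress_threshold = 38,
    heatstress_units_max1 = 75, heatstress_units_max2 = 150,
    distro_mean = 200, distro_var = 15000,
    xdist1 = 60, xdist2 = 350,
    distro_shape = "lognormal",
    n_cohorts = 7L,
    stgorder = c("OL", "P", "A", "E", "L"),
    obligate_diapause = TRUE,
    calctype = "triangle"
  )
}

numeric_param_keys <- function() {
  setdiff(names(eab_defaults()),
          c("distro_shape", "stgorder", "obligate_diapause", "calctype"))
}

validate_params <- function(p) {
  fail <- function(...) stop("invalid species parameters: ", ..., call. = FALSE)
  for (k in numeric_param_keys()) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      fail("'", k, "' must be a single finite number")
    p[[k]] <- as.numeric(v)
  }
  for (st in c("egg", "larvae", "pupae", "adult")) {
    ldt <- p[[paste0(st, "_ldt")]]; udt <- p[[paste0(st, "_udt")]]
    if (ldt >= udt)
      fail("'", st, "_ldt' (", ldt, ") must be below '", st, "_udt' (", udt, ")")
  }
  for (k in c("egg_dd", "larvae_dd", "pup_dd", "adult_dd",
              "egg_event_dd", "larvae_event_dd", "pupae_event_dd",
              "adult_event_dd"))
    if (p[[k]] <= 0) fail("'", k, "' must be > 0")
  if (!(p$xdist1 < p$distro_mean && p$distro_mean < p$xdist2))
    fail("'xdist1' < 'distro_mean' < 'xdist2' is required (got ",
         p$xdist1, ", ", p$distro_mean, ", ", p$xdist2, ")")
  if (p$distro_var <= 0) fail("'distro_var' must be > 0")
  if (p$coldstress_units_max1 >= p$coldstress_units_max2)
    fail("'coldstress_units_max1' must be below 'coldstress_units_max2'")
  if (p$heatstress_units_max1 >= p$heatstress_units_max2)
    fail("'heatstress_units_max1' must be below 'heatstress_units_max2'")
  p$n_cohorts <- as.integer(p$n_cohorts)
  if (p$n_cohorts < 1L) fail("'n_cohorts' must be >= 1")
  if (!is.character(p$stgorder) ||
      !identical(sort(p$stgorder), sort(c("OL", "P", "A", "E", "L"))) ||
      p$stgorder[1] != "OL")
    fail("'stgorder' must be a permutation of OL,P,A,E,L starting with OL")
  if (!identical(p$distro_shape, "lognormal"))
    fail("'distro_shape': only 'lognormal' is supported")
  if (!identical(p$calctype, "triangle"))
    fail("'calctype': only 'triangle' is supported")
  p$obligate_diapause <- isTRUE(p$obligate_diapause) ||
    identical(p$obligate_diapause, 1) || identical(p$obligate_diapause, "1")
  structure(p[names(eab_defaults())], class = "species_params")
}

#' Read a species parameter file
#'
#' Parses a plain `key = value` parameter file (one pair per line, `#`
#' comments allowed) using the field's standard code names
#' (`coldstress_threshold`, `distro_mean`, `stgorder`, ...). Missing keys
#' fall back to the packaged emerald ash borer defaults; unknown keys are
#' reported with a warning; invariant violations raise an error naming the
#' offending key.
#'
#' @param path path to a parameter file. The packaged default file is at
#'   `system.file("extdata", "emerald_ash_borer.txt", package = "phenorisk")`.
#' @return A validated [species_params()] object.
#' @examples
#' f <- system.file("extdata", "emerald_ash_borer.txt", package = "phenorisk")
#' p <- load_params(f)
#' p$coldstress_threshold
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed parameter line(s): ",
         paste(shQuote(lines[bad]), collapse = ", "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  if (anyDuplicated(keys))
    stop("duplicate parameter key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  ov <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% numeric_param_keys()) {
      num <- suppressWarnings(as.numeric(gsub("−", "-", v)))
      if (is.na(num))
        stop("parameter '", k, "' has non-numeric value '", v, "'")
      ov[[k]] <- num
    } else if (k == "stgorder") {
      ov[[k]] <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    } else if (k == "obligate_diapause") {
      ov[[k]] <- v %in% c("1", "TRUE", "true")
    } else {
      ov[[k]] <- v
    }
  }
  do.call(species_params, ov)
}

#' Write a species parameter set
#'
#' `write_params()` serializes to the `key = value` text dialect read by
#' [load_params()] (round-trip safe); `params_to_json()` exports a JSON
#' record of the validated set for provenance logging.
#'
#' @param params a [species_params()] object.
#' @param path output file path.
#' @return `path`, invisibly (`write_params`); a JSON string
#'   (`params_to_json`).
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "species_params"))
  fmt <- function(k) {
    v <- params[[k]]
    if (k == "stgorder") v <- paste(v, collapse = ",")
    if (k == "obligate_diapause") v <- if (v) "1" else "0"
    paste0(k, " = ", v)
  }
  writeLines(vapply(names(params), fmt, ""), path)
  invisible(path)
}

#' @rdname write_params
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "species_params"))
  jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>\n")
  cat("  thresholds (degC): LDT",
      paste(unique(unlist(x[paste0(c("egg", "larvae", "pupae", "adult"),
                                   "_ldt")])), collapse = "/"),
      " UDT",
      paste(unique(unlist(x[paste0(c("egg", "larvae", "pupae", "adult"),
                                   "_udt")])), collapse = "/"), "\n")
  cat("  stage DD: egg", x$egg_dd, "larvae", x$larvae_dd,
      "pupae", x$pup_dd, "adult", x$adult_dd, "\n")
  cat("  cold stress:", x$coldstress_threshold, "degC, limits",
      x$coldstress_units_max1, "/", x$coldstress_units_max2, "\n")
  cat("  heat stress:", x$heatstress_threshold, "degC, limits",
      x$heatstress_units_max1, "/", x$heatstress_units_max2, "\n")
  cat("  cohorts:", x$n_cohorts, x$distro_shape, "mean", x$distro_mean,
      "var", x$distro_var, "on [", x$xdist1, ",", x$xdist2, "]\n")
  invisible(x)
}
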