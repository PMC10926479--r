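# Time-distributed overwintering cohorts. Within-site variation in spring
# emergence is represented by n subpopulations that differ in the
# degree-days their overwintered J-larvae need to finish development.

# log-space parameters of a lognormal with arithmetic mean m and variance v
.lnorm_pars <- function(m, v) {
  s2 <- log(1 + v / m^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Construct the overwintering cohort set
#'
#' Partitions the distribution of J-larval development-completion
#' requirements into `n_cohorts` cohorts. The distribution is lognormal
#' with arithmetic mean `distro_mean` and variance `distro_var`
#' (log-space `sigma^2 = log(1 + var/mean^2)`,
#' `mu = log(mean) - sigma^2/2`), truncated to `[xdist1, xdist2]`. The
#' truncated range is split into `n_cohorts` equal-width bins; each
#' cohort's weight is its bin's probability mass (renormalized over the
#' truncation window) and its completion requirement is the
#' density-weighted mean of the bin.
#'
#' With the packaged emerald ash borer defaults (mean 200, variance 15000,
#' bounds [60, 350], 7 cohorts) the implied adult-emergence window —
#' completion requirement plus the 135 DD pupal stage — spans about 218 to
#' 463 DDC.
#'
#' @param params a [species_params()] object.
#' @return A `cohort_set`: list with `completion_dd` (strictly increasing),
#'   `weight` (positive, summing to 1) and `n`.
#' @examples
#' co <- make_cohorts(species_params())
#' round(co$completion_dd + 135)
#' @export
make_cohorts <- function(params) {
  stopifnot(inherits(params, "species_params"))
  lp <- .lnorm_pars(params$distro_mean, params$distro_var)
  n <- params$n_cohorts
  br <- seq(params$xdist1, params$xdist2, length.out = n + 1)
  cdf <- stats::plnorm(br, lp$meanlog, lp$sdlog)
  z <- cdf[n + 1] - cdf[1]
  if (z < 1e-6)
    stop("lognormal mass over [xdist1, xdist2] is below 1e-6; ",
         "check distro_mean/distro_var against the truncation bounds")
  w <- diff(cdf) / z
  completion <- vapply(seq_len(n), function(i) {
    num <- stats::integrate(function(x) x * stats::dlnorm(x, lp$meanlog,
                                                          lp$sdlog),
                            br[i], br[i + 1], rel.tol = 1e-10)$value
    num / (cdf[i + 1] - cdf[i])
  }, numeric(1))
  structure(list(completion_dd = completion, weight = w, n = n),
            class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("<cohort_set> ", x$n, " cohorts\n", sep = "")
  print(data.frame(completion_dd = round(x$completion_dd, 2),
                   weight = round(x$weight, 4)))
  invisible(x)
}

#' Calibrate cohort-distribution parameters by grid search
#'
#' Scores candidate `(xdist1, distro_mean, xdist2, distro_var)` tuples
#' against observed first and peak (50%) adult emergence dates: for each
#' candidate, a cohort set is built, the phenology engine is run for every
#' site-year, and the combined mean absolute error MAE(first) + MAE(peak)
#' is computed. Candidates violating `xdist1 < mean < xdist2` or with
#' non-positive variance are skipped with a warning. Peak emergence is the
#' weighted median: the earliest day by which cohorts holding at least
#' half the population weight have emerged.
#'
#' @param observed data.frame with columns `site`, `year`, `event`
#'   (`"first_emergence"` or `"peak_emergence"`), `doy`.
#' @param site_weather named list of single-site
#'   [daily_temperature_grid()]s, names `"<site>_<year>"`.
#' @param candidates data.frame with columns `xdist1`, `distro_mean`,
#'   `xdist2`, `distro_var`.
#' @param params baseline [species_params()] supplying all other values.
#' @return The candidate data.frame with `mae_first`, `mae_peak` and
#'   `combined_mae` attached, sorted ascending by `combined_mae`.
#' @export
calibrate_cohort_params <- function(observed, site_weather, candidates,
                                    params = species_params()) {
  stopifnot(is.data.frame(observed),
            all(c("site", "year", "event", "doy") %in% names(observed)),
            nrow(candidates) >= 1)
  keys <- paste(observed$site, observed$year, sep = "_")
  missing_wx <- setdiff(unique(keys), names(site_weather))
  if (length(missing_wx))
    stop("no weather for site-year(s): ", paste(missing_wx, collapse = ", "))
  ok <- with(candidates, xdist1 < distro_mean & distro_mean < xdist2 &
               distro_var > 0)
  if (any(!ok))
    warning(sum(!ok), " candidate(s) violating xdist1 < mean < xdist2 ",
            "(or var <= 0) skipped")
  cand <- candidates[ok, , drop = FALSE]
  res <- lapply(seq_len(nrow(cand)), function(i) {
    p <- params
    p$xdist1 <- cand$xdist1[i]; p$xdist2 <- cand$xdist2[i]
    p$distro_mean <- cand$distro_mean[i]; p$distro_var <- cand$distro_var[i]
    p <- validate_params(unclass(p))
    co <- make_cohorts(p)
    pred <- lapply(unique(keys), function(k) {
      em <- run_all_cohorts(site_weather[[k]], p, co)
      c(first = em$first$adult_emergence[1, 1],
        peak = weighted_median_doy(
          vapply(em$per_cohort, function(m) m$adult_emergence[1, 1],
                 numeric(1)), co$weight))
    })
    names(pred) <- unique(keys)
    err_f <- err_p <- numeric(0)
    for (j in seq_len(nrow(observed))) {
      pr <- pred[[keys[j]]]
      if (observed$event[j] == "first_emergence")
        err_f <- c(err_f, pr[["first"]] - observed$doy[j])
      else if (observed$event[j] == "peak_emergence")
        err_p <- c(err_p, pr[["peak"]] - observed$doy[j])
    }
    c(mae_first = if (length(err_f)) mean(abs(err_f), na.rm = TRUE) else NA,
      mae_peak = if (length(err_p)) mean(abs(err_p), na.rm = TRUE) else NA)
  })
  res <- do.call(rbind, res)
  out <- cbind(cand, res)
  out$combined_mae <- rowSums(res, na.rm = TRUE)
  out[order(out$combined_mae), , drop = FALSE]
}

# earliest DOY by which cohorts comprising >= half the total weight have
# reached the event; NA if they never do
weighted_median_doy <- function(doys, weights) {
  if (all(is.na(doys))) return(NA_real_)
  o <- order(doys, na.last = TRUE)
  cw <- cumsum(weights[o])
  hit <- which(cw >= 0.5 & !is.na(doys[o]))
  if (!length(hit)) return(NA_real_)
  doys[o][hit[1]]
}
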