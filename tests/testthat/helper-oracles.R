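# Independent oracles, kept deliberately naive and separate from the
# package's closed-form / vectorized code paths.

# Minute-resolution numerical integration of the triangular diurnal curve.
# The day's temperature rises linearly from tmin (midnight) to tmax (noon)
# and back; thermal units are the time-average of the clipped excess.
tri_minute_curve <- function(tmin, tmax, n_min = 1440L) {
  t <- (seq_len(n_min) - 0.5) / n_min            # fraction of day
  up <- t <= 0.5
  tmin + (tmax - tmin) * ifelse(up, 2 * t, 2 * (1 - t))
}

dd_oracle <- function(tmin, tmax, ldt, udt) {
  T <- tri_minute_curve(tmin, tmax)
  mean(pmin(pmax(T, ldt), udt) - ldt)
}

cold_oracle <- function(tmin, tmax, threshold) {
  mean(pmax(threshold - tri_minute_curve(tmin, tmax), 0))
}

heat_oracle <- function(tmin, tmax, threshold) {
  mean(pmax(tri_minute_curve(tmin, tmax) - threshold, 0))
}

# Brute-force Mann-Kendall: literal pair enumeration, no vectorization.
mk_brute <- function(x) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tie <- table(x); tie <- tie[tie > 1]
  U <- sum(tie * (tie - 1) / 2)
  tau <- if (n0 - U > 0) (conc - disc) / sqrt((n0 - U) * n0) else 0
  list(S = S, tau = tau)
}

# Mean of the [lo, hi]-truncated lognormal (arithmetic-moment
# parameterization), by adaptive quadrature.
trunc_lnorm_mean <- function(m, v, lo, hi) {
  s2 <- log(1 + v / m^2)
  mu <- log(m) - s2 / 2
  num <- integrate(function(x) x * dlnorm(x, mu, sqrt(s2)), lo, hi,
                   rel.tol = 1e-10)$value
  den <- plnorm(hi, mu, sqrt(s2)) - plnorm(lo, mu, sqrt(s2))
  num / den
}

# Small constant-temperature site grid (1 x 1) for engine arithmetic.
const_grid <- function(temp, year = 2021) {
  nd <- as.integer(as.Date(paste0(year, "-12-31")) -
                     as.Date(paste0(year, "-01-01"))) + 1L
  daily_temperature_grid(rep(temp, nd), rep(temp, nd), year = year)
}

default_synth <- function(seed, nrow = 20, ncol = 20, ...) {
  synth_weather(synthetic_weather_config(nrow = nrow, ncol = ncol,
                                         seed = seed, ...))
}
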