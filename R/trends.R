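# Mann-Kendall monotone-trend testing for yearly raster stacks.

#' Mann-Kendall trend test
#'
#' Rank-based nonparametric test for a monotone trend in an ordered yearly
#' series. `S` is the signed pair count `sum_{i<j} sign(x_j - x_i)`; its
#' variance is tie-corrected,
#' `var_S = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of
#' size `t`; the effect size is Kendall's tau-b
#' `S / sqrt((n0 - U) n0)` with `n0 = n(n-1)/2` and `U = sum_t t(t-1)/2`;
#' the z score uses the +/-1 continuity correction and the two-sided
#' p-value comes from the standard normal. Significance is declared at
#' p <= 0.1, the customary level for low-power trend scans of yearly
#' series.
#'
#' @param x numeric series ordered by year; `NA`s are removed. Needs
#'   n >= 3 after removal (otherwise a flagged, non-computable result is
#'   returned rather than an error).
#' @return A `trend_result`: `n`, `S`, `var_S`, `tau`, `z`, `p`,
#'   `significant`, `computable`.
#' @examples
#' mann_kendall(c(1, 2, 3, 4, 5))$S   # 10
#' mann_kendall(c(1, 1, 2))$tau       # 2/sqrt(6)
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3)
    return(structure(list(n = n, S = NA_real_, var_S = NA_real_,
                          tau = NA_real_, z = NA_real_, p = NA_real_,
                          significant = NA, computable = FALSE),
                     class = "trend_result"))
  S <- 0
  for (i in seq_len(n - 1))
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  tie <- table(x)
  tie <- tie[tie > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tie * (tie - 1) * (2 * tie + 5))) / 18
  n0 <- n * (n - 1) / 2
  U <- sum(tie * (tie - 1) / 2)
  denom <- sqrt((n0 - U) * n0)
  tau <- if (denom > 0) S / denom else 0
  z <- if (var_S > 0) {
    if (S > 0) (S - 1) / sqrt(var_S)
    else if (S < 0) (S + 1) / sqrt(var_S)
    else 0
  } else 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(n = n, S = S, var_S = var_S, tau = tau, z = z, p = p,
                 significant = p <= 0.1, computable = TRUE),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  if (!x$computable) {
    cat("<trend_result> not computable (n =", x$n, "< 3)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<trend_result> n = %d  S = %g  tau = %.3f  z = %.3f  p = %.4f%s\n",
    x$n, x$S, x$tau, x$z, x$p,
    if (isTRUE(x$significant)) "  *(p <= 0.1)" else ""))
  invisible(x)
}

#' Per-pixel Mann-Kendall trend map
#'
#' Applies [mann_kendall()] to every pixel of a multi-year stack. Pixels
#' with any missing year are masked. For exclusion-class stacks set
#' `flip_sign = TRUE`: values are negated (absolute class values) before
#' testing, so a decreasing trend reads as decreasing climate stress.
#' Pixels with `S = 0` carry the no-trend label.
#'
#' @param stack list of co-registered yearly matrices (>= 3), or a
#'   `year x row x col` array.
#' @param flip_sign negate values before testing (use for class stacks).
#' @return List of matrices: `tau`, `p`, `z`, `S`, `significant` (logical,
#'   p <= 0.1), `no_trend` (logical, S == 0), `masked` (logical).
#' @export
trend_map <- function(stack, flip_sign = FALSE) {
  if (is.list(stack)) {
    dims <- unique(lapply(stack, dim))
    if (length(dims) != 1) stop("stack layers have mismatched shapes")
    stack <- array(unlist(stack), c(dims[[1]], length(stack)))
    stack <- aperm(stack, c(3, 1, 2))
  }
  stopifnot(length(dim(stack)) == 3)
  if (dim(stack)[1] < 3) stop("need at least 3 yearly layers")
  if (flip_sign) stack <- -stack
  nr <- dim(stack)[2]; nc <- dim(stack)[3]
  out <- list(tau = matrix(NA_real_, nr, nc), p = matrix(NA_real_, nr, nc),
              z = matrix(NA_real_, nr, nc), S = matrix(NA_real_, nr, nc),
              significant = matrix(NA, nr, nc),
              no_trend = matrix(NA, nr, nc),
              masked = matrix(FALSE, nr, nc))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    x <- stack[, i, j]
    if (anyNA(x)) { out$masked[i, j] <- TRUE; next }
    r <- mann_kendall(x)
    if (!r$computable) { out$masked[i, j] <- TRUE; next }
    out$tau[i, j] <- r$tau; out$p[i, j] <- r$p; out$z[i, j] <- r$z
    out$S[i, j] <- r$S
    out$significant[i, j] <- r$significant
    out$no_trend[i, j] <- r$S == 0
  }
  out
}
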