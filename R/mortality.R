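#' Linearized length-converted catch curve
#'
#' Estimates the total instantaneous mortality rate Z from a pooled
#' length-frequency distribution. Bin midpoints are converted to relative
#' ages with the inverse VBGF; each bin's time-to-grow-through is
#' `dt = (1/k) * log((Linf - L_lower)/(Linf - L_upper))`; the descending
#' limb of `log(N/dt)` against relative age is fit by ordinary least
#' squares and `Z = -slope`.
#'
#' Automatic point selection starts at the bin after the global maximum
#' of the response and ends at the last occupied bin whose upper edge is
#' below `0.95 * Linf`; an explicit index range overrides it.
#'
#' @param x an [lfq] object (pooled across dates internally).
#' @param p a [growth_params] object; `Linf` must exceed the lower edge
#'   of every used bin.
#' @param selection `"auto"` or an integer vector of bin indices (into
#'   the usable-bin table) to regress over.
#' @return An object of class `catch_curve_fit`: a per-bin `table`
#'   (midpoint, t, dt, N, y), the `used` indices, the `lm` fit, `slope`,
#'   `intercept`, `se_slope`, `r_squared`, `z_per_year` and its 0.95
#'   confidence interval `z_ci`.
#' @export
catch_curve <- function(x, p, selection = "auto") {
  stopifnot(inherits(x, "lfq"), inherits(p, "growth_params"))
  pooled <- if (ncol(x$counts) > 1L) pool_lfq(x) else x
  N <- as.numeric(pooled$counts)
  lower <- pooled$midpoints - pooled$bin_width / 2
  upper <- pooled$midpoints + pooled$bin_width / 2
  ok <- upper < p$linf_mm
  if (any(!ok & N > 0))
    warning("bins with upper edge >= Linf excluded from the catch curve")
  mid <- pooled$midpoints[ok]; N <- N[ok]
  lower <- lower[ok]; upper <- upper[ok]
  t <- vbgf_age_at_length(p, mid)
  dt <- (1 / p$k_per_year) * log((p$linf_mm - lower) / (p$linf_mm - upper))
  y <- ifelse(N > 0, log(N / dt), NA_real_)
  tab <- data.frame(midpoint_mm = mid, t_years = t, dt_years = dt,
                    n = N, y = y)
  if (identical(selection, "auto")) {
    peak <- which.max(y)
    last <- max(which(N > 0 & upper < 0.95 * p$linf_mm))
    if (last <= peak)
      stop("no descending limb beyond the modal bin")
    used <- seq.int(peak + 1L, last)
    used <- used[N[used] > 0]
  } else {
    used <- as.integer(selection)
  }
  if (length(used) < 3L || any(used < 1L) || any(used > nrow(tab)))
    stop("fewer than 3 usable points for the catch-curve regression")
  fit <- stats::lm(y ~ t_years, data = tab[used, ])
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  z <- -slope
  structure(list(table = tab, used = used, fit = fit,
                 slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 se_slope = se, r_squared = sm$r.squared,
                 z_per_year = z, z_ci = z + c(-1, 1) * 1.96 * se,
                 growth = p),
            class = "catch_curve_fit")
}

#' @export
print.catch_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Length-converted catch curve: Z = %.3f /yr (0.95 CI %.3f-%.3f), r^2 = %.3f\n",
    x$z_per_year, x$z_ci[1], x$z_ci[2], x$r_squared))
  cat("  regression over", length(x$used), "bins\n")
  invisible(x)
}

#' @export
coef.catch_curve_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    z_per_year = object$z_per_year)
}

#' @export
summary.catch_curve_fit <- function(object, ...) {
  print(object)
  print(summary(object$fit))
  invisible(object)
}

#' @export
plot.catch_curve_fit <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$t_years, tab$y, xlab = "Relative age (years)",
                 ylab = "log(N / dt)", pch = 1, ...)
  graphics::points(tab$t_years[x$used], tab$y[x$used], pch = 16)
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

#' Empirical natural-mortality suite
#'
#' Evaluates thirteen published empirical estimators of the natural
#' mortality rate M (per year) from lifespan `tmax`, VBGF parameters and
#' water temperature, and reports their arithmetic mean. Unit
#' conventions: the Pauly temperature formula uses `Linf` in cm and
#' base-10 logarithms; the Then growth formula uses `Linf` in mm.
#' A negative result (possible for the linear-in-k rule at small k) is
#' retained and flagged with a warning.
#'
#' @param linf_mm asymptotic length (mm).
#' @param k growth coefficient (1/year).
#' @param tmax lifespan (years), typically [lifespan()] = 3/k.
#' @param temp_c mean annual water temperature (deg C).
#' @return An object of class `m_suite`: a data frame with columns `id`,
#'   `formula`, `m_per_year`, and attributes `m_mean_per_year` and the
#'   echoed inputs.
#' @export
empirical_m_suite <- function(linf_mm, k, tmax, temp_c) {
  if (any(c(linf_mm, k, tmax, temp_c) <= 0))
    stop("all inputs must be positive")
  linf_cm <- linf_mm / 10
  rows <- list(
    list("tmax_5",        "M = 5/tmax",                       5 / tmax),
    list("tmax_2996",     "M = 2.996/tmax",                   2.996 / tmax),
    list("tmax_25",       "M = 2.5/tmax",                     2.5 / tmax),
    list("exp_decay",     "M = 3k/(exp(0.38 tmax k) - 1)",
      3 * k / (exp(0.38 * tmax * k) - 1)),
    list("pauly_temp",
      "M = 10^(-0.0066 - 0.279 log10(Linf_cm) + 0.6543 log10(k) + 0.4634 log10(T))",
      10^(-0.0066 - 0.279 * log10(linf_cm) + 0.6543 * log10(k) +
            0.4634 * log10(temp_c))),
    list("tmax_3",        "M = 3/tmax",                       3 / tmax),
    list("tmax_46",       "M = 4.6/tmax",                     4.6 / tmax),
    list("then_growth",   "M = 1.0661 Linf_mm^-0.1172 k^0.5092",
      1.0661 * linf_mm^(-0.1172) * k^0.5092),
    list("linear_k",      "M = -0.1778 + 3.1687 k",           -0.1778 + 3.1687 * k),
    list("k_16",          "M = 1.6 k",                        1.6 * k),
    list("k_15",          "M = 1.5 k",                        1.5 * k),
    list("k_14",          "M = 1.4 k",                        1.4 * k),
    list("tmax_422",      "M = 4.22/tmax",                    4.22 / tmax))
  tab <- data.frame(id = vapply(rows, `[[`, "", 1L),
                    formula = vapply(rows, `[[`, "", 2L),
                    m_per_year = vapply(rows, function(r) as.numeric(r[[3L]]), 0),
                    stringsAsFactors = FALSE)
  if (any(tab$m_per_year < 0))
    warning("negative M retained for: ",
            paste(tab$id[tab$m_per_year < 0], collapse = ", "))
  structure(tab, class = c("m_suite", "data.frame"),
            m_mean_per_year = mean(tab$m_per_year),
            inputs = c(linf_mm = linf_mm, k = k, tmax = tmax,
                       temp_c = temp_c))
}

#' @export
print.m_suite <- function(x, ...) {
  cat("Empirical natural-mortality estimates (per year)\n")
  print(data.frame(id = x$id, M = round(x$m_per_year, 4),
                   formula = x$formula), row.names = FALSE)
  cat(sprintf("Mean M = %.4f /yr\n", attr(x, "m_mean_per_year")))
  invisible(x)
}

#' Mean of an empirical natural-mortality suite
#' @param x an `m_suite` object.
#' @return The arithmetic mean M (per year).
#' @export
m_mean <- function(x) {
  stopifnot(inherits(x, "m_suite"))
  attr(x, "m_mean_per_year")
}

#' Fishing mortality and exploitation rate
#'
#' `fishing_mortality()` returns `F = Z - M` (a negative value is
#' flagged with a warning); `exploitation_rate()` returns
#' `E = F/(F + M)`; `f_from_e()` is its exact inverse
#' `F = E M/(1 - E)`.
#'
#' @param z total mortality (per year), >= 0.
#' @param m natural mortality (per year), > 0.
#' @param f fishing mortality (per year).
#' @param e exploitation rate in `[0, 1)`.
#' @return A rate (per year) or dimensionless exploitation rate.
#' @export
fishing_mortality <- function(z, m) {
  if (z < 0 || m <= 0) stop("need z >= 0 and m > 0")
  f <- z - m
  if (f < 0) warning("Z < M: negative fishing mortality")
  f
}

#' @rdname fishing_mortality
#' @export
exploitation_rate <- function(f, m) {
  if (m <= 0) stop("m must be positive")
  f / (f + m)
}

#' @rdname fishing_mortality
#' @export
f_from_e <- function(e, m) {
  if (m <= 0) stop("m must be positive")
  if (any(e < 0 | e >= 1)) stop("e must lie in [0, 1)")
  e * m / (1 - e)
}

#' Combined mortality estimates
#'
#' Convenience wrapper assembling Z (from a catch-curve fit), the
#' empirical M table and its mean, F = Z - M and E = F/Z.
#'
#' @param cc a `catch_curve_fit` object.
#' @param msuite an `m_suite` object.
#' @return A list of class `mortality_estimates`.
#' @export
mortality_estimates <- function(cc, msuite) {
  stopifnot(inherits(cc, "catch_curve_fit"), inherits(msuite, "m_suite"))
  z <- cc$z_per_year
  m <- m_mean(msuite)
  f <- fishing_mortality(z, m)
  structure(list(z_per_year = z, z_ci = cc$z_ci, m_table = msuite,
                 m_mean_per_year = m, f_per_year = f,
                 e_rate = exploitation_rate(f, m)),
            class = "mortality_estimates")
}

#' @export
print.mortality_estimates <- function(x, ...) {
  cat(sprintf(
    "Mortality: Z = %.3f, mean M = %.3f, F = %.3f (/yr), E = %.3f\n",
    x$z_per_year, x$m_mean_per_year, x$f_per_year, x$e_rate))
  invisible(x)
}
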