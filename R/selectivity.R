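#' Capture probabilities from the catch-curve ascending limb
#'
#' Back-extrapolates the catch-curve regression over the ascending limb
#' (bins strictly before the regression range): expected fully selected
#' counts are `Nhat = exp(intercept + slope * t) * dt`, and the capture
#' probability of a bin is `P = min(N / Nhat, 1)`. Bins in or beyond the
#' descending limb are assigned `P = 1`.
#'
#' @param cc a `catch_curve_fit` from [catch_curve()].
#' @return Data frame with columns `midpoint_mm`, `t_years`, `n`,
#'   `n_expected` and `p_capture`.
#' @export
capture_probabilities <- function(cc) {
  stopifnot(inherits(cc, "catch_curve_fit"))
  tab <- cc$table
  asc <- seq_len(min(cc$used) - 1L)
  if (!length(asc))
    stop("no ascending-limb bins; selectivity ogive not estimable")
  nhat <- exp(cc$intercept + cc$slope * tab$t_years) * tab$dt_years
  p <- rep(1, nrow(tab))
  p[asc] <- pmin(tab$n[asc] / nhat[asc], 1)
  data.frame(midpoint_mm = tab$midpoint_mm, t_years = tab$t_years,
             n = tab$n, n_expected = nhat, p_capture = p)
}

#' Fit a logistic selectivity ogive to capture probabilities
#'
#' Ordinary least squares of `log(1/P - 1)` on length over bins with
#' `0 < P < 1` estimates the logit ogive
#' `log(1/P - 1) = s1 - s2 * L`, whence `L50 = s1/s2` and
#' `L25, L75 = (s1 -/+ log 3)/s2`.
#'
#' @param ptab probability table from [capture_probabilities()], or any
#'   data frame with columns `midpoint_mm` and `p_capture`.
#' @return An object of class `selectivity_ogive` with `s1`, `s2`,
#'   `l25_mm`, `l50_mm`, `l75_mm`, the regression `fit` and the points
#'   used.
#' @export
fit_selectivity <- function(ptab) {
  use <- ptab$p_capture > 0 & ptab$p_capture < 1
  if (sum(use) < 3L)
    stop("need at least 3 bins with interior capture probability")
  d <- data.frame(L = ptab$midpoint_mm[use],
                  y = log(1 / ptab$p_capture[use] - 1))
  fit <- stats::lm(y ~ L, data = d)
  s1 <- unname(stats::coef(fit)[1L])
  s2 <- -unname(stats::coef(fit)[2L])
  if (s2 <= 0) stop("non-monotone ogive: estimated s2 <= 0")
  structure(list(s1 = s1, s2 = s2,
                 l25_mm = (s1 - log(3)) / s2,
                 l50_mm = s1 / s2,
                 l75_mm = (s1 + log(3)) / s2,
                 fit = fit, points = d, prob_table = ptab),
            class = "selectivity_ogive")
}

#' @export
print.selectivity_ogive <- function(x, ...) {
  cat(sprintf(
    "Logistic selectivity ogive: L25 = %.2f, L50 = %.2f, L75 = %.2f mm\n",
    x$l25_mm, x$l50_mm, x$l75_mm))
  cat(sprintf("  logit: log(1/P - 1) = %.3f - %.4f L\n", x$s1, x$s2))
  invisible(x)
}

#' @export
coef.selectivity_ogive <- function(object, ...) {
  c(s1 = object$s1, s2 = object$s2, l25_mm = object$l25_mm,
    l50_mm = object$l50_mm, l75_mm = object$l75_mm)
}

#' Retention probability at length for a fitted ogive
#' @param object a `selectivity_ogive`.
#' @param newdata numeric vector of lengths (mm), or a data frame with a
#'   `midpoint_mm` column.
#' @param ... unused.
#' @return Retention probabilities in (0, 1).
#' @export
predict.selectivity_ogive <- function(object, newdata, ...) {
  L <- if (is.data.frame(newdata)) newdata$midpoint_mm else newdata
  1 / (1 + exp(object$s1 - object$s2 * L))
}

#' @export
plot.selectivity_ogive <- function(x, ...) {
  pt <- x$prob_table
  graphics::plot(pt$midpoint_mm, pt$p_capture, xlab = "Length (mm)",
                 ylab = "Capture probability", ylim = c(0, 1), ...)
  L <- seq(min(pt$midpoint_mm), max(pt$midpoint_mm), length.out = 200)
  graphics::lines(L, predict(x, L), col = "firebrick")
  graphics::abline(v = x$l50_mm, lty = 2)
  invisible(x)
}

#' Age at first capture
#'
#' Converts the length at 50% retention to an age with the inverse VBGF.
#'
#' @param ogive a `selectivity_ogive`, or a numeric L50 in mm.
#' @param p a [growth_params] object; `L50` must be below `Linf`.
#' @return Age at first capture tc (years).
#' @export
age_at_first_capture <- function(ogive, p) {
  l50 <- if (inherits(ogive, "selectivity_ogive")) ogive$l50_mm else ogive
  if (l50 >= p$linf_mm) stop("L50 must be below Linf")
  vbgf_age_at_length(p, l50)
}
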