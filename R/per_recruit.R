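#' Beverton-Holt relative yield per recruit (knife-edge selection)
#'
#' Relative yield per recruit as a function of the exploitation rate
#' `E = F/Z`, the relative length at first capture `c = Lc/Linf` and the
#' life-history ratio `M/k`:
#' `Y'/R = E U^(M/k) [1 - 3U/(1+m) + 3U^2/(1+2m) - U^3/(1+3m)]` with
#' `U = 1 - c` and `m = (1-E)/(M/k)`.
#'
#' @param E exploitation rate(s) in `[0, 1]`.
#' @param c relative length at first capture `Lc/Linf` in (0, 1).
#' @param mk ratio `M/k` > 0.
#' @return Dimensionless relative yield per recruit.
#' @export
relative_ypr <- function(E, c, mk) {
  if (any(E < 0 | E > 1)) stop("E must lie in [0, 1]")
  if (c <= 0 || c >= 1) stop("c = Lc/Linf must lie in (0, 1)")
  if (mk <= 0) stop("M/k must be positive")
  U <- 1 - c
  m <- (1 - E) / mk
  E * U^mk * ypr_bracket(U, m)
}

# cubic bracket shared by yield and biomass forms
ypr_bracket <- function(U, m) {
  1 - 3 * U / (1 + m) + 3 * U^2 / (1 + 2 * m) - U^3 / (1 + 3 * m)
}

#' Relative biomass ratio B(E)/B(0) (knife-edge selection)
#'
#' The exploited-to-virgin biomass ratio implied by the Beverton-Holt
#' relative model: `(1 - E) * bracket(E) / bracket(0)` where `bracket`
#' is the cubic factor of [relative_ypr()] (equivalently Y'/(R F)
#' normalized to its unfished limit). Strictly decreasing from 1 at
#' `E = 0`.
#'
#' @inheritParams relative_ypr
#' @return Ratio in (0, 1].
#' @export
relative_biomass_ratio <- function(E, c, mk) {
  if (any(E < 0 | E > 1)) stop("E must lie in [0, 1]")
  if (c <= 0 || c >= 1) stop("c = Lc/Linf must lie in (0, 1)")
  if (mk <= 0) stop("M/k must be positive")
  U <- 1 - c
  (1 - E) * ypr_bracket(U, (1 - E) / mk) / ypr_bracket(U, 1 / mk)
}

#' Per-recruit analysis with reference points
#'
#' Computes the relative yield-per-recruit and biomass-ratio curves over
#' an exploitation-rate grid and locates the reference points:
#' `Emax` (exploitation rate maximizing Y'/R; grid search refined by
#' golden-section), `E10` (smallest E where the marginal yield drops to
#' one tenth of its value at the origin) and `E50` (the unique E at which
#' the stock is halved relative to its virgin biomass). Corresponding
#' fishing mortalities use `F = E M/(1 - E)`.
#'
#' In `mode = "ogive"` the curves come from the length-structured
#' recursion [length_structured_per_recruit()] with the supplied
#' selectivity ogive instead of knife-edge selection.
#'
#' @param linf_mm asymptotic length (mm).
#' @param k growth coefficient (1/year).
#' @param m natural mortality (1/year).
#' @param lc_mm knife-edge length at first capture (mm), < `linf_mm`.
#' @param ogive optional `selectivity_ogive` for `mode = "ogive"`.
#' @param mode `"knife_edge"` (default) or `"ogive"`.
#' @param weight_ab optional length-weight coefficients `c(a, b)` used by
#'   the ogive mode (defaults to cubic weight `a = 1, b = 3`).
#' @param e_grid exploitation-rate grid (default step 1e-3).
#' @return An object of class `per_recruit`: data frame `curve`
#'   (`E`, `F`, `yr`, `br`) plus reference points `e10`, `e50`, `emax`,
#'   `f10`, `fmax` and the echoed inputs.
#' @export
per_recruit <- function(linf_mm, k, m, lc_mm = NULL, ogive = NULL,
                        mode = c("knife_edge", "ogive"),
                        weight_ab = c(1, 3),
                        e_grid = seq(0, 1, by = 1e-3)) {
  mode <- match.arg(mode)
  if (m <= 0 || k <= 0) stop("m and k must be positive")
  if (mode == "knife_edge") {
    if (is.null(lc_mm)) stop("knife-edge mode needs lc_mm")
    if (lc_mm <= 0 || lc_mm >= linf_mm)
      stop("lc_mm must lie in (0, Linf)")
    cc <- lc_mm / linf_mm
    mk <- m / k
    yfun <- function(E) relative_ypr(E, cc, mk)
    bfun <- function(E) relative_biomass_ratio(E, cc, mk)
  } else {
    if (is.null(ogive)) stop("ogive mode needs an ogive")
    ls0 <- length_structured_per_recruit(
      linf_mm, k, m, ogive, f_grid = 0, weight_ab = weight_ab)
    b0 <- ls0$curve$br[1L]
    yfun <- function(E) {
      f <- f_from_e(pmin(E, 1 - 1e-9), m)
      length_structured_per_recruit(linf_mm, k, m, ogive, f_grid = f,
                                    weight_ab = weight_ab)$curve$yr
    }
    bfun <- function(E) {
      f <- f_from_e(pmin(E, 1 - 1e-9), m)
      length_structured_per_recruit(linf_mm, k, m, ogive, f_grid = f,
                                    weight_ab = weight_ab)$curve$br / b0
    }
  }
  e_grid <- sort(unique(pmin(pmax(e_grid, 0), 1)))
  yr <- vapply(e_grid, yfun, 0)
  br <- vapply(e_grid, bfun, 0)

  # Emax: grid argmax refined by golden-section within a bracket
  i <- which.max(yr)
  if (i == length(e_grid) && yr[i] >= yr[i - 1L]) {
    warning("yield still increasing at E = 1; Emax set to 1")
    emax <- e_grid[i]
  } else {
    lo <- e_grid[max(i - 1L, 1L)]
    hi <- e_grid[min(i + 1L, length(e_grid))]
    emax <- stats::optimize(yfun, c(lo, hi), maximum = TRUE,
                            tol = 1e-9)$maximum
  }

  # E10: marginal yield equal to 10% of the slope at the origin
  h <- 1e-5
  slope0 <- (yfun(h) - yfun(0)) / h
  dfun <- function(E) {
    if (E < h) (yfun(E + h) - yfun(max(E - h, 0))) / (h + min(E, h))
    else if (E > 1 - h) (yfun(1) - yfun(1 - h)) / h
    else (yfun(E + h) - yfun(E - h)) / (2 * h)
  }
  g <- function(E) dfun(E) - 0.1 * slope0
  e10 <- NA_real_
  gv <- g(0)
  for (E in seq(0.01, 1, by = 0.01)) {
    gv2 <- g(E)
    if (is.finite(gv) && is.finite(gv2) && gv > 0 && gv2 <= 0) {
      e10 <- stats::uniroot(g, c(E - 0.01, E), tol = 1e-8)$root
      break
    }
    gv <- gv2
  }

  # E50: unique root of the biomass ratio at one half
  e50 <- stats::uniroot(function(E) bfun(E) - 0.5, c(0, 1),
                        tol = 1e-6)$root

  structure(list(curve = data.frame(E = e_grid,
                                    F = f_from_e(pmin(e_grid, 1 - 1e-12), m),
                                    yr = yr, br = br),
                 e10 = e10, e50 = e50, emax = emax,
                 f10 = if (is.finite(e10)) f_from_e(e10, m) else NA_real_,
                 fmax = if (emax < 1) f_from_e(emax, m) else Inf,
                 mode = mode,
                 inputs = list(linf_mm = linf_mm, k = k, m = m,
                               lc_mm = lc_mm, ogive = ogive,
                               weight_ab = weight_ab)),
            class = "per_recruit")
}

#' @export
print.per_recruit <- function(x, ...) {
  cat("Beverton-Holt per-recruit analysis (", x$mode, " selection)\n",
      sep = "")
  cat(sprintf("  E10 = %.3f  E50 = %.3f  Emax = %.3f\n",
              x$e10, x$e50, x$emax))
  cat(sprintf("  F10 = %.3f  Fmax = %.3f (per year, M = %.3f)\n",
              x$f10, x$fmax, x$inputs$m))
  invisible(x)
}

#' @export
plot.per_recruit <- function(x, ...) {
  graphics::plot(x$curve$E, x$curve$yr, type = "l",
                 xlab = "Exploitation rate E", ylab = "Relative Y'/R",
                 col = "black", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$curve$E, x$curve$br, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", lty = 2,
                 ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("Relative biomass B'/R", side = 4, line = 2)
  graphics::abline(v = c(x$e10, x$e50, x$emax), lty = 3,
                   col = c("darkgreen", "steelblue", "firebrick"))
  invisible(x)
}

#' Sensitivity of per-recruit reference points to the length at first
#' capture
#'
#' One row of reference points per candidate Lc, with the corresponding
#' age at first capture from the inverse VBGF.
#'
#' @inheritParams per_recruit
#' @param lc_list numeric vector of candidate Lc values (mm), each below
#'   `linf_mm`.
#' @return Data frame of class `lc_sensitivity` with columns `lc_mm`,
#'   `tc_years`, `f10`, `fmax`, `e50`, `e10`, `emax`.
#' @export
lc_sensitivity <- function(linf_mm, k, m, lc_list, ...) {
  p <- growth_params(linf_mm, k)
  rows <- lapply(lc_list, function(lc) {
    pr <- per_recruit(linf_mm, k, m, lc_mm = lc, ...)
    data.frame(lc_mm = lc, tc_years = vbgf_age_at_length(p, lc),
               f10 = pr$f10, fmax = pr$fmax, e50 = pr$e50,
               e10 = pr$e10, emax = pr$emax)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lc_sensitivity", "data.frame")
  out
}

#' @export
print.lc_sensitivity <- function(x, ...) {
  cat("Per-recruit reference points by length at first capture\n")
  fmt <- x
  for (cn in names(fmt)) fmt[[cn]] <- sprintf("%.2f", fmt[[cn]])
  names(fmt) <- c("Lc", "tc", "F10", "Fmax", "E50", "E10", "Emax")
  print.data.frame(fmt, row.names = FALSE)
  invisible(x)
}

#' Length-structured yield and biomass per recruit
#'
#' Thompson-Bell style recursion over length classes. For class `i` with
#' edges `L_i`, `L_{i+1}`: residence time
#' `dt_i = (1/k) log((Linf - L_i)/(Linf - L_{i+1}))`, total mortality
#' `Z_i = M + F s_i` with `s_i` the gear retention at the class
#' midlength, survivorship `N_{i+1} = N_i exp(-Z_i dt_i)` from
#' `N_1 = 1`, catch `C_i = (F s_i / Z_i) N_i (1 - exp(-Z_i dt_i))`, and
#' mean weight `a L_mid^b`. The terminal class absorbs survivors with
#' infinite residence time. `Y/R = sum C_i w_i`;
#' `B/R = sum (N_i/Z_i)(1 - exp(-Z_i dt_i)) w_i`.
#'
#' @param linf_mm asymptotic length (mm).
#' @param k growth coefficient (1/year).
#' @param m natural mortality (1/year).
#' @param ogive a `selectivity_ogive`, or a function of length returning
#'   retention in `[0, 1]` (e.g. a knife-edge step).
#' @param f_grid non-negative fishing mortalities to evaluate.
#' @param weight_ab length-weight coefficients `c(a, b)`;
#'   `w = a L^b` (g for L in mm).
#' @param l_start lower edge of the first length class (mm).
#' @param class_width length-class width (mm).
#' @return An object of class `per_recruit_ls` with a data frame `curve`
#'   (`F`, `E`, `yr`, `br`).
#' @export
length_structured_per_recruit <- function(linf_mm, k, m, ogive,
                                          f_grid,
                                          weight_ab = c(1, 3),
                                          l_start = 0,
                                          class_width = 0.5) {
  if (any(f_grid < 0)) stop("F must be non-negative")
  sfun <- if (is.function(ogive)) ogive else
    function(L) predict(ogive, L)
  edges <- seq(l_start, linf_mm * (1 - 1e-9), by = class_width)
  if (length(edges) < 3L) stop("length classes do not span the range")
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  mid <- (lo + hi) / 2
  dt <- (1 / k) * log((linf_mm - lo) / (linf_mm - hi))
  s <- pmin(pmax(sfun(mid), 0), 1)
  w <- weight_ab[1] * mid^weight_ab[2]
  one <- function(f) {
    z <- m + f * s
    surv <- exp(-z * dt)
    N <- cumprod(c(1, surv[-length(surv)]))
    take <- N * (1 - surv)
    yr <- sum((f * s / z) * take * w)
    br <- sum((N / z) * (1 - surv) * w)
    # plus group: survivors past the last edge, infinite residence
    Nplus <- N[length(N)] * surv[length(surv)]
    zp <- z[length(z)]
    sp <- s[length(s)]
    wp <- w[length(w)]
    yr <- yr + (f * sp / zp) * Nplus * wp
    br <- br + (Nplus / zp) * wp
    c(yr = yr, br = br)
  }
  res <- t(vapply(f_grid, one, c(yr = 0, br = 0)))
  structure(list(curve = data.frame(F = f_grid,
                                    E = f_grid / (f_grid + m),
                                    yr = res[, "yr"], br = res[, "br"]),
                 inputs = list(linf_mm = linf_mm, k = k, m = m,
                               weight_ab = weight_ab,
                               l_start = l_start,
                               class_width = class_width)),
            class = "per_recruit_ls")
}

#' @export
print.per_recruit_ls <- function(x, ...) {
  cat("Length-structured per-recruit curve (", nrow(x$curve),
      " F values)\n", sep = "")
  print(utils::head(x$curve))
  invisible(x)
}
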