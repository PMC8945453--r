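#' Von Bertalanffy growth parameters
#'
#' Container for the modified von Bertalanffy growth function (VBGF)
#' without a theoretical age at length zero, so that `L(0) = 0`:
#' `L(t) = Linf * (1 - exp(-k * t))`.
#'
#' @param linf_mm asymptotic length (mm), > 0.
#' @param k_per_year growth coefficient (1/year), > 0.
#' @param t_anchor fractional year in `[0, 1)` positioning cohort births
#'   within the calendar year (used by ELEFAN scoring).
#' @return An object of class `growth_params` with fields `linf_mm`,
#'   `k_per_year`, `t_anchor` and the derived growth performance index
#'   `phi_prime`.
#' @export
growth_params <- function(linf_mm, k_per_year, t_anchor = 0) {
  if (!is.finite(linf_mm) || linf_mm <= 0) stop("linf_mm must be positive")
  if (!is.finite(k_per_year) || k_per_year <= 0)
    stop("k_per_year must be positive")
  if (t_anchor < 0 || t_anchor >= 1) stop("t_anchor must be in [0, 1)")
  structure(list(linf_mm = linf_mm, k_per_year = k_per_year,
                 t_anchor = t_anchor,
                 phi_prime = growth_performance_index(linf_mm, k_per_year)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "VBGF growth parameters: Linf = %.2f mm, k = %.3f /yr, t_anchor = %.3f, phi' = %.2f\n",
    x$linf_mm, x$k_per_year, x$t_anchor, x$phi_prime))
  invisible(x)
}

#' @export
coef.growth_params <- function(object, ...) {
  c(linf_mm = object$linf_mm, k_per_year = object$k_per_year,
    t_anchor = object$t_anchor, phi_prime = object$phi_prime)
}

#' Length at age under the modified VBGF
#'
#' @param p a [growth_params] object.
#' @param t age in years, >= 0.
#' @return Length in mm: `Linf * (1 - exp(-k t))`.
#' @export
vbgf_length_at_age <- function(p, t) {
  stopifnot(inherits(p, "growth_params"))
  if (any(t < 0)) stop("age must be non-negative")
  p$linf_mm * (1 - exp(-p$k_per_year * t))
}

#' Age at length under the modified VBGF (inverse growth curve)
#'
#' @param p a [growth_params] object.
#' @param L length in mm, `0 <= L < Linf`.
#' @return Age in years: `-(1/k) * log(1 - L/Linf)`.
#' @export
vbgf_age_at_length <- function(p, L) {
  stopifnot(inherits(p, "growth_params"))
  if (any(L < 0)) stop("length must be non-negative")
  if (any(L >= p$linf_mm))
    stop("age undefined for lengths at or above Linf")
  -(1 / p$k_per_year) * log(1 - L / p$linf_mm)
}

#' Approximate lifespan from the growth coefficient
#'
#' Lifespan is taken as the age at which ~95% of the asymptotic length is
#' reached: `tmax = 3/k`.
#'
#' @param k growth coefficient (1/year), > 0.
#' @return Lifespan in years.
#' @export
lifespan <- function(k) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  3 / k
}

#' Growth performance index phi-prime
#'
#' `phi' = log10(k) + 2 log10(Linf)` with `Linf` in mm; allows growth
#' comparisons across stocks along the k-Linf trade-off.
#'
#' @param linf_mm asymptotic length (mm), > 0.
#' @param k growth coefficient (1/year), > 0.
#' @return Dimensionless index.
#' @export
growth_performance_index <- function(linf_mm, k) {
  if (!is.finite(linf_mm) || linf_mm <= 0 || !is.finite(k) || k <= 0)
    stop("linf_mm and k must be positive")
  log10(k) + 2 * log10(linf_mm)
}

## ---- ELEFAN scoring -------------------------------------------------------

# oldest cohort entertained by the scoring trajectories (years); slow
# growth implies lifespans 3/k beyond any plausible crustacean age, so
# the family is capped at the oldest published lifespan estimate
.elefan_age_cap <- 60

#' Candidate cohort birth anchors for ELEFAN scoring
#'
#' One growth trajectory per birth year whose curve intersects the
#' observed length range during the sampling window. Ages are capped at
#' the approximate lifespan 3/k.
#'
#' @param x an [lfq] or restructured object.
#' @param p a [growth_params] object.
#' @return Numeric vector of birth times (decimal years).
#' @keywords internal
cohort_anchors <- function(x, p) {
  t <- date_to_decimal(x$dates)
  occ <- if (!is.null(x$counts)) rowSums(x$counts) > 0 else
    rowSums(abs(x$rvalues)) > 0
  if (!any(occ)) occ <- rep(TRUE, length(x$midpoints))
  lmin <- max(min(x$midpoints[occ]) - x$bin_width / 2, 0)
  lmax <- min(max(x$midpoints[occ]) + x$bin_width / 2,
              p$linf_mm * (1 - 1e-9))
  amin <- vbgf_age_at_length(p, lmin)
  amax <- min(vbgf_age_at_length(p, lmax), lifespan(p$k_per_year),
              .elefan_age_cap)
  lo <- floor(min(t) - amax)
  hi <- ceiling(max(t) - amin)
  (lo:hi) + p$t_anchor
}

#' ELEFAN goodness-of-fit score
#'
#' Scores a candidate growth curve against restructured length-frequency
#' data. ASP (available sum of peaks) is the sum, over columns, of the
#' maximum score inside each maximal run of positive bins. ESP (explained
#' sum of peaks) sums the scores of bins crossed by the family of cohort
#' trajectories evaluated at each sample date. Runs are treated
#' symmetrically: within a column each positive run is credited at most
#' once (the crossed bin's score), and each crossed negative run
#' contributes its minimum score exactly once, however many trajectories
#' pass through it -- so densely spaced cohort families (small k) are
#' not penalized merely for having more trajectories. The fit score is
#' `Rn = 10^(ESP/ASP) / 10`, at most 1.
#'
#' @param r an `lfq_restructured` object (see [restructure()]).
#' @param p a [growth_params] object.
#' @return A list of class `elefan_score` with `esp`, `asp`, `rn`.
#' @export
elefan_score <- function(r, p) {
  stopifnot(inherits(r, "lfq_restructured"), inherits(p, "growth_params"))
  rv <- r$rvalues
  if (!any(rv > 0)) stop("no positive restructured values; score undefined")
  nb <- nrow(rv)
  lower <- r$midpoints - r$bin_width / 2
  runs <- r$runs
  asp <- r$asp
  tdec <- date_to_decimal(r$dates)
  births <- cohort_anchors(r, p)
  esp <- 0
  for (j in seq_len(ncol(rv))) {
    age <- tdec[j] - births
    age <- age[age > 0 & age <= min(lifespan(p$k_per_year),
                                    .elefan_age_cap)]
    if (!length(age)) next
    L <- vbgf_length_at_age(p, age)
    inside <- L >= lower[1L] & L < lower[nb] + r$bin_width
    idx <- unique(floor((L[inside] - lower[1L]) / r$bin_width) + 1L)
    credited <- logical(max(runs[, j]) + 1L)
    ncredited <- logical(max(r$nruns[, j]) + 1L)
    for (i in idx) {
      v <- rv[i, j]
      if (v > 0) {
        rid <- runs[i, j]
        if (!credited[rid]) {
          esp <- esp + v
          credited[rid] <- TRUE
        }
      } else if (v < 0) {
        rid <- r$nruns[i, j]
        if (!ncredited[rid]) {
          esp <- esp + r$negmin[[j]][[as.character(rid)]]
          ncredited[rid] <- TRUE
        }
      }
    }
  }
  structure(list(esp = esp, asp = asp, rn = 10^(esp / asp) / 10),
            class = "elefan_score")
}

#' @export
print.elefan_score <- function(x, ...) {
  cat(sprintf("ELEFAN score: ESP = %.3f, ASP = %.3f, Rn = %.4f\n",
              x$esp, x$asp, x$rn))
  invisible(x)
}

## ---- genetic-algorithm fit ------------------------------------------------

#' Control settings for the ELEFAN genetic algorithm
#'
#' @param popsize population size.
#' @param generations number of generations.
#' @param pmutation per-gene Gaussian mutation probability.
#' @param elitism number of best candidates copied unchanged.
#' @param tournament tournament size for parent selection.
#' @param mut_sd mutation standard deviation as a fraction of each
#'   parameter's search range.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(popsize = 50L, generations = 30L, pmutation = 0.1,
                       elitism = 2L, tournament = 3L, mut_sd = 0.1) {
  stopifnot(popsize >= 2L, generations >= 1L, elitism >= 0L,
            tournament >= 1L, pmutation >= 0, pmutation <= 1, mut_sd > 0)
  structure(list(popsize = as.integer(popsize),
                 generations = as.integer(generations),
                 pmutation = pmutation, elitism = as.integer(elitism),
                 tournament = as.integer(tournament), mut_sd = mut_sd),
            class = "ga_control")
}

#' Default ELEFAN search bounds for a length-frequency object
#'
#' `Linf` spans 0.9-1.3 times the largest occupied bin's upper edge,
#' `k` spans 0.01-1 per year, `t_anchor` the full calendar year.
#'
#' @param x an [lfq] object.
#' @return A list with `linf`, `k` and `t_anchor` ranges.
#' @export
default_search_bounds <- function(x) {
  stopifnot(inherits(x, "lfq"))
  occ <- rowSums(x$counts) > 0
  lmax <- max(x$midpoints[occ]) + x$bin_width / 2
  list(linf = c(0.9, 1.3) * lmax, k = c(0.01, 1), t_anchor = c(0, 1))
}

#' Fit VBGF growth parameters by ELEFAN with a genetic algorithm
#'
#' Maximizes the ELEFAN fit score Rn over `(Linf, k, t_anchor)` with a
#' generational genetic algorithm (tournament selection, uniform
#' crossover, Gaussian mutation, elitism). Deterministic for a fixed
#' `seed`.
#'
#' @param x an [lfq] object.
#' @param bounds search bounds as from [default_search_bounds()].
#' @param control GA settings from [ga_control()].
#' @param window moving-average window passed to [restructure()].
#' @param seed integer RNG seed.
#' @return An object of class `elefan_fit` with elements `par`
#'   (a [growth_params]), `score` (an [elefan_score()]), `trace`
#'   (best Rn per generation), plus the settings used.
#' @export
elefan_ga <- function(x, bounds = default_search_bounds(x),
                      control = ga_control(), window = 5L, seed = 1L) {
  stopifnot(inherits(x, "lfq"))
  r <- if (inherits(x, "lfq_restructured")) x else restructure(x, window)
  lo <- c(bounds$linf[1], bounds$k[1], bounds$t_anchor[1])
  hi <- c(bounds$linf[2], bounds$k[2], bounds$t_anchor[2])
  if (any(lo > hi) || any(lo[1:2] <= 0))
    stop("degenerate or invalid search bounds")
  fit_par <- function(v) growth_params(v[1], v[2], min(v[3], 1 - 1e-12))
  evalfn <- function(v) elefan_score(r, fit_par(v))$rn
  span <- hi - lo
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  np <- control$popsize
  pop <- matrix(stats::runif(3 * np, lo, hi), ncol = 3, byrow = TRUE)
  # deterministic coarse-grid screen (k log-spaced); its best points
  # seed half the population so every growth-rate regime is represented
  if (any(span > 0)) {
    grid <- as.matrix(expand.grid(
      linf = seq(lo[1], hi[1], length.out = 5),
      k = exp(seq(log(max(lo[2], 1e-6)), log(hi[2]), length.out = 8)),
      ta = seq(lo[3], min(hi[3], lo[3] + span[3] * 7 / 8),
               length.out = 8)))
    gfit <- apply(grid, 1, evalfn)
    ng <- min(nrow(grid), np %/% 2L)
    pop[seq_len(ng), ] <- grid[order(gfit, decreasing = TRUE)[seq_len(ng)], ]
  } else {
    pop <- matrix(lo, np, 3, byrow = TRUE)
  }
  fit <- apply(pop, 1, evalfn)
  trace <- numeric(control$generations)
  for (g in seq_len(control$generations)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- matrix(0, np, 3)
    ne <- min(control$elitism, np)
    if (ne > 0) newpop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
    pick <- function() {
      cand <- sample.int(np, control$tournament, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    for (i in seq.int(ne + 1L, np)) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      mask <- stats::runif(3) < 0.5
      child <- ifelse(mask, p1, p2)
      mut <- stats::runif(3) < control$pmutation
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, control$mut_sd * pmax(span[mut], 1e-12))
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    fit <- apply(pop, 1, evalfn)
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  bestv <- pop[best, ]
  # local Nelder-Mead polish of the GA optimum (bounds enforced by clamp)
  if (any(span > 0)) {
    pol <- stats::optim(bestv, function(v) {
      v <- pmin(pmax(v, lo), hi)
      -evalfn(v)
    }, method = "Nelder-Mead",
    control = list(maxit = 200, reltol = 1e-8))
    cand <- pmin(pmax(pol$par, lo), hi)
    if (-pol$value > evalfn(bestv)) bestv <- cand
  }
  par <- fit_par(bestv)
  structure(list(par = par, score = elefan_score(r, par), trace = trace,
                 bounds = bounds, control = control, window = r$window,
                 seed = seed, lfq = x),
            class = "elefan_fit")
}

#' @export
print.elefan_fit <- function(x, ...) {
  cat("ELEFAN genetic-algorithm growth fit\n")
  print(x$par)
  cat(sprintf("  Rn = %.4f (pop %d, %d generations, seed %d)\n",
              x$score$rn, x$control$popsize, x$control$generations, x$seed))
  invisible(x)
}

#' @export
coef.elefan_fit <- function(object, ...) coef(object$par)

#' @export
plot.elefan_fit <- function(x, ...) {
  plot(x$lfq, growth = x$par, ...)
  invisible(x)
}

#' Bootstrap confidence intervals for ELEFAN growth parameters
#'
#' Each replicate redraws every sample column as a multinomial with that
#' column's total and cell probabilities proportional to the observed
#' counts, then refits with [elefan_ga()]. All-zero columns stay
#' all-zero. Deterministic for a fixed seed.
#'
#' @inheritParams elefan_ga
#' @param n_boot number of bootstrap resamples (>= 1). The conventional
#'   production setting is 1000; tests and demos use fewer.
#' @return Object of class `elefan_boot`: the full-data `point` fit, a
#'   `replicates` matrix (Linf, k, t_anchor, phi_prime per row), and a
#'   `ci` table with mean and 2.5/97.5 percentiles per parameter.
#' @export
elefan_ga_boot <- function(x, bounds = default_search_bounds(x),
                           control = ga_control(), window = 5L,
                           n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(x, "lfq"), n_boot >= 1L)
  point <- elefan_ga(x, bounds, control, window, seed = seed)
  reps <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("linf_mm", "k_per_year",
                                         "t_anchor", "phi_prime")))
  for (b in seq_len(n_boot)) {
    bseed <- (seed + 104729 * b) %% 2147483647
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(bseed)
    cnt <- x$counts
    for (j in seq_len(ncol(cnt))) {
      tot <- sum(cnt[, j])
      if (tot > 0)
        cnt[, j] <- as.numeric(stats::rmultinom(1, tot, cnt[, j] / tot))
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    xb <- lfq(x$midpoints, x$dates, cnt, bin_width = x$bin_width)
    fb <- elefan_ga(xb, bounds, control, window, seed = bseed)
    reps[b, ] <- coef(fb)[c("linf_mm", "k_per_year", "t_anchor",
                            "phi_prime")]
  }
  ci <- t(apply(reps, 2, function(v)
    c(mean = mean(v), lower = unname(stats::quantile(v, 0.025)),
      upper = unname(stats::quantile(v, 0.975)))))
  structure(list(point = point, n_boot = as.integer(n_boot),
                 replicates = reps, ci = ci, seed = seed),
            class = "elefan_boot")
}

#' @export
print.elefan_boot <- function(x, ...) {
  cat("Bootstrapped ELEFAN growth fit (", x$n_boot, " resamples)\n",
      sep = "")
  print(x$point$par)
  cat("  0.95 percentile intervals:\n")
  print(round(x$ci, 4))
  invisible(x)
}

#' @export
summary.elefan_boot <- function(object, ...) {
  out <- list(point = coef(object$point), ci = object$ci,
              n_boot = object$n_boot)
  print(object)
  invisible(out)
}
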