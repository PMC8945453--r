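#' Configuration for the trap-survey simulator
#'
#' Defaults emulate an 8-month (July-February) exploratory trap survey
#' around volcanic islands: 550 sets of 15 traps over 40-222 m depth
#' with abundance peaking at 80-120 m, a long-lived slow-growing spiny
#' lobster (Linf = 176.76 mm CL, k = 0.07 per year), total mortality
#' Z = 0.19 per year of which M = 0.13 is natural, trap selectivity with
#' L50 near 101.65 mm, a female-biased sex ratio (about 0.61 males per
#' female) with females shallower and males dominating the largest
#' sizes, and sex-specific allometric length-weight laws. A single
#' annual recruitment pulse (SD 0.15 year) structures the cohorts.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    months = seq(as.Date("2000-07-15"), by = "month", length.out = 8),
    n_sets = 550L, traps_per_set = 15L, n_invalid_sets = 34L,
    depth_range = c(40, 222),
    # relative density by 20-m stratum midpoint over the depth range
    depth_density = stats::setNames(
      c(0.6, 0.8, 1.0, 1.0, 0.7, 0.55, 0.45, 0.35, 0.3, 0.25),
      seq(50, 230, by = 20)),
    linf_mm = 176.76, k_per_year = 0.07, cv_linf = 0.05,
    recruit_length_mm = 30,
    t_pulse = 0.3, pulse_sd = 0.15,
    z_per_year = 0.19, m_per_year = 0.13,
    gear_l50_mm = 101.65, gear_l75_mm = 111.65,
    # intercept calibrated so the size-selected catch shows ~0.61 males
    # per female (the gear favours large, male-dominated sizes)
    sex_b0 = 0.75, sex_b_len = -0.02, sex_b_depth = -0.004,
    unknown_sex_frac = 0.2,
    lwr = list(m = c(a = 0.002, b = 2.839),
               f = c(a = 0.003, b = 2.769), sigma = 0.08),
    juvenile_depth_shift_m = 40, depth_kernel_sd_m = 20,
    mean_catch_per_set = 2.19,
    pop_n = 20000L, length_precision_mm = 0.1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$z_per_year <= 0 || cfg$k_per_year <= 0 || cfg$linf_mm <= 0)
    stop("rates and lengths must be positive")
  if (!(cfg$gear_l50_mm < cfg$gear_l75_mm &&
          cfg$gear_l75_mm < cfg$linf_mm))
    stop("need L50 < L75 < Linf")
  structure(cfg, class = "sim_config")
}

# inverse-CDF draw from an exponential(rate) truncated to [0, upper]
rtruncexp <- function(n, rate, upper) {
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

# gear retention probability at length
gear_ogive <- function(cfg, L) {
  s2 <- log(3) / (cfg$gear_l75_mm - cfg$gear_l50_mm)
  1 / (1 + exp(-s2 * (L - cfg$gear_l50_mm)))
}

#' Simulate a depth-structured lobster population
#'
#' Individual ages are drawn from an exponential(Z) distribution over
#' the recruited age range (age at the recruitment length up to the
#' lifespan 3/k); birth dates are snapped to annual
#' recruitment pulses with Gaussian jitter; per-individual asymptotic
#' lengths are lognormal around `linf_mm` with coefficient of variation
#' `cv_linf`; sexes follow a logistic model in depth and length; depths
#' follow the stratum density profile with juveniles displaced deeper.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return Data frame of class `sim_population`: `id`, `birth_dec`
#'   (decimal year), `age_ref` (years at the last survey month),
#'   `linf_i_mm`, `length_ref_mm`, `sex`, `depth_m`, `weight_ref_g`.
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- cfg$pop_n
  tmax <- lifespan(cfg$k_per_year)
  ref <- date_to_decimal(max(cfg$months))
  # individuals below the recruitment length occupy settlement habitat
  # outside the surveyed depths and are not part of this population
  amin <- -log(1 - cfg$recruit_length_mm / cfg$linf_mm) / cfg$k_per_year
  age <- amin + rtruncexp(n, cfg$z_per_year, tmax - amin)
  birth <- ref - age
  birth <- round(birth - cfg$t_pulse) + cfg$t_pulse +
    stats::rnorm(n, 0, cfg$pulse_sd)
  age <- pmax(ref - birth, 0.05)
  sdlog <- sqrt(log(1 + cfg$cv_linf^2))
  linf_i <- stats::rlnorm(n, log(cfg$linf_mm) - sdlog^2 / 2, sdlog)
  len <- linf_i * (1 - exp(-cfg$k_per_year * age))

  # depth: stratum draw by relative density, uniform within stratum,
  # juveniles displaced deeper (smaller-deeper size structure)
  mids <- as.numeric(names(cfg$depth_density))
  st <- sample(seq_along(mids), n, replace = TRUE,
               prob = cfg$depth_density)
  depth <- mids[st] + stats::runif(n, -10, 10)
  depth <- depth + cfg$juvenile_depth_shift_m /
    (1 + exp((len - 75) / 10))
  depth <- pmin(pmax(depth, cfg$depth_range[1]), cfg$depth_range[2])

  pf <- stats::plogis(cfg$sex_b0 + cfg$sex_b_len * (len - 110) +
                        cfg$sex_b_depth * (depth - 100))
  sex <- ifelse(stats::runif(n) < pf, "f", "m")
  lw <- cfg$lwr
  ab <- rbind(m = lw$m, f = lw$f)[sex, , drop = FALSE]
  wt <- ab[, "a"] * len^ab[, "b"] * exp(stats::rnorm(n, 0, lw$sigma))
  structure(data.frame(id = seq_len(n), birth_dec = birth,
                       age_ref = age, linf_i_mm = linf_i,
                       length_ref_mm = len, sex = sex, depth_m = depth,
                       weight_ref_g = wt),
            class = c("sim_population", "data.frame"))
}

#' Simulate a trap survey over a simulated population
#'
#' Sets are spread across the survey months and placed by the depth
#' density profile; per-set catch counts are Poisson with mean
#' proportional to local density and trap effort; individuals enter the
#' catch with probability proportional to the gear ogive at their
#' current length and a Gaussian depth kernel around the set depth.
#' A configurable number of sets is marked invalid and carries no
#' records. Lengths are recorded to 0.1 mm and weights to 0.1 g; a
#' fraction of records has unknown sex.
#'
#' @param pop a `sim_population` from [simulate_population()].
#' @param cfg the same [sim_config()] used for the population.
#' @param seed integer seed.
#' @return List with `records` (catch-record data frame: `set_id`,
#'   `date`, `depth_m`, `sex`, `cl_mm`, `ww_g`) and `sets` (trap-set
#'   data frame: `set_id`, `date`, `depth_m`, `n_traps`, `valid`).
#' @export
simulate_trap_survey <- function(pop, cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(pop, "sim_population"), inherits(cfg, "sim_config"))
  if (nrow(pop) == 0L) stop("population is empty")
  set.seed(seed)
  ns <- cfg$n_sets
  months <- rep(cfg$months, length.out = ns)[sample.int(ns)]
  mids <- as.numeric(names(cfg$depth_density))
  st <- sample(seq_along(mids), ns, replace = TRUE,
               prob = cfg$depth_density)
  sdepth <- pmin(pmax(mids[st] + stats::runif(ns, -10, 10),
                      cfg$depth_range[1]), cfg$depth_range[2])
  valid <- rep(TRUE, ns)
  if (cfg$n_invalid_sets > 0)
    valid[sample.int(ns, min(cfg$n_invalid_sets, ns))] <- FALSE
  sets <- data.frame(set_id = sprintf("S%04d", seq_len(ns)),
                     date = months, depth_m = round(sdepth, 1),
                     n_traps = cfg$traps_per_set, valid = valid)
  tdec <- date_to_decimal(sets$date)
  # catchability weight of individual j for set i: gear retention at the
  # individual's current length times a Gaussian depth kernel
  set_weights <- function(i) {
    age <- pmax(tdec[i] - pop$birth_dec, 0)
    len <- pop$linf_i_mm * (1 - exp(-cfg$k_per_year * age))
    w <- gear_ogive(cfg, len) *
      exp(-(pop$depth_m - sets$depth_m[i])^2 /
            (2 * cfg$depth_kernel_sd_m^2))
    w[age <= 0.05] <- 0
    w
  }
  sw <- vapply(seq_len(ns), function(i) sum(set_weights(i)), 0)
  # expected catch proportional to trap effort and locally catchable
  # abundance; mean_catch_per_set calibrates a reference 15-trap set
  lambda <- cfg$mean_catch_per_set * (cfg$traps_per_set / 15) *
    sw / mean(sw)
  counts <- stats::rpois(ns, lambda)
  counts[!valid] <- 0L
  recs <- vector("list", ns)
  for (i in which(counts > 0L)) {
    w <- set_weights(i)
    take <- sample.int(nrow(pop), min(counts[i], sum(w > 0)),
                       prob = w)
    if (!length(take)) next
    age <- pmax(tdec[i] - pop$birth_dec[take], 0.05)
    L <- pop$linf_i_mm[take] * (1 - exp(-cfg$k_per_year * age))
    sex <- pop$sex[take]
    lw <- cfg$lwr
    ab <- rbind(m = lw$m, f = lw$f)[sex, , drop = FALSE]
    wt <- ab[, "a"] * L^ab[, "b"] * exp(stats::rnorm(length(take), 0,
                                                     lw$sigma))
    sex[stats::runif(length(take)) < cfg$unknown_sex_frac] <- "u"
    recs[[i]] <- data.frame(set_id = sets$set_id[i],
                            date = sets$date[i],
                            depth_m = sets$depth_m[i], sex = sex,
                            cl_mm = round(L / cfg$length_precision_mm) *
                              cfg$length_precision_mm,
                            ww_g = round(wt, 1))
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  rownames(records) <- NULL
  list(records = records, sets = sets)
}

#' Quick cohort-mixture length-frequency fixture with known truth
#'
#' Draws individual lengths per sampling month directly from the cohort
#' mixture implied by the stated growth and mortality truth (no survey
#' layer) and bins them. Intended as a fast substrate for
#' parameter-recovery tests.
#'
#' @param linf_mm,k_per_year,cv_linf growth truth.
#' @param z_per_year total mortality truth.
#' @param t_pulse,pulse_sd recruitment pulse timing (fractional year)
#'   and spread (years).
#' @param months sampling dates.
#' @param n total number of individuals across months (>= 1).
#' @param bin_width_mm length-class width.
#' @param seed integer seed.
#' @return List with `lfq` (an [lfq] object) and `truth` (the inputs,
#'   echoed).
#' @export
make_lfq_fixture <- function(linf_mm = 176.76, k_per_year = 0.07,
                             cv_linf = 0.05, z_per_year = 0.19,
                             t_pulse = 0.3, pulse_sd = 0.15,
                             months = seq(as.Date("2000-07-15"),
                                          by = "month", length.out = 8),
                             n = 5000L, bin_width_mm = 2, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  tmax <- lifespan(k_per_year)
  per <- diff(round(seq(0, n, length.out = length(months) + 1L)))
  sdlog <- sqrt(log(1 + cv_linf^2))
  recs <- lapply(seq_along(months), function(j) {
    nj <- per[j]
    if (nj == 0L) return(NULL)
    tj <- date_to_decimal(months[j])
    age <- rtruncexp(nj, z_per_year, tmax)
    birth <- round(tj - age - t_pulse) + t_pulse +
      stats::rnorm(nj, 0, pulse_sd)
    age <- pmax(tj - birth, 0.05)
    linf_i <- if (cv_linf > 0)
      stats::rlnorm(nj, log(linf_mm) - sdlog^2 / 2, sdlog)
    else rep(linf_mm, nj)
    data.frame(date = months[j],
               cl_mm = linf_i * (1 - exp(-k_per_year * age)))
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  list(lfq = bin_lengths(recs, bin_width = bin_width_mm),
       truth = list(linf_mm = linf_mm, k_per_year = k_per_year,
                    cv_linf = cv_linf, z_per_year = z_per_year,
                    t_pulse = t_pulse, pulse_sd = pulse_sd, n = n,
                    seed = seed))
}
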