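# Shared fixture builders (all generated in code; no stored data)

# Pooled length-frequency object following exact exponential decay in
# relative age: N_i = C * exp(-z * t_i) * dt_i.  The catch-curve
# regression is exact on this input by construction.
exact_decay_lfq <- function(p = growth_params(176.76, 0.07), z = 0.19,
                            lmin = 40, lmax = 160, width = 2, C = 1e4) {
  mids <- seq(lmin + width / 2, lmax - width / 2, by = width)
  lower <- mids - width / 2
  upper <- mids + width / 2
  t <- vbgf_age_at_length(p, mids)
  dt <- (1 / p$k_per_year) *
    log((p$linf_mm - lower) / (p$linf_mm - upper))
  counts <- C * exp(-z * t) * dt
  lfq(mids, as.Date("2000-10-15"), matrix(counts, ncol = 1),
      bin_width = width)
}

# Multinomial sample of the exact decay fixture (n individuals)
noisy_decay_lfq <- function(n = 10000, z = 0.19, seed = 1,
                            p = growth_params(176.76, 0.07)) {
  x <- exact_decay_lfq(p = p, z = z)
  set.seed(seed)
  cnt <- as.numeric(stats::rmultinom(1, n, x$counts[, 1]))
  lfq(x$midpoints, x$dates, matrix(cnt, ncol = 1),
      bin_width = x$bin_width)
}

# Pooled survey lengths thinned by a known logistic gear ogive
gear_thinned_lfq <- function(n = 5000, l50 = 100, sel_width = 10,
                             seed = 1, z = 0.19, linf = 176.76,
                             k = 0.07, cv = 0.05) {
  set.seed(seed)
  m <- 10 * n
  tmax <- 3 / k
  age <- -log(1 - stats::runif(m) * (1 - exp(-z * tmax))) / z
  sdlog <- sqrt(log(1 + cv^2))
  linf_i <- stats::rlnorm(m, log(linf) - sdlog^2 / 2, sdlog)
  L <- linf_i * (1 - exp(-k * age))
  s2 <- 2 * log(3) / sel_width           # L75 - L25 = sel_width
  keep <- stats::runif(m) < 1 / (1 + exp(-s2 * (L - l50)))
  L <- L[keep][seq_len(min(n, sum(keep)))]
  bin_lengths(data.frame(date = as.Date("2000-10-15"), cl_mm = L), 2)
}

# Simulated length-weight records with known power law
lwr_records <- function(n = 400, a = 0.002, b = 2.812, sigma = 0.1,
                        seed = 1, sex = "u") {
  set.seed(seed)
  cl <- stats::runif(n, 40, 170)
  data.frame(set_id = "S1", date = as.Date("2000-08-01"), depth_m = 100,
             sex = sex, cl_mm = cl,
             ww_g = a * cl^b * exp(stats::rnorm(n, 0, sigma)))
}

tiny_ga <- function() ga_control(popsize = 10L, generations = 3L)
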