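test_that("Welch F equals the published formula and the squared Welch t", {
  set.seed(11)
  g2 <- list(rnorm(20, 0, 1), rnorm(15, 0.8, 2))
  w <- welch_anova(g2)
  tt <- t.test(g2[[1]], g2[[2]])
  expect_lt(abs(w$statistic - unname(tt$statistic)^2), 1e-9)
  expect_lt(abs(w$p_value - tt$p.value), 1e-9)

  # fixed three-group fixture against a hand computation of the
  # Welch (1951) statistic
  g3 <- list(c(4.1, 5.2, 3.9, 4.8, 5.0),
             c(6.3, 6.9, 7.4, 6.1),
             c(3.0, 2.2, 2.8, 3.5, 2.6, 3.1))
  w3 <- welch_anova(g3)
  nj <- lengths(g3); mj <- sapply(g3, mean); vj <- sapply(g3, var)
  wj <- nj / vj
  mw <- sum(wj * mj) / sum(wj)
  gnum <- sum(wj * (mj - mw)^2) / (length(g3) - 1)
  lam <- sum((1 - wj / sum(wj))^2 / (nj - 1)) / (length(g3)^2 - 1)
  Fw <- gnum / (1 + 2 * lam * (length(g3) - 2))
  df2 <- 1 / (3 * lam)
  expect_equal(w3$statistic, Fw, tolerance = 1e-9)
  expect_equal(w3$df1, 2)
  expect_equal(w3$df2, df2, tolerance = 1e-9)

  dup <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  wd <- welch_anova(dup)
  expect_equal(wd$statistic, 0)
  expect_equal(wd$p_value, 1)
  expect_error(welch_anova(list(c(1, 1), c(1, 2))), "variance")
})

test_that("pairwise Welch-Bonferroni letters separate shifted groups", {
  set.seed(3)
  base <- rnorm(30)
  same <- list(a = base, b = base + rnorm(30, 0, 1e-3), c = base)
  ps <- pairwise_welch_bonferroni(same)
  expect_true(all(ps$p_adjusted >= 1 - 1e-6, na.rm = TRUE))
  expect_length(unique(ps$letters), 1L)

  shifted <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25, 10))
  pp <- pairwise_welch_bonferroni(shifted)
  expect_false(pp$letters["c"] %in% pp$letters[c("a", "b")])
  # adjusted p never drops below the raw pairwise p
  raw <- t.test(shifted$a, shifted$b)$p.value
  expect_gte(pp$p_adjusted["a", "b"], raw)
})

test_that("sex-ratio chi-square matches the two-cell Pearson statistic", {
  even <- sex_ratio_chisq(50, 50)
  expect_equal(even$chisq, 0)
  expect_equal(even$p_value, 1)
  skew <- sex_ratio_chisq(25, 75)
  expect_equal(skew$chisq, 25)
  expect_equal(skew$p_value,
               chisq.test(c(25, 75), correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(sex_ratio_chisq(61, 100)$ratio, 0.61)
  expect_error(sex_ratio_chisq(0, 0), "at least one")
})

test_that("length-weight regression is exact on noiseless power laws", {
  cl <- seq(40, 170, by = 5)
  recs <- data.frame(set_id = "S", date = as.Date("2000-08-01"),
                     depth_m = 80, sex = "u", cl_mm = cl,
                     ww_g = 0.002 * cl^2.812)
  fit <- fit_lwr(recs, "pooled")
  expect_equal(fit$a, 0.002, tolerance = 1e-9)
  expect_equal(fit$b, 2.812, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(2)
  iso <- recs
  iso$ww_g <- 0.001 * cl^3 * exp(rnorm(length(cl), 0, 0.01))
  at <- allometry_test(fit_lwr(iso, "pooled"))
  expect_gt(at$p_value, 0.05)
  expect_error(fit_lwr(recs[1:2, ], "pooled"), "at least 3")
})

test_that("allometry t follows (b - 3)/SE with n - 2 df", {
  fake <- structure(list(b = 2.839, se_b = 0.027, n = 198L),
                    class = "lwr_fit")
  at <- allometry_test(fake)
  expect_equal(round(at$t, 2), -5.96)
  expect_equal(at$df, 196L)
  fake2 <- structure(list(b = 2.812, se_b = 0.021, n = 413L),
                     class = "lwr_fit")
  expect_equal(round(allometry_test(fake2)$t, 2), -8.95)
})

test_that("slope estimates land within 2 SE under lognormal noise", {
  hits <- vapply(1:20, function(s) {
    recs <- lwr_records(n = 400, b = 2.812, sigma = 0.1, seed = s)
    fit <- fit_lwr(recs, "pooled")
    abs(fit$b - 2.812) <= 2 * fit$se_b
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("between-sex comparison recovers a common-slope offset", {
  make2 <- function(seed, off = 0.08, db = 0) {
    m <- lwr_records(400, a = 0.002, b = 2.8, sigma = 0.1,
                     seed = seed, sex = "m")
    f <- lwr_records(400, a = 0.002 * exp(off), b = 2.8 + db,
                     sigma = 0.1, seed = seed + 1000, sex = "f")
    rbind(m, f)
  }
  res <- vapply(1:20, function(s) {
    cmp <- compare_lwr_sexes(make2(s))
    c(cover = cmp$offset_ci["lower"] <= 0.08 &&
        cmp$offset_ci["upper"] >= 0.08,
      noint = cmp$slope_test$p_value > 0.05)
  }, c(cover = TRUE, noint = TRUE))
  expect_gte(mean(res["cover", ]), 0.9)
  expect_gte(mean(res["noint", ]), 0.9)

  # identical sexes: nothing significant, offset interval covers zero
  same <- make2(99, off = 0)
  cmp0 <- compare_lwr_sexes(same)
  expect_true(cmp0$offset_ci["lower"] <= 0 && cmp0$offset_ci["upper"] >= 0)

  # a real slope difference is detected
  cmp1 <- compare_lwr_sexes(make2(7, off = 0, db = 0.3))
  expect_lt(cmp1$slope_test$p_value, 0.05)
})

test_that("per-set CPUE aggregates conserve the record count", {
  sets <- data.frame(set_id = c("A", "B", "C"),
                     date = as.Date("2000-08-01"),
                     depth_m = c(50, 95, 110), n_traps = 15L,
                     valid = TRUE)
  recs <- data.frame(set_id = rep(c("A", "B"), c(30, 6)),
                     date = as.Date("2000-08-01"), depth_m = 50,
                     sex = "u", cl_mm = 100, ww_g = NA_real_)
  out <- cpue_by_stratum(sets, recs)
  expect_equal(out$mean_cpue[out$depth_lo == 40], 2)
  # zero-catch set C contributes a zero to its stratum
  expect_equal(out$n_sets[out$depth_lo == 100], 1)
  expect_equal(out$mean_cpue[out$depth_lo == 100], 0)
  g <- cpue_groups(sets, recs)
  expect_equal(sum(unlist(g)) * 15, 36)
  bad <- recs; bad$set_id[1] <- "ZZ"
  expect_error(cpue_by_stratum(sets, bad), "unknown set")
})

test_that("stratum CPUE ranking follows the imposed depth density", {
  cfg <- sim_config()
  pop <- simulate_population(cfg, seed = 31)
  sv <- simulate_trap_survey(pop, cfg, seed = 32)
  out <- cpue_by_stratum(sv$sets, sv$records)
  peak <- out$depth_lo[which.max(out$mean_cpue)]
  # density profile peaks at 80-120 m
  expect_true(peak >= 60 && peak <= 120)
  shallow <- out$mean_cpue[out$depth_lo == 80]
  deep <- out$mean_cpue[out$depth_lo == 200]
  expect_gt(shallow, deep)
})
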