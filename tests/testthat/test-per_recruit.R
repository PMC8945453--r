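test_that("relative yield per recruit satisfies its boundary identities", {
  for (cc in c(0.3, 0.575, 0.8)) {
    for (mk in c(0.5, 1.857, 3)) {
      expect_equal(relative_ypr(0, cc, mk), 0)
      U <- 1 - cc
      expect_equal(relative_ypr(1, cc, mk), U^mk * (1 - U)^3,
                   tolerance = 1e-12)
    }
  }
  expect_equal(relative_ypr(1, 0.575, 1.857), 0.0388, tolerance = 1e-3)
  expect_error(relative_ypr(1.2, 0.5, 1), "E")
  expect_error(relative_ypr(0.5, 1.1, 1), "c")
})

test_that("relative biomass ratio is 1 unfished and strictly decreasing", {
  E <- seq(0, 1, by = 0.01)
  for (cc in c(0.3, 0.575, 0.8)) {
    for (mk in c(0.5, 1.857, 3)) {
      b <- relative_biomass_ratio(E, cc, mk)
      expect_equal(b[1], 1, tolerance = 1e-12)
      expect_true(all(diff(b) < 0))
    }
  }
  expect_equal(relative_biomass_ratio(0.4, 0.575, 1.857), 0.486,
               tolerance = 1e-3)
})

test_that("reference points are internally consistent", {
  pr <- per_recruit(176.76, 0.07, 0.13, lc_mm = 101.65)
  # E50 halves the virgin biomass to the bisection tolerance
  expect_lt(abs(relative_biomass_ratio(pr$e50, 101.65 / 176.76,
                                       0.13 / 0.07) - 0.5), 1e-5)
  # grid argmax agrees with the refined optimum
  grid_emax <- pr$curve$E[which.max(pr$curve$yr)]
  expect_lt(abs(grid_emax - pr$emax), 1e-3 + 1e-9)
  # every reported (E, F) pair obeys F = E M / (1 - E)
  expect_equal(pr$f10, f_from_e(pr$e10, 0.13), tolerance = 1e-12)
  if (pr$emax < 1)
    expect_equal(pr$fmax, f_from_e(pr$emax, 0.13), tolerance = 1e-12)
  # marginal yield at E10 is a tenth of the origin slope
  h <- 1e-5
  yfun <- function(E) relative_ypr(E, 101.65 / 176.76, 0.13 / 0.07)
  d0 <- (yfun(h) - yfun(0)) / h
  d10 <- (yfun(pr$e10 + h) - yfun(pr$e10 - h)) / (2 * h)
  expect_lt(abs(d10 - 0.1 * d0), 1e-3 * d0)
})

test_that("published F/E reference pairs obey the conversion at 2 dp", {
  # Lc sensitivity rows: (F10, E10) and (Fmax, Emax) with M = 0.13
  pairs <- rbind(c(0.12, 0.48), c(0.16, 0.55),
                 c(0.08, 0.38), c(0.17, 0.56),
                 c(0.05, 0.27), c(0.18, 0.58))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(round(f_from_e(pairs[i, 2], 0.13), 2), pairs[i, 1])
  }
})

test_that("Lc sensitivity table carries consistent ages and direction", {
  tab <- suppressWarnings(
    lc_sensitivity(176.76, 0.07, 0.13, lc_list = c(90, 101.65, 113.30)))
  expect_equal(nrow(tab), 3L)
  expect_lt(max(abs(tab$tc_years - c(10.16, 12.22, 14.63))), 0.015)
  # under knife-edge selection later first capture raises every
  # exploitation reference point
  expect_true(all(diff(tab$e10) > 0))
  expect_true(all(diff(tab$e50) > 0))
  expect_true(all(diff(tab$emax) > 0))
  one <- suppressWarnings(
    lc_sensitivity(176.76, 0.07, 0.13, lc_list = 101.65))
  expect_equal(nrow(one), 1L)
})

test_that("length-structured recursion matches the knife-edge closed form", {
  linf <- 176.76; k <- 0.07; m <- 0.13; lc <- 101.65
  knife <- function(L) as.numeric(L >= lc)
  f_grid <- c(0, 0.05, 0.1, 0.2, 0.4, 0.8)
  ls <- length_structured_per_recruit(linf, k, m, knife, f_grid,
                                      weight_ab = c(1, 3),
                                      class_width = 0.5)
  expect_equal(ls$curve$yr[1], 0)
  expect_gt(ls$curve$br[1], 0)
  # relative agreement with the Beverton-Holt closed form (proportional)
  E <- f_grid[-1] / (f_grid[-1] + m)
  closed <- relative_ypr(E, lc / linf, m / k)
  ratio <- ls$curve$yr[-1] / closed
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
  # linearity in the weight coefficient
  ls2 <- length_structured_per_recruit(linf, k, m, knife, f_grid,
                                       weight_ab = c(2, 3),
                                       class_width = 0.5)
  expect_equal(ls2$curve$yr, 2 * ls$curve$yr, tolerance = 1e-12)
  expect_equal(ls2$curve$br, 2 * ls$curve$br, tolerance = 1e-12)
  expect_error(length_structured_per_recruit(linf, k, m, knife, -0.1),
               "non-negative")
})

test_that("ogive-mode per-recruit reference points are ordered and finite", {
  og <- structure(list(s1 = 101.65 * log(3) / 5, s2 = log(3) / 5),
                  class = "selectivity_ogive")
  pr <- suppressWarnings(
    per_recruit(176.76, 0.07, 0.13, ogive = og, mode = "ogive",
                weight_ab = c(0.002, 2.812),
                e_grid = seq(0, 0.99, by = 0.01)))
  expect_true(pr$e50 > 0 && pr$e50 < pr$emax)
  expect_true(pr$e10 > 0 && pr$e10 <= 1)
  expect_equal(pr$f10, f_from_e(pr$e10, 0.13), tolerance = 1e-12)
})
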