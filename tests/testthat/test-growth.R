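test_that("VBGF length-age functions are exact mutual inverses", {
  p <- growth_params(176.76, 0.07)
  expect_equal(vbgf_length_at_age(p, 0), 0)
  for (t in seq(0, 60, by = 2.5)) {
    expect_lt(abs(vbgf_age_at_length(p, vbgf_length_at_age(p, t)) - t),
              1e-9)
  }
  # half-saturation identity
  p2 <- growth_params(100, 0.5)
  expect_equal(vbgf_length_at_age(p2, log(2) / 0.5), 50)
  expect_error(vbgf_length_at_age(p, -1), "non-negative")
  expect_error(vbgf_age_at_length(p, 176.76), "Linf")
})

test_that("inverse VBGF reproduces published ages at first capture", {
  p <- growth_params(176.76, 0.07)
  expect_lt(abs(vbgf_age_at_length(p, 101.65) - 12.22), 0.01)
  expect_lt(abs(vbgf_age_at_length(p, 113.30) - 14.63), 0.01)
  expect_lt(abs(vbgf_length_at_age(p, 12.22) - 101.6), 0.05)
  expect_equal(vbgf_age_at_length(p, 0), 0)
})

test_that("lifespan and growth performance index follow their formulas", {
  expect_equal(round(lifespan(0.07), 2), 42.86)
  expect_equal(round(lifespan(0.05), 2), 60)
  expect_equal(lifespan(3), 1)
  expect_error(lifespan(0), "positive")

  expect_equal(growth_performance_index(100, 1), 4)
  expect_equal(round(growth_performance_index(176.76, 0.07), 2), 3.34)
  expect_equal(round(growth_performance_index(157.18, 0.07), 2), 3.24)
  # invariant under the k ~ Linf trade-off k -> k/c^2, Linf -> c*Linf
  for (cc in c(0.5, 2, 3.7)) {
    expect_equal(growth_performance_index(cc * 176.76, 0.07 / cc^2),
                 growth_performance_index(176.76, 0.07),
                 tolerance = 1e-12)
  }
  expect_error(growth_performance_index(-1, 0.1), "positive")
})

test_that("ELEFAN score credits a crossed peak and penalizes troughs", {
  x <- lfq(seq(101, 109, 2), as.Date("2000-07-15"),
           matrix(c(0, 0, 8, 0, 0), ncol = 1), bin_width = 2)
  r <- restructure(x, window = 3)
  # one cohort trajectory through the central peak bin only
  hit <- elefan_score(r, growth_params(200, 1, 0.795))
  expect_equal(hit$esp, 4 / 3, tolerance = 1e-9)
  expect_equal(hit$asp, 4 / 3, tolerance = 1e-9)
  expect_equal(hit$rn, 1, tolerance = 1e-9)
  # trajectory through a trough bin only
  miss <- elefan_score(r, growth_params(200, 1, 0.837))
  expect_lt(miss$esp, 0)
  expect_lt(miss$rn, 0.1)
  # flat data has no peaks to score
  flat <- restructure(lfq(seq(41, 49, 2), as.Date("2000-07-15"),
                          matrix(rep(3, 5), ncol = 1)), 3)
  expect_error(elefan_score(flat, growth_params(100, 0.5)), "positive")
})

test_that("genetic-algorithm fit is deterministic and internally consistent", {
  fx <- make_lfq_fixture(n = 800, seed = 9)
  ctl <- tiny_ga()
  f1 <- elefan_ga(fx$lfq, control = ctl, seed = 4)
  f2 <- elefan_ga(fx$lfq, control = ctl, seed = 4)
  expect_identical(coef(f1), coef(f2))
  # the reported score is the score of the reported parameters
  r <- restructure(fx$lfq, 5)
  expect_equal(f1$score$rn, elefan_score(r, f1$par)$rn, tolerance = 1e-12)
  # elitism makes the generation-best non-decreasing
  expect_true(all(diff(f1$trace) >= -1e-12))
  # a collapsed search box returns that point
  pt <- elefan_ga(fx$lfq,
                  bounds = list(linf = c(180, 180), k = c(0.08, 0.08),
                                t_anchor = c(0.25, 0.25)),
                  control = ctl, seed = 1)
  expect_equal(unname(coef(pt)[1:3]), c(180, 0.08, 0.25))
  expect_error(elefan_ga(fx$lfq,
                         bounds = list(linf = c(200, 100), k = c(0.01, 1),
                                       t_anchor = c(0, 1))),
               "bounds")
})

test_that("bootstrap respects percentile ordering, determinism and n_boot = 1", {
  fx <- make_lfq_fixture(n = 600, seed = 5)
  ctl <- tiny_ga()
  b1 <- elefan_ga_boot(fx$lfq, control = ctl, n_boot = 1, seed = 2)
  expect_equal(unname(b1$ci[, "lower"]), unname(b1$replicates[1, ]))
  expect_equal(unname(b1$ci[, "upper"]), unname(b1$replicates[1, ]))

  b5 <- elefan_ga_boot(fx$lfq, control = ctl, n_boot = 5, seed = 2)
  expect_true(all(b5$ci[, "lower"] <= b5$ci[, "mean"] + 1e-12))
  expect_true(all(b5$ci[, "mean"] <= b5$ci[, "upper"] + 1e-12))
  b5b <- elefan_ga_boot(fx$lfq, control = ctl, n_boot = 5, seed = 2)
  expect_identical(b5$replicates, b5b$replicates)
  # per-month sample sizes are preserved by the multinomial resampling
  expect_equal(sum(b5$point$lfq$counts), sum(fx$lfq$counts))
})

test_that("bootstrap interval brackets the truth on a recovery fixture", {
  fx <- make_lfq_fixture(n = 2000, seed = 21)
  b <- elefan_ga_boot(fx$lfq,
                      control = ga_control(popsize = 20L,
                                           generations = 8L),
                      n_boot = 10, seed = 3)
  expect_lt(b$ci["linf_mm", "lower"], 1.15 * 176.76)
  expect_gt(b$ci["linf_mm", "upper"], 0.85 * 176.76)
})
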