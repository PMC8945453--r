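test_that("binning assigns half-open classes and conserves totals", {
  recs <- data.frame(date = as.Date(c("2000-07-03", "2000-07-20")),
                     cl_mm = c(39.6, 174.3))
  x <- bin_lengths(recs, bin_width = 2, origin = 38)
  occ <- x$midpoints[rowSums(x$counts) > 0]
  expect_equal(range(occ), c(39, 175))
  expect_equal(sum(x$counts), 2)

  # a record exactly on a lower bin edge belongs to that bin
  x2 <- bin_lengths(data.frame(date = as.Date("2000-07-01"), cl_mm = 40),
                    bin_width = 2, origin = 38)
  expect_equal(x2$midpoints[x2$counts[, 1] == 1], 41)
  expect_equal(sum(x2$counts), 1)

  # column sums match per-month record counts for arbitrary input
  set.seed(42)
  recs3 <- data.frame(
    date = sample(seq(as.Date("2000-07-01"), as.Date("2001-02-20"), 1),
                  1000, replace = TRUE),
    cl_mm = runif(1000, 40, 175))
  x3 <- bin_lengths(recs3)
  expect_equal(unname(colSums(x3$counts)),
               unname(as.vector(table(format(recs3$date, "%Y-%m")))))

  # conservation holds for other widths and origins
  for (w in c(1, 2, 5)) {
    expect_equal(sum(bin_lengths(recs3, bin_width = w)$counts), 1000)
  }
})

test_that("binning rejects empty input and records below the origin", {
  expect_error(bin_lengths(data.frame()), "non-empty")
  expect_error(
    bin_lengths(data.frame(date = as.Date("2000-07-01"), cl_mm = 30),
                origin = 38),
    "below the bin origin")
})

test_that("restructuring matches the hand-computed single-peak column", {
  x <- lfq(seq(101, 109, 2), as.Date("2000-07-15"),
           matrix(c(0, 0, 8, 0, 0), ncol = 1), bin_width = 2)
  r <- restructure(x, window = 3)
  # MA = (0, 8/3, 8/3, 8/3, 0); q = (0, 0, 3, 0, 0); qbar = 0.6;
  # raw r = (-1, -1, 4, -1, -1); peak down-weighted by 1/(nz+1) = 1/3;
  # negatives rescaled to balance: 4/3 against four bins of -1/3.
  expect_equal(r$rvalues[, 1], c(-1, -1, 4, -1, -1) / 3,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(abs(sum(r$rvalues)), 1e-9)
})

test_that("restructuring is flat-zero on uniform columns and handles all-zero columns", {
  x <- lfq(seq(41, 59, 2), as.Date(c("2000-07-15", "2000-08-15")),
           cbind(rep(7, 10), rep(0, 10)))
  r <- restructure(x, 5)
  expect_equal(max(abs(r$rvalues)), 0)
})

test_that("restructured columns balance to zero and are scale invariant", {
  set.seed(7)
  for (rep in 1:5) {
    cnt <- matrix(rpois(40 * 3, 4), 40, 3)
    x <- lfq(seq(41, 119, 2), as.Date(c("2000-07-15", "2000-08-15",
                                        "2000-09-15")), cnt)
    r <- restructure(x, 5)
    for (j in 1:3) {
      col <- r$rvalues[, j]
      if (any(col > 0) && any(col < 0))
        expect_lt(abs(sum(col)), 1e-9)
    }
    # multiplying a column by a constant leaves its scores unchanged
    x2 <- lfq(x$midpoints, x$dates, cnt * rep(c(3, 1, 1), each = 40))
    expect_equal(restructure(x2, 5)$rvalues, r$rvalues,
                 tolerance = 1e-12)
  }
  expect_error(restructure(lfq(1, Sys.Date(), matrix(1), 2), 4), "odd")
})

test_that("catch-record CSV round-trips preserve all fields", {
  recs <- lwr_records(n = 500, seed = 3, sex = "f")
  recs$sex[1:100] <- "m"
  recs$cl_mm <- round(recs$cl_mm, 1)
  recs$ww_g <- round(recs$ww_g, 1)
  recs$ww_g[5] <- NA   # blank weight must survive the round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_catch_records_csv(recs, path)
  back <- read_catch_records_csv(path)
  expect_equal(back$cl_mm, recs$cl_mm)
  expect_equal(back$ww_g, recs$ww_g)
  expect_equal(back$sex, recs$sex)
  expect_equal(back$date, recs$date)

  sets <- data.frame(set_id = c("S1", "S2", "S3"),
                     date = as.Date("2000-08-01") + 0:2,
                     depth_m = c(50, 100.5, 210), n_traps = 15L,
                     valid = c(TRUE, TRUE, FALSE))
  sp <- withr::local_tempfile(fileext = ".csv")
  write_trap_sets_csv(sets, sp)
  expect_equal(read_trap_sets_csv(sp), sets)
})

test_that("catch-record reader names missing columns and bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("set_id,date,sex,cl_mm", path)
  expect_error(read_catch_records_csv(path), "depth_m")
  writeLines(c("set_id,date,depth_m,sex,cl_mm,ww_g",
               "S1,2000-08-01,50,m,101.2,340.1",
               "S2,2000-08-02,60,x,99.0,"), path)
  expect_error(read_catch_records_csv(path), "row 2")
})

test_that("length-frequency CSV round-trips and rejects malformed grids", {
  x <- make_lfq_fixture(n = 300, seed = 2)$lfq
  path <- withr::local_tempfile(fileext = ".csv")
  write_lfq_csv(x, path)
  back <- read_lfq_csv(path)
  expect_equal(back$midpoints, x$midpoints)
  expect_equal(back$dates, x$dates)
  expect_equal(unname(back$counts), unname(x$counts))

  writeLines(c("midpoint_mm,2000-07-15", "43,1", "41,2"), path)
  expect_error(read_lfq_csv(path), "increasing")
  writeLines(c("midpoint_mm,2000-07-15", "41,-1", "43,2"), path)
  expect_error(read_lfq_csv(path), "non-negative")
})
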