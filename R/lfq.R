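#' Length-frequency data objects
#'
#' An `lfq` object holds binned counts of body lengths (carapace length in
#' mm for lobsters) on a uniform length grid, one column per sample date.
#' It is the substrate for ELEFAN growth estimation ([elefan_ga()]) and the
#' length-converted catch curve ([catch_curve()]).
#'
#' @param midpoints numeric vector of ascending, evenly spaced bin
#'   midpoints (mm).
#' @param dates vector of sample dates (`Date` or coercible).
#' @param counts non-negative numeric matrix, `length(midpoints)` rows and
#'   `length(dates)` columns.
#' @param bin_width positive scalar bin width (mm); default inferred from
#'   the midpoint spacing.
#'
#' @return An object of class `lfq`: a list with elements `midpoints`,
#'   `dates`, `counts` and `bin_width`.
#' @seealso [bin_lengths()], [restructure()], [read_lfq_csv()]
#' @export
lfq <- function(midpoints, dates, counts, bin_width = NULL) {
  midpoints <- as.numeric(midpoints)
  dates <- as.Date(dates)
  counts <- as.matrix(counts)
  if (length(midpoints) < 1L) stop("lfq needs at least one length bin")
  if (nrow(counts) != length(midpoints) || ncol(counts) != length(dates))
    stop("counts must be a (bins x dates) matrix matching midpoints and dates")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.unsorted(dates)) stop("sample dates must be ascending")
  if (length(midpoints) > 1L) {
    d <- diff(midpoints)
    if (any(d <= 0)) stop("bin midpoints must be strictly increasing")
    if (max(d) - min(d) > 1e-8 * max(d))
      stop("bin midpoints must be evenly spaced")
    if (is.null(bin_width)) bin_width <- d[1L]
  }
  if (is.null(bin_width)) stop("bin_width required for a single-bin lfq")
  if (bin_width <= 0) stop("bin_width must be positive")
  dimnames(counts) <- list(format(midpoints), format(dates))
  structure(list(midpoints = midpoints, dates = dates, counts = counts,
                 bin_width = bin_width),
            class = "lfq")
}

#' @export
print.lfq <- function(x, ...) {
  cat("Length-frequency data (", nrow(x$counts), " bins x ",
      ncol(x$counts), " dates)\n", sep = "")
  cat("  bin width : ", x$bin_width, " mm\n", sep = "")
  cat("  lengths   : ", min(x$midpoints), "-", max(x$midpoints),
      " mm (midpoints)\n", sep = "")
  cat("  dates     : ", format(min(x$dates)), " to ", format(max(x$dates)),
      "\n", sep = "")
  cat("  total n   : ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lfq <- function(object, ...) {
  tot <- colSums(object$counts)
  occ <- object$midpoints[rowSums(object$counts) > 0]
  cat("Length-frequency summary\n")
  cat("  per-date totals:\n")
  print(tot)
  if (length(occ))
    cat("  occupied midpoints: ", min(occ), "-", max(occ), " mm\n", sep = "")
  invisible(list(totals = tot, occupied_range = range(occ)))
}

#' @export
plot.lfq <- function(x, ..., growth = NULL) {
  t <- date_to_decimal(x$dates)
  graphics::image(t, x$midpoints, t(sqrt(x$counts)),
                  xlab = "Sample date (decimal year)",
                  ylab = "Carapace length (mm)",
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE), ...)
  if (!is.null(growth)) {
    tt <- seq(min(t) - 3 / growth$k_per_year, max(t), length.out = 400)
    for (a in cohort_anchors(x, growth)) {
      age <- tt - a
      L <- ifelse(age > 0, vbgf_length_at_age(growth, pmax(age, 0)), NA)
      graphics::lines(tt, L, col = "firebrick", lwd = 1.2)
    }
  }
  invisible(x)
}

#' Bin individual length records into monthly length frequencies
#'
#' Records are grouped by calendar month and assigned to half-open length
#' bins `[origin + i*w, origin + (i+1)*w)`.
#'
#' @param records data frame of catch records with at least columns
#'   `date` and `cl_mm` (see [read_catch_records_csv()]).
#' @param bin_width positive bin width in mm (default 2, the conventional
#'   class interval for lobster carapace length).
#' @param origin lower edge of the first bin (mm). Default: the minimum
#'   observed length floored to an even millimetre.
#' @return An [lfq] object; total count equals `nrow(records)`.
#' @export
bin_lengths <- function(records, bin_width = 2, origin = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame")
  if (bin_width <= 0) stop("bin_width must be positive")
  cl <- as.numeric(records$cl_mm)
  if (any(!is.finite(cl)) || any(cl <= 0)) stop("cl_mm must be positive")
  if (is.null(origin)) origin <- 2 * floor(floor(min(cl)) / 2)
  below <- which(cl < origin)
  if (length(below))
    stop("record ", below[1L], " (cl_mm = ", cl[below[1L]],
         ") lies below the bin origin ", origin)
  dates <- as.Date(records$date)
  mon <- format(dates, "%Y-%m")
  umon <- sort(unique(mon))
  # mid-month representative date per sample
  mdates <- as.Date(paste0(umon, "-15"))
  idx <- floor((cl - origin) / bin_width)
  nb <- max(idx) + 1L
  counts <- matrix(0, nrow = nb, ncol = length(umon))
  for (j in seq_along(umon)) {
    tab <- tabulate(idx[mon == umon[j]] + 1L, nbins = nb)
    counts[, j] <- tab
  }
  mids <- origin + (seq_len(nb) - 0.5) * bin_width
  lfq(mids, mdates, counts, bin_width = bin_width)
}

#' ELEFAN restructuring of a length-frequency matrix
#'
#' Transforms raw counts into peak/trough scores so that candidate growth
#' curves can be rewarded for passing through modes.  Per sample (column):
#' a centred moving average `MA` of the counts over `window` bins
#' (shrinking to the available bins at the grid edges, so a uniform
#' column scores zero everywhere); quotients `q = N/MA` (0 where `MA` is 0);
#' scores `r = q/mean(q) - 1`; positive scores are down-weighted by
#' `1/(nz+1)` where `nz` counts zero-count immediate neighbours (bins
#' outside the grid count as zero); finally negative scores are rescaled
#' by one per-column factor so the column sums to zero (skipped when a
#' column carries only one sign).
#'
#' @param x an [lfq] object.
#' @param window odd moving-average window, >= 3. Default 5.
#' @return An object of class `lfq_restructured`: the same grid with a
#'   matrix `rvalues` and the `window` used.
#' @export
restructure <- function(x, window = 5L) {
  stopifnot(inherits(x, "lfq"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  half <- (window - 1L) %/% 2L
  nb <- nrow(x$counts)
  rv <- matrix(0, nb, ncol(x$counts))
  for (j in seq_len(ncol(x$counts))) {
    N <- x$counts[, j]
    if (all(N == 0)) next
    ma <- vapply(seq_len(nb), function(i)
      mean(N[max(1L, i - half):min(nb, i + half)]), 0)
    q <- ifelse(ma > 0, N / ma, 0)
    r <- q / mean(q) - 1
    # de-emphasize isolated peaks flanked by empty bins
    nz <- vapply(seq_len(nb), function(i) {
      left <- if (i > 1L) N[i - 1L] == 0 else TRUE
      right <- if (i < nb) N[i + 1L] == 0 else TRUE
      sum(left, right)
    }, 0L)
    pos <- r > 0
    r[pos] <- r[pos] / (nz[pos] + 1)
    sp <- sum(r[pos])
    sn <- -sum(r[r < 0])
    if (sp > 0 && sn > 0) r[r < 0] <- r[r < 0] * sp / sn
    rv[, j] <- r
  }
  dimnames(rv) <- dimnames(x$counts)
  # per-column run structure of positive and negative stretches,
  # cached for ELEFAN scoring
  runs <- matrix(0L, nb, ncol(rv))
  nruns <- matrix(0L, nb, ncol(rv))
  negmin <- vector("list", ncol(rv))
  asp <- 0
  for (j in seq_len(ncol(rv))) {
    pos <- rv[, j] > 0
    id <- cumsum(c(pos[1L], diff(pos)) == 1) * pos
    runs[, j] <- id
    if (any(pos))
      asp <- asp + sum(tapply(rv[pos, j], id[pos], max))
    neg <- rv[, j] < 0
    nid <- cumsum(c(neg[1L], diff(neg)) == 1) * neg
    nruns[, j] <- nid
    negmin[[j]] <- if (any(neg))
      tapply(rv[neg, j], nid[neg], min) else numeric(0)
  }
  structure(list(midpoints = x$midpoints, dates = x$dates, rvalues = rv,
                 bin_width = x$bin_width, window = window,
                 counts = x$counts, runs = runs, asp = asp,
                 nruns = nruns, negmin = negmin),
            class = "lfq_restructured")
}

#' @export
print.lfq_restructured <- function(x, ...) {
  cat("Restructured length-frequency data (window ", x$window, ")\n",
      sep = "")
  cat("  ", nrow(x$rvalues), " bins x ", ncol(x$rvalues), " dates; ",
      sum(x$rvalues > 0), " positive bins\n", sep = "")
  invisible(x)
}

#' Pool a length-frequency object across sample dates
#'
#' @param x an [lfq] object.
#' @return An [lfq] object with a single column holding the row sums
#'   (dated at the last sample).
#' @export
pool_lfq <- function(x) {
  stopifnot(inherits(x, "lfq"))
  lfq(x$midpoints, max(x$dates),
      matrix(rowSums(x$counts), ncol = 1), bin_width = x$bin_width)
}

## ---- catch-record and trap-set I/O ----------------------------------------

#' Read and write catch records and trap sets
#'
#' `catch_records.csv` has columns `set_id,date,depth_m,sex,cl_mm,ww_g`
#' (sex coded `m`/`f`/`u`; `ww_g` may be blank). `sets.csv` has columns
#' `set_id,date,depth_m,n_traps,valid`.
#'
#' @param path file path.
#' @return `read_catch_records_csv()` returns a data frame of records;
#'   `read_trap_sets_csv()` a data frame of sets. Writers return the path
#'   invisibly. Round-trips are exact to the recorded precision
#'   (0.1 mm, 0.1 g).
#' @export
read_catch_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "date", "depth_m", "sex", "cl_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (!"ww_g" %in% names(df)) df$ww_g <- NA_real_
  df$date <- as.Date(df$date)
  bad <- which(is.na(df$date) | !is.finite(df$cl_mm) | df$cl_mm <= 0 |
                 !df$sex %in% c("m", "f", "u") |
                 (!is.na(df$ww_g) & df$ww_g <= 0) | df$depth_m < 0)
  if (length(bad)) stop("unparseable or invalid record at row ", bad[1L])
  df[c("set_id", "date", "depth_m", "sex", "cl_mm", "ww_g")]
}

#' @rdname read_catch_records_csv
#' @param records data frame as returned by [read_catch_records_csv()].
#' @export
write_catch_records_csv <- function(records, path) {
  out <- records
  out$cl_mm <- sprintf("%.1f", out$cl_mm)
  out$ww_g <- ifelse(is.na(records$ww_g), "", sprintf("%.1f", records$ww_g))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_catch_records_csv
#' @export
read_trap_sets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "date", "depth_m", "n_traps", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df$valid <- as.logical(df$valid)
  if (any(df$n_traps < 1)) stop("n_traps must be >= 1")
  df[need]
}

#' @rdname read_catch_records_csv
#' @param sets data frame of trap sets.
#' @export
write_trap_sets_csv <- function(sets, path) {
  utils::write.csv(sets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write length-frequency CSV files
#'
#' Format: a `midpoint_mm` column followed by one column of counts per
#' sample date (ISO 8601 headers).
#'
#' @param path file path.
#' @return An [lfq] object (reader); the path, invisibly (writer).
#' @export
read_lfq_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "midpoint_mm")
    stop("first column must be midpoint_mm")
  mids <- df[[1L]]
  if (is.unsorted(mids, strictly = TRUE))
    stop("bin midpoints must be strictly increasing")
  counts <- as.matrix(df[-1L])
  if (any(counts < 0)) stop("counts must be non-negative")
  lfq(mids, as.Date(names(df)[-1L]), counts)
}

#' @rdname read_lfq_csv
#' @param x an [lfq] object.
#' @export
write_lfq_csv <- function(x, path) {
  stopifnot(inherits(x, "lfq"))
  df <- data.frame(midpoint_mm = x$midpoints, x$counts,
                   check.names = FALSE)
  names(df) <- c("midpoint_mm", format(x$dates))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- date helpers ---------------------------------------------------------

#' Convert dates to decimal years
#' @param d a `Date` vector.
#' @return numeric decimal years.
#' @keywords internal
date_to_decimal <- function(d) {
  lt <- as.POSIXlt(d)
  yr <- lt$year + 1900
  start <- as.numeric(as.Date(paste0(yr, "-01-01")))
  len <- as.numeric(as.Date(paste0(yr + 1, "-01-01"))) - start
  yr + (as.numeric(as.Date(d)) - start + 0.5) / len
}
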