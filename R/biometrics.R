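#' CPUE by depth stratum
#'
#' Catch per unit effort (individuals per trap) for each valid set,
#' summarized over 20-m depth strata spanning 0-240 m with
#' normal-approximation 0.95 confidence intervals.
#'
#' @param sets data frame of trap sets (`set_id`, `depth_m`, `n_traps`,
#'   `valid`).
#' @param records data frame of catch records; every `set_id` must refer
#'   to a set.
#' @param strata_breaks stratum edges in m (default `seq(0, 240, 20)`).
#' @return Data frame with one row per occupied stratum: bounds,
#'   `n_sets`, `mean_cpue`, `ci_lower`, `ci_upper`.
#' @export
cpue_by_stratum <- function(sets, records,
                            strata_breaks = seq(0, 240, by = 20)) {
  missing_set <- setdiff(unique(records$set_id), sets$set_id)
  if (length(missing_set))
    stop("records reference unknown set(s): ",
         paste(utils::head(missing_set, 3), collapse = ", "))
  valid <- sets[sets$valid, , drop = FALSE]
  nrec <- table(factor(records$set_id[records$set_id %in% valid$set_id],
                       levels = valid$set_id))
  cpue <- as.numeric(nrec) / valid$n_traps
  stratum <- cut(valid$depth_m, strata_breaks, right = FALSE)
  out <- do.call(rbind, lapply(levels(stratum), function(s) {
    v <- cpue[!is.na(stratum) & stratum == s]
    if (!length(v)) return(NULL)
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    i <- match(s, levels(stratum))
    data.frame(depth_lo = strata_breaks[i], depth_hi = strata_breaks[i + 1L],
               n_sets = length(v), mean_cpue = mean(v),
               ci_lower = mean(v) - 1.96 * se,
               ci_upper = mean(v) + 1.96 * se)
  }))
  rownames(out) <- NULL
  out
}

#' Per-set CPUE values grouped by depth stratum
#' @inheritParams cpue_by_stratum
#' @return Named list of per-set CPUE vectors, one element per occupied
#'   stratum.
#' @export
cpue_groups <- function(sets, records,
                        strata_breaks = seq(0, 240, by = 20)) {
  valid <- sets[sets$valid, , drop = FALSE]
  nrec <- table(factor(records$set_id[records$set_id %in% valid$set_id],
                       levels = valid$set_id))
  cpue <- as.numeric(nrec) / valid$n_traps
  stratum <- cut(valid$depth_m, strata_breaks, right = FALSE)
  g <- split(cpue, stratum, drop = TRUE)
  g[vapply(g, length, 0L) > 0L]
}

#' Welch's heteroscedastic one-way F test
#'
#' Wrapper around [stats::oneway.test()] with `var.equal = FALSE`.
#'
#' @param groups list of numeric vectors, each of length >= 2 with
#'   positive variance.
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  n <- vapply(groups, length, 0L)
  if (any(n < 2L)) stop("every group needs n >= 2")
  if (any(vapply(groups, stats::var, 0) <= 0))
    stop("every group needs positive variance")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  ow <- stats::oneway.test(y ~ g, var.equal = FALSE)
  list(statistic = unname(ow$statistic), df1 = unname(ow$parameter[1L]),
       df2 = unname(ow$parameter[2L]), p_value = unname(ow$p.value))
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' All pairwise two-sample Welch t-tests; p-values multiplied by the
#' number of pairs (capped at 1). A compact letter display assigns
#' letters so that groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the letter display.
#' @return List with the adjusted p-value `matrix` and `letters`.
#' @export
pairwise_welch_bonferroni <- function(groups, alpha = 0.05) {
  ng <- length(groups)
  if (ng < 2L) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(ng))
  praw <- matrix(NA_real_, ng, ng, dimnames = list(nm, nm))
  for (i in seq_len(ng - 1L)) for (j in seq.int(i + 1L, ng)) {
    praw[i, j] <- praw[j, i] <-
      stats::t.test(groups[[i]], groups[[j]])$p.value
  }
  npair <- ng * (ng - 1L) / 2
  padj <- pmin(praw * npair, 1)
  # greedy compact letter display: merge groups not separable at alpha
  sig <- padj < alpha
  letters_out <- rep("", ng)
  lab <- 0L
  remaining <- seq_len(ng)
  while (length(remaining)) {
    lab <- lab + 1L
    seedg <- remaining[1L]
    members <- seedg
    for (gnd in setdiff(seq_len(ng), seedg)) {
      if (!any(sig[gnd, members], na.rm = TRUE)) members <- c(members, gnd)
    }
    letters_out[members] <- paste0(letters_out[members], letters[lab])
    remaining <- setdiff(remaining, members)
  }
  list(p_adjusted = padj, letters = stats::setNames(letters_out, nm))
}

#' Sex-ratio chi-square test against 1:1
#'
#' Two-cell Pearson statistic `(n_m - n_f)^2/(n_m + n_f)` on 1 degree of
#' freedom; the ratio is reported as males per female.
#'
#' @param n_m,n_f male and female counts; their sum must be positive.
#' @return List with `ratio` (m per 1 f), `chisq`, `p_value`.
#' @export
sex_ratio_chisq <- function(n_m, n_f) {
  if (n_m + n_f <= 0) stop("need at least one sexed individual")
  chisq <- (n_m - n_f)^2 / (n_m + n_f)
  list(ratio = n_m / n_f, chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Length-weight power-law regression
#'
#' Fits `WW = a CL^b` by ordinary least squares on the natural-log
#' scale. The intercept is back-transformed without bias correction.
#'
#' @param records catch-record data frame with `cl_mm`, `ww_g` and
#'   `sex` columns; rows without weight are dropped.
#' @param group `"pooled"`, `"m"` or `"f"`.
#' @return An object of class `lwr_fit` wrapping the underlying `lm`:
#'   `a`, `b`, `se_log_a`, `se_b`, `r_squared`, `n`, `group`.
#' @export
fit_lwr <- function(records, group = c("pooled", "m", "f")) {
  group <- match.arg(group)
  d <- records[!is.na(records$ww_g), , drop = FALSE]
  if (group != "pooled") d <- d[d$sex == group, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 weighted records in group ",
                         group)
  fit <- stats::lm(log(ww_g) ~ log(cl_mm), data = d)
  sm <- summary(fit)
  structure(list(group = group, n = nrow(d),
                 a = exp(unname(stats::coef(fit)[1L])),
                 b = unname(stats::coef(fit)[2L]),
                 se_log_a = sm$coefficients[1L, 2L],
                 se_b = sm$coefficients[2L, 2L],
                 r_squared = sm$r.squared, fit = fit),
            class = "lwr_fit")
}

#' @export
print.lwr_fit <- function(x, ...) {
  cat(sprintf(
    "Length-weight fit (%s, n = %d): WW = %.4g CL^%.3f, r^2 = %.3f\n",
    x$group, x$n, x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
coef.lwr_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.lwr_fit <- function(object, newdata, ...) {
  cl <- if (is.data.frame(newdata)) newdata$cl_mm else newdata
  object$a * cl^object$b
}

#' @export
residuals.lwr_fit <- function(object, ...) stats::residuals(object$fit)

#' Test for departure from isometric growth (b = 3)
#'
#' @param fit an `lwr_fit`.
#' @return List with `t` = `(b - 3)/SE(b)`, `df` = n - 2, two-sided
#'   `p_value`.
#' @export
allometry_test <- function(fit) {
  stopifnot(inherits(fit, "lwr_fit"))
  t <- (fit$b - 3) / fit$se_b
  df <- fit$n - 2L
  list(t = t, df = df,
       p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Compare length-weight relationships between sexes
#'
#' Full model `log(WW) ~ log(CL) * sex`: the interaction F-test checks
#' slope homogeneity; under a common slope, the sex main effect tests an
#' intercept difference and its 0.95 confidence interval gives the
#' between-sex weight offset on the log scale (female minus male).
#'
#' @param records catch-record data frame; both sexes need >= 3 weighted
#'   rows.
#' @return List with `slope_test` (F, df, p), `intercept_test`
#'   (F, df, p), and `offset_ci` (estimate, lower, upper; log scale).
#' @export
compare_lwr_sexes <- function(records) {
  d <- records[!is.na(records$ww_g) & records$sex %in% c("m", "f"), ,
               drop = FALSE]
  if (min(table(d$sex)) < 3L) stop("both sexes need >= 3 weighted records")
  d$sex <- factor(d$sex, levels = c("m", "f"))
  full <- stats::lm(log(ww_g) ~ log(cl_mm) * sex, data = d)
  add <- stats::lm(log(ww_g) ~ log(cl_mm) + sex, data = d)
  base <- stats::lm(log(ww_g) ~ log(cl_mm), data = d)
  a1 <- stats::anova(add, full)
  a2 <- stats::anova(base, add)
  ci <- stats::confint(add)["sexf", ]
  list(slope_test = list(F = a1$F[2L], df1 = a1$Df[2L],
                         df2 = a1$Res.Df[2L], p_value = a1$`Pr(>F)`[2L]),
       intercept_test = list(F = a2$F[2L], df1 = a2$Df[2L],
                             df2 = a2$Res.Df[2L],
                             p_value = a2$`Pr(>F)`[2L]),
       offset_ci = c(estimate = unname(stats::coef(add)["sexf"]),
                     lower = unname(ci[1L]), upper = unname(ci[2L])))
}
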