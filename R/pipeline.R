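#' Run the full length-based assessment pipeline
#'
#' Executes the complete analysis sequence on a dataset that is either
#' simulated (a `simulate:` block of [sim_config()] overrides) or read
#' from CSV files (an `inputs:` block with `records` and `sets` paths):
#' survey statistics (CPUE by depth stratum with Welch/Bonferroni
#' comparisons, sex ratio, length-weight regressions), length binning
#' and ELEFAN restructuring, genetic-algorithm growth estimation with
#' bootstrap confidence intervals, the length-converted catch curve,
#' the empirical natural-mortality suite, F and E, the selectivity
#' ogive, and Beverton-Holt per-recruit reference points with an Lc
#' sensitivity table. Each stage logs its parameters; any stage error
#' aborts with a stage-named message.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list. Recognized blocks: `seed`, `simulate`, `inputs`,
#'   `growth` (`window`, `n_boot`, `popsize`, `generations`,
#'   `bin_width`), `mortality` (`temp_c`), `per_recruit`
#'   (`lc_factors`), `out_dir`.
#' @param quiet suppress stage logging.
#' @return An object of class `assessment_report` (a nested list of
#'   stage outputs plus echoed settings). When `out_dir` is set, a JSON
#'   report and diagnostic plots are written there.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  gcfg <- config$growth %||% list()
  window <- as.integer(gcfg$window %||% 5L)
  n_boot <- as.integer(gcfg$n_boot %||% 50L)
  bin_width <- as.numeric(gcfg$bin_width %||% 2)
  ctrl <- ga_control(popsize = as.integer(gcfg$popsize %||% 50L),
                     generations = as.integer(gcfg$generations %||% 30L))
  temp_c <- as.numeric((config$mortality %||% list())$temp_c %||% 18)
  lc_factors <- as.numeric((config$per_recruit %||%
                              list())$lc_factors %||%
                             c(0.885, 1, 1.115))
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$inputs)) {
    dat <- stage("input", {
      say("input", "reading ", config$inputs$records)
      list(records = read_catch_records_csv(config$inputs$records),
           sets = read_trap_sets_csv(config$inputs$sets))
    })
  } else {
    dat <- stage("simulate", {
      cfg <- do.call(sim_config, config$simulate %||% list())
      say("simulate", "population of ", cfg$pop_n,
          " individuals, seed ", seed)
      pop <- simulate_population(cfg, seed = seed)
      sv <- simulate_trap_survey(pop, cfg, seed = seed + 1L)
      truth <- list(
        linf_mm = cfg$linf_mm, k_per_year = cfg$k_per_year,
        z_per_year = cfg$z_per_year, m_per_year = cfg$m_per_year,
        f_per_year = cfg$z_per_year - cfg$m_per_year,
        gear_l50_mm = cfg$gear_l50_mm)
      sv
    })
  }

  stats_out <- stage("stats", {
    say("stats", "CPUE strata, sex ratio, length-weight fits")
    strata <- cpue_by_stratum(dat$sets, dat$records)
    grp <- cpue_groups(dat$sets, dat$records)
    grp2 <- grp[vapply(grp, length, 0L) >= 2L &
                  vapply(grp, stats::var, 0) > 0]
    welch <- if (length(grp2) >= 2L) welch_anova(grp2) else NULL
    posthoc <- if (length(grp2) >= 2L)
      pairwise_welch_bonferroni(grp2) else NULL
    nm <- sum(dat$records$sex == "m")
    nf <- sum(dat$records$sex == "f")
    lwr_pooled <- fit_lwr(dat$records, "pooled")
    list(cpue_strata = strata, welch_cpue = welch,
         posthoc_letters = posthoc$letters,
         sex_ratio = sex_ratio_chisq(nm, nf),
         lwr = list(pooled = lwr_pooled,
                    m = fit_lwr(dat$records, "m"),
                    f = fit_lwr(dat$records, "f")),
         allometry = allometry_test(lwr_pooled),
         lwr_sex_comparison = compare_lwr_sexes(dat$records))
  })

  x <- stage("bin", {
    say("bin", "monthly length frequencies, ", bin_width, " mm classes")
    bin_lengths(dat$records, bin_width = bin_width)
  })

  growth <- stage("growth", {
    say("growth", "ELEFAN GA (pop ", ctrl$popsize, ", ",
        ctrl$generations, " generations), ", n_boot,
        " bootstrap resamples")
    elefan_ga_boot(x, control = ctrl, window = window,
                   n_boot = n_boot, seed = seed)
  })
  p <- growth$point$par

  mort <- stage("mortality", {
    say("mortality", "catch curve and empirical M suite (T = ",
        temp_c, " C)")
    cc <- catch_curve(x, p)
    ms <- empirical_m_suite(p$linf_mm, p$k_per_year,
                            lifespan(p$k_per_year), temp_c)
    list(cc = cc, msuite = ms, est = mortality_estimates(cc, ms))
  })

  sel <- stage("selectivity", {
    say("selectivity", "logit ogive from catch-curve ascending limb")
    og <- fit_selectivity(capture_probabilities(mort$cc))
    list(ogive = og, tc_years = age_at_first_capture(og, p))
  })

  pr <- stage("per_recruit", {
    say("per_recruit", "Beverton-Holt reference points, Lc = ",
        round(sel$ogive$l50_mm, 2), " mm")
    m <- mort$est$m_mean_per_year
    main <- per_recruit(p$linf_mm, p$k_per_year, m,
                        lc_mm = sel$ogive$l50_mm)
    sens <- lc_sensitivity(p$linf_mm, p$k_per_year, m,
                           lc_list = lc_factors * sel$ogive$l50_mm)
    list(main = main, sensitivity = sens)
  })

  report <- structure(list(
    settings = list(seed = seed, window = window, n_boot = n_boot,
                    bin_width = bin_width, popsize = ctrl$popsize,
                    generations = ctrl$generations, temp_c = temp_c,
                    lc_factors = lc_factors,
                    version = as.character(
                      utils::packageVersion("lfqassess"))),
    truth = truth,
    stats = stats_out,
    growth = growth,
    mortality = mort$est,
    m_table = mort$msuite,
    selectivity = sel,
    per_recruit = pr),
    class = "assessment_report")

  if (!is.null(config$out_dir)) {
    stage("report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jp <- file.path(config$out_dir, "report.json")
      say("report", "writing ", jp)
      write_report_json(report, jp)
      grDevices::png(file.path(config$out_dir, "plots.png"),
                     width = 1600, height = 1200, res = 150)
      graphics::par(mfrow = c(2, 2))
      plot(growth$point)
      plot(mort$cc)
      plot(sel$ogive)
      plot(pr$main)
      grDevices::dev.off()
    })
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assessment_report <- function(x, ...) {
  cat("Length-based assessment report\n")
  print(x$growth$point$par)
  print(x$mortality)
  print(x$selectivity$ogive)
  print(x$per_recruit$main)
  invisible(x)
}

#' Flatten an assessment report to plain JSON-ready values
#' @param report an `assessment_report`.
#' @return A nested list of plain vectors and tables.
#' @keywords internal
report_to_list <- function(report) {
  og <- report$selectivity$ogive
  pr <- report$per_recruit$main
  list(
    settings = report$settings,
    truth = report$truth,
    stats = list(
      cpue_strata = report$stats$cpue_strata,
      welch_cpue = report$stats$welch_cpue,
      posthoc_letters = as.list(report$stats$posthoc_letters),
      sex_ratio = report$stats$sex_ratio,
      lwr = lapply(report$stats$lwr, function(f)
        list(group = f$group, n = f$n, a = f$a, b = f$b,
             se_b = f$se_b, r_squared = f$r_squared)),
      allometry = report$stats$allometry,
      lwr_sex_comparison = report$stats$lwr_sex_comparison),
    growth = list(point = as.list(coef(report$growth$point)),
                  rn = report$growth$point$score$rn,
                  n_boot = report$growth$n_boot,
                  ci = as.data.frame(report$growth$ci)),
    mortality = list(z_per_year = report$mortality$z_per_year,
                     z_ci = report$mortality$z_ci,
                     m_mean_per_year = report$mortality$m_mean_per_year,
                     f_per_year = report$mortality$f_per_year,
                     e_rate = report$mortality$e_rate),
    m_table = data.frame(id = report$m_table$id,
                         m_per_year = report$m_table$m_per_year),
    selectivity = list(s1 = og$s1, s2 = og$s2, l25_mm = og$l25_mm,
                       l50_mm = og$l50_mm, l75_mm = og$l75_mm,
                       tc_years = report$selectivity$tc_years),
    per_recruit = list(e10 = pr$e10, e50 = pr$e50, emax = pr$emax,
                       f10 = pr$f10, fmax = pr$fmax,
                       lc_sensitivity = as.data.frame(
                         report$per_recruit$sensitivity)))
}

#' Write an assessment report as JSON
#' @param report an `assessment_report`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Validate the structure of an assessment report
#'
#' Checks that every headline quantity is present and numeric.
#'
#' @param report an `assessment_report` or the list from
#'   [report_to_list()].
#' @return `TRUE` invisibly; otherwise an error naming the first
#'   offending field.
#' @export
validate_report <- function(report) {
  x <- if (inherits(report, "assessment_report"))
    report_to_list(report) else report
  need <- list(
    c("growth", "point", "linf_mm"), c("growth", "point", "k_per_year"),
    c("growth", "point", "phi_prime"), c("growth", "rn"),
    c("mortality", "z_per_year"), c("mortality", "m_mean_per_year"),
    c("mortality", "f_per_year"), c("mortality", "e_rate"),
    c("selectivity", "l50_mm"), c("selectivity", "tc_years"),
    c("per_recruit", "e10"), c("per_recruit", "e50"),
    c("per_recruit", "emax"), c("per_recruit", "f10"),
    c("per_recruit", "fmax"),
    c("stats", "sex_ratio", "chisq"))
  for (path in need) {
    v <- x
    for (k in path) v <- v[[k]]
    if (is.null(v) || !is.numeric(v) || !all(is.finite(v)))
      stop("report field missing or non-numeric: ",
           paste(path, collapse = "$"))
  }
  if (nrow(x$m_table) != 13L)
    stop("m_table must have 13 rows")
  invisible(TRUE)
}
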