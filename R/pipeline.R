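#' Configuration for a full analysis run
#'
#' Validates and bundles everything [run_pipeline()] needs: either paths to
#' cohort / spectrum (and optionally registry) tables, or
#' [simulation_params] from which synthetic inputs are generated.
#'
#' @param cohort_table Path to a cohort AF table ([read_cohort_table()]).
#' @param spectrum_table Path to a spectrum table ([read_spectrum_table()]).
#' @param registry_table Optional path to a registry table
#'   ([read_registry_table()]); regions found there get their `q` from
#'   prevalence.
#' @param sim_params Optional [simulation_params]; when given, table paths
#'   are ignored and inputs are simulated.
#' @param q Optional fallback disease-allele frequency for regions without
#'   a registry record (e.g. a national estimate).
#' @param keep Categories kept apart in comparisons; the rest pool into
#'   `"other"`.
#' @param exclude_regions Regions left out of the across-region test
#'   (aggregate rows such as a national total).
#' @param ci_level Confidence level for binomial intervals, in (0, 1).
#' @param yates Continuity-correction policy for [chi_square_test()].
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed for any simulated input.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_table = NULL, spectrum_table = NULL,
                            registry_table = NULL, sim_params = NULL,
                            q = NULL,
                            keep = c("F508del", "CFTRdele2,3(21kb)"),
                            exclude_regions = character(),
                            ci_level = 0.95,
                            yates = c("auto", "on", "off"),
                            out_dir = tempfile("cftrmonitor_run_"),
                            seed = 1L) {
  yates <- match.arg(yates)
  if (!is.finite(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie in (0, 1)")
  }
  if (is.null(sim_params)) {
    for (p in c(cohort_table, spectrum_table, registry_table)) {
      if (!file.exists(p)) stop("input stage: file not found: '", p, "'")
    }
    if (is.null(cohort_table) || is.null(spectrum_table)) {
      stop("supply cohort_table and spectrum_table, or sim_params")
    }
  } else {
    stopifnot(inherits(sim_params, "simulation_params"))
  }
  structure(
    list(cohort_table = cohort_table, spectrum_table = spectrum_table,
         registry_table = registry_table, sim_params = sim_params,
         q = q, keep = keep, exclude_regions = exclude_regions,
         ci_level = ci_level, yates = yates, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Append a timestamped structured line to the run log.
log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(line)
}

# Run an expression for a named stage, routing messages and warnings to the
# log and prefixing errors with the stage name.
run_stage <- function(stage, log_path, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      log_line(log_path, stage, paste("ERROR:", conditionMessage(e)))
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    }),
    message = function(m) {
      log_line(log_path, stage, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    },
    warning = function(w) {
      log_line(log_path, stage, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
}

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) the inputs, then emits a report bundle under
#' `config$out_dir`:
#' \describe{
#'   \item{`cohort_afs.tsv`}{Wide cohort frequency matrix with a
#'     total-burden row (missing entries excluded and counted).}
#'   \item{`cohort_cis.tsv`}{Per-cohort, per-variant binomial confidence
#'     intervals from (reconstructed) allele counts.}
#'   \item{`spectra.tsv`}{Per-region spectrum with frequencies and counts.}
#'   \item{`indirect_af.tsv`}{Per-region indirect AF estimates (`Fd`, `q`,
#'     `fa`, `af`); regions take `q` from the registry when available,
#'     else from `config$q`.}
#'   \item{`comparisons.tsv`}{Across-region and pairwise chi-squared
#'     results.}
#'   \item{`run.log`}{Structured log of every reconstructed count, warning
#'     and skipped comparison.}
#' }
#' Rerunning with the same config and seed reproduces the TSVs
#' byte-identically; timestamps are confined to the log.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the data frames behind each report and
#'   the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)

  # -- ingest -----------------------------------------------------------
  if (!is.null(config$sim_params)) {
    inputs <- run_stage("ingest", log_path, {
      sp <- config$sim_params
      sp$seed <- config$seed
      sim <- simulate_registry(sp)
      cohort <- simulate_population(sp)
      log_line(log_path, "ingest",
               sprintf("simulated registry (%d cases) and cohort (n=%d), seed=%d",
                       sim$record$n_cases, sp$n_population, sp$seed))
      list(cohorts = stats::setNames(list(cohort), cohort$cohort_id),
           spectra = stats::setNames(list(sim$spectrum),
                                     sim$spectrum$region_id),
           registry = stats::setNames(list(sim$record),
                                      sim$record$region_id))
    })
  } else {
    inputs <- run_stage("ingest", log_path, {
      list(cohorts = read_cohort_table(config$cohort_table),
           spectra = read_spectrum_table(config$spectrum_table),
           registry = if (is.null(config$registry_table)) list()
                      else read_registry_table(config$registry_table))
    })
  }
  cohorts <- inputs$cohorts
  spectra <- inputs$spectra
  registry <- inputs$registry

  # -- estimate: cohort matrix, burdens, CIs ----------------------------
  est <- run_stage("estimate", log_path, {
    wide <- format_cohort_table(cohorts)
    burden <- lapply(cohorts, total_burden)
    total_row <- wide[1, ]
    total_row$legacy_name <- "Total frequency"
    total_row$rsid <- "-"
    for (co in cohorts) {
      b <- burden[[co$cohort_id]]
      total_row[[sprintf("%s (n=%d)", co$cohort_id, co$n_individuals)]] <-
        b$total
      log_line(log_path, "estimate",
               sprintf("total burden %s = %.4f (%d missing excluded)",
                       co$cohort_id, b$total, b$n_missing))
    }
    cis <- do.call(rbind, lapply(cohorts, function(co) {
      e <- co$entries
      rows <- lapply(seq_len(nrow(e)), function(i) {
        if (is.na(e$af[i]) && is.na(e$allele_count[i])) return(NULL)
        ac <- e$allele_count[i]
        if (is.na(ac)) {
          ac <- allele_count_from_af(e$af[i], co$allele_number)
          log_line(log_path, "estimate",
                   sprintf("reconstructed AC=%d from af=%g, AN=%d for '%s' in cohort '%s'",
                           ac, e$af[i], co$allele_number, e$variant[i],
                           co$cohort_id))
        }
        ci <- binomial_ci(ac, co$allele_number, level = config$ci_level)
        data.frame(cohort = co$cohort_id, variant = e$variant[i],
                   allele_count = ac, allele_number = co$allele_number,
                   af = ci$estimate, ci_low = ci$low, ci_high = ci$high,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
    rownames(cis) <- NULL
    list(wide = rbind(wide, total_row), cis = cis)
  })

  # -- estimate: per-region spectra and indirect AFs --------------------
  spec_tab <- run_stage("estimate", log_path, {
    do.call(rbind, lapply(spectra, function(sp) {
      fa <- spectrum_proportions(sp)
      data.frame(region = sp$region_id, n_patients = sp$n_patients,
                 category = names(fa), AF = as.numeric(fa),
                 AC = as.integer(sp$counts[names(fa)]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })

  indirect <- run_stage("estimate", log_path, {
    rows <- lapply(spectra, function(sp) {
      if (sp$region_id %in% names(registry)) {
        estimate_indirect_af(sp, record = registry[[sp$region_id]])
      } else if (!is.null(config$q)) {
        log_line(log_path, "estimate",
                 sprintf("region '%s' has no registry record; using supplied q=%g",
                         sp$region_id, config$q))
        estimate_indirect_af(sp, q = config$q)
      } else {
        log_line(log_path, "estimate",
                 sprintf("region '%s' skipped: no registry record and no fallback q",
                         sp$region_id))
        NULL
      }
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) rownames(out) <- NULL
    out
  })

  # -- compare ----------------------------------------------------------
  comparisons <- run_stage("compare", log_path, {
    rows <- list()
    test_spectra <- spectra[!names(spectra) %in% config$exclude_regions]
    if (length(test_spectra) >= 2L) {
      res <- tryCatch(
        chi_square_test(build_contingency_table(test_spectra, config$keep),
                        yates = config$yates),
        error = function(e) {
          log_line(log_path, "compare",
                   paste("across-region test skipped:", conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          comparison_id = "across_regions",
          rows = length(test_spectra), cols = length(config$keep) + 1L,
          statistic = res$statistic, df = res$df, p_value = res$p_value,
          yates = res$yates_applied, min_expected = res$min_expected,
          stringsAsFactors = FALSE)
      }
    } else {
      log_line(log_path, "compare",
               "across-region test skipped: fewer than 2 regions")
    }
    do.call(rbind, rows)
  })

  # -- report -----------------------------------------------------------
  paths <- run_stage("report", log_path, {
    p <- list(
      cohort_afs = file.path(config$out_dir, "cohort_afs.tsv"),
      cohort_cis = file.path(config$out_dir, "cohort_cis.tsv"),
      spectra = file.path(config$out_dir, "spectra.tsv"),
      indirect_af = file.path(config$out_dir, "indirect_af.tsv"),
      comparisons = file.path(config$out_dir, "comparisons.tsv"))
    write_report_table(est$wide, p$cohort_afs)
    write_report_table(est$cis, p$cohort_cis)
    write_report_table(spec_tab, p$spectra)
    if (!is.null(indirect)) write_report_table(indirect, p$indirect_af)
    if (!is.null(comparisons)) {
      comparisons$p_value_rendered <- format_p_value(comparisons$p_value)
      write_report_table(comparisons, p$comparisons)
    }
    p
  })

  invisible(list(cohorts = cohorts, spectra = spectra, registry = registry,
                 cohort_matrix = est$wide, cohort_cis = est$cis,
                 spectrum_table = spec_tab, indirect = indirect,
                 comparisons = comparisons, paths = paths,
                 log = log_path))
}

#' Replay the published reference tables and check headline numbers
#'
#' Runs the packaged reference fixtures (the 12-variant cohort frequency
#' table and the per-region patient spectrum table) through the pipeline
#' and recomputes the headline quantities of the reference analysis,
#' printing a pass/fail table: the four total-burden sums, the
#' across-district chi-squared (df 14), the North Caucasus "other"
#' frequency, the exact binomial CI for F508del in the healthy
#' population cohort, the indirect CFTRdele2,3(21kb) frequency, and the
#' St. Petersburg vs Yugra 2x2 Yates statistic.
#'
#' The disease-allele frequency used for indirect estimates is derived
#' from the published national calculated F508del frequency divided by the
#' registry F508del spectrum share, since the underlying per-region case
#' and birth counts are not part of the published tables.
#'
#' @param targets_only If `TRUE`, skip writing the report bundle and only
#'   run the checks.
#' @param out_dir Output directory for the report bundle.
#' @param quiet Suppress the printed pass/fail table.
#' @param t1_path,t2_path Paths to the cohort and spectrum tables; default
#'   to the packaged reference fixtures.
#' @return Invisibly, a list with `checks` (data.frame: check, expected,
#'   actual, tolerance, pass) and, unless `targets_only`, the
#'   [run_pipeline()] bundle.
#' @export
reproduce_reference <- function(targets_only = FALSE,
                                out_dir = tempfile("cftrmonitor_ref_"),
                                quiet = FALSE,
                                t1_path = system.file("extdata", "tables_t1.tsv",
                                                      package = "cftrmonitor"),
                                t2_path = system.file("extdata", "tables_t2.tsv",
                                                      package = "cftrmonitor")) {
  cohorts <- read_cohort_table(t1_path)
  spectra <- suppressWarnings(read_spectrum_table(t2_path))

  national <- spectra[["Russian Federation"]]
  fa_nat <- spectrum_proportions(national)
  calc_f508 <- with(cohorts$Calculated$entries, af[variant == "F508del"])
  q_nat <- calc_f508 / fa_nat[["F508del"]]

  checks <- list()
  add <- function(name, expected, actual, tol) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, expected = expected, actual = actual, tolerance = tol,
      pass = abs(actual - expected) <= tol, stringsAsFactors = FALSE)
  }

  for (co in c("RUSeq", "Infertile", "Petrova", "Calculated")) {
    exp_val <- c(RUSeq = 0.0117, Infertile = 0.0240, Petrova = 0.0072,
                 Calculated = 0.0081)[[co]]
    add(paste0("total_burden_", co), exp_val,
        round(total_burden(cohorts[[co]])$total, 4), 0)
  }

  districts <- spectra[grepl("Federal [Dd]istrict", names(spectra))]
  dist_res <- chi_square_test(
    build_contingency_table(districts, c("F508del", "CFTRdele2,3(21kb)")))
  add("district_chi_squared", 197.55, dist_res$statistic, 197.55 * 0.01)
  add("district_df", 14, dist_res$df, 0)

  nc <- spectra[["North Caucasian Federal District"]]
  add("north_caucasus_other_af", 0.7706,
      round(af_from_counts(nc$counts[["other"]], sum(nc$counts)), 4), 0)

  ruseq <- cohorts$RUSeq
  ac <- allele_count_from_af(
    with(ruseq$entries, af[variant == "F508del"]), ruseq$allele_number)
  ci <- binomial_ci(ac, ruseq$allele_number, level = 0.95)
  add("f508del_ci_low", 0.0053, round(ci$low, 4), 0)
  add("f508del_ci_high", 0.0117, round(ci$high, 4), 0)

  add("indirect_cftrdele_af", 0.0006,
      round(indirect_af(q_nat, fa_nat[["CFTRdele2,3(21kb)"]]), 4), 0)

  pair <- suppressWarnings(chi_square_test(build_contingency_table(
    spectra[c("St.Petersburg", "Yugra region")], "F508del")))
  add("spb_vs_yugra_chi_squared", 15.238, pair$statistic, 15.238 * 0.002)

  checks <- do.call(rbind, checks)
  if (!quiet) {
    print(checks, digits = 6)
  }

  bundle <- NULL
  if (!targets_only) {
    cfg <- pipeline_config(cohort_table = t1_path, spectrum_table = t2_path,
                           q = as.numeric(q_nat),
                           exclude_regions = c("Russian Federation",
                                               "St.Petersburg",
                                               "Yugra region"),
                           out_dir = out_dir)
    bundle <- run_pipeline(cfg)
  }
  invisible(list(checks = checks, bundle = bundle, q_national = q_nat))
}
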