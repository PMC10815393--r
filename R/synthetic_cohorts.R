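#' Parameters for synthetic cohort and registry generation
#'
#' Bundles the ground truth for the generative model the estimation chain
#' assumes: a Hardy-Weinberg diploid population in which each chromosome
#' independently carries a disease allele with probability `q_true`, and
#' each disease allele is one of the named variants with probabilities
#' `fa_true`. Defaults emulate the national study conditions: the
#' registry-implied disease-allele frequency (about 0.0105), the national
#' patient spectrum over F508del / CFTRdele2,3(21kb) / other, an annual
#' birth cohort sized so that 18 years of births at prevalence `q^2` yield
#' about 3.3 thousand registered cases, a healthy genotyped cohort of 1671,
#' and 3292 genotyped patients.
#'
#' @param q_true True disease-allele frequency in \[0, 1\].
#' @param fa_true Named proportions of variants among disease alleles;
#'   must sum to 1 (within 1e-12).
#' @param n_population Diploid individuals in the healthy-cohort draw.
#' @param births_per_year Annual births feeding the registry.
#' @param horizon_years Registry ascertainment horizon (years).
#' @param n_patients_genotyped Patients whose alleles form the spectrum.
#' @param seed Master seed; replicate streams are split by counter.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(q_true = 0.0105,
                              fa_true = c("F508del" = 3400 / 6596,
                                          "CFTRdele2,3(21kb)" = 403 / 6596,
                                          "other" = 2793 / 6596),
                              n_population = 1671L,
                              births_per_year = 1.67e6,
                              horizon_years = 18L,
                              n_patients_genotyped = 3292L,
                              seed = 1L) {
  if (!is.finite(q_true) || q_true < 0 || q_true > 1) {
    stop("q_true must lie in [0, 1]")
  }
  if (is.null(names(fa_true)) || any(!nzchar(names(fa_true)))) {
    stop("fa_true must be named")
  }
  if (any(fa_true < 0) || abs(sum(fa_true) - 1) > 1e-12) {
    stop("fa_true must be non-negative and sum to 1")
  }
  sizes <- c(n_population = n_population, births_per_year = births_per_year,
             horizon_years = horizon_years,
             n_patients_genotyped = n_patients_genotyped)
  if (any(sizes < 1)) stop("all sizes must be >= 1")
  structure(
    list(q_true = q_true, fa_true = fa_true,
         n_population = as.integer(n_population),
         births_per_year = births_per_year,
         horizon_years = as.integer(horizon_years),
         n_patients_genotyped = as.integer(n_patients_genotyped),
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' Simulate a directly genotyped healthy cohort
#'
#' Draws `2 * n_population` chromosomes; each carries a disease allele with
#' probability `q_true` and, when it does, one of the named variants with
#' probabilities `fa_true`. Returns the observed per-variant allele counts
#' and frequencies as a [cohort_af] — the synthetic analogue of a
#' population sequencing database.
#'
#' @param params A [simulation_params].
#' @param cohort_id Label for the simulated cohort.
#' @return A [cohort_af] with one entry per variant category.
#' @export
simulate_population <- function(params, cohort_id = "synthetic_population") {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  an <- 2L * params$n_population
  n_disease <- stats::rbinom(1L, an, params$q_true)
  counts <- as.integer(stats::rmultinom(1L, n_disease, params$fa_true))
  cohort_af(
    cohort_id, params$n_population,
    data.frame(variant = names(params$fa_true),
               af = counts / an, allele_count = counts,
               stringsAsFactors = FALSE)
  )
}

#' Simulate a regional CF registry and patient spectrum
#'
#' Under Hardy-Weinberg equilibrium the number of affected children born
#' over the horizon is binomial with size `births_per_year * horizon_years`
#' and probability `q_true^2`; the allele spectrum of the genotyped
#' patients is multinomial over `2 * n_patients_genotyped` chromosomes with
#' probabilities `fa_true` (counts sum exactly to the chromosome number).
#' Ascertainment is complete: every affected child is registered.
#'
#' @param params A [simulation_params].
#' @param region_id Label for the simulated region.
#' @return List with `record` (a [region_registry_record]) and `spectrum`
#'   (a [patient_spectrum], validated strictly).
#' @export
simulate_registry <- function(params, region_id = "synthetic_region") {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  total_births <- params$births_per_year * params$horizon_years
  n_cases <- stats::rbinom(1L, round(total_births), params$q_true^2)
  record <- region_registry_record(region_id, n_cases,
                                   params$births_per_year,
                                   params$horizon_years)
  alleles <- 2L * params$n_patients_genotyped
  counts <- as.integer(stats::rmultinom(1L, alleles, params$fa_true))
  names(counts) <- names(params$fa_true)
  spectrum <- patient_spectrum(region_id, params$n_patients_genotyped,
                               counts, strict = TRUE)
  list(record = record, spectrum = spectrum)
}

#' Parameter-recovery experiment for the indirect estimator
#'
#' Repeatedly simulates a registry, runs the full indirect chain
#' (prevalence, Hardy-Weinberg `q`, `q * fa`) and summarises how well the
#' indirect allele frequencies recover the ground truth
#' `q_true * fa_true`. Replicate `i` uses seed `seed + i - 1`, so the whole
#' experiment is reproducible from the master seed.
#'
#' @param params A [simulation_params].
#' @param n_replicates Number of independent registry replicates (>= 1).
#' @return List with `summary`, a data.frame of per-variant `truth`,
#'   `mean_af`, `bias`, `rmse` (and `sd`, `NA` for a single replicate),
#'   and `estimates`, the replicate-by-variant matrix of indirect AFs.
#' @export
recovery_experiment <- function(params, n_replicates) {
  stopifnot(inherits(params, "simulation_params"), n_replicates >= 1L)
  vars <- names(params$fa_true)
  est <- matrix(NA_real_, nrow = n_replicates, ncol = length(vars),
                dimnames = list(NULL, vars))
  for (i in seq_len(n_replicates)) {
    rep_params <- params
    rep_params$seed <- params$seed + i - 1L
    sim <- simulate_registry(rep_params)
    q_hat <- allele_freq_from_prevalence(cf_prevalence(sim$record))
    fa_hat <- spectrum_proportions(sim$spectrum)
    est[i, ] <- indirect_af(q_hat, as.numeric(fa_hat[vars]))
  }
  truth <- params$q_true * as.numeric(params$fa_true)
  mean_af <- colMeans(est)
  summary <- data.frame(
    variant = vars, truth = truth, mean_af = mean_af,
    bias = mean_af - truth,
    rmse = sqrt(colMeans((est - rep(truth, each = n_replicates))^2)),
    sd = if (n_replicates > 1L) apply(est, 2L, stats::sd) else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(summary = summary, estimates = est)
}
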