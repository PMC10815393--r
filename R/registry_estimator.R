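#' Birth prevalence of CF from a registry record
#'
#' Computes the disease prevalence at birth, `Fd = n / (N * horizon)`, where
#' `n` is the number of registered children with CF under the ascertainment
#' age and `N` the region's mean annual birth count: the registered cases
#' divided by all births over the ascertainment horizon.
#'
#' @param record A [region_registry_record].
#' @return Prevalence `Fd` in \[0, 1\].
#' @examples
#' r <- region_registry_record("demo", 110, 55000)
#' cf_prevalence(r)  # 1.1111e-04
#' @export
cf_prevalence <- function(record) {
  stopifnot(inherits(record, "region_registry_record"))
  fd <- record$n_cases / (record$mean_annual_births * record$horizon_years)
  stopifnot(fd >= 0, fd <= 1)
  fd
}

#' Disease-allele frequency under Hardy-Weinberg equilibrium
#'
#' For an autosomal recessive disease under random mating, birth prevalence
#' equals `q^2`, so the frequency of the disease allele (the aggregate of
#' all pathogenic alleles at the locus) is `q = sqrt(Fd)`.
#'
#' @param Fd Disease prevalence at birth, in \[0, 1\].
#' @return Disease-allele frequency `q` in \[0, 1\].
#' @examples
#' allele_freq_from_prevalence(2.5e-5)  # 0.005
#' @export
allele_freq_from_prevalence <- function(Fd) {
  if (any(!is.finite(Fd) | Fd < 0 | Fd > 1)) {
    stop("prevalence must lie in [0, 1]")
  }
  sqrt(Fd)
}

#' Indirect population allele frequency of one variant
#'
#' The population frequency of a specific pathogenic variant is estimated
#' without genotyping the general population, as the disease-allele
#' frequency times the variant's share among the alleles of affected
#' patients: `af = q * fa`. Summed over a partition of patient alleles the
#' indirect AFs recover `q`.
#'
#' @param q Disease-allele frequency, in \[0, 1\].
#' @param fa Proportion of the variant among patient disease alleles.
#' @return Indirect allele frequency `q * fa`.
#' @examples
#' indirect_af(0.010475, 0.5155)  # ~0.0054
#' @export
indirect_af <- function(q, fa) {
  if (any(!is.finite(q) | q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (any(!is.finite(fa) | fa < 0 | fa > 1)) stop("fa must lie in [0, 1]")
  q * fa
}

#' Allele frequency from allele counts
#'
#' @param allele_count Copies of the allele observed.
#' @param allele_number Chromosomes assayed (`2n` for `n` diploid subjects).
#' @return `allele_count / allele_number`.
#' @examples
#' af_from_counts(262, 340)  # 0.7706 at 4 decimals
#' @export
af_from_counts <- function(allele_count, allele_number) {
  if (any(allele_number <= 0)) stop("allele_number must be > 0")
  if (any(allele_count < 0 | allele_count > allele_number)) {
    stop("allele_count must lie in [0, allele_number]")
  }
  allele_count / allele_number
}

#' Reconstruct an allele count from a rounded frequency
#'
#' Published tables print frequencies at 3-4 decimals; the underlying count
#' is recovered as the nearest integer to `af * allele_number`. The
#' reconstruction is lossy at the printing precision, which is why
#' statistics recomputed from reconstructed counts can differ slightly from
#' published ones.
#'
#' @param af Rounded allele frequency.
#' @param allele_number Chromosomes assayed.
#' @return Integer allele count.
#' @export
allele_count_from_af <- function(af, allele_number) {
  if (any(!is.finite(af) | af < 0 | af > 1)) stop("af must lie in [0, 1]")
  as.integer(round(af * allele_number))
}

#' Exact binomial confidence interval for an allele frequency
#'
#' Two-sided confidence interval for a proportion from allele counts. The
#' default is the Clopper-Pearson exact interval (inversion of the binomial
#' tail probabilities, via [stats::binom.test()]); the Wilson score
#' interval is available as an alternative.
#'
#' @param allele_count Copies of the allele observed.
#' @param allele_number Chromosomes assayed.
#' @param level Coverage probability, in (0, 1); default 0.95.
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return An object of class `binomial_ci`: a list with `allele_count`,
#'   `allele_number`, `estimate`, `level`, `low`, `high`, `method`.
#' @examples
#' binomial_ci(27, 3342)  # (0.0053, 0.0117) at 4 decimals
#' @export
binomial_ci <- function(allele_count, allele_number, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  if (allele_number <= 0 || allele_count < 0 || allele_count > allele_number) {
    stop("require 0 <= allele_count <= allele_number and allele_number > 0")
  }
  p <- allele_count / allele_number
  if (method == "clopper-pearson") {
    ci <- stats::binom.test(allele_count, allele_number,
                            conf.level = level)$conf.int
    low <- ci[1]; high <- ci[2]
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    n <- allele_number
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    low <- max(0, centre - half); high <- min(1, centre + half)
  }
  structure(
    list(allele_count = as.integer(allele_count),
         allele_number = as.integer(allele_number),
         estimate = p, level = level, low = low, high = high,
         method = method),
    class = "binomial_ci"
  )
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("<binomial_ci> %d/%d = %.4f, %g%% CI (%.4f, %.4f) [%s]\n",
              x$allele_count, x$allele_number, x$estimate, 100 * x$level,
              x$low, x$high, x$method))
  invisible(x)
}

#' Variant proportions among patient alleles
#'
#' Converts a patient allele spectrum into per-category proportions
#' `fa = count / sum(counts)`, the variant shares among disease alleles that
#' the indirect estimator multiplies by `q`.
#'
#' @param spectrum A [patient_spectrum].
#' @return Named numeric vector of proportions summing to 1.
#' @examples
#' sp <- patient_spectrum("Yugra", 54,
#'                        c(F508del = 43, "CFTRdele2,3(21kb)" = 5, other = 60))
#' spectrum_proportions(sp)
#' @export
spectrum_proportions <- function(spectrum) {
  stopifnot(inherits(spectrum, "patient_spectrum"))
  total <- sum(spectrum$counts)
  if (total <= 0) stop("spectrum has no alleles")
  spectrum$counts / total
}

#' Per-region indirect allele-frequency estimates
#'
#' Runs the full indirect chain for one region: registry prevalence
#' (`Fd`), Hardy-Weinberg disease-allele frequency (`q = sqrt(Fd)`), and
#' per-category indirect AFs (`q * fa`) from the region's patient allele
#' spectrum. Either a registry record or a precomputed `q` (e.g. a national
#' estimate) may supply the disease-allele frequency.
#'
#' @param spectrum A [patient_spectrum] for the region.
#' @param record A [region_registry_record] for the same region, or `NULL`
#'   when `q` is given directly.
#' @param q Disease-allele frequency to use when no record is available.
#' @return A data.frame with columns `region`, `variant`, `Fd`, `q`, `fa`,
#'   `af` (one row per spectrum category).
#' @export
estimate_indirect_af <- function(spectrum, record = NULL, q = NULL) {
  stopifnot(inherits(spectrum, "patient_spectrum"))
  if (is.null(record) == is.null(q)) {
    stop("supply exactly one of 'record' or 'q'")
  }
  fd <- NA_real_
  if (!is.null(record)) {
    fd <- cf_prevalence(record)
    q <- allele_freq_from_prevalence(fd)
  }
  fa <- spectrum_proportions(spectrum)
  data.frame(
    region = spectrum$region_id,
    variant = names(fa),
    Fd = fd, q = q, fa = as.numeric(fa),
    af = indirect_af(q, as.numeric(fa)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
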