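#' Collapse a patient spectrum to a kept set of categories
#'
#' Replicates the grouping used for regional comparisons: every category not
#' in `keep` is pooled into the reserved remainder category `"other"`. The
#' total allele count is conserved. Categories in `keep` that are absent
#' from the spectrum contribute a zero count.
#'
#' @param spectrum A [patient_spectrum].
#' @param keep Character vector of categories to keep apart; may not
#'   contain `"other"`.
#' @return A [patient_spectrum] whose categories are `keep` plus `"other"`.
#' @examples
#' sp <- patient_spectrum("Yugra", 54,
#'                        c(F508del = 43, "CFTRdele2,3(21kb)" = 5, other = 60))
#' collapse_spectrum(sp, "F508del")$counts  # F508del 43, other 65
#' @export
collapse_spectrum <- function(spectrum, keep) {
  stopifnot(inherits(spectrum, "patient_spectrum"), length(keep) >= 1L)
  if (.OTHER %in% keep) stop("'other' is reserved and may not be kept")
  kept <- vapply(keep, function(k) {
    if (k %in% names(spectrum$counts)) spectrum$counts[[k]] else 0L
  }, integer(1))
  rest <- sum(spectrum$counts[!names(spectrum$counts) %in% keep])
  counts <- c(kept, stats::setNames(rest, .OTHER))
  patient_spectrum(spectrum$region_id, spectrum$n_patients, counts,
                   tol = abs(sum(counts) - 2L * spectrum$n_patients))
}

#' Build a region-by-category contingency table
#'
#' Stacks collapsed spectra into an allele-count matrix with one row per
#' region and columns `keep` plus `"other"`, ready for [chi_square_test()].
#'
#' @param spectra List of [patient_spectrum] objects (at least 2, distinct
#'   regions).
#' @param keep Categories to keep apart; the rest pool into `"other"`.
#' @return An integer matrix of class `contingency_table` with region row
#'   names and category column names.
#' @export
build_contingency_table <- function(spectra, keep) {
  if (length(spectra) < 2L) stop("need at least 2 spectra")
  ids <- vapply(spectra, `[[`, "", "region_id")
  if (anyDuplicated(ids)) {
    stop("duplicate region_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  rows <- lapply(spectra, function(sp) collapse_spectrum(sp, keep)$counts)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  if (any(rowSums(m) <= 0)) stop("a region has no alleles")
  structure(m, class = c("contingency_table", class(m)))
}

#' Pearson chi-squared test of homogeneity on a contingency table
#'
#' Computes the Pearson chi-squared statistic with expected counts from the
#' row and column margins, `sum((|O - E| - c)^2 / E)`, and a p-value from
#' the chi-squared distribution with `(r-1)(c-1)` degrees of freedom. The
#' Yates continuity correction (`c = 1/2`, capped so a corrected deviation
#' cannot change sign) follows the convention of mainstream statistical
#' software: under `yates = "auto"` it is applied iff the table is 2x2;
#' `"on"` forces it for any table and `"off"` disables it. The smallest
#' expected count is reported and a warning raised when it falls below 5,
#' where the chi-squared approximation becomes unreliable.
#'
#' @param table A `contingency_table` (or plain count matrix, at least 2x2).
#' @param yates Continuity-correction policy: `"auto"`, `"on"`, or `"off"`.
#' @return An object of class `contingency_result`: list with `statistic`,
#'   `df`, `p_value`, `yates_applied`, `expected`, `min_expected`,
#'   `observed`.
#' @examples
#' m <- rbind(SPb = c(2846, 1977), Yugra = c(43, 65))
#' chi_square_test(m)  # Yates-corrected 2x2
#' @export
chi_square_test <- function(table, yates = c("auto", "on", "off")) {
  yates <- match.arg(yates)
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) stop("table must be at least 2x2")
  if (any(!is.finite(m)) || any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) <= 0)) stop("degenerate table: a zero row margin")
  if (any(colSums(m) <= 0)) stop("degenerate table: a zero column margin")
  n <- sum(m)
  expected <- outer(unname(rowSums(m)), unname(colSums(m))) / n
  dimnames(expected) <- dimnames(m)
  apply_yates <- switch(yates,
                        auto = nrow(m) == 2L && ncol(m) == 2L,
                        on = TRUE, off = FALSE)
  dev <- abs(m - expected)
  if (apply_yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  min_exp <- min(expected)
  if (min_exp < 5) {
    warning("smallest expected count is ", signif(min_exp, 3),
            " (< 5); the chi-squared approximation may be unreliable")
  }
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         yates_applied = apply_yates, expected = expected,
         min_expected = min_exp, observed = m),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> chi-squared = %.4g, df = %d, p = %s%s\n",
              x$statistic, x$df, format_p_value(x$p_value),
              if (x$yates_applied) " (Yates)" else ""))
  invisible(x)
}

#' Render a p-value for reports
#'
#' P-values below the double-precision floor reported by common statistical
#' software are rendered as `"< 2.2e-16"`; larger ones in scientific
#' notation.
#'
#' @param p P-value(s).
#' @return Character rendering.
#' @export
format_p_value <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", format(signif(p, 4), scientific = TRUE))
}

#' Total frequency burden of a variant panel in one cohort
#'
#' Sums the non-missing allele frequencies of the listed variants — the
#' "total frequency" row of a cohort table. Missing entries are excluded,
#' never zero-filled, and their number is reported.
#'
#' @param cohort A [cohort_af].
#' @param variants Variants to sum; default all in the cohort.
#' @return List with `total` (summed AF) and `n_missing`.
#' @examples
#' t1 <- read_cohort_table(system.file("extdata", "tables_t1.tsv",
#'                                     package = "cftrmonitor"))
#' total_burden(t1$RUSeq)  # total 0.0117, 2 missing
#' @export
total_burden <- function(cohort, variants = NULL) {
  stopifnot(inherits(cohort, "cohort_af"))
  e <- cohort$entries
  if (is.null(variants)) variants <- e$variant
  miss_var <- setdiff(variants, e$variant)
  if (length(miss_var) > 0) {
    stop("variants not in cohort '", cohort$cohort_id, "': ",
         paste(miss_var, collapse = ", "))
  }
  af <- e$af[match(variants, e$variant)]
  list(total = sum(af, na.rm = TRUE), n_missing = sum(is.na(af)))
}

#' Compare one variant's frequency between two cohorts
#'
#' 2x2 chi-squared test of carrier-allele versus other-allele counts
#' between two cohorts. Allele counts are taken from the cohort entries
#' when present and otherwise reconstructed from the rounded published
#' frequency as `round(af * allele_number)`; each reconstruction is
#' reported through `message()` so small discrepancies with published
#' statistics are traceable. A missing frequency is an error — it is never
#' treated as zero.
#'
#' @param a,b [cohort_af] objects.
#' @param variant Variant to compare.
#' @param yates Continuity-correction policy, as in [chi_square_test()].
#' @return A `contingency_result` for the 2x2 table.
#' @export
compare_cohort_afs <- function(a, b, variant, yates = c("auto", "on", "off")) {
  yates <- match.arg(yates)
  counts <- lapply(list(a, b), function(co) {
    e <- co$entries
    i <- match(variant, e$variant)
    if (is.na(i)) stop("variant '", variant, "' absent from cohort '",
                       co$cohort_id, "'")
    if (is.na(e$af[i]) && is.na(e$allele_count[i])) {
      stop("variant '", variant, "' is missing (n.a.) in cohort '",
           co$cohort_id, "'; missing data cannot be compared")
    }
    ac <- e$allele_count[i]
    if (is.na(ac)) {
      ac <- allele_count_from_af(e$af[i], co$allele_number)
      message("reconstructed AC=", ac, " from af=", e$af[i],
              ", AN=", co$allele_number, " for '", variant,
              "' in cohort '", co$cohort_id, "'")
    }
    c(ac, co$allele_number - ac)
  })
  m <- do.call(rbind, counts)
  dimnames(m) <- list(c(a$cohort_id, b$cohort_id),
                      c(variant, "other alleles"))
  chi_square_test(m, yates = yates)
}
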