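#' @keywords internal
"_PACKAGE"

# Tokens the cohort-table reader treats as a missing allele frequency.
.MISSING_TOKENS <- c("n.a.", "NA", "")

# "other" is reserved for the collapsed remainder category and may not name
# a variant.
.OTHER <- "other"

#' Variant catalog of common pathogenic CFTR alleles
#'
#' Reads a tab-separated variant catalog mapping each variant's legacy name
#' (the label used in clinical genetics, e.g. `"F508del"`) to its cDNA- and
#' protein-level HGVS descriptions and, where assigned, a dbSNP rsID. The
#' packaged catalog covers the 12 variants most frequently seen in Russian
#' CF and infertility cohorts.
#'
#' @param path Path to a catalog TSV with columns `legacy_name`, `hgvs_c`,
#'   `hgvs_p`, `rsid`; `"-"` marks an absent `hgvs_p` or `rsid`. Defaults to
#'   the packaged catalog.
#' @return A data.frame with columns `legacy_name`, `hgvs_c`, `hgvs_p`,
#'   `rsid` (`NA` where absent).
#' @examples
#' cat <- read_variant_catalog()
#' cat[cat$legacy_name == "F508del", ]
#' @export
read_variant_catalog <- function(path = system.file("extdata", "cftr_variants.tsv",
                                                    package = "cftrmonitor")) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("legacy_name", "hgvs_c", "hgvs_p", "rsid")
  if (!all(need %in% names(tab))) {
    stop("variant catalog must have columns: ", paste(need, collapse = ", "))
  }
  tab$hgvs_p[tab$hgvs_p == "-"] <- NA_character_
  tab$rsid[tab$rsid == "-"] <- NA_character_
  validate_variant_catalog(tab)
  tab
}

validate_variant_catalog <- function(catalog) {
  if (anyDuplicated(catalog$legacy_name)) {
    stop("duplicate legacy_name in variant catalog: ",
         paste(unique(catalog$legacy_name[duplicated(catalog$legacy_name)]),
               collapse = ", "))
  }
  if (any(!nzchar(catalog$hgvs_c))) stop("hgvs_c must be non-empty")
  if (.OTHER %in% catalog$legacy_name) {
    stop("'other' is a reserved category label and may not name a variant")
  }
  bad_rs <- !is.na(catalog$rsid) & !grepl("^rs[0-9]+$", catalog$rsid)
  if (any(bad_rs)) {
    stop("malformed rsID: ", paste(catalog$rsid[bad_rs], collapse = ", "))
  }
  invisible(catalog)
}

#' Per-cohort variant allele frequencies
#'
#' Constructs a `cohort_af` object: the allele frequencies (and, when known,
#' allele counts) of a set of variants measured in one diploid cohort.
#' Cohorts are diploid, so the allele number is always `2 * n_individuals`.
#' A missing frequency stays `NA` — it is never coerced to zero.
#'
#' @param cohort_id Cohort label.
#' @param n_individuals Number of diploid subjects genotyped.
#' @param entries A data.frame with columns `variant`, `af` (frequency in
#'   \[0, 1\] or `NA` for missing) and optionally `allele_count`.
#' @return An object of class `cohort_af` with fields `cohort_id`,
#'   `n_individuals`, `allele_number`, `entries`.
#' @export
cohort_af <- function(cohort_id, n_individuals, entries) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) {
    stop("n_individuals must be a positive integer")
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("variant", "af") %in% names(entries))) {
    stop("entries must have columns 'variant' and 'af'")
  }
  if (is.null(entries$allele_count)) {
    entries$allele_count <- rep(NA_integer_, nrow(entries))
  }
  entries$allele_count <- as.integer(entries$allele_count)
  if (anyDuplicated(entries$variant)) {
    stop("duplicate variant in cohort '", cohort_id, "'")
  }
  an <- 2L * n_individuals
  ok <- !is.na(entries$af)
  if (any(entries$af[ok] < 0 | entries$af[ok] > 1)) {
    stop("allele frequency outside [0, 1] in cohort '", cohort_id, "'")
  }
  ac <- entries$allele_count
  if (any(!is.na(ac) & (ac < 0L | ac > an))) {
    stop("allele_count outside [0, allele_number] in cohort '", cohort_id, "'")
  }
  both <- ok & !is.na(ac)
  # 4-decimal rounding tolerance between a printed AF and its count
  if (any(abs(entries$af[both] - ac[both] / an) >= 5e-5)) {
    stop("af and allele_count disagree beyond rounding in cohort '",
         cohort_id, "'")
  }
  structure(
    list(cohort_id = cohort_id, n_individuals = n_individuals,
         allele_number = an, entries = entries),
    class = "cohort_af"
  )
}

#' @export
print.cohort_af <- function(x, ...) {
  cat("<cohort_af> ", x$cohort_id, ": n = ", x$n_individuals,
      " (", x$allele_number, " alleles), ", nrow(x$entries), " variants, ",
      sum(is.na(x$entries$af)), " missing\n", sep = "")
  invisible(x)
}

#' Allele spectrum of variant categories among CF patients
#'
#' Constructs a `patient_spectrum` object: allele counts of variant
#' categories observed on the chromosomes of CF patients from one region.
#' Categories are named variants plus the reserved remainder category
#' `"other"`. Published registry rows can be internally off by a few alleles
#' because their counts were back-computed from rounded frequencies, so by
#' default the total is only required to be within `tol` of
#' `2 * n_patients` (a larger deviation warns, it does not fail); synthetic
#' data should be validated with `strict = TRUE`, which enforces exact
#' equality.
#'
#' @param region_id Region label.
#' @param n_patients Number of CF patients genotyped.
#' @param counts Named vector of non-negative allele counts per category.
#' @param strict Require `sum(counts) == 2 * n_patients` exactly.
#' @param tol Allowed deviation of `sum(counts)` from `2 * n_patients`
#'   before a warning is raised (default 1 allele).
#' @return An object of class `patient_spectrum`.
#' @export
patient_spectrum <- function(region_id, n_patients, counts,
                             strict = FALSE, tol = 1L) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) {
    stop("n_patients must be a positive integer")
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector")
  }
  if (anyDuplicated(names(counts))) stop("duplicate category label")
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("negative or non-integer allele count in region '", region_id, "'")
  }
  dev <- abs(sum(counts) - 2L * n_patients)
  if (strict && dev != 0L) {
    stop("spectrum counts for '", region_id, "' sum to ", sum(counts),
         ", expected exactly ", 2L * n_patients)
  }
  if (!strict && dev > tol) {
    warning("spectrum counts for '", region_id, "' sum to ", sum(counts),
            " but 2 * n_patients = ", 2L * n_patients,
            " (deviation ", dev, " alleles)")
  }
  structure(
    list(region_id = region_id, n_patients = n_patients, counts = counts),
    class = "patient_spectrum"
  )
}

#' @export
print.patient_spectrum <- function(x, ...) {
  cat("<patient_spectrum> ", x$region_id, ": n = ", x$n_patients,
      ", ", sum(x$counts), " alleles over ", length(x$counts),
      " categories\n", sep = "")
  invisible(x)
}

#' Epidemiological registry record for one region
#'
#' Holds the inputs to the prevalence calculation: the number of registered
#' children with CF under the ascertainment age and the region's average
#' annual birth count over the corresponding horizon.
#'
#' @param region_id Region label.
#' @param n_cases Children with CF under the ascertainment age.
#' @param mean_annual_births Average newborns per year over the horizon.
#' @param horizon_years Ascertainment horizon in years; the registry
#'   convention is "under 18", hence the default of 18.
#' @return An object of class `region_registry_record`.
#' @export
region_registry_record <- function(region_id, n_cases, mean_annual_births,
                                   horizon_years = 18L) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  n_cases <- as.numeric(n_cases)
  horizon_years <- as.integer(horizon_years)
  if (is.na(n_cases) || n_cases < 0) stop("n_cases must be >= 0")
  if (!is.finite(mean_annual_births) || mean_annual_births <= 0) {
    stop("mean_annual_births must be > 0")
  }
  if (is.na(horizon_years) || horizon_years < 1L) {
    stop("horizon_years must be >= 1")
  }
  if (n_cases > mean_annual_births * horizon_years) {
    stop("n_cases exceeds total births over the horizon in '", region_id, "'")
  }
  structure(
    list(region_id = region_id, n_cases = n_cases,
         mean_annual_births = mean_annual_births,
         horizon_years = horizon_years),
    class = "region_registry_record"
  )
}

#' Read a cohort allele-frequency table
#'
#' Parses a tab-separated cohort table in the layout of the published
#' 12-variant frequency table: the first two columns are `legacy_name` and
#' `rsid`, each further column is one cohort with its size encoded in the
#' header as `"<cohort_id> (n=<N>)"`. The token `"n.a."` (also accepted:
#' `"NA"`, empty cell) denotes a missing frequency and is preserved as
#' missing; `"-"` denotes an absent rsID.
#'
#' @param path Path to the TSV file.
#' @return A named list of [cohort_af] objects, one per cohort column, with
#'   variant row order preserved.
#' @examples
#' t1 <- read_cohort_table(system.file("extdata", "tables_t1.tsv",
#'                                     package = "cftrmonitor"))
#' t1$RUSeq
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L || names(tab)[1] != "legacy_name") {
    stop("cohort table must start with columns legacy_name, rsid")
  }
  if (nrow(tab) > 0 && anyDuplicated(tab$legacy_name)) {
    stop("duplicate legacy_name in cohort table: ",
         paste(unique(tab$legacy_name[duplicated(tab$legacy_name)]),
               collapse = ", "))
  }
  if (nrow(tab) == 0L) return(list())
  cohort_cols <- names(tab)[-(1:2)]
  out <- list()
  for (col in cohort_cols) {
    m <- regmatches(col, regexec("^(.*?)\\s*\\(n\\s*=\\s*([0-9]+)\\)$", col))[[1]]
    if (length(m) != 3L) {
      stop("cohort column header '", col, "' must look like 'id (n=123)'")
    }
    id <- m[2]
    n <- as.integer(m[3])
    af <- vapply(seq_len(nrow(tab)), function(i) {
      tok <- trimws(tab[[col]][i])
      if (tok %in% .MISSING_TOKENS) return(NA_real_)
      val <- suppressWarnings(as.numeric(tok))
      if (is.na(val) || val < 0 || val > 1) {
        stop("malformed AF token '", tok, "' at row '", tab$legacy_name[i],
             "', column '", col, "'")
      }
      val
    }, numeric(1))
    out[[id]] <- cohort_af(
      id, n,
      data.frame(variant = tab$legacy_name, af = af,
                 stringsAsFactors = FALSE)
    )
  }
  out
}

#' Read a per-region patient allele-spectrum table
#'
#' Parses a tab-separated table with one row per region: columns `region`
#' and `n` (patients genotyped) followed by `<category>.AF` / `<category>.AC`
#' pairs. The AC (allele count) columns are taken as the counts; each AF
#' column is cross-checked against `AC / sum(AC)` and a warning is issued
#' when they disagree by more than `5e-4`, which flags rows whose printed
#' frequencies and counts are mutually inconsistent.
#'
#' @param path Path to the TSV file.
#' @return A named list of [patient_spectrum] objects, one per row.
#' @examples
#' t2 <- suppressWarnings(
#'   read_spectrum_table(system.file("extdata", "tables_t2.tsv",
#'                                   package = "cftrmonitor")))
#' t2[["Yugra region"]]
#' @export
read_spectrum_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("region", "n") %in% names(tab))) {
    stop("spectrum table must have columns 'region' and 'n'")
  }
  ac_cols <- grep("\\.AC$", names(tab), value = TRUE)
  if (length(ac_cols) == 0L) stop("spectrum table has no .AC columns")
  cats <- sub("\\.AC$", "", ac_cols)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    counts <- stats::setNames(as.integer(tab[i, ac_cols]), cats)
    if (any(counts < 0L, na.rm = TRUE)) {
      stop("negative allele count in region '", tab$region[i], "'")
    }
    sp <- patient_spectrum(as.character(tab$region[i]), tab$n[i], counts)
    for (cat in cats) {
      af_col <- paste0(cat, ".AF")
      if (af_col %in% names(tab)) {
        printed <- tab[i, af_col]
        implied <- counts[[cat]] / sum(counts)
        if (is.finite(printed) && abs(printed - implied) > 5e-4) {
          warning("region '", sp$region_id, "', category '", cat,
                  "': printed AF ", printed, " differs from AC-implied ",
                  signif(implied, 4), " by more than 5e-4")
        }
      }
    }
    out[[sp$region_id]] <- sp
  }
  out
}

#' Read a regional registry table
#'
#' Parses a TSV with columns `region`, `n_cases`, `mean_annual_births` and
#' optionally `horizon_years` (default 18) into registry records.
#'
#' @param path Path to the TSV file.
#' @param horizon_years Default horizon for rows without an explicit one.
#' @return A named list of [region_registry_record] objects.
#' @export
read_registry_table <- function(path, horizon_years = 18L) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("region", "n_cases", "mean_annual_births")
  if (!all(need %in% names(tab))) {
    stop("registry table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$horizon_years)) tab$horizon_years <- horizon_years
  out <- lapply(seq_len(nrow(tab)), function(i) {
    region_registry_record(as.character(tab$region[i]), tab$n_cases[i],
                           tab$mean_annual_births[i], tab$horizon_years[i])
  })
  stats::setNames(out, vapply(out, `[[`, "", "region_id"))
}

# Format one numeric report column. Frequencies use fixed decimals (the
# published tables print 4); prevalence and allele frequency of the disease
# allele (Fd, q) carry 6 significant digits; whole-number columns stay
# integers.
format_report_column <- function(x, name, af_digits = 4L) {
  if (!is.numeric(x)) return(as.character(x))
  if (name %in% c("Fd", "q")) return(as.character(signif(x, 6)))
  if (all(is.na(x) | x == round(x))) return(as.character(x))
  if (grepl("^(statistic|chi|p_value|min_expected)", name)) {
    return(as.character(signif(x, 6)))
  }
  formatC(x, format = "f", digits = af_digits)
}

#' Write a report table as TSV
#'
#' Writes a homogeneous data.frame of results to a tab-separated file with
#' the rendering conventions of the source tables: allele frequencies and
#' spectrum proportions at a fixed number of decimals (default 4), the
#' prevalence `Fd` and disease-allele frequency `q` at 6 significant
#' digits, counts as integers. Missing values are rendered as `"n.a."`.
#'
#' @param rows A data.frame of results.
#' @param path Output path.
#' @param af_digits Decimal places for frequency columns (4 or 3).
#' @return Invisibly, the formatted character data.frame written.
#' @export
write_report_table <- function(rows, path, af_digits = 4L) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  out <- rows
  for (j in seq_along(out)) {
    col <- format_report_column(rows[[j]], names(rows)[j], af_digits)
    col[is.na(rows[[j]])] <- "n.a."
    out[[j]] <- col
  }
  ok <- tryCatch({
    suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report table to '", path, "': ",
                        conditionMessage(ok))
  invisible(out)
}

#' Lay out cohorts as a wide frequency matrix
#'
#' Inverse of [read_cohort_table()]: assembles a list of [cohort_af] objects
#' back into the wide table layout (`legacy_name`, `rsid`, one column per
#' cohort headed `"id (n=N)"`), suitable for [write_report_table()].
#'
#' @param cohorts Named list of [cohort_af] objects sharing a variant list.
#' @param catalog Optional variant catalog supplying the rsid column.
#' @return A data.frame in the wide cohort-table layout.
#' @export
format_cohort_table <- function(cohorts, catalog = NULL) {
  stopifnot(length(cohorts) >= 1L)
  variants <- cohorts[[1]]$entries$variant
  rsid <- rep("-", length(variants))
  if (!is.null(catalog)) {
    idx <- match(variants, catalog$legacy_name)
    rsid <- ifelse(is.na(idx) | is.na(catalog$rsid[idx]), "-",
                   catalog$rsid[idx])
  }
  out <- data.frame(legacy_name = variants, rsid = rsid,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (co in cohorts) {
    if (!identical(co$entries$variant, variants)) {
      stop("cohorts do not share the same variant list")
    }
    out[[sprintf("%s (n=%d)", co$cohort_id, co$n_individuals)]] <- co$entries$af
  }
  out
}
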