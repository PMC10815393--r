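#!/usr/bin/env Rscript
# Contingency comparisons of the variant spectra: the eight federal
# districts against each other, the two local biocollections
# (St. Petersburg, Yugra), and infertile-vs-population cohort contrasts on
# reconstructed allele counts.

suppressPackageStartupMessages(library(cftrmonitor))
dir.create("results", showWarnings = FALSE)

cohorts <- read_cohort_table(system.file("extdata", "tables_t1.tsv",
                                         package = "cftrmonitor"))
spectra <- suppressWarnings(
  read_spectrum_table(system.file("extdata", "tables_t2.tsv",
                                  package = "cftrmonitor")))

rows <- list()
keep2 <- c("F508del", "CFTRdele2,3(21kb)")

districts <- spectra[grepl("Federal [Dd]istrict", names(spectra))]
res <- chi_square_test(build_contingency_table(districts, keep2))
rows$districts <- data.frame(comparison_id = "districts_8x3",
                             statistic = res$statistic, df = res$df,
                             p_value = res$p_value, yates = res$yates_applied,
                             min_expected = res$min_expected)
cat(sprintf("across-district spectrum heterogeneity: chi-squared = %.2f, df = %d, p %s\n",
            res$statistic, res$df, format_p_value(res$p_value)))

pair <- chi_square_test(build_contingency_table(
  spectra[c("St.Petersburg", "Yugra region")], "F508del"))
rows$pair <- data.frame(comparison_id = "spb_vs_yugra_f508del_2x2",
                        statistic = pair$statistic, df = pair$df,
                        p_value = pair$p_value, yates = pair$yates_applied,
                        min_expected = pair$min_expected)
cat(sprintf("St. Petersburg vs Yugra (F508del vs rest, Yates): chi-squared = %.3f, df = %d, p = %s\n",
            pair$statistic, pair$df, format_p_value(pair$p_value)))

pair3 <- chi_square_test(build_contingency_table(
  spectra[c("St.Petersburg", "Yugra region")], keep2))
rows$pair3 <- data.frame(comparison_id = "spb_vs_yugra_2x3",
                         statistic = pair3$statistic, df = pair3$df,
                         p_value = pair3$p_value, yates = pair3$yates_applied,
                         min_expected = pair3$min_expected)
cat(sprintf("St. Petersburg vs Yugra (2x3): chi-squared = %.3f, df = %d, p = %s\n",
            pair3$statistic, pair3$df, format_p_value(pair3$p_value)))

# CFTRdele2,3(21kb) is unreported (n.a.) in RUSeq, so its population
# contrast uses the Petrova cohort instead
contrasts <- list(c("F508del", "RUSeq"), c("CFTRdele2,3(21kb)", "Petrova"))
for (ct in contrasts) {
  v <- ct[1]; ref_cohort <- ct[2]
  res <- suppressWarnings(suppressMessages(
    compare_cohort_afs(cohorts$Infertile, cohorts[[ref_cohort]], v,
                       yates = "off")))
  rows[[paste0("inf_", v)]] <- data.frame(
    comparison_id = sprintf("infertile_vs_%s_%s", ref_cohort, v),
    statistic = res$statistic, df = res$df, p_value = res$p_value,
    yates = res$yates_applied, min_expected = res$min_expected)
  cat(sprintf("infertile vs %s, %s: chi-squared = %.3f, p = %s\n",
              ref_cohort, v, res$statistic, format_p_value(res$p_value)))
}

# three-cohort comparison of the summed 12-variant burden on reconstructed
# counts (carrier alleles vs other alleles)
burden3 <- t(vapply(c("RUSeq", "Infertile", "InfertileNonCBAVD"),
                    function(id) {
  co <- cohorts[[id]]
  ac <- allele_count_from_af(total_burden(co)$total, co$allele_number)
  c(ac, co$allele_number - ac)
}, numeric(2)))
res <- chi_square_test(burden3)
rows$burden <- data.frame(comparison_id = "total_burden_3x2",
                          statistic = res$statistic, df = res$df,
                          p_value = res$p_value, yates = res$yates_applied,
                          min_expected = res$min_expected)
cat(sprintf("total burden across RUSeq / infertile / non-CBAVD: chi-squared = %.2f, df = %d, p %s\n",
            res$statistic, res$df, format_p_value(res$p_value)))
cat("note: nominal p-values; no multiple-testing correction is applied\n")

write_report_table(do.call(rbind, rows), "results/comparisons.tsv")
cat("wrote results/comparisons.tsv\n")
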