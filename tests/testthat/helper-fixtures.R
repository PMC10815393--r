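t1_fixture <- function() system.file("extdata", "tables_t1.tsv",
                                     package = "cftrmonitor")
t2_fixture <- function() system.file("extdata", "tables_t2.tsv",
                                     package = "cftrmonitor")

read_fixture_cohorts <- function() read_cohort_table(t1_fixture())
read_fixture_spectra <- function() {
  suppressWarnings(read_spectrum_table(t2_fixture()))
}

fixture_districts <- function() {
  sp <- read_fixture_spectra()
  sp[grepl("Federal [Dd]istrict", names(sp))]
}

yugra_spectrum <- function() {
  patient_spectrum("Yugra region", 54,
                   c("F508del" = 43, "CFTRdele2,3(21kb)" = 5, "other" = 60))
}

# Independent Clopper-Pearson oracle: invert the binomial tail sums by
# root finding, without touching binom.test.
cp_tail_oracle <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low = lo, high = hi)
}

# Independent Pearson/Yates oracle: explicit double loop over cells.
chisq_loop_oracle <- function(m, yates = FALSE) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- rs[i] * cs[j] / n
      d <- abs(m[i, j] - e)
      if (yates) d <- max(d - 0.5, 0)
      stat <- stat + d^2 / e
    }
  }
  stat
}
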