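test_that("collapsing a spectrum pools the remainder and conserves alleles", {
  sp5 <- patient_spectrum("synth", 65,
                          c(F508del = 100, "CFTRdele2,3(21kb)" = 20,
                            E92K = 5, W1282X = 3, L138ins = 2))
  col <- collapse_spectrum(sp5, c("F508del", "CFTRdele2,3(21kb)"))
  expect_equal(unname(col$counts), c(100L, 20L, 10L))
  expect_named(col$counts, c("F508del", "CFTRdele2,3(21kb)", "other"))

  yug <- collapse_spectrum(yugra_spectrum(), "F508del")
  expect_equal(unname(yug$counts), c(43L, 65L))

  all_kept <- collapse_spectrum(sp5, c("F508del", "CFTRdele2,3(21kb)",
                                       "E92K", "W1282X", "L138ins"))
  expect_equal(all_kept$counts[["other"]], 0L)

  # a kept category absent from the spectrum contributes zero
  miss <- collapse_spectrum(yugra_spectrum(), c("F508del", "G542X"))
  expect_equal(miss$counts[["G542X"]], 0L)

  expect_error(collapse_spectrum(yugra_spectrum(), c("F508del", "other")),
               "reserved")
})

test_that("collapse conserves the total allele count for arbitrary keep sets", {
  set.seed(11)
  cats <- c("F508del", "CFTRdele2,3(21kb)", "E92K", "W1282X", "G542X")
  for (i in 1:20) {
    counts <- stats::setNames(rpois(5, 20), cats)
    n_pat <- as.integer(ceiling(sum(counts) / 2))
    sp <- suppressWarnings(patient_spectrum("p", max(n_pat, 1L), counts))
    keep <- sample(cats, sample(4, 1))
    col <- suppressWarnings(collapse_spectrum(sp, keep))
    expect_equal(sum(col$counts), sum(counts))
  }
})

test_that("contingency tables stack collapsed regional spectra", {
  districts <- fixture_districts()
  tab <- build_contingency_table(districts, c("F508del", "CFTRdele2,3(21kb)"))
  expect_equal(dim(tab), c(8L, 3L))
  expect_equal(unname(tab["Central Federal District", ]),
               c(839L, 126L, 645L))

  spectra <- read_fixture_spectra()
  two <- build_contingency_table(
    spectra[c("St.Petersburg", "Yugra region")],
    c("F508del", "CFTRdele2,3(21kb)"))
  expect_equal(unname(two["St.Petersburg", ]), c(2846L, 178L, 1799L))
  expect_equal(unname(two["Yugra region", ]), c(43L, 5L, 60L))

  expect_error(build_contingency_table(list(yugra_spectrum(),
                                            yugra_spectrum()), "F508del"),
               "duplicate region_id")
  expect_error(build_contingency_table(list(yugra_spectrum()), "F508del"),
               "at least 2")
})

test_that("chi-squared test reproduces the across-district heterogeneity", {
  tab <- build_contingency_table(fixture_districts(),
                                 c("F508del", "CFTRdele2,3(21kb)"))
  res <- chi_square_test(tab)
  expect_equal(res$df, 14L)
  expect_false(res$yates_applied)
  expect_equal(res$statistic, 198.68, tolerance = 1e-4)
  expect_true(res$p_value < 2.2e-16)
  # independent route: the stock Pearson test on the same counts
  ref <- suppressWarnings(stats::chisq.test(unclass(tab), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$expected, ref$expected, tolerance = 1e-12)
})

test_that("Yates policy matches the 2x2 convention and is overridable", {
  m <- rbind(SPb = c(2846, 1977), Yugra = c(43, 65))
  auto <- chi_square_test(m, yates = "auto")
  expect_true(auto$yates_applied)
  # frozen from the closed form N(|ad-bc|-N/2)^2 / product of margins
  expect_equal(auto$statistic, 15.25879, tolerance = 1e-6)
  off <- chi_square_test(m, yates = "off")
  expect_false(off$yates_applied)
  expect_equal(off$statistic, 16.04014, tolerance = 1e-6)
  # stock test agrees on both policies for 2x2
  expect_equal(auto$statistic,
               unname(stats::chisq.test(m, correct = TRUE)$statistic),
               tolerance = 1e-12)
  # auto leaves larger tables uncorrected; "on" forces the correction
  m3 <- rbind(c(30, 20, 10), c(25, 25, 10))
  expect_false(chi_square_test(m3)$yates_applied)
  expect_true(chi_square_test(m3, yates = "on")$yates_applied)
})

test_that("chi-squared statistic matches the brute-force oracle on small tables", {
  set.seed(7)
  for (i in 1:40) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    m <- matrix(sample.int(17, nr * nc, replace = TRUE), nr, nc)  # margins <= 51
    got <- suppressWarnings(chi_square_test(m, yates = "off"))
    expect_equal(got$statistic, chisq_loop_oracle(m), tolerance = 1e-10)
    if (nr == 2 && nc == 2) {
      gy <- suppressWarnings(chi_square_test(m, yates = "auto"))
      expect_equal(gy$statistic, chisq_loop_oracle(m, yates = TRUE),
                   tolerance = 1e-10)
    }
  }
})

test_that("chi-squared test is permutation invariant, zero under independence, monotone in p", {
  m <- rbind(c(30, 20, 10), c(25, 25, 10), c(5, 45, 50))
  base <- chi_square_test(m)
  perm <- chi_square_test(m[c(3, 1, 2), c(2, 3, 1)])
  expect_equal(base$statistic, perm$statistic, tolerance = 1e-12)
  expect_equal(base$p_value, perm$p_value, tolerance = 1e-12)

  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square_test(prop, yates = "off")$statistic, 0)

  stats <- c(0.5, 1, 5, 20, 100)
  ps <- stats::pchisq(stats, df = 3, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  expect_error(chi_square_test(rbind(c(0, 5), c(0, 7))), "zero column")
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 7))), "zero row")
  expect_warning(chi_square_test(rbind(c(2, 3), c(3, 2)), yates = "off"),
                 "expected count")
})

test_that("total burden sums non-missing frequencies and counts exclusions", {
  cohorts <- read_fixture_cohorts()
  ruseq <- total_burden(cohorts$RUSeq)
  expect_equal(round(ruseq$total, 4), 0.0117)
  expect_equal(ruseq$n_missing, 2L)
  inf <- total_burden(cohorts$Infertile)
  expect_equal(round(inf$total, 4), 0.0240)
  expect_equal(inf$n_missing, 0L)

  blank <- cohort_af("empty", 10,
                     data.frame(variant = letters[1:12], af = NA_real_))
  b <- total_burden(blank)
  expect_equal(b$total, 0)
  expect_equal(b$n_missing, 12L)

  expect_error(total_burden(cohorts$RUSeq, c("F508del", "nope")),
               "not in cohort")
})

test_that("pairwise cohort comparison reconstructs counts and refuses missing data", {
  cohorts <- read_fixture_cohorts()
  msgs <- capture_messages(
    res <- compare_cohort_afs(cohorts$Infertile, cohorts$RUSeq, "F508del",
                              yates = "off"))
  # reconstructed counts are reported for traceability
  expect_true(any(grepl("reconstructed AC=183", msgs)))
  expect_true(any(grepl("reconstructed AC=27", msgs)))
  expect_equal(res$df, 1L)
  # frozen from the direct Pearson closed form on 183/12066 vs 27/3342
  expect_equal(res$statistic, 9.779291, tolerance = 1e-6)
  expect_true(res$p_value < 0.01)

  same <- suppressMessages(
    compare_cohort_afs(cohorts$RUSeq, cohorts$RUSeq, "F508del",
                       yates = "off"))
  expect_equal(same$statistic, 0)

  expect_error(
    suppressMessages(
      compare_cohort_afs(cohorts$RUSeq, cohorts$Infertile,
                         "CFTRdele2,3(21kb)")),
    "missing")

  zero <- cohort_af("z1", 100, data.frame(variant = "F508del", af = 0))
  zero2 <- cohort_af("z2", 100, data.frame(variant = "F508del", af = 0))
  expect_error(suppressMessages(
    compare_cohort_afs(zero, zero2, "F508del", yates = "off")),
    "zero column")
})
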