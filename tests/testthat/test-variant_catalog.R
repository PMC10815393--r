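test_that("packaged variant catalog lists the 12 variants with valid identifiers", {
  cat <- read_variant_catalog()
  expect_equal(nrow(cat), 12L)
  expect_true(all(c("F508del", "CFTRdele2,3(21kb)", "L138ins", "W1282X")
                  %in% cat$legacy_name))
  expect_equal(cat$rsid[cat$legacy_name == "F508del"], "rs113993960")
  expect_true(is.na(cat$rsid[cat$legacy_name == "CFTRdele2,3(21kb)"]))
  expect_true(all(grepl("^rs[0-9]+$", cat$rsid[!is.na(cat$rsid)])))

  bad <- cat
  bad$legacy_name[2] <- bad$legacy_name[1]
  expect_error(validate_variant_catalog(bad), "duplicate")
  bad2 <- cat
  bad2$rsid[1] <- "rsX"
  expect_error(validate_variant_catalog(bad2), "rsID")
})

test_that("cohort table reader preserves missing entries and row order", {
  cohorts <- read_fixture_cohorts()
  expect_named(cohorts, c("RUSeq", "Petrova", "Infertile",
                          "InfertileNonCBAVD", "Calculated"))
  ruseq <- cohorts$RUSeq
  expect_s3_class(ruseq, "cohort_af")
  expect_equal(ruseq$n_individuals, 1671L)
  expect_equal(ruseq$allele_number, 3342L)
  e <- ruseq$entries
  expect_equal(e$af[e$variant == "F508del"], 0.008)
  expect_true(is.na(e$af[e$variant == "CFTRdele2,3(21kb)"]))
  expect_true(is.na(e$af[e$variant == "2184insA"]))
  # zero frequencies stay zero, missing stays NA: never conflated
  expect_equal(e$af[e$variant == "1677delTA"], 0)
  expect_equal(e$variant[1:3], c("F508del", "CFTRdele2,3(21kb)", "L138ins"))
})

test_that("cohort table reader rejects malformed input and accepts vacuous input", {
  hdr <- "legacy_name\trsid\tA (n=10)"
  empty <- withr::local_tempfile(lines = hdr, fileext = ".tsv")
  expect_identical(read_cohort_table(empty), list())

  bad_af <- withr::local_tempfile(
    lines = c(hdr, "F508del\trs1\t1.5"), fileext = ".tsv")
  expect_error(read_cohort_table(bad_af), "malformed AF token '1.5'.*F508del")

  bad_tok <- withr::local_tempfile(
    lines = c(hdr, "F508del\trs1\tabc"), fileext = ".tsv")
  expect_error(read_cohort_table(bad_tok), "malformed AF token")

  dup <- withr::local_tempfile(
    lines = c(hdr, "F508del\trs1\t0.1", "F508del\trs1\t0.2"),
    fileext = ".tsv")
  expect_error(read_cohort_table(dup), "duplicate legacy_name")

  bad_hdr <- withr::local_tempfile(
    lines = c("legacy_name\trsid\tA", "F508del\trs1\t0.1"), fileext = ".tsv")
  expect_error(read_cohort_table(bad_hdr), "n=123")
})

test_that("spectrum table reader recovers published counts and flags inconsistent rows", {
  w <- capture_warnings(spectra <- read_spectrum_table(t2_fixture()))
  # the published national and Southern rows are internally off by a few
  # alleles; both must be flagged, not silently repaired
  expect_true(any(grepl("Russian Federation.*deviation 12", w)))
  expect_true(any(grepl("Southern Federal District.*deviation 6", w)))
  rf <- spectra[["Russian Federation"]]
  expect_equal(unname(rf$counts),
               c(3400L, 403L, 2793L))
  expect_named(rf$counts, c("F508del", "CFTRdele2,3(21kb)", "other"))

  yug <- spectra[["Yugra region"]]
  expect_equal(unname(yug$counts), c(43L, 5L, 60L))
  expect_equal(yug$n_patients, 54L)
  expect_equal(sum(yug$counts), 2L * 54L)

  neg <- withr::local_tempfile(
    lines = c("region\tn\tA.AF\tA.AC\tother.AF\tother.AC",
              "X\t5\t0.5\t-1\t0.5\t11"),
    fileext = ".tsv")
  expect_error(read_spectrum_table(neg), "negative")

  # AF/AC cross-check
  off <- withr::local_tempfile(
    lines = c("region\tn\tA.AF\tA.AC\tother.AF\tother.AC",
              "X\t5\t0.9\t5\t0.5\t5"),
    fileext = ".tsv")
  expect_warning(read_spectrum_table(off), "printed AF")
})

test_that("patient_spectrum validates counts and sum tolerance", {
  expect_s3_class(patient_spectrum("tiny", 1, c(A = 1, other = 1)),
                  "patient_spectrum")
  expect_warning(patient_spectrum("off", 5, c(A = 5, other = 9)),
                 "deviation 4")
  expect_silent(patient_spectrum("off1", 5, c(A = 5, other = 6)))
  expect_error(patient_spectrum("strict", 5, c(A = 5, other = 6),
                                strict = TRUE), "exactly")
  expect_error(patient_spectrum("neg", 5, c(A = -1, other = 11)), "negative")
  expect_error(patient_spectrum("dup", 5,
                                stats::setNames(c(5, 5), c("A", "A"))),
               "duplicate")
})

test_that("registry records enforce epidemiological invariants", {
  r <- region_registry_record("demo", 110, 55000)
  expect_equal(r$horizon_years, 18L)
  expect_error(region_registry_record("x", -1, 1000), "n_cases")
  expect_error(region_registry_record("x", 1, 0), "mean_annual_births")
  expect_error(region_registry_record("x", 10, 100, horizon_years = 0),
               "horizon_years")
  expect_error(region_registry_record("x", 2000, 100, horizon_years = 10),
               "exceeds")
})

test_that("report rendering follows the 4-decimal convention", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(region = "RF", af = c(0.515468, 0, 0.00064))
  out <- write_report_table(df, tmp)
  expect_equal(out$af, c("0.5155", "0.0000", "0.0006"))
  # Fd and q carry 6 significant digits instead
  df2 <- data.frame(Fd = 1.097331e-4, q = 0.01047527, af = 0.0054)
  out2 <- write_report_table(df2, tmp)
  expect_equal(out2$q, "0.0104753")
  expect_equal(out2$af, "0.0054")
  expect_error(write_report_table(df, "/nonexistent/dir/x.tsv"),
               "cannot write")
})

test_that("writing then re-reading a cohort table round-trips AFs to 4 decimals", {
  cohorts <- read_fixture_cohorts()
  wide <- format_cohort_table(cohorts, catalog = read_variant_catalog())
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_report_table(wide, tmp)
  back <- read_cohort_table(tmp)
  expect_named(back, names(cohorts))
  for (id in names(cohorts)) {
    orig <- cohorts[[id]]$entries$af
    got <- back[[id]]$entries$af
    expect_identical(is.na(orig), is.na(got))
    expect_equal(got[!is.na(got)], round(orig[!is.na(orig)], 4),
                 tolerance = 1e-12)
  }
})
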