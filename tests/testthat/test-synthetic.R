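test_that("identical configurations generate identical extracts", {
  cfg <- cohort_config(n_patients = 25, seed = 1234L, missingness = 0.2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tb in c("patients", "diagnoses", "reports", "variants", "specimens")) {
    expect_identical(a[[tb]], b[[tb]], label = tb)
  }
  # a different seed changes the content
  c2 <- generate_cohort(cohort_config(n_patients = 25, seed = 1235L,
                                      missingness = 0.2))
  expect_false(identical(a$patients, c2$patients))
})

test_that("generated extracts satisfy their own referential contract", {
  fx <- small_fixture()
  expect_silent(validate_extract(fx$extract))
  ex <- fx$extract
  expect_setequal(names(ex$patients),
                  c("patient_id", "birth_date", "sex", "race", "ethnicity"))
  expect_true(all(ex$reports$patient_id %in% ex$patients$patient_id))
  expect_true(all(ex$variants$report_id %in% ex$reports$report_id))
  expect_true(all(ex$specimens$patient_id %in% ex$patients$patient_id))
  expect_true(all(ex$diagnoses$patient_id %in% ex$patients$patient_id))
  af <- ex$variants$allelic_frequency
  expect_true(all(is.na(af) | (af >= 0 & af <= 1)))
})

test_that("validate_extract names the offending identifier", {
  fx <- small_fixture()
  ex <- fx$extract
  bad_id <- ex$reports$report_id[3]
  ex$reports$patient_id[3] <- "PTnope"
  expect_error(validate_extract(ex), "PTnope|PTnope")
  ex2 <- fx$extract
  dup <- ex2$patients$patient_id[1]
  ex2$patients <- rbind(ex2$patients, ex2$patients[1, ])
  expect_error(validate_extract(ex2), dup)
})

test_that("missingness behaves like the configured Bernoulli rate", {
  n <- 600
  cfg0 <- cohort_config(n_patients = n, seed = 99L, missingness = 0)
  ex0 <- generate_cohort(cfg0)
  expect_false(anyNA(ex0$patients$race))
  expect_false(anyNA(ex0$variants$amino_acid_change))

  cfg1 <- cohort_config(n_patients = n, seed = 99L, missingness = 1)
  ex1 <- generate_cohort(cfg1)
  expect_true(all(is.na(ex1$patients$race)))
  expect_true(all(is.na(ex1$patients$ethnicity)))
  expect_true(all(is.na(ex1$variants$clinical_significance)))
  # non-maskable fields are never blanked
  expect_false(anyNA(ex1$patients$birth_date))
  expect_false(anyNA(ex1$variants$gene_symbol))

  p <- 0.3
  exp_ <- generate_cohort(cohort_config(n_patients = n, seed = 7L,
                                        missingness = p))
  frac <- mean(is.na(exp_$patients$race))
  # 5 sigma band around the Bernoulli rate
  expect_lt(abs(frac - p), 5 * sqrt(p * (1 - p) / n))
})

test_that("per-field missingness only masks the named fields", {
  cfg <- cohort_config(n_patients = 80, seed = 5L,
                       missingness = c(race = 1, allelic_frequency = 1))
  ex <- generate_cohort(cfg)
  expect_true(all(is.na(ex$patients$race)))
  expect_true(all(is.na(ex$variants$allelic_frequency)))
  expect_false(anyNA(ex$patients$ethnicity))
  expect_false(anyNA(ex$variants$dna_change_type))
})

test_that("writing and re-reading an extract is lossless", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  manifest <- write_extract(fx$extract, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  back <- read_extract(dir, as_of = fx$cfg$as_of)
  for (tb in c("patients", "diagnoses", "reports", "variants", "specimens")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(fx$extract[[tb]]),
                 label = tb)
  }
})

test_that("read_extract reports the corrupt file and column", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  write_extract(fx$extract, dir)
  pat <- readr::read_csv(file.path(dir, "patients.csv"), show_col_types = FALSE)
  pat$sex <- NULL
  readr::write_csv(pat, file.path(dir, "patients.csv"), na = "")
  err <- tryCatch(read_extract(dir), error = identity)
  expect_match(conditionMessage(err), "patients")
  expect_match(conditionMessage(err), "sex")
})

test_that("degenerate diagnosis models are rejected with a clear message", {
  expect_error(
    cohort_config(n_patients = 5,
                  diagnosis_model = list(EGFR = c(`165.1` = 1.4))),
    "probabilit")
  expect_error(
    cohort_config(n_patients = 5,
                  diagnosis_model = list(NOSUCHGENE = c(`165.1` = 0.2))),
    "NOSUCHGENE")
})

test_that("a zero-patient cohort is valid and empty", {
  ex <- generate_cohort(cohort_config(n_patients = 0, seed = 3L))
  expect_silent(validate_extract(ex))
  expect_identical(nrow(ex$patients), 0L)
  expect_identical(nrow(ex$variants), 0L)
})
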