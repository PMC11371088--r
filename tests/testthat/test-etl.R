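test_that("the packaged mapping covers every profile field", {
  mapping <- mapping_table()
  expect_silent(validate_mapping(mapping))
  expect_true(all(c("source_table", "source_column", "profile_kind",
                    "field_path", "disposition") %in% names(mapping$rules)))
})

test_that("a mapping with a missing rule fails coverage validation", {
  mapping <- mapping_table()
  keep <- !(mapping$rules$profile_kind == "GenomicVariant" &
              mapping$rules$field_path == "gene")
  mapping$rules <- mapping$rules[keep, ]
  expect_error(validate_mapping(mapping), "gene")
})

test_that("transforming a clean extract yields P+R+V+G+S valid profiles", {
  fx <- small_fixture()
  bundle <- fx$bundle
  expect_identical(nrow(attr(bundle, "errors")), 0L)
  expect_length(bundle, expected_profile_count(fx$extract))
  k <- table(bundle_kinds(bundle))
  expect_identical(unname(k[["CancerPatient"]]), nrow(fx$extract$patients))
  expect_identical(unname(k[["GenomicsReport"]]), nrow(fx$extract$reports))
  expect_identical(unname(k[["GenomicVariant"]]), nrow(fx$extract$variants))
  expect_identical(unname(k[["GenomicSpecimen"]]), nrow(fx$extract$specimens))
  for (p in bundle) expect_true(validate_profile(p)$valid)
})

test_that("resource ids are deterministic functions of source keys", {
  fx <- small_fixture()
  ids1 <- bundle_ids(fx$bundle)
  ids2 <- bundle_ids(transform_cohort(fx$extract, fx$mapping))
  expect_identical(ids1, ids2)
  pat <- fx$extract$patients$patient_id[1]
  expect_true(paste0("pat:", pat) %in% ids1)
  rep1 <- fx$extract$reports$report_id[1]
  expect_true(paste0("rep:", rep1) %in% ids1)
})

test_that("masked source cells become data-absent reasons, not silent drops", {
  cfg <- cohort_config(n_patients = 15, seed = 31L,
                       missingness = c(race = 1, clinical_significance = 1))
  bundle <- transform_cohort(generate_cohort(cfg), mapping_table())
  pats <- profiles_of_kind(bundle, "CancerPatient")
  for (p in pats) {
    expect_false("race" %in% names(p$fields))
    expect_true("race" %in% names(p$absent_reasons))
  }
  vars <- profiles_of_kind(bundle, "GenomicVariant")
  for (v in vars) {
    expect_true("clinical_significance" %in% names(v$absent_reasons))
  }
})

test_that("an untranslatable code fails its row and names the value", {
  fx <- small_fixture()
  ex <- fx$extract
  bad_pat <- ex$patients$patient_id[2]
  ex$patients$sex[2] <- "Q"
  bundle <- transform_cohort(ex, fx$mapping)
  errs <- attr(bundle, "errors")
  expect_true(any(errs$source_table == "patients" & errs$row_key == bad_pat))
  expect_true(any(grepl("Q", errs$message) & grepl("sex", errs$message)))
  # dependent rows of the failed patient are skipped, and recorded
  dep_reports <- ex$reports$report_id[ex$reports$patient_id == bad_pat]
  for (r in dep_reports) {
    expect_true(any(errs$source_table == "reports" & errs$row_key == r))
    expect_false(paste0("rep:", r) %in% bundle_ids(bundle))
  }
  # unrelated rows are unaffected: only the failed patient and its report
  # groups are missing from the bundle
  lost <- 1L + sum(ex$specimens$patient_id == bad_pat) +
    sum(vapply(dep_reports, function(r) {
      has_region <- length(ex$reports$regions_studied[[
        which(ex$reports$report_id == r)]]) > 0L
      1L + sum(ex$variants$report_id == r) + has_region
    }, integer(1)))
  expect_length(bundle, expected_profile_count(ex) - lost)
})

test_that("the audit accounts for every populated source cell", {
  fx <- small_fixture()
  audit <- audit_transform(fx$extract, fx$bundle, fx$mapping)
  expect_true(all(audit$accounted))
  # a clean extract yields no dropped cells
  expect_setequal(unique(audit$disposition),
                  c("field", "extension", "identifier"))
  # the audit covers all five source tables
  expect_setequal(unique(audit$source_table),
                  c("patients", "diagnoses", "reports", "variants",
                    "specimens"))
})

test_that("the audit flags a value the bundle does not carry", {
  fx <- small_fixture()
  bundle <- fx$bundle
  k <- bundle_kinds(bundle)
  i <- which(k == "GenomicVariant")[1]
  tampered <- bundle
  tampered[[i]]$fields$dna_change <- coded_value("hgvs", "c.0A>T")
  audit <- audit_transform(fx$extract, tampered, fx$mapping)
  expect_false(all(audit$accounted))
  bad <- audit[!audit$accounted, ]
  expect_true(all(bad$source_column == "dna_change"))
})

test_that("loading with 1 worker or several gives identical store contents", {
  fx <- small_fixture()
  s1 <- profile_store()
  s8 <- profile_store()
  r1 <- load_bundle(fx$bundle, s1, batch_size = 37L, workers = 1L)
  r8 <- load_bundle(fx$bundle, s8, batch_size = 37L, workers = 4L)
  expect_identical(r1$loaded, r8$loaded)
  expect_setequal(store_ids(s1), store_ids(s8))
  o <- function(s) {
    d <- as.data.frame(s$rows)
    d[order(d$resource_id, d$attribute_path, d$value), ]
  }
  expect_equal(o(s1), o(s8), ignore_attr = TRUE)
})

test_that("an invalid profile is rejected at load and the rest still load", {
  fx <- small_fixture()
  bundle <- fx$bundle
  i <- which(bundle_kinds(bundle) == "GenomicSpecimen")[1]
  broken <- bundle[[i]]
  broken$fields$specimen_type <- NULL
  broken$absent_reasons <-
    broken$absent_reasons[names(broken$absent_reasons) != "specimen_type"]
  bundle[[i]] <- broken
  store <- profile_store()
  report <- load_bundle(bundle, store, batch_size = 25L)
  expect_identical(report$attempted, length(bundle))
  expect_identical(report$loaded, length(bundle) - 1L)
  expect_length(report$rejected, 1L)
  expect_identical(report$rejected[[1]]$resource_id, broken$resource_id)
  expect_false(report$rejected[[1]]$report$valid)
  expect_identical(report$batches, as.integer(ceiling(length(bundle) / 25)))
  expect_null(store_get(store, broken$resource_id))
})

test_that("batch count follows ceiling(n / batch_size)", {
  fx <- small_fixture()
  n <- length(fx$bundle)
  for (bs in c(1L, 7L, n, n + 50L)) {
    store <- profile_store()
    rep_ <- load_bundle(fx$bundle, store, batch_size = bs)
    expect_identical(rep_$batches, as.integer(ceiling(n / bs)), label = bs)
    expect_identical(store_count(store), n)
  }
})
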