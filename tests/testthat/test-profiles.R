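test_that("profile construction rejects unknown kinds and fields", {
  expect_error(mcode_profile("NotAKind", "x1"), "unknown profile kind")
  expect_error(mcode_profile("GenomicVariant", "v1", subject_ref = "p1",
                             fields = list(wrong_field = "x")),
               "wrong_field")
  expect_error(mcode_profile("CancerPatient", "p1", subject_ref = "p2"),
               "no subject_ref")
})

test_that("every unpopulated must-support field must carry a reason", {
  p <- mcode_profile("GenomicSpecimen", "s1", subject_ref = "p1",
                     fields = list(specimen_type =
                                     coded_value("sys", "TUMOR", "TUMOR")))
  rep1 <- validate_profile(p)
  expect_false(rep1$valid)
  expect_true("collected_date" %in% rep1$findings$field_path)
  p2 <- apply_data_absent_reason(p, "collected_date", "not-asked")
  expect_true(validate_profile(p2)$valid)
  # the original profile is untouched
  expect_false(validate_profile(p)$valid)
})

test_that("data-absent reasons are restricted to declared codes and fields", {
  p <- mcode_profile("GenomicSpecimen", "s1", subject_ref = "p1",
                     fields = list(collected_date = "2015-04-01",
                                   specimen_type =
                                     coded_value("sys", "TUMOR", "TUMOR")))
  expect_error(apply_data_absent_reason(p, "collected_date", "unknown"),
               "populated")
  expect_error(apply_data_absent_reason(p, "no_such_field", "unknown"),
               "no_such_field")
  p$fields$collected_date <- NULL
  expect_error(apply_data_absent_reason(p, "collected_date", "because"),
               "because")
  p2 <- apply_data_absent_reason(p, "collected_date", "masked")
  expect_error(apply_data_absent_reason(p2, "collected_date", "unknown"),
               "already")
})

test_that("extensions are anchored, namespaced, and unique by url", {
  p <- mcode_profile("CancerPatient", "p1",
                     fields = list(birth_date = "1960-01-01", sex = "female",
                                   race = coded_value("s", "2106-3", "White"),
                                   ethnicity = coded_value("s", "2186-5",
                                                           "Not Hispanic or Latino")))
  base <- p$extension_base
  p2 <- attach_extension(p, "resource", paste0(base, "diagnosis/165.1"),
                         coded_value("urn:example:phecode", "165.1",
                                     "Cancer of bronchus; lung"))
  expect_length(p2$extensions, 1)
  expect_error(attach_extension(p2, "resource", paste0(base, "diagnosis/165.1"),
                                "again"), "duplicate")
  expect_error(attach_extension(p, "resource", "urn:other:thing", "x"),
               "namespace")
  expect_error(attach_extension(p, "no_such_anchor", paste0(base, "x"), "v"),
               "anchor")
})

test_that("structural equality is independent of field insertion order", {
  f1 <- list(birth_date = "1960-01-01", sex = "female")
  f2 <- list(sex = "female", birth_date = "1960-01-01")
  a <- mcode_profile("CancerPatient", "p1", fields = f1)
  b <- mcode_profile("CancerPatient", "p1", fields = f2)
  expect_identical(a, b)
})

test_that("bundle validation catches duplicate ids and dangling references", {
  fx <- small_fixture()
  bundle <- fx$bundle
  expect_silent(validate_bundle(bundle))

  expect_error(profile_bundle(c(bundle[1], bundle[1])), "duplicate resource_id")

  k <- bundle_kinds(bundle)
  v <- bundle[[which(k == "GenomicVariant")[1]]]
  v$subject_ref <- "pat:GHOST"
  expect_error(profile_bundle(list(v)), "GHOST")

  r <- bundle[[which(k == "GenomicsReport")[1]]]
  pat <- bundle[[which(k == "CancerPatient")[1]]]
  r$subject_ref <- pat$resource_id
  # result_refs / specimen_ref do not resolve inside this two-profile bundle
  expect_error(profile_bundle(list(pat, r)), "unresolved|result_refs")
})

test_that("all five kinds and their must-support registries are declared", {
  expect_setequal(profile_kinds(),
                  c("CancerPatient", "GenomicsReport", "GenomicVariant",
                    "GenomicRegionStudied", "GenomicSpecimen"))
  expect_setequal(must_support_fields("GenomicVariant"),
                  c("gene", "dna_change", "dna_change_type",
                    "genomic_source_class", "amino_acid_change",
                    "allelic_frequency", "clinical_significance"))
  expect_setequal(must_support_fields("CancerPatient"),
                  c("birth_date", "sex", "race", "ethnicity"))
})
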