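# Three-step ETL: extract rows from a Clarity-style export, transform them
# into mCODE profiles through a versioned mapping table, and load them into
# the profile store in validated, batched, order-independent fashion.
#
# The mapping table ships as a data file rather than code because
# reconciling source naming conventions against the mCODE implementation
# guide is a curation task, not a programming one.

#' Load the source-to-mCODE mapping table
#'
#' Reads the ordered mapping rules ((source_table, source_column) ->
#' (profile_kind, field_path, code_system)) together with the per-column
#' value-translation maps (source sex codes to FHIR administrative gender,
#' source race/ethnicity letters to coded concepts, variant attribute codes
#' to their answer lists, gene symbols to HGNC ids). The table is checked at
#' load time: every must-support field of every kind must appear in exactly
#' one rule or be explicitly declared as derived.
#'
#' @param rules_path,value_maps_path Optional overrides for the packaged
#'   CSV files.
#' @param extension_base Namespace for local extensions on transformed
#'   profiles.
#' @param as_of Reference date carried through to transformed cohorts.
#' @return A `mapping_table`.
#' @export
mapping_table <- function(rules_path = NULL, value_maps_path = NULL,
                          extension_base = DEFAULT_EXTENSION_BASE,
                          as_of = "2020-12-31") {
  rules <- if (is.null(rules_path)) read_extdata_csv("mapping_table.csv")
           else readr::read_csv(rules_path, show_col_types = FALSE)
  vm_raw <- if (is.null(value_maps_path)) read_extdata_csv("value_maps.csv")
            else readr::read_csv(value_maps_path, show_col_types = FALSE)
  value_maps <- lapply(split(vm_raw, vm_raw$map), function(df) {
    list(code = setNames(df$code, df$source),
         display = setNames(df$display, df$source))
  })
  genes <- cancer_genes()
  value_maps$gene <- list(code = setNames(genes$hgnc_id, genes$symbol),
                          display = setNames(genes$symbol, genes$symbol))
  m <- structure(
    list(rules = rules, value_maps = value_maps,
         extension_base = extension_base, as_of = as_of),
    class = "mapping_table"
  )
  validate_mapping(m)
  m
}

validate_mapping <- function(mapping) {
  rules <- mapping$rules
  for (kind in profile_kinds()) {
    for (f in must_support_fields(kind)) {
      n <- sum(rules$profile_kind == kind & rules$field_path == f &
                 rules$disposition %in% c("field", "derived", "identifier"))
      if (n != 1L) {
        abort(paste0("mapping table must cover must-support field ", kind,
                     ".", f, " exactly once (found ", n, ")"))
      }
    }
  }
  invisible(mapping)
}

translate_code <- function(mapping, map_name, value, column) {
  vm <- mapping$value_maps[[map_name]]
  if (is.null(vm)) abort(paste0("no value map named ", map_name))
  if (!value %in% names(vm$code)) {
    abort(paste0("untranslatable value '", value, "' in column ", column),
          class = "mcodeflow_translate_error")
  }
  list(code = unname(vm$code[[value]]), display = unname(vm$display[[value]]))
}

pid <- function(patient_id) paste0("pat:", patient_id)
rid <- function(report_id) paste0("rep:", report_id)
vid <- function(report_id, ordinal) paste0("var:", report_id, ":", ordinal)
gid <- function(report_id) paste0("reg:", report_id)
sid <- function(specimen_id) paste0("spec:", specimen_id)

present <- function(x) !is.null(x) && length(x) == 1L && !is.na(x) && nzchar(as.character(x))

# set field when source present, otherwise record a data-absent reason
set_or_dar <- function(profile, field, value) {
  if (field_populated(value)) {
    profile$fields[[field]] <- value
    normalize_profile(profile)
  } else {
    apply_data_absent_reason(profile, field, "unknown")
  }
}

gene_cv <- function(mapping, symbol, column = "gene_symbol") {
  tr <- translate_code(mapping, "gene", symbol, column)
  coded_value(fhir_systems$hgnc, tr$code, tr$display)
}

#' Transform a patient row into a CancerPatient profile
#'
#' Populated columns are translated through the mapping's value maps; any
#' must-support field with an empty source cell receives a data-absent
#' reason placeholder. Phecode diagnoses, which have no slot among the five
#' implemented profile kinds, are attached as namespaced extensions (one
#' coded diagnosis extension plus one onset-date extension per row).
#'
#' @param row A single row of the patients table (list or one-row tibble).
#' @param mapping A [mapping_table()].
#' @param diagnoses Optional tibble of this patient's diagnosis rows.
#' @return A validated CancerPatient `mcode_profile`.
#' @export
transform_patient <- function(row, mapping, diagnoses = NULL) {
  p <- mcode_profile("CancerPatient", pid(row$patient_id),
                     extension_base = mapping$extension_base)
  p <- set_or_dar(p, "birth_date", if (present(row$birth_date)) row$birth_date else NULL)
  if (present(row$sex)) {
    tr <- translate_code(mapping, "sex", row$sex, "sex")
    p$fields$sex <- tr$code
    p <- normalize_profile(p)
  } else {
    p <- apply_data_absent_reason(p, "sex", "unknown")
  }
  for (f in c("race", "ethnicity")) {
    if (present(row[[f]])) {
      tr <- translate_code(mapping, f, row[[f]], f)
      p$fields[[f]] <- coded_value(fhir_systems$`cdc-race-ethnicity`,
                                   tr$code, tr$display)
      p <- normalize_profile(p)
    } else {
      p <- apply_data_absent_reason(p, f, "unknown")
    }
  }
  if (!is.null(diagnoses) && nrow(diagnoses)) {
    for (i in seq_len(nrow(diagnoses))) {
      d <- diagnoses[i, ]
      url <- paste0(mapping$extension_base, DIAG_EXT_PREFIX, d$phecode)
      p <- attach_extension(p, "resource", url,
                            coded_value(fhir_systems$phecode, d$phecode,
                                        if (present(d$label)) d$label else NULL))
      if (present(d$onset_date)) {
        p <- attach_extension(p, "resource", paste0(url, "/onset"),
                              as.character(d$onset_date))
      }
    }
  }
  p
}

transform_variant <- function(vrow, report_id, ordinal, subject, mapping) {
  p <- mcode_profile("GenomicVariant", vid(report_id, ordinal),
                     subject_ref = subject,
                     extension_base = mapping$extension_base)
  p <- set_or_dar(p, "gene",
                  if (present(vrow$gene_symbol)) gene_cv(mapping, vrow$gene_symbol) else NULL)
  p <- set_or_dar(p, "dna_change",
                  if (present(vrow$dna_change))
                    coded_value(fhir_systems$hgvs, vrow$dna_change) else NULL)
  if (present(vrow$dna_change_type)) {
    tr <- translate_code(mapping, "dna_change_type", vrow$dna_change_type,
                         "dna_change_type")
    p$fields$dna_change_type <-
      coded_value(fhir_systems$`sequence-ontology`, tr$code, tr$display)
    p <- normalize_profile(p)
  } else {
    p <- apply_data_absent_reason(p, "dna_change_type", "unknown")
  }
  if (present(vrow$genomic_source_class)) {
    tr <- translate_code(mapping, "genomic_source_class",
                         vrow$genomic_source_class, "genomic_source_class")
    p$fields$genomic_source_class <-
      coded_value(fhir_systems$loinc, tr$code, tr$display)
    p <- normalize_profile(p)
  } else {
    p <- apply_data_absent_reason(p, "genomic_source_class", "unknown")
  }
  p <- set_or_dar(p, "amino_acid_change",
                  if (present(vrow$amino_acid_change))
                    coded_value(fhir_systems$hgvs, vrow$amino_acid_change) else NULL)
  p <- set_or_dar(p, "allelic_frequency",
                  if (present(vrow$allelic_frequency))
                    as.numeric(vrow$allelic_frequency) else NULL)
  if (present(vrow$clinical_significance)) {
    tr <- translate_code(mapping, "clinical_significance",
                         vrow$clinical_significance, "clinical_significance")
    p$fields$clinical_significance <-
      coded_value(fhir_systems$loinc, tr$code, tr$display)
    p <- normalize_profile(p)
  } else {
    p <- apply_data_absent_reason(p, "clinical_significance", "unknown")
  }
  p
}

transform_specimen <- function(srow, mapping) {
  p <- mcode_profile("GenomicSpecimen", sid(srow$specimen_id),
                     subject_ref = pid(srow$patient_id),
                     extension_base = mapping$extension_base)
  if (present(srow$specimen_type)) {
    tr <- translate_code(mapping, "specimen_type", srow$specimen_type,
                         "specimen_type")
    p$fields$specimen_type <- coded_value(fhir_systems$`v2-0487`,
                                          tr$code, tr$display)
    p <- normalize_profile(p)
  } else {
    p <- apply_data_absent_reason(p, "specimen_type", "unknown")
  }
  set_or_dar(p, "collected_date",
             if (present(srow$collected_date)) srow$collected_date else NULL)
}

#' Transform one genomic report group into a profile bundle
#'
#' One GenomicsReport plus one GenomicVariant per variant row, one
#' GenomicRegionStudied when the report lists studied regions, and one
#' GenomicSpecimen. The report's `result_refs` lists every variant id; all
#' profiles validate individually.
#'
#' @param report A single reports-table row.
#' @param variants Tibble of this report's variant rows (may be empty).
#' @param specimen The matching specimens-table row.
#' @param mapping A [mapping_table()].
#' @return A `profile_bundle` (in-bundle patient reference left external).
#' @export
transform_report_group <- function(report, variants, specimen, mapping) {
  if (nrow(variants) && any(variants$report_id != report$report_id)) {
    abort(paste0("variant rows reference a different report than ",
                 report$report_id))
  }
  if (specimen$specimen_id != report$specimen_id ||
      specimen$patient_id != report$patient_id) {
    abort(paste0("specimen row does not match report ", report$report_id))
  }
  subject <- pid(report$patient_id)
  var_profiles <- if (nrow(variants)) {
    lapply(seq_len(nrow(variants)), function(i) {
      transform_variant(variants[i, ], report$report_id, i, subject, mapping)
    })
  } else list()

  regions <- report$regions_studied
  if (is.list(regions)) regions <- regions[[1]]
  region_profiles <- list()
  if (length(regions)) {
    rp <- mcode_profile("GenomicRegionStudied", gid(report$report_id),
                        subject_ref = subject,
                        extension_base = mapping$extension_base)
    rp$fields$genes <- lapply(regions, function(g)
      gene_cv(mapping, g, "regions_studied"))
    region_profiles <- list(normalize_profile(rp))
  }

  rep_p <- mcode_profile("GenomicsReport", rid(report$report_id),
                         subject_ref = subject,
                         extension_base = mapping$extension_base)
  rep_p <- set_or_dar(rep_p, "test_date",
                      if (present(report$test_date)) report$test_date else NULL)
  rep_p$fields$specimen_ref <- sid(report$specimen_id)
  rep_p <- normalize_profile(rep_p)
  if (length(var_profiles)) {
    rep_p$fields$result_refs <- vapply(var_profiles, `[[`, "", "resource_id")
    rep_p <- normalize_profile(rep_p)
  } else {
    rep_p <- apply_data_absent_reason(rep_p, "result_refs", "not-performed")
  }
  if (length(region_profiles)) {
    rep_p$fields$region_refs <- vapply(region_profiles, `[[`, "", "resource_id")
    rep_p <- normalize_profile(rep_p)
  }

  out <- c(list(rep_p), var_profiles, region_profiles,
           list(transform_specimen(specimen, mapping)))
  structure(out, class = "profile_bundle")
}

#' Transform a whole extract into a profile bundle
#'
#' Pure function of (extract, mapping): one CancerPatient per patient row,
#' one report group per report (see [transform_report_group()]) and one
#' GenomicSpecimen per specimen row, so the bundle size is
#' P + R + V + G + S (patients, reports, variant rows, reports with
#' non-empty regions, specimens). Row-level failures do not abort the
#' cohort: they are collected with their row coordinates in the bundle's
#' `errors` attribute and dependent rows of a failed patient are skipped
#' (also recorded).
#'
#' @param extract A `clarity_extract`.
#' @param mapping A [mapping_table()].
#' @return A `profile_bundle` with attribute `errors` (tibble of
#'   source_table, row_key, message).
#' @export
transform_cohort <- function(extract, mapping) {
  validate_extract(extract)
  errors <- list()
  err <- function(tb, key, msg) {
    errors[[length(errors) + 1L]] <<- tibble::tibble(
      source_table = tb, row_key = key, message = msg)
  }
  diag_split <- split(extract$diagnoses, extract$diagnoses$patient_id)
  patients <- list()
  for (i in seq_len(nrow(extract$patients))) {
    row <- extract$patients[i, ]
    p <- tryCatch(transform_patient(row, mapping, diag_split[[row$patient_id]]),
                  error = function(e) {
                    err("patients", row$patient_id, conditionMessage(e)); NULL
                  })
    if (!is.null(p)) patients[[length(patients) + 1L]] <- p
  }
  patient_ids <- vapply(patients, `[[`, "", "resource_id")

  var_split <- split(extract$variants, extract$variants$report_id)
  spec_by_id <- split(extract$specimens, extract$specimens$specimen_id)
  empty_variants <- extract$variants[0, ]
  groups <- list()
  used_specimens <- character()
  for (i in seq_len(nrow(extract$reports))) {
    rrow <- extract$reports[i, ]
    if (!pid(rrow$patient_id) %in% patient_ids) {
      err("reports", rrow$report_id, "skipped: patient row failed to transform")
      next
    }
    g <- tryCatch(
      transform_report_group(rrow, var_split[[rrow$report_id]] %||% empty_variants,
                             spec_by_id[[rrow$specimen_id]][1, ], mapping),
      error = function(e) {
        err("reports", rrow$report_id, conditionMessage(e)); NULL
      })
    if (!is.null(g)) {
      groups[[length(groups) + 1L]] <- g
      used_specimens <- c(used_specimens, rrow$specimen_id)
    }
  }
  orphans <- list()
  leftover <- extract$specimens[!extract$specimens$specimen_id %in% used_specimens, ]
  for (i in seq_len(nrow(leftover))) {
    srow <- leftover[i, ]
    if (!pid(srow$patient_id) %in% patient_ids) {
      err("specimens", srow$specimen_id, "skipped: patient row failed to transform")
      next
    }
    s <- tryCatch(transform_specimen(srow, mapping),
                  error = function(e) {
                    err("specimens", srow$specimen_id, conditionMessage(e)); NULL
                  })
    if (!is.null(s)) orphans[[length(orphans) + 1L]] <- s
  }
  bundle <- c(patients, do.call(c, c(groups, list(list()))), orphans)
  bundle <- structure(bundle, class = "profile_bundle")
  validate_bundle(bundle)
  attr(bundle, "errors") <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(source_table = character(), row_key = character(),
                   message = character())
  bundle
}

#' Bulk-load a bundle into the store
#'
#' Splits the bundle into `ceiling(n / batch_size)` batches; profile
#' validation and EAV flattening within a batch may run on parallel workers
#' (nonblocking preparation of profiles), while store insertion is applied
#' in deterministic order, so the final store contents are identical for
#' any `workers` and `batch_size` (order-independence contract). Invalid
#' profiles are rejected with their validation reports; the report
#' arithmetic `attempted = loaded + rejected` always holds. An unusable
#' store yields an all-fail report, never partial silent loss.
#'
#' @param bundle A `profile_bundle` or list of profiles.
#' @param store An `mcode_store`.
#' @param batch_size Profiles per batch (>= 1).
#' @param workers Parallel workers for batch preparation (>= 1).
#' @return A `load_report`: attempted, loaded, rejected (list of
#'   resource_id + validation report), batches, elapsed seconds.
#' @export
load_bundle <- function(bundle, store, batch_size = 500L, workers = 1L) {
  if (batch_size < 1) abort("batch_size must be >= 1")
  if (workers < 1) abort("workers must be >= 1")
  t0 <- Sys.time()
  n <- length(bundle)
  if (!inherits(store, "mcode_store")) {
    rejected <- lapply(bundle, function(p) {
      list(resource_id = p$resource_id, report = NULL,
           message = "store unavailable")
    })
    return(new_load_report(n, 0L, rejected, 0L, t0))
  }
  idx_batches <- if (n) split(seq_len(n), ceiling(seq_len(n) / batch_size)) else list()
  loaded <- 0L
  rejected <- list()
  prepare <- function(i) {
    p <- bundle[[i]]
    report <- validate_profile(p)
    list(i = i, profile = p, report = report,
         eav = if (report$valid) eav_rows(p) else NULL)
  }
  for (batch in idx_batches) {
    prepared <- if (workers > 1L) {
      parallel::mclapply(batch, prepare, mc.cores = workers)
    } else {
      lapply(batch, prepare)
    }
    failed <- vapply(prepared, function(x) inherits(x, "try-error") || is.null(x$report),
                     logical(1))
    if (any(failed)) prepared[failed] <- lapply(batch[failed], prepare)
    valid <- vapply(prepared, function(pr) pr$report$valid, logical(1))
    for (pr in prepared[!valid]) {
      rejected[[length(rejected) + 1L]] <-
        list(resource_id = pr$profile$resource_id, report = pr$report)
    }
    store_bulk_put(store,
                   lapply(prepared[valid], `[[`, "profile"),
                   lapply(prepared[valid], `[[`, "eav"))
    loaded <- loaded + sum(valid)
  }
  new_load_report(n, loaded, rejected, length(idx_batches), t0)
}

new_load_report <- function(attempted, loaded, rejected, batches, t0) {
  structure(
    list(attempted = as.integer(attempted), loaded = as.integer(loaded),
         rejected = rejected, batches = as.integer(batches),
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "load_report"
  )
}

#' @export
print.load_report <- function(x, ...) {
  cat("<load_report>", x$loaded, "of", x$attempted, "loaded in", x$batches,
      "batches;", length(x$rejected), "rejected;",
      sprintf("%.2fs", x$elapsed), "\n")
  invisible(x)
}
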