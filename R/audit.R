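# Field-level conservation audit: every populated source cell of an
# extract must be recoverable from the transformed bundle — in exactly one
# profile field, one extension, or one logged drop. No silent data loss.

#' Audit a transformation for silent data loss
#'
#' Walks every populated cell of the extract and verifies its disposition
#' against the bundle: `field` cells must equal the (value-translated)
#' profile field, `extension` cells must appear in the owning patient's
#' diagnosis extensions, `identifier` cells must resolve to the
#' deterministically derived resource ids and references, and cells of rows
#' that failed to transform must be covered by a logged error (`dropped`).
#'
#' @param extract The source `clarity_extract`.
#' @param bundle The `profile_bundle` produced by [transform_cohort()]
#'   (its `errors` attribute supplies the logged drops).
#' @param mapping The [mapping_table()] used for the transformation.
#' @return A tibble with one row per populated source cell: source_table,
#'   source_column, row_key, disposition, accounted (logical).
#' @export
audit_transform <- function(extract, bundle, mapping) {
  profs <- new.env(parent = emptyenv())
  for (p in bundle) assign(p$resource_id, p, envir = profs)
  pget <- function(id) if (exists(id, envir = profs, inherits = FALSE))
    get(id, envir = profs) else NULL
  errors <- attr(bundle, "errors") %||%
    tibble::tibble(source_table = character(), row_key = character())
  dropped <- function(tb, key) {
    any(errors$source_table == tb & errors$row_key == key)
  }
  out <- list()
  cell <- function(tb, col, key, disposition, accounted) {
    out[[length(out) + 1L]] <<- list(source_table = tb, source_column = col,
                                     row_key = key, disposition = disposition,
                                     accounted = accounted)
  }
  # a populated cell is accounted either by the check or by a logged drop
  check <- function(tb, col, key, value, ok_fn) {
    if (is.list(value)) value <- value[[1]]
    if (length(value) != 1L || is.na(value) || !nzchar(as.character(value))) {
      return(invisible())
    }
    if (dropped(tb, key)) { cell(tb, col, key, "dropped", TRUE); return(invisible()) }
    cell(tb, col, key, "field", isTRUE(ok_fn(value)))
  }
  id_check <- function(tb, col, key, ok) {
    if (dropped(tb, key)) cell(tb, col, key, "dropped", TRUE)
    else cell(tb, col, key, "identifier", isTRUE(ok))
  }
  cv_eq <- function(cv, map_name, src, system = NULL) {
    if (!is_coded_value(cv)) return(FALSE)
    tr <- translate_code(mapping, map_name, src, map_name)
    identical(cv$code, tr$code)
  }

  # patients -------------------------------------------------------------
  for (i in seq_len(nrow(extract$patients))) {
    r <- extract$patients[i, ]
    key <- r$patient_id
    p <- pget(pid(key))
    id_check("patients", "patient_id", key, !is.null(p))
    if (is.null(p) && !dropped("patients", key)) next
    check("patients", "birth_date", key, r$birth_date,
          function(v) identical(p$fields$birth_date, v))
    check("patients", "sex", key, r$sex, function(v)
      identical(p$fields$sex, translate_code(mapping, "sex", v, "sex")$code))
    check("patients", "race", key, r$race, function(v)
      cv_eq(p$fields$race, "race", v))
    check("patients", "ethnicity", key, r$ethnicity, function(v)
      cv_eq(p$fields$ethnicity, "ethnicity", v))
  }

  # diagnoses: carried as extensions on the patient ----------------------
  find_ext <- function(p, url) {
    for (e in p$extensions) if (identical(e$url, url)) return(e)
    NULL
  }
  for (i in seq_len(nrow(extract$diagnoses))) {
    r <- extract$diagnoses[i, ]
    key <- paste0(r$patient_id, ":", r$phecode)
    p <- pget(pid(r$patient_id))
    drop_key <- r$patient_id  # diagnoses drop with their patient
    if (is.null(p)) {
      ok <- dropped("patients", drop_key)
      for (col in c("phecode", "label", "onset_date")) {
        if (present(r[[col]])) cell("diagnoses", col, key, "dropped", ok)
      }
      next
    }
    url <- paste0(mapping$extension_base, DIAG_EXT_PREFIX, r$phecode)
    e <- find_ext(p, url)
    if (present(r$phecode)) {
      cell("diagnoses", "phecode", key, "extension",
           !is.null(e) && is_coded_value(e$value) && identical(e$value$code, r$phecode))
    }
    if (present(r$label)) {
      cell("diagnoses", "label", key, "extension",
           !is.null(e) && is_coded_value(e$value) && identical(e$value$display, r$label))
    }
    if (present(r$onset_date)) {
      oe <- find_ext(p, paste0(url, "/onset"))
      cell("diagnoses", "onset_date", key, "extension",
           !is.null(oe) && identical(oe$value, r$onset_date))
    }
  }

  # reports ---------------------------------------------------------------
  for (i in seq_len(nrow(extract$reports))) {
    r <- extract$reports[i, ]
    key <- r$report_id
    p <- pget(rid(key))
    id_check("reports", "report_id", key, !is.null(p))
    if (is.null(p)) next
    id_check("reports", "patient_id", key,
             identical(p$subject_ref, pid(r$patient_id)))
    id_check("reports", "specimen_id", key,
             identical(p$fields$specimen_ref, sid(r$specimen_id)))
    check("reports", "test_date", key, r$test_date,
          function(v) identical(p$fields$test_date, v))
    regions <- r$regions_studied[[1]]
    if (length(regions)) {
      g <- pget(gid(key))
      syms <- if (!is.null(g)) vapply(g$fields$genes, function(x) x$display %||% "",
                                      character(1)) else character()
      cell("reports", "regions_studied", key, "field",
           setequal(syms, regions))
    }
  }

  # variants --------------------------------------------------------------
  ord <- stats::ave(seq_len(nrow(extract$variants)), extract$variants$report_id,
                    FUN = seq_along)
  for (i in seq_len(nrow(extract$variants))) {
    r <- extract$variants[i, ]
    key <- paste0(r$report_id, ":", ord[i])
    p <- pget(vid(r$report_id, ord[i]))
    if (is.null(p)) {
      ok <- dropped("reports", r$report_id)
      for (col in setdiff(names(r), "report_id")) {
        if (present(r[[col]])) cell("variants", col, key, "dropped", ok)
      }
      id_check("variants", "report_id", r$report_id, ok)
      next
    }
    id_check("variants", "report_id", key, TRUE)
    check("variants", "gene_symbol", key, r$gene_symbol, function(v)
      is_coded_value(p$fields$gene) && identical(p$fields$gene$display, v))
    check("variants", "dna_change", key, r$dna_change, function(v)
      is_coded_value(p$fields$dna_change) && identical(p$fields$dna_change$code, v))
    check("variants", "dna_change_type", key, r$dna_change_type, function(v)
      cv_eq(p$fields$dna_change_type, "dna_change_type", v))
    check("variants", "genomic_source_class", key, r$genomic_source_class,
          function(v) cv_eq(p$fields$genomic_source_class, "genomic_source_class", v))
    check("variants", "amino_acid_change", key, r$amino_acid_change, function(v)
      is_coded_value(p$fields$amino_acid_change) &&
        identical(p$fields$amino_acid_change$code, v))
    check("variants", "allelic_frequency", key, r$allelic_frequency, function(v)
      isTRUE(all.equal(p$fields$allelic_frequency, as.numeric(v))))
    check("variants", "clinical_significance", key, r$clinical_significance,
          function(v) cv_eq(p$fields$clinical_significance, "clinical_significance", v))
  }

  # specimens -------------------------------------------------------------
  for (i in seq_len(nrow(extract$specimens))) {
    r <- extract$specimens[i, ]
    key <- r$specimen_id
    p <- pget(sid(key))
    id_check("specimens", "specimen_id", key, !is.null(p))
    if (is.null(p)) next
    id_check("specimens", "patient_id", key,
             identical(p$subject_ref, pid(r$patient_id)))
    check("specimens", "specimen_type", key, r$specimen_type, function(v)
      cv_eq(p$fields$specimen_type, "specimen_type", v))
    check("specimens", "collected_date", key, r$collected_date, function(v)
      identical(p$fields$collected_date, v))
  }

  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}
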