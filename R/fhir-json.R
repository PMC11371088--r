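# FHIR R4 JSON serialization of mCODE profiles, both directions.
#
# Serialization is canonical: keys are sorted recursively and output is
# compact UTF-8, so structurally equal profiles serialize to identical
# bytes. Data-absent reasons are emitted with FHIR's dataAbsentReason
# machinery (component dataAbsentReason for Observation components,
# primitive-companion `_field` extensions elsewhere) and local extensions
# are emitted on their anchor element.

LOINC_DISPLAY <- c(
  `69548-6` = "Genetic variant assessment",
  `81247-9` = "Master HL7 genetic variant reporting panel",
  `53041-0` = "DNA region of interest panel",
  `48018-6` = "Gene studied [ID]",
  `48004-6` = "DNA change (c.HGVS)",
  `48019-4` = "DNA change type",
  `48002-0` = "Genomic source class [Type]",
  `48005-3` = "Amino acid change (pHGVS)",
  `81258-6` = "Sample variant allelic frequency",
  `53037-8` = "Genetic variation clinical significance"
)

VARIANT_COMPONENT_CODES <- c(
  gene = "48018-6", dna_change = "48004-6", dna_change_type = "48019-4",
  genomic_source_class = "48002-0", amino_acid_change = "48005-3",
  allelic_frequency = "81258-6", clinical_significance = "53037-8"
)

compact <- function(x) x[!vapply(x, is.null, logical(1))]

loinc_cc <- function(code) {
  list(coding = list(list(system = fhir_systems$loinc, code = unname(code),
                          display = unname(LOINC_DISPLAY[code]))))
}

cc_to_list <- function(cv) {
  list(coding = list(compact(list(system = cv$system, code = cv$code,
                                  display = cv$display))))
}

cc_from_list <- function(x) {
  c1 <- x$coding[[1]]
  coded_value(c1$system, c1$code, c1$display)
}

dar_cc <- function(reason) {
  list(coding = list(list(system = fhir_systems$data_absent_reason,
                          code = reason)))
}

dar_ext <- function(reason) list(url = DAR_EXTENSION_URL, valueCode = reason)

ext_to_list <- function(e) {
  v <- e$value
  out <- list(url = e$url)
  if (is_coded_value(v)) {
    out$valueCoding <- compact(list(system = v$system, code = v$code,
                                    display = v$display))
  } else if (is.character(v)) {
    out$valueString <- v
  } else if (is.logical(v)) {
    out$valueBoolean <- v
  } else if (is.numeric(v)) {
    out$valueDecimal <- v
  }
  out
}

ext_from_list <- function(x, anchor) {
  value <- if (!is.null(x$valueCoding)) {
    cc1 <- x$valueCoding
    coded_value(cc1$system, cc1$code, cc1$display)
  } else if (!is.null(x$valueString)) x$valueString
  else if (!is.null(x$valueBoolean)) x$valueBoolean
  else if (!is.null(x$valueDecimal)) x$valueDecimal
  else abort(paste0("extension without a supported value: ", x$url))
  list(url = x$url, value = value, anchor_path = anchor)
}

exts_for <- function(profile, anchor) {
  keep <- vapply(profile$extensions, function(e) e$anchor_path == anchor,
                 logical(1))
  lapply(profile$extensions[keep], ext_to_list)
}

# Element-companion list for a primitive field: DAR extension first, then
# anchored local extensions; NULL when neither applies.
companion <- function(profile, field) {
  exts <- exts_for(profile, field)
  if (field %in% names(profile$absent_reasons)) {
    exts <- c(list(dar_ext(profile$absent_reasons[[field]])), exts)
  }
  if (length(exts)) list(extension = exts) else NULL
}

ref_str <- function(type, id) paste0(type, "/", id)
ref_id <- function(x) sub("^[A-Za-z]+/", "", x)

canonical_sort <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x))) x <- x[order(names(x))]
  lapply(x, canonical_sort)
}

resource_shell <- function(profile) {
  list(resourceType = unname(RESOURCE_TYPES[[profile$kind]]),
       id = profile$resource_id,
       meta = list(profile = list(unname(MCODE_PROFILE_URLS[[profile$kind]]))))
}

fhir_list_CancerPatient <- function(p) {
  x <- resource_shell(p)
  if (field_populated(p$fields$birth_date)) x$birthDate <- p$fields$birth_date
  cb <- companion(p, "birth_date")
  if (!is.null(cb)) x[["_birthDate"]] <- cb
  if (field_populated(p$fields$sex)) x$gender <- p$fields$sex
  cg <- companion(p, "sex")
  if (!is.null(cg)) x[["_gender"]] <- cg
  entries <- list()
  for (f in c("race", "ethnicity")) {
    url <- if (f == "race") US_CORE_RACE_URL else US_CORE_ETHNICITY_URL
    entry <- list(url = url)
    v <- p$fields[[f]]
    if (field_populated(v)) {
      entry$valueCoding <- compact(list(system = v$system, code = v$code,
                                        display = v$display))
    }
    comp <- companion(p, f)
    if (!is.null(comp)) entry$extension <- comp$extension
    if (!is.null(entry$valueCoding) || !is.null(entry$extension)) {
      entries[[length(entries) + 1L]] <- entry
    }
  }
  entries <- c(entries, exts_for(p, "resource"))
  if (length(entries)) x$extension <- entries
  x
}

parse_companion <- function(comp, field, state) {
  for (e in comp$extension %||% list()) {
    if (identical(e$url, DAR_EXTENSION_URL)) {
      state$absent[[field]] <- e$valueCode
    } else {
      state$exts[[length(state$exts) + 1L]] <- ext_from_list(e, field)
    }
  }
  state
}

parse_CancerPatient <- function(x, extension_base = DEFAULT_EXTENSION_BASE) {
  fields <- list()
  state <- list(absent = list(), exts = list(), extension_base = extension_base)
  if (!is.null(x$birthDate)) fields$birth_date <- x$birthDate
  if (!is.null(x[["_birthDate"]])) state <- parse_companion(x[["_birthDate"]], "birth_date", state)
  if (!is.null(x$gender)) fields$sex <- x$gender
  if (!is.null(x[["_gender"]])) state <- parse_companion(x[["_gender"]], "sex", state)
  for (entry in x$extension %||% list()) {
    if (identical(entry$url, US_CORE_RACE_URL) ||
        identical(entry$url, US_CORE_ETHNICITY_URL)) {
      f <- if (identical(entry$url, US_CORE_RACE_URL)) "race" else "ethnicity"
      if (!is.null(entry$valueCoding)) {
        vc <- entry$valueCoding
        fields[[f]] <- coded_value(vc$system, vc$code, vc$display)
      }
      state <- parse_companion(list(extension = entry$extension), f, state)
    } else if (identical(entry$url, DAR_EXTENSION_URL)) {
      # not produced by the serializer at root; ignore defensively
    } else {
      state$exts[[length(state$exts) + 1L]] <- ext_from_list(entry, "resource")
    }
  }
  finish_parse("CancerPatient", x, NULL, fields, state)
}

fhir_list_GenomicVariant <- function(p) {
  x <- resource_shell(p)
  x$status <- "final"
  x$code <- loinc_cc("69548-6")
  x$subject <- list(reference = ref_str("Patient", p$subject_ref))
  comps <- list()
  for (f in names(VARIANT_COMPONENT_CODES)) {
    v <- p$fields[[f]]
    dar <- p$absent_reasons[names(p$absent_reasons) == f]
    exts <- exts_for(p, f)
    if (!field_populated(v) && !length(dar) && !length(exts)) next
    comp <- list(code = loinc_cc(VARIANT_COMPONENT_CODES[[f]]))
    if (field_populated(v)) {
      if (f == "allelic_frequency") {
        comp$valueQuantity <- list(value = unname(v),
                                   system = "http://unitsofmeasure.org",
                                   code = "1")
      } else {
        comp$valueCodeableConcept <- cc_to_list(v)
      }
    }
    if (length(dar)) comp$dataAbsentReason <- dar_cc(unname(dar[[1]]))
    if (length(exts)) comp$extension <- exts
    comps[[length(comps) + 1L]] <- comp
  }
  if (length(comps)) x$component <- comps
  rexts <- exts_for(p, "resource")
  if (length(rexts)) x$extension <- rexts
  x
}

parse_GenomicVariant <- function(x, extension_base = DEFAULT_EXTENSION_BASE) {
  fields <- list()
  state <- list(absent = list(), exts = list(), extension_base = extension_base)
  for (comp in x$component %||% list()) {
    code <- comp$code$coding[[1]]$code
    f <- names(VARIANT_COMPONENT_CODES)[match(code, VARIANT_COMPONENT_CODES)]
    if (is.na(f)) abort(paste0("unknown variant component code: ", code))
    if (!is.null(comp$valueCodeableConcept)) {
      fields[[f]] <- cc_from_list(comp$valueCodeableConcept)
    }
    if (!is.null(comp$valueQuantity)) fields[[f]] <- comp$valueQuantity$value
    if (!is.null(comp$dataAbsentReason)) {
      state$absent[[f]] <- comp$dataAbsentReason$coding[[1]]$code
    }
    state <- parse_companion(list(extension = comp$extension), f, state)
  }
  state <- parse_root_exts(x, state)
  finish_parse("GenomicVariant", x, ref_id(x$subject$reference), fields, state)
}

fhir_list_GenomicRegionStudied <- function(p) {
  x <- resource_shell(p)
  x$status <- "final"
  x$code <- loinc_cc("53041-0")
  x$subject <- list(reference = ref_str("Patient", p$subject_ref))
  comps <- list()
  genes <- p$fields$genes
  if (field_populated(genes)) {
    comps <- lapply(genes, function(g) {
      list(code = loinc_cc("48018-6"), valueCodeableConcept = cc_to_list(g))
    })
  }
  dar <- p$absent_reasons[names(p$absent_reasons) == "genes"]
  if (length(dar)) {
    comps[[length(comps) + 1L]] <- list(code = loinc_cc("48018-6"),
                                        dataAbsentReason = dar_cc(unname(dar[[1]])))
  }
  exts <- exts_for(p, "genes")
  if (length(exts)) {
    if (!length(comps)) comps <- list(list(code = loinc_cc("48018-6")))
    comps[[1]]$extension <- exts
  }
  if (length(comps)) x$component <- comps
  rexts <- exts_for(p, "resource")
  if (length(rexts)) x$extension <- rexts
  x
}

parse_GenomicRegionStudied <- function(x, extension_base = DEFAULT_EXTENSION_BASE) {
  fields <- list()
  state <- list(absent = list(), exts = list(), extension_base = extension_base)
  genes <- list()
  for (comp in x$component %||% list()) {
    if (!is.null(comp$valueCodeableConcept)) {
      genes[[length(genes) + 1L]] <- cc_from_list(comp$valueCodeableConcept)
    }
    if (!is.null(comp$dataAbsentReason)) {
      state$absent[["genes"]] <- comp$dataAbsentReason$coding[[1]]$code
    }
    state <- parse_companion(list(extension = comp$extension), "genes", state)
  }
  if (length(genes)) fields$genes <- genes
  state <- parse_root_exts(x, state)
  finish_parse("GenomicRegionStudied", x, ref_id(x$subject$reference), fields, state)
}

REF_DISPLAY <- c(result_refs = "Genomic Variant",
                 region_refs = "Genomic Region Studied")

fhir_list_GenomicsReport <- function(p) {
  x <- resource_shell(p)
  x$status <- "final"
  x$code <- loinc_cc("81247-9")
  x$subject <- list(reference = ref_str("Patient", p$subject_ref))
  if (field_populated(p$fields$test_date)) {
    x$effectiveDateTime <- p$fields$test_date
  }
  ce <- companion(p, "test_date")
  if (!is.null(ce)) x[["_effectiveDateTime"]] <- ce
  # specimen
  sp <- p$fields$specimen_ref
  sp_comp <- companion(p, "specimen_ref")
  if (field_populated(sp) || !is.null(sp_comp)) {
    entry <- list()
    if (field_populated(sp)) entry$reference <- ref_str("Specimen", sp)
    if (!is.null(sp_comp)) entry$extension <- sp_comp$extension
    x$specimen <- list(entry)
  }
  # result: variant refs then region refs, distinguished by display
  entries <- list()
  for (f in c("result_refs", "region_refs")) {
    ids <- p$fields[[f]] %||% character()
    sub <- lapply(ids, function(id) {
      list(reference = ref_str("Observation", id),
           display = unname(REF_DISPLAY[[f]]))
    })
    comp <- companion(p, f)
    if (!is.null(comp)) {
      if (!length(sub)) sub <- list(list(display = unname(REF_DISPLAY[[f]])))
      sub[[1]]$extension <- comp$extension
    }
    entries <- c(entries, sub)
  }
  if (length(entries)) x$result <- entries
  rexts <- exts_for(p, "resource")
  if (length(rexts)) x$extension <- rexts
  x
}

parse_GenomicsReport <- function(x, extension_base = DEFAULT_EXTENSION_BASE) {
  fields <- list()
  state <- list(absent = list(), exts = list(), extension_base = extension_base)
  if (!is.null(x$effectiveDateTime)) fields$test_date <- x$effectiveDateTime
  if (!is.null(x[["_effectiveDateTime"]])) {
    state <- parse_companion(x[["_effectiveDateTime"]], "test_date", state)
  }
  for (entry in x$specimen %||% list()) {
    if (!is.null(entry$reference)) fields$specimen_ref <- ref_id(entry$reference)
    state <- parse_companion(list(extension = entry$extension), "specimen_ref", state)
  }
  refs <- list(result_refs = character(), region_refs = character())
  for (entry in x$result %||% list()) {
    f <- names(REF_DISPLAY)[match(entry$display, REF_DISPLAY)]
    if (is.na(f)) abort(paste0("unrecognized result display: ", entry$display))
    if (!is.null(entry$reference)) refs[[f]] <- c(refs[[f]], ref_id(entry$reference))
    state <- parse_companion(list(extension = entry$extension), f, state)
  }
  for (f in names(refs)) if (length(refs[[f]])) fields[[f]] <- refs[[f]]
  state <- parse_root_exts(x, state)
  finish_parse("GenomicsReport", x, ref_id(x$subject$reference), fields, state)
}

fhir_list_GenomicSpecimen <- function(p) {
  x <- resource_shell(p)
  x$subject <- list(reference = ref_str("Patient", p$subject_ref))
  tv <- p$fields$specimen_type
  tcomp <- companion(p, "specimen_type")
  if (field_populated(tv) || !is.null(tcomp)) {
    entry <- if (field_populated(tv)) cc_to_list(tv) else list()
    if (!is.null(tcomp)) entry$extension <- tcomp$extension
    x$type <- entry
  }
  coll <- list()
  if (field_populated(p$fields$collected_date)) {
    coll$collectedDateTime <- p$fields$collected_date
  }
  ccomp <- companion(p, "collected_date")
  if (!is.null(ccomp)) coll[["_collectedDateTime"]] <- ccomp
  if (length(coll)) x$collection <- coll
  rexts <- exts_for(p, "resource")
  if (length(rexts)) x$extension <- rexts
  x
}

parse_GenomicSpecimen <- function(x, extension_base = DEFAULT_EXTENSION_BASE) {
  fields <- list()
  state <- list(absent = list(), exts = list(), extension_base = extension_base)
  if (!is.null(x$type)) {
    if (!is.null(x$type$coding)) fields$specimen_type <- cc_from_list(x$type)
    state <- parse_companion(list(extension = x$type$extension), "specimen_type", state)
  }
  if (!is.null(x$collection)) {
    if (!is.null(x$collection$collectedDateTime)) {
      fields$collected_date <- x$collection$collectedDateTime
    }
    if (!is.null(x$collection[["_collectedDateTime"]])) {
      state <- parse_companion(x$collection[["_collectedDateTime"]],
                               "collected_date", state)
    }
  }
  state <- parse_root_exts(x, state)
  finish_parse("GenomicSpecimen", x, ref_id(x$subject$reference), fields, state)
}

parse_root_exts <- function(x, state) {
  for (e in x$extension %||% list()) {
    state$exts[[length(state$exts) + 1L]] <- ext_from_list(e, "resource")
  }
  state
}

finish_parse <- function(kind, x, subject_ref, fields, state) {
  p <- mcode_profile(kind, x$id, subject_ref = subject_ref, fields = fields,
                     extension_base = state$extension_base %||% DEFAULT_EXTENSION_BASE)
  p$absent_reasons <- unlist(state$absent) %||% character()
  if (!is.character(p$absent_reasons)) p$absent_reasons <- character()
  p$extensions <- state$exts
  normalize_profile(p)
}

profile_to_fhir_list <- function(profile) {
  switch(profile$kind,
    CancerPatient = fhir_list_CancerPatient(profile),
    GenomicsReport = fhir_list_GenomicsReport(profile),
    GenomicVariant = fhir_list_GenomicVariant(profile),
    GenomicRegionStudied = fhir_list_GenomicRegionStudied(profile),
    GenomicSpecimen = fhir_list_GenomicSpecimen(profile)
  )
}

#' Serialize a profile to canonical FHIR R4 JSON
#'
#' Emits a single FHIR-shaped JSON document: `resourceType` per kind
#' (Patient / DiagnosticReport / Observation / Specimen), `meta.profile`
#' carrying the mCODE canonical URL, coded fields as CodeableConcepts,
#' absences as FHIR dataAbsentReason extensions, and local extensions on
#' their anchor elements. Output is canonical (recursively sorted keys,
#' compact), so equal profiles give byte-identical text.
#'
#' @param profile A valid `mcode_profile`; an invalid profile is rejected
#'   with its [validate_profile()] report attached to the error condition.
#' @return A JSON string.
#' @export
to_fhir_json <- function(profile) {
  report <- validate_profile(profile)
  if (!report$valid) {
    abort(paste0("profile ", profile$resource_id %||% "?",
                 " fails validation: ",
                 paste(report$findings$message[report$findings$severity == "error"],
                       collapse = "; ")),
          class = "mcodeflow_invalid_profile", report = report)
  }
  x <- canonical_sort(profile_to_fhir_list(profile))
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Reconstruct a profile from FHIR JSON
#'
#' Inverse of [to_fhir_json()]: rebuilds the profile including data-absent
#' reasons and anchored extensions. Malformed JSON, an unknown
#' `resourceType`, and a missing `meta.profile` each raise distinct errors.
#'
#' @param text A JSON string.
#' @param extension_base Namespace recorded on the reconstructed profile for
#'   its local extensions (the serialization itself is namespace-agnostic).
#' @return An `mcode_profile`.
#' @export
from_fhir_json <- function(text, extension_base = DEFAULT_EXTENSION_BASE) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) abort(paste0("malformed JSON: ",
                                                 conditionMessage(e)),
                                          class = "mcodeflow_parse_error"))
  from_fhir_list(x, extension_base)
}

from_fhir_list <- function(x, extension_base = DEFAULT_EXTENSION_BASE) {
  rt <- x$resourceType
  if (is.null(rt) || !rt %in% RESOURCE_TYPES) {
    abort(paste0("unknown resourceType: ", rt %||% "<missing>"),
          class = "mcodeflow_unknown_kind")
  }
  purl <- x$meta$profile[[1]] %||% NULL
  if (is.null(purl)) {
    abort("missing meta.profile", class = "mcodeflow_missing_profile")
  }
  kind <- names(MCODE_PROFILE_URLS)[match(purl, MCODE_PROFILE_URLS)]
  if (is.na(kind)) {
    abort(paste0("unknown profile canonical URL: ", purl),
          class = "mcodeflow_unknown_kind")
  }
  switch(kind,
    CancerPatient = parse_CancerPatient(x, extension_base),
    GenomicsReport = parse_GenomicsReport(x, extension_base),
    GenomicVariant = parse_GenomicVariant(x, extension_base),
    GenomicRegionStudied = parse_GenomicRegionStudied(x, extension_base),
    GenomicSpecimen = parse_GenomicSpecimen(x, extension_base)
  )
}

#' Write a bundle as NDJSON
#'
#' One FHIR resource per line, mirroring bulk-import conventions.
#'
#' @param bundle A `profile_bundle` or list of profiles.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bundle_ndjson <- function(bundle, path) {
  lines <- vapply(bundle, to_fhir_json, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a bundle from NDJSON
#'
#' @param path NDJSON file, one FHIR resource per line.
#' @return A `profile_bundle`.
#' @export
read_bundle_ndjson <- function(path) {
  if (!file.exists(path)) abort(paste0("no such bundle file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  profile_bundle(lapply(lines, from_fhir_json))
}
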