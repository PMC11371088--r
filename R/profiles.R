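# Domain types for the five implemented mCODE profile kinds, must-support
# validation with data-absent-reason placeholders, and anchored extensions
# for source data that has no mCODE home.

# Field registry per profile kind. Realization drives both validation and
# FHIR serialization:
#   date/code  -> primitive element
#   coded      -> CodeableConcept
#   codedlist  -> repeated CodeableConcept (Observation components)
#   ref        -> single Reference
#   reflist    -> repeated Reference
#   number     -> Quantity
KIND_FIELDS <- list(
  CancerPatient = c(birth_date = "date", sex = "code", race = "coded",
                    ethnicity = "coded"),
  GenomicsReport = c(test_date = "date", specimen_ref = "ref",
                     result_refs = "reflist", region_refs = "reflist"),
  GenomicVariant = c(gene = "coded", dna_change = "coded",
                     dna_change_type = "coded", genomic_source_class = "coded",
                     amino_acid_change = "coded", allelic_frequency = "number",
                     clinical_significance = "coded"),
  GenomicRegionStudied = c(genes = "codedlist"),
  GenomicSpecimen = c(specimen_type = "coded", collected_date = "date")
)

#' Profile kinds implemented by the package
#'
#' The Cancer Patient profile plus the four genomics subprofiles (Genomics
#' Report, Genomic Variant, Genomic Region Studied, Genomic Specimen). The
#' registry of kinds and their must-support fields is data-driven
#' (`inst/extdata/must_support.csv`), so further kinds can be added without
#' code change.
#'
#' @return Character vector of kind names.
#' @export
profile_kinds <- function() names(KIND_FIELDS)

must_support_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_extdata_csv("must_support.csv")
    cache
  }
})

#' Must-support fields of a profile kind
#'
#' @param kind One of [profile_kinds()].
#' @return Character vector of field paths that must be populated or covered
#'   by a data-absent reason for the profile to validate.
#' @export
must_support_fields <- function(kind) {
  if (!kind %in% profile_kinds()) abort(paste0("unknown profile kind: ", kind))
  reg <- must_support_registry()
  reg$field[reg$kind == kind]
}

#' Construct a coded value
#'
#' A (code system, code, display) triple, the unit of every coded profile
#' field; serialized as a FHIR CodeableConcept.
#'
#' @param system Code-system URI (non-empty).
#' @param code Code string (non-empty).
#' @param display Optional human-readable label.
#' @return A `coded_value`.
#' @export
coded_value <- function(system, code, display = NULL) {
  assert_scalar_string(system, "system")
  assert_scalar_string(code, "code")
  if (!is.null(display)) assert_scalar_string(display, "display")
  structure(list(system = system, code = code, display = display),
            class = "coded_value")
}

is_coded_value <- function(x) inherits(x, "coded_value")

#' @export
format.coded_value <- function(x, ...) {
  paste0("[", x$code, if (!is.null(x$display)) paste0(" ", x$display), "]")
}

#' @export
print.coded_value <- function(x, ...) {
  cat("<coded_value>", x$system, x$code, x$display %||% "", "\n")
  invisible(x)
}

field_populated <- function(value) {
  !is.null(value) && length(value) > 0L &&
    !(is.atomic(value) && all(is.na(value)))
}

#' Construct an mCODE profile
#'
#' @param kind One of [profile_kinds()].
#' @param resource_id Opaque resource identifier.
#' @param subject_ref Resource id of the owning CancerPatient (absent only
#'   for CancerPatient profiles).
#' @param fields Named list of payload fields; names must belong to the
#'   kind's field registry. Coded fields take [coded_value()] objects;
#'   `genes` a list of coded values; `*_refs` character vectors.
#' @param extension_base Namespace URI under which local extensions live.
#' @return An `mcode_profile`.
#' @export
mcode_profile <- function(kind, resource_id, subject_ref = NULL,
                          fields = list(),
                          extension_base = DEFAULT_EXTENSION_BASE) {
  if (!kind %in% profile_kinds()) abort(paste0("unknown profile kind: ", kind))
  assert_scalar_string(resource_id, "resource_id")
  if (kind != "CancerPatient") {
    if (!is.null(subject_ref)) assert_scalar_string(subject_ref, "subject_ref")
  } else if (!is.null(subject_ref)) {
    abort("CancerPatient profiles carry no subject_ref")
  }
  unknown <- setdiff(names(fields), names(KIND_FIELDS[[kind]]))
  if (length(unknown)) {
    abort(paste0("unknown field(s) for ", kind, ": ",
                 paste(unknown, collapse = ", ")))
  }
  fields <- fields[lengths(fields) > 0L]
  p <- structure(
    list(kind = kind, resource_id = resource_id, subject_ref = subject_ref,
         fields = fields, absent_reasons = character(), extensions = list(),
         extension_base = extension_base),
    class = "mcode_profile"
  )
  normalize_profile(p)
}

# Deterministic internal ordering so structurally equal profiles compare
# equal and serialize to identical bytes.
normalize_profile <- function(p) {
  order_f <- names(KIND_FIELDS[[p$kind]])
  p$fields <- p$fields[intersect(order_f, names(p$fields))]
  if (length(p$absent_reasons)) {
    p$absent_reasons <- p$absent_reasons[order(names(p$absent_reasons))]
  }
  if (length(p$extensions)) {
    p$extensions <- p$extensions[order(vapply(p$extensions, `[[`, "", "url"))]
  }
  p
}

#' @export
print.mcode_profile <- function(x, ...) {
  cat("<mcode_profile>", x$kind, x$resource_id, "\n")
  cat("  populated:", paste(names(x$fields), collapse = ", "), "\n")
  if (length(x$absent_reasons)) {
    cat("  absent:", paste(names(x$absent_reasons), x$absent_reasons,
                           sep = "=", collapse = ", "), "\n")
  }
  if (length(x$extensions)) {
    cat("  extensions:", length(x$extensions), "\n")
  }
  invisible(x)
}

#' Validate an mCODE profile
#'
#' Enumerates, as findings, every must-support field that is neither
#' populated nor covered by exactly one data-absent reason, any field that
#' is both populated and declared absent, unknown reason codes, absence
#' declarations on undeclared paths, type problems on coded fields, missing
#' subject references, and out-of-range allelic fractions. Extensions never
#' produce findings. All problems are report findings, never errors.
#'
#' @param profile An `mcode_profile`.
#' @return A `validation_report`: list with `valid` (no error-severity
#'   findings) and `findings` (tibble of severity, field_path, message).
#' @export
validate_profile <- function(profile) {
  findings <- list()
  note <- function(severity, field_path, message) {
    findings[[length(findings) + 1L]] <<-
      c(severity = severity, field_path = field_path, message = message)
  }
  if (!inherits(profile, "mcode_profile")) {
    note("error", "", "not an mcode_profile")
    return(new_validation_report(findings))
  }
  kind <- profile$kind
  registry <- KIND_FIELDS[[kind]]
  ms <- must_support_fields(kind)

  dup <- names(profile$absent_reasons)[duplicated(names(profile$absent_reasons))]
  for (d in unique(dup)) note("error", d, "multiple data-absent reasons for one field")
  for (path in names(profile$absent_reasons)) {
    if (!path %in% ms) {
      note("error", path, "data-absent reason on a field that is not must-support")
    }
    reason <- profile$absent_reasons[[path]]
    if (!reason %in% DAR_REASON_CODES) {
      note("error", path, paste0("unknown data-absent reason code: ", reason))
    }
  }
  for (f in ms) {
    pop <- field_populated(profile$fields[[f]])
    covered <- f %in% names(profile$absent_reasons)
    if (pop && covered) {
      note("error", f, "field is both populated and declared absent")
    } else if (!pop && !covered) {
      note("error", f, "must-support field unpopulated and no data-absent reason")
    }
  }
  for (f in names(profile$fields)) {
    v <- profile$fields[[f]]
    if (!field_populated(v)) next
    t <- registry[[f]]
    if (t == "coded" && !is_coded_value(v)) {
      note("error", f, "expected a coded_value")
    }
    if (t == "codedlist" && !(is.list(v) && all(vapply(v, is_coded_value, logical(1))))) {
      note("error", f, "expected a list of coded_value")
    }
    if (t == "number" && !(is.numeric(v) && length(v) == 1L)) {
      note("error", f, "expected a single number")
    }
  }
  af <- profile$fields$allelic_frequency
  if (field_populated(af) && is.numeric(af) && (af < 0 || af > 1)) {
    note("error", "allelic_frequency", "allelic fraction outside [0,1]")
  }
  if (kind != "CancerPatient" && is.null(profile$subject_ref)) {
    note("error", "subject_ref", "missing subject reference")
  }
  new_validation_report(findings)
}

new_validation_report <- function(findings) {
  pick <- function(k) vapply(findings, `[[`, character(1), k)
  f <- tibble::new_tibble(list(severity = pick("severity"),
                               field_path = pick("field_path"),
                               message = pick("message")),
                          nrow = length(findings))
  structure(list(valid = !any(f$severity == "error"), findings = f),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> valid:", x$valid, "\n")
  if (nrow(x$findings)) print(x$findings)
  invisible(x)
}

#' Declare a must-support field absent with a reason
#'
#' Records a data-absent-reason placeholder for an unpopulated must-support
#' field, mirroring the load-time rule that no must-support slot may simply
#' be left empty. The input profile is not modified.
#'
#' @param profile An `mcode_profile`.
#' @param field_path A declared must-support field of the profile's kind.
#' @param reason_code One of `unknown`, `masked`, `not-performed`,
#'   `not-asked`.
#' @return A new profile carrying the reason.
#' @export
apply_data_absent_reason <- function(profile, field_path,
                                     reason_code = "unknown") {
  if (!inherits(profile, "mcode_profile")) abort("profile must be an mcode_profile")
  ms <- must_support_fields(profile$kind)
  if (!field_path %in% ms) {
    abort(paste0("not a must-support field of ", profile$kind, ": ", field_path))
  }
  if (!reason_code %in% DAR_REASON_CODES) {
    abort(paste0("unknown data-absent reason code: ", reason_code))
  }
  if (field_populated(profile$fields[[field_path]])) {
    abort(paste0("field is populated, cannot also be absent: ", field_path))
  }
  if (field_path %in% names(profile$absent_reasons)) {
    abort(paste0("field already carries a data-absent reason: ", field_path))
  }
  profile$absent_reasons[[field_path]] <- reason_code
  normalize_profile(profile)
}

#' Attach a local extension to a profile
#'
#' Carries source data that has no mCODE home, anchored to its related data
#' field (or to the resource root with `anchor_path = "resource"`).
#' Serialization emits it as a FHIR extension element on the anchor.
#'
#' @param profile An `mcode_profile`.
#' @param anchor_path A field of the profile's kind, or `"resource"`.
#' @param url Extension URL; must fall under the profile's extension base
#'   namespace and be unique within the profile.
#' @param value A scalar string/number/logical or a [coded_value()].
#' @return A new profile carrying the extension.
#' @export
attach_extension <- function(profile, anchor_path, url, value) {
  if (!inherits(profile, "mcode_profile")) abort("profile must be an mcode_profile")
  assert_scalar_string(url, "url")
  if (!startsWith(url, profile$extension_base)) {
    abort(paste0("extension url must fall under the namespace ",
                 profile$extension_base))
  }
  known <- c("resource", names(KIND_FIELDS[[profile$kind]]))
  if (!anchor_path %in% known) {
    abort(paste0("unknown anchor_path for ", profile$kind, ": ", anchor_path))
  }
  if (url %in% vapply(profile$extensions, `[[`, "", "url")) {
    abort(paste0("duplicate extension url: ", url))
  }
  ok <- is_coded_value(value) ||
    (length(value) == 1L && (is.character(value) || is.numeric(value) ||
                             is.logical(value)))
  if (!ok) abort("extension value must be a scalar primitive or a coded_value")
  profile$extensions[[length(profile$extensions) + 1L]] <-
    list(url = url, value = value, anchor_path = anchor_path)
  normalize_profile(profile)
}

#' Bundle a collection of profiles
#'
#' @param profiles List of `mcode_profile` objects.
#' @return A `profile_bundle` (validated: unique resource ids, resolvable
#'   in-bundle references).
#' @export
profile_bundle <- function(profiles = list()) {
  b <- structure(profiles, class = "profile_bundle")
  validate_bundle(b)
  b
}

#' Validate referential closure of a bundle
#'
#' Checks that resource ids are unique, that every `subject_ref` resolves to
#' a CancerPatient in the bundle, and that report result/region/specimen
#' references resolve to profiles of the right kind.
#'
#' @param bundle A `profile_bundle` (or plain list of profiles).
#' @return The bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  ids <- vapply(bundle, `[[`, "", "resource_id")
  kinds <- vapply(bundle, `[[`, "", "kind")
  d <- unique(ids[duplicated(ids)])
  if (length(d)) {
    abort(paste0("duplicate resource_id in bundle: ", paste(head(d, 3), collapse = ", ")))
  }
  patient_ids <- ids[kinds == "CancerPatient"]
  variant_ids <- ids[kinds == "GenomicVariant"]
  region_ids <- ids[kinds == "GenomicRegionStudied"]
  specimen_ids <- ids[kinds == "GenomicSpecimen"]
  for (p in bundle) {
    if (!is.null(p$subject_ref) && !p$subject_ref %in% patient_ids) {
      abort(paste0("unresolved subject_ref ", p$subject_ref, " in ", p$resource_id))
    }
    if (p$kind == "GenomicsReport") {
      bad <- setdiff(p$fields$result_refs %||% character(), variant_ids)
      if (length(bad)) {
        abort(paste0("result_refs must reference GenomicVariant profiles; unresolved: ",
                     paste(head(bad, 3), collapse = ", ")))
      }
      bad <- setdiff(p$fields$region_refs %||% character(), region_ids)
      if (length(bad)) {
        abort(paste0("unresolved region_refs: ", paste(head(bad, 3), collapse = ", ")))
      }
      sp <- p$fields$specimen_ref
      if (field_populated(sp) && !sp %in% specimen_ids) {
        abort(paste0("unresolved specimen_ref: ", sp))
      }
    }
  }
  invisible(bundle)
}

#' @export
print.profile_bundle <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat("<profile_bundle>", length(x), "profiles\n")
  print(table(kinds))
  invisible(x)
}
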