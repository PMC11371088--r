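#' @importFrom rlang abort %||% .data
#' @importFrom stats rbinom rpois runif setNames ave
#' @importFrom utils head
NULL

# Canonical code-system URIs used across profiles. Keys match the
# `code_system` column of the packaged mapping table.
fhir_systems <- list(
  hgnc                  = "http://www.genenames.org/geneId",
  hgvs                  = "http://varnomen.hgvs.org",
  `sequence-ontology`   = "http://sequenceontology.org",
  loinc                 = "http://loinc.org",
  `administrative-gender` = "http://hl7.org/fhir/administrative-gender",
  `cdc-race-ethnicity`  = "urn:oid:2.16.840.1.113883.6.238",
  `v2-0487`             = "http://terminology.hl7.org/CodeSystem/v2-0487",
  phecode               = "urn:example:phecode",
  data_absent_reason    = "http://terminology.hl7.org/CodeSystem/data-absent-reason"
)

# FHIR extension URL that flags a value as absent, and the default namespace
# under which locally-defined extensions live.
DAR_EXTENSION_URL <- "http://hl7.org/fhir/StructureDefinition/data-absent-reason"
DEFAULT_EXTENSION_BASE <- "urn:example:mcode-pilot:"
US_CORE_RACE_URL <- "http://hl7.org/fhir/us/core/StructureDefinition/us-core-race"
US_CORE_ETHNICITY_URL <- "http://hl7.org/fhir/us/core/StructureDefinition/us-core-ethnicity"

MCODE_PROFILE_URLS <- c(
  CancerPatient        = "http://hl7.org/fhir/us/mcode/StructureDefinition/mcode-cancer-patient",
  GenomicsReport       = "http://hl7.org/fhir/us/mcode/StructureDefinition/mcode-genomics-report",
  GenomicVariant       = "http://hl7.org/fhir/us/mcode/StructureDefinition/mcode-genomic-variant",
  GenomicRegionStudied = "http://hl7.org/fhir/us/mcode/StructureDefinition/mcode-genomic-region-studied",
  GenomicSpecimen      = "http://hl7.org/fhir/us/mcode/StructureDefinition/mcode-genomic-specimen"
)

RESOURCE_TYPES <- c(
  CancerPatient = "Patient", GenomicsReport = "DiagnosticReport",
  GenomicVariant = "Observation", GenomicRegionStudied = "Observation",
  GenomicSpecimen = "Specimen"
)

DAR_REASON_CODES <- c("unknown", "masked", "not-performed", "not-asked")

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "mcodeflow")
  if (!nzchar(path)) {
    # during development the package may be loaded from source
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(paste0("packaged data file not found: ", file))
  path
}

read_extdata_csv <- function(file) {
  readr::read_csv(extdata_path(file), show_col_types = FALSE, progress = FALSE)
}

#' Packaged cancer gene list
#'
#' A curated list of recurrently altered cancer genes (symbol plus HGNC id)
#' used by the synthetic cohort generator and by code translation. The list
#' ships as an editable CSV data file.
#'
#' @return A tibble with columns `symbol` and `hgnc_id`.
#' @export
cancer_genes <- function() read_extdata_csv("cancer_genes.csv")

#' Packaged neoplasm Phecode list
#'
#' Neoplasm Phecodes (code plus human-readable label) used to code synthetic
#' cancer diagnoses. The set is aligned one-to-one with the packaged
#' TCGA-style cancer label set.
#'
#' @return A tibble with columns `phecode` and `label`.
#' @export
neoplasm_phecodes <- function() {
  out <- read_extdata_csv("neoplasm_phecodes.csv")
  out$phecode <- as.character(out$phecode)
  out
}

#' TCGA-style cancer label set
#'
#' The 33 study abbreviations of the TCGA program, used as the label set of
#' the incidence calculator. The Phecode-to-label mapping is a synthetic
#' one-to-one stand-in shipped alongside (`phecode_tcga_map()`).
#'
#' @return A tibble with columns `tcga_label` and `description`.
#' @export
cancer_labels <- function() read_extdata_csv("tcga_labels.csv")

#' Phecode to TCGA-label mapping
#'
#' @return A tibble with columns `phecode` and `tcga_label`.
#' @export
phecode_tcga_map <- function() {
  out <- read_extdata_csv("phecode_tcga_map.csv")
  out$phecode <- as.character(out$phecode)
  out
}

# Deterministic sub-seed per named random stream, derived from one user seed.
# Keeps each generated table on its own RNG stream.
sub_seed <- function(seed, stream) {
  offsets <- c(patients = 1L, reports = 2L, variants = 3L, specimens = 4L,
               diagnoses = 5L, missingness = 6L, generic = 7L)
  k <- offsets[[stream]]
  (as.integer(seed) %% 20000003L) * 97L + k * 1009L
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_scalar_string <- function(x, what) {
  if (!is_scalar_string(x) || !nzchar(x)) {
    abort(paste0(what, " must be a non-empty string"))
  }
  invisible(x)
}
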