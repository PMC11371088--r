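# Shared fixtures and independent oracles used across the test files.

# One small end-to-end fixture, built once per test run: extract -> bundle ->
# loaded store. Kept small so every file can lean on it cheaply.
fixture_env <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (!is.null(fixture_env$fx)) return(fixture_env$fx)
  cfg <- cohort_config(n_patients = 40, seed = 20240901L, missingness = 0.15)
  extract <- generate_cohort(cfg)
  mapping <- mapping_table()
  bundle <- transform_cohort(extract, mapping)
  store <- profile_store()
  load_bundle(bundle, store)
  fixture_env$fx <- list(cfg = cfg, extract = extract, mapping = mapping,
                         bundle = bundle, store = store)
  fixture_env$fx
}

bundle_kinds <- function(bundle) vapply(bundle, `[[`, character(1), "kind")
bundle_ids <- function(bundle) vapply(bundle, `[[`, character(1), "resource_id")

profiles_of_kind <- function(bundle, kind) bundle[bundle_kinds(bundle) == kind]

# Expected bundle size straight from the extract tables: patients + reports +
# variant rows + reports with a non-empty region list + specimens.
expected_profile_count <- function(extract) {
  regions <- extract$reports$regions_studied
  n_regions <- sum(vapply(regions, length, integer(1)) > 0L)
  nrow(extract$patients) + nrow(extract$reports) + nrow(extract$variants) +
    n_regions + nrow(extract$specimens)
}

# Brute-force incidence counting over the raw profile list, bypassing the
# store, its index, and the incidence implementation entirely.
oracle_incidence <- function(bundle, gene, label) {
  map <- phecode_tcga_map()
  pats <- profiles_of_kind(bundle, "CancerPatient")
  diag_of <- function(p) {
    codes <- vapply(p$extensions, function(e) {
      rel <- substring(e$url, nchar(p$extension_base) + 1L)
      if (startsWith(rel, "diagnosis/") && !endsWith(rel, "/onset") &&
          inherits(e$value, "coded_value")) e$value$code else NA_character_
    }, character(1))
    codes[!is.na(codes)]
  }
  plabels <- lapply(pats, function(p)
    unique(map$tcga_label[map$phecode %in% diag_of(p)]))
  names(plabels) <- bundle_ids(pats)
  vars <- profiles_of_kind(bundle, "GenomicVariant")
  carrier <- unique(vapply(
    vars[vapply(vars, function(v) {
      g <- v$fields$gene
      !is.null(g) && identical(g$display, gene)
    }, logical(1))],
    `[[`, character(1), "subject_ref"))
  n <- length(pats)
  count_v <- length(carrier)
  count_c <- sum(vapply(plabels, function(l) label %in% l, logical(1)))
  count_vc <- sum(vapply(carrier, function(id) label %in% plabels[[id]],
                         logical(1)))
  list(n = n, count_v = count_v, count_c = count_c, count_vc = count_vc)
}

# Brute-force search match set over the raw profile list (conjunctive
# semantics re-derived from first principles, not from the store index).
oracle_match_ids <- function(bundle, as_of, resource_type = NULL, sex = NULL,
                             gene = NULL, phecode = NULL,
                             age_min = NULL, age_max = NULL) {
  kinds <- bundle_kinds(bundle)
  rtypes <- c(CancerPatient = "Patient", GenomicsReport = "DiagnosticReport",
              GenomicVariant = "Observation",
              GenomicRegionStudied = "Observation",
              GenomicSpecimen = "Specimen")
  pats <- profiles_of_kind(bundle, "CancerPatient")
  pat_ids <- bundle_ids(pats)
  sex_map <- c(f = "female", m = "male")
  pat_ok <- rep(TRUE, length(pats))
  restricted <- FALSE
  if (!is.null(sex)) {
    restricted <- TRUE
    want <- unname(sex_map[tolower(sex)])
    if (is.na(want)) want <- tolower(sex)
    pat_ok <- pat_ok & vapply(pats, function(p)
      identical(p$fields$sex, want), logical(1))
  }
  if (!is.null(age_min) || !is.null(age_max)) {
    restricted <- TRUE
    ages <- vapply(pats, function(p) {
      bd <- p$fields$birth_date
      if (is.null(bd)) return(NA_real_)
      floor(as.numeric(as.Date(as_of) - as.Date(bd)) / 365.25)
    }, numeric(1))
    ok <- !is.na(ages)
    if (!is.null(age_min)) ok <- ok & ages >= age_min
    if (!is.null(age_max)) ok <- ok & ages <= age_max
    pat_ok <- pat_ok & ok
  }
  if (!is.null(phecode)) {
    restricted <- TRUE
    pat_ok <- pat_ok & vapply(pats, function(p) {
      any(vapply(p$extensions, function(e) {
        rel <- substring(e$url, nchar(p$extension_base) + 1L)
        startsWith(rel, "diagnosis/") && !endsWith(rel, "/onset") &&
          inherits(e$value, "coded_value") && identical(e$value$code, phecode)
      }, logical(1)))
    }, logical(1))
  }
  if (!is.null(gene)) {
    restricted <- TRUE
    vars <- profiles_of_kind(bundle, "GenomicVariant")
    carriers <- unique(vapply(
      vars[vapply(vars, function(v) {
        g <- v$fields$gene
        !is.null(g) && (identical(g$display, gene) || identical(g$code, gene))
      }, logical(1))],
      `[[`, character(1), "subject_ref"))
    pat_ok <- pat_ok & pat_ids %in% carriers
  }
  allowed_subjects <- if (restricted) pat_ids[pat_ok] else NULL
  keep <- vapply(seq_along(bundle), function(i) {
    p <- bundle[[i]]
    if (!is.null(resource_type) &&
        !(p$kind == resource_type || rtypes[[p$kind]] == resource_type)) {
      return(FALSE)
    }
    if (!is.null(allowed_subjects)) {
      subj <- if (p$kind == "CancerPatient") p$resource_id else p$subject_ref
      if (is.null(subj) || !subj %in% allowed_subjects) return(FALSE)
    }
    # the gene predicate additionally restricts variant profiles themselves
    if (!is.null(gene) && p$kind == "GenomicVariant") {
      g <- p$fields$gene
      if (is.null(g) || !(identical(g$display, gene) || identical(g$code, gene))) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  sort(bundle_ids(bundle)[keep])
}
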