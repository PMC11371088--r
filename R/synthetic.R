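# Synthetic Clarity-style extract generator.
#
# Real oncology EHR extracts (Epic Clarity exports) are private; this module
# emulates their content so the downstream ETL, store and analytics are fully
# testable. Five related tables are produced: patients, diagnoses, genomic
# test reports, gene-variant observations and specimens, linked by opaque
# identifiers.

MASKABLE_FIELDS <- c(
  "race", "ethnicity",                      # patients
  "dna_change_type", "genomic_source_class", "amino_acid_change",
  "allelic_frequency", "clinical_significance"  # variants
)

EXTRACT_COLUMNS <- list(
  patients  = c("patient_id", "birth_date", "sex", "race", "ethnicity"),
  diagnoses = c("patient_id", "phecode", "label", "onset_date"),
  reports   = c("report_id", "patient_id", "specimen_id", "test_date",
                "regions_studied"),
  variants  = c("report_id", "gene_symbol", "dna_change", "dna_change_type",
                "genomic_source_class", "amino_acid_change",
                "allelic_frequency", "clinical_significance"),
  specimens = c("specimen_id", "patient_id", "specimen_type", "collected_date")
)

#' Configure a synthetic cohort
#'
#' Describes the statistical structure of a generated extract: cohort size,
#' the gene and Phecode vocabularies, the variant yield per report, the
#' gene-conditional diagnosis model, per-field missingness and the RNG seed.
#'
#' The diagnosis model gives, per gene, a named vector of Bernoulli
#' probabilities over Phecodes: a patient carrying gene *g* receives
#' diagnosis *c* with probability `diagnosis_model[[g]][[c]]`, independently
#' per carried gene, and a patient's diagnosis set is the union of the
#' triggered codes. When no other carried gene loads on the same Phecode the
#' configured weight is exactly the population conditional probability
#' P(diagnosis | carrier), which makes the generator's parameters
#' statistically recoverable from its output.
#'
#' @param n_patients Number of patients (non-negative integer).
#' @param genes Character vector of gene symbols to draw variants from.
#' @param cancer_phecodes Tibble/data frame with columns `phecode`, `label`.
#' @param variant_rate Mean number of variants per report (Poisson, >= 0).
#' @param reports_per_patient Genomic reports per patient (positive integer).
#' @param diagnosis_model Named list: gene -> named numeric vector of
#'   per-Phecode conditional probabilities in \[0,1\]. Defaults to a sparse
#'   model assigning each gene one strongly and one weakly associated cancer.
#' @param missingness Either a single probability applied to every maskable
#'   field, or a named vector over a subset of
#'   `race, ethnicity, dna_change_type, genomic_source_class,
#'   amino_acid_change, allelic_frequency, clinical_significance`.
#' @param seed Integer seed; the five tables draw from independent RNG
#'   streams derived from it, so identical configs give byte-identical
#'   extracts.
#' @param as_of ISO date used downstream as the reference date for age
#'   computation (never the wall clock).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          genes = cancer_genes()$symbol,
                          cancer_phecodes = neoplasm_phecodes(),
                          variant_rate = 2,
                          reports_per_patient = 1,
                          diagnosis_model = NULL,
                          missingness = 0.1,
                          seed = 1L,
                          as_of = "2020-12-31") {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || is.na(n_patients) ||
      n_patients < 0 || n_patients != floor(n_patients)) {
    abort("n_patients must be a non-negative integer")
  }
  if (!is.character(genes) || length(genes) == 0L) {
    abort("genes must be a non-empty character vector")
  }
  cancer_phecodes <- tibble::as_tibble(cancer_phecodes)
  if (!all(c("phecode", "label") %in% names(cancer_phecodes))) {
    abort("cancer_phecodes must have columns phecode and label")
  }
  cancer_phecodes$phecode <- as.character(cancer_phecodes$phecode)
  if (!is.numeric(variant_rate) || variant_rate < 0) {
    abort("variant_rate must be >= 0")
  }
  if (!is.numeric(reports_per_patient) || reports_per_patient < 1 ||
      reports_per_patient != floor(reports_per_patient)) {
    abort("reports_per_patient must be a positive integer")
  }
  miss <- normalize_missingness(missingness)
  if (is.null(diagnosis_model)) {
    diagnosis_model <- default_diagnosis_model(genes, cancer_phecodes$phecode)
  }
  validate_diagnosis_model(diagnosis_model, genes, cancer_phecodes$phecode)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("seed must be a single integer")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), genes = genes,
      cancer_phecodes = cancer_phecodes, variant_rate = variant_rate,
      reports_per_patient = as.integer(reports_per_patient),
      diagnosis_model = diagnosis_model, missingness = miss,
      seed = as.integer(seed), as_of = as_of
    ),
    class = "cohort_config"
  )
}

normalize_missingness <- function(missingness) {
  if (is.numeric(missingness) && length(missingness) == 1L &&
      is.null(names(missingness))) {
    missingness <- setNames(rep(missingness, length(MASKABLE_FIELDS)),
                            MASKABLE_FIELDS)
  }
  if (!is.numeric(missingness) || is.null(names(missingness))) {
    abort("missingness must be a single probability or a named numeric vector")
  }
  unknown <- setdiff(names(missingness), MASKABLE_FIELDS)
  if (length(unknown)) {
    abort(paste0("missingness names not maskable fields: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(is.na(missingness)) || any(missingness < 0) || any(missingness > 1)) {
    abort("missingness probabilities must lie in [0,1]")
  }
  full <- setNames(rep(0, length(MASKABLE_FIELDS)), MASKABLE_FIELDS)
  full[names(missingness)] <- missingness
  full
}

#' Default gene-conditional diagnosis model
#'
#' Assigns gene *i* a strong association (probability 0.35) with one Phecode
#' and a weak one (0.08) with another, cycling through the Phecode list, so
#' generated cohorts show the enrichment structure the incidence calculator
#' is meant to surface.
#'
#' @param genes Character vector of gene symbols.
#' @param phecodes Character vector of Phecodes.
#' @return Named list gene -> named probability vector.
#' @export
default_diagnosis_model <- function(genes, phecodes) {
  k <- length(phecodes)
  out <- lapply(seq_along(genes), function(i) {
    strong <- phecodes[(i - 1L) %% k + 1L]
    weak <- phecodes[(i + 2L) %% k + 1L]
    w <- c(0.35, 0.08)
    names(w) <- c(strong, weak)
    w[!duplicated(names(w))]
  })
  names(out) <- genes
  out
}

validate_diagnosis_model <- function(model, genes, phecodes) {
  if (!is.list(model)) abort("diagnosis_model must be a named list")
  if (length(model) && is.null(names(model))) {
    abort("diagnosis_model must be a named list (gene -> weights)")
  }
  bad_genes <- setdiff(names(model), genes)
  if (length(bad_genes)) {
    abort(paste0("diagnosis_model genes not in config genes: ",
                 paste(bad_genes, collapse = ", ")))
  }
  for (g in names(model)) {
    w <- model[[g]]
    if (!is.numeric(w) || is.null(names(w))) {
      abort(paste0("diagnosis_model[['", g, "']] must be a named numeric vector"))
    }
    if (any(is.na(w)) || any(w < 0) || any(w > 1)) {
      abort(paste0("diagnosis_model[['", g, "']] probabilities must lie in [0,1]"))
    }
    bad <- setdiff(names(w), phecodes)
    if (length(bad)) {
      abort(paste0("diagnosis_model[['", g, "']] references unknown phecodes: ",
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(model)
}

sample_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  span <- as.integer(to - from)
  format(from + sample.int(span + 1L, n, replace = TRUE) - 1L, "%Y-%m-%d")
}

BASES <- c("A", "C", "G", "T")
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
         "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

hgvs_dna <- function(type, pos, len, ref, alt, ins) {
  switch(type,
    SNV = paste0("c.", pos, ref, ">", alt),
    DEL = paste0("c.", pos, "_", pos + len, "del"),
    INS = paste0("c.", pos, "_", pos + 1L, "ins", ins),
    DUP = paste0("c.", pos, "_", pos + len, "dup"),
    DELINS = paste0("c.", pos, "_", pos + len, "delins", ins)
  )
}

#' Generate a synthetic Clarity-style extract
#'
#' Draws the five extract tables from independent RNG streams derived from
#' `config$seed`. The output satisfies referential integrity by
#' construction; per-field absences follow the configured missingness, and
#' diagnosis frequencies conditional on carried genes follow the diagnosis
#' model (see [cohort_config()]).
#'
#' @param config A [cohort_config()].
#' @return A `clarity_extract`: a named list of tibbles `patients`,
#'   `diagnoses`, `reports`, `variants`, `specimens`, plus the `as_of` date.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("config must be created with cohort_config()")
  }
  n <- config$n_patients

  # patients ------------------------------------------------------------
  set.seed(sub_seed(config$seed, "patients"))
  patients <- tibble::tibble(
    patient_id = sprintf("PT%06d", seq_len(n)),
    birth_date = if (n) sample_dates(n, "1930-01-01", "1995-12-31") else character(),
    sex = if (n) sample(c("F", "M"), n, replace = TRUE, prob = c(0.52, 0.48)) else character(),
    race = if (n) sample(c("W", "B", "A", "N", "P", "O"), n, replace = TRUE,
                         prob = c(0.62, 0.15, 0.07, 0.01, 0.01, 0.14)) else character(),
    ethnicity = if (n) sample(c("H", "N"), n, replace = TRUE,
                              prob = c(0.09, 0.91)) else character()
  )

  # reports + regions ---------------------------------------------------
  set.seed(sub_seed(config$seed, "reports"))
  n_rep <- n * config$reports_per_patient
  rep_patient <- rep(patients$patient_id, each = config$reports_per_patient)
  region_sizes <- if (n_rep) sample(0:8, n_rep, replace = TRUE,
                                    prob = c(0.1, rep(0.9 / 8, 8))) else integer()
  regions <- lapply(region_sizes, function(k) {
    if (k == 0L) character() else sort(sample(config$genes, min(k, length(config$genes))))
  })
  reports <- tibble::tibble(
    report_id = sprintf("RPT%06d", seq_len(n_rep)),
    patient_id = rep_patient,
    specimen_id = sprintf("SPM%06d", seq_len(n_rep)),
    test_date = if (n_rep) sample_dates(n_rep, "2000-01-01", "2020-12-31") else character(),
    regions_studied = regions
  )

  # variants ------------------------------------------------------------
  set.seed(sub_seed(config$seed, "variants"))
  n_var_per <- if (n_rep) rpois(n_rep, config$variant_rate) else integer()
  n_var <- sum(n_var_per)
  if (n_var) {
    pos <- sample.int(5000L, n_var, replace = TRUE)
    len <- sample.int(6L, n_var, replace = TRUE)
    ref <- sample(BASES, n_var, replace = TRUE)
    alt_idx <- (match(ref, BASES) + sample.int(3L, n_var, replace = TRUE) - 1L) %% 4L + 1L
    ins <- vapply(sample.int(4L, n_var, replace = TRUE) + 1L,
                  function(k) paste(sample(BASES, k, replace = TRUE), collapse = ""),
                  character(1))
    type <- sample(c("SNV", "DEL", "INS", "DUP", "DELINS"), n_var, replace = TRUE,
                   prob = c(0.7, 0.12, 0.08, 0.05, 0.05))
    dna <- vapply(seq_len(n_var), function(i) {
      hgvs_dna(type[i], pos[i], len[i], ref[i], BASES[alt_idx[i]], ins[i])
    }, character(1))
    aa_pos <- pmax(1L, pos %/% 3L)
    aa <- paste0("p.", sample(AA3, n_var, replace = TRUE), aa_pos,
                 sample(AA3, n_var, replace = TRUE))
    variants <- tibble::tibble(
      report_id = rep(reports$report_id, times = n_var_per),
      gene_symbol = sample(config$genes, n_var, replace = TRUE),
      dna_change = dna,
      dna_change_type = type,
      genomic_source_class = sample(c("somatic", "germline"), n_var,
                                    replace = TRUE, prob = c(0.8, 0.2)),
      amino_acid_change = aa,
      allelic_frequency = round(stats::rbeta(n_var, 2, 5), 4),
      clinical_significance = sample(
        c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS", "LIKELY_BENIGN", "BENIGN"),
        n_var, replace = TRUE, prob = c(0.25, 0.15, 0.35, 0.1, 0.15))
    )
  } else {
    variants <- tibble::tibble(
      report_id = character(), gene_symbol = character(),
      dna_change = character(), dna_change_type = character(),
      genomic_source_class = character(), amino_acid_change = character(),
      allelic_frequency = double(), clinical_significance = character()
    )
  }

  # specimens -----------------------------------------------------------
  set.seed(sub_seed(config$seed, "specimens"))
  specimens <- tibble::tibble(
    specimen_id = reports$specimen_id,
    patient_id = reports$patient_id,
    specimen_type = if (n_rep) sample(
      c("TUMOR", "BLOOD", "TISSUE", "SALIVA", "BONE_MARROW"), n_rep,
      replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.03, 0.02)) else character(),
    collected_date = if (n_rep) sample_dates(n_rep, "2000-01-01", "2020-12-31") else character()
  )

  # diagnoses: union over carried genes of per-gene Bernoulli draws ------
  set.seed(sub_seed(config$seed, "diagnoses"))
  carriers <- unique(dplyr::inner_join(
    variants[, c("report_id", "gene_symbol")],
    reports[, c("report_id", "patient_id")], by = "report_id"
  )[, c("patient_id", "gene_symbol")])
  carriers <- carriers[order(carriers$patient_id, carriers$gene_symbol), ]
  model_rows <- dplyr::bind_rows(lapply(names(config$diagnosis_model), function(g) {
    w <- config$diagnosis_model[[g]]
    tibble::tibble(gene_symbol = g, phecode = names(w), prob = unname(w))
  }))
  if (nrow(carriers) && nrow(model_rows)) {
    cand <- dplyr::inner_join(carriers, model_rows, by = "gene_symbol",
                              relationship = "many-to-many")
    cand <- cand[order(cand$patient_id, cand$gene_symbol, cand$phecode), ]
    hit <- rbinom(nrow(cand), 1L, cand$prob) == 1L
    diag <- unique(cand[hit, c("patient_id", "phecode")])
  } else {
    diag <- tibble::tibble(patient_id = character(), phecode = character())
  }
  diag <- dplyr::left_join(diag, config$cancer_phecodes, by = "phecode")
  diagnoses <- tibble::tibble(
    patient_id = diag$patient_id,
    phecode = diag$phecode,
    label = diag$label,
    onset_date = if (nrow(diag)) sample_dates(nrow(diag), "2000-01-01", "2020-12-31") else character()
  )

  # missingness ---------------------------------------------------------
  set.seed(sub_seed(config$seed, "missingness"))
  mask <- function(x, p) {
    if (!length(x) || p <= 0) return(x)
    x[runif(length(x)) < p] <- NA
    x
  }
  for (f in c("race", "ethnicity")) {
    patients[[f]] <- mask(patients[[f]], config$missingness[[f]])
  }
  for (f in c("dna_change_type", "genomic_source_class", "amino_acid_change",
              "allelic_frequency", "clinical_significance")) {
    variants[[f]] <- mask(variants[[f]], config$missingness[[f]])
  }

  out <- structure(
    list(patients = patients, diagnoses = diagnoses, reports = reports,
         variants = variants, specimens = specimens, as_of = config$as_of),
    class = "clarity_extract"
  )
  validate_extract(out)
  out
}

#' @export
print.clarity_extract <- function(x, ...) {
  cat("<clarity_extract>\n")
  for (tb in names(EXTRACT_COLUMNS)) {
    cat(sprintf("  %-9s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Validate referential integrity of an extract
#'
#' Checks primary-key uniqueness of patients, reports and specimens, that
#' every foreign key resolves, and that allelic fractions lie in \[0,1\].
#' Errors name the offending identifier and relation.
#'
#' @param extract A `clarity_extract`.
#' @return The extract, invisibly.
#' @export
validate_extract <- function(extract) {
  if (!is.list(extract) || !all(names(EXTRACT_COLUMNS) %in% names(extract))) {
    abort("extract must contain the five tables patients/diagnoses/reports/variants/specimens")
  }
  dup <- function(x, what) {
    d <- unique(x[duplicated(x)])
    if (length(d)) abort(paste0("duplicate ", what, ": ", paste(head(d, 3), collapse = ", ")))
  }
  dup(extract$patients$patient_id, "patient_id")
  dup(extract$reports$report_id, "report_id")
  dup(extract$specimens$specimen_id, "specimen_id")
  fk <- function(child, col, parent_ids, rel) {
    bad <- setdiff(child[[col]], parent_ids)
    if (length(bad)) {
      abort(paste0("dangling foreign key in ", rel, ": ",
                   paste(head(bad, 3), collapse = ", ")))
    }
  }
  fk(extract$diagnoses, "patient_id", extract$patients$patient_id, "diagnoses.patient_id")
  fk(extract$reports, "patient_id", extract$patients$patient_id, "reports.patient_id")
  fk(extract$reports, "specimen_id", extract$specimens$specimen_id, "reports.specimen_id")
  fk(extract$variants, "report_id", extract$reports$report_id, "variants.report_id")
  fk(extract$specimens, "patient_id", extract$patients$patient_id, "specimens.patient_id")
  af <- extract$variants$allelic_frequency
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    abort("allelic_frequency outside [0,1]")
  }
  invisible(extract)
}

#' Write an extract to a directory of CSV files
#'
#' Emits the five tables as UTF-8, RFC-4180 CSV files with fixed headers;
#' absent values are written as empty cells (distinct from the literal
#' string "unknown"); `regions_studied` is pipe-delimited.
#'
#' @param extract A `clarity_extract`.
#' @param directory Output directory (created if needed).
#' @return A tibble manifest with columns `file` and `rows`.
#' @export
write_extract <- function(extract, directory) {
  validate_extract(extract)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tabs <- extract[names(EXTRACT_COLUMNS)]
  tabs$reports$regions_studied <- vapply(
    tabs$reports$regions_studied, paste, character(1), collapse = "|")
  files <- paste0(names(tabs), ".csv")
  for (i in seq_along(tabs)) {
    path <- file.path(directory, files[i])
    tryCatch(
      readr::write_csv(tabs[[i]], path, na = "", progress = FALSE),
      error = function(e) abort(paste0("failed to write ", path, ": ",
                                       conditionMessage(e)))
    )
  }
  tibble::tibble(file = files,
                 rows = vapply(tabs, nrow, integer(1), USE.NAMES = FALSE))
}

#' Read an extract from a directory of CSV files
#'
#' Strict inverse of [write_extract()]: all five files must be present, the
#' header must match the documented schema exactly (an unrecognized or
#' missing column is an error naming it), empty cells become absent values,
#' and referential integrity is validated.
#'
#' @param directory Directory containing the five CSV files.
#' @param as_of Reference date attached to the extract (ISO string).
#' @return A `clarity_extract`.
#' @export
read_extract <- function(directory, as_of = "2020-12-31") {
  tabs <- list()
  for (tb in names(EXTRACT_COLUMNS)) {
    path <- file.path(directory, paste0(tb, ".csv"))
    if (!file.exists(path)) abort(paste0("missing extract file: ", path))
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, na = "")
    expected <- EXTRACT_COLUMNS[[tb]]
    extra <- setdiff(names(df), expected)
    if (length(extra)) {
      abort(paste0("unknown column in ", tb, ".csv: ", paste(extra, collapse = ", ")))
    }
    missing <- setdiff(expected, names(df))
    if (length(missing)) {
      abort(paste0("missing column in ", tb, ".csv: ", paste(missing, collapse = ", ")))
    }
    df <- df[, expected]
    tabs[[tb]] <- tibble::as_tibble(df)
  }
  tabs$variants$allelic_frequency <- as.numeric(tabs$variants$allelic_frequency)
  tabs$reports$regions_studied <- lapply(tabs$reports$regions_studied, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
  })
  out <- structure(c(tabs, list(as_of = as_of)), class = "clarity_extract")
  validate_extract(out)
  out
}
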