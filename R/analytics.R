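# Cohort analytics over the profile store: the pilot application's
# computations as library operations — top-N gene/Phecode distributions,
# filtered deidentified summary tables (10 initial rows, capped at 200),
# and the Bayes conditional cancer-incidence calculator.

SUMMARY_ROW_CAP <- 200L
SUMMARY_DEFAULT_LIMIT <- 10L
DEFAULT_TOP_N <- 30L

#' Gene / Phecode distribution of the stored cohort
#'
#' Tallies either gene variations (one count per stored GenomicVariant
#' profile) or Phecode diagnoses (one count per diagnosis extension on the
#' stored CancerPatient profiles), sorted by count descending with
#' lexicographic tie-breaks. Percentages are computed over all categories,
#' so the shown percentages sum to at most 100 when the table is truncated
#' to the top `top_n` (30 by default, as on the pilot's home page).
#'
#' @param store An `mcode_store`.
#' @param axis `"gene"` or `"phecode"`.
#' @param top_n Number of entries to keep (>= 1).
#' @return A `distribution_table`: list with `axis`, `entries` (tibble of
#'   code, label, count, percentage) and `truncated_to` (the cap, or `NA`
#'   when nothing was cut).
#' @export
distribution <- function(store, axis = c("gene", "phecode"),
                         top_n = DEFAULT_TOP_N) {
  if (!is.character(axis) || !axis[1] %in% c("gene", "phecode")) {
    abort(paste0("unknown distribution axis: ", axis[1]))
  }
  axis <- axis[1]
  if (!is.numeric(top_n) || top_n < 1) abort("top_n must be >= 1")
  if (axis == "gene") {
    vr <- store$index[store$index$kind == "GenomicVariant", ]
    sym <- vr$gene_symbol[!is.na(vr$gene_symbol)]
    tab <- tibble::tibble(code = sym, label = sym)
  } else {
    tab <- tibble::tibble(code = store$diag$phecode, label = store$diag$label)
  }
  counts <- dplyr::summarise(dplyr::group_by(tab, .data$code),
                             label = dplyr::first(.data$label),
                             count = dplyr::n(), .groups = "drop")
  counts <- counts[order(-counts$count, counts$label), ]
  total <- sum(counts$count)
  counts$percentage <- if (total) 100 * counts$count / total else numeric(nrow(counts))
  truncated <- nrow(counts) > top_n
  entries <- utils::head(counts[, c("code", "label", "count", "percentage")], top_n)
  structure(list(axis = axis, entries = entries,
                 truncated_to = if (truncated) as.integer(top_n) else NA_integer_),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat("<distribution_table>", x$axis,
      if (!is.na(x$truncated_to)) paste0("(top ", x$truncated_to, ")"), "\n")
  print(x$entries)
  invisible(x)
}

#' Demographic / genomic cohort filter
#'
#' @param race Optional race code or display text.
#' @param sex Optional sex code (`F`/`M` or FHIR administrative gender).
#' @param age_range Optional numeric `c(lo, hi)` in whole years.
#' @param gene Optional gene symbol or HGNC code.
#' @return A `cohort_filter`.
#' @export
cohort_filter <- function(race = NULL, sex = NULL, age_range = NULL,
                          gene = NULL) {
  if (!is.null(age_range)) {
    if (!is.numeric(age_range) || length(age_range) != 2L ||
        age_range[1] > age_range[2]) {
      abort("age_range must be numeric c(lo, hi) with lo <= hi")
    }
  }
  structure(list(race = race, sex = sex, age_range = age_range, gene = gene),
            class = "cohort_filter")
}

# deidentified surrogate keys: dense rank over sorted patient resource ids
surrogate_keys <- function(patient_ids) {
  uniq <- sort(unique(patient_ids))
  setNames(sprintf("S%05d", seq_along(uniq)), uniq)
}

#' Deidentified patient-variant summary table
#'
#' One row per (patient, gene variation) pair, carrying demographics plus
#' the six variant attributes (DNA change, DNA change type, genomic source
#' class, amino acid change, allelic frequency, clinical significance).
#' Deidentification replaces patient ids with surrogate keys and birth
#' dates with age in whole years (against the store's `as_of` date). The
#' default request returns the initial 10 rows; any request is capped at
#' 200 rows.
#'
#' @param store An `mcode_store`.
#' @param filter A [cohort_filter()]; predicates apply conjunctively.
#' @param offset Rows to skip (>= 0).
#' @param limit Rows to return (>= 1; clamped to 200).
#' @return A `summary_rows`: list with `rows` (tibble), `offset`, `limit`
#'   (the effective, clamped value).
#' @export
summary_table <- function(store, filter = cohort_filter(), offset = 0L,
                          limit = SUMMARY_DEFAULT_LIMIT) {
  if (!inherits(filter, "cohort_filter")) abort("filter must be a cohort_filter")
  if (!is.numeric(offset) || offset < 0) abort("offset must be >= 0")
  if (!is.numeric(limit) || limit < 1) abort("limit must be >= 1")
  limit <- as.integer(min(limit, SUMMARY_ROW_CAP))
  idx <- store$index
  pat <- idx[idx$kind == "CancerPatient", ]
  vr <- idx[idx$kind == "GenomicVariant", ]
  if (!nrow(vr)) {
    return(structure(list(rows = empty_summary_rows(), offset = as.integer(offset),
                          limit = limit), class = "summary_rows"))
  }
  keys <- surrogate_keys(pat$resource_id)
  demo <- tibble::tibble(
    subject = pat$resource_id,
    patient_key = unname(keys[pat$resource_id]),
    sex = pat$sex,
    race = pat$race_display,
    age = suppressWarnings(age_years(pat$birth_date, store$as_of))
  )
  rows <- dplyr::inner_join(
    tibble::tibble(
      subject = vr$subject, variant_id = vr$resource_id,
      gene = vr$gene_symbol, dna_change = vr$dna_change,
      dna_change_type = vr$dna_change_type,
      genomic_source_class = vr$source_class_display,
      amino_acid_change = vr$amino_acid_change,
      allelic_frequency = vr$allelic_frequency,
      clinical_significance = vr$clinical_significance
    ),
    demo, by = "subject")
  if (!is.null(filter$sex)) {
    rows <- rows[!is.na(rows$sex) & rows$sex == normalize_sex(filter$sex), ]
  }
  if (!is.null(filter$race)) {
    q <- tolower(filter$race)
    rows <- rows[!is.na(rows$race) & rows$race == q, ]
  }
  if (!is.null(filter$age_range)) {
    rows <- rows[!is.na(rows$age) & rows$age >= filter$age_range[1] &
                   rows$age <= filter$age_range[2], ]
  }
  if (!is.null(filter$gene)) {
    rows <- rows[!is.na(rows$gene) & rows$gene == filter$gene, ]
  }
  rows <- rows[order(rows$patient_key, rows$variant_id), ]
  rows <- rows[, c("patient_key", "sex", "race", "age", "gene", "dna_change",
                   "dna_change_type", "genomic_source_class",
                   "amino_acid_change", "allelic_frequency",
                   "clinical_significance")]
  window <- rows[seq_len(nrow(rows)) > offset, ]
  window <- utils::head(window, limit)
  structure(list(rows = tibble::as_tibble(window), offset = as.integer(offset),
                 limit = limit),
            class = "summary_rows")
}

empty_summary_rows <- function() {
  tibble::tibble(patient_key = character(), sex = character(),
                 race = character(), age = double(), gene = character(),
                 dna_change = character(), dna_change_type = character(),
                 genomic_source_class = character(),
                 amino_acid_change = character(),
                 allelic_frequency = double(),
                 clinical_significance = character())
}

#' @export
print.summary_rows <- function(x, ...) {
  cat("<summary_rows>", nrow(x$rows), "rows (offset", x$offset, ", limit",
      x$limit, ")\n")
  print(x$rows)
  invisible(x)
}

# per-patient TCGA label sets derived from stored diagnosis extensions
patient_labels <- function(store) {
  map <- phecode_tcga_map()
  d <- merge(as.data.frame(store$diag), as.data.frame(map), by = "phecode")
  unique(d[, c("resource_id", "tcga_label")])
}

variant_carriers <- function(store, gene_variant, granularity) {
  vr <- store$index[store$index$kind == "GenomicVariant", ]
  hit <- if (granularity == "hgvs") {
    !is.na(vr$dna_change) & vr$dna_change == gene_variant
  } else {
    variant_gene_match(vr, gene_variant)
  }
  unique(vr$subject[hit & !is.na(vr$subject)])
}

#' Conditional cancer incidence given a gene variant
#'
#' For each cancer label `c`, estimates the probability of being diagnosed
#' with `c` given carriage of the gene variant `v`, over distinct patients
#' (a patient with two variants of the same gene counts once):
#'
#'   P(C|V) = P(V|C) P(C) / P(V)
#'
#' with count estimators P(V|C) = n(V&C)/n(C), P(C) = n(C)/N and
#' P(V) = n(V)/N, which reduces identically to n(V&C)/n(V). Supporting
#' counts are returned so the arithmetic is auditable; no smoothing or
#' priors are applied. A variant with zero carriers yields an explicit
#' not-observed outcome (probabilities `NA`), never a division error.
#'
#' @param store An `mcode_store`.
#' @param gene_variant Gene symbol (default granularity) or exact c.HGVS
#'   string with `granularity = "hgvs"`.
#' @param labels Character vector of cancer labels to evaluate (non-empty);
#'   defaults to the packaged 33-label TCGA-style set.
#' @param granularity `"gene"` (as in the pilot's calculator) or `"hgvs"`.
#' @return An `incidence_result` tibble, sorted by probability descending,
#'   with columns gene_variant, label, count_v_and_c, count_c, count_v,
#'   n_patients, p_c_given_v, p_v_given_c, p_c, p_v and attribute
#'   `variant_observed`.
#' @export
incidence <- function(store, gene_variant, labels = NULL,
                      granularity = c("gene", "hgvs")) {
  granularity <- match.arg(granularity)
  if (is.null(labels)) labels <- cancer_labels()$tcga_label
  if (!length(labels)) abort("labels must be non-empty")
  n_patients <- sum(store$index$kind == "CancerPatient")
  carriers <- variant_carriers(store, gene_variant, granularity)
  count_v <- length(carriers)
  plab <- patient_labels(store)
  count_c <- vapply(labels, function(l)
    sum(plab$tcga_label == l), integer(1), USE.NAMES = FALSE)
  count_vc <- vapply(labels, function(l)
    length(intersect(plab$resource_id[plab$tcga_label == l], carriers)),
    integer(1), USE.NAMES = FALSE)
  observed <- count_v > 0L
  p_c_given_v <- if (observed) count_vc / count_v else rep(NA_real_, length(labels))
  p_v_given_c <- ifelse(count_c > 0L, count_vc / count_c, NA_real_)
  p_c <- if (n_patients > 0L) count_c / n_patients else rep(NA_real_, length(labels))
  p_v <- if (n_patients > 0L) count_v / n_patients else NA_real_
  res <- tibble::tibble(
    gene_variant = gene_variant,
    label = labels,
    count_v_and_c = count_vc,
    count_c = count_c,
    count_v = count_v,
    n_patients = n_patients,
    p_c_given_v = p_c_given_v,
    p_v_given_c = p_v_given_c,
    p_c = p_c,
    p_v = p_v
  )
  res <- res[order(-replace(res$p_c_given_v, is.na(res$p_c_given_v), -1),
                   res$label), ]
  structure(res, class = c("incidence_result", class(res)),
            variant_observed = observed)
}

#' Ranked incidence report for one gene
#'
#' Evaluates [incidence()] across the full packaged cancer label set and
#' returns the ranked table (the per-label numbers are identical to calling
#' [incidence()] label by label).
#'
#' @param store An `mcode_store`.
#' @param gene Gene symbol.
#' @return An `incidence_result` tibble over all labels, ranked by
#'   probability.
#' @export
incidence_report <- function(store, gene) {
  incidence(store, gene, labels = cancer_labels()$tcga_label,
            granularity = "gene")
}
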