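# FHIR-style search over the EAV store: conjunctive parameter predicates,
# deterministic (resource_type, resource_id) ordering, pages capped at the
# store's page limit, keyset continuation tokens (tokens encode the last
# returned key, so inserts between pages never duplicate results).

#' Build a search query
#'
#' All supplied predicates are combined conjunctively. Demographic and
#' diagnosis predicates (`sex`, `race`, `age_min`/`age_max`, `phecode`)
#' resolve to the set of matching patients; a non-patient profile matches
#' when its subject is in that set. `gene` and `genomic_source_class` apply
#' directly to GenomicVariant profiles and, for other kinds, to the carrier
#' status of the owning patient.
#'
#' @param resource_type Optional profile kind (`"GenomicVariant"`, ...) or
#'   FHIR resource type (`"Observation"`, ...).
#' @param subject Optional patient resource id.
#' @param gene Optional gene symbol (e.g. `"EGFR"`) or HGNC code.
#' @param phecode Optional diagnosis Phecode.
#' @param sex Optional sex; accepts FHIR administrative-gender codes or the
#'   source codes `F`/`M`.
#' @param race Optional race; accepts the coded value or its display text.
#' @param age_min,age_max Optional age range in whole years, resolved
#'   against the store's `as_of` date.
#' @param genomic_source_class Optional `somatic`/`germline` (or the coded
#'   answer value).
#' @param page_token Continuation token from a previous page.
#' @return A `search_query`.
#' @export
search_query <- function(resource_type = NULL, subject = NULL, gene = NULL,
                         phecode = NULL, sex = NULL, race = NULL,
                         age_min = NULL, age_max = NULL,
                         genomic_source_class = NULL, page_token = NULL) {
  if (!is.null(resource_type) &&
      !resource_type %in% c(profile_kinds(), unique(unname(RESOURCE_TYPES)))) {
    abort(paste0("unknown resource_type: ", resource_type))
  }
  if (!is.null(age_min) && !is.null(age_max) && age_min > age_max) {
    abort("age_min must not exceed age_max")
  }
  structure(
    list(resource_type = resource_type, subject = subject, gene = gene,
         phecode = phecode, sex = sex, race = race, age_min = age_min,
         age_max = age_max, genomic_source_class = genomic_source_class,
         page_token = page_token),
    class = "search_query"
  )
}

normalize_sex <- function(x) {
  x <- tolower(x)
  map <- c(f = "female", m = "male", o = "other", u = "unknown")
  if (x %in% names(map)) unname(map[[x]]) else x
}

encode_page_token <- function(resource_type, resource_id) {
  jsonlite::base64_enc(charToRaw(jsonlite::toJSON(
    list(t = resource_type, i = resource_id), auto_unbox = TRUE)))
}

decode_page_token <- function(token) {
  out <- tryCatch(
    jsonlite::fromJSON(rawToChar(jsonlite::base64_dec(token)),
                       simplifyVector = FALSE),
    error = function(e) NULL)
  if (is.null(out) || !is_scalar_string(out$t %||% NULL) ||
      !is_scalar_string(out$i %||% NULL)) {
    abort("malformed page_token", class = "mcodeflow_bad_token")
  }
  out
}

age_years <- function(birth_date, as_of) {
  floor(as.numeric(as.Date(as_of) - as.Date(birth_date)) / 365.25)
}

# Patient ids satisfying all patient-level predicates; NULL when the query
# imposes none (meaning: no subject restriction).
matching_patients <- function(store, query) {
  idx <- store$index
  pat <- idx[idx$kind == "CancerPatient", ]
  restricted <- FALSE
  keep <- rep(TRUE, nrow(pat))
  if (!is.null(query$sex)) {
    restricted <- TRUE
    keep <- keep & !is.na(pat$sex) & pat$sex == normalize_sex(query$sex)
  }
  if (!is.null(query$race)) {
    restricted <- TRUE
    q <- tolower(query$race)
    keep <- keep & ((!is.na(pat$race_code) & tolower(pat$race_code) == q) |
                    (!is.na(pat$race_display) & pat$race_display == q))
  }
  if (!is.null(query$age_min) || !is.null(query$age_max)) {
    restricted <- TRUE
    age <- suppressWarnings(age_years(pat$birth_date, store$as_of))
    ok <- !is.na(age)
    if (!is.null(query$age_min)) ok <- ok & age >= query$age_min
    if (!is.null(query$age_max)) ok <- ok & age <= query$age_max
    keep <- keep & ok
  }
  if (!is.null(query$phecode)) {
    restricted <- TRUE
    with_code <- unique(store$diag$resource_id[store$diag$phecode == query$phecode])
    keep <- keep & pat$resource_id %in% with_code
  }
  if (!is.null(query$gene)) {
    restricted <- TRUE
    vr <- idx[idx$kind == "GenomicVariant", ]
    carriers <- unique(vr$subject[variant_gene_match(vr, query$gene)])
    keep <- keep & pat$resource_id %in% carriers
  }
  if (!is.null(query$genomic_source_class)) {
    restricted <- TRUE
    vr <- idx[idx$kind == "GenomicVariant", ]
    hits <- unique(vr$subject[variant_class_match(vr, query$genomic_source_class)])
    keep <- keep & pat$resource_id %in% hits
  }
  if (!is.null(query$subject)) {
    restricted <- TRUE
    keep <- keep & pat$resource_id == query$subject
  }
  if (!restricted) return(NULL)
  pat$resource_id[keep]
}

variant_gene_match <- function(vr, gene) {
  (!is.na(vr$gene_symbol) & vr$gene_symbol == gene) |
    (!is.na(vr$gene_code) & vr$gene_code == gene)
}

variant_class_match <- function(vr, klass) {
  q <- tolower(klass)
  (!is.na(vr$source_class_code) & tolower(vr$source_class_code) == q) |
    (!is.na(vr$source_class_display) & vr$source_class_display == q)
}

#' Search the store
#'
#' Returns one page of matching profiles in deterministic
#' (resource_type, resource_id) order, capped at the store's page limit
#' (1,000 by default, matching the deployed server's constraint); the
#' continuation token on the page retrieves the next one. `total` is the
#' exact match count, and successive pages partition the match set.
#'
#' @param store An `mcode_store`.
#' @param query A [search_query()].
#' @return A `search_page`: list with `profiles`, `total`, `next_token`.
#' @export
store_search <- function(store, query) {
  if (!inherits(query, "search_query")) abort("query must be a search_query")
  idx <- store$index
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(query$resource_type)) {
    keep <- keep & (idx$kind == query$resource_type |
                    idx$resource_type == query$resource_type)
  }
  subjects <- matching_patients(store, query)
  if (!is.null(subjects)) {
    keep <- keep & !is.na(idx$subject) & idx$subject %in% subjects
  }
  # own-attribute restriction for variant profiles
  if (!is.null(query$gene)) {
    is_var <- idx$kind == "GenomicVariant"
    keep <- keep & (!is_var | variant_gene_match(idx, query$gene))
  }
  if (!is.null(query$genomic_source_class)) {
    is_var <- idx$kind == "GenomicVariant"
    keep <- keep & (!is_var | variant_class_match(idx, query$genomic_source_class))
  }
  hits <- idx[keep, c("resource_type", "resource_id")]
  hits <- hits[order(hits$resource_type, hits$resource_id), ]
  total <- nrow(hits)
  if (!is.null(query$page_token)) {
    last <- decode_page_token(query$page_token)
    after <- hits$resource_type > last$t |
      (hits$resource_type == last$t & hits$resource_id > last$i)
    hits <- hits[after, ]
  }
  page <- utils::head(hits, store$page_limit)
  more <- nrow(hits) > nrow(page)
  profiles <- lapply(page$resource_id, function(id) store_get(store, id))
  structure(
    list(
      profiles = profiles,
      total = total,
      next_token = if (more) {
        encode_page_token(page$resource_type[nrow(page)],
                          page$resource_id[nrow(page)])
      } else NULL
    ),
    class = "search_page"
  )
}

#' @export
print.search_page <- function(x, ...) {
  cat("<search_page>", length(x$profiles), "of", x$total, "profiles;",
      if (is.null(x$next_token)) "last page" else "more available", "\n")
  invisible(x)
}

#' Collect every page of a search
#'
#' Convenience wrapper that follows continuation tokens until exhaustion
#' (the deployed server's 1,000-profile page limit makes multiple calls
#' necessary for comprehensive data).
#'
#' @param store An `mcode_store`.
#' @param query A [search_query()]; its `page_token` is ignored.
#' @return List of all matching `mcode_profile`s in page order.
#' @export
search_all <- function(store, query) {
  query$page_token <- NULL
  out <- list()
  repeat {
    page <- store_search(store, query)
    out <- c(out, page$profiles)
    if (is.null(page$next_token)) break
    query$page_token <- page$next_token
  }
  out
}
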