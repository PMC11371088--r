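# In-process profile store following the entity-attribute-value model:
# every stored resource is a set of (resource_id, resource_type,
# attribute_path, value) rows from which the resource is reconstructible.
# Stands in for a managed FHIR server: validation on write, idempotent
# upsert, FHIR-style conjunctive search with a 1,000-profile page limit and
# keyset continuation tokens. Persistable as a single TSV file.

DIAG_EXT_PREFIX <- "diagnosis/"

empty_eav <- function() {
  data.table::data.table(resource_id = character(), resource_type = character(),
                         attribute_path = character(), value = character(),
                         vtype = character())
}

empty_index <- function() {
  data.table::data.table(
    resource_id = character(), resource_type = character(), kind = character(),
    subject = character(), gene_symbol = character(), gene_code = character(),
    source_class_code = character(), source_class_display = character(),
    dna_change = character(), dna_change_type = character(),
    amino_acid_change = character(), allelic_frequency = double(),
    clinical_significance = character(),
    sex = character(), race_code = character(), race_display = character(),
    ethnicity_display = character(), birth_date = character()
  )
}

empty_diag <- function() {
  data.table::data.table(resource_id = character(), phecode = character(),
                         label = character())
}

#' Flatten a profile into entity-attribute-value rows
#'
#' Serializes the profile to its canonical FHIR form and flattens every leaf
#' into a row with a dotted, 1-based-indexed attribute path (for example
#' `component[2].valueCodeableConcept.coding[1].code`). Values are stored as
#' text with a type tag so the resource is exactly reconstructible.
#'
#' @param profile A valid `mcode_profile`.
#' @return A tibble of EAV rows: `resource_id`, `resource_type`,
#'   `attribute_path`, `value`, `vtype`.
#' @export
to_eav <- function(profile) {
  report <- validate_profile(profile)
  if (!report$valid) {
    abort("cannot flatten an invalid profile",
          class = "mcodeflow_invalid_profile", report = report)
  }
  eav_rows(profile)
}

# Flattening without the validation pass, for callers that have already
# validated the profile (the bulk loader).
eav_rows <- function(profile) {
  x <- canonical_sort(profile_to_fhir_list(profile))
  leaves <- flatten_leaves(x, "")
  nr <- nrow(leaves)
  tibble::new_tibble(list(
    resource_id = rep.int(profile$resource_id, nr),
    resource_type = rep.int(unname(RESOURCE_TYPES[[profile$kind]]), nr),
    attribute_path = leaves$attribute_path,
    value = leaves$value,
    vtype = leaves$vtype
  ), nrow = nr)
}

flatten_leaves <- function(x, prefix) {
  paths <- character(64L); vals <- character(64L); vts <- character(64L)
  n <- 0L
  walk <- function(x, prefix) {
    if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        p <- if (is.null(nms)) paste0(prefix, "[", i, "]")
             else if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
        walk(x[[i]], p)
      }
    } else {
      vt <- if (is.character(x)) "string" else if (is.logical(x)) "boolean" else "number"
      n <<- n + 1L
      if (n > length(paths)) {
        length(paths) <<- 2L * length(paths)
        length(vals) <<- length(paths)
        length(vts) <<- length(paths)
      }
      paths[n] <<- prefix
      vals[n] <<- if (vt == "number") sprintf("%.17g", x) else as.character(x)
      vts[n] <<- vt
    }
  }
  walk(x, prefix)
  keep <- seq_len(n)
  data.table::data.table(attribute_path = paths[keep], value = vals[keep],
                         vtype = vts[keep])
}

#' Reconstruct a profile from its EAV rows
#'
#' @param rows EAV rows for exactly one resource (as produced by
#'   [to_eav()]); rows spanning multiple resource ids or lacking a resource
#'   type are errors.
#' @return An `mcode_profile`.
#' @export
from_eav <- function(rows) {
  rows <- as.data.frame(rows)
  if (!nrow(rows)) abort("no EAV rows supplied")
  if (!"resource_type" %in% names(rows) || any(is.na(rows$resource_type)) ||
      any(!nzchar(rows$resource_type))) {
    abort("rows missing resource_type")
  }
  if (length(unique(rows$resource_id)) != 1L) {
    abort("rows for mixed resource_ids cannot form one resource")
  }
  lst <- unflatten_leaves(rows$attribute_path, rows$value, rows$vtype)
  from_fhir_list(lst)
}

unflatten_leaves <- function(paths, values, vtypes) {
  root <- list()
  for (k in seq_along(paths)) {
    v <- switch(vtypes[k],
                string = values[k],
                number = as.numeric(values[k]),
                boolean = as.logical(values[k]),
                abort(paste0("unknown value type tag: ", vtypes[k])))
    segs <- strsplit(paths[k], ".", fixed = TRUE)[[1]]
    root <- assign_segs(root, segs, v)
  }
  root
}

assign_segs <- function(node, segs, value) {
  if (!length(segs)) return(value)
  m <- regmatches(segs[1], regexec("^([^][]+)(\\[([0-9]+)\\])?$", segs[1]))[[1]]
  if (!length(m)) abort(paste0("malformed attribute path segment: ", segs[1]))
  name <- m[2]; idx <- m[4]
  if (is.null(node)) node <- list()
  if (!nzchar(idx)) {
    node[[name]] <- assign_segs(node[[name]], segs[-1], value)
  } else {
    i <- as.integer(idx)
    arr <- node[[name]]
    if (is.null(arr)) arr <- list()
    cur <- if (i <= length(arr)) arr[[i]] else NULL
    arr[i] <- list(assign_segs(cur, segs[-1], value))
    node[[name]] <- arr
  }
  node
}

#' Create or open a profile store
#'
#' @param path Optional TSV file written by [store_save()]; when given, the
#'   store is loaded from it.
#' @param as_of Reference date for age predicates (ISO string); ignored when
#'   loading, which restores the saved value.
#' @param page_limit Maximum profiles per search page (the deployed FHIR
#'   server's limit of 1,000; exposed as a configuration constant).
#' @return An `mcode_store` environment.
#' @export
profile_store <- function(path = NULL, as_of = "2020-12-31",
                          page_limit = 1000L) {
  store <- new.env(parent = emptyenv())
  store$rows <- empty_eav()
  store$index <- empty_index()
  store$diag <- empty_diag()
  store$as_of <- as_of
  store$page_limit <- as.integer(page_limit)
  class(store) <- "mcode_store"
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("no such store file: ", path))
    all_rows <- data.table::fread(path, sep = "\t", colClasses = "character",
                                  showProgress = FALSE)
    meta <- all_rows[all_rows$resource_type == "#store", ]
    body <- all_rows[all_rows$resource_type != "#store", ]
    if (nrow(meta)) {
      mv <- setNames(meta$value, meta$attribute_path)
      if (!is.na(mv["as_of"])) store$as_of <- unname(mv[["as_of"]])
      if (!is.na(mv["page_limit"])) store$page_limit <- as.integer(mv[["page_limit"]])
    }
    for (id in unique(body$resource_id)) {
      p <- from_eav(body[body$resource_id == id, ])
      store_put(store, p)
    }
  }
  store
}

#' @export
print.mcode_store <- function(x, ...) {
  cat("<mcode_store>", store_count(x), "profiles; as_of", x$as_of,
      "; page_limit", x$page_limit, "\n")
  invisible(x)
}

#' Persist a store to a single TSV file
#'
#' @param store An `mcode_store`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
store_save <- function(store, path) {
  meta <- data.table::data.table(
    resource_id = "#store", resource_type = "#store",
    attribute_path = c("as_of", "page_limit"),
    value = c(store$as_of, as.character(store$page_limit)),
    vtype = "string")
  out <- data.table::rbindlist(list(meta, store$rows))
  data.table::fwrite(out, path, sep = "\t", quote = TRUE)
  invisible(path)
}

index_row_for <- function(profile) {
  f <- profile$fields
  gene <- f$gene
  src <- f$genomic_source_class
  race <- f$race
  eth <- f$ethnicity
  cv_code <- function(v) if (is_coded_value(v)) v$code else NA_character_
  cv_disp <- function(v) if (is_coded_value(v)) v$display %||% v$code else NA_character_
  data.table::data.table(
    resource_id = profile$resource_id,
    resource_type = unname(RESOURCE_TYPES[[profile$kind]]),
    kind = profile$kind,
    subject = if (profile$kind == "CancerPatient") profile$resource_id
              else profile$subject_ref %||% NA_character_,
    gene_symbol = if (!is.null(gene)) gene$display %||% NA_character_ else NA_character_,
    gene_code = cv_code(gene),
    source_class_code = cv_code(src),
    source_class_display = if (!is.null(src)) tolower(src$display %||% src$code)
                           else NA_character_,
    dna_change = cv_code(f$dna_change),
    dna_change_type = cv_disp(f$dna_change_type),
    amino_acid_change = cv_code(f$amino_acid_change),
    allelic_frequency = if (field_populated(f$allelic_frequency))
      as.numeric(f$allelic_frequency) else NA_real_,
    clinical_significance = cv_disp(f$clinical_significance),
    sex = f$sex %||% NA_character_,
    race_code = cv_code(race),
    race_display = if (!is.null(race)) tolower(race$display %||% race$code)
                   else NA_character_,
    ethnicity_display = cv_disp(eth),
    birth_date = f$birth_date %||% NA_character_
  )
}

diag_rows_for <- function(profile) {
  if (profile$kind != "CancerPatient" || !length(profile$extensions)) {
    return(empty_diag())
  }
  base <- profile$extension_base
  rows <- lapply(profile$extensions, function(e) {
    rel <- substring(e$url, nchar(base) + 1L)
    if (!startsWith(rel, DIAG_EXT_PREFIX) || endsWith(rel, "/onset")) return(NULL)
    v <- e$value
    if (!is_coded_value(v)) return(NULL)
    data.table::data.table(resource_id = profile$resource_id,
                           phecode = v$code, label = v$display %||% v$code)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) empty_diag() else data.table::rbindlist(rows)
}

store_delete_id <- function(store, id) {
  store$rows <- store$rows[store$rows$resource_id != id, ]
  store$index <- store$index[store$index$resource_id != id, ]
  store$diag <- store$diag[store$diag$resource_id != id, ]
}

#' Store a profile (validated, idempotent upsert)
#'
#' Every profile is validated at the time of being loaded; an invalid
#' profile is rejected with its [validate_profile()] report attached and
#' the store is left unchanged. Re-putting a profile with the same
#' `resource_id` replaces the stored copy.
#'
#' @param store An `mcode_store`.
#' @param profile An `mcode_profile`.
#' @param eav Optional precomputed [to_eav()] rows for the profile (used by
#'   the bulk loader).
#' @return The `resource_id`, invisibly.
#' @export
store_put <- function(store, profile, eav = NULL) {
  report <- validate_profile(profile)
  if (!report$valid) {
    abort(paste0("profile rejected by validation: ",
                 profile$resource_id %||% "?"),
          class = "mcodeflow_invalid_profile", report = report)
  }
  if (is.null(eav)) eav <- to_eav(profile)
  store_delete_id(store, profile$resource_id)
  store$rows <- data.table::rbindlist(list(store$rows,
                                           data.table::as.data.table(eav)))
  store$index <- data.table::rbindlist(list(store$index, index_row_for(profile)))
  store$diag <- data.table::rbindlist(list(store$diag, diag_rows_for(profile)))
  invisible(profile$resource_id)
}

# Insert many already-validated profiles in one pass: one delete of any
# pre-existing copies and one append per table, so bulk loads stay linear in
# the number of profiles. Within a call the last profile wins per id,
# matching sequential store_put semantics.
store_bulk_put <- function(store, profiles, eavs) {
  if (!length(profiles)) return(invisible(character()))
  ids <- vapply(profiles, function(p) p$resource_id, character(1))
  store$rows <- store$rows[!store$rows$resource_id %in% ids, ]
  store$index <- store$index[!store$index$resource_id %in% ids, ]
  store$diag <- store$diag[!store$diag$resource_id %in% ids, ]
  keep <- which(!duplicated(ids, fromLast = TRUE))
  store$rows <- data.table::rbindlist(
    c(list(store$rows), lapply(eavs[keep], data.table::as.data.table)))
  store$index <- data.table::rbindlist(
    c(list(store$index), lapply(profiles[keep], index_row_for)))
  store$diag <- data.table::rbindlist(
    c(list(store$diag), lapply(profiles[keep], diag_rows_for)))
  invisible(ids)
}

#' Retrieve one profile by resource id
#'
#' @param store An `mcode_store`.
#' @param resource_id Identifier to fetch.
#' @return The `mcode_profile`, or `NULL` when absent.
#' @export
store_get <- function(store, resource_id) {
  rows <- store$rows[store$rows$resource_id == resource_id, ]
  if (!nrow(rows)) return(NULL)
  from_eav(rows)
}

#' Number of stored profiles
#'
#' @param store An `mcode_store`.
#' @return Integer count of resources.
#' @export
store_count <- function(store) nrow(store$index)

#' Resource ids held by a store
#'
#' @param store An `mcode_store`.
#' @param kind Optional profile kind filter.
#' @return Character vector of resource ids.
#' @export
store_ids <- function(store, kind = NULL) {
  idx <- store$index
  if (!is.null(kind)) idx <- idx[idx$kind == kind, ]
  idx$resource_id
}
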