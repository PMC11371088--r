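test_that("conjunctive search matches a brute-force oracle", {
  fx <- small_fixture()
  cases <- list(
    list(resource_type = "CancerPatient", sex = "F"),
    list(resource_type = "GenomicVariant", sex = "F"),
    list(resource_type = "CancerPatient", age_min = 40, age_max = 70),
    list(sex = "M"),
    list(resource_type = "Observation")
  )
  # add a gene and a phecode that actually occur in the fixture
  genes <- vapply(profiles_of_kind(fx$bundle, "GenomicVariant"),
                  function(v) v$fields$gene$display, character(1))
  g <- names(sort(table(genes), decreasing = TRUE))[1]
  cases <- c(cases, list(list(resource_type = "GenomicVariant", gene = g),
                         list(gene = g, sex = "F")))
  ph <- fx$store$diag$phecode[1]
  cases <- c(cases, list(list(resource_type = "CancerPatient", phecode = ph)))
  for (cs in cases) {
    q <- do.call(search_query, cs)
    got <- sort(vapply(search_all(fx$store, q), `[[`, character(1),
                       "resource_id"))
    want <- do.call(oracle_match_ids,
                    c(list(bundle = fx$bundle, as_of = fx$store$as_of), cs))
    expect_identical(got, want, label = paste(names(cs), unlist(cs),
                                              collapse = " "))
  }
})

test_that("the gene predicate restricts variants to their own gene", {
  fx <- small_fixture()
  genes <- vapply(profiles_of_kind(fx$bundle, "GenomicVariant"),
                  function(v) v$fields$gene$display, character(1))
  g <- names(sort(table(genes), decreasing = TRUE))[1]
  hits <- search_all(fx$store, search_query(resource_type = "GenomicVariant",
                                            gene = g))
  expect_gt(length(hits), 0)
  for (v in hits) expect_identical(v$fields$gene$display, g)
  # ...but reports of carrier patients do match on carrier status
  reps <- search_all(fx$store, search_query(resource_type = "GenomicsReport",
                                            gene = g))
  carriers <- unique(vapply(hits, `[[`, character(1), "subject_ref"))
  for (r in reps) expect_true(r$subject_ref %in% carriers)
})

test_that("pages partition the match set under a small page limit", {
  fx <- small_fixture()
  store <- profile_store(page_limit = 7L)
  load_bundle(fx$bundle, store)
  q <- search_query(resource_type = "Observation")
  seen <- character()
  pages <- 0L
  repeat {
    page <- store_search(store, q)
    ids <- vapply(page$profiles, `[[`, character(1), "resource_id")
    expect_lte(length(ids), 7L)
    expect_length(intersect(seen, ids), 0)  # disjoint
    seen <- c(seen, ids)
    pages <- pages + 1L
    if (is.null(page$next_token)) break
    q$page_token <- page$next_token
  }
  all_ids <- vapply(search_all(fx$store,
                               search_query(resource_type = "Observation")),
                    `[[`, character(1), "resource_id")
  expect_setequal(seen, all_ids)
  expect_identical(pages, as.integer(ceiling(length(all_ids) / 7)))
  # every page reports the same exact total
  expect_identical(store_search(store, search_query(resource_type = "Observation"))$total,
                   length(all_ids))
})

test_that("continuation tokens are deterministic and order is stable", {
  fx <- small_fixture()
  store <- profile_store(page_limit = 10L)
  load_bundle(fx$bundle, store)
  q <- search_query()
  p1 <- store_search(store, q)
  p2 <- store_search(store, q)
  expect_identical(p1$next_token, p2$next_token)
  ids1 <- vapply(p1$profiles, `[[`, character(1), "resource_id")
  ids2 <- vapply(p2$profiles, `[[`, character(1), "resource_id")
  expect_identical(ids1, ids2)
  # deterministic (resource_type, resource_id) ordering within the page
  types <- vapply(p1$profiles, function(p)
    c(CancerPatient = "Patient", GenomicsReport = "DiagnosticReport",
      GenomicVariant = "Observation", GenomicRegionStudied = "Observation",
      GenomicSpecimen = "Specimen")[[p$kind]], character(1))
  expect_false(is.unsorted(order(types, ids1)))
  key <- paste(types, ids1)
  expect_identical(key, sort(key))
})

test_that("an insert between pages never duplicates results", {
  fx <- small_fixture()
  store <- profile_store(page_limit = 9L)
  load_bundle(fx$bundle, store)
  q <- search_query(resource_type = "GenomicVariant")
  page1 <- store_search(store, q)
  ids1 <- vapply(page1$profiles, `[[`, character(1), "resource_id")
  # insert a new variant that sorts before the already-returned page
  v <- fx$bundle[[which(bundle_kinds(fx$bundle) == "GenomicVariant")[1]]]
  v$resource_id <- "var:AAA0:1"
  store_put(store, v)
  q$page_token <- page1$next_token
  rest <- character()
  repeat {
    page <- store_search(store, q)
    rest <- c(rest, vapply(page$profiles, `[[`, character(1), "resource_id"))
    if (is.null(page$next_token)) break
    q$page_token <- page$next_token
  }
  expect_length(intersect(ids1, rest), 0)
})

test_that("malformed queries and tokens raise clear errors", {
  fx <- small_fixture()
  expect_error(search_query(resource_type = "Bogus"), "unknown resource_type")
  expect_error(search_query(age_min = 50, age_max = 40), "age_min")
  expect_error(
    store_search(fx$store, search_query(page_token = "###notatoken")),
    class = "mcodeflow_bad_token")
  expect_error(store_search(fx$store, list(sex = "F")), "search_query")
})

test_that("a query matching nothing returns an empty final page", {
  fx <- small_fixture()
  page <- store_search(fx$store, search_query(subject = "pat:NOBODY"))
  expect_identical(page$total, 0L)
  expect_length(page$profiles, 0)
  expect_null(page$next_token)
})
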