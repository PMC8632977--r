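api_db <- function() {
  db <- cdkn2a_like_db()
  mgr <- add_user(db, "mgr", role_global = "manager")
  add_disease(db, "melanoma", omim_id = 155600L)
  # 3 public observations of one description + 1 of another, on NM_000077.4;
  # 2 observations annotated on NM_058195.3 via a second description
  for (k in 1:3) {
    create_variant_observation(db, "g.21971172C>T", "9", visibility = "public",
                               transcripts = list(list(accession = "NM_000077.4")))
  }
  create_variant_observation(db, "g.21971200A>G", "9", visibility = "public",
                             transcripts = list(list(accession = "NM_000077.4")))
  create_variant_observation(db, "g.21971300A>G", "9", visibility = "public",
                             transcripts = list(list(accession = "NM_058195.3")))
  db
}

test_that("retrieval lists genes by symbol, chromosome and position", {
  db <- api_db()
  r <- handle_retrieval(db, list(resource = "genes", symbol = "CDKN2A"))
  expect_equal(r$status, "ok")
  expect_equal(nrow(r$data), 1)
  r <- handle_retrieval(db, list(resource = "genes", chromosome = "9"))
  expect_equal(r$data$symbol, "CDKN2A")
  # search by a chromosomal position inside the locus
  r <- handle_retrieval(db, list(resource = "genes", position = 21971172))
  expect_equal(r$data$symbol, "CDKN2A")
  r <- handle_retrieval(db, list(resource = "genes", position = 1))
  expect_equal(nrow(r$data), 0)
})

test_that("variant retrieval groups by unique description with counts", {
  db <- api_db()
  r <- handle_retrieval(db, list(resource = "variants", gene = "CDKN2A",
                                 group = TRUE))
  # 5 observations of 3 unique descriptions across the gene's transcripts
  expect_equal(nrow(r$data), 3)
  counts <- setNames(r$data$observation_count, r$data$dna_description)
  expect_equal(unname(counts["g.21971172C>T"]), 3L)
  expect_equal(unname(counts["g.21971200A>G"]), 1L)
  # grouping conservation: group counts sum to the visible observation total
  ungrouped <- handle_retrieval(db, list(resource = "variants", gene = "CDKN2A"))
  expect_equal(sum(r$data$observation_count), nrow(ungrouped$data))
  # metadata fields ride along on ungrouped listings
  expect_true(all(c("owner_id", "created_by", "created_at", "edited_at")
                  %in% names(ungrouped$data)))
})

test_that("the default transcript is the most-annotated one", {
  db <- api_db()
  # NM_000077.4 carries 4 annotations, NM_058195.3 carries 1
  r <- handle_retrieval(db, list(resource = "variants", gene = "CDKN2A"))
  expect_equal(unique(r$data$default_transcript), "NM_000077.4")
  r <- handle_retrieval(db, list(resource = "genes", symbol = "CDKN2A"))
  expect_equal(r$data$default_transcript, "NM_000077.4")
  # unknown gene: empty result, ok status, warning attached
  r <- handle_retrieval(db, list(resource = "variants", gene = "NOPE"))
  expect_equal(r$status, "ok")
  expect_equal(nrow(r$data), 0)
  expect_match(r$warnings, "Unknown gene")
  expect_error(
    handle_retrieval(db, list(resource = "variants", gene = "CDKN2A",
                              range = c(5, 1))),
    class = "varlocus_validation_error"
  )
  expect_error(
    handle_retrieval(db, list(resource = "variants", api_version = "v9")),
    class = "varlocus_version_error"
  )
})

test_that("submissions validate against the account's authorization", {
  db <- api_db()
  sub <- add_user(db, "lab")                    # not variant-only authorized
  lab <- add_user(db, "lims", variant_only = TRUE)
  doc <- generate_submission_doc(fixture_spec(seed = 2), db)

  r <- validate_submission(db, doc$valid, sub$token)
  expect_true(r$valid)
  expect_equal(r$status, "queued")
  expect_true(r$queue_id > 0)

  r <- validate_submission(db, doc$mutants$no_individual, sub$token)
  expect_false(r$valid)
  expect_match(paste(r$errors$message, collapse = " "), "variant-only")
  # the same document is fine for a variant-only authorized account
  r <- validate_submission(db, doc$mutants$no_individual, lab$token)
  expect_true(r$valid)

  r <- validate_submission(db, doc$mutants$bad_effect, sub$token)
  expect_false(r$valid)
  expect_match(r$errors$path, "variants\\[1\\]\\.effect_reported")
  r <- validate_submission(db, doc$mutants$missing_dna, sub$token)
  expect_match(r$errors$path, "dna_description")
  r <- validate_submission(db, doc$mutants$unknown_transcript, sub$token)
  expect_match(r$errors$path, "transcripts\\[1\\]\\.accession")

  expect_error(validate_submission(db, doc$valid, "tok-bogus"),
               class = "varlocus_authentication_error")
  expect_error(validate_submission(db, doc$valid, sub$token, api_version = "v0"),
               class = "varlocus_version_error")
})

test_that("queued documents import per the account flags", {
  db <- api_db()
  plain <- add_user(db, "plain")
  auto <- add_user(db, "auto", auto_import = TRUE)
  publisher <- add_user(db, "pub", auto_import = TRUE, auto_publish = TRUE)
  doc <- generate_submission_doc(fixture_spec(seed = 4), db)$valid

  validate_submission(db, doc, plain$token)
  validate_submission(db, doc, auto$token)
  validate_submission(db, doc, publisher$token)

  n_before <- nrow(db$variants_genome)
  rep <- process_queue(db)
  expect_equal(sort(rep$status), c("imported", "imported", "queued"))
  # auto-import account's records are non-public, auto-publish's are public
  new <- db$variants_genome[db$variants_genome$id > n_before, ]
  expect_setequal(
    paste(new$owner_id, new$visibility),
    c(paste(auto$id, "non_public"), paste(publisher$id, "public"))
  )
  # the un-flagged account's document waits for a manager
  rep <- process_queue(db, manager_trigger = TRUE)
  expect_true(any(rep$status == "imported"))
  imported <- db$variants_genome[which(db$variants_genome$owner_id == plain$id), ]
  expect_equal(nrow(imported), 1)
  expect_equal(imported$visibility, "non_public")
  # the imported case hierarchy exists
  expect_true(nrow(db$individuals) >= 3)
  expect_true(nrow(db$screenings_variants) >= 3)
})

test_that("documents that validate never fail import for a validation reason", {
  db <- api_db()
  acct <- add_user(db, "gen", auto_import = TRUE)
  for (seed in 1:10) {
    doc <- generate_submission_doc(fixture_spec(seed = seed), db)$valid
    r <- validate_submission(db, doc, acct$token)
    expect_true(r$valid)
  }
  rep <- process_queue(db)
  expect_true(all(rep$status == "imported"))
})

test_that("federated queries aggregate public hits from listed instances", {
  db1 <- api_db()
  db2 <- api_db()
  db3 <- cdkn2a_like_db()  # registered but holds no matching variant
  reg <- federated_registry(
    federated_instance("https://one.example", db1),
    federated_instance("https://two.example", db2),
    federated_instance("https://three.example", db3)
  )
  r <- federated_query(reg, chromosome = "9", position = 21971172)
  expect_equal(nrow(r$hits), 6) # 3 public observations on each of 2 instances
  expect_setequal(unique(r$hits$instance_url),
                  c("https://one.example", "https://two.example"))
  expect_match(r$hits$record_link[1], "^https://one.example/variants/")

  # opting out of the listing excludes an instance from the fan-out
  reg2 <- federated_registry(
    federated_instance("https://one.example", db1),
    federated_instance("https://two.example", db2, listed = FALSE)
  )
  r <- federated_query(reg2, chromosome = "9", position = 21971172)
  expect_setequal(unique(r$hits$instance_url), "https://one.example")

  # gene filter restricts hits to annotated records
  r <- federated_query(reg, chromosome = "9",
                       range = c(21970000, 21975000), gene = "CDKN2A")
  expect_true(all(r$hits$gene_symbol == "CDKN2A"))

  # unreachable instances are warnings, not failures
  reg3 <- federated_registry(
    federated_instance("https://one.example", db1),
    federated_instance("https://down.example", NULL)
  )
  r <- federated_query(reg3, chromosome = "9", position = 21971172)
  expect_equal(nrow(r$hits), 3)
  expect_match(r$warnings, "unreachable")

  r <- federated_query(federated_registry(), chromosome = "9", position = 1)
  expect_equal(nrow(r$hits), 0)
  expect_match(r$notice, "No instances")
})

test_that("a single-instance federation equals direct public retrieval", {
  db <- api_db()
  reg <- federated_registry(federated_instance("https://solo.example", db))
  fed <- federated_query(reg, chromosome = "9", range = c(21970000, 21975000))
  direct <- query_records(db, "variant", viewer = NULL,
                          filters = list(chromosome = "9",
                                         range = c(21970000, 21975000)),
                          page_size = 1000)
  expect_equal(sort(fed$hits$dna_description), sort(direct$dna_description))
  expect_equal(nrow(fed$hits), nrow(direct))
})
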