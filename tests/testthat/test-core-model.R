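test_that("gene registration enforces uniqueness and input validity", {
  db <- lovd_instance("hg19")
  g <- register_gene(db, "CDKN2A", 1787, "9", "-")
  expect_equal(g$symbol, "CDKN2A")
  expect_equal(nrow(db$genes), 1)

  expect_error(register_gene(db, "CDKN2A", 9999, "9", "-"),
               class = "varlocus_conflict_error")
  expect_error(register_gene(db, "OTHER", 1787, "1", "+"),
               class = "varlocus_conflict_error")
  expect_error(register_gene(db, "", 5, "1", "+"),
               class = "varlocus_validation_error")
  expect_error(register_gene(db, "BAD", -1, "1", "+"),
               class = "varlocus_validation_error")
  expect_error(register_gene(db, "BAD", 5, "99", "+"),
               class = "varlocus_validation_error")
})

test_that("a gene can carry several transcripts, with exon validation", {
  db <- cdkn2a_like_db()
  txs <- list_transcripts(db, "CDKN2A")
  expect_setequal(txs$accession, c("NM_000077.4", "NM_058195.3"))

  expect_error(
    add_transcript(db, "CDKN2A", "BAD.1",
                   exons = rbind(c(100, 200), c(150, 300)),
                   cds_start = 120, cds_end = 280, strand = "+"),
    class = "varlocus_validation_error"
  )
  expect_error(
    add_transcript(db, "CDKN2A", "BAD.2",
                   exons = rbind(c(100, 200)),
                   cds_start = 120, cds_end = 280, strand = "+"),
    class = "varlocus_validation_error"
  )
  expect_error(add_transcript(db, "NOGENE", "X.1", rbind(c(1, 9)), 1, 9, "+"),
               class = "varlocus_validation_error")
})

test_that("coding length sums the exon/CDS intersections", {
  # CDS spans all three exons: portions 70 + 90 + 62
  tx <- toy_tx("+")
  expect_equal(coding_length(tx), 222)
  # oracle: enumerate exonic positions and count those inside the CDS span
  positions <- unlist(apply(tx$exons, 1, function(e) seq(e[1], e[2])))
  expect_equal(coding_length(tx),
               sum(positions >= tx$cds_start & positions <= tx$cds_end))
})

test_that("each observation is stored separately but shares a DBID", {
  db <- cdkn2a_like_db()
  ann <- list(list(accession = "NM_000077.4"))
  v1 <- create_variant_observation(db, "g.21971172C>T", "9", transcripts = ann)
  v2 <- create_variant_observation(db, "g.21971172C>T", "9", transcripts = ann)
  expect_equal(nrow(db$variants_genome), 2)
  expect_false(v1$variant$id == v2$variant$id)
  expect_equal(v1$variant$dbid, v2$variant$dbid)
  expect_equal(v1$variant$dbid, "CDKN2A_000001")
})

test_that("intergenic variants are stored without transcript annotation", {
  db <- cdkn2a_like_db()
  v <- create_variant_observation(db, "g.5000000A>G", "9")
  expect_equal(nrow(db$variants_transcript), 0)
  expect_equal(v$variant$dbid, "chr9_000001")
  # genome-wide listing includes it; gene listing does not
  all_v <- query_records(db, "variant", viewer = NULL,
                         filters = list(visibility = "non_public"))
  expect_equal(attr(all_v, "total_n"), 0) # anonymous cannot see non_public
  mgr <- add_user(db, "m", role_global = "manager")
  all_v <- query_records(db, "variant", viewer = mgr$id)
  expect_equal(attr(all_v, "total_n"), 1)
  gene_v <- query_records(db, "variant", viewer = mgr$id,
                          filters = list(gene = "CDKN2A"))
  expect_equal(attr(gene_v, "total_n"), 0)
})

test_that("one observation carries independent effects on two transcripts", {
  db <- cdkn2a_like_db()
  v <- create_variant_observation(
    db, "g.21971172C>T", "9",
    transcripts = list(
      list(accession = "NM_000077.4", effect_reported = "missense"),
      list(accession = "NM_058195.3", effect_reported = "synonymous")
    )
  )
  tx <- db$variants_transcript
  expect_equal(nrow(tx), 2)
  expect_setequal(tx$effect_reported, c("missense", "synonymous"))
  expect_true(all(tx$rna_description == "r.(?)"))
  expect_error(
    create_variant_observation(db, "g.21971000A>G", "9",
                               transcripts = list(list(accession = "NM_404.1"))),
    class = "varlocus_validation_error"
  )
  expect_error(
    create_variant_observation(db, "g.21971000A>G", "9", genome_build = "hg38"),
    class = "varlocus_validation_error"
  )
})

test_that("DBID allocation starts at 1, reuses, and honours seeded ids", {
  db <- lovd_instance("hg19")
  expect_equal(assign_dbid(db, "c.100A>G", gene_context = "DMD"), "DMD_000001")
  expect_equal(assign_dbid(db, "c.100A>G", gene_context = "DMD"), "DMD_000001")
  expect_equal(assign_dbid(db, "c.101A>G", gene_context = "DMD"), "DMD_000002")
  # intergenic fallback prefix has its own counter
  expect_equal(assign_dbid(db, "g.500A>G", chromosome = "9"), "chr9_000001")

  db2 <- lovd_instance("hg19")
  seed_dbid(db2, "DMD", 67, "NM_004006.2:c.10141C>T")
  expect_equal(assign_dbid(db2, "NM_004006.2:c.10141C>T", gene_context = "DMD"),
               "DMD_000067")
  # the next fresh description allocates past the seeded number
  expect_equal(assign_dbid(db2, "c.1A>G", gene_context = "DMD"), "DMD_000068")
})

test_that("custom columns are disease-scoped and core columns protected", {
  db <- lovd_instance("hg19")
  dA <- add_disease(db, "disease A")
  dB <- add_disease(db, "disease B")
  i1 <- add_individual(db)
  define_custom_column(db, "Phenotype/Age_of_onset", "phenotype", "integer")
  activate_column(db, "Phenotype/Age_of_onset", dA$id)

  ph <- add_phenotype(db, i1$id, dA$id, "2020-01-01",
                      custom_values = list("Phenotype/Age_of_onset" = 34))
  expect_equal(ph[["Phenotype/Age_of_onset"]], "34")
  # not active for disease B
  expect_error(
    add_phenotype(db, i1$id, dB$id, "2020-01-01",
                  custom_values = list("Phenotype/Age_of_onset" = 12)),
    class = "varlocus_validation_error"
  )
  # idempotent re-activation
  expect_silent(activate_column(db, "Phenotype/Age_of_onset", dA$id))
  # the RNA core field can never be deactivated
  expect_error(deactivate_column(db, "VariantOnTranscript/RNA"),
               class = "varlocus_validation_error")
})

test_that("core columns stay active under random activate/deactivate churn", {
  db <- lovd_instance("hg19")
  define_custom_column(db, "Individual/Remark", "individual")
  core_ids <- db$columns$column_id[db$columns$core]
  withr::with_seed(11, {
    for (k in 1:60) {
      cid <- sample(db$columns$column_id, 1)
      if (runif(1) < 0.5) {
        try(activate_column(db, cid), silent = TRUE)
      } else {
        try(deactivate_column(db, cid), silent = TRUE)
      }
    }
  })
  for (cid in core_ids) {
    expect_true(varlocus:::column_active_for(db, cid))
  }
  expect_true(all(db$columns$core[match(core_ids, db$columns$column_id)]))
})

test_that("queries filter by visibility, region and entity rules", {
  db <- cdkn2a_like_db()
  owner <- add_user(db, "owner")
  create_variant_observation(db, "g.21971172C>T", "9", visibility = "public",
                             owner_id = owner$id,
                             transcripts = list(list(accession = "NM_000077.4")))
  create_variant_observation(db, "g.21971200A>G", "9", visibility = "non_public",
                             owner_id = owner$id)
  # anonymous viewer sees only the public row
  v <- query_records(db, "variant", viewer = NULL)
  expect_equal(nrow(v), 1)
  expect_equal(v$visibility, "public")
  # a genomic range query needs no gene and finds the literature variant
  v <- query_records(db, "variant", viewer = owner$id,
                     filters = list(chromosome = "9",
                                    range = c(21970000, 21975000)))
  expect_true("g.21971172C>T" %in% v$dna_description)
  # phenotype listing requires a disease selection
  expect_error(query_records(db, "phenotype"),
               class = "varlocus_guidance_error")
  expect_error(query_records(db, "variant", filters = list(range = c(2, 1))),
               class = "varlocus_validation_error")
})

test_that("reference keys retrieve tagged individuals and variants", {
  db <- cdkn2a_like_db()
  mgr <- add_user(db, "m", role_global = "manager")
  add_individual(db, reference = "PMID:25533962")
  add_individual(db, reference = "PMID:11111111")
  create_variant_observation(db, "g.21971172C>T", "9",
                             reference = "PMID:25533962; DOI:10.1038/nature14135")
  create_variant_observation(db, "g.21971201A>G", "9",
                             reference = "PMID:25533962")

  hit <- filter_by_reference(db, "PMID:25533962", viewer = mgr$id)
  expect_equal(nrow(hit$individuals) + nrow(hit$variants), 3)
  hit <- filter_by_reference(db, "DOI:10.1038", viewer = mgr$id)
  expect_equal(nrow(hit$variants), 1)
  hit <- filter_by_reference(db, "PMID:99999999", viewer = mgr$id)
  expect_equal(nrow(hit$individuals) + nrow(hit$variants), 0)
  expect_error(filter_by_reference(db, "PM:123"),
               class = "varlocus_validation_error")
})

test_that("read-only mode refuses mutations but serves queries", {
  db <- cdkn2a_like_db()
  set_read_only(db, TRUE, "Maintenance until noon.")
  err <- tryCatch(create_variant_observation(db, "g.21971172C>T", "9"),
                  varlocus_read_only_error = function(e) e)
  expect_s3_class(err, "varlocus_read_only_error")
  expect_match(conditionMessage(err), "Maintenance until noon")
  v <- query_records(db, "variant")
  expect_equal(attr(v, "announcement"), "Maintenance until noon.")
  set_read_only(db, FALSE)
  expect_silent(create_variant_observation(db, "g.21971172C>T", "9"))
})

test_that("screenings without findings never link to variants", {
  db <- cdkn2a_like_db()
  ind <- add_individual(db)
  scr <- add_screening(db, ind$id, variants_found = FALSE)
  v <- create_variant_observation(db, "g.21971172C>T", "9")
  expect_error(varlocus:::link_screening_variant(db, scr$id, v$variant$id),
               class = "varlocus_validation_error")
})

test_that("longitudinal phenotypes allow repeat (individual, disease) pairs", {
  db <- lovd_instance("hg19")
  d <- add_disease(db, "toy")
  i <- add_individual(db)
  add_phenotype(db, i$id, d$id, "2019-01-01")
  add_phenotype(db, i$id, d$id, "2021-01-01")
  expect_equal(nrow(db$phenotypes), 2)
  expect_error(add_phenotype(db, i$id, d$id, "2021-01-01"),
               class = "varlocus_validation_error")
})
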