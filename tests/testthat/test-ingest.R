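ingest_db <- function() {
  db <- cdkn2a_like_db()
  owner <- add_user(db, "owner")
  for (p in c(21971172, 21971200, 21971300, 21971400, 21971500)) {
    ref <- substr(get_transcript(db, "NM_000077.4")$sequence,
                  p - get_transcript(db, "NM_000077.4")$seq_start + 1,
                  p - get_transcript(db, "NM_000077.4")$seq_start + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    create_variant_observation(db, sprintf("g.%d%s>%s", p, ref, alt), "9",
                               owner_id = owner$id,
                               transcripts = list(list(accession = "NM_000077.4")))
  }
  db
}

test_that("update import applies at most one change per entry", {
  db <- ingest_db()
  text <- export_sections(db, "Variants_On_Genome")
  # change one field on each of the 5 entries
  lines <- strsplit(text, "\n")[[1]]
  header <- strsplit(lines[2], "\t")[[1]]
  eff <- match("effect_reported", header)
  for (i in 3:7) {
    f <- strsplit(lines[i], "\t")[[1]]
    f[eff] <- "missense"
    lines[i] <- paste(f, collapse = "\t")
  }
  rep <- import_update_file(db, paste(lines, collapse = "\n"), mode = "update")
  expect_false(rep$fatal)
  expect_equal(rep$accepted, 5)
  expect_true(all(db$variants_genome$effect_reported == "missense"))
})

test_that("two changes on one entry reject the whole file atomically", {
  db <- ingest_db()
  before <- varlocus:::db_snapshot(db)
  text <- export_sections(db, "Variants_On_Genome")
  lines <- strsplit(text, "\n")[[1]]
  header <- strsplit(lines[2], "\t")[[1]]
  # entry 1: a legitimate single change; entry 2: two changed fields
  f <- strsplit(lines[3], "\t")[[1]]
  f[match("effect_reported", header)] <- "missense"
  lines[3] <- paste(f, collapse = "\t")
  f <- strsplit(lines[4], "\t")[[1]]
  f[match("effect_reported", header)] <- "missense"
  f[match("visibility", header)] <- "public"
  lines[4] <- paste(f, collapse = "\t")
  rep <- import_update_file(db, paste(lines, collapse = "\n"), mode = "update")
  expect_true(rep$fatal)
  expect_equal(rep$accepted, 0)
  expect_match(paste(rep$messages$message, collapse = " "), "More than one change")
  # byte-identical database state
  expect_identical(varlocus:::db_snapshot(db), before)
})

test_that("unknown ids and malformed headers are fatal; simulate never writes", {
  db <- ingest_db()
  before <- varlocus:::db_snapshot(db)
  text <- export_sections(db, "Variants_On_Genome")
  bad <- sub("\n1\t", "\n999\t", text, fixed = TRUE)
  rep <- import_update_file(db, bad, mode = "update")
  expect_true(rep$fatal)
  expect_identical(varlocus:::db_snapshot(db), before)

  rep <- import_update_file(db, "### Nonsense_Table\nid\n1\n", mode = "update")
  expect_true(rep$fatal)

  lines <- strsplit(text, "\n")[[1]]
  header <- strsplit(lines[2], "\t")[[1]]
  f <- strsplit(lines[3], "\t")[[1]]
  f[match("effect_reported", header)] <- "missense"
  lines[3] <- paste(f, collapse = "\t")
  rep <- import_update_file(db, paste(lines, collapse = "\n"), mode = "simulate")
  expect_false(rep$fatal)
  expect_equal(rep$accepted, 1)
  expect_identical(varlocus:::db_snapshot(db), before)
})

test_that("an unchanged export re-imports with zero changes", {
  db <- ingest_db()
  rep <- import_update_file(db, export_sections(db), mode = "update")
  expect_false(rep$fatal)
  expect_equal(rep$accepted, 0)
  expect_equal(nrow(rep$messages), 0)
})

test_that("find and replace counts, previews and protects mandatory fields", {
  db <- ingest_db()
  mgr <- add_user(db, "mgr", role_global = "manager")
  db$variants_genome$reference <- c("hg19 map", "hg19 set", "hg19", NA, "other")
  r <- find_and_replace(db, "variant", "reference", "hg19", "GRCh37",
                        preview = TRUE, actor = mgr$id)
  expect_equal(r$affected, 3)
  expect_false(r$written)
  expect_false(any(grepl("GRCh37", db$variants_genome$reference), na.rm = TRUE))
  r <- find_and_replace(db, "variant", "reference", "hg19", "GRCh37",
                        preview = FALSE, actor = mgr$id)
  expect_equal(r$affected, 3)
  expect_equal(sum(grepl("GRCh37", db$variants_genome$reference), na.rm = TRUE), 3)
  # emptying the mandatory DNA field is refused
  full <- db$variants_genome$dna_description[1]
  expect_error(
    find_and_replace(db, "variant", "VariantOnGenome/DNA", full, "",
                     preview = FALSE, actor = mgr$id),
    class = "varlocus_validation_error"
  )
  # plain submitters may not run it
  sub <- add_user(db, "sub")
  expect_error(
    find_and_replace(db, "variant", "reference", "x", "y", actor = sub$id),
    class = "varlocus_authorization_error"
  )
})

test_that("VCF records convert to HGVS g. descriptions", {
  db <- lovd_instance("hg19")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=9>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "9\t21971172\t.\tC\tT\t.\t.\t.",
    "9\t500\t.\tAT\tA\t.\t.\t.",
    "9\t600\t.\tA\tAGG\t.\t.\t.",
    "9\t700\t.\tACGT\tATTT\t.\t.\t.",
    "9\t800\t.\tG\tC,A\t.\t.\t.",
    "9\t900\t.\tG\t.\t.\t.\t."
  ), vcf)
  drafts <- import_vcf(db, vcf, "hg19")
  expect_equal(drafts$dna_description[drafts$position == 21971172], "g.21971172C>T")
  # anchor-base stripping: deletion of the T at position 501
  expect_equal(drafts$dna_description[drafts$position == 500], "g.501del")
  expect_false(drafts$normalized[drafts$position == 500])
  expect_equal(drafts$dna_description[drafts$position == 600], "g.600_601insGG")
  # shared prefix A and shared suffix T are trimmed: CG -> TT remains
  expect_equal(drafts$dna_description[drafts$position == 700], "g.701_702delinsTT")
  # multi-allelic sites split into one draft per ALT
  expect_equal(sum(drafts$position == 800), 2)
  # '.' ALT is skipped with a message
  expect_match(drafts$message[drafts$position == 900], "skipped")
  expect_error(import_vcf(db, vcf, "hg38"), class = "varlocus_validation_error")
})

test_that("indels are 3'-shifted when sequence is available", {
  db <- lovd_instance("hg19")
  #        1234567890123
  seqctx <- "GGATTTTCAGGGG"
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t3\t.\tAT\tA\t.\t.\t.",      # deletes one T of the T-run 4..7
    "1\t3\t.\tA\tAT\t.\t.\t."       # inserts a T into the same run
  ), vcf)
  drafts <- import_vcf(db, vcf, "hg19", sequence = seqctx, seq_start = 1L)
  # deletion shifts to the 3'-most T (position 7)
  expect_equal(drafts$dna_description[1], "g.7del")
  expect_true(drafts$normalized[1])
  # insertion of T after a T-run is a duplication of the run's last base
  expect_equal(drafts$dna_description[2], "g.7dup")
})

test_that("VCF conversion and direct allele comparison agree on random fixtures", {
  db <- lovd_instance("hg19")
  withr::with_seed(31, {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    lines <- c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    truth <- list()
    for (k in 1:40) {
      pos <- sample(50:400, 1)
      type <- sample(c("snv", "del", "ins"), 1)
      ref_here <- substr(s, pos, pos)
      if (type == "snv") {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_here), 1)
        lines <- c(lines, sprintf("1\t%d\t.\t%s\t%s\t.\t.\t.", pos, ref_here, alt))
        truth[[k]] <- list(kind = "substitution", n = 1L)
      } else if (type == "del") {
        n <- sample(1:4, 1)
        ref <- substr(s, pos, pos + n)
        lines <- c(lines, sprintf("1\t%d\t.\t%s\t%s\t.\t.\t.", pos, ref, ref_here))
        truth[[k]] <- list(kind = "deletion", n = n)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE),
                     collapse = "")
        lines <- c(lines, sprintf("1\t%d\t.\t%s\t%s%s\t.\t.\t.",
                                  pos, ref_here, ref_here, ins))
        truth[[k]] <- list(kind = c("insertion", "duplication"), n = nchar(ins))
      }
    }
    vcf <- tempfile(fileext = ".vcf")
    writeLines(lines, vcf)
    drafts <- import_vcf(db, vcf, "hg19", sequence = s, seq_start = 1L)
    expect_equal(nrow(drafts), 40)
    for (k in 1:40) {
      pv <- parse_description(drafts$dna_description[k])
      expect_true(pv$kind %in% truth[[k]]$kind)
      affected <- switch(pv$kind,
        substitution = 1L,
        deletion = pv$end - pv$start + 1L,
        duplication = pv$end - pv$start + 1L,
        insertion = nchar(pv$alt_seq)
      )
      expect_equal(affected, truth[[k]]$n, info = drafts$dna_description[k])
    }
  })
})

test_that("BED export groups observations and converts coordinates", {
  db <- ingest_db()
  mgr <- add_user(db, "m2", role_global = "manager")
  # duplicate the first observation so grouping is exercised
  d <- db$variants_genome$dna_description[1]
  create_variant_observation(db, d, "9")
  v <- query_records(db, "variant", viewer = mgr$id, page_size = 100)
  bed <- export_bed(v, track_name = "toy")
  lines <- strsplit(bed, "\n")[[1]]
  expect_match(lines[1], '^track name="toy"')
  expect_equal(length(lines) - 1, 5) # 6 observations, 5 unique descriptions
  # 1-based [21971172, 21971172] becomes 0-based half-open [21971171, 21971172)
  hit <- grep("21971171\t21971172", lines, value = TRUE)
  expect_length(hit, 1)
  expect_match(hit, "^chr9\t")
  expect_equal(export_bed(v[0, ]), 'track name="varlocus" description="variant track"\n')
})

test_that("legacy flat rows split into the eight-table layout", {
  flat <- tibble::tibble(
    patientid = c("P1", "P1", "P2", "", "P3"),
    gene = "CDKN2A",
    transcript = "NM_000077.4",
    cdna = c("c.9C>G", "c.15A>G", "c.9C>G", "c.1A>G", ""),
    genomic_dna = c("g.21971990G>C", "g.21971984T>C", "g.21971990G>C",
                    "g.1A>G", ""),
    chromosome = "9",
    disease = c("melanoma", "melanoma", NA, NA, "melanoma")
  )
  out <- convert_legacy_rows(flat)
  # rows 4 (no patient id) and 5 (no DNA) fail at row level
  expect_equal(nrow(out$errors), 2)
  expect_setequal(out$errors$message, c("Missing patient id.", "Missing DNA field."))
  # P1's two rows share one individual
  expect_equal(nrow(out$individuals), 2)
  expect_equal(nrow(out$variants_genome), 3)
  expect_equal(nrow(out$variants_transcript), 3)
  expect_equal(nrow(out$screenings), 3)
  expect_equal(nrow(out$screenings_variants), 3)
  expect_equal(nrow(out$diseases), 1)
  expect_length(out, 9) # 8 tables + errors
})
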