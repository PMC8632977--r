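# Deterministic synthetic fixtures: toy loci (optionally a dual-reading-frame
# locus emulating the CDKN2A p16/p14ARF configuration), variant observation
# streams with a controlled duplication rate, case hierarchies and submission
# documents. All randomness flows through R's Mersenne-Twister generator under
# withr::with_seed, so one seed + spec always yields identical output.
#
# Coding regions are drawn from the {A, C, G} alphabet only: every stop codon
# (TAA, TAG, TGA) contains both T and A, so a T-free plus strand and its
# (A-free) reverse complement are stop-free in all three frames. This makes
# any CDS span with length divisible by 3 a valid open reading frame without
# rejection sampling.

#' Describe a synthetic fixture
#'
#' @param seed Integer seed; the same seed and spec always generate identical
#'   fixtures.
#' @param n_genes Number of toy genes.
#' @param n_transcripts_per_gene Transcripts configured per gene.
#' @param exon_count_range Inclusive range of exon counts per transcript.
#' @param locus_length Length of each gene's locus sequence in bp.
#' @param n_individuals,n_observations Case-hierarchy sizes.
#' @param duplicate_description_rate Probability in `[0, 1]` that an
#'   observation repeats an already-generated description (exercises DBID
#'   grouping).
#' @param divergent_locus If `TRUE`, the first gene carries two transcripts
#'   sharing exonic sequence in reading frames offset by one base, so single
#'   substitutions can be protein-changing on one and silent on the other.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 1L, n_transcripts_per_gene = 1L,
                         exon_count_range = c(3L, 6L), locus_length = 8000L,
                         n_individuals = 10L, n_observations = 100L,
                         duplicate_description_rate = 0.5,
                         divergent_locus = FALSE) {
  if (length(exon_count_range) != 2 || any(exon_count_range < 1)) {
    abort_validation("exon_count_range must be two values >= 1.")
  }
  if (duplicate_description_rate < 0 || duplicate_description_rate > 1) {
    abort_validation("duplicate_description_rate must lie in [0, 1].")
  }
  if (n_genes < 1) abort_validation("n_genes must be >= 1.")
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_transcripts_per_gene = as.integer(n_transcripts_per_gene),
      exon_count_range = as.integer(exon_count_range),
      locus_length = as.integer(locus_length),
      n_individuals = as.integer(n_individuals),
      n_observations = as.integer(n_observations),
      duplicate_description_rate = duplicate_description_rate,
      divergent_locus = isTRUE(divergent_locus)
    ),
    class = "fixture_spec"
  )
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate toy genes, transcript models and locus sequence
#'
#' Every generated transcript satisfies the model invariants (sorted
#' non-overlapping exons, CDS inside exons, coding length a positive multiple
#' of 3) and carries its locus sequence, so effect prediction works out of the
#' box.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `toy_locus`: `genes` (tibble), `transcripts` (named
#'   list of [transcript_model()]), `fasta` (named character vector of locus
#'   sequences).
#' @export
generate_locus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    genes <- list()
    transcripts <- list()
    fasta <- character()
    tx_counter <- 0L
    for (g in seq_len(spec$n_genes)) {
      symbol <- sprintf("TG%02d", g)
      chromosome <- as.character(sample(1:22, 1))
      strand <- sample(c("+", "-"), 1)
      base <- 100000L + (g - 1L) * (spec$locus_length + 1000L)
      dual <- spec$divergent_locus && g == 1L

      n_exons <- if (dual) 1L else {
        rng <- seq(spec$exon_count_range[1], spec$exon_count_range[2])
        rng[sample.int(length(rng), 1)]
      }
      exon_lens <- if (dual) {
        min(900L, spec$locus_length - 400L)
      } else {
        sample(60:180, n_exons, replace = TRUE)
      }
      intron_lens <- if (n_exons > 1) sample(80:400, n_exons - 1, replace = TRUE) else integer()
      span <- sum(exon_lens) + sum(intron_lens)
      if (span + 200L > spec$locus_length) {
        abort_validation(sprintf(
          "Locus of %d bp is too short for the requested exon structure (%d bp).",
          spec$locus_length, span + 200L
        ))
      }
      starts <- base + 100L + cumsum(c(0L, head(exon_lens, -1) + intron_lens))
      exons <- cbind(starts, starts + exon_lens - 1L)

      # CDS: start a little into the first exon, end inside the last, trimmed
      # to a multiple of 3.
      cds_start <- exons[1, 1] + sample(9:30, 1)
      cds_end <- exons[n_exons, 2] - sample(9:30, 1)
      probe <- transcript_model("probe", symbol, exons, cds_start, cds_end, strand)
      cds_end <- cds_end - coding_length(probe) %% 3L

      seq_chars <- strsplit(random_sequence(spec$locus_length), "")[[1]]
      lo <- pmax(exons[, 1], cds_start) - base + 1L
      hi <- pmin(exons[, 2], cds_end) - base + 1L
      for (i in seq_len(n_exons)) {
        if (lo[i] <= hi[i]) {
          seq_chars[lo[i]:hi[i]] <- sample(c("A", "C", "G"), hi[i] - lo[i] + 1L,
                                           replace = TRUE)
        }
      }
      sequence <- paste(seq_chars, collapse = "")

      genes[[g]] <- tibble(
        symbol = symbol, hgnc_id = 10000L + g, chromosome = chromosome,
        strand = strand, name = sprintf("toy gene %d", g)
      )
      n_tx <- if (dual) 2L else spec$n_transcripts_per_gene
      for (t in seq_len(n_tx)) {
        tx_counter <- tx_counter + 1L
        acc <- sprintf("NM_9%05d.1", tx_counter)
        if (dual && t == 2L) {
          # same exon, reading frame shifted by one base
          tx <- transcript_model(acc, symbol, exons, cds_start + 1L,
                                 cds_end + 1L, strand, sequence, base)
        } else {
          # additional isoforms truncate the CDS by whole codons
          shift <- 3L * (t - 1L)
          tx <- transcript_model(acc, symbol, exons, cds_start,
                                 cds_end - shift, strand, sequence, base)
        }
        transcripts[[acc]] <- tx
      }
      fasta[sprintf("%s:%s:%d-%d", symbol, chromosome, base,
                    base + spec$locus_length - 1L)] <- sequence
    }
    structure(
      list(genes = bind_rows(genes), transcripts = transcripts, fasta = fasta),
      class = "toy_locus"
    )
  })
}

#' Write a toy locus to FASTA
#'
#' @param locus A `toy_locus` from [generate_locus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(locus, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(locus$fasta), path)
  invisible(path)
}

#' Exonic genomic positions inside a transcript's CDS
#'
#' @param tx A [transcript_model()].
#' @return Integer vector of genomic positions, ascending.
#' @export
coding_positions <- function(tx) {
  lo <- pmax(tx$exons[, 1], tx$cds_start)
  hi <- pmin(tx$exons[, 2], tx$cds_end)
  unlist(lapply(which(lo <= hi), function(i) seq(lo[i], hi[i])))
}

#' Generate a case hierarchy and a variant observation stream
#'
#' Observations are single-base coding substitutions on the locus's first
#' transcript; duplicates of earlier descriptions occur at the configured
#' rate. Individuals carry one to three longitudinal phenotype records and one
#' screening each; about 10% of screenings found no variants (and receive no
#' observations).
#'
#' @param spec A [fixture_spec()].
#' @param locus A `toy_locus` from [generate_locus()].
#' @return List of tibbles: `diseases`, `individuals`, `phenotypes`,
#'   `screenings`, `observations`.
#' @export
generate_observations <- function(spec, locus) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(locus, "toy_locus"))
  tx <- locus$transcripts[[1]]
  gene <- tx$gene_symbol
  chromosome <- locus$genes$chromosome[match(gene, locus$genes$symbol)]
  pool <- coding_positions(tx)
  base_at <- function(p) substr(tx$sequence, p - tx$seq_start + 1, p - tx$seq_start + 1)

  withr::with_seed(spec$seed, {
    diseases <- tibble(key = 1:2, name = c("toy syndrome A", "toy syndrome B"))
    individuals <- tibble(key = seq_len(spec$n_individuals))
    phenotypes <- list()
    for (i in individuals$key) {
      k <- sample(1:3, 1)
      phenotypes[[i]] <- tibble(
        individual_key = i,
        disease_key = sample(diseases$key, 1),
        observation_date = sprintf("20%02d-0%d-01", 18 + seq_len(k), seq_len(k))
      )
    }
    phenotypes <- bind_rows(phenotypes)
    screenings <- tibble(
      key = seq_len(spec$n_individuals),
      individual_key = seq_len(spec$n_individuals),
      technique = sample(c("SEQ-NG", "SANGER"), spec$n_individuals, replace = TRUE),
      variants_found = runif(spec$n_individuals) > 0.1
    )
    carriers <- screenings$key[screenings$variants_found]

    seen <- character()
    obs <- vector("list", spec$n_observations)
    for (k in seq_len(spec$n_observations)) {
      if (length(seen) > 0 && runif(1) < spec$duplicate_description_rate) {
        desc <- sample(seen, 1)
      } else {
        repeat {
          p <- sample(pool, 1)
          ref <- base_at(p)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
          desc <- sprintf("g.%d%s>%s", p, ref, alt)
          if (!desc %in% seen) break
        }
        seen <- c(seen, desc)
      }
      obs[[k]] <- tibble(
        dna_description = desc, chromosome = chromosome, gene = gene,
        transcript_accession = tx$accession,
        screening_key = if (length(carriers)) {
          carriers[sample.int(length(carriers), 1)]
        } else {
          NA_integer_
        }
      )
    }
    list(
      diseases = diseases, individuals = individuals, phenotypes = phenotypes,
      screenings = screenings, observations = bind_rows(obs)
    )
  })
}

#' Build and populate a database instance from a fixture spec
#'
#' Creates an instance, registers the generated genes and transcripts, a
#' manager and a submitter account, the case hierarchy, and inserts every
#' generated observation through [create_variant_observation()] (so DBID
#' grouping and the two-table layout are exercised end to end).
#'
#' @param spec A [fixture_spec()].
#' @param locus Optionally a pre-generated `toy_locus` (default: generated
#'   from `spec`).
#' @return A populated [lovd_instance()].
#' @export
fixture_instance <- function(spec, locus = generate_locus(spec)) {
  db <- lovd_instance("hg19")
  for (i in seq_len(nrow(locus$genes))) {
    g <- locus$genes[i, ]
    register_gene(db, g$symbol, g$hgnc_id, g$chromosome, g$strand, g$name)
  }
  for (tx in locus$transcripts) {
    add_transcript(db, tx$gene_symbol, tx$accession, tx$exons, tx$cds_start,
                   tx$cds_end, tx$strand, tx$sequence, tx$seq_start)
  }
  manager <- add_user(db, "fixture manager", role_global = "manager")
  submitter <- add_user(db, "fixture submitter")
  fx <- generate_observations(spec, locus)

  disease_ids <- integer()
  for (i in seq_len(nrow(fx$diseases))) {
    disease_ids[fx$diseases$key[i]] <- add_disease(db, fx$diseases$name[i])$id
  }
  ind_ids <- integer()
  for (i in fx$individuals$key) {
    ind_ids[i] <- add_individual(db, visibility = "non_public",
                                 owner_id = submitter$id)$id
  }
  for (i in seq_len(nrow(fx$phenotypes))) {
    ph <- fx$phenotypes[i, ]
    add_phenotype(db, ind_ids[ph$individual_key],
                  disease_ids[ph$disease_key], ph$observation_date)
  }
  scr_ids <- integer()
  for (i in seq_len(nrow(fx$screenings))) {
    s <- fx$screenings[i, ]
    scr_ids[s$key] <- add_screening(db, ind_ids[s$individual_key],
                                    technique = s$technique,
                                    genes_screened = locus$genes$symbol[1],
                                    variants_found = s$variants_found)$id
  }
  for (i in seq_len(nrow(fx$observations))) {
    o <- fx$observations[i, ]
    tx <- locus$transcripts[[o$transcript_accession]]
    pv <- parse_description(o$dna_description)
    cv <- genomic_substitution_on_transcript(tx, pv$start, pv$ref_seq, pv$alt_seq)
    eff <- if (is.null(cv)) "unknown" else predict_substitution_effect(tx, cv)
    obs <- create_variant_observation(
      db, o$dna_description, o$chromosome, owner_id = submitter$id,
      transcripts = list(list(
        accession = o$transcript_accession,
        cdna_description = if (!is.null(cv)) render_description(cv),
        effect_reported = eff
      ))
    )
    if (!is.na(o$screening_key)) {
      link_screening_variant(db, scr_ids[o$screening_key], obs$variant$id)
    }
  }
  db
}

#' Generate a submission document plus targeted invalid mutants
#'
#' The valid document passes [validate_submission()]; each mutant fails with
#' exactly the rule its name targets.
#'
#' @param spec A [fixture_spec()].
#' @param db A populated [lovd_instance()] (e.g. from [fixture_instance()])
#'   providing transcripts and diseases to reference.
#' @return List with `valid` (a submission document) and `mutants` (named list
#'   of documents: `no_individual`, `missing_dna`, `bad_effect`,
#'   `unknown_transcript`).
#' @export
generate_submission_doc <- function(spec, db) {
  stopifnot(inherits(spec, "fixture_spec"))
  tx <- db$transcripts[[1]]
  gene_row <- db$genes[db$genes$symbol == tx$gene_symbol, ]
  withr::with_seed(spec$seed + 7L, {
    p <- sample(coding_positions(tx), 1)
    ref <- substr(tx$sequence, p - tx$seq_start + 1, p - tx$seq_start + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    valid <- list(
      individual = list(
        reference = "PMID:25533962",
        phenotypes = list(list(disease_id = db$diseases$id[1],
                               observation_date = "2020-06-01"))
      ),
      variants = list(list(
        dna_description = sprintf("g.%d%s>%s", p, ref, alt),
        chromosome = gene_row$chromosome,
        effect_reported = "unknown",
        transcripts = list(list(accession = tx$accession))
      ))
    )
  })
  mutants <- list(
    no_individual = valid[setdiff(names(valid), "individual")],
    missing_dna = local({
      d <- valid
      d$variants[[1]]$dna_description <- NULL
      d
    }),
    bad_effect = local({
      d <- valid
      d$variants[[1]]$effect_reported <- "pathogenic"
      d
    }),
    unknown_transcript = local({
      d <- valid
      d$variants[[1]]$transcripts[[1]]$accession <- "NM_000000.0"
      d
    })
  )
  list(valid = valid, mutants = mutants)
}
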