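# Variant observations: genome-centered storage in two tables. Every
# submission creates a new VariantsOnGenome row (observations are never
# merged), with zero or more VariantsOnTranscripts rows attached. Unique
# variants are grouped only through the observation-independent DBID.

#' Assign (or look up) the DBID for a variant description
#'
#' The DBID groups all observations of one unique variant description under a
#' prefix: the gene symbol when the variant is annotated to a gene, otherwise
#' `chr<name>`. The first occurrence of a normalized description allocates the
#' next free 6-digit number in the prefix; later occurrences return the stored
#' DBID.
#'
#' @param db An [lovd_instance()].
#' @param dna_description HGVS description (normalized internally).
#' @param gene_context Gene symbol to use as prefix, or `NULL` for intergenic
#'   variants.
#' @param chromosome Chromosome name; required when `gene_context` is `NULL`.
#' @return The DBID as a string, e.g. `"DMD_000067"`.
#' @export
assign_dbid <- function(db, dna_description, gene_context = NULL,
                        chromosome = NULL) {
  if (is.null(gene_context)) {
    if (is.null(chromosome)) {
      abort_validation("Intergenic DBID assignment needs a chromosome.")
    }
    prefix <- paste0("chr", chromosome)
  } else {
    prefix <- gene_context
  }
  desc <- normalize_description(dna_description)
  reg <- db$dbid_registry
  hit <- reg$prefix == prefix & reg$description == desc
  if (any(hit)) {
    row <- reg[which(hit)[1], ]
    return(sprintf("%s_%06d", row$prefix, row$number))
  }
  in_prefix <- reg$number[reg$prefix == prefix]
  number <- if (length(in_prefix)) max(in_prefix) + 1L else 1L
  db$dbid_registry <- bind_rows(
    reg, tibble(prefix = prefix, number = number, description = desc)
  )
  sprintf("%s_%06d", prefix, number)
}

#' Seed a specific DBID into the registry
#'
#' Used when loading data that already carries DBIDs (e.g. converted legacy
#' databases), so later observations of the same description resolve to the
#' historical identifier.
#'
#' @param db An [lovd_instance()].
#' @param prefix DBID prefix (gene symbol or `chr<name>`).
#' @param number Positive integer.
#' @param dna_description Description the DBID belongs to.
#' @return The DBID string, invisibly.
#' @export
seed_dbid <- function(db, prefix, number, dna_description) {
  check_mutable(db)
  number <- as.integer(number)
  desc <- normalize_description(dna_description)
  reg <- db$dbid_registry
  if (any(reg$prefix == prefix & reg$number == number)) {
    abort_conflict(sprintf("DBID %s_%06d is already allocated.", prefix, number))
  }
  if (any(reg$prefix == prefix & reg$description == desc)) {
    abort_conflict("This description already carries a DBID in the prefix.")
  }
  db$dbid_registry <- bind_rows(
    reg, tibble(prefix = prefix, number = number, description = desc)
  )
  invisible(sprintf("%s_%06d", prefix, number))
}

#' Store one variant observation
#'
#' Each call creates one new genomic record, regardless of how many times the
#' same description has been recorded before; repeated descriptions share a
#' DBID. Zero transcript annotations are allowed (intergenic variants); each
#' annotation attaches one per-transcript record with its own effect fields.
#'
#' @param db An [lovd_instance()].
#' @param dna_description HGVS `g.` description; positions and alleles are
#'   derived from it.
#' @param chromosome Chromosome the variant lies on.
#' @param genome_build Must equal the instance build.
#' @param effect_reported,effect_concluded Genomic-level effect classes.
#' @param visibility `"public"` or `"non_public"`.
#' @param owner_id,created_by User ids.
#' @param reference Optional literature tags (`PMID:`/`DOI:`).
#' @param custom_values Named list for active variant-genome columns.
#' @param transcripts List of annotations, each a list with `accession`,
#'   optional `cdna_description`, `rna_description` (defaults to `"r.(?)"`;
#'   this core field is always present), `protein_description`,
#'   `effect_reported`, `effect_concluded`.
#' @return List with `variant` (one-row tibble) and `transcripts` (tibble).
#' @export
create_variant_observation <- function(db, dna_description, chromosome,
                                       genome_build = db$settings$genome_build,
                                       effect_reported = "unknown",
                                       effect_concluded = "unknown",
                                       visibility = c("non_public", "public"),
                                       owner_id = NA_integer_,
                                       created_by = owner_id,
                                       reference = NA_character_,
                                       custom_values = list(),
                                       transcripts = list()) {
  check_mutable(db)
  visibility <- arg_match(visibility)
  if (!identical(genome_build, db$settings$genome_build)) {
    abort_validation(sprintf(
      "Genome build mismatch: instance uses %s, observation declares %s.",
      db$settings$genome_build, genome_build
    ))
  }
  if (!chromosome %in% ALLOWED_CHROMOSOMES) {
    abort_validation(sprintf("Unknown chromosome '%s'.", chromosome))
  }
  pv <- parse_description(dna_description)
  if (pv$level != "g") {
    abort_validation("Genomic records require a g.-level description.")
  }
  span <- if (pv$kind == "insertion") c(pv$start, pv$start) else c(pv$start, pv$end)
  effect_reported <- check_effect_class(effect_reported, "effect_reported")
  effect_concluded <- check_effect_class(effect_concluded, "effect_concluded")

  tx_rows <- map(transcripts, function(ann) {
    acc <- ann$accession
    if (is.null(acc) || !acc %in% names(db$transcripts)) {
      abort_validation(sprintf("Unknown transcript accession %s.", acc %||% "<missing>"))
    }
    tibble(
      transcript_accession = acc,
      cdna_description = ann$cdna_description %||% NA_character_,
      rna_description = ann$rna_description %||% "r.(?)",
      protein_description = ann$protein_description %||% NA_character_,
      effect_reported = check_effect_class(ann$effect_reported %||% "unknown"),
      effect_concluded = check_effect_class(ann$effect_concluded %||% "unknown")
    )
  })
  genes <- sort(unique(map_chr(
    tx_rows, function(r) db$transcripts[[r$transcript_accession]]$gene_symbol
  )))
  dbid <- assign_dbid(
    db, dna_description,
    gene_context = if (length(genes)) genes[1] else NULL,
    chromosome = chromosome
  )
  now <- utc_now()
  vid <- next_id(db, "variant")
  row <- tibble(
    id = vid, chromosome = chromosome,
    position_start = as.double(span[1]), position_end = as.double(span[2]),
    ref_allele = pv$ref_seq, alt_allele = pv$alt_seq,
    dna_description = normalize_description(dna_description),
    genome_build = genome_build, dbid = dbid,
    effect_reported = effect_reported, effect_concluded = effect_concluded,
    visibility = visibility, owner_id = as.integer(owner_id),
    created_by = as.integer(created_by), created_at = now, edited_at = now,
    reference = reference
  )
  db$variants_genome <- insert_with_custom(db, "variants_genome", row,
                                           custom_values,
                                           scope = "variant_genome")
  if (length(tx_rows)) {
    tx_tbl <- bind_rows(tx_rows)
    tx_tbl <- mutate(tx_tbl, genomic_variant_id = vid,
                     .before = "transcript_accession")
    db$variants_transcript <- bind_rows(db$variants_transcript, tx_tbl)
  } else {
    tx_tbl <- db$variants_transcript[0, ]
  }
  list(variant = tail(db$variants_genome, 1), transcripts = tx_tbl)
}

# Genes a genomic variant is linked to, via its transcript annotations.
variant_genes <- function(db, variant_id) {
  accs <- db$variants_transcript$transcript_accession[
    db$variants_transcript$genomic_variant_id == variant_id
  ]
  sort(unique(map_chr(accs, function(a) db$transcripts[[a]]$gene_symbol)))
}

# Genes an individual is linked to, via screenings and their variants.
individual_genes <- function(db, individual_id) {
  scr <- db$screenings$id[db$screenings$individual_id == individual_id]
  g1 <- db$screenings_genes$gene_symbol[db$screenings_genes$screening_id %in% scr]
  vids <- db$screenings_variants$variant_id[db$screenings_variants$screening_id %in% scr]
  g2 <- unlist(lapply(vids, variant_genes, db = db))
  sort(unique(c(g1, g2)))
}

#' Query records with visibility filtering and paging
#'
#' Returns only records the viewer may see (see [can_view()]); anonymous
#' viewers see public records only. Genome-wide variant listings need no gene
#' selection; phenotype listings require a disease filter.
#'
#' @param db An [lovd_instance()].
#' @param entity_kind `"variant"`, `"individual"`, `"phenotype"` or
#'   `"screening"`.
#' @param filters Named list; supported keys: `chromosome`, `range`
#'   (`c(start, end)`, requires `chromosome`), `gene`, `disease`, `owner`,
#'   `visibility`, `dbid`, `dna_description`.
#' @param viewer User id, or `NULL` for anonymous access.
#' @param page,page_size Paging over the filtered set; the total row count is
#'   attached as attribute `total_n`.
#' @return A tibble of visible records.
#' @export
query_records <- function(db, entity_kind = c("variant", "individual",
                                              "phenotype", "screening"),
                          filters = list(), viewer = NULL,
                          page = 1, page_size = 25) {
  entity_kind <- arg_match(entity_kind)
  bad <- setdiff(names(filters),
                 c("chromosome", "range", "gene", "disease", "owner",
                   "visibility", "dbid", "dna_description"))
  if (length(bad)) {
    abort_validation(sprintf("Unknown filter(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!is.null(filters$range) &&
      (length(filters$range) != 2 || any(is.na(as.numeric(filters$range))) ||
       filters$range[1] > filters$range[2])) {
    abort_validation("range must be c(start, end) with start <= end.")
  }

  out <- switch(entity_kind,
    variant = {
      v <- db$variants_genome
      if (!is.null(filters$chromosome)) v <- v[v$chromosome == filters$chromosome, ]
      if (!is.null(filters$range)) {
        if (is.null(filters$chromosome)) {
          abort_validation("Range queries require a chromosome filter.")
        }
        r <- as.numeric(filters$range)
        v <- v[v$position_end >= r[1] & v$position_start <= r[2], ]
      }
      if (!is.null(filters$gene)) {
        keep_ids <- v$id[map_lgl(v$id, function(i) filters$gene %in% variant_genes(db, i))]
        v <- v[v$id %in% keep_ids, ]
      }
      if (!is.null(filters$dbid)) v <- v[v$dbid == filters$dbid, ]
      if (!is.null(filters$dna_description)) {
        v <- v[v$dna_description == normalize_description(filters$dna_description), ]
      }
      v
    },
    individual = db$individuals,
    phenotype = {
      if (is.null(filters$disease)) {
        abort_guidance(
          "Phenotype records are not listed without selecting a disease first."
        )
      }
      db$phenotypes[db$phenotypes$disease_id == filters$disease, ]
    },
    screening = db$screenings
  )
  if (!is.null(filters$owner) && "owner_id" %in% names(out)) {
    out <- out[!is.na(out$owner_id) & out$owner_id == filters$owner, ]
  }
  if (!is.null(filters$visibility) && "visibility" %in% names(out)) {
    out <- out[out$visibility == filters$visibility, ]
  }
  if (nrow(out)) {
    visible <- map_lgl(out$id, function(i) can_view(db, viewer, entity_kind, i))
    out <- out[visible, ]
  }
  total <- nrow(out)
  lo <- (page - 1) * page_size + 1
  out <- if (lo > total) out[0, ] else out[lo:min(total, lo + page_size - 1), ]
  attr(out, "total_n") <- total
  with_announcement(db, out)
}

#' Retrieve records tagged with a literature reference
#'
#' Matches individuals and genomic variants whose reference field carries the
#' key. `PMID:<digits>` matches exactly; `DOI:` keys match by prefix, so
#' `DOI:10.1038` retrieves every record tagged with a DOI under that prefix.
#'
#' @param db An [lovd_instance()].
#' @param reference_key `"PMID:<digits>"` or `"DOI:<prefix or full doi>"`.
#' @param viewer User id or `NULL`; visibility filtering applies.
#' @return List with tibbles `individuals` and `variants`.
#' @export
filter_by_reference <- function(db, reference_key, viewer = NULL) {
  if (grepl("^PMID:[0-9]+$", reference_key)) {
    match_fun <- function(field) {
      map_lgl(field, function(f) {
        !is.na(f) && reference_key %in% strsplit(f, "[;, ]+")[[1]]
      })
    }
  } else if (grepl("^DOI:10\\.[0-9]+(/\\S*)?$", reference_key)) {
    match_fun <- function(field) {
      map_lgl(field, function(f) {
        !is.na(f) && any(startsWith(strsplit(f, "[;, ]+")[[1]], reference_key))
      })
    }
  } else {
    abort_validation(
      "Reference key must be 'PMID:<digits>' or 'DOI:10.<prefix or full doi>'."
    )
  }
  ind <- db$individuals[match_fun(db$individuals$reference), ]
  var <- db$variants_genome[match_fun(db$variants_genome$reference), ]
  if (nrow(ind)) {
    ind <- ind[map_lgl(ind$id, function(i) can_view(db, viewer, "individual", i)), ]
  }
  if (nrow(var)) {
    var <- var[map_lgl(var$id, function(i) can_view(db, viewer, "variant", i)), ]
  }
  list(individuals = ind, variants = var)
}
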