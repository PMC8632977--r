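#' Create an in-memory LSDB instance
#'
#' The instance is the mutable database handle every other function operates
#' on: a set of relational tables (tibbles) mirroring the eight-table
#' full-submission layout, plus the transcript models, the custom-column
#' registry, the DBID registry, user accounts and instance settings. Like a
#' DBI connection, the handle has reference semantics: operations mutate it in
#' place and queries return tibbles.
#'
#' @param genome_build Reference genome build used by the whole instance,
#'   `"hg19"` or `"hg38"`. Fixed at creation; observations submitted against
#'   the other build are refused.
#' @return An object of class `lovd_instance`.
#' @examples
#' db <- lovd_instance("hg19")
#' register_gene(db, "CDKN2A", hgnc_id = 1787, chromosome = "9", strand = "-")
#' @export
lovd_instance <- function(genome_build = c("hg19", "hg38")) {
  genome_build <- arg_match(genome_build)
  db <- new.env(parent = emptyenv())
  db$settings <- list(genome_build = genome_build, read_only = FALSE,
                      announcement = NA_character_)
  db$genes <- tibble(
    symbol = character(), hgnc_id = integer(), chromosome = character(),
    strand = character(), name = character()
  )
  db$transcripts <- list()
  db$diseases <- tibble(id = integer(), name = character(), omim_id = integer())
  db$individuals <- tibble(
    id = integer(), visibility = character(), owner_id = integer(),
    reference = character()
  )
  db$phenotypes <- tibble(
    id = integer(), individual_id = integer(), disease_id = integer(),
    observation_date = character()
  )
  db$screenings <- tibble(
    id = integer(), individual_id = integer(), technique = character(),
    variants_found = logical()
  )
  db$screenings_genes <- tibble(screening_id = integer(), gene_symbol = character())
  db$screenings_variants <- tibble(screening_id = integer(), variant_id = integer())
  db$variants_genome <- tibble(
    id = integer(), chromosome = character(), position_start = double(),
    position_end = double(), ref_allele = character(), alt_allele = character(),
    dna_description = character(), genome_build = character(),
    dbid = character(), effect_reported = character(),
    effect_concluded = character(), visibility = character(),
    owner_id = integer(), created_by = integer(), created_at = character(),
    edited_at = character(), reference = character()
  )
  db$variants_transcript <- tibble(
    genomic_variant_id = integer(), transcript_accession = character(),
    cdna_description = character(), rna_description = character(),
    protein_description = character(), effect_reported = character(),
    effect_concluded = character()
  )
  db$dbid_registry <- tibble(
    prefix = character(), number = integer(), description = character()
  )
  db$columns <- core_column_registry()
  db$users <- tibble(
    id = integer(), name = character(), role_global = character(),
    curated_genes = list(), collaborator_genes = list(),
    auto_import = logical(), auto_publish = logical(),
    variant_only = logical(), token = character()
  )
  db$colleague_grants <- tibble(
    grantor_id = integer(), grantee_id = integer(), can_edit = logical()
  )
  db$queue <- list()
  db$counters <- list(
    individual = 0L, phenotype = 0L, screening = 0L, variant = 0L,
    disease = 0L, user = 0L, queue = 0L
  )
  class(db) <- "lovd_instance"
  db
}

#' @export
print.lovd_instance <- function(x, ...) {
  cat(sprintf(
    "<lovd_instance> build %s%s\n  %d gene(s), %d transcript(s), %d variant observation(s), %d individual(s)\n",
    x$settings$genome_build,
    if (x$settings$read_only) " [READ-ONLY]" else "",
    nrow(x$genes), length(x$transcripts), nrow(x$variants_genome),
    nrow(x$individuals)
  ))
  invisible(x)
}

next_id <- function(db, what) {
  db$counters[[what]] <- db$counters[[what]] + 1L
  db$counters[[what]]
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

check_mutable <- function(db) {
  if (isTRUE(db$settings$read_only)) abort_read_only(db$settings$announcement)
  invisible(TRUE)
}

ALLOWED_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "M")

EFFECT_CLASSES <- c("synonymous", "missense", "nonsense", "frameshift",
                    "in_frame", "splice", "no_effect", "unknown")

check_effect_class <- function(x, field = "effect") {
  if (is.na(x)) return("unknown")
  if (!x %in% EFFECT_CLASSES) {
    abort_validation(sprintf(
      "%s must be one of %s, got %s.", field,
      paste(EFFECT_CLASSES, collapse = ", "), x
    ))
  }
  x
}

#' Register a gene
#'
#' Gene symbols and HGNC IDs are unique instance-wide. Symbol verification
#' against an external registry is pluggable: pass a `verifier` function that
#' returns `TRUE` for acceptable symbols (the default offline stub accepts any
#' well-formed symbol).
#'
#' @param db An [lovd_instance()].
#' @param symbol Gene symbol (uppercase alphanumeric, may contain `-`).
#' @param hgnc_id Positive integer HGNC identifier.
#' @param chromosome Chromosome name: 1-22, X, Y or M.
#' @param strand `"+"` or `"-"`.
#' @param name Optional full gene name.
#' @param verifier Optional function `(symbol, hgnc_id) -> logical` standing in
#'   for a live registry lookup.
#' @return The registered gene as a one-row tibble, invisibly.
#' @export
register_gene <- function(db, symbol, hgnc_id, chromosome, strand = c("+", "-"),
                          name = NA_character_, verifier = NULL) {
  check_mutable(db)
  strand <- arg_match(strand)
  if (!is.character(symbol) || length(symbol) != 1 || !nzchar(symbol) ||
      !grepl("^[A-Z0-9][A-Z0-9-]*$", symbol)) {
    abort_validation("Gene symbol must be a non-empty uppercase identifier.")
  }
  hgnc_id <- as.integer(hgnc_id)
  if (is.na(hgnc_id) || hgnc_id <= 0) {
    abort_validation("hgnc_id must be a positive integer.")
  }
  if (!chromosome %in% ALLOWED_CHROMOSOMES) {
    abort_validation(sprintf("Unknown chromosome '%s'.", chromosome))
  }
  if (symbol %in% db$genes$symbol) {
    abort_conflict(sprintf("Gene symbol %s is already registered.", symbol))
  }
  if (hgnc_id %in% db$genes$hgnc_id) {
    abort_conflict(sprintf("HGNC ID %d is already registered.", hgnc_id))
  }
  if (!is.null(verifier) && !isTRUE(verifier(symbol, hgnc_id))) {
    abort_validation(sprintf("Gene symbol %s failed registry verification.", symbol))
  }
  row <- tibble(symbol = symbol, hgnc_id = hgnc_id, chromosome = chromosome,
                strand = strand, name = name)
  db$genes <- bind_rows(db$genes, row)
  invisible(row)
}

#' Attach a transcript model to a registered gene
#'
#' A gene may carry any number of transcripts, including models sharing exons
#' in different reading frames.
#'
#' @inheritParams register_gene
#' @param gene_symbol Symbol of an already registered gene.
#' @param accession Versioned transcript accession.
#' @param exons,cds_start,cds_end,strand,sequence,seq_start
#'   See [transcript_model()].
#' @return The stored [transcript_model()], invisibly.
#' @export
add_transcript <- function(db, gene_symbol, accession, exons, cds_start,
                           cds_end, strand = c("+", "-"), sequence = NULL,
                           seq_start = NULL) {
  check_mutable(db)
  if (!gene_symbol %in% db$genes$symbol) {
    abort_validation(sprintf("Gene %s is not registered.", gene_symbol))
  }
  if (accession %in% names(db$transcripts)) {
    abort_conflict(sprintf("Transcript %s is already configured.", accession))
  }
  tx <- transcript_model(accession, gene_symbol, exons, cds_start, cds_end,
                         strand, sequence, seq_start)
  db$transcripts[[accession]] <- tx
  invisible(tx)
}

#' Retrieve a configured transcript model
#'
#' @param db An [lovd_instance()].
#' @param accession Transcript accession.
#' @return A [transcript_model()].
#' @export
get_transcript <- function(db, accession) {
  tx <- db$transcripts[[accession]]
  if (is.null(tx)) {
    abort_validation(sprintf("Unknown transcript accession %s.", accession))
  }
  tx
}

#' List transcripts configured for a gene
#'
#' @param db An [lovd_instance()].
#' @param gene_symbol Gene symbol.
#' @return Tibble with one row per transcript.
#' @export
list_transcripts <- function(db, gene_symbol = NULL) {
  txs <- db$transcripts
  if (!is.null(gene_symbol)) {
    txs <- keep(txs, function(t) t$gene_symbol == gene_symbol)
  }
  tibble(
    accession = map_chr(txs, "accession"),
    gene_symbol = map_chr(txs, "gene_symbol"),
    strand = map_chr(txs, "strand"),
    n_exons = map_int(txs, function(t) nrow(t$exons)),
    coding_length = map_int(txs, coding_length)
  )
}

#' Register a disease
#'
#' @param db An [lovd_instance()].
#' @param name Disease name.
#' @param omim_id Optional OMIM identifier.
#' @return One-row tibble, invisibly.
#' @export
add_disease <- function(db, name, omim_id = NA_integer_) {
  check_mutable(db)
  if (!nzchar(name)) abort_validation("Disease name must be non-empty.")
  row <- tibble(id = next_id(db, "disease"), name = name,
                omim_id = as.integer(omim_id))
  db$diseases <- bind_rows(db$diseases, row)
  invisible(row)
}

#' Add an individual record
#'
#' @param db An [lovd_instance()].
#' @param visibility `"public"` or `"non_public"`.
#' @param owner_id Owning user id.
#' @param reference Optional literature reference tags (e.g.
#'   `"PMID:25533962"`), searchable via [filter_by_reference()].
#' @param custom_values Named list of values for active individual-scope
#'   custom columns.
#' @return One-row tibble, invisibly.
#' @export
add_individual <- function(db, visibility = c("non_public", "public"),
                           owner_id = NA_integer_, reference = NA_character_,
                           custom_values = list()) {
  check_mutable(db)
  visibility <- arg_match(visibility)
  row <- tibble(id = next_id(db, "individual"), visibility = visibility,
                owner_id = as.integer(owner_id), reference = reference)
  db$individuals <- insert_with_custom(db, "individuals", row, custom_values,
                                       scope = "individual")
  invisible(tail(db$individuals, 1))
}

#' Add a phenotype record for an individual
#'
#' Several phenotype records per (individual, disease) pair are allowed as
#' long as their observation dates differ, supporting longitudinal data.
#'
#' @param db An [lovd_instance()].
#' @param individual_id,disease_id Existing record ids.
#' @param observation_date ISO date string.
#' @param custom_values Named list of values for phenotype-scope columns
#'   active for the disease.
#' @return One-row tibble, invisibly.
#' @export
add_phenotype <- function(db, individual_id, disease_id, observation_date,
                          custom_values = list()) {
  check_mutable(db)
  if (!individual_id %in% db$individuals$id) {
    abort_validation("Unknown individual id.")
  }
  if (!disease_id %in% db$diseases$id) abort_validation("Unknown disease id.")
  dup <- db$phenotypes$individual_id == individual_id &
    db$phenotypes$disease_id == disease_id &
    db$phenotypes$observation_date == observation_date
  if (any(dup)) {
    abort_validation(
      "A phenotype record for this individual, disease and date already exists."
    )
  }
  row <- tibble(id = next_id(db, "phenotype"),
                individual_id = as.integer(individual_id),
                disease_id = as.integer(disease_id),
                observation_date = observation_date)
  db$phenotypes <- insert_with_custom(db, "phenotypes", row, custom_values,
                                      scope = "phenotype",
                                      target = disease_id)
  invisible(tail(db$phenotypes, 1))
}

#' Add a screening record
#'
#' A screening that found no variants is stored with `variants_found = FALSE`
#' and must never be linked to variants.
#'
#' @param db An [lovd_instance()].
#' @param individual_id Existing individual id.
#' @param technique Free-text screening technique.
#' @param genes_screened Character vector of gene symbols covered.
#' @param variants_found Whether the screening returned any variants.
#' @return One-row tibble, invisibly.
#' @export
add_screening <- function(db, individual_id, technique = NA_character_,
                          genes_screened = character(), variants_found = TRUE) {
  check_mutable(db)
  if (!individual_id %in% db$individuals$id) {
    abort_validation("Unknown individual id.")
  }
  unknown <- setdiff(genes_screened, db$genes$symbol)
  if (length(unknown)) {
    abort_validation(sprintf("Unknown gene(s): %s.", paste(unknown, collapse = ", ")))
  }
  row <- tibble(id = next_id(db, "screening"),
                individual_id = as.integer(individual_id),
                technique = technique, variants_found = variants_found)
  db$screenings <- bind_rows(db$screenings, row)
  if (length(genes_screened)) {
    db$screenings_genes <- bind_rows(
      db$screenings_genes,
      tibble(screening_id = row$id, gene_symbol = genes_screened)
    )
  }
  invisible(row)
}

# Link an existing variant observation to a screening.
link_screening_variant <- function(db, screening_id, variant_id) {
  check_mutable(db)
  scr <- db$screenings[db$screenings$id == screening_id, ]
  if (nrow(scr) == 0) abort_validation("Unknown screening id.")
  if (!isTRUE(scr$variants_found)) {
    abort_validation("A screening with variants_found = FALSE cannot link to variants.")
  }
  if (!variant_id %in% db$variants_genome$id) {
    abort_validation("Unknown variant id.")
  }
  db$screenings_variants <- bind_rows(
    db$screenings_variants,
    tibble(screening_id = as.integer(screening_id),
           variant_id = as.integer(variant_id))
  )
  invisible(db)
}

#' Put the instance into (or out of) read-only mode
#'
#' While set, every mutating operation is refused with an error carrying the
#' announcement; queries keep working and carry the announcement as an
#' attribute.
#'
#' @param db An [lovd_instance()].
#' @param flag `TRUE` to enable read-only mode.
#' @param announcement Text shown with every refusal and query while set.
#' @return The instance, invisibly.
#' @export
set_read_only <- function(db, flag, announcement = NA_character_) {
  db$settings$read_only <- isTRUE(flag)
  db$settings$announcement <- if (isTRUE(flag)) announcement else NA_character_
  invisible(db)
}

# Attach the read-only announcement to query output, if any.
with_announcement <- function(db, x) {
  if (isTRUE(db$settings$read_only)) {
    attr(x, "announcement") <- db$settings$announcement
  }
  x
}

# Snapshot / restore the full table state (used for atomic imports).
db_snapshot <- function(db) {
  nm <- c("genes", "transcripts", "diseases", "individuals", "phenotypes",
          "screenings", "screenings_genes", "screenings_variants",
          "variants_genome", "variants_transcript", "dbid_registry",
          "columns", "users", "colleague_grants", "queue", "counters",
          "settings")
  setNames(lapply(nm, function(n) db[[n]]), nm)
}

db_restore <- function(db, snapshot) {
  for (n in names(snapshot)) db[[n]] <- snapshot[[n]]
  invisible(db)
}
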