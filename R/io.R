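# Standard-format adapters for transcript structure and locus sequence.

#' Read transcript models from a GFF3 file
#'
#' Expects `exon` and `CDS` features carrying a `transcript_id` attribute
#' (and `gene_id`/`gene_name` for the gene symbol). The CDS span is taken as
#' the min/max over the transcript's CDS features.
#'
#' @param path GFF3 file.
#' @param sequence,seq_start Optional locus sequence to attach to every model.
#' @return Named list of [transcript_model()]s.
#' @export
read_transcripts_gff3 <- function(path, sequence = NULL, seq_start = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort_capability("Reading GFF3 requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(gr))
  if (!"transcript_id" %in% names(d)) {
    if ("Parent" %in% names(d)) {
      d$transcript_id <- vapply(d$Parent, function(p) {
        if (length(p)) as.character(p[[1]]) else NA_character_
      }, character(1))
    } else {
      abort_validation("GFF3 features need a transcript_id (or Parent) attribute.")
    }
  }
  gene_col <- intersect(c("gene_name", "gene_id"), names(d))[1]
  out <- list()
  for (acc in unique(stats::na.omit(d$transcript_id))) {
    sub <- d[!is.na(d$transcript_id) & d$transcript_id == acc, ]
    ex <- sub[tolower(sub$type) == "exon", c("start", "end")]
    cds <- sub[toupper(sub$type) == "CDS", c("start", "end")]
    if (nrow(ex) == 0 || nrow(cds) == 0) next
    ex <- ex[order(ex$start), ]
    out[[acc]] <- transcript_model(
      accession = acc,
      gene_symbol = if (!is.na(gene_col)) sub[[gene_col]][1] else NA_character_,
      exons = as.matrix(ex),
      cds_start = min(cds$start), cds_end = max(cds$end),
      strand = as.character(sub$strand[1]),
      sequence = sequence, seq_start = seq_start
    )
  }
  out
}

#' Read a locus sequence from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_locus_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}
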