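#' Construct a transcript model
#'
#' A transcript model is the exon structure of one transcript on the genome,
#' plus its CDS span and strand. It is the basis for genomic/cDNA coordinate
#' mapping, consequence prediction and the reading-frame checker. Coordinates
#' are 1-based and inclusive throughout; `cds_start < cds_end` in genomic
#' orientation regardless of strand (on the minus strand translation starts at
#' `cds_end`).
#'
#' @param accession Versioned transcript identifier, e.g. `"NM_000077.4"`.
#' @param gene_symbol Symbol of the gene the transcript belongs to.
#' @param exons Two-column matrix (or list of length-2 vectors) of genomic
#'   `[start, end]` spans, non-overlapping.
#' @param cds_start,cds_end Genomic CDS boundaries; both must fall inside
#'   exons.
#' @param strand `"+"` or `"-"`.
#' @param sequence Optional nucleotide string covering the locus (plus
#'   strand). Required for sequence-based effect prediction.
#' @param seq_start Genomic position of the first base of `sequence`
#'   (defaults to the first exon start).
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(accession, gene_symbol, exons, cds_start, cds_end,
                             strand = c("+", "-"), sequence = NULL,
                             seq_start = NULL) {
  strand <- arg_match(strand)
  if (is.list(exons)) exons <- do.call(rbind, lapply(exons, as.numeric))
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (nrow(exons) < 1) abort_validation("A transcript needs at least one exon.")
  if (any(exons[, 1] > exons[, 2])) {
    abort_validation("Exon start must not exceed exon end.")
  }
  ord <- order(exons[, 1])
  if (!identical(ord, seq_len(nrow(exons)))) {
    abort_validation("Exons must be sorted by genomic start.")
  }
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    abort_validation("Exons must not overlap or abut out of order.")
  }
  in_exon <- function(p) any(p >= exons[, 1] & p <= exons[, 2])
  if (cds_start > cds_end) abort_validation("cds_start must not exceed cds_end.")
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    abort_validation("CDS boundaries must fall inside exons.")
  }
  if (is.null(seq_start)) seq_start <- exons[1, 1]
  obj <- structure(
    list(
      accession = accession, gene_symbol = gene_symbol, exons = exons,
      cds_start = cds_start, cds_end = cds_end, strand = strand,
      sequence = sequence, seq_start = seq_start
    ),
    class = "transcript_model"
  )
  if (!is.null(sequence)) {
    span <- seq_start + nchar(sequence) - 1L
    if (exons[1, 1] < seq_start || exons[nrow(exons), 2] > span) {
      abort_validation("Provided sequence does not cover the exon span.")
    }
  }
  obj
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s, strand %s)\n  %d exon(s), CDS %d-%d, coding length %d nt%s\n",
    x$accession, x$gene_symbol, x$strand, nrow(x$exons),
    x$cds_start, x$cds_end, coding_length(x),
    if (is.null(x$sequence)) "" else ", sequence attached"
  ))
  invisible(x)
}

# Genomic span covered by the transcript (first exon start .. last exon end).
locus_span <- function(tx) c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2])

# Coding portion (intersection with the CDS span) of each exon, in nt.
exon_coding_lengths <- function(tx) {
  lo <- pmax(tx$exons[, 1], tx$cds_start)
  hi <- pmin(tx$exons[, 2], tx$cds_end)
  pmax(0, hi - lo + 1)
}

#' Total coding length of a transcript in nucleotides
#'
#' Sum over exons of the intersection of each exon with the CDS span.
#'
#' @param tx A [transcript_model()].
#' @return Integer number of coding nucleotides.
#' @export
coding_length <- function(tx) as.integer(sum(exon_coding_lengths(tx)))

# Exon matrix in transcript order: row 1 contains the 5'-most exon of the
# transcript (highest genomic coordinates on the minus strand).
exons_tx_order <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), , drop = FALSE]
}

# Extract the spliced CDS on the coding strand. Requires sequence.
cds_sequence <- function(tx) {
  if (is.null(tx$sequence)) {
    abort_capability(sprintf(
      "Transcript %s has no sequence attached; sequence-based prediction unavailable.",
      tx$accession
    ))
  }
  lo <- pmax(tx$exons[, 1], tx$cds_start)
  hi <- pmin(tx$exons[, 2], tx$cds_end)
  keep <- lo <= hi
  parts <- substring(tx$sequence, lo[keep] - tx$seq_start + 1, hi[keep] - tx$seq_start + 1)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

translate_dna <- function(s) {
  if (nchar(s) == 0) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}
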