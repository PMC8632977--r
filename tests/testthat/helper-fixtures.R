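# Shared toy objects, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw one element from a vector (safe for length-1 numeric vectors)
pick <- function(x) x[sample.int(length(x), 1)]

# Stop-free random coding alphabet (every stop codon needs T and A).
acg_seq <- function(n, seed = 42) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G"), n, replace = TRUE),
                               collapse = ""))
}

# A 3-exon toy transcript: exons 101-190 / 301-390 / 501-590, CDS 121-562
# (coding portions 70 + 90 + 62 = 222 nt). Sequence covers 1-700.
toy_tx <- function(strand = "+", accession = paste0("TOY", strand, ".1"),
                   seed = 42) {
  transcript_model(
    accession, "TOY",
    exons = rbind(c(101, 190), c(301, 390), c(501, 590)),
    cds_start = 121, cds_end = 562, strand = strand,
    sequence = acg_seq(700, seed), seq_start = 1
  )
}

# A locus mimicking the CDKN2A neighbourhood on chromosome 9, with the base at
# g.21971172 forced to C so the literature example variant parses cleanly.
cdkn2a_like_db <- function() {
  db <- lovd_instance("hg19")
  register_gene(db, "CDKN2A", 1787, "9", "-")
  seq_start <- 21970801
  s <- acg_seq(1500, seed = 99)
  substr(s, 21971172 - seq_start + 1, 21971172 - seq_start + 1) <- "C"
  # single exon 21970900-21972100, genomic CDS 21971000-21971998 (999 nt)
  add_transcript(db, "CDKN2A", "NM_000077.4",
                 exons = rbind(c(21970900, 21972100)),
                 cds_start = 21971000, cds_end = 21971998, strand = "-",
                 sequence = s, seq_start = seq_start)
  # same exon, reading frame shifted by one base
  add_transcript(db, "CDKN2A", "NM_058195.3",
                 exons = rbind(c(21970900, 21972100)),
                 cds_start = 21971001, cds_end = 21971999, strand = "-",
                 sequence = s, seq_start = seq_start)
  db
}

# Independent coordinate oracle: enumerate the full genomic -> c. table of a
# transcript by walking its exonic positions in transcript order (a different
# code path from the arithmetic in the package).
coordinate_table_oracle <- function(tx) {
  ex <- tx$exons
  plus_order <- unlist(lapply(seq_len(nrow(ex)), function(i) seq(ex[i, 1], ex[i, 2])))
  tx_order <- if (tx$strand == "+") plus_order else rev(plus_order)
  start_anchor <- if (tx$strand == "+") tx$cds_start else tx$cds_end
  end_anchor <- if (tx$strand == "+") tx$cds_end else tx$cds_start
  i_start <- match(start_anchor, tx_order)
  i_end <- match(end_anchor, tx_order)
  labels <- vapply(seq_along(tx_order), function(i) {
    if (i < i_start) as.character(i - i_start)
    else if (i <= i_end) as.character(i - i_start + 1)
    else paste0("*", i - i_end)
  }, character(1))
  data.frame(genomic = tx_order, c_label = labels, stringsAsFactors = FALSE)
}

# Independent effect oracle: rebuild the entire mutated locus sequence,
# re-extract and translate the full CDS, and classify by comparing proteins.
full_translation_oracle <- function(tx, gpos, alt_plus_strand) {
  s <- tx$sequence
  substr(s, gpos - tx$seq_start + 1, gpos - tx$seq_start + 1) <- alt_plus_strand
  tx2 <- tx
  tx2$sequence <- s
  before <- translate_str(varlocus:::cds_sequence(tx))
  after <- translate_str(varlocus:::cds_sequence(tx2))
  if (before == after) return("synonymous")
  diff_at <- which(strsplit(before, "")[[1]] != strsplit(after, "")[[1]])[1]
  if (substr(after, diff_at, diff_at) == "*") "nonsense" else "missense"
}

translate_str <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}
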