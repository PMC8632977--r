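#' Reading-frame check for whole-exon deletions and duplications
#'
#' Predicts whether removing or duplicating a contiguous run of exons
#' preserves the reading frame. Only the coding portion of each affected exon
#' counts: the change is `in_frame` when the summed coding length is a
#' positive multiple of 3, `frameshift` otherwise, and `no_coding_change` when
#' the affected exons carry no coding sequence at all (pure-UTR exons).
#' Deletions and duplications follow the same rule — both shift the frame iff
#' the affected coding length is not a multiple of 3.
#'
#' @param tx A [transcript_model()].
#' @param first_exon,last_exon 1-based exon ordinals in transcript order (exon
#'   1 is the transcript's 5'-most exon, which on the minus strand has the
#'   highest genomic coordinates).
#' @param kind `"deletion"` or `"duplication"`.
#' @return A one-row tibble with the exon range, the affected coding length
#'   and `frame_class`.
#' @examples
#' tx <- transcript_model("TOY.1", "TOY",
#'   exons = rbind(c(101, 190), c(301, 390), c(501, 590)),
#'   cds_start = 121, cds_end = 560, strand = "+")
#' predict_exon_change_frame(tx, 2, 2, "deletion")
#' @export
predict_exon_change_frame <- function(tx, first_exon, last_exon,
                                      kind = c("deletion", "duplication")) {
  kind <- arg_match(kind)
  n <- nrow(tx$exons)
  first_exon <- as.integer(first_exon)
  last_exon <- as.integer(last_exon)
  if (is.na(first_exon) || is.na(last_exon) ||
      first_exon < 1 || last_exon > n || first_exon > last_exon) {
    abort_validation(sprintf(
      "Exon ordinals must satisfy 1 <= first <= last <= %d.", n
    ))
  }
  # coding lengths in transcript order
  lens <- exon_coding_lengths(tx)
  if (tx$strand == "-") lens <- rev(lens)
  affected <- sum(lens[first_exon:last_exon])
  frame_class <- if (affected == 0) {
    "no_coding_change"
  } else if (affected %% 3 == 0) {
    "in_frame"
  } else {
    "frameshift"
  }
  tibble(
    transcript_accession = tx$accession, kind = kind,
    first_exon = first_exon, last_exon = last_exon,
    coding_length_affected = as.integer(affected),
    remainder_mod3 = as.integer(affected %% 3),
    frame_class = frame_class
  )
}
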