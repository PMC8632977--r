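#' @title HGVS descriptions: parsing, rendering, coordinate mapping
#' @description
#' The engine stores variants as HGVS descriptions on both the genomic (`g.`)
#' and coding-DNA (`c.`) level and works with a pragmatic subset of the
#' nomenclature: substitutions, deletions, duplications, insertions and
#' deletion-insertions. RNA (`r.`) and protein (`p.`) descriptions are carried
#' as free text.
#' @name hgvs
NULL

#' Construct a coding-DNA position
#'
#' `c.` positions combine a base number (negative for the 5' UTR, positive
#' within the CDS, `*n` — flagged by `utr3` — for the 3' UTR) with a signed
#' intron offset (0 for exonic positions).
#'
#' @param base Integer base number, never 0. For `utr3` positions this is the
#'   offset past the CDS end (the `n` of `*n`).
#' @param intron_offset Signed offset into the neighbouring intron; 0 = exonic.
#' @param utr3 Whether the position lies past the stop codon.
#' @return An object of class `position_c`.
#' @export
position_c <- function(base, intron_offset = 0L, utr3 = FALSE) {
  base <- as.integer(base)
  if (is.na(base) || base == 0) abort_validation("c. base number must be non-zero.")
  if (utr3 && base < 0) abort_validation("*n positions must have positive n.")
  structure(
    list(base = base, intron_offset = as.integer(intron_offset), utr3 = isTRUE(utr3)),
    class = "position_c"
  )
}

#' @export
format.position_c <- function(x, ...) {
  paste0(
    if (x$utr3) "*", x$base,
    if (x$intron_offset != 0) sprintf("%+d", x$intron_offset)
  )
}

#' @export
print.position_c <- function(x, ...) {
  cat("<position_c> c.", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.position_c` <- function(e1, e2) {
  e1$base == e2$base && e1$intron_offset == e2$intron_offset && e1$utr3 == e2$utr3
}

C_POS_RE <- "\\*?-?[0-9]+(?:[+-][0-9]+)?"

parse_c_pos <- function(s) {
  m <- regmatches(s, regexec("^(\\*)?(-?[0-9]+)([+-][0-9]+)?$", s))[[1]]
  if (length(m) == 0) abort_parse(sprintf("Invalid c. position '%s'.", s))
  base <- as.integer(m[3])
  if (base == 0) abort_parse("c. position 0 does not exist.")
  utr3 <- m[2] == "*"
  if (utr3 && base < 0) abort_parse("Negative *n position is invalid.")
  offset <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  position_c(base, offset, utr3)
}

#' Parse an HGVS variant description
#'
#' Accepts `g.` and `c.` descriptions of substitutions, deletions,
#' duplications, insertions and delins, optionally prefixed with a reference
#' accession (`NM_000077.4:c.301G>T`).
#'
#' @param text The description.
#' @return An object of class `hgvs_variant` with fields `reference`, `level`
#'   (`"g"` or `"c"`), `start`, `end` (integers for `g.`, [position_c()] for
#'   `c.`), `kind`, `ref_seq`, `alt_seq`.
#' @examples
#' parse_description("NC_000009.11:g.21971172C>T")
#' parse_description("NM_004006.2:c.10141C>T")
#' @export
parse_description <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    abort_parse("Empty variant description.")
  }
  text <- trimws(text)
  reference <- ""
  body <- text
  colon <- regexpr(":", text, fixed = TRUE)
  if (colon > 0) {
    reference <- substr(text, 1, colon - 1)
    body <- substr(text, colon + 1, nchar(text))
  }
  m <- regmatches(body, regexec("^([gc])\\.(.+)$", body))[[1]]
  if (length(m) == 0) {
    abort_parse(
      sprintf("Expected a 'g.' or 'c.' description, got '%s'.", body),
      position = colon + 1L
    )
  }
  level <- m[2]
  desc <- m[3]
  pos_re <- if (level == "g") "[0-9]+" else C_POS_RE
  p <- function(s) if (level == "g") as.integer(s) else parse_c_pos(s)

  grab <- function(pattern) {
    mm <- regmatches(desc, regexec(pattern, desc))[[1]]
    if (length(mm) == 0) NULL else mm
  }
  one <- sprintf("^(%s)", pos_re)
  rng <- sprintf("^(%s)(?:_(%s))?", pos_re, pos_re)

  if (!is.null(mm <- grab(paste0(one, "([ACGT])>([ACGT])$")))) {
    v <- list(kind = "substitution", start = p(mm[2]), end = p(mm[2]),
              ref_seq = mm[3], alt_seq = mm[4])
  } else if (!is.null(mm <- grab(paste0(rng, "delins([ACGT]+)$")))) {
    v <- list(kind = "delins", start = p(mm[2]),
              end = p(if (nzchar(mm[3])) mm[3] else mm[2]),
              ref_seq = "", alt_seq = mm[4])
  } else if (!is.null(mm <- grab(paste0(rng, "del([ACGT]*)$")))) {
    v <- list(kind = "deletion", start = p(mm[2]),
              end = p(if (nzchar(mm[3])) mm[3] else mm[2]),
              ref_seq = mm[4], alt_seq = "")
  } else if (!is.null(mm <- grab(paste0(rng, "dup([ACGT]*)$")))) {
    v <- list(kind = "duplication", start = p(mm[2]),
              end = p(if (nzchar(mm[3])) mm[3] else mm[2]),
              ref_seq = mm[4], alt_seq = "")
  } else if (!is.null(mm <- grab(paste0("^(", pos_re, ")_(", pos_re, ")ins([ACGT]+)$")))) {
    v <- list(kind = "insertion", start = p(mm[2]), end = p(mm[3]),
              ref_seq = "", alt_seq = mm[4])
  } else {
    abort_parse(
      sprintf("Unparseable variant description '%s'.", desc),
      position = nchar(text) - nchar(desc) + 1L
    )
  }
  if (level == "g" && v$kind != "insertion" && v$start > v$end) {
    abort_parse("Range start exceeds range end.")
  }
  if (level == "g" && v$kind == "insertion" && v$end != v$start + 1L) {
    abort_parse("Insertion positions must be adjacent (p_p+1).")
  }
  structure(
    c(list(reference = reference, level = level), v),
    class = "hgvs_variant"
  )
}

#' Render an HGVS variant to its normalized spelling
#'
#' Deleted/duplicated sequences are omitted from the rendering (the positions
#' define them), so `render_description(parse_description(x))` is a canonical
#' spelling of `x` and rendering is idempotent under re-parsing.
#'
#' @param v An `hgvs_variant`.
#' @return Character description.
#' @export
render_description <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  fmt <- function(p) if (v$level == "g") as.character(p) else format(p)
  same <- if (v$level == "g") v$start == v$end else v$start == v$end
  pos <- if (same && v$kind != "insertion") fmt(v$start) else {
    paste0(fmt(v$start), "_", fmt(v$end))
  }
  body <- switch(v$kind,
    substitution = paste0(fmt(v$start), v$ref_seq, ">", v$alt_seq),
    deletion = paste0(pos, "del"),
    duplication = paste0(pos, "dup"),
    insertion = paste0(fmt(v$start), "_", fmt(v$end), "ins", v$alt_seq),
    delins = paste0(pos, "delins", v$alt_seq)
  )
  paste0(
    if (nzchar(v$reference)) paste0(v$reference, ":"),
    v$level, ".", body
  )
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat("<hgvs_variant> ", render_description(x), "\n", sep = "")
  invisible(x)
}

# Canonical spelling used for DBID grouping; unparseable text passes through
# trimmed (stored as given, flagged unnormalized upstream).
normalize_description <- function(text) {
  tryCatch(render_description(parse_description(text)),
           varlocus_parse_error = function(e) trimws(text))
}

# ---- coordinate mapping ----------------------------------------------------

# Transcript-order index (1 = transcript 5' end) of an exonic genomic position,
# or NA if intronic.
tx_index_of_genomic <- function(tx, g) {
  ex <- tx$exons
  i <- which(g >= ex[, 1] & g <= ex[, 2])
  if (length(i) == 0) return(NA_integer_)
  before <- if (i > 1) sum(ex[seq_len(i - 1), 2] - ex[seq_len(i - 1), 1] + 1) else 0
  plus_idx <- before + (g - ex[i, 1] + 1)
  L <- sum(ex[, 2] - ex[, 1] + 1)
  as.integer(if (tx$strand == "+") plus_idx else L - plus_idx + 1)
}

genomic_of_tx_index <- function(tx, txi) {
  ex <- tx$exons
  L <- sum(ex[, 2] - ex[, 1] + 1)
  if (is.na(txi) || txi < 1 || txi > L) {
    abort_range("Transcript index outside the transcript.")
  }
  plus_idx <- if (tx$strand == "+") txi else L - txi + 1
  lens <- ex[, 2] - ex[, 1] + 1
  cum <- cumsum(lens)
  i <- which(plus_idx <= cum)[1]
  before <- if (i > 1) cum[i - 1] else 0
  as.integer(ex[i, 1] + (plus_idx - before) - 1)
}

# Transcript indices of the CDS boundaries (translation start / stop end).
cds_tx_bounds <- function(tx) {
  if (tx$strand == "+") {
    c(tx_index_of_genomic(tx, tx$cds_start), tx_index_of_genomic(tx, tx$cds_end))
  } else {
    c(tx_index_of_genomic(tx, tx$cds_end), tx_index_of_genomic(tx, tx$cds_start))
  }
}

pos_c_of_tx_index <- function(txi, bounds) {
  if (txi < bounds[1]) {
    position_c(txi - bounds[1])
  } else if (txi <= bounds[2]) {
    position_c(txi - bounds[1] + 1L)
  } else {
    position_c(txi - bounds[2], utr3 = TRUE)
  }
}

#' Map a genomic position to a coding-DNA position
#'
#' Exonic positions map with intron offset 0; intronic positions anchor to the
#' nearest exon boundary in transcript orientation with a signed offset (ties
#' anchor to the transcript-preceding exon, i.e. the `+` side).
#'
#' @param tx A [transcript_model()].
#' @param genomic_position 1-based genomic position inside the transcript
#'   locus.
#' @return A [position_c()].
#' @export
map_genomic_to_cdna <- function(tx, genomic_position) {
  g <- as.integer(genomic_position)
  span <- locus_span(tx)
  if (is.na(g) || g < span[1] || g > span[2]) {
    abort_range(sprintf(
      "Position %s lies outside the locus of %s (%d-%d).",
      genomic_position, tx$accession, span[1], span[2]
    ))
  }
  bounds <- cds_tx_bounds(tx)
  txi <- tx_index_of_genomic(tx, g)
  if (!is.na(txi)) return(pos_c_of_tx_index(txi, bounds))
  ex <- tx$exons
  i <- max(which(ex[, 2] < g))
  d_low <- g - ex[i, 2]        # distance to the lower-coordinate exon
  d_high <- ex[i + 1, 1] - g   # distance to the higher-coordinate exon
  if (tx$strand == "+") {
    if (d_low <= d_high) {
      anchor <- ex[i, 2]; off <- d_low
    } else {
      anchor <- ex[i + 1, 1]; off <- -d_high
    }
  } else {
    if (d_high <= d_low) {
      anchor <- ex[i + 1, 1]; off <- d_high
    } else {
      anchor <- ex[i, 2]; off <- -d_low
    }
  }
  pc <- pos_c_of_tx_index(tx_index_of_genomic(tx, anchor), bounds)
  position_c(pc$base, off, pc$utr3)
}

#' Map a coding-DNA position back to the genome
#'
#' Exact inverse of [map_genomic_to_cdna()] on every position of the locus.
#'
#' @param tx A [transcript_model()].
#' @param pos A [position_c()].
#' @return Integer genomic position.
#' @export
map_cdna_to_genomic <- function(tx, pos) {
  stopifnot(inherits(pos, "position_c"))
  bounds <- cds_tx_bounds(tx)
  txi <- if (pos$utr3) {
    bounds[2] + pos$base
  } else if (pos$base > 0) {
    bounds[1] + pos$base - 1L
  } else {
    bounds[1] + pos$base
  }
  g <- genomic_of_tx_index(tx, txi)
  if (pos$intron_offset != 0) {
    g <- if (tx$strand == "+") g + pos$intron_offset else g - pos$intron_offset
  }
  span <- locus_span(tx)
  if (g < span[1] || g > span[2]) abort_range("Mapped position falls outside the locus.")
  as.integer(g)
}

# ---- consequence prediction ------------------------------------------------

#' Predict the consequence of a single-base coding substitution
#'
#' Translates the affected codon before and after the change: identical amino
#' acid is `synonymous`, a gained stop is `nonsense`, any other amino-acid
#' change is `missense`. Intronic positions at offset 1 or 2 from an exon are
#' `splice`; other intronic and UTR positions are `unknown`.
#'
#' @param tx A [transcript_model()] with sequence attached and a CDS length
#'   that is a multiple of 3.
#' @param variant A `c.`-level substitution as an `hgvs_variant` or text.
#' @return One of the effect classes (see [classify_dual_effect()]).
#' @examples
#' \dontrun{
#' predict_substitution_effect(tx, "c.301G>T")
#' }
#' @export
predict_substitution_effect <- function(tx, variant) {
  if (is.character(variant)) variant <- parse_description(variant)
  stopifnot(inherits(variant, "hgvs_variant"))
  if (variant$level != "c" || variant$kind != "substitution") {
    abort_validation("Effect prediction covers c.-level substitutions only.")
  }
  pos <- variant$start
  if (pos$intron_offset != 0) {
    return(if (abs(pos$intron_offset) <= 2) "splice" else "unknown")
  }
  if (pos$base < 0 || pos$utr3) return("unknown")
  cds <- cds_sequence(tx)
  L <- nchar(cds)
  if (L %% 3 != 0) {
    abort_validation(sprintf(
      "CDS length of %s (%d nt) is not a multiple of 3.", tx$accession, L
    ))
  }
  if (pos$base > L) return("unknown")
  ref_here <- substr(cds, pos$base, pos$base)
  if (nzchar(variant$ref_seq) && variant$ref_seq != ref_here) {
    abort_validation(sprintf(
      "Reference allele mismatch at c.%d of %s: description says %s, sequence has %s.",
      pos$base, tx$accession, variant$ref_seq, ref_here
    ))
  }
  ci <- (pos$base - 1L) %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  within <- pos$base - ci * 3L
  codon_after <- codon
  substr(codon_after, within, within) <- variant$alt_seq
  aa_before <- Biostrings::GENETIC_CODE[[codon]]
  aa_after <- Biostrings::GENETIC_CODE[[codon_after]]
  if (aa_before == aa_after) {
    "synonymous"
  } else if (aa_after == "*") {
    "nonsense"
  } else {
    "missense"
  }
}

# Lift a g.-level substitution onto a transcript as a c. substitution,
# complementing alleles on the minus strand. Returns NULL when the position is
# outside the locus.
genomic_substitution_on_transcript <- function(tx, gpos, ref, alt) {
  pc <- tryCatch(map_genomic_to_cdna(tx, gpos),
                 varlocus_range_error = function(e) NULL)
  if (is.null(pc)) return(NULL)
  if (tx$strand == "-") {
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  }
  structure(
    list(reference = tx$accession, level = "c", kind = "substitution",
         start = pc, end = pc, ref_seq = ref, alt_seq = alt),
    class = "hgvs_variant"
  )
}
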