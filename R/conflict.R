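# Dual-transcript effect-conflict analysis. Some loci express isoforms from
# two different reading frames over shared exons (CDKN2A is the canonical
# case), so one substitution can be protein-changing on one transcript and
# silent on the other. When laboratories classify against different
# transcripts, their classifications can appear to conflict. This module
# classifies variants as divergent-effect or not, tabulates that against
# conflicting-classification status, and tests the association with a
# two-sided Fisher's exact test.

DIVERGENT_CHANGING <- c("missense", "nonsense")

#' Classify a substitution's effects on two overlapping transcripts
#'
#' A variant is *divergent* when it is missense or nonsense on one of the two
#' transcripts but synonymous on the other; the call is symmetric in the two
#' transcripts. Positions outside either CDS (or outside a transcript's locus)
#' yield `unknown` on that side and are never divergent.
#'
#' @param variant A `g.`-level substitution (text or `hgvs_variant`).
#' @param tx_a,tx_b Two [transcript_model()]s with sequence attached.
#' @return One-row tibble: `dna_description`, `effect_a`, `effect_b`,
#'   `divergent`.
#' @export
classify_dual_effect <- function(variant, tx_a, tx_b) {
  if (is.character(variant)) variant <- parse_description(variant)
  stopifnot(inherits(variant, "hgvs_variant"))
  if (variant$level != "g" || variant$kind != "substitution") {
    abort_validation("Dual-effect classification covers g.-level substitutions.")
  }
  one_side <- function(tx) {
    cv <- genomic_substitution_on_transcript(tx, variant$start,
                                             variant$ref_seq, variant$alt_seq)
    if (is.null(cv)) return("unknown")
    tryCatch(predict_substitution_effect(tx, cv),
             varlocus_capability_error = function(e) "unknown")
  }
  ea <- one_side(tx_a)
  eb <- one_side(tx_b)
  tibble(
    dna_description = render_description(variant),
    effect_a = ea, effect_b = eb,
    divergent = is_divergent(ea, eb)
  )
}

is_divergent <- function(effect_a, effect_b) {
  (effect_a %in% DIVERGENT_CHANGING & effect_b == "synonymous") |
    (effect_b %in% DIVERGENT_CHANGING & effect_a == "synonymous")
}

#' Build the conflict-by-divergence contingency table
#'
#' Rows split the calls by conflicting-classification status, columns by
#' divergent-effect status: `a` = conflicting & divergent, `b` = conflicting &
#' non-divergent, `c` = non-conflicting & divergent, `d` = non-conflicting &
#' non-divergent.
#'
#' @param calls Data frame with a logical `divergent` column (as returned by
#'   [classify_dual_effect()]).
#' @param conflict_labels Logical vector, one per call: does the variant have
#'   conflicting classifications? These labels are inputs (taken from an
#'   external archive's annotations), not computed.
#' @return A `contingency_2x2` object (named integer vector a, b, c, d).
#' @export
build_contingency <- function(calls, conflict_labels) {
  divergent <- if (is.data.frame(calls)) calls$divergent else calls
  if (length(conflict_labels) != length(divergent) ||
      any(is.na(conflict_labels))) {
    abort_validation("Every call needs a non-missing conflict label.")
  }
  if (any(is.na(divergent))) {
    abort_validation("Every call needs a non-missing divergent flag.")
  }
  tab <- c(
    a = sum(conflict_labels & divergent),
    b = sum(conflict_labels & !divergent),
    c = sum(!conflict_labels & divergent),
    d = sum(!conflict_labels & !divergent)
  )
  structure(as.integer(tab), names = names(tab), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("conflicting", "non-conflicting"),
                              c("divergent", "non-divergent")))
  print(m)
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by the minimum-likelihood convention:
#' with the margins fixed, sum the hypergeometric probabilities of every table
#' whose probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-12 for ties). A table with a zero margin carries
#' no information; p is defined as 1 with a warning.
#'
#' @param a,b,c,d Cell counts (row-wise), or pass a `contingency_2x2` /
#'   length-4 vector as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(44, 15, 235, 212)
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    x <- as.integer(unclass(a))
    stopifnot(length(x) == 4)
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort_validation("Cell counts must be non-negative.")
  }
  m <- a + b        # row 1 total
  n2 <- c + d       # row 2 total
  k <- a + c        # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) {
    warn("A margin of the 2x2 table is zero; p = 1 by definition.")
    return(1)
  }
  support <- max(0L, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

# round-half-up at 1 decimal, as printed percentages are reported
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Run the full dual-transcript conflict analysis
#'
#' Combines the per-variant effect calls with external conflicting-
#' classification labels: reports the fraction of all input variants labelled
#' conflicting, the divergent-effect percentage within each label group
#' (computed over the calls whose effects could be determined on both
#' transcripts), the 2x2 table, and the Fisher p-value. Calls with an unknown
#' effect on either transcript count toward the conflicting fraction but are
#' excluded from the table.
#'
#' @param calls Data frame with columns `effect_a`, `effect_b` (effect classes,
#'   possibly `"unknown"`), e.g. rows from [classify_dual_effect()].
#' @param conflict_labels Logical vector parallel to `calls`.
#' @return An object of class `conflict_analysis` with [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
run_conflict_analysis <- function(calls, conflict_labels) {
  stopifnot(is.data.frame(calls),
            all(c("effect_a", "effect_b") %in% names(calls)))
  if (length(conflict_labels) != nrow(calls) || any(is.na(conflict_labels))) {
    abort_validation("Every call needs a non-missing conflict label.")
  }
  determinate <- calls$effect_a != "unknown" & calls$effect_b != "unknown"
  divergent <- is_divergent(calls$effect_a, calls$effect_b)
  tab <- build_contingency(divergent[determinate], conflict_labels[determinate])
  degenerate <- (tab["a"] + tab["b"]) == 0 || (tab["c"] + tab["d"]) == 0 ||
    (tab["a"] + tab["c"]) == 0 || (tab["b"] + tab["d"]) == 0
  if (degenerate) {
    warn("Degenerate contingency table (a zero margin); the Fisher test is uninformative.")
  }
  p <- withCallingHandlers(
    fisher_exact_2x2(tab),
    warning = function(w) invokeRestart("muffleWarning")
  )
  pct <- function(num, den) {
    if (den == 0) NA_real_ else unname(round1_half_up(100 * num / den))
  }
  structure(
    list(
      table = tab,
      n_input = nrow(calls),
      n_conflicting = sum(conflict_labels),
      n_determinate = sum(determinate),
      pct_conflicting = pct(sum(conflict_labels), nrow(calls)),
      pct_divergent_conflicting = pct(tab["a"], tab["a"] + tab["b"]),
      pct_divergent_non_conflicting = pct(tab["c"], tab["c"] + tab["d"]),
      p_value = p
    ),
    class = "conflict_analysis"
  )
}

#' @export
print.conflict_analysis <- function(x, ...) {
  cat("Dual-transcript effect-conflict analysis\n")
  cat(sprintf("  %d variants, %d (%.1f%%) with conflicting classifications\n",
              x$n_input, x$n_conflicting, x$pct_conflicting))
  cat(sprintf("  divergent effect: %.1f%% of conflicting vs %.1f%% of non-conflicting\n",
              x$pct_divergent_conflicting, x$pct_divergent_non_conflicting))
  print(x$table)
  cat(sprintf("  Fisher's exact test (two-sided): p = %.2g\n", x$p_value))
  invisible(x)
}
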