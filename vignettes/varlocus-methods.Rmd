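---
title: "varlocus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{varlocus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varlocus)
```

varlocus is an in-memory engine for locus-specific variant databases
(LSDBs): curated collections of sequence variants with case-level context —
who carries the variant, with which phenotype, found by which screening. This
vignette explains the data model, the algorithms, the statistical conventions
and the design decisions, and states what the synthetic fixtures do and do not
demonstrate about real data.

## The genome-centered data model

Variant observations are stored in two tables. `VariantsOnGenome` holds one
row per *observation* — position, alleles, the HGVS `g.` description, owner,
visibility, timestamps — and `VariantsOnTranscripts` holds zero or more
per-transcript annotations per observation, each with its own `c.`/`r.`/`p.`
descriptions and its own reported and concluded effect. Observations are never
merged: submitting the same description twice creates two rows. What groups
them is the **DBID**, an observation-independent identifier of the form
`GENE_000001` (or `chr9_000001` for intergenic variants, which the
genome-centered layout supports without any gene linkage). The first
occurrence of a normalized description under a prefix allocates the next free
number; repeats resolve to the stored DBID.

Case-level data follow the hierarchy individual → phenotype(s) → screening(s)
→ variant(s). Phenotypes are per disease and may repeat over time with
distinct observation dates (longitudinal records); a screening may be stored
with `variants_found = FALSE` and then never links to variants.

Optional fields are **custom columns**, activated per gene
(variant-transcript scope), per disease (phenotype scope) or instance-wide.
They are realized as physical relational columns added to and dropped from the
backing tables, not as entity–attribute–value rows: EAV saves nothing on disk
in practice and pays on every insert and most queries, whereas adding a
physical column is a rare, bounded operation. Core fields (the genomic and
transcript DNA descriptions and the RNA description) can never be deactivated.

One instance carries exactly one genome build (`hg19` or `hg38`), fixed at
creation; observations declaring the other build are refused rather than
lifted over.

## HGVS subset, coordinate mapping, effect prediction

The parser covers the descriptions an LSDB stores in bulk: substitutions,
deletions, duplications, insertions and delins on the `g.` and `c.` levels.
`r.` and `p.` strings are carried as free text. Parsing and rendering are
mutually inverse over this subset, and the rendered spelling (positions only,
no redundant deleted sequence) is the canonical form used for DBID grouping.
Inversions, repeats and allele notation are out of scope.

Coordinate mapping between the genome and a transcript's `c.` system is exact
arithmetic over the exon structure. Exonic positions get intron offset 0;
intronic positions anchor to the nearest exon boundary in transcript
orientation with a signed offset, ties going to the preceding exon (the `+`
side, matching the convention that the first half of an intron is counted
from its 5' boundary). The inverse map reproduces every genomic position of
the locus; the tests verify this exhaustively against an independently built
enumeration table on both strands.

Consequence prediction for coding substitutions translates the affected codon
before and after the change: same amino acid → `synonymous`, gained stop →
`nonsense`, otherwise `missense`. Intronic positions one or two bases from an
exon are called `splice`; other intronic and UTR positions are `unknown`
(single-codon logic has nothing defensible to say there). The prediction
requires an attached sequence and a CDS length divisible by 3, and it is
checked against a brute-force oracle that rebuilds and translates the entire
mutated CDS for every possible exonic substitution of a toy transcript.

VCF import converts anchored REF/ALT pairs to HGVS by trimming the shared
prefix and suffix. When a reference sequence is supplied, deletions and
insertions are shifted to their 3'-most equivalent position and insertions
that replicate the immediately preceding sequence are rewritten as
duplications, per HGVS convention; without sequence, the coordinates pass
through flagged `normalized = FALSE`. BED export converts the model's 1-based
inclusive spans to BED's 0-based half-open convention at the boundary and
nowhere else.

## The reading-frame checker

A whole-exon deletion or duplication is classified by the summed *coding*
length of the affected exons — the intersection of each exon with the CDS
span. A positive multiple of 3 is `in_frame`, any other positive value is
`frameshift`, zero (pure UTR exons) is `no_coding_change`. Deletions and
duplications follow the same rule because both displace the downstream frame
by the same length mod 3. Exons partially overlapping the CDS contribute only
their coding portion; this matches an oracle that rebuilds the post-change
CDS. The checker deliberately does not scan for stop codons created at the
novel junction — that would require sequence and makes a weaker, different
claim — though the arithmetic needed to add such a scan is exposed
(`coding_length_affected`).

## The dual-transcript conflict analysis

Some loci express isoforms from two different reading frames over shared
exons; CDKN2A (p16INK4a via NM_000077, p14ARF via NM_058195) is the canonical
human case. A substitution can then be missense or nonsense on one transcript
and synonymous on the other — a **divergent-effect** variant. Laboratories
classifying against different transcripts will appear to disagree.

`run_conflict_analysis()` takes per-variant effect pairs and external
*conflicting-classification* labels (these labels are inputs taken from an
archive's annotations, never computed here) and builds the 2×2 table

|                  | divergent | non-divergent |
|------------------|-----------|---------------|
| conflicting      | a         | b             |
| non-conflicting  | c         | d             |

Calls whose effect could not be determined on both transcripts (unmapped
variants, non-coding positions) count toward the conflicting-fraction
denominator but are excluded from the table and the within-group percentages —
they carry no information about divergence. Percentages are rounded half-up
at one decimal.

The association is tested with a two-sided Fisher's exact test implemented by
the minimum-likelihood convention: with all margins fixed, the p-value is the
sum of hypergeometric probabilities of every table whose probability does not
exceed the observed table's, ties included within a relative tolerance of
1e-12. A table with a zero margin is uninformative and returns p = 1 with a
warning. The implementation is cross-checked in the tests against
`stats::fisher.test` and against exhaustive enumeration from binomial
coefficients on every non-degenerate table with total count ≤ 60 (agreement
to 1e-12).

```{r conflict}
divergent <- c(rep(TRUE, 44), rep(FALSE, 15), rep(TRUE, 235), rep(FALSE, 212))
conflicting <- c(rep(TRUE, 59), rep(FALSE, 447))
fisher_exact_2x2(build_contingency(divergent, conflicting))
```

## Roles and visibility

Every account is a submitter; extra rights stack on top. Administrators and
managers view and edit everything, including non-public records. Curators
hold view and edit rights over all records linked (through transcript
annotations) to the genes in their care; collaborators hold the same
visibility without edit rights. Any submitter can grant colleagues view-only
or full edit rights over their own records. Edit always implies view, and the
submitter's reported classification is immutable under curation: curators
write only the concluded effect. Record-level visibility (`public` /
`non_public`) gates anonymous access; phenotypes and screenings inherit
visibility and ownership from their individual. Bulk file imports are a
manager operation; curators can validate a file in simulate mode.

## Import semantics

The tab-delimited section dialect (`### <Section>` headers, a column-name
row, tab-separated records, `#` comments) is this package's own; update
imports match entries by internal id and permit **at most one changed field
per entry** — a single mistyped id would otherwise silently overwrite a whole
record. Any entry with two or more changes, an unknown id or a malformed
section makes the entire file fatal, and a fatal import leaves the database
byte-identical (changes are staged and only applied after full validation;
the tests compare serialized snapshots). Simulate mode reports the same
diffs without writing.

## The fixture generator

Fixtures are fully deterministic: all randomness flows through R's
Mersenne-Twister generator under `withr::with_seed`, so one seed and spec
yield byte-identical output on any platform. Defaults are sized for unit
work: loci of 8 kb, 3–6 exons of 60–180 bp with 80–400 bp introns, 100
observations over 10 individuals at a 50% duplicate-description rate (so DBID
grouping is exercised), one to three longitudinal phenotype records per
individual, and roughly 10% of screenings returning no variants.

Coding regions are drawn from the {A, C, G} alphabet. Every stop codon (TAA,
TAG, TGA) contains both T and A, so a T-free plus strand — whose reverse
complement is A-free — is stop-free in all three frames on both strands. Any
CDS span with length divisible by 3 is therefore a valid open reading frame
without rejection sampling, and the dual-frame option can shift the second
transcript's CDS by one base to emulate the CDKN2A configuration knowing both
frames translate cleanly.

What the fixtures do **not** emulate: realistic allele frequencies or
mutational spectra, sequencing error, indel-heavy loci, multi-gene overlap
beyond the dual-frame pair, or the scale of production databases. Passing
tests demonstrate the correctness of the mechanics (storage semantics,
coordinate arithmetic, translation logic, access control, import atomicity)
on well-formed inputs, not robustness to malformed real-world submissions
beyond the validation rules tested.

## Numerical and design choices

- **Rounding**: reported percentages use half-up rounding at one decimal
  (`floor(x * 10 + 0.5) / 10`), not banker's rounding.
- **Fisher ties**: probabilities within a relative 1e-12 of the observed
  table count as "as extreme"; this keeps the test exact for the table sizes
  an LSDB produces while remaining robust to floating-point noise.
- **Intergenic DBID prefix**: `chr<name>` with its own counter per
  chromosome.
- **Multi-gene variants**: a variant annotated on transcripts of several
  genes takes the alphabetically first gene symbol as its DBID prefix, for
  determinism.
- **Conflicting g./c. pairs**: the engine recomputes `c.` from `g.` over its
  own transcript models and never overwrites submitted text; mismatches are a
  reporting concern, not a write.
- **Timestamps** are UTC ISO-8601; record ids are monotonically increasing
  integers.
- **Registry verification** (gene symbols against HGNC, diseases against
  OMIM) is an injectable function with an offline default that accepts
  well-formed input; live lookups are out of scope.
- **Test problem sizes**: exhaustive checks run over toy loci (≤ 8 kb, every
  position), every non-degenerate 2×2 table with N ≤ 60, 1,000 random exon
  changes, and 1,000 generated observations at 50% duplication — large enough
  to exercise every code path and boundary, small enough to re-run on every
  change.

## Limitations

The engine is an in-memory reference implementation: persistence is limited
to the section-file export/import, and the service surfaces are functions
over request objects rather than a network server. The HGVS subset excludes
inversion/repeat/allele grammar; protein-level prediction stops at
single-codon substitution classes; the reading-frame checker assumes
breakpoints on exon boundaries. Federated queries fan out sequentially over
an explicit registry; result sets are independent of visit order, which is
the contract a parallel implementation must keep.
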