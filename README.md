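# varlocus

An in-memory, genome-centered engine for locus-specific variant databases
(LSDBs) — the curated, case-level databases clinical laboratories and gene
curators use to share sequence variants together with the individuals,
phenotypes and screenings behind them.

The package is for people building or analysing such databases in R:
it implements the storage semantics (one row per variant *observation*, with
per-transcript annotations and observation-independent DBID grouping),
gene- and disease-scoped custom columns realized as physical relational
columns, role-based record visibility (administrator / manager / curator /
collaborator / colleague grants), a pragmatic HGVS parser with exact
genomic↔cDNA mapping and single-codon consequence prediction, a whole-exon
reading-frame checker, bulk import with one-change-per-entry update semantics
(VCF in, BED out), retrieval / validated-submission / federated-query
surfaces, and a deterministic synthetic fixture generator so everything is
testable offline.

## The statistic at the core

Some loci express isoforms from **two different reading frames** over shared
exons (CDKN2A, with p16INK4a and p14ARF, is the canonical case). A single
substitution can then be missense or nonsense on one transcript but
synonymous on the other — a *divergent-effect* variant — and laboratories
classifying against different transcripts will appear to disagree. Given
per-variant effect pairs and external conflicting-classification labels, the
package tabulates

|                 | divergent | non-divergent |
|-----------------|----------:|--------------:|
| conflicting     |       *a* |           *b* |
| non-conflicting |       *c* |           *d* |

and tests the association with a two-sided Fisher's exact test computed by
minimum-likelihood enumeration: with margins fixed,
*p* = Σ P(T) over all tables T with P(T) ≤ P(observed), where
P(a) = C(a+b, a) · C(c+d, c) / C(n, a+c) is the hypergeometric probability.

## Worked example

```r
library(varlocus)

# a dual-reading-frame toy locus: two transcripts over one exon, frames
# shifted by one base
spec  <- fixture_spec(seed = 42, divergent_locus = TRUE)
locus <- generate_locus(spec)
txA <- locus$transcripts[[1]]; txB <- locus$transcripts[[2]]

classify_dual_effect("g.100118C>T", txA, txB)
#> # A tibble: 1 × 4
#>   dna_description effect_a effect_b   divergent
#>   <chr>           <chr>    <chr>      <lgl>
#> 1 g.100118C>T     missense synonymous TRUE
```

The same substitution changes an amino acid in transcript A's frame and is
silent in transcript B's — the call is divergent, and it is symmetric in the
two transcripts.

With effect calls and conflicting-classification labels for a variant set
(here encoded directly from a 2×2 of 44/15 divergent/non-divergent
conflicting and 235/212 non-conflicting variants):

```r
divergent   <- c(rep(TRUE, 44), rep(FALSE, 15), rep(TRUE, 235), rep(FALSE, 212))
conflicting <- c(rep(TRUE, 59), rep(FALSE, 447))
fisher_exact_2x2(build_contingency(divergent, conflicting))
#> [1] 0.001309842
```

A p-value of 0.0013 says divergent effect and conflicting classification are
associated far beyond chance: variants that hit the two reading frames
differently are exactly the ones laboratories disagree about. The full
summary object (`run_conflict_analysis()`) adds the within-group percentages
(here 74.6% of conflicting vs 52.6% of non-conflicting variants divergent)
and has `tidy()`, `glance()` and `autoplot()` methods.

Day-to-day database work goes through an instance handle:

```r
db <- lovd_instance("hg19")
register_gene(db, "CDKN2A", hgnc_id = 1787, chromosome = "9", strand = "-")
# add_transcript(), create_variant_observation(), query_records(), ...
```

## Documentation

The methods vignette (`vignettes/varlocus-methods.Rmd`) covers the data
model, the coordinate and translation conventions, the statistical choices,
what the fixture generator does and does not emulate, and known limitations.
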