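---
title: "Identifying and comparing SLC transporter families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and comparing SLC transporter families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcid)
```

## The identification model

Solute carrier (SLC) families are defined functionally but are each
monophyletic, with members sharing roughly 20% or more identity. That
makes a two-stage homology strategy natural: a sensitive profile-HMM
screen to gather everything remotely SLC-like, then a stricter
reciprocal-BLAST test against a curated model-species set to decide
*which* family — or none. Structural filters then remove sequences that
are homologous but implausible as full-length transporters.

The package assumes one protein per gene (longest isoform), curated
references in which every protein carries a family label, and search
results in the standard tabular dialects (HMMER per-target tables,
12-column BLAST tabular, TM-predictor summaries). It never runs the
external tools itself unless asked: `run_external()` adapters exist for
convenience, but precomputed tables drive everything, which keeps runs
reproducible and testable offline.

### Stage 1: the HMM screen

A protein becomes a candidate when any family profile reaches a
full-sequence E-value of at most 0.01. Two reading choices deserve a
note. First, HMM search tools report E-values rather than p-values, so
the printed 0.01 cutoff is applied to the E-value; at proteome scale
the two are nearly interchangeable for small values, and the threshold
is an argument for users who disagree. Second, the threshold is
applied to the pooled hits across all family profiles rather than per
profile; a per-profile application would only matter for proteins
hovering at the cutoff in several families at once, which the BLAST
stage re-adjudicates anyway. The best profile family is recorded purely
as a diagnostic — final labels come only from stage 2, so a candidate
screened in by the "wrong" profile costs nothing.

### Stage 2: reciprocal-BLAST family assignment

For each candidate the ranked back-search hits decide its fate. Hits
are ordered by E-value ascending, bit score descending, subject id
ascending — the last key exists only to make ties deterministic, so
identical inputs always give identical labels. With *F* the top hit's
family, assignment to *F* requires ≥ 4 of the top 5 hits in *F* and a
top-hit identity above 20%. Families with fewer than five curated
members cannot satisfy "4 of 5" in a meaningful way, so for them every
curated member must appear among the top five. When fewer than five
hits exist at all, all of them must be in *F*; this is the lenient
reading consistent with the small-family clause, since demanding five
hits that cannot exist would silently unclassify short hit lists.

The override: a top hit more than 10³⁰-fold more significant than the
runner-up assigns *F* even when the criteria fail. The rule is a pure
E-value ratio, hence invariant to rescaling all E-values (database-size
effects cancel). A top E-value of exactly zero with a nonzero runner-up
is treated as infinite fold change and fires; a zero runner-up too
means the ratio is uninformative and the override does not fire. A
candidate with a single hit cannot be evaluated under criteria or
ratio, so it fires the override when its identity clears 20% — the one
criterion that is still measurable — and is logged with its rule.

Candidates failing all of the above are "Unsorted": confidently
SLC-like (they survived the screen) but not attributable to a family.
Unsorted genes are reported but excluded from all family counts. The
rule that fired (`ALL_CRITERIA`, `SMALL_FAMILY`, `OVERWHELMING`,
`UNSORTED`) is recorded per gene so that downstream audits of any
assignment can be explained without re-running anything.

### Stage 3: structural filters

Per family, curated lengths give an acceptance window
$[\lfloor \tfrac{2}{3} L_{\min} \rfloor,\ \lceil \tfrac{4}{3} L_{\max} \rceil]$
— one third below the curated minimum to one third above the curated
maximum. Boundaries are inclusive and rounded outward, so every curated
sequence passes its own family's filter; that is the reason for the
floor/ceiling choice. The TM filter requires at least
$\lfloor \min(\text{curated TM counts})/2 \rfloor$ predicted
transmembrane segments; a threshold of 0 (families whose least TM-rich
curated member has 0 or 1 segments) disables the filter for that family
rather than erroring, since a filter that rejects everything or demands
segments the curated members lack would be meaningless. Both filters
are monotone: widening the window or lowering the threshold can only
turn rejections into acceptances, a property the test suite checks
directly.

When no external TM-predictor output is supplied, `fallback_tm_count()`
provides a deterministic hydropathy count: Kyte–Doolittle values
averaged over a 19-residue window (the canonical helix-spanning
width), segments as maximal runs of window centers with mean ≥ 1.6,
runs separated by fewer than 5 residues merged. These are conventional
hydropathy-analysis settings, not a reimplementation of any
predictor's HMM; for real proteomes an external predictor's counts
should be supplied, and each verdict records which source was used.

Families observed in only one model species take their statistics from
that species alone — with a single curated source there is nothing to
union, and dropping such families would discard real signal.

### Merging, gating, counting

A gene identified by either the human-reference or the fly-reference
search counts as a candidate, so the merge is a union. When the two
searches assign different families the smaller top-hit E-value wins,
with exact ties going to the human reference on curation-quality
grounds; conflicts are always flagged. This tie-break makes the merge
label-commutative, which the tests verify. Species with BUSCO
completeness below 75% (strictly) are dropped before any comparison;
fragmented annotations bias counts in both directions. The family-size
matrix has a fixed numeric column order over the family universe, with
zeros for absent families, and conserves counts: row sums equal each
species' sorted total.

## The comparative layer

Per family and per categorical trait (taxonomic group, dietary breadth
"phagy", dietary type "vory"), a one-way ANOVA compares family size
across trait groups. Groups with fewer than eight species are excluded
per comparison; fewer than two eligible groups makes the comparison
untestable rather than an error. Significance requires both p < 10⁻⁵
and a "maximum effect" above three genes. Maximum effect is implemented
as the largest absolute pairwise difference of group means, in genes —
of the plausible readings (range of means, model coefficient) this is
the one consistent with reporting effects in gene units, and it is
deliberately isolated in one small function should a different reading
be wanted. Degenerate inputs follow fixed conventions: identical groups
give F = 0, p = 1; zero within-group variance with separated means
gives F = ∞, p = 0.

The Bonferroni multiplier `m` is the number of family × trait tests
actually performed after eligibility filtering — not a hard-coded
constant, because no fixed closed form reproduces every reasonable
filtering state; `m` is computed, attached to the result, and
configurable through which covariables are requested. The ANOVA itself
is a standard linear-model fit; the test suite cross-checks F and p
against an explicit sum-of-squares computation to 10⁻¹⁰ relative.

Coefficients of variation (sample SD over mean, per family column) give
a scale-free stability measure; mean-zero families are reported as
missing rather than infinite. Species clustering uses Euclidean
distance with complete linkage — common defaults for count profiles —
and both choices are recorded in the output, with the dendrogram also
emitted as Newick. The CAFE export writes the tab-separated count
dialect (Desc, Family ID, one column per species) and prunes the
user-supplied ultrametric tree to the exported species, preserving
branch lengths; it validates ultrametricity (root-to-tip depth spread
≤ 10⁻⁶ in branch-length units) rather than time-calibrating anything,
because calibration is a modelling decision upstream of this package.

## What the fixtures emulate — and what they do not

The fixture generators exist so every decision rule can be tested
against known truth. Reference and target sequences are built from
per-family residue signatures: transmembrane segments are 19-mers of a
strongly hydrophobic residue, linkers and padding strongly hydrophilic,
so the hydropathy fallback recovers planted TM counts exactly and
families are compositionally distinct. Planted decoys each violate
exactly one constraint: fragments sit below the length window while
carrying enough TM segments to pass the TM filter, soluble homologs
have in-window lengths and zero segments, and non-SLC background
proteins receive no significant screen hit. Hit tables are constructed
directly from the planted truth — at zero noise the top-five subjects
are true-family members on a fixed E-value ladder, so the classifier
must recover 100% of planted labels, and a rank-swap probability
degrades the tables controllably. The E-value ladder's spacing (10⁸
per rank) is far below the override threshold, so the override never
fires spuriously in fixtures.

Fixture cohorts draw family counts as rounded Gaussians truncated at
zero around per-group templates, with an ultrametric coalescent tree
over the species and a configurable fraction of sub-75% completeness
scores. Defaults in the property tests mirror realistic desk-scale
study conditions: groups of 8–20 species, within-group SD of one gene,
planted between-group shifts of five genes for power checks and zero
for null checks.

What passing these tests does *not* show: real proteomes have
fragmented gene models, paralog ambiguity, compositional drift between
lineages, and BLAST statistics that correlate across hits — none of
which the fixtures model. Fixture results validate the decision logic,
not the biological error rate; benchmarking against curated species
sets (e.g. a precompiled fly transporter list, via
`compare_gene_sets()`) remains the way to estimate real-world
sensitivity.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run entirely from
generated fixtures at sizes chosen to exercise every rule while keeping
a full run in the order of a minute or two: 10,000 randomized hit
tables for the classifier/oracle equivalence check, 1,000 random
cohorts for the ANOVA oracle, 500 seeded cohorts for the power and
type-I checks, cohorts of 40 species for the gating/clustering/export
path. Seeds are explicit everywhere; regenerating any fixture with the
same seed is byte-identical.

## Known limitations

- Family assignment trusts the tabular percent identity; it never
  realigns.
- The "four of five hits in different families" reading of the
  Unsorted rule is implemented as its superset — anything failing the
  criteria and the override is Unsorted — which may label slightly more
  candidates Unsorted than a narrower reading.
- The hydropathy TM fallback is a stand-in for convenience and testing;
  per-species results intended for publication should use a dedicated
  TM predictor's output.
- The comparative layer treats species as independent observations, as
  one-way ANOVA requires; phylogenetic non-independence is only
  addressed downstream by the CAFE export.
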