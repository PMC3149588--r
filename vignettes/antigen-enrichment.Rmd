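---
title: "Methods: property enrichment analysis for autoantigen gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: property enrichment analysis for autoantigen gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antigenrich)
```

## The scientific question

Autoantibodies against self-proteins occur in autoimmune disease, in
cancer, and in healthy individuals, yet for most antigens the cause of
immunogenicity is unknown. A tractable computational question is whether
antigen gene sets — tumor-associated (TAG), autoimmunity-associated (AAG)
and natural-occurring (HAG) antigens — differ systematically from ordinary
protein-coding genes in measurable properties: exon length, variant burden,
sequence motifs, functional annotation, evolutionary conservation of their
protein domains, and sequence similarity to the proteomes of other species
(molecular mimicry). `antigenrich` implements that comparison as a tested,
reusable pipeline over plain-text inputs.

## Test sets and references

A *universe* holds every protein-coding gene with its mean exon length in
nucleotides. Antigen *test sets* are read from a GMT file; their union is
the combined set `ALL`. Two reference sets are built:

* `ProteinCodingGenes` (PCG): every universe gene not in `ALL`. Reference
  construction, not the caller, guarantees test/reference disjointness.
* `ProteinCodingGenesLongerExons` (PCGLE): the PCG genes with mean exon
  length **strictly greater than 3100 nt**. Because antigen sets skew
  toward long-exon genes, length-dependent features (SNP counts, motif
  content, mimicry hits) are confounded by length when compared against
  PCG; PCGLE is an upper-tail length-matched control. Every analysis is
  run against both references and reported side by side.

Antigen identifiers missing from the universe are kept in the set but
contribute nothing to statistics that need universe attributes; antigen
lists typically predate whatever gene build supplies the universe.

## The two tests

**Binary annotations** (GO-like terms, pathways, subcellular locations,
protein domains, sequence motifs) are tested by one-sided
over-representation: with a population of $N$ genes of which $K$ carry the
category, and $k$ of the $n$ test-set genes carrying it, the p-value is the
hypergeometric upper tail $P(X \ge k)$, computed with survival-function
arithmetic (`stats::phyper`). Only enrichment is tested; the analyses this
package supports report no depletion.

**Numeric features** (mean exon length; SNP counts by type; somatic
mutation counts; their normalized variants) are tested by the unpaired
one-tailed Wilcoxon–Mann–Whitney test of a rightward shift of the test-set
values. $U$ counts (test, reference) pairs with test $>$ reference, ties at
half weight. For combined samples of at most `exact_limit` (default 12) the
p-value is exact even under ties: a subset-sum dynamic program over doubled
midranks counts the label assignments with a rank sum at least as large as
observed. Above the cutoff a normal approximation with midranks,
tie-corrected variance and continuity correction is used — identical to
`wilcox.test(correct = TRUE)` on tie-free data. The cutoff of 12 was chosen
so that at the crossover (combined $n$ of 13–16) the two branches agree to
better than 0.01 in p; the test suite asserts this.

**Multiple testing.** P-values are Benjamini–Hochberg adjusted. One
adjustment family is one analysis run: all categories of one namespace for
one test set (e.g. all GO-like terms for `lit_aag`), all six UNIVERSAL sets
for one test set, or all organisms for one test set. The family is
recoverable from the output's `set_name`/`namespace` columns. How the
original analyses grouped their corrections is not documented; per-run
families are this package's choice and are what the defaults implement.

**Reporting filters.** A result *passes* when all three hold:

* adjusted p strictly below `alpha` (default 0.05);
* at least `min_category_size` (default 2) annotated genes in the tested
  population ($K$);
* prevalence of at least `prevalence_fraction` (default 0.05, inclusive):
  $k$ divided by the prevalence denominator.

Nothing is deleted — rows carry a `passes_filters` flag.

Two conventions are deliberately config-exposed because the source analyses
leave them ambiguous. First, the ORA population: by default it is
restricted to genes carrying at least one annotation in the tested
namespace (unannotated genes are uninformative for, say, a pathway
database that never saw them); `population = "full"` uses every
test-plus-reference gene. Second, the prevalence denominator: by default
the number of test-set genes with any annotation in the namespace
(matching the "annotated proteins of a data set" reading); `prevalence_on
= "all"` divides by the whole test set. For namespaces defined on every
gene — UNIVERSAL membership and per-organism mimicry — the full population
is always used and the denominator is the test-set size.

## Numeric features and normalization

Count features come from a wide TSV (`gene_id` plus one column per
feature). Missing cells mean *unknown*, not zero: absence from a variant
database is not evidence of zero variants, so such genes are excluded from
that feature's test rather than imputed. Normalized variants divide the
count by mean exon length and multiply by `norm_scale` (default 1000, i.e.
counts per kilobase of exon); the normalization used originally is
undocumented, so the per-kilobase convention is this package's choice and
the scale is a parameter. Genes with zero exon length are dropped from
normalized features with a warning.

## Sequence motifs

The ELR tripeptide (Glu-Leu-Arg, the CXC-chemokine motif) is scanned
exactly, case-insensitively, reporting all (possibly overlapping) 1-based
positions; `X` is accepted in sequences but never matches. Presence of at
least one hit defines the binary category. Granzyme-B cleavage sites and
coiled-coils are outputs of external predictors, so they enter as
precomputed two-column annotation TSVs in the same `motif` namespace; no
minimum number of sites per protein is imposed.

## UNIVERSAL ancient-domain sets

From organism metadata (kingdom, complete-genome flag, domain scheme) and
organism-by-domain tables, organisms are retained when completely
sequenced **and** annotated with at least 150 distinct domains
(inclusive). Per kingdom, a domain is "ancient" when it occurs in at least
70% of retained species (inclusive). Mapping those domains through a
domain-to-gene table yields one gene set per kingdom and scheme —
`UNIVERSAL_BACTERIA_CATH` and so on, six sets when CATH-like and Pfam-like
schemes are both supplied — containing every gene that carries at least
one ancient domain. When one organism is annotated under several schemes,
the domain table carries a `scheme` column and both thresholds are
evaluated per (organism, scheme). Each antigen set is then tested against
each UNIVERSAL set by ORA on the full population.

## Molecular mimicry

BLAST tabular hits (12-column dialect, `#` comments allowed) of human
proteins against other species are kept when the similarity score is at
least 100 **and** the E-value at most 0.001 (both inclusive). "Similarity
score" is read as the bit score (column 12); the original description does
not distinguish raw from bit score, so the column is a parameter. Hits are
mapped subject→organism and query→gene; hits to organisms without a
complete published genome are dropped, and a human gene joins an
organism's hit list when at least one of its hits survives. One ORA per
organism (category = its similar-gene list) with a single BH family across
all organisms for a test set — the reported hundreds of per-organism calls
imply a joint correction — and the standard filters.

## The synthetic corpus

`simulate_corpus()` writes every input format with planted effects and a
ground-truth manifest, so each stage has a recoverable signal without any
database download. Defaults emulate the motivating study design:

* six antigen sets with the published sizes (1471, 85, 74, 298, 84, 348)
  drawn with natural overlap from a 25 000-gene universe;
* log-normal mean exon lengths (log-mean 8.0, log-sd 0.6 — right-skewed,
  strictly positive, population mean ≈ 3800 nt, inside the published
  3800–6300 nt range), with a +0.3 log-mean shift for antigen genes;
* sparse binary annotations (per-category probability 0.05) over four
  namespaces with configurable planted enrichments;
* Poisson count features proportional to exon length (so normalized
  variants are informative), with 10% missingness;
* random protein sequences in which accidental ELR occurrences are removed
  and the motif is inserted in exactly the recorded carrier genes (rates
  0.35 test / 0.15 reference);
* organisms in the published per-kingdom counts (447 Bacteria, 39 Archaea,
  82 Eukaryota), two domain schemes, domains universal within a kingdom
  with probability 0.25 and present in 90% (universal) or 20% (other) of
  its species; "ancient-carrier" genes are mapped to core domains
  universal in all three kingdoms;
* per-organism BLAST rows on the keep side of both thresholds, plus a few
  decoy rows on the violation side to exercise the filters.

One master seed feeds independent named substreams (universe, annotations,
features, sequences, organisms, BLAST), so adding a generator never
perturbs existing outputs, and identical configurations give byte-identical
corpora.

The generator deliberately does **not** emulate GO DAG structure or
correlation between namespaces, realistic BLAST score distributions,
linkage between exon length and annotation status, or shared domain
architecture between genes. Passing tests therefore demonstrate the
statistical machinery and the plumbing, not robustness to those real-data
structures.

## Orchestration and outputs

`run_all()` executes every block with available inputs for every test set
(GMT sets plus `ALL`) against both references, and writes fully sorted
result tables plus one significance matrix per block: categories × set/
reference columns, cells $-\log_{10}(p_{\mathrm{adjusted}})$ for passing
results and 0 otherwise (adjusted p is exposed in the matrices; raw p
stays in the tables). Row order is descending maximum significance, then
lexical. Because every table is sorted on all keys, a rerun — or a rerun
after shuffling input rows — is byte-identical; the test suite asserts
this. Stage failures abort with a stage-named error, and partially written
bundles are removed.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at sizes chosen to make
the checks sharp yet quick: exhaustive enumeration oracles at $N \le 12$
(hypergeometric) and combined $n \le 10$ (rank assignments); null
calibration on corpora of 2000 genes, 100-gene test sets and 500
categories with annotation probability 0.2 (large categories make the
discrete tail nearly continuous; the pooled rejection rate is compared to
0.05 within three binomial standard errors at $n = 500$, the number of
categories per corpus — a one-sided discrete test is conservative, so its
attained size sits slightly below nominal); and planted-effect recovery on
2200-gene corpora with 200-gene test sets across 100 replicate seeds. The
end-to-end determinism corpus uses 700–800 genes and nine organisms.

## Known limitations

* Gene identifiers are opaque strings; no symbol/accession mapping layer.
* No GSEA-style ranked enrichment, no permutation-based FWER control, and
  no depletion testing.
* GrB-cleavage and coiled-coil prediction are out of scope by design;
  only precomputed calls are consumed.
* The heat-map matrices are TSVs; plotting is left to the user (e.g.
  `pheatmap` on the exported matrix).
* With very small test sets the prevalence filter is coarse: one gene can
  be worth more than 5% of the denominator.
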