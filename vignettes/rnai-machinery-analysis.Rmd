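---
title: "Identifying and comparing RNAi machinery genes with rnaikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and comparing RNAi machinery genes with rnaikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaikit)
```

## The problem

RNA interference rests on three protein families: RNA-dependent RNA
polymerases (RdRP) convert aberrant single-stranded RNA into dsRNA, Dicer
slices dsRNA into 21-25 nt fragments, and Argonaute loads those fragments
into the RNA-induced silencing complex. The families are ancient and
widespread, but their copy numbers vary enormously across kingdoms —
whole fungal subphyla (e.g. Ustilaginomycotina, most Saccharomycotina)
have lost the machinery outright, while plants and nematodes carry dozens
of Argonaute paralogs. `rnaikit` identifies these genes from protein
domain annotations and supports the comparative analyses that typically
follow: taxonomic census statistics, catalytic-motif variation,
alignment conservation, and duplication/loss history reconstruction.

## Domain-profile classification

The classifier works purely at the level of InterPro domain
architectures; it never inspects sequences. Each family is a *profile*:
a conjunction of requirement clauses, where a clause holds if the total
number of annotation hits whose accession falls in the clause's
alternative set reaches a minimum count. The default profiles are

| Family    | Clauses                                                    |
|-----------|------------------------------------------------------------|
| Argonaute | {IPR003100 (PAZ)} ≥ 1 **and** {IPR003165 (Piwi)} ≥ 1       |
| Dicer     | {IPR000999 (RNase III)} ≥ 2 **and** {IPR001159, IPR005034 (dsRNA-binding)} ≥ 1 |
| RdRP      | {IPR007855 (eukaryotic RdRP)} ≥ 1                          |

Two details matter. First, hits are counted per annotation row, not per
distinct accession: a canonical Dicer carries two separate RNase III
domains, so proteins with a single RNase III hit are rejected. This is
why near-miss architectures (one RNase III plus a dsRNA-binding domain,
as in some plant Dicer-like genes) are deliberately excluded. Second,
the dsRNA-binding clause accepts either of two InterPro signatures
because the two dsRNA-binding folds are interchangeable evidence in
fungal Dicers; non-fungal Dicers sometimes lack both, so
`default_profiles(require_dsrbd = FALSE)` relaxes the clause per run
rather than hard-coding either convention.

Classification is multi-label: a protein satisfying two profiles is
reported under both, and census counts count each membership. No
precedence rule is imposed because none is biologically justified — a
PAZ+Piwi+RNase III architecture is genuinely ambiguous at this level of
evidence.

`build_profile_from_references()` reproduces how such profiles are
curated: given reference proteins with their annotated accessions, it
keeps every accession shared by at least a threshold fraction of
references (default 1.0, i.e. strictly common domains) and returns the
full share table so a curator can merge interchangeable accessions into
OR-clauses.

### Recall evaluation and the 500-aa filter

`evaluate_recall()` applies a 500-residue length filter to the labeled
test set before scoring. The rationale is that the reference sequences
defining the profiles average roughly 900 aa (Argonaute) to 1,600 aa
(Dicer); database fragments shorter than 500 aa mostly lack complete
domain complements and would contaminate the denominator. The filter
applies to evaluation by default but *not* to plain classification
(`classify_proteome(min_length = NULL)`), since whether a production
scan should drop short proteins is a curation choice; a flag enables it.
An empty post-filter denominator yields `NA`, never 0 — recall is
undefined there, not failing.

## Census statistics

`taxon_summary()` aggregates per-genome family counts at kingdom, phylum
or subphylum level and formats each cell as `"mean (min-max)"` with the
mean to two decimals. Genomes present in the taxonomy but with zero
predicted genes contribute zeros to the mean — losses are data, not
missingness. Group comparisons use the Welch (unequal-variance)
two-sided t-test; the plain "t-test" description of such comparisons is
ambiguous, and Welch is the safer default when copy-number variance
differs as drastically as it does between, say, Agaricomycotina (SD
3.63 for RdRP) and Pezizomycotina (SD 0.64). The degenerate case of two
zero-variance groups with equal means returns p = 1 by contract.

`auxiliary_domains()` counts, per classified protein, the *distinct*
annotated accessions outside the family's essential set. Counting
distinct accessions rather than hits was a genuine design choice: domain
databases emit multiple overlapping rows per region, and "how many kinds
of accessory domain does this Dicer carry" is the comparative question.
The presence/absence matrix is exported with `O`/`X` symbols.

## Catalytic-motif analysis

Argonaute slicer activity depends on an Asp-Asp-His catalytic triad in
the Piwi domain; functional variants substitute the His with Asp, Glu or
Lys (the relaxed DD[HDEK] motif). `extract_motif()` anchors these
positions on a reference row of a multiple alignment (positions are
given in the reference's *ungapped* coordinates and mapped through its
gaps) and `classify_ddh_variant()` assigns one of five categories:

* `conserved_DDH` — exactly D, D, H;
* `H_sub_DEK` — D, D, then D/E/K;
* `H_sub_other` — D, D, then any other residue;
* `other_variant` — first or second position not D;
* `missing` — a gap at any anchored column.

Gaps get their own category rather than folding into `other_variant`: a
gap means the alignment provides no residue evidence at that position,
which is qualitatively different from observing a substitution. The
classifier is total over all 21³ residue/gap triples (this is asserted
exhaustively in the tests).

`column_conservation()` scores anchored columns as the fraction of all
rows — gapped rows included in the denominator, never matching — that
carry the reference residue, flagging columns at or above the threshold
(default 0.70, so exactly 70% is flagged). Match-to-reference is the
default mode because the anchoring residues are defined by a structurally
characterized reference protein; a modal-residue mode is provided for
alignments without a privileged row. `filter_short_domain()` drops
proteins whose merged defining-domain span falls below a caller-chosen
threshold; the threshold is a parameter, not a global constant, because
the known use case is excluding a single 68-aa truncated RdRP domain, and
100 aa is a reasonable working value for that purpose.

## Phylogenomics

### Composition vectors

Species distances are alignment-free: all overlapping K-strings of the
whole proteome are counted (within proteins only, never across
boundaries), normalized to frequencies, and a (K−2)-order Markov
background `f0(a1..aK) = f(a1..aK−1) f(a2..aK) / f(a2..aK−1)` is
subtracted, scoring each observed K-string as `(f − f0)/f0` (0 where
`f0 = 0`). The distance between two proteomes is `(1 − C)/2` where `C`
is the cosine similarity over the union of supports. K = 7 is the
default tuple length, the value established as optimal for fungal
phylogeny. Scores are kept only for K-strings observed in the proteome;
unobserved strings contribute zeros to the cosine. The triangle
inequality is *not* guaranteed by this construction and is not asserted
anywhere.

### Neighbor joining and rooting

`neighbor_joining()` implements the standard Saitou–Nei agglomeration
with the Q-criterion. Numerical choices: Q-ties break on the first
row-major pair, so output is deterministic; negative branch lengths
(possible on non-additive input) are clamped to zero with the deficit
transferred to the sister branch, preserving the pair's summed length.
On additive matrices the generating topology and lengths are recovered
exactly (asserted to 1e-9). NJ is used for gene trees on p-distances; it
is the standard greedy heuristic for the Minimum Evolution criterion, and
full ME search with bootstrap support is out of scope.

`midpoint_root()` places the root halfway along the longest
leaf-to-leaf path, breaking exact ties by the lexicographically smallest
sorted leaf-label pair. `root_min_dl()` alternatively scans every edge
and keeps the rooting minimizing duplications + losses; which rooting to
use before reconciliation is a run parameter, since no single convention
is canonical for species trees built from distance matrices.

### Reconciliation

`reconcile_lca()` embeds a rooted binary gene tree into a rooted binary
species tree by LCA mapping: each gene node maps to the species LCA of
its descendants' species. A node is a duplication iff its mapping equals
a child's mapping; losses along a child edge number
`depth(M(child)) − depth(M(node)) − 1`, plus one when the node is a
duplication whose child maps strictly below. Losses are attributed to
the sibling species branch at each level the lineage skips, which yields
the per-terminal-branch tallies used to annotate species trees.
Multifurcating inputs are rejected rather than resolved — resolution
policy changes event counts and should be an explicit upstream choice.
The LCA reconciliation is the parsimony optimum; the test suite checks it
against a brute-force enumeration of all valid embeddings for gene trees
up to six leaves.

## What the synthetic generators emulate

`gen_annotated_proteome()` emulates the *annotation layer* of a scanned
proteome: planted family members receive exactly the clause-satisfying
hits, background proteins receive either accessions from a pool disjoint
from all profile accessions or near-miss architectures (single RNase
III + dsRBD, PAZ without Piwi, Piwi without PAZ). Sequences are uniform
random residues of 600 aa (clearing the 500-aa filter) with hits placed
non-overlapping left to right. Because the background pool is disjoint,
planted truth is unambiguous and classifier recovery must be exact; this
deliberately does **not** test robustness to annotation noise, partial
domains, or biased residue composition — passing these tests shows the
classification logic is correct, not that InterProScan output on real
proteomes is clean.

`gen_family_history()` runs a birth–death process along a species tree
from one ancestral gene (duplication and loss as Poisson events per unit
branch length; every surviving lineage enters both daughters at each
speciation) and returns the observable gene tree — extinct lineages
pruned, unifurcations suppressed — plus the true per-branch event
counts. Since pruning hides dup-then-loss pairs, inferred parsimony
events can only ever undercount the truth; that bound is asserted over
100 seeded replicates, and with the loss rate at zero the inferred
duplication count equals the truth exactly. Replicates where fewer than
two gene copies survive are regenerated from the next seed substream.

Validation problem sizes were chosen to keep each suite fast while still
exercising the combinatorics: proteomes of ~50-100 proteins, 4-7-taxon
trees for NJ (where brute-force topology search is feasible), gene trees
of 3-6 leaves for the reconciliation oracle (the embedding enumeration
grows exponentially), and 5-species trees with duplication/loss rates
0.3/0.25 per unit branch length for the birth–death replicates — high
enough that multi-event histories are common, low enough that most
replicates survive.

## Bundled census data

`rnai_gene_census()` returns the published per-species Argonaute and
RdRP gene counts for the 34 genomes used in reconciliation and RdRP
conservation analysis (25 fungi, 1 Oomycete, 1 bacterium, 2 archaea, 2
plants, 3 animals). Three arithmetic facts follow from it and are
recomputed by `scripts/acceptance.R`: 183 Argonaute genes in total; 84
fungal RdRP sequences after the short-domain exclusion (85 predicted
minus the one truncated-domain gene); and the 34-genome composition
itself.

## Known limitations

* Domain calls are trusted as given; there is no HMM or similarity
  search fallback, so annotation gaps propagate directly to missed
  genes.
* Isoforms are not collapsed: counts are per input protein record, and
  callers working with proteomes that include alternative transcripts
  must deduplicate upstream.
* The composition-vector score is kept sparse over observed K-strings;
  strings expected under the Markov background but unobserved do not
  contribute negative scores, which can slightly compress distances
  between very small proteomes.
* Reconciliation models duplication and loss only — no transfers, no
  incomplete lineage sorting — and requires binary trees.
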