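---
title: "Annotating Sadhu-like non-LTR retroelements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating Sadhu-like non-LTR retroelements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrokit)
```

## The problem

Sadhu elements are non-autonomous, non-protein-coding retroposons of
*Arabidopsis*. They resemble SINEs — a poly(A) tract, a flanking target site
duplication (TSD) of roughly 7–18 bp, no long terminal repeats — but carry no
similarity to known structural RNAs. A typical full-length element runs from
a conserved 5' motif (consensus `CAATCGTTSC`, S = C or G) past a ~20 bp
polypyrimidine patch to a 3' poly(A) tract approximately 900 bp downstream.
Families like this are small (tens of copies per genome) and highly diverged
(often below 75% pairwise identity between subfamilies), which defeats
generic repeat annotators tuned for abundant young families. `retrokit`
implements the family-scale analyses such elements call for:

* structure-based discovery of candidate elements (`scan_elements`),
* TSD detection under the target-primed reverse transcription (TPRT)
  staggered-cut model and integration-site consensus statistics
  (`find_tsd`, `build_site_consensus`),
* subfamily classification and nomenclature (`classify_elements`,
  `assign_names`),
* uncorrected-distance neighbor-joining trees with bootstrap support
  (`distance_matrix`, `neighbor_joining`, `bootstrap_support`),
* iterative homology closure to find all relatives in a new genome
  (`closure_search`, `report_elements`),
* filled/empty genotyping of insertion loci across strain panels and
  recent-vs-ancestral age calls (`genotype_site`, `call_insertion_age`),
* a seeded TPRT insertion simulator with machine-readable ground truth
  (`simulate_tprt_insertion`, `simulate_radiation`, ...).

Coordinates are 1-based and closed throughout, the native convention of R
and of the GFF3 files the package writes; spans are `c(start, end)` on the
forward strand with a separate strand field.

## Structural scanning

`scan_elements` anchors on motif hits (IUPAC semantics, both strands,
`motif_max_mismatch` substitutions allowed; `N` in the genome matches no
motif position). For each hit it searches for a 3' poly(A) tract in two
distance bands: first at 700–1100 bp downstream (the full-length band — the
"approximately 900 bp" structure operationalized with generous margins),
then, only if that fails, at 350–700 bp (the partial band). Searching the
full-length band first matters once elements diverge: a chance A-rich patch
inside the element body must not demote a genuine full-length element whose
tail has decayed. A motif hit with no compatible poly(A) is reported as a
`fragment` covering the motif alone.

`find_polya` defines a poly(A) tract as the longest window that starts and
ends on an A, is at least `polya_min_len` (6) long and is at least
`polya_min_purity` (80%) adenine, ties broken leftmost. The purity criterion
(rather than a pure run) reflects that genomic tails decay by point
mutation; the A-endpoint constraint stops the window from dangling over
non-A flanks. One consequence is intrinsic: when the duplicated target
itself begins with adenines — which TSDs of TPRT elements preferentially do
— the element's tail and the downstream TSD copy merge into one run, and the
annotated 3' boundary can overshoot the biological one by a few bases. The
package treats this as irreducible ambiguity: recovery tests score the 5'
boundary exactly and the 3' boundary by reciprocal overlap (at least 95%),
and the TSD detector carries a matching `boundary_slack`.

The polypyrimidine patch (≥15 bp at ≥90% C/T within 120 bp of the motif) is
annotated when present but is *not* required for the full-length call: the
family literature describes it as typical, not diagnostic.

Overlapping candidate annotations on the same strand are resolved by
structural class (full-length over partial over fragment), then motif
fidelity (fewer mismatches), then length, then position. Ranking by motif
fidelity before length is deliberate: under a permissive mismatch allowance,
chance motif look-alikes paired with a distant A-window produce long spans
that would otherwise displace genuine elements.

The mismatch allowance is an analysis knob to be matched to the divergence
regime: exact (`0`) for undiverged material, the default `1` for consensus
scanning, and `2–3` when the family of interest has drifted ~5–10% from the
motif consensus (a 10-mer at 10% per-site divergence fails a one-mismatch
test about a quarter of the time).

## TSD detection and the TPRT model

TPRT integration makes two staggered nicks; repair duplicates the target
between the nicks, leaving identical direct repeats hugging the element.
`find_tsd` searches for the maximal-length repeat with one copy ending
within `boundary_slack` (3 bp) of the element 5' boundary and the other
starting within the same slack of the 3' boundary, exactly matching by
default (`max_mismatch = 0`: sequenced clean empty sites carry a single
*identical* copy; tolerance is configurable for old, diverged insertions).
Lengths 7–18 bp are considered — the union of the ranges reported for the
family in *A. thaliana* (7–16) and *A. lyrata* (8–18). Ties break by fewer
mismatches, then smaller total boundary offset, then leftmost copy. The
search is a bounded enumeration (~600 window comparisons per locus), so an
exhaustive oracle can verify it exactly; the test suite does this on 500
random planted loci.

Two contract details deserve emphasis. First, the detector returns the
*maximal* repeat: when flank characters happen to coincide, the repeat can
properly contain the biologically annotated TSD, and the filled site alone
cannot disambiguate — containment, not equality, is the guarantee. Second,
the searchable repeat length is capped by the available flank (an error
names the offending side only when a flank cannot hold even a minimum-length
repeat), which lets the detector run on tightly cropped loci such as the
package's curated worked examples, where each flank is the 9 nt nicking
context plus the repeat itself.

Integration-site statistics follow the sequence-logo convention:
`extract_nick_contexts` takes the 9-mer 5' of the left copy (the 5' nicking
site), the first 7 nt of the repeat, and the 9-mer 3' of the right copy,
orientation-normalized for minus-strand elements; `build_site_consensus`
tallies exact base counts and per-position information content
`2 + sum_b p_b log2 p_b` bits, without small-sample correction — at the
family's n = 14 the plain statistic is the reproducible one.

## Classification and nomenclature

`pairwise_identity` aligns globally with free terminal gaps (match +1,
mismatch −1, gap open −5, gap extend −1) and reports matches over aligned
residue columns, the complement of an uncorrected distance. Identity is
forced symmetric by aligning each pair in canonical order (co-optimal
alignments could otherwise report slightly different identities depending on
argument order). Because a free-end-gap alignment of unrelated sequences
degenerates into a tiny perfect overlap, classification only compares
references aligning over at least `min_like_aligned` (50) bp.

Relations follow the family scheme: a structurally full-length candidate is
a subfamily member; a candidate above `derived_min_identity` (75%) to a
*unique* best reference — best-vs-second-best gap of at least
`unique_margin` (2%) — is `derived` from it; anything else is `like`,
attached to its best qualifying match. The threshold sits exactly where the
family literature puts it, with the caveat that the same source also quotes
">80%" for the same derivative sets; the knob is exposed and the boundary
case (identity exactly at threshold) classifies as `like`. Names follow the
published convention — `Sadhu5-1` (member 1 of subfamily 5), `Sadhu5-1d2`
(its second derivative), `Sadhu3L1` (first "like" element of subfamily 3) —
with an optional species prefix (`AlSadhu...`), and `parse_element_name`
inverts them.

`subfamily_consensus` builds a star alignment to an anchor (the longest
member) and takes per-column plurality bases, ties resolved in
A &lt; C &lt; G &lt; T order. Member insertions relative to the anchor are
ignored — adequate for families whose divergence is substitution-dominated,
and verified by ancestor-recovery tests at 5% within-subfamily divergence.

## Distances, trees, support

Distance matrices are uncorrected p-distances with pairwise deletion of gap
columns, matching `distmat` "run without corrections". Trees are
neighbor-joining (via `ape::nj`; negative branch lengths clamped to zero and
flagged). The original analysis used maximum parsimony in PAUP*; NJ on
uncorrected distances is substituted deliberately — subfamily assignment
needs coarse, reproducible clustering, and the family's own published
divergence matrices are distance-based. `bootstrap_support` resamples
alignment columns, rebuilds the tree per replicate, and reports the
percentage of replicates containing each bipartition of the point tree;
the default is 100 replicates, with the literature-scale 500 a flag away.
All resampling flows from an explicit seed.

## Homology closure

`local_search` is a self-contained seed-and-extend search: exact 11-mer
seeds, diagonal clustering, then a local-alignment refinement with BLAST-like
scoring (+1/−2, gaps −5/−2). With these scores an alignment only extends
while local identity stays roughly above two-thirds, so low-identity
stretches fall below `min_hit_len` and drop out naturally. Hits pass
`min_identity` (70%) over at least `min_hit_len` (100 bp) and merge within
`merge_gap` (50 bp) per strand. A bespoke search (rather than an external
aligner binary) keeps the pipeline self-contained and lets the test suite
pin its behavior against planted truth.

`closure_search` iterates the search with a growing query set until
self-reference: sequences of new hits join the query set unless already
represented at ≥95% identity over ≥90% of their length (the novelty rule
that operationalizes "a self-referencing set"; the original procedure states
no threshold, and these values prevent duplicate-entry loops). The closed
set provably contains the single-pass result, reaches a fixed point
(verified by running one extra pass), and is invariant to seed order; the
test suite also verifies the transitive property that motivates iteration —
a chain A–B–C in which C is reachable from the seed only through B.

`report_elements` keeps merged hits of at least 350 bp (the reporting floor
used for the family's cross-species catalogue), types each structurally,
attempts TSD detection in the surrounding genome, and names hits against
the reference set with a species prefix.

## Insertion-site genotyping

`predict_empty_site` reconstructs the pre-insertion allele of a filled locus
— 5' flank, a single TSD copy, 3' flank — the diagnostic structure of a
clean TPRT empty site; it exactly inverts `simulate_tprt_insertion`, and the
suite checks this inverse on hundreds of seeded events. `genotype_site`
compares a strain's locus sequence with the filled reference and the
reconstructed empty allele by normalized edit distance: the better-fitting
model within `tolerance` (2% edits, matching within-species neutral
divergence) gives `filled` or `empty_clean`; a locus that clearly lacks the
element but fits no clean model (for example a deletion spanning one flank)
is `empty_other`; sequences fitting neither model at all (above 30%
edits) are `undetermined`. `call_insertion_age` then labels each locus
`recent_polymorphic` (at least one clean empty and one filled strain) or
`fixed_in_sample` (filled in every informative strain), ignoring
undetermined cells with a completeness note — the same logic by which
presence/absence polymorphism demonstrates recent retrotransposition and
uniform presence marks ancestral insertions.

The curated strain panel (24 natural accessions × 4 subfamily loci) ships as
a verbatim fixture; its marks map conservatively (`X`/`X*` filled, `ES`
clean empty, `Short`/`Long`/blank undetermined — the undefined marks are not
guessed at). The panel's printed text elsewhere implies more empty-site
strains for one locus than the table shows; the fixture preserves the table
as printed rather than resolving the inconsistency.

## The simulator and what it does (not) emulate

`sim_params` defaults *are* the study conditions the package is tested
under: 900 bp elements built as motif (S drawn from C/G) + ~20 bp C/T patch
+ random body + 12 bp poly(A); TSD lengths uniform on 7–16 bp; 5–20%
within-subfamily and ≥25% between-subfamily divergence; derivative modes
(5' truncation, template switch with a 10–30 bp foreign block before the
poly(A), early polyadenylation, internal deletion) patterned on the
documented partial-element structures; strain panels with ancestral
insertions fixed before strain divergence and recent insertions present in
the reference strain plus a random proper subset of the others, at 0.5%
per-strain divergence (natural accessions of a selfing species differ well
under 1% genome-wide). Recent loci are polymorphic by construction,
emulating loci ascertained for polymorphism.

Mutation is one-pass per-site substitution (probability = branch
divergence, uniform over the three alternatives) with no indels by default;
the expected proportion of differing sites between two copies at branch
divergence *p* is `2p(1−p) + (2/3)p²`, and a calibration test checks
realized identities against this closed form. What the simulator does *not*
emulate — indel divergence, nested insertions, segmental duplications,
variable tail lengths, GC heterogeneity, selection — bounds what passing
tests show about real genomes: the pipeline's contracts hold under
substitution-dominated neutral divergence, which is also the regime the
family's uncorrected-distance analyses assume.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk-scale run: recovery
tests use five genomes of ~21 kb with 20 planted elements each (100
elements per condition, divergence 0 and 10%), 500 random TSD loci against
the exhaustive oracle, 200 insertion/empty-site round trips, 50 random
additive trees of 5–8 taxa, and an 8-strain panel with 4 ancestral + 3
recent loci. Elements are packed with ~150 bp spacers so structural false
positives in the intervening random sequence are measurable but the
per-genome search space stays honest. All simulations are seeded; reruns
are byte-identical.

Degenerate inputs are handled explicitly: empty FASTA aborts the pipeline at
ingest; inverted spans, ragged alignments, mixed context lengths, asymmetric
distance matrices, sub-minimum flanks, and all-undetermined genotype columns
raise named errors rather than propagating nonsense.

## Known limitations

* The scanner is motif-anchored: 5'-truncated derivatives lacking the motif
  are found by homology (`closure_search`), not structurally.
* Maximal-repeat TSD detection can overshoot the biological TSD when flank
  characters coincide; downstream statistics use the printed/curated TSDs
  where exactness matters.
* The NJ tree is a grouping device, not a model-based phylogeny; no rate
  heterogeneity, no ML/Bayesian inference.
* `local_search` is tuned for family-scale genomes (≤ a few Mb); it is not
  a general-purpose genome aligner.
* Star-alignment consensus ignores member insertions relative to the
  anchor; supply a pre-aligned set where indel structure matters.
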