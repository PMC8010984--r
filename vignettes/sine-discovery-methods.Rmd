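---
title: "Methods: SINE discovery and characterization with sinescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SINE discovery and characterization with sinescout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinescout)
```

## The problem

Short interspersed nuclear elements (SINEs) are non-autonomous
retrotransposons a few hundred bp long, built from a 5' head derived from an
RNA polymerase III transcript (a tRNA or a 5S rRNA), a central body, and a
simple-repeat 3' tail recognized by the reverse transcriptase of a partner
LINE. Characterizing a SINE family in a genome assembly involves a chain of
steps: find the copies, reconstruct the ancestral consensus, pin down the
element boundaries against empty insertion sites, recognize the internal
Pol III promoter boxes and the tail, estimate how diverged the copies are
(a proxy for insertion age), ask where the copies sit relative to genes,
find the partner LINE through the shared tail, and screen for anomalously
similar elements in distant hosts (horizontal transposon transfer, HTT).
`sinescout` implements this chain as composable functions and pairs it with
a synthetic-genome simulator so every stage can be validated against known
ground truth.

## Threshold regimes

Three distinct homology-search regimes are used at different stages, held in
`run_config()`:

| regime          | identity | length requirement         | used for |
|-----------------|----------|----------------------------|----------|
| discovery       | >= 70%   | >= 50 bp                   | finding candidate copies of a seed query |
| copy counting   | >= 80%   | >= 100 bp                  | family copy number |
| divergence set  | >= 80%   | >= 80% of consensus length | copies entering the divergence average |

Copy counting additionally excludes hits confined to an *ambiguous region*:
when two families share a nearly identical 5' stretch (e.g. a common 120-bp
head), fragments aligning only inside that stretch cannot be attributed to
either family and are dropped (`count_copies(ambiguous_region = ...)`; a
5-bp slack absorbs chance one-base alignment extensions).

## Search: seeding and alignment

`seed_and_extend_search()` finds copies by exact k-mer seeding (word size
11), chaining seeds that lie on nearly the same alignment diagonal (band 25,
maximum seed gap 150 bp), and aligning the query locally against a window
derived from the cluster's diagonals (`diag + 1 .. diag + query length`,
padded by 50 bp). Both strands are searched; identity is matches over
alignment columns, with internal gaps counted as mismatches, terminal gaps
excluded, and N never counting as a match. The window is deliberately tight:
deriving it from the diagonals rather than from raw seed extents keeps a
window from swallowing a neighboring copy a few hundred bp away, which would
otherwise cost recall in dense clusters of insertions.

Alignment itself is delegated to `Biostrings::pairwiseAlignment` (match +1,
mismatch -2, gap open 5, gap extend 2). The test suite checks the whole
search path against an exhaustive iterative-masking Smith–Waterman oracle on
50-kb genomes: hit loci agree within 2 bp and identities within 0.01.

Redundancy resolution (`merge_overlapping_hits()`) first removes *shadow
hits* — hits contained inside a longer same-strand hit, which arise when a
simple-repeat tail seeds an off-diagonal window onto a fragment of an
already-found copy — then resolves >50%-of-the-shorter overlaps by identity
(ties: longer alignment, then lower start).

## Consensus reconstruction

`reconstruct_consensus()` selects a reconstruction set (query coverage
>= 0.9, capped at 60 members chosen by coverage then identity — real
reconstructions of this kind use a few dozen to ~170 copies, and the cap
keeps the quadratic center-selection step cheap), aligns it by center-star
(`build_msa_center_star()`), and takes a majority-rule consensus
(`majority_consensus()`: columns with more than 50% gaps dropped, ties
broken A < C < G < T).

Two numerical choices deserve note. First, the center is the sequence
maximizing the *summed pairwise alignment score* against the others rather
than summed percent identity: scores come from the aligner's fast
score-only path, and under the fixed +1/-2 scoring the score-maximizing
copy is the most central one; computing exact identities would require
materializing ~n^2 full alignments for no change in the outcome. Second,
the member-to-center alignments are global, so 5'-truncated copies appear
as end-gap runs and divergent sequences cannot be silently trimmed away (an
ends-free alignment at ~60% identity collapses to a short high-identity
core, which would wreck the distance estimates used for the consensus
tree). The parameter-recovery property — consensus at least 99% identical
to the generating master for simulated families with 20+ copies at
divergence <= 0.10 — is asserted in the tests.

## Boundaries, TSDs and empty sites

`refine_boundaries_empty_site()` aligns the left and right flanks of a
filled locus against the orthologous empty site; element boundaries are the
innermost ends of the two flank alignments, and if the alignments overlap on
the empty site by at least 5 bp that duplicated segment is the target site
duplication (TSD). The flank windows extend across the whole candidate
element (plus 60 bp), so a locus with no insertion collapses to a
zero-length element. Flank matches must reach 70% identity over at least
100 bp — without the length floor, any random pair of 500-bp sequences
contains some short perfect local match.

One genuine ambiguity is worth understanding: if the element's first base
happens to equal the base that follows the empty-site target, a duplication
one base longer than the implanted TSD is *literally present* in the
sequence, and no method can prefer the shorter reading from the sequence
alone. On unconstrained random constructions this happens at about 1/4 per
side; the packaged ground-truth constructions therefore make the element's
terminal bases differ from the adjacent flank bases so the decomposition is
unique, and under that condition recovery is exact.

`detect_tsd()` is the alignment-free variant for ordinary copies: the
longest suffix of the upstream flank matching a prefix of the downstream
flank with at most one mismatch, length 5–20 bp.

## Promoter boxes, head origin, tails

`scan_pol3_boxes()` scans the 5' 120 bp for the type 2 architecture (A box
then B box, B starting 25–60 bp after the A box end) and the type 1
architecture (A box, intermediate element, C box in order). The default
motifs (`pol3_box_motifs()`) are degenerate IUPAC consensi shaped on the
canonical internal-promoter boxes (B box core `GWTCRANNC` and its C-box
relative, a shared A box, a short G-rich IE); internal-promoter consensi
vary across lineages, so all four motifs are plain arguments. The mismatch
budget (default 2 at informative positions) is shared across the boxes of an
architecture — with per-box budgets, chance matches of the short motifs make
random 300-bp sequences light up regularly, while the shared budget keeps
the empirical false-architecture rate below 5% on i.i.d. random sequence
(asserted by a Monte-Carlo test; note this null is calibrated against the
simulator's i.i.d. background, not against compositionally biased real
genomes).

`classify_head()` aligns reference heads (tRNA and 5S classes) to the 5'
150 bp; the best reference's class is called when its identity reaches 0.55
— deliberately below the 60–66% head identities typical of real calls, so
such cases classify positively — or when the box architecture agrees with
that class; otherwise the head is `unknown`.

`detect_tail_repeat()` searches the 3' 60 bp for a tandem run (unit 1–6 bp,
at least 3 complete units, at least 8 bp, purity >= 0.8) ending within 5 bp
of the 3' end, and reports the unit as the lexicographically smallest
rotation of its primitive period, so `(GT)n` vs `(TG)n` is deterministic and
`ATAT` reduces to `AT`. Candidates are ranked by matched bases rather than
raw run length: an impure longer-unit tiling can stretch a base or two
further than the true pure repeat, and ranking by matches makes the pure
repeat win; the 8-bp floor removes the 3-bp chance runs every random window
contains.

## Divergence and relative age

`kimura2p_distance()` implements the Kimura two-parameter distance
`d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with P and Q the transition and
transversion proportions over gap- and N-free columns (pairwise deletion).
Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raise a typed
condition; `family_divergence_summary()` excludes them from the family mean
and counts them separately rather than clamping, which would bias the mean.
The implementation is cross-checked in the tests against
`ape::dist.dna(model = "K80")`.

`age_distribution()` bins copy-to-consensus identities (integer percent,
rounded half-up — plain "rounded to an integer" conventions differ and
half-up is fixed here) into the 80–100 histogram whose shape reads as a
relative age profile: a spike near 100 is a recent burst, a broad scatter an
old, diffuse accumulation. Identities are taken from the copy-counting
alignments; no realignment happens.

## Insertion context

`classify_insertion_context()` assigns each copy one of eight categories by
its midpoint — CDS, 5' UTR, 3' UTR, non-coding exon, intron, 5-kb
downstream, 5-kb upstream, intergenic — with that precedence when features
of one or several (possibly nested) genes overlap; UTR5 outranks UTR3 at
the same level as a fixed convention. The gene reported is the one
contributing the winning feature (ties: smaller gene id). Midpoint
classification is a deliberate simplification for copies straddling feature
boundaries. Interval lookups use `GenomicRanges`; the test suite checks
exact agreement with a brute-force oracle that enumerates every feature of
every gene. `per_gene_insertion_counts()` counts genic-category copies
(CDS/UTR/exon/intron) toward a gene's insertion total; flank-category
copies keep their gene id but are not counted as inserted into the gene.

## Comparative layer and HTT screening

`consensus_p_distance_matrix()` gives base differences per site between
family consensi under pairwise deletion. `nj_tree_with_bootstrap()` builds a
neighbor-joining topology on K2P distances from a center-star alignment of
the consensi, with site-resampling bootstrap supports — a deliberate,
documented substitution for likelihood tree building: only the topology is
used downstream, supports are not claimed to reproduce any published
values, and the NJ step is validated against an independent NJ
implementation in the tests.

`find_partner_line_candidates()` searches with the 3'-terminal 50 bp of a
family consensus, keeps hits with at least 2 kb of sequence upstream of the
matched tail, and annotates each candidate span (3 kb back from the tail
end) with its longest open reading frame on both strands and TSD detection
on the span flanks. The ORF heuristic (>= 200 codons) stands in for
endonuclease/reverse-transcriptase domain detection; profile searches are
out of scope, so `orf_ok` should be read as "long coding capacity present",
not as a domain call.

`flag_htt_candidates()` scores cross-species consensus pairs: a pair is
flagged when identity >= 0.90 and the hosts are at least cross-family
apart in a user-supplied lineage table (ranks: same genus < same family <
cross-family < cross-kingdom). High identity between congeners is expected
under vertical inheritance and is never flagged, no matter how high.
`orthologous_empty_site_check()` adds the corroborating evidence: in a
related genome, both flanks of the filled locus must align (>= 70% identity
over >= 100 bp) adjacent to each other (gap <= 50 bp; overlap up to 30 bp
allowed, since an empty site carries a single copy of the TSD). Verdicts
stay provisional until that evidence is attached; mechanism inference (e.g.
from a missing TSD) is reported as raw fields only.

## The simulator and what passing tests mean

`generate_genome_with_families()` builds an i.i.d. background contig at a
chosen GC content, lays out non-overlapping gene models (>= 2 exons, CDS,
UTRs, >= 11 kb apart so the 5-kb flank windows of neighboring genes never
overlap), and implants mutated family copies with fresh TSDs duplicated
from the insertion point. Families are specified by `family_spec()`:
head class (tRNA-like with A+B boxes or 5S-like with A+IE+C, carried by
built-in synthetic head references), body, tail unit, copy number, an age
model (single burst at divergence d, or a mixture), a truncation
probability (default 0.1, 5' truncations up to 50%), TSD lengths 5–15 bp,
and context weights (defaults: intron 0.45, downstream 0.30, upstream 0.05,
intergenic 0.15, CDS 0.02, 3' UTR 0.03 — shaped on the reported real-data
pattern of intron- and downstream-biased accumulation with rare exonic
hits). The default element is 263 bp (72-bp head + 175-bp body + (GT)8).

Mutations follow the exact K2P process: for target distance d and
transition:transversion ratio kappa (default 2), per-site substitution
probabilities are the closed-form K2P transition probabilities, so the K2P
estimator recovers d in expectation, multiple hits included
(`mutate_copy_k2p()`, checked by an estimator round-trip at d = 0.10).
Indels are not simulated by default so identity arithmetic in the tests is
exact.

Flank-category insertion offsets are drawn from 0.2–3.4 kb rather than the
full 5-kb window: a neighboring implant between a gene end and a flank site
inflates the final distance, and the headroom guarantees the configured
category weights survive into the final coordinates (a recheck relabels any
site still pushed out, as a safety net). The optional partner LINE is a
~3.1-kb element (long ORF, final 43 bp at ~84% identity to the chosen
family's tail) implanted intergenically with a 13-bp TSD. The optional HTT
event inserts a near-identical family copy bluntly (no TSD) into a separate
small virus record and emits two related virus records carrying the
directly joined empty site, plus a lineage table placing the virus
cross-kingdom from the host.

The simulator emulates the statistical structure the pipeline's claims rest
on — divergence distributions, TSDs, context biases, shared tails,
cross-kingdom identity anomalies — but not compositional heterogeneity,
nested/fragmented repeat landscapes, segmental duplications, or sequencing
artifacts of real assemblies. Passing the suite therefore demonstrates the
pipeline's internal correctness and calibration under its stated model, not
performance parity with curated annotation of real genomes.

## Problem sizes used by the checks

The test suite and the acceptance script use: a 3-Mb genome with 200 copies
of one 263-bp family at d = 0.05 (recall, consensus recovery, divergence
recovery); a 2-Mb genome with 240 copies in two bursts at identity centers
98% and 85% (age-profile bimodality); a 4-Mb genome with 50 genes and 1,000
implants (context classification against a brute-force oracle and a
chi-square check of the configured weights); 20 seeded 50-kb genomes with
0–5 implants each (search-vs-oracle equivalence); 200 constructed
filled/empty site pairs (TSD and boundary recovery); and 50 purely vertical
four-species replicates (HTT specificity). Consensus reconstruction
properties use 12 replicates of 20 copies each at d <= 0.10.

## Known limitations

* BLAST-style E-values, repeat masking and protein-space search are out of
  scope; the search is calibrated by explicit identity/length thresholds.
* The default box motifs are reasonable lineage-generic consensi, not
  covariance models; a real tRNA scan will outperform them on divergent
  heads, which is why they are parameters.
* Copy ages are relative (identity bins); no absolute dating is attempted.
* The HTT screen requires the user's lineage table and related-genome
  sequences; it does not fetch taxonomy or assemblies.
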