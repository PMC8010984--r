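# sinescout

Discovery and characterization of SINE retrotransposon families in genome
assemblies, as a tested, self-contained R pipeline.

Short interspersed nuclear elements (SINEs) are non-autonomous
retrotransposons (~150–500 bp) composed of an RNA-polymerase-III-derived 5'
head (tRNA-like, with internal A and B promoter boxes, or 5S rRNA-like, with
A, IE and C boxes), a central body, and a simple-repeat 3' tail recognized
by the reverse transcriptase of a partner LINE. `sinescout` implements the
full characterization chain for such families:

* **Homology search** — seed-and-extend genomic search with the three
  threshold regimes used at different stages: discovery (identity ≥ 70%
  over ≥ 50 bp), copy counting (≥ 80% over ≥ 100 bp, with exclusion of
  fragments confined to a head region shared between families), and the
  divergence set (≥ 80% identity over ≥ 80% of the consensus length).
* **Consensus reconstruction** — center-star alignment of the copies and a
  majority-rule consensus.
* **Structural annotation** — Pol III promoter box architectures, head
  origin (tRNA vs 5S rRNA) by reference alignment, simple-repeat 3' tails
  in canonical rotation, target site duplications (TSDs), and element
  boundary refinement against empty insertion sites.
* **Divergence and relative age** — Kimura two-parameter distances,
  `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`, with pairwise deletion; family mean
  divergence; relative-age histograms over integer identity bins 80–100.
* **Insertion context** — classification of every copy against gene models
  (CDS / UTRs / non-coding exon / intron / 5-kb flanks / intergenic) and
  per-gene accumulation reports.
* **Comparative layer** — consensus p-distance matrices, neighbor-joining
  trees with bootstrap supports, partner-LINE discovery via shared 3'
  tails, and horizontal-transposon-transfer (HTT) screening: cross-species
  consensus identity ≥ 90% between hosts at least a taxonomic family
  apart, corroborated by orthologous empty sites in related genomes.
* **Synthetic data** — a simulator that implants SINE families with known
  divergence, TSDs, truncations, context biases, a partner LINE, and a
  virus-borne HTT event, with a full ground-truth table, so every stage is
  testable without downloads.

## Worked example

Simulate a genome with one implanted family and characterize it end to end:

```r
library(sinescout)

cfg <- simulation_config(
  genome_bp = 500000, n_genes = 10,
  families = list(family_spec(name = "SE1", n_copies = 40,
                              age = list(type = "burst", d = 0.05))),
  seed = 42)
sim <- generate_genome_with_families(cfg)

cc   <- count_copies(sim$masters[["SE1"]], sim$genome)
cons <- reconstruct_consensus(cc$copies, "SE1")
scan_pol3_boxes(cons$seq)$type
detect_tail_repeat(cons$seq)
family_divergence_summary(select_divergence_set(cons$seq, cc$copies), cons$seq)
age_distribution(cc$copies, "SE1")
classify_insertion_context(cc$copies, sim$genes)
```

Output (abridged):

```
copy number: 40
consensus length: 263 from 34 copies
promoter: pol3_type2
  box start end mismatches score
1   A     8  20          0     8
2   B    48  57          0     7
tail: (GT)n x 8
head origin: tRNA   identity: 1
mean K2P divergence: 0.051 over 36 copies
age bins (nonzero): 93:2 94:12 95:11 96:10 97:4 98:1
context: intron 30.0%  downstream_5k 47.5%  intergenic 12.5%  CDS 5.0%  upstream_5k 5.0%
```

Reading this: all 40 implanted copies were recovered at copy-counting
thresholds; the reconstructed 263-bp consensus carries a type-2 (tRNA-like)
internal promoter with exact A and B boxes, a (GT)n tail, and a tRNA-derived
head; the mean copy-to-consensus K2P divergence of 0.051 matches the
simulated burst at d = 0.05, and the age histogram is the corresponding
narrow peak in the mid-90s identity bins; the insertion contexts reflect the
configured intron/downstream bias.

The methods vignette (`vignettes/sine-discovery-methods.Rmd`) documents the
model, the parameter choices, the numerical conventions, and what the
synthetic validation does and does not establish.

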