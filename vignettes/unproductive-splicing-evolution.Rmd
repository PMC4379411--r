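---
title: "Tracing the evolution of unproductive splicing in a gene family"
author: "splicevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the evolution of unproductive splicing in a gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicevo)
```

## The scientific problem

Many RNA-binding proteins — the SR splicing factors prominently among them —
regulate their own expression by *unproductive splicing*: an alternative
splice form (a poison cassette exon, or a retained intron) introduces an
in-frame premature termination codon (PTC), and the resulting mRNA is
degraded by nonsense-mediated decay (NMD) instead of making protein.
Paradoxically, the sequences involved are often under extreme constraint
(ultraconserved elements of ≥ 200 nt perfect identity between distant
genomes) even though the events themselves have arisen repeatedly and
independently in related genes.

For a duplicating gene family this poses a concrete inference problem. Given
orthologs and paralogs across many species, each with EST evidence of
alternative splicing, did unproductive splicing (a) originate once in the
common ancestor, (b) originate independently in each paralog, or (c)
originate once and then get *replaced* — the ancestral event lost on the same
lineage where a new, functionally equivalent event was gained? This package
implements that comparative analysis end-to-end and validates every stage on
a simulator with complete ground truth.

## Intron positions as phylogenetic characters

Sequence trees of highly similar paralogs are often poorly resolved near the
base, so the package leans on gene structure. An intron interrupting a coding
sequence after `c` coding nucleotides is summarized as the pair
`(codon_index, phase) = (floor(c/3), c mod 3)`; phase-1/2 introns are
assigned to the codon they interrupt, which makes the simulator round trip
exact. Sites are projected onto a protein multiple alignment through each
gene's own gap pattern, and shared `(column, phase)` keys become binary
presence/absence characters. Two parameters matter:

* `window` (default **0** columns): positional slack when merging sites into
  one character, applied by single-linkage chaining within a phase. The
  default is the strictest interpretation — exon boundaries either match or
  they do not; a positive window is available for noisy alignments. This was
  a genuinely open choice: nothing in the underlying comparative approach
  fixes a tolerance, and we prefer to fail conservatively (two characters)
  rather than merge non-homologous positions.
* `max_gap_fraction` (default **0.5**): characters anchored at mostly-gap
  columns are flagged low-confidence, since such columns cannot support a
  homology claim.

Subfamily membership is called by Jaccard similarity between a gene's binary
character profile and named reference profiles, with ties and all-zero
similarities reported as `unclassified`. The underlying comparison was
historically done by eye; Jaccard over shared boundaries is the simplest
defensible quantification.

UTR-only introns are excluded from the character matrix (the characters live
in protein coordinates) but are still visible to event calling.

## Splice events and the NMD rule

Events are called from spliced EST-like alignments (BED12 blocks) against the
reference model by pure interval logic:

* **cassette exon** — an internal EST block strictly inside a reference
  intron whose flanking junctions match the host intron's donor/acceptor
  exon edges *exactly*;
* **intron retention** — one EST block covering a whole intron with at least
  `min_overhang` (default **10 nt**) aligned on each flanking exon, guarding
  against spurious 1-nt overlaps;
* **early polyadenylation** — a polyA-flagged EST terminating inside an
  intron (or inside a novel exon).

Alternative 5'/3' splice-site usage is out of scope. Isoforms implied by the
events are rebuilt explicitly and classified by the standard **50-nt junction
rule**: translate from the reference start codon; if the first nucleotide 3'
of the stop codon lies ≥ `threshold_nt` (default **50**) upstream of the last
exon–exon junction, the transcript is an NMD target. A stop in the last exon
escapes; a polyA-truncated transcript escapes as `ESCAPE_TRUNCATED`
(predicted to make truncated protein); the annotated stop is always
`PRODUCTIVE`. The threshold is deliberately a configuration knob rather than
a constant because NMD determinants are known to differ between lineages
(fungal NMD in particular); the rule engine takes the threshold wherever it
is called.

The NMD-inhibition comparison mirrors the classic stabilization experiment:
per-isoform fractions of the gene total in wild-type versus NMD-deficient
conditions, with a pseudocount of 0.5 on every count, and `stabilized` iff
the fraction fold change reaches `min_fold` (default **2**). The in-silico
RT-PCR assay requires exact primer matches on the mature mRNA; a primer
spanning an exon–exon junction therefore amplifies only isoforms containing
that junction — the trick used experimentally to assay processed mRNA while
excluding pre-mRNA, and to distinguish the spliced from the retained form as
two bands whose lengths differ by exactly the intron length.

## Gain/loss histories and the origin-model verdict

Event homology groups (events anchored at the same intron character) become
binary leaf states on an outgroup-rooted gene tree. External
maximum-likelihood trees in newick are first-class inputs; the built-in path
is p-distance (pairwise deletion) plus neighbor joining with a
column-resampling bootstrap (replicate *r* seeded `seed + r`, so replicates
are reproducible and parallelizable). Tree building is intentionally *not*
the package's contribution; the character analysis is.

Each group is reconstructed under **Dollo parsimony** — a single gain on the
branch above the MRCA of the state-1 leaves, plus the minimal set of loss
branches (maximal all-zero subtrees within the gain clade). Dollo is the
right default because parallel gain of an intron or a poison exon at the
identical position is vastly less likely than repeated loss; the unrestricted
Fitch cost is also computed and reported for comparison, and equal-cost
alternative gain placements are surfaced rather than suppressed, since
parsimony cannot always distinguish an early origin with many losses from a
later origin.

The family verdict follows a three-way rule: one group ⇒ `SINGLE_ORIGIN`;
otherwise `REPLACEMENT` if any group's gain lies on or below a loss branch
of another group; otherwise `INDEPENDENT`. A `relaxed_linkage` flag widens
the linkage to the clade of the loss branch's parent, acknowledging
branch-resolution uncertainty in real trees.

## Conservation scans

Ultraconservation is measured literally: maximal runs of alignment columns
where all rows agree and none is a gap, reported at `min_len` (default
**200** columns, the classical ultraconserved-element cutoff). Gaps break
runs — a gap is not identity. Per-column identity profiles (fraction of
agreeing row pairs, gaps counting as disagreement) are smoothed with a
centered 25-column moving average, purely presentational. The intron-length
percentile report answers "is this intron in the longest q fraction of the
genome's introns", the observation that the fungal retained intron has
resisted the strong drift toward short introns.

## What the simulator emulates — and what it does not

`simulate_family()` evolves an ancestral 8-exon gene (360 codons, 25-nt
UTRs) down a 12-species opisthokont-like tree with a fungal outgroup:
nucleotide substitution on CDS, UTRs, and intron interiors; intron gain (GT..AG,
at codon boundaries, log-normal lengths, ln-scale mean 4.0 and sd 0.6);
intron loss; and poison-exon birth/death with optional death-birth coupling
(replacement). The bundled `srsf_scenario()` is a synthetic analogue of the
SRSF4/5/6 history: an ancestral poison exon in the long fifth intron,
conserved from fungus to human in the ancestral copy; a chordate-stem
duplication whose new copy loses that host intron while rebuilding its
structure and gaining a replacement exon before the vertebrate-stem
duplication; and a mammal-only third event in the youngest copy.
`regime_config()` generates randomized scenarios under each of the three
regimes for recovery studies.

Deliberate simplifications, each chosen so that downstream *structure*
inference is tested without confounds:

* **No indels in coding sequence.** Family proteins stay equal-length, so the
  identity alignment is exact and no aligner is needed for synthetic data;
  external MSAs are accepted for real data. Consequently the tests exercise
  anchoring through gap patterns via constructed gapped alignments, not via
  simulated indels.
* **Stop-rejecting substitution, standard code only.** Substitutions that
  would create an in-frame stop in the productive frame are resampled;
  sequence evolution realism (codon models, rate variation) is out of scope
  because downstream stages consume structure, not substitution patterns.
* **Poison exons are copied without substitution**, emulating their extreme
  constraint; this is what makes perfect-identity runs a meaningful target
  (the run detector finds exactly the poison exon between orthologous
  included isoforms).
* **Intron interiors carry an early stop block covering all three frames**,
  so retention always introduces a PTC — as observed for the fungal retained
  intron. Without it, a short in-frame intron could be silently translated
  through.
* **Event isoform mixture.** `inclusion_rate` (0.25), `retention_rate`
  (0.15) and `polyA_rate` (0.05) define the *per-gene* isoform mixture;
  genes carrying several poison exons share this unproductive flux equally.
  This bounds the unproductive fraction of any gene's output (here at 45%)
  regardless of event count — with additive per-exon rates a two-exon gene
  would route 80% of transcripts into NMD, which both is unrealistic and
  mathematically caps the observable fraction fold change below the
  stabilization threshold.
* **NMD-safety margin at event birth.** Poison exons are only born into
  introns where both the cassette and the retention isoform satisfy the
  junction rule with ≥ 10 nt to spare, so truth NMD labels are guaranteed by
  construction and independently re-derivable by the classifier.
* **ESTs** are windows (400 nt, 20% full-length) of isoforms drawn from the
  post-degradation mixture (`nmd_efficiency` 0.8 in wild type, 0 in the
  NMD-deficient condition); polyA-isoform reads are 3'-anchored and flagged,
  as oligo-dT-primed reads are. There is no alignment noise: event-calling
  tests therefore demonstrate correctness of the calling logic, not
  robustness to mismapping.

None of the quantitative rates are estimates from real data — gain/loss and
birth/death rates are order-of-magnitude defaults (0.02 per unit branch
length; substitutions 0.06 per site) chosen to produce visible but
non-saturating turnover on a tree of total depth ≈ 2.

## Numerical and procedural choices

* All internal coordinates are 0-based half-open; GFF3 converts at the I/O
  boundary; BED12 is natively 0-based. Minus-strand logic lives in exactly
  one place (mRNA-coordinate resolution).
* GFF3 and BED12 are *read* with rtracklayer; files are *written* by small
  deterministic writers so that identical inputs give byte-identical outputs
  (the pipeline's determinism contract); the only non-deterministic output
  is the timestamped log.
* Negative NJ branch lengths are clamped to zero with a warning. NJ
  tie-breaking is deterministic (first minimum).
* Problem sizes used in the validation suite: 1,000 random isoforms for the
  NMD oracle; 200 random trees (≤ 10 leaves) against exhaustive single-gain
  enumeration; several hundred random alignments for the scanners; 50
  replicates per generating regime for origin-model recovery; 20 replicates
  for the stabilization screen.

## Known limitations

* Gene-model correction from EST evidence is not implemented; corrected
  models are inputs.
* The cassette-exon caller requires both flanks to match the host intron
  edges, so *coordinate* multi-exon inclusions are represented by their
  flanking structure, and the simulator models such events as a single exon.
* Dollo's verdict cannot rule out an earlier origin followed by many losses;
  equal-cost alternatives are reported, but resolving them needs priors the
  method does not have.
* The replacement-linkage rule operates on the inferred tree; with poorly
  resolved trees the `relaxed_linkage` mode trades specificity for
  robustness.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(srsf_scenario(seed = 3), "srsf_run")
res$report$verdict        # "REPLACEMENT"
res$origin$linkages       # ancestral loss and replacement gains, per branch
res$report$metrics        # recovery metrics against simulated truth
```
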