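---
title: "Mining complete mRNA-display selection datasets: methods and design notes"
author: "rapidmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining complete mRNA-display selection datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RaPID-style mRNA display screens a library of ~10^12 macrocyclic peptides
against an immobilised protein target over a handful of selection rounds, then
sequences the surviving DNA pools. Each amplicon encodes a peptide of fixed
layout: a reprogrammed initiator (a chloroacetyl amino acid charged onto the
initiator tRNA, so the AUG position reads out as Tyr — lowercase `y` when the
d-stereoisomer library is used), a random region of NNK codons (15 by
default), a cysteine whose thiol closes the thioether macrocycle, and a
Gly/Ser spacer before the stop.

The conventional readout ranks unique peptides by abundance and carries the
top *k* (often 200) into a multiple sequence alignment. By the final round,
however, selection has usually collapsed onto one dominant sequence family:
the top of the abundance table is that family's mutation cloud, and smaller
families — which may be *better* binders, or functionally different ones —
never reach the list. `rapidmine` implements the alternative workflow: decode
everything, cluster the **entire** round at high identity to collapse
near-duplicates into representatives, align the representatives, and extract
conserved families from the alignment. The expensive step (progressive MSA,
quadratic and worse) then runs on thousands of representatives instead of
hundreds of thousands of reads, with no abundance cut-off anywhere.

## Decoding under a reprogrammed code

`decode_reads()` locates the constant 5' flank (exact match by default,
`max_flank_mismatches` to relax; the reverse complement is tried when the
forward strand fails), translates initiator + random region with the standard
code, reassigning only the initiator position, and requires the cysteine
anchor codon immediately after the random region. Every read is accepted or
rejected with exactly one reason, assigned in a fixed order:

1. `anchor_not_found` — 5' flank absent on both strands, read too short for
   the footprint, initiator codon mismatched, or no cysteine codon within
   ±2 codons of its expected position;
2. `ambiguous_base` — a non-ACGT base inside the decoded window;
3. `internal_stop` — an in-frame stop inside the random region. Such a
   peptide terminates before the cysteine and cannot cyclise, so it is
   rejected by default; `keep_internal_stops = TRUE` retains these reads for
   diagnostics;
4. `length_mismatch` — the cysteine codon found, but shifted by a whole
   codon (±1–2): an indel in the random region. Accepted peptides must have
   exactly `random_codon_count + 2` residues, so indel variants are only
   classified, never accepted.

NNK violations at the wobble position are counted per read but only reject
under `strict_nnk = TRUE`: a single sequencing error can break the K
constraint on a perfectly real library member, so discarding by default would
bias against nothing but sequencing noise. Base qualities are read and
ignored — quality-aware filtering, paired-end merging and UMIs are out of
scope.

## Counting, ranking, convergence

`count_unique()` tallies a round; ranks are by descending count with a
lexicographic tie-break on the peptide string. The tie-break is what makes
every downstream stage a pure function of the multiset of reads: clustering
scans records in rank order, so a total order means byte-identical outputs
under permutation of the input stream.

`top_n_fraction()` is the convergence statistic (the share of a round's reads
held by its top-*n* unique sequences); `enrichment_trajectory()` computes
per-peptide frequency ratios between rounds, giving peptides unseen in the
earlier round a pseudo-frequency of `0.5 / total_reads` of that round — the
usual half-count that keeps ratios finite without inventing precision. The
default analysis round is 3 in a five-round selection: the last round before
strong enrichment, where diversity is still high. L- and D-libraries are
never pooled; ranks, clusters and names are all per-library.

## Greedy identity clustering

`greedy_cluster()` re-implements the classic greedy incremental algorithm:
records in abundance order; each joins the first existing cluster whose
*representative* has identity at or above the threshold, else founds a new
cluster. Representatives are therefore always the most abundant member, and
cluster indices count creation order — the numbers that appear in hit names.

Identity is the count of identical aligned positions under a global alignment
that maximises matches (match +1, mismatch 0, gap open 2, gap extend 1, a gap
of length *g* costing `open + (g-1)·extend`), divided by the shorter
sequence's length. For the equal-length 17-mers of this library the optimal
alignment is almost always gapless and identity reduces to the Hamming
fraction; the gap terms exist so truncated or indel-bearing variants compare
sensibly. The default threshold 0.90 merges single-mismatch variants of a
17-mer (16/17 ≈ 0.94) while keeping two-mismatch variants (15/17 ≈ 0.88)
separate — "near duplicates" in the strictest sense. Both the threshold and
the word size are exposed (`--cluster-id`, `word_k`) rather than hard-coded,
since reasonable values depend on library length.

A two-letter word prefilter (inverted index over representatives) makes the
scan fast: a pair can only reach identity ≥ *t* if it shares at least

```
(m - k + 1) - (k - 1)(runs - 1) - k(L_long - L_short),   m = ceil(t · L_short)
```

*k*-words, where `runs - 1` is bounded by `2(L_short - m) + (L_long -
L_short)` — a deliberately slack bound (each non-match column can break at
most one match run, and gap columns are never free under the identity
scoring, but we do not rely on that sharpness). Slackness costs only runtime:
random 17-mer pairs share ~0.6 two-words against a requirement of ~13 at
t = 0.9, so >99.9% of pairs skip the alignment. Correctness does not depend
on the filter at all — the suite checks that enabling/disabling it never
changes a partition, and that 100 random instances match a filter-free greedy
oracle exactly.

Output is a `.clstr`-compatible text file (0-based cluster headers, starred
representatives, member identities to one decimal) plus a representatives
FASTA whose headers carry library, cluster index, rank and count.

## Progressive alignment and families

Representatives are aligned progressively: UPGMA guide tree
(`stats::hclust(method = "average")` on `1 - identity`), then
profile–profile Needleman–Wunsch–Gotoh merges up the tree, BLOSUM62, gap
open 10 / extend 0.5 — ordinary defaults for short peptides; the source
method for the original analysis is not parameterised anywhere we could copy,
so these are package defaults, exposed as arguments. Column score between
profiles is the frequency-weighted sum of substitution scores with gaps
contributing zero. Traceback ties resolve match > deletion > insertion, and
on two sequences the profile engine *is* the pairwise aligner, so the
reduction property holds exactly. The d-initiator `y` is scored as `Y`
(stereochemistry does not change the side chain) but preserved in all output.

Per-column conservation is `1 - H/ln 20`, with `H` the Shannon entropy
(natural log) of non-gap residue frequencies; columns with more than 50% gaps
are defined unconserved (score 0) — a gappy column mostly measures alignment
uncertainty, not residue preference. Consensus is majority-rule per column,
gap if gaps hold a strict majority, ties alphabetical.

`extract_families()` groups alignment rows by single-linkage at gapped
identity ≥ 0.6 (identical residues in shared non-gap columns over the shorter
ungapped length). Single linkage is the right topology here: a family is a
mutation cloud around a seed, and members far from each other are still
chained through the seed-like centre. Rows with no neighbour stay singleton
families — the situation of a genuinely isolated representative whose
homologues are buried below the clustering's resolution, which is exactly the
case that motivates looking at families rather than top-k lists.

## Hits, names, truncations

Hits are named `[library][cluster]-[rank]` — library tag, 1-based cluster
index in creation order, abundance rank among all unique sequences of the
analysis round. `split_macrocycle_tail()` cuts at the **first** cysteine: the
chloroacetyl initiator alkylates the first thiol available during translation,
so later cysteines are tail residues. `suggest_truncation()` compares mean
conservation over ring columns against tail columns (skipping columns where
the row itself is gapped) and flags `cycle - tail >= 0.3` by default; the
contrast in the motivating case is qualitative, so the threshold is a package
default, exposed as an argument, and the boundary convention (`>=`, so a zero
threshold with equal conservations *does* suggest) is pinned by a test.
`family_report()` assembles one row per family: representative, hit name,
member counts, summed round frequency over all peptides condensed into the
family's clusters, enrichment ratio versus round 1, consensus, and the
truncation flag.

## The synthetic selection world

The simulator exists so every stage above is verifiable without the deposited
data. Its model, and what each default means:

* **Round-1 pool** — `pool_size` distinct species (default 10× reads; a real
  library vastly exceeds sequencing depth). Background species are uniform
  NNK codon draws, translated, with the single NNK stop (TAG) redrawn —
  so background residue frequencies follow the 31-codon stop-conditioned
  census (Leu/Arg/Ser 3/31, Met/Trp 1/31, …). Planted families are seeds with
  independent per-position mutations, uniform over the 19 other residues.
* **Selection** — per-family fitness `w`; frequencies update as
  `p' ∝ p·w` each round (so family shares follow `f·w^(r-1)` renormalised,
  in closed form), and reads are drawn multinomially. No new mutations after
  round 1: PCR re-amplifies, it does not re-diversify (PCR bias, chimeras and
  indel errors are deliberately out of scope).
* **Emission** — peptides are reverse-translated uniformly over
  NNK-compatible codons, wrapped in the architecture, hit with per-base
  substitution error (default 0.001, an ordinary Illumina-class figure), and
  written with constant placeholder qualities. The whole simulation is a pure
  function of the config seed, down to FASTQ bytes.

A green test on this world establishes that the pipeline recovers what was
planted under multinomial sampling and substitution noise. It does not
establish robustness to PCR chimeras, indels, quality pathologies, or
real-library codon bias — none of which the generator emulates.

### The headline scenario

`headline_sim_config()` pins the contrast the workflow exists to demonstrate:
one dominant family that converges to ≈60% of round-5 reads and four minor
families at ≈0.6% each (inside the 0.5–2% band), in a 150,000-species pool
sequenced at 3,000 reads/round. Fitness values (4.92 dominant, 1.68 minor
vs background 1) come from inverting the closed-form update for those
round-5 shares given the round-1 fractions (0.0027 and 0.002). Mutation rates
set the *diversity structure*: 0.08/position gives the dominant family a
~290-variant mutation cloud whose members each draw several round-5 reads —
so the cloud alone over-fills a top-200 list, as a converged selection does —
while 0.25/position spreads the minor families thin enough that no single
minor variant reaches the top-200 count threshold. Our first parameterisation
(dominant mutation 0.05 in a 50,000-species pool) met the fraction targets
but not that structure — nearly half its species collapsed onto the literal
seed peptide — and was re-derived once, again in closed form; thresholds,
assertions and test seeds were untouched throughout.

Under this scenario the acceptance suite shows, across ten seeds: the top-200
at round 5 contains members of at most two planted families, while clustering
the full round-3 dataset, aligning the representatives and extracting
families recovers all five planted consensuses at ≥80% positional identity.

## Numerical choices and degenerate inputs

* Identity and alignment tie-breaks are all deterministic (documented above);
  with the rank/lexicographic input order this makes every pipeline output
  reproducible bit-for-bit.
* Empty inputs: empty read streams give empty count tables; empty peptide
  sets give empty clusterings; single sequences give trivial trees and
  profiles. Empty strings are errors everywhere.
* `sequence_identity` uses the shorter-sequence denominator, so a contained
  substring scores 1 — the convention of the clustering tool family this
  mirrors.
* Guide-tree determinism relies on `hclust`'s index-order tie-break over a
  totally ordered input rather than an explicit lexicographic comparator;
  the two coincide whenever inputs are fed in rank order, which
  `mine_selection()` guarantees.
* The acceptance check of the background sampler uses a chi-square
  goodness-of-fit at the two-sided 3-sigma significance (plus a
  Bonferroni-held per-residue bound) rather than twenty independent 3-SE
  screens, which would falsely fail ~14% of correct samplers.

## Known limitations

* Flank location tolerates substitutions (configurable) but not indels in the
  constant regions; an indel in the 5' flank rejects the read.
* Progressive MSA has no iterative refinement; on thousands of mostly
  unrelated singleton representatives the alignment outside conserved
  families is decorative, and only within-family columns should be
  interpreted.
* `family_report` attributes a cluster's whole abundance to the family of its
  representative; sub-threshold members of a cluster are not re-assigned.
* The real-data convergence check (round-5 top-10 read fraction of the
  deposited dataset) needs a network download and is therefore not part of
  the offline test suite; the statistic itself is implemented and tested on
  synthetic rounds.

## A worked miniature

```{r, eval = FALSE}
library(rapidmine)

cfg <- headline_sim_config(seed = 1, reads_per_round = 1500)
sim <- simulate_selection(cfg)
dec <- decode_reads(sim$rounds[[3]]$dna, cfg$arch)
counts <- count_unique(dec$peptide[dec$accepted], round = 3)
ana <- mine_selection(counts, round = 3, from_round = NULL)
head(ana$report[, c("hit_name", "members", "summed_freq", "consensus")])
```
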