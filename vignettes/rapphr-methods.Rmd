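---
title: "rapphr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rapphr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rap-Phr systems are two-gene quorum-sensing cassettes of *Bacillus*: a
cytoplasmic receptor (Rap) that represses the Spo0A and/or ComA stress
pathways, and an adjacent propeptide gene (*phr*) whose secreted,
re-imported 5–6-residue C-terminal peptide inhibits its cognate receptor.
The family has expanded massively — dozens of distinct autoinducers coexist
within one species group — through a combination of horizontal transfer of
whole cassettes and duplication/divergence of the autoinducer coding region.

`rapphr` implements the computational side of studying that expansion as a
tested pipeline: cassette mining from assemblies, autoinducer calling and
repeat detection, monophyletic peptide clustering on receptor trees, GC-based
core/mobile classification with population statistics, and gain/loss
parsimony of target regulation — plus a ground-truthed synthetic-genome
generator so every stage is testable without genome downloads.

## Mining model

**Receptor search.** Seed receptor proteins are searched against genome
nucleotide sequence by translated homology (NCBI `tblastn`, driven through
temporary files; precomputed `-outfmt 6` tables can be imported instead).
Hits are kept when the e-value against *any* seed is at most `1e-20` and the
aligned length is at least 300 aa (the `nprr` profile tightens the e-value
to `1e-30`); overlapping hits at one locus are merged, keeping the best
score. Each merged hit is extended in frame to the nearest upstream bounding
stop, the first `ATG`/`GTG`/`TTG` after it, and the next downstream stop.
An ORF that covers fewer than 300 aa despite strong homology is flagged as a
candidate frameshift rather than silently dropped; hits running off a contig
without a stop are flagged partial and excluded. We chose the installed
BLAST+ engine over an internal seeded Smith–Waterman because it is the
field-standard tool for exactly this step and removes a large amount of
bespoke numerical code; the module's filtering, merging and extension
semantics are independent of the engine.

**Propeptide scan.** The window runs from 100 bp before to 600 bp after the
receptor stop codon, in receptor orientation (500 bp after, for the NprR-like
profile). Candidate ORFs must start inside the window, lie on the receptor
strand, encode 35–120 aa, and score at least 0.3 under the secretion-signal
model below. Candidates are ranked by score, then proximity, then leftmost
coordinate; overlapping candidates are resolved greedily in rank order. A
receptor with no accepted candidate is an orphan; two or more accepted
candidates record a *phr* gene duplication.

**Signal-peptide score.** A 30-position position-weight matrix encodes the
classical Sec-signal architecture: initiator M, a positively charged
n-region (K/R), a hydrophobic h-region (L/A/V/I/F), a small-residue c-region
and an Ala-X-Ala-like cleavage motif. Per-position log-odds against a
uniform background are summed and rescaled so that the PWM consensus scores
exactly 1 while a sequence of *typical coding composition* (amino-acid
frequencies of equal usage over the 61 sense codons) scores 0 in
expectation, with clamping to [0, 1]. Anchoring the zero point at coding
composition, rather than at a uniform residue distribution, matters:
open reading frames translated from ordinary genomic DNA are
leucine/arginine-rich and would otherwise drift toward the 0.3 decision
threshold. With this calibration, background ORFs pass at roughly 1% while
generator-drawn signal peptides score above 0.6. Residues beyond position 30
never affect the score.

## Autoinducer calling and repeats

Within a group of aligned propeptides the mature peptide is called as the
5- or 6-column window maximising mean per-column conservation, plus (when a
library of known autoinducers is available) similarity of the window
consensus to the closest library peptide of the same length, at equal
weights. Ties resolve toward the C-terminus — the typical location of the
mature peptide — comparing window *end* positions, and to the hexapeptide
form on equal ends. Singleton groups are called purely by library
similarity. Peptides are compared as exact strings: a pentapeptide is never
identified with its hexapeptide extension, since receptors discriminate
between the two forms experimentally.

Intragenic repeats are maximal sets of two or more non-overlapping windows
within a mismatch budget of a common majority consensus; every window is
tried as a seed and additional copies are collected greedily left to right.
Consensus ties resolve to the seed window's residue, which keeps the growing
consensus stable when later copies are diverged. A degenerate bracket
pattern (e.g. `E[K/R]PVGT`) summarises the copies. When the group's
autoinducer is already known, detection can instead be anchored on that
motif, which the pipeline uses for per-cassette copy counts.

## Trees, clusters, diversity

Multiple alignment is delegated to `mafft` (two sequences use global
Needleman–Wunsch with BLOSUM62). Receptor trees are neighbor-joining on
p-distances with gap sites pairwise-deleted, with nonparametric bootstrap
supports from column resampling; negative NJ branch lengths are clamped to
zero. Maximum-likelihood inference is deliberately out of scope — externally
computed trees are imported as newick, and every downstream analysis is
tree-agnostic.

Clusters are maximal clades whose leaves all encode the same called peptide.
Orphan leaves merge when they form a monophyletic group (the behaviour that
matches named orphan clusters in the source data), otherwise they stand as
singletons. Because the paper's manual "conservation pattern" screening has
no stated rule, the pipeline automates it as follows: receptors are
pre-grouped by complete-linkage at cophenetic distance 0.25, each group with
at least half its members carrying a propeptide is called by conservation
(singletons after the others, through the accumulated library), and groups
where most receptors lack a propeptide are treated as orphan groups — their
minority candidates are almost always spurious window ORFs.

Phylogenetic diversity of a leaf subset is the summed branch length on the
root-to-leaf paths of the subset divided by the total branch length. The
rooted, pendant-edge-inclusive convention is chosen so that one leaf on a
star of *n* equal branches scores 1/*n* and the full set scores exactly 1.

## Mobility and population structure

A gene is called mobile when its GC fraction is significantly below the
strain's gene-GC distribution by a one-sided z-test at α = 0.05; "significantly
lower" is not defined more precisely in the source, and the z-test is the
simplest defensible reading (α and the majority-vote rule for cluster-level
labels are configurable). The strain background is the GC of all ORFs above
a length floor (100 aa, relaxed to 50 then 30 aa if fewer than 20 ORFs are
found), *excluding* ORFs within 1.3 kb of a mined receptor locus: the tested
genes and their flanking mobile-element context must not contaminate the
null distribution. The association matrix, per-species frequencies
(cross-species mean over species where the cluster occurs), duplicate
same-cluster-per-genome cases (orphan cases counted separately), and
rarefaction curves (uniform sampling without replacement, 500 resamples by
default via `vegan::specaccum`, least-squares tail slope over the last 20
sizes) follow directly. The gene-vs-neighborhood GC regression uses the
window 1 kb to 300 bp upstream of the receptor start, a through-origin
least-squares slope, and R² = 1 − RSS/TSS about the mean, floored at zero —
so anti-correlated data score 0, which a squared-correlation definition
would not.

## Gain/loss parsimony

Target-regulation measurements (sporulation efficiency for the Spo0A
pathway, reporter expression for ComA) binarize as "represses" when strictly
below their cutoffs; values at the cutoff score 0 and missing values become
unconstrained tips. Equal-cost Sankoff dynamic programming gives the exact
minimum event count, with the root either free or fixed (the ancestral
receptor regulated the Spo0A pathway, so that analysis fixes Spo0A-on).
Ambiguous minimal assignments resolve by preferring the parent's state
(delayed transformation; accelerated is selectable). Every run self-audits:
the realised number of state changes must equal the dynamic-programming
optimum and no single internal flip may reduce it. Per-trait and joint event
counts are both reported, since the published total could be read either
way. Interface-residue conservation is 1 − normalised Shannon entropy per
column with gaps excluded, with per-group modal consensus residues.

## The synthetic-data generator

The generator defines the study conditions; its defaults emulate a
*B. subtilis*-group-like population and are not tuned per run:

* 20 strains in 4 species on a coalescent species tree (depth 1) with
  within-species coalescent subtrees (depth 0.1), so species are
  monophyletic by construction.
* 6 core clusters per species drawn from a shared pool (so related species
  share some core clusters), of which half are orphan — matching ~3 orphan
  receptors per strain; core clusters are present in at least 90% of a
  species' strains by construction (dropout capped).
* a pool of 25 mobile clusters gained and lost along the tree by a two-state
  process (loss/gain ratio 3, root absent) whose gain rate is calibrated so
  the expected cassette count per strain equals 11, giving mobile clusters
  their characteristic low per-species frequencies; every event is logged
  per branch and replaying the log reproduces the tip states exactly.
* receptors of 360 aa derived from one family root via per-cluster ancestors
  (35% divergence) and per-member divergence of 5% — between-cluster
  identity ~45–55%, comfortably detected by the 1e-20/300 aa filters while
  keeping clusters monophyletic.
* propeptides of 40–80 aa: a PWM-drawn signal peptide, a non-hydrophobic
  linker, and 1–3 autoinducer copies (first exact, later copies diverged by
  up to 2 residues) separated by 2-residue spacers; ~4% of cassettes carry
  a duplicated *phr* gene whose autoinducer diverges by 1 residue.
* background DNA i.i.d. at GC 0.45; mobile cassettes sit in islands
  (cassette ± 1.1 kb) at depressed GC, with codon choices weighted by an
  i.i.d. nucleotide model at the target GC and a synonymous-codon repair
  pass guaranteeing mobile gene GC ≤ background − 0.08. The 1.1 kb pad puts
  the entire upstream neighborhood window inside the island, giving the
  GC-vs-neighborhood regression its signal. The source does not state an
  empirical GC delta for mobile elements; 0.08 is a realistic default for
  low-GC mobile elements against a 0.45 background and is a free parameter.
* an in-frame stop codon is planted immediately before each gene's start so
  ORF extension recovers the planted CDS exactly — the generator analogue of
  the near-universal upstream in-frame stop in real genomes.
* two binary regulatory traits (Spo0A-control, root on; ComA-control, root
  off) evolve with equal gain and loss rates (0.4), with recorded histories.

What the generator does *not* emulate: operon promoters and realistic
intergenic architecture, amino-acid substitution-model realism (mutations
are uniform over residues), codon-usage bias beyond the GC target, and
assembly artefacts (one contig per strain, no N runs). Passing recovery
tests on this material therefore demonstrates the correctness of the
pipeline's logic under the assumed statistical structure, not its robustness
to real-assembly noise.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere, the R/Bioconductor
  convention, and what the GFF3 output prints.
* All randomness flows from a single seed through fixed per-stage offsets;
  reruns are byte-identical (checked in the suite).
* Degenerate cases: zero-sd GC distributions fall back to a strict
  comparison with a flagged undefined p-value; all-gap alignment columns
  score `NA` with a flag; `N`-containing codons translate to `X` and ORFs
  with more than 5% `X` are excluded; empty inputs return empty tables
  rather than erroring wherever the operation is total.
* Problem sizes in the default suite — 4–20 strains, receptor sets of a few
  hundred, 945 six-leaf topologies with sampled state masks (exhaustive
  through five leaves) — were chosen as the smallest sizes at which the
  statistical properties under test are stable.

## Known limitations

* The miner requires the BLAST+ and mafft executables on `PATH` (both are
  standard bioinformatics installations); import paths exist for
  externally computed hits and alignments.
* Non-C-terminal autoinducers (phrH/phrE-like) are covered by the window
  scan but the confidence semantics for them are unvalidated, as no
  detection rule is published.
* Cluster-level mobility uses a per-gene z-test plus majority vote; with
  very few background ORFs (tiny contigs) the test loses power and the
  length floor relaxation trades variance for coverage.
* The published headline mining numbers require the original genome set and
  supplementary database, which are not redistributable inside the package;
  the corresponding checks run only when those files are supplied locally.
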