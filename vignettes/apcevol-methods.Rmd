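---
title: "Methods and design notes for apcevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for apcevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

apcevol implements the computational core of a comparative study of the
plant anaphase-promoting complex (APC/C): how its subunits and activator
genes duplicated and diverged across land-plant genomes. This vignette
documents the models behind each module, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
design decisions taken where the methodology was genuinely open.

## Pairwise alignment

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment use affine
gap penalties in a three-state Gotoh recursion implemented in C++. A gap of
length L costs `gap_open + (L - 1) * gap_extend`; end gaps are charged in
global mode. Defaults mirror the EMBOSS `needle`/`water` defaults that
comparative studies conventionally cite: BLOSUM62 (taken from Biostrings),
gap open 10, gap extend 0.5.

Percent identity is identical columns divided by the *full alignment
length* (gap columns included), and percent similarity additionally counts
residue pairs with a positive substitution score — both EMBOSS
conventions. Published paralog identity figures rarely state the aligner or
the denominator, so reproduction within a couple of percentage points, not
bit-exactness, is the realistic contract; the acceptance suite uses a
±2-point band.

Numerical choices: traceback ties prefer the diagonal state, then a gap in
the second sequence, then the first, making alignments deterministic
(scores are invariant to the choice). State-equality tests in the traceback
use a 1e-9 tolerance so non-half-integer penalties remain safe. The empty
local alignment (score 0) is returned when no residue pair scores
positively.

## TPR repeat detection and duplication matrices

The tetratricopeptide repeat (TPR) is a 34-residue helix-turn-helix
protein-protein interaction unit; five APC subunits (CDC27, APC5, CDC16,
APC7, CDC23) carry tandem arrays of it. The original analyses used the
SMART and TPRpred web services, which cannot be embedded; the package
instead ships a transparent position model: column i of the profile is the
BLOSUM62 row of residue i of the idealized 34-residue TPR consensus
(`AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN`, stored as a versioned plain-text
fixture). A window's score is the sum over its 34 positions; windows
scoring at least the threshold (default 60) are selected greedily in
descending score order with overlaps forbidden, and reported N-to-C.

The threshold default was chosen once so that the synthetic reference
bundle reproduces the published Arabidopsis repeat counts
(9/9/2/9/10/10 for CDC27a/CDC27b/APC5/CDC16/APC7/CDC23); with the
consensus-profile score scale (self-score about 180, random 34-mers about
-40 ± 16) any threshold in a wide band separates planted units from
background, so 60 is not finely tuned. Units are fixed at 34 residues with
no internal indels — this matches the repeat definition and keeps
duplication matrices index-comparable, at the cost of missing genuinely
indel-containing repeats.

Duplication structure is read from the all-vs-all Smith–Waterman score
matrix between repeat units. Because BLOSUM scores scale with composition,
no absolute score cut is meaningful; duplication blocks are defined
relationally as maximal diagonal runs (length >= 2) of cells above the
0.75 per-matrix quantile, with the main diagonal excluded for
self-comparisons. This quantile/min-run rule is this package's
formalisation of "visible diagonal pattern"; the source analyses never
stated a numeric criterion.

APC-specific short motifs are matched literally: C-box `DR[FY]IPxR`,
IR tail = C-terminal `IR` dipeptide, KEN box `KEN`, and the minimal D-box
form `RxxL` (the field names the motif without a tighter consensus; the
minimal form over-calls rather than misses).

## Phylogenetics

Distances are Poisson-corrected protein distances `d = -ln(1 - p)` with p
the proportion of differing residues over usable sites. The gap/ambiguity
policy defaults to complete deletion (drop any column containing a gap or
`X` in any row) — the MEGA default — with pairwise deletion available;
the original runs do not state which was used, and the clade structure
should be robust to either. A pair with p >= 1 is an error naming the pair,
not a silent cap.

Trees are built by Saitou–Nei neighbor joining. Ties in the Q criterion go
to the lowest (row, column) pair and negative intermediate branch lengths
are clamped to zero, so output is deterministic; on additive matrices the
method is exact (verified against a least-squares fit over all fifteen
5-taxon topologies). Bootstrap supports resample alignment columns with
replacement; replicate r seeds the RNG with `xor(seed, r)`, making supports
reproducible. Support is the percentage of replicates containing each
original bipartition, attached as integer internal-node labels, which is
also how Newick output round-trips them. Condensation removes internal
edges with support below the threshold (default 50) and reattaches their
children to the parent; the collapsed edge's length is discarded (condensed
trees are read topologically), leaves are never removed, and the operation
is idempotent.

## Ka/Ks

The estimator is Nei–Gojobori (1986) with the standard genetic code: per
codon, the fractional synonymous site count is the per-position fraction of
single-nucleotide changes that preserve the amino acid (changes to stop
codons count as nonsynonymous); observed differences are averaged with
equal weight over all 1-, 2- or 3-step single-substitution pathways, a step
being synonymous iff it leaves the amino acid unchanged (steps through stop
codons are therefore nonsynonymous); proportions are corrected with
Jukes–Cantor `d = -(3/4) ln(1 - 4p/3)`, undefined at p >= 3/4. Codons
containing gaps, `N` or a stop in either sequence are excluded pairwise.
The ratio is flagged undefined when Ks = 0.

The study cited a windowed, tree-based Ka/Ks elaboration whose exact
configuration is not reproducible from the text; NG86 is the transparent,
testable core, and the qualitative claim it supports (TPR genes under
weaker constraint than activators and APC11) is estimator-robust. The
windowed variant is explicitly out of scope.

## Promoter motif over-representation

Motifs are IUPAC words (PLACE-style); counting reports every, possibly
overlapping, start position whose window falls inside the pattern's IUPAC
expansion. `N` in a promoter never matches. The default scans the forward
strand only — PLACE elements are recorded strand-specifically, making this
the conservative reading of "word counting" — with a both-strands option
that adds reverse-complement occurrences.

The null for a motif is the vector of its counts over a background promoter
set (the study used 1000 rice gene promoters; the module takes whatever
background it is given and records its size), summarised by the sample
mean and standard deviation (n-1). The test statistic is
`Z = (Ctrue - Csurr) / SDsurr` with a one-tailed p from the standard-normal
right tail, and the per-motif 5% rule decides significance — faithfully
uncorrected, as in the source procedure; a Benjamini–Hochberg column is
emitted for information only, and an empirical p
(`(1 + #{surrogate >= Ctrue}) / (n + 1)`) is available. When the surrogate
standard deviation is zero, z is flagged degenerate and p is 0, 1 or 0.5 by
the sign of the count difference. Because counts are discrete and the
normal tail is an approximation, the type-I error of the 5% cut is only
required (and tested) to lie in a loose [0.01, 0.12] band under the null.

## Synthetic data: what a green test establishes

All generators are pure functions of (parameters, seed), restore the
caller's RNG state, and return truth records sufficient to recompute every
expected downstream quantity.

- *Repeat proteins*: units derive from the TPR consensus by uniform
  replacement at the given rate; planted duplicated pairs re-derive one
  unit from another at a lower divergence; linkers are random
  low-complexity sequence. Real TPR arrays have correlated, structurally
  constrained divergence and indels; the generator does not emulate those.
- *Tree sequences*: along each edge of length b, each site substitutes with
  probability `1 - exp(-b)` to a uniformly chosen different residue, so
  observed p-distances match `p = 1 - exp(-d)` up to the small
  back-substitution term of a 20-letter alphabet (about `p^2/19`,
  negligible at the simulated divergences). No empirical matrix (WAG/LG),
  no rate heterogeneity, no indels.
- *CDS pairs*: proposals are uniform point mutations; stop-creating
  proposals are rejected and synonymous/nonsynonymous acceptance is scaled
  to the planted omega, the standard construction for planting a Ka/Ks
  ratio. Codon usage is uniform over the 61 sense codons.
- *Promoter sets*: i.i.d. letters under a mildly AT-rich composition
  (A = T = 0.3, C = G = 0.2), with motif instances planted at
  non-overlapping random positions. Real promoters have k-mer structure,
  CpG avoidance and positional biases that this null lacks.

The published sequence supplement itself is not redistributable, so
`synthetic_supplement()` constructs a stand-in with its *published summary
properties*: the five TPR families with 15/11/12/9/14 members (61 records),
paralog pairs mutated to the printed identity/similarity percentages
(mutations are capped at 25% inside repeat units and concentrated in
linkers, so heavily diverged paralogs keep detectable repeats), and
activator records with or without the C-box/KEN/IR elements as reported.
Green acceptance tests on this bundle establish that the pipeline
*measures these properties correctly* — not that the real sequences were
re-derived. Analyses of the real supplement would use the same entry
points on the downloaded FASTA.

## Pipeline and reproducibility

Stages communicate only through files named in a JSON config; every run
writes a provenance block (config hash, seed, package version) and
re-running an unchanged config reproduces byte-identical reports, including
seeded stages. The CLI returns 0 on success, 2 for config/usage errors and
3 for stage failures.

## Known limitations

- The TPR position model is a single-consensus BLOSUM profile, not an HMM;
  it is calibrated for this package's analyses and simulators, and will
  under-detect highly diverged natural repeats compared to TPRpred.
- Identity/similarity percentages depend on alignment conventions; other
  tools' figures may differ by a point or two.
- NG86 underestimates rates at high divergence and ignores
  transition/transversion bias.
- The enrichment test inherits the normal approximation and the per-motif
  (uncorrected) 5% rule from the source procedure; for modern analyses use
  the empirical p and the BH column.
- Condensed trees discard collapsed-edge lengths; multiple sequence
  alignment construction, genome-database mining and promoter extraction
  from annotation are out of scope by design.
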