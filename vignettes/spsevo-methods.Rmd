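---
title: "Methods and modeling choices in spsevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in spsevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsevo)
```

`spsevo` reconstructs the evolutionary history of selenophosphate synthetase
(SPS/SelD) genes: which residue sits at the UGA-homologous catalytic site,
which genomes can use selenium and how, where terminal fusions arose, how
selective pressure changed after gene duplication, and which RNA signals
support UGA readthrough. This vignette documents the models behind each
analysis, the parameters that matter, the conventions adopted where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## Site classification

**Model.** A candidate protein is aligned to a seed profile — per-column
symbol frequencies over a 21-letter alphabet in which selenocysteine (U) is
its own symbol — and classified by the residue mapped to the profile's Sec
column. Keeping U distinct from C is essential: the U/C distinction *is* the
functional marker separating Sec-SPS2 from Cys-SPS2, and both occur at the
same column in real families.

**Profile scoring.** Column frequencies use add-one pseudocounts,
$f_{a,j} = (c_{a,j} + 1) / (n_j + 21)$ with $n_j$ the non-gap count, and are
scored as log-odds against the uniform background $1/21$ in half-bits,
$s_{a,j} = 2\log_2(21 f_{a,j})$. Ambiguous residues (X) score 0.

**Alignment.** Overlap (free-end-gap) dynamic programming with affine gaps
(open 11, extend 1, on the half-bit scale) rather than local alignment:
SPS homologs are full-length, and a terminal fusion must dangle as an
unaligned overhang instead of truncating the column map. At each terminus
the overhang is free in one sequence only; simultaneous overhangs in both are
bridged by a penalized gap. Traceback is deterministic — diagonal, then
profile-column gap, then protein insertion — so identical inputs always give
identical maps.

**Site call.** The residue is the protein symbol mapped to the Sec column
(`x` for a gap). Flank identity is the fraction of the ±10 surrounding
columns whose aligned residue equals the column consensus; a call is
confident iff flank identity ≥ 0.4. The threshold is deliberately permissive:
at 5% random substitution noise the expected flank identity of a true
homolog stays far above it, while reversed or shuffled sequences in our
tests fall essentially to zero. Classification then follows the residue and
the SECIS annotation: U with SECIS → `SPS2-Sec`; U without → `SPS1-UGA`;
C → `SPS2-Cys`; anything else → `SPS1-<res>`; unconfident or gapped calls →
`unclassified`. A genome is Sec-capable iff it has at least one SPS2, and a
consistency flag marks disagreement with a reported selenoproteome size.

## Trait profiling

Markers are boolean columns per genome (SelD, SelA, ybbB, tRNAsec) plus a
selenoproteome size. The Sec trait is SelD ∧ (SelA ∨ tRNAsec ∨
selenoproteins > 0) — an OR because archaeal Sec users lack SelA; the SeU
trait is SelD ∧ ybbB; SelD with neither is orphan-SelD (the
*Enterococcus*-like configuration pointing to a third selenium use).

Trait co-occurrence is tested one-tailed in the enrichment direction: with
margins fixed to the two trait counts, $P(X \ge \text{both})$ under the
hypergeometric distribution, computed from `lchoose` with log-sum-exp
accumulation. The test suite verifies this tail to 12 significant digits
against exact integer-arithmetic enumeration on all-size-≤30 tables (every
binomial coefficient involved is ≤ $\binom{30}{15}$, exactly representable
in doubles), and cross-checks `stats::phyper` on the headline table.

Percent specifications are converted to counts by nearest-integer rounding
with the residual assigned to the "neither" class.

## Fusion and extension detection

Each annotated CDS is extended codon-by-codon in frame, upstream and
downstream, stopping exclusively at the first stop codon (all three of
TAA/TAG/TGA — in this context TGA is a terminator) or the contig edge;
minus-strand genes are handled by reverse complement. The extended
translation is aligned to the profile, and residues before the first /
after the last mapped position form N-/C-terminal extension candidates.

* `min_extension = 50` aa: large enough to exclude ragged alignment ends,
  small enough to catch domain-scale fusions. Config-exposed.
* Clustering is single-linkage with a link iff global-alignment identity
  ≥ 0.30 (matches / longer length, match +2 mismatch −1, gap open 10 extend
  4 via `Biostrings::pairwiseAlignment`) over ≥ 0.80 mutual length coverage.
  Cluster ids are assigned by decreasing size, ties by smallest member gene
  id; singletons are flagged low-confidence, since recurrence across species
  is the main guard against assembly artifacts.
* Screening against an external protein database is out of scope at desk
  scale; profile-alignment coverage plays that role, and the extension
  sequences are reported so an external search can be layered on.

## Selection analysis

**Ancestral reconstruction.** Minimum-change parsimony over a 62-state codon
space (61 sense codons plus TGA as the Sec state), realized as a unit-cost
Sankoff dynamic program so multifurcations are handled exactly; candidate
states per column are those observed at the leaves, which always contain a
minimum-change labeling under unit costs. Ties are broken deterministically:
the root prefers TGA, then TGC/TGT, then the lexicographically smallest
codon — encoding the inference that the ancestral metazoan SPS carried Sec —
and a child keeps its parent's state whenever that is change-minimal.
Internal TAA/TAG columns are rejected as pseudogene-like.

**Ka/Ks.** Nei–Gojobori (1986) counting on each (parent, child) branch pair:
per codon, each position contributes the fraction of its three
single-nucleotide mutants that are synonymous to S (mutants creating stops
count as nonsynonymous, preserving N + S = 3 per codon exactly); differences
average over all orderings of the changed positions, excluding pathways
through stops unless all are excluded; Jukes–Cantor correction
$K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. Proportions at or beyond 3/4 are
saturation: fatal in the pairwise function, reported per branch (as NA with
a flag) in the branch-wise wrapper. The Sec-site column is masked by
default — the U↔C↔other change there is the object of study, not background
selection.

**Aggregation.** Clade summaries report mean and median of per-branch ω and
a pooled estimator that sums counts before the ratio,
$\omega_{pool} = (\sum N_d / \sum N)/(\sum S_d / \sum S)$ — the stable choice
when individual branches are short. The headline comparison is the *trend*
(SPS2 above SPS1 after duplication), not absolute ω values: a counting
method with parsimony ancestors systematically differs from ML codon models,
which is why the package validates ω recovery on its own simulator rather
than against external tools.

## The codon simulator

Branch length is defined as the expected number of *candidate* point
mutations per codon (pre-acceptance). Along each branch, a
Poisson(length × codons) number of candidates arise; each picks a uniform
codon and position, proposes a nucleotide with transition:transversion
weight κ:1, and is accepted with probability 1 if synonymous, ω if
nonsynonymous, 0 if it would create a stop. Every accepted event is logged
(branch, column, from, to, type), and replaying the log from the root must
reproduce the tip sequences exactly — a standing invariant of the test
suite. This definition makes ω, not branch length, the recoverable quantity,
which is the intended acceptance surface.

Study conditions used by the acceptance analyses: 16-tip balanced trees with
branch length 0.2, κ = 2, 400 codons, 10 replicates per condition, ω ∈
{0.15, 0.5, 1.0} for recovery and ω(SPS2) = 0.6 vs ω(SPS1) = 0.15 for the
duplication contrast. These sizes give stable pooled estimates in seconds
per replicate while keeping the whole analysis desk-scale.

## Readthrough-signal scanning

**Hexanucleotide.** Exact match of GGGTGC/GGGTGT starting 1–9 nt after the
in-frame TGA. The motif description fixes composition but not a window, so
the scan reports the offset and flags offset 1 as `adjacent`; deterministic
string matching gives exact recall and zero false positives by construction.

**Folding.** Maximum-weighted base pairing (GC = 3, AU = 2, GU = 1; GU
admissible everywhere; DNA alphabet with T ≡ U) over nested structures with
hairpin loops ≥ 3, by Nussinov-style dynamic programming. This replaces
free-energy folding deliberately: it is self-contained and exactly checkable
against brute-force enumeration (the tests verify optimality on random
sequences up to length 14). Traceback prefers leaving the 5′ base unpaired,
then the smallest admissible partner — fully deterministic. Stems are
maximal runs of ≥ 3 stacked pairs; the UGA context is `in_apical_loop` if
the whole codon lies inside a hairpin loop, `in_stem` if any UGA base is
paired, else `unpaired_outside`.

**Consensus.** Across ≥ 4 aligned windows (per-column gap fraction ≤ 0.5), a
column pair is admissible iff complementary (including GU) in at least
q = 0.8 of the gapless rows, weighted by the mean pair weight; the
admissible matrix is folded as above. Covariation counts consensus pairs at
which some row differs from the modal pair at both positions while remaining
complementary — the classic structural signature. The randomization control
shuffles residues *within* each row: a single column permutation shared
across rows would merely relocate complementary column pairs (per-pair
complementarity is permutation-invariant), so per-row shuffling is the null
that actually destroys pairability.

**Element classes.** HRE: ≥ 3 stems with the UGA in an apical loop or the
apical half of the central stem (the three-stem clover with the UGA at the
middle-stem apex). SRE: 1–2 stems, the first beginning no later than 12 nt
downstream of the UGA (SREs overlap or immediately trail the codon).
bSECIS-like: in prokaryotic scan mode, a single stem entirely 3′ of the UGA.
These thresholds are package conventions validated against planted
structures only.

## History inference

Duplication labeling uses species overlap: an internal gene-tree node is a
duplication iff its child subtrees share a species. Site-residue history is
unit-cost parsimony over the residue alphabet with root preference U, then
C, then alphabetical (exposed via `root_preference` for neutral analyses);
each change emits SC (U→C), SO (U→other) or `other` (changes not from U,
which the event vocabulary does not name), and GD events are copied from the
duplication labels. Leaves with unknown residue (`x`) are pruned before
inference; supplying duplication labels computed on the unpruned tree then
triggers a warning, because node numbers shift. Intron or expression
evidence that a full study would use to veto a duplication is accepted only
as external annotation, never inferred.

## What the synthetic data does and does not emulate

The generator plants: marker panels with exact category counts at requested
frequencies (only the genome-to-category assignment and optional-marker
fill-in are random); SPS genes built on the packaged profile consensus with
a controlled site residue, SECIS flag, hexanucleotide, SRE-like hairpin
(pure-GC 9-bp stem whose hairpin loop is exactly the TGA, making the planted
fold the unique weight-maximum), N/C fusion domains beyond the annotated
boundary, and stop-bounded flanks of random sense codons; standalone
SRE/HRE/none windows with {A}-only spacers so planting is exact; and codon
alignments under the simulator above. The packaged profile is a small
synthetic alignment (10 sequences × 120 columns, Sec column 60 with both U
and C) standing in for a curated family profile.

Not emulated: indels and alignment error, site-to-site rate heterogeneity,
realistic codon usage and intergenic composition, genuine SECIS structures
(the SECIS is a boolean annotation; structure prediction for it is out of
scope), and database-scale homology search. Passing the planted-recovery
tests therefore demonstrates correctness of the algorithms under their own
assumptions, not field performance on real genomes.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 is converted at the
  boundary. Minus-strand features keep genomic order.
* Unknown nucleotides N translate to X, never to a stop; N-containing
  codons are skipped by the Ka/Ks counters and are unpairable in folding.
* In-frame TGA translates to U; a terminal stop is dropped; internal
  TAA/TAG rejects the CDS as pseudogene-like.
* Floating-point tie detection in tracebacks uses absolute tolerance 1e-7
  (alignment) and 1e-9 (consensus folding); all tie-breaking orders are
  fixed and documented above, so every function is deterministic given its
  inputs, and seeded generators are byte-reproducible.
* Degenerate cases: empty trait tables, all-`x` leaf states, zero-length
  branches, empty extension reports and saturated branches all either return
  well-defined empty/NA results or raise classed errors
  (`spsevo_*_error`) that callers can trap.

## Known limitations

Counting-method ω with parsimony ancestors underestimates change on long
branches (the Jukes–Cantor correction only partly compensates), so absolute
ω values on deep trees should be read with caution; the package's claims are
calibrated on short-branch regimes. The folding model has no
thermodynamics — scores are not energies and should only be compared within
the package. The profile aligner is a single-profile tool, not a
gene finder: it assumes the candidate is roughly full-length SPS, and the
fusion detector assumes clean assemblies (a frameshift truncates the
extension walk at the first spurious stop).
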