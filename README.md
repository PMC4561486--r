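# spsevo

Tools for reconstructing the evolutionary history of selenophosphate
synthetase (**SPS**, prokaryotic **SelD**) genes — and, through them, of
selenium utilization across the tree of life.

SPS is the enzyme that makes selenophosphate, the selenium donor for
selenocysteine (Sec, the 21st amino acid, encoded by UGA) and for
2-selenouridine tRNA modification (SeU). SPS is itself often a selenoprotein:
many homologs carry Sec at a single catalytic site, others carry Cys, and
metazoan paralogs (**SPS1**) carry Thr, Gly, Leu, Arg — or retain the UGA
codon without a SECIS element and rely on readthrough. The residue at this
one site is a precise marker of function (SPS2 = Sec/Cys, selenophosphate
synthesis; SPS1 = everything else, a distinct function), which makes SPS
families a uniquely tractable system for studying gene duplication and
subfunctionalization. `spsevo` implements the computational analyses this
kind of study needs, end-to-end, with a synthetic-data generator that plants
every signal with known ground truth.

## What the package does

* **Site classification** (`build_profile()`, `align_to_profile()`,
  `call_site_residue()`, `classify_sps()`, `classify_genome()`): align
  candidate proteins to a seed profile over a 21-letter alphabet (U is its
  own symbol, never silently equated to C), read the residue at the
  UGA-homologous column, and classify genes as `SPS2-Sec`, `SPS2-Cys`,
  `SPS1-UGA` or `SPS1-<res>`. A genome is Sec-capable iff it carries an
  SPS2.
* **Trait profiling** (`call_traits()`, `fisher_overlap_test()`,
  `summarize_panel()`): from a genome × marker table (SelD, SelA, ybbB,
  tRNAsec, selenoproteome size) call the Sec trait (SelD ∧ (SelA ∨ tRNAsec ∨
  selenoproteins)), the SeU trait (SelD ∧ ybbB) and orphan-SelD, and test
  trait co-occurrence with a one-tailed exact hypergeometric test computed
  via log-gamma.
* **Fusion detection** (`extend_orf()`, `detect_extension()`,
  `cluster_extensions()`): extend each annotated CDS in frame to the
  flanking stop codons, report terminal stretches not covered by the profile
  alignment (default ≥ 50 aa), and single-linkage-cluster recurrent
  extensions (link iff global identity ≥ 0.30 over ≥ 0.80 mutual coverage).
* **Selection analysis** (`fitch_ancestral_codons()`, `ng86_pairwise()`,
  `branch_ka_ks()`, `aggregate_omega()`): reconstruct ancestral codons by
  minimum-change parsimony over the 62-state space (61 sense codons + TGA as
  the Sec state), then compute per-branch Ka/Ks by the Nei–Gojobori (1986)
  counting method with Jukes–Cantor correction,
  `K = -3/4 · ln(1 − 4p/3)`, pooling counts per clade as
  `ω = (Nd/N)/(Sd/S)`. This is how the package quantifies the relaxation of
  constraint in SPS2 after duplication versus the SPS1 copy.
* **Readthrough-signal scanning** (`scan_hexamer()`, `fold_window()`,
  `consensus_fold()`, `classify_recoding_element()`): exact search for the
  readthrough-enhancing hexanucleotide GGG-UG[C/U] after the UGA;
  maximum-weighted-pair folding (GC=3, AU=2, GU=1, hairpin loop ≥ 3) of the
  UGA window; consensus folding with covariation counting across aligned
  windows; classification into SRE (1–2 stems at the UGA), HRE (three-stem
  clover with the UGA at the middle-stem apex) or bSECIS-like.
* **History inference** (`label_duplications()`,
  `reconstruct_site_history()`): species-overlap duplication labeling on
  gene trees and parsimony reconstruction of the site residue, emitting GD /
  SC (Sec→Cys) / SO (Sec→other) events with a root preference for Sec.
* **Synthetic data** (`generate_marker_panel()`, `generate_sps_gene()`,
  `generate_recoding_window()`, `simulate_codon_evolution()`,
  `sim_tree()`): every input above with planted ground truth, including
  codon alignments evolved under known per-branch ω and a complete,
  replayable event log.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for result objects, `autoplot()` / `plot_*()` helpers for
figures. Trees are `ape::phylo`; sequence I/O goes through Biostrings,
rtracklayer and ape (`read_fasta()`, `read_cds_annotations()`,
`read_newick()`, …).

## Worked example

```r
library(spsevo)
library(dplyr)

# A 223-genome marker panel at realistic trait frequencies
panel <- generate_marker_panel(223, p_sec = 0.18, p_seu = 0.16,
                               p_both = 0.10, seed = 42)
panel$markers |> call_traits() |> fisher_overlap_test()
#> Sec/SeU co-occurrence: 22 of 223 genomes carry both (Sec 40, SeU 36)
#> one-tailed exact P = 8.412e-11
```

22 of 223 genomes carry both traits where ~6.5 would be expected at
independence: the two selenium-utilization pathways co-occur far more often
than chance, reflecting their shared dependence on SelD.

```r
# Classify a planted UGA-without-SECIS gene and scan its readthrough signal
pr <- sps_seed_profile()
g  <- generate_sps_gene(pr, site_residue = "U", secis = FALSE,
                        hexamer = TRUE, seed = 7)
classify_proteins(setNames(translate_cds(g$cds), "ant_sps1"), pr,
                  secis = c(ant_sps1 = FALSE))
#> # A tibble: 1 × 6
#>   gene_id  residue flank_identity confident secis_flag class
#> 1 ant_sps1 U                  0.9 TRUE      FALSE      SPS1-UGA

scan_hexamer(g$cds, g$truth$uga_nt_pos, gene_id = "ant_sps1")
#> # A tibble: 1 × 4
#>   gene_id  offset variant adjacency
#> 1 ant_sps1      1 GGGTGC  adjacent
```

The gene reads through its UGA without a SECIS (the hymenopteran SPS1
configuration) and carries the viral-type readthrough hexanucleotide
immediately after the stop — exactly as planted.

## Package layout

```
R/                 implementation (one file per analysis area)
inst/extdata/      packaged seed profile (aligned FASTA + Sec-column sidecar)
tests/testthat/    unit, property and end-to-end tests with independent oracles
scripts/           acceptance script
vignettes/         methods vignette (models, conventions, limitations)
```
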