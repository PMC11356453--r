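---
title: "Typing FLS and DFR by substrate-preference residues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing FLS and DFR by substrate-preference residues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavotype)
```

## The biological question

Flavonol synthase (FLS, a 2-oxoglutarate-dependent dioxygenase) and
dihydroflavonol 4-reductase (DFR, an NADPH-dependent reductase) compete for
the same dihydroflavonol substrates — dihydrokaempferol (DHK),
dihydroquercetin (DHQ) and dihydromyricetin (DHM) — at the branching point
between flavonol and anthocyanin biosynthesis. Which substrates each enzyme
accepts is strongly associated with a single amino acid position: position
133 of DFR and position 132 of FLS, both in *Arabidopsis thaliana*
numbering. DFR with asparagine (DFR_N) accepts all three dihydroflavonols;
aspartate (DFR_D) shifts preference to DHQ/DHM; alanine (DFR_A) restricts
the enzyme to DHK; a reported leucine substitution likewise restricts to
DHK but is not treated as a named type. For FLS the residues histidine,
phenylalanine and tyrosine define FLS_H, FLS_F and FLS_Y, whose preferred
substrates (H: DHK+DHQ, F: DHK, Y: DHQ) are hypothesized from mutagenesis
and structural work rather than directly assayed, which is why the package
carries a `confidence` tag (`reported` vs `hypothesized`) through all
classifications.

`flavotype` implements this classification as a reusable pipeline: locate
the anchor position in any candidate sequence by alignment to a family
reference, classify by the anchor residue, screen for residues and motifs
required for catalytic function, place the typed sequences on a
neighbor-joining tree, and quantify how mutually exclusive *FLS* and *DFR*
expression is across RNA-seq samples.

## Reference-anchored position mapping

Candidates are globally aligned to the family reference with an affine-gap
Needleman–Wunsch (Gotoh) algorithm over BLOSUM62. A gap run of length
$L$ costs $g_o + L \cdot g_e$ with defaults $g_o = 10$, $g_e = 1$ — the
conventional defaults for BLOSUM62 protein alignment, exposed through
`scoring_scheme()`. `X` (ambiguous translation) scores 0 against every
residue, so ambiguity neither rewards nor penalizes a column. Ties are
broken deterministically during traceback (match/mismatch, then gap in the
candidate, then gap in the reference), so identical inputs always produce
identical alignments.

The alignment induces a `PositionMap`: each reference position maps to the
candidate position in the same column, or to `NA` where the candidate is
deleted. All downstream position logic — anchor extraction
(`residue_at_anchor()`), region extraction (`extract_region()`), residue
rules (`screen_rules()`) — runs through this map, so every rule is stated
once, in reference numbering. A candidate whose anchor column is deleted is
typed `absent`, never `other`: a deletion is evidence of a different kind
than a substitution.

Pairwise alignment to the reference (rather than a full multiple
alignment) is the default anchoring mechanism because it is deterministic
and sufficient for locating reference-numbered positions; externally
computed alignments can be supplied as aligned FASTA, and
`clean_columns()` reproduces the standard low-occupancy column cleaning
(columns with non-gap fraction strictly below 0.1 are dropped; occupancy
exactly at the threshold is kept) with a kept-column index so anchors can
be re-located afterwards.

## Functionality screening

The functional screen is family-specific:

* **FLS**: the fold residues G68, H75, P207, G261; the substrate-binding
  residues at 132 (H/F/Y allowed), F134, K202, F293, E295; the
  FLS-specific motifs `PxxxIRxxxEQP` and `SxxTxLVP`; the ferrous-iron
  binding motif `HX(D/E)XnH`; and the 2-oxoglutarate binding `RXS`. The
  iron motif's gap length $n$ is not fixed by any published table, so the
  shipped default scans a wide window, $n \in [40, 150]$; a sequence fails
  the check only when no match exists anywhere. `RXS` is similarly scanned
  in the C-terminal half rather than at a fixed position. Both choices
  deliberately trade specificity for sensitivity: a false "missing motif"
  would wrongly demote a functional enzyme to "-like" status.
* **DFR**: published residue tables for the NADPH-binding region are not
  complete enough to ship as defaults, so the rule file contains
  placeholders and the structural screen is the presence of the
  26-residue substrate-binding region (reference positions
  anchor−2 .. anchor+23) with at most 30% of its columns deleted.

Any failed check (including an internal stop codon in a CDS input) sets
`functional = FALSE`, and the sequence is reported as a "-like" candidate;
classification by anchor residue is still performed, because pseudogene
candidates remain informative for phylogenetic placement. Rules and motifs
are plain TSV configuration (`default_rules()`, `default_motifs()`) and can
be replaced without touching code.

## Phylogenetics

Distances are protein p-distances with pairwise deletion — the
self-contained stand-in for likelihood-based inference, which is out of
this package's scope (externally built newick trees can be imported with
`read_newick()` at any point). `neighbor_joining()` is a direct Saitou–Nei
implementation with two deterministic conventions: Q-matrix ties break to
the smallest index pair, and negative branch lengths are clamped to zero
with the deficit moved to the sister edge, preserving the path length of
the joined pair. On additive matrices the algorithm provably reconstructs
the generating topology and path distances; the tests verify this to
1e-9 on random additive matrices. `bootstrap_support()` resamples
alignment columns with replacement and reports, for every internal
bipartition of the full-data tree, the percentage of replicates that
contain it; the replicate stream is a pure function of the seed.

Typed leaves are annotated via an injective color map over the nine type
labels plus `untyped`, exported in iTOL color-strip format, and
`clade_type_summary()` reports per-clade type counts with a monophyly
verdict per type (a type is monophyletic iff some subtree contains exactly
its leaves; singleton types are monophyletic by definition).

## Expression exclusivity

Per-sample kallisto-dialect abundance tables are merged into genes ×
samples TPM/count matrices (`merge_samples()`); all statistics run on TPM,
which is length- and depth-normalized and therefore comparable across the
heterogeneous samples this analysis targets; counts are carried along and
summed under the same rules. Close paralogs — same species, same family,
same anchor residue, pairwise protein identity ≥ 0.8 (single linkage) —
are summed into one row (`aggregate_paralogs()`). "Close" has no published
numeric definition, so the threshold is a reported configuration value;
genes with different anchor residues are never merged, and per-sample
focal totals are conserved exactly.

`pair_focal()` reduces each sample to an (FLS TPM, DFR TPM) pair over the
functional members of each family, tagged with the type combination.
The qualitative observation that a given sample expresses either *FLS* or
*DFR* but rarely both is made quantitative by a statistic this package
defines: the **exclusivity index**, the median over expressed samples
($F + D \ge$ a detection floor, default 1 TPM) of $|F - D| / (F + D)$. It
is 1 under perfect exclusivity, 0 under perfectly balanced co-expression,
and invariant both to swapping the two genes and to rescaling all TPM by a
positive constant. The median (not the mean) makes the index insensitive
to a minority of co-expressing samples. `density_grid()` bins the pairs on
shared $\log_{10}(\mathrm{TPM}+1)$ axes — so swapping the genes transposes
the grid — with marginal histograms as row/column sums, and
`plot_exclusivity()` renders the grid with a $\log_{10}(\mathrm{count}+1)$
color scale.

## Synthetic data: what it emulates, and what it does not

Because the original corpora (hundreds of genomes, thousands of RNA-seq
runs) are not reproducible at desk scale, every stage is validated against
generators with planted ground truth:

* `simulate_family()` derives homologs from a reference by iid
  substitutions and geometric-length indels, plants a chosen residue at
  the anchor column, and back-translates with uniformly chosen synonymous
  codons (the anchor codon is recorded, so codon-level checks have truth).
  Indels avoid the first/last three columns, and `protect_anchor` keeps a
  three-column guard around the anchor: a planted residue generally
  differs from the reference residue, so an indel immediately flanking the
  anchor would make the anchor column unidentifiable in principle — the
  guard is what keeps the planted truth well-defined rather than a
  convenience.
* `simulate_expression()` gives each species one FLS type and one DFR type
  and, per sample, expresses exactly one of the two families with
  probability `rho` (TPM lognormal, meanlog $\log 100$, sdlog 1 — a
  plausibly strong signal over a 0.01 TPM noise floor), both otherwise,
  splitting family TPM over paralogs by a symmetric Dirichlet draw.

The generators are deliberately simple: divergence is star-shaped (iid
from the reference, not tree-structured), substitution is uniform across
residues and sites, expression has no organ or batch structure, and
paralog identity is controlled only via substitution count. Passing tests
therefore demonstrate that the pipeline's logic is correct under its own
stated model — they do not demonstrate robustness to deep divergence,
domain rearrangements, alignment-hostile low-complexity regions, or the
messiness of real RNA-seq quantification.

The packaged references returned by `toy_reference()` are synthetic: a
deterministic random background with every screened feature planted at its
canonical Arabidopsis-numbered position. They make the pipeline fully
exercisable offline; any real analysis should supply genuine reference
proteins through `reference_anchor()`.

## Numerical and scale choices

Default problem sizes keep the full validation suite fast: 200 homologs
for recovery checks, 6-taxon matrices for topology oracles, 100 bootstrap
replicates (1,000 is the conventional publication setting and is a single
argument away), 500 samples for exclusivity calibration. All generators
and the bootstrap take explicit seeds; there is no hidden RNG state, and
the helpers restore the caller's RNG after use. Branch-length and distance
comparisons use 1e-9 tolerances; TPM conservation checks use 1e-12
(floating-point summation order is the only permitted difference).

## Known limitations

* Classification keys on a single residue; compensating substitutions
  elsewhere in the substrate-binding region are invisible to it.
* Substrate assignments for FLS types are hypothesized, not assayed; the
  `confidence` tag should be propagated to any downstream claim.
* p-distance NJ is a screening-grade phylogeny; for publication-grade
  trees, import an externally inferred newick and use only the annotation
  and clade-summary layers.
* The exclusivity index treats samples as exchangeable; it does not model
  organ composition, and bulk RNA-seq mixes cell types by construction.
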