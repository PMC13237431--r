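---
title: "Diagnostic-residue fingerprinting and duplication-history analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic-residue fingerprinting and duplication-history analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdx)
```

## The problem

When a gene duplicates recently — as the hydroxycarboxylic acid receptor
gene HCAR2/3 did repeatedly during ape evolution — the resulting paralogs can
be nearly identical in sequence (here, 95–100% pairwise identity), yet carry
distinct functions. Two questions then arise for every new genome. First,
*which paralog is this copy?* — answered at the sequence level by a small set
of diagnostic residues. Second, *how are the copies in different species
related?* — answered by reconciling the gene tree with the species tree,
because copies that look like 1:1 orthologs may in fact descend from
independent duplication events. `paralogdx` implements both inference chains,
plus the structural comparison used to corroborate functional assignment, and
a simulator that generates fully ground-truthed data for all of it.

## Diagnostic positions and profile classification

A reference-anchored alignment (`ref_alignment`) maps alignment columns to
1-based residue numbers on one reference protein, so that "position 27" means
the same thing everywhere. Columns where the reference is gapped are
insertions relative to the reference: they carry no residue number, are
skipped by diagnostic analysis, and are consumed by indel analysis.

A position is **diagnostic** (strict mode, the default) when

* every group-A residue at that column is identical,
* every group-B residue is identical,
* the two states differ, and
* neither group carries a gap or `X` there (an unknown residue cannot be
  unambiguous).

Relaxed mode allows within-group polymorphism and only requires the two
per-group state *sets* to be disjoint. "Consistently and unambiguously
distinguishing" is not otherwise a formal notion; this operationalisation is
the package's own and the exhaustive per-column scan in the test suite is its
specification.

Classification calls each profile position of a query `MATCH_A`, `MATCH_B`,
`NEITHER`, or `AMBIGUOUS` (gap/`X`). `AMBIGUOUS` is deliberately distinct
from `NEITHER`: unknowable is not the same as mismatching.

### Verdict rules

Two rules are provided:

* `"pocket"` (default): `A_LIKE` requires a strict majority of A-matches
  *and* no B-match at any pocket-proximal position. This encodes the
  functional argument that mismatches far from the ligand-binding pocket are
  unlikely to matter, while a pocket-lining mismatch undermines the
  assignment.
* `"majority"`: counts alone decide.

The rules genuinely disagree on interesting cases. In the worked example the
siamang blue-clade copy matches the HCAR3 state at 8 of 12 positions but
keeps HCAR2 states at two pocket-proximal positions (86 and 176); the pocket
rule therefore returns `MIXED` where a narrative assignment by majority would
say HCAR3-like. The same happens for the orangutan HCAR3-like copies
(HCAR2 state at pocket-proximal position 86). We regard the conservative
`MIXED` as the defensible automated call and leave the override to the
`"majority"` rule. Ties (`n_a == n_b`) are always `MIXED`; nothing is broken
silently. For simulated data, which has no pocket annotation, `"majority"`
is the appropriate rule.

Discovery requires at least 2 sequences per group and warns below 4, the
size used when the HCAR profile was defined; within-group fixation observed
in fewer than 4 sequences is weak evidence.

## Indels and percent identity

Indel blocks are maximal runs of reference-gap columns (insertions) or of
gapped reference positions (deletions) per record; records sharing *exactly*
the same block coordinates are merged into one carrier set. Near-identical
blocks are reported separately — no fuzzy merging — so calls stay auditable.
`min_length` defaults to 3 to suppress single-column alignment noise; the
24-residue insertion and the 11-residue Colobinae deletion of the worked
example are robust to this choice.

Percent identity needs a denominator convention, and published values rarely
state one. Three are implemented: `ungapped_columns` (default; columns where
both records carry residues), `shorter_seq`, and `all_columns`. The default
is the convention under which the worked example reproduces the published
range (100% for bonobo vs chimpanzee HCAR2 down to ~95% for human HCAR3 vs
gorilla HCAR2). Percentages are never rounded in computation.

## Reconciliation

`lca_reconcile()` is the standard parsimony LCA mapping: each gene-tree leaf
maps to its species, each internal node to the species-tree LCA of its
children's images, and a node is a duplication iff its image equals a child's
image. Losses along a gene-tree edge (u, v) follow the classical path-depth
formula: with d the species-tree depth difference between the images,
a speciation parent contributes d − 1 losses and a duplication parent d, each
placed on the sibling branch bypassed along the path. Losses above the
gene-tree root's image are not counted (nothing in the data attests the gene
ever existed there); a practical corollary is that pruning a leaf that hangs
directly off the root shrinks the root image instead of adding a loss.

Gene trees must be rooted and binary. Polytomies are rejected unless
`resolve_polytomies = TRUE` resolves them (arbitrarily, with a message);
rooting helpers (`root_tree()`) announce what they did and are never silent.
Support values are carried through but not used.

`compare_scenarios()` turns a narrative disagreement about duplication
history into a computable comparison: each candidate gene tree over the same
gene set is reconciled and costed as
`dup_cost * duplications + loss_cost * losses` (defaults 1:1). Ties are
reported explicitly. In the worked example the observed topology needs 4
duplications and 2 losses, while the single-ancestral-duplication
alternative — transcribed so that the non-ape single copies are HCAR2
orthologs, which is what that hypothesis claims — forces the duplication to
the primate root with 5 losses. Under 1:1 weights these tie at cost 6, which
is itself informative: the dup/loss parsimony comparison alone does not
decide the question; the observed topology is preferred on sequence-level
grounds (it is the maximum-likelihood tree), and the scenario table
quantifies what the alternative must pay in losses.

`species_clustering_test()` checks the gene-conversion expectation: under
conversion, copies within a genome homogenise and should form
species-specific clades. Species with one copy are `NA`, not counted in the
fraction.

## Structural comparison

`kabsch_superpose()` computes the least-squares optimal rigid superposition
via SVD of the 3×3 covariance matrix, with the standard determinant sign
correction so reflections are never returned; rotations are orthonormal with
det +1 to 1e-10 in the property tests, and agreement with an independent
quaternion (Horn) implementation is required to 1e-9 Å. Geometry whose
second covariance singular value is below 1e-12 of the largest (collinear
points) is rejected as degenerate rather than silently resolved.

`rmsd_over_range()` restricts the comparison to a stated residue interval
(such as 8–302 or 17–300) and *errors* on missing residues, listing them,
instead of dropping them — so n is identical across the comparisons being
contrasted. `paired_ttest()` is the classical paired t on matched RMSD
samples; zero-variance differences are reported as t = 0, p = 1 (all-zero)
or t = ±Inf, p = 0, flagged `degenerate`, never hidden.

## The simulator

`simulate_family()` evolves a protein down a species tree. Background sites
substitute with probability 1 − exp(−rate · branch length) to a uniformly
chosen different residue; the D designated diagnostic sites never substitute
in the background and, at each duplication event, switch in the new daughter
lineage to states never used before at that site. Within-group invariance
and between-group disjointness therefore hold *by construction*, which is
what makes ground-truthed recovery experiments possible. Duplication events
are placed deterministically on named branches (an event duplicates every
lineage traversing the branch); losses are either forced on named branches
or drawn per branch for post-duplication lineages. Indels are placed
deterministically by specification, not evolved: the motivating data treats
them as discrete lineage-specific features. One global random stream is
seeded once per run; identical seeds give byte-identical output.

What the simulator does *not* emulate — deliberately: empirical amino-acid
exchangeabilities, rate heterogeneity across sites, indel evolution, and
alignment error. Passing recovery tests therefore show the inference chain
is correct on data that satisfies its assumptions, not that real alignments
satisfy them.

`simulate_hcar_like()` is the preset study condition: 15 primate species,
duplications on the hominine ancestor, orangutan ancestor and
Hoolock+Symphalangus ancestor plus a nested duplication on the Hoolock
branch, loss of the ancestral-group lineage in Hoolock, D = 12 diagnostic
sites on a 363-residue protein, and a 24-residue C-terminal insertion in the
human/chimpanzee/bonobo members of the hominine-derived group. LCA
reconciliation of its output gives 4 duplications and 1 loss by
construction. Note this preset is a *qualitative* emulation: the worked
example's transcribed gene tree places the gibbon duplication at the gibbon
root (making the green clade monophyletic), which implies a second loss.

Coordinate simulation (`simulate_coord_pairs()`) builds a base backbone as a
3.8 Å-step random walk with a 2 Å clash distance and perturbs copies with
isotropic per-axis Gaussian noise σ, giving expected RMSD ≈ σ√3 after an
arbitrary rigid motion. `simulate_rmsd_study()` mirrors the two-reference
design — one set of models compared to a near and a far reference, with
default target means 0.801 and 1.336 Å taken from the motivating study's
printed values — and feeds the paired t-test.

## The worked-example fixture

Real HCAR sequences are not shipped. `hcar_fixture_alignment()` (also under
`inst/extdata/` as `hcar_synthetic_*`) is a synthetic alignment over a
repeating-pattern background whose engineered residues reproduce the
published *pattern*: text-derived facts are the 12 diagnostic positions and
their TM placement, the profile states at positions 27 (V/A), 173 (G/T) and
167 (HCAR3 = L), the per-lineage match counts (tarsier 9/2 with S at 173;
New World monkey 9/1 with S at 27 and N at 173; Old World monkey 11 + T at
173; strepsirrhine 9/2 at 27 and 168; siamang 11/1 and 3/8 with position 91
matching neither; hoolock 9/3; orangutan 10 of 12 with exceptions 86 and
142), the 18 differing positions between human HCAR2 and HCAR3, the
24-residue insertion absent from gorilla HCAR3, and the 11-residue Colobinae
deletion. Everything else — the background sequence, the states at the other
nine diagnostic positions, the TM boundary coordinates, all branch lengths —
is invented. Conclusions about real receptors must come from real sequences
run through the same functions.

## Numerical and design choices

* Coordinates are 1-based and end-inclusive everywhere, including the region
  track (unlike BED).
* `X` never matches any state: it is `AMBIGUOUS` in classification and never
  counts as identical in percent identity.
* Kabsch degeneracy tolerance 1e-12 (relative, second singular value);
  oracle agreement asserted at 1e-9 Å; t-test reference agreement at 1e-10.
* Scenario ties and clustering `NA`s are reported, never resolved silently.
* Problem sizes used by the shipped checks: 1,000 random alignments
  (8 × 50) against the exhaustive discovery oracle; 1,000 random tree pairs
  (≤ 6 species, ≤ 12 genes) against the ancestor-set reconciliation oracle;
  100 random point clouds for the quaternion cross-check; 200 replicates of
  the 6-model paired RMSD design (60 residues) for power calibration;
  100 preset simulations for recall/false-positive calibration. These sizes
  make the whole suite run in well under a minute while keeping Monte-Carlo
  noise far from the asserted bounds.

## Limitations

* Reconciliation is parsimony-based; it does not model incomplete lineage
  sorting or use branch lengths, and it requires correctly rooted inputs.
* Diagnostic discovery is exact-match logic; it has no notion of
  biochemical similarity between residues.
* The identity conventions cover the common denominators but cannot recover
  which convention an external publication used if none reproduces its
  value.
* Tree inference itself (alignment, model selection, ML search, support) is
  out of scope: trees are consumed as Newick.
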