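---
title: "Methods: models, parameters and design choices in septinevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in septinevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septinevo)
```

`septinevo` implements the stages of a comparative analysis of septin
paralog evolution across opisthokonts. This vignette is the package's
account of the underlying science: the models and their assumptions, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the choices made where the design was genuinely open.

## Septin identification

Candidate septins are retained when they carry a recognised septin
domain label (`P-Loop_NTPase`, `CDC3`, `CDC_septin`) or, failing that,
at least two of the three G boxes of the GTPase core without a
conflicting domain (`LysM`, `DNA_binding`). The two routes are ordered:
a recognised domain always wins, which is what lets a known septin with
a degenerate box (a CDC3-like case) through, while the box route catches
divergent septins that domain databases miss (an AspE-like case).

Septins are Ras-superfamily GTPases, and the package's default box
patterns are the canonical GTPase elements:

| box | pattern | role |
|-----|---------------------|---------------------------------|
| G1  | `[AG]-x(4)-G-K-[ST]` | Walker A / phosphate binding |
| G3  | `D-x(2)-G`           | Mg2+ / switch II |
| G4  | `[NT]-K-x-D`         | guanine specificity |

G3 is short and frequent by chance, so hits must form a chain compatible
with a single GTPase domain: starts ordered G1 < G3 < G4 and a maximal
span of 400 residues from first to last box. Both constraints are
assumptions (whether the original filtering required order or span is
not recoverable) and both are arguments; among consistent chains the one
with the most boxes wins, ties broken towards the leftmost positions.

## Paralog Groups and rooting

Group identity is anchored: for each Group, the largest clade containing
at least one of its anchor septins (model-organism proteins such as the
*Aspergillus* or *Drosophila* septins) and no anchor of any other Group
is assigned wholesale. The exclusion rule makes overlapping assignments
impossible; leaves outside every anchored clade stay `UNCLASSIFIED`
rather than being forced into a Group. With no recognisable outgroup for
the septin family itself, gene trees are rooted either on a supplied
leaf set (in practice the branch separating Groups 3 and 5) or at the
midpoint of the longest leaf-to-leaf path; the two agree for trees whose
deepest split is that branch.

## Duplication-loss reconciliation

A gene tree is embedded in the species tree by the LCA map: each leaf
goes to its taxon, each internal node to the LCA of its children's
images. A node is a duplication iff its image equals the image of at
least one child. Losses on a gene edge (p, c) count the species branches
skipped: `depth(M(c)) - depth(M(p)) - 1` below a speciation,
`depth(M(c)) - depth(M(p))` below a duplication (depths in edges from
the species root). The LCA map minimises duplications + losses at unit
costs; the test suite verifies the minimum against a brute-force
enumeration of all valid reconciliation maps on small instances.

Weakly supported gene-tree nodes should not be allowed to inflate the
event count, so edges whose child support falls below a threshold
(default 0.90; supports above 1 are read as percentages) are contracted
into polytomies and every polytomy is re-resolved exhaustively, keeping
all resolutions that attain the minimal event count. Exhaustive
resolution is deliberate: a polytomy of degree *k* has (2k-3)!! rooted
resolutions, 10395 at the default cap of 7 children, and beyond the cap
the package raises an explicit error rather than resolving
heuristically — correctness over coverage at the scale of a per-family
analysis. Equally parsimonious reconciliations are all returned (up to
32, in deterministic lexicographic-Newick order) because downstream
summaries are defined as their average: per-branch copy numbers count,
for every species branch, the gene lineages present at the bottom of
that branch, and `copy_number_profile()` averages the count across
co-optima. Duplication and loss costs are exposed (`dup_cost`,
`loss_cost`, default 1/1) since the original tool's weights are not
documented.

## Mk ancestral states

Group presence/absence evolves as a 2-state continuous-time Markov
chain with gain rate `q01` and loss rate `q10`;
`P(t) = exp(Qt)` has the closed form
`P00 = pi0 + pi1 exp(-st)`, `P11 = pi1 + pi0 exp(-st)` with
`s = q01 + q10`, `pi1 = q01/s`. MK1 constrains `q01 = q10`; MK2 does
not. Likelihoods come from Felsenstein pruning (missing states
contribute flat partials) and are verified to 1e-10 against full
enumeration over internal-state assignments on small trees.

Choices worth recording:

* **Root prior.** The default is uniform (0.5, 0.5), the convention of
  the desktop ancestral-state tools this workflow mirrors; a stationary
  prior is a flag. For simulation-recovery analyses the package's own
  generator draws root states from the stationary distribution, and the
  matching (stationary) prior is used there: with a uniform prior the
  loss rate was visibly over-estimated (about 0.65–0.71 for a true 0.6
  across seeds) purely from prior mismatch.
* **Fitting.** Rates are optimised on the log scale in [1e-8, 1e3].
  MK1 is one-dimensional and uses a Brent interval search with explicit
  boundary checks (constant characters drive the rate to the floor);
  MK2 uses L-BFGS-B from five log-spaced starts, keeping the best.
* **Proportional likelihood** is the normalised *marginal* posterior of
  each state at each node (an up-down pass), not the joint
  reconstruction; a node is called resolved when one state exceeds 95%
  of the proportional likelihood.
* **Wilks test.** MK1 sits in the interior of the MK2 parameter space
  (the constraint is equality, not a boundary), so the statistic
  `2(lnL2 - lnL1)` is referred to chi-square with df = 1 without
  boundary correction. Calibration under the null is checked by
  simulation: 500 replicates of 5 characters each on a 22-taxon
  unit-depth tree at `q01 = q10 = 1` — a regime chosen once, with a
  handful of expected transitions per character, neither trivial nor
  saturated — give a rejection rate within [0.02, 0.08] at the 5%
  level. Characters are fitted independently per Group; pooling across
  characters sums their log-likelihoods.

Rate-recovery checks use a unit-depth species tree: rates of 0.3–0.6
per unit length on a 1350-Myr-deep tree would saturate the chain,
leaving only the rate *ratio* identifiable.

## Jensen-Shannon conservation

Column conservation is the Jensen-Shannon divergence (base-2, lambda =
0.5, hence symmetric and bounded by 1) between the column's residue
distribution and a background, down-weighted multiplicatively by the
gap fraction; all-gap columns score 0. The default background is the
BLOSUM62 marginal amino-acid frequency vector (the default of the
standard JSD conservation scorer); uniform is available. "Window size
one" in the upstream tool's sense is interpreted as no flank smoothing,
the package's default; an optional window average gives the centre
column weight 0.5 and the flanks the other 0.5 jointly. The exact
pseudocount and gap constants of the original webserver build are not
recoverable, so both are arguments (pseudocount default 1e-7).
Column-wise results are mapped onto a reference septin's residue
numbering (columns where the reference is ungapped map to successive
residue numbers), and `motif_overlap()` counts interface positions
inside/outside user-supplied region intervals — the package ships no
hard-coded motif coordinates, since no authoritative coordinate table
exists.

## Interface contacts

Dimer structures are scanned for inter-chain atom pairs with
`d <= r_i + r_j + probe_diameter` (probe 0.5 Å, boundary inclusive with
a 1e-9 guard against floating-point ties). Intra-chain pairs are
ignored; pairs where both atoms are peptide-backbone (`N`, `CA`, `C`,
`O`) *and* overlapping (`d < r_i + r_j`) are discarded as modelling
clashes. This threshold rule is a deterministic, oracle-checkable
surrogate for a dot-surface contact program; the element radii (C 1.70,
N 1.55, O 1.52, S 1.80, H 1.10, P 1.80 Å) are a standard published set
and overridable. Hydrogens are used if present in the input but never
added, so results on un-hydrogenated structures approximate
hydrogen-placed contacts — a documented limitation.

Contacts are deduplicated to residues, translated into reference
coordinates through each taxon's alignment row (residues at
reference-gap columns are dropped, with a logged count), counted per
template, and maximised over the templates of each interface type —
different crystal templates resolve different regions, so no single one
sees every interface. A position is consensus when its best template
shows interaction in at least `min_taxa` (10) of `n_taxa` (17) taxa.
Consensus positions are clustered into "interacting groups" by a
`max_gap` rule (successive positions at most 3 apart; the delimitation
used in the original figures is unstated, so this is an explicit
assumption), and per-Group residue frequency matrices with information
content `max_bits - H` are emitted as logo input (`max_bits` defaults
to 2, following the package's fixed contract for these profiles; pass
`log2(20)` for the conventional amino-acid logo ceiling).

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of its arguments and a seed, and each
returns ground truth alongside the data:

* **Species trees**: pure-birth conditioned on the taxon count,
  rescaled to a 1350-Myr root — the age scale of the opisthokont crown
  group; 22 taxa by default.
* **Gene families**: branch-wise birth-death with exponential waiting
  times; duplications copy the lineage in place, extinct subtrees are
  pruned, and the recorded truth is the *observable* history (a
  duplication whose one child died entirely collapses and is not
  counted; each pruned lineage is one loss). With losses disabled,
  reconciliation recovers the true duplication count exactly — the
  round-trip test; with losses enabled, parsimony may legitimately
  relocate events (a duplication followed closely by a loss is
  indistinguishable from a later single duplication).
* **Characters**: the same 2-state chain the Mk module fits, root drawn
  from the stationary distribution, true node states recorded.
* **Proteomes**: planted septins (all three boxes + domain), borderline
  septins (two boxes, no domain), low decoys (at most one box) and
  conflicting-domain decoys (two boxes + LysM/DNA_binding). Linker and
  decoy sequence is drawn from an 18-letter alphabet omitting D and K,
  which every box needs, so no decoy can acquire a second box by
  chance and filter precision/recall against truth is exactly 1 by
  construction — the test verifies the rule, not a statistical claim.
* **Structures**: one carbon pseudo-atom per residue (radius 1.7 Å) on
  two chains, homologous residues face to face 10 Å apart along the
  chain axis; planted positions sit at 3.8 Å across the interface (just
  inside the 3.9 Å carbon-carbon threshold), everything else at 6.5 Å or
  farther, so the planted contact set is geometrically unambiguous.
  29 G- and 20 NC-interface positions are planted by default — the size
  of interface sets such an analysis reports — across 17 taxa and the
  five template labels (`G:1-1`, `G:2-2`, `G:1-2`, `NC:2-2`, `NC:1-2`).
  Each taxon carries a few deletions relative to the reference so that
  taxon numbering and reference numbering genuinely differ, and a
  `dropout` argument removes planted contacts from chosen taxa to
  exercise the 10-of-17 rule. A 30% fraction of alignment columns
  (always including the planted positions) is globally conserved,
  mimicking the association between interface residues and
  conservation.

What the generators do **not** emulate: realistic substitution models
or indels, rate heterogeneity, homology-modelling error, full-atom
side-chain geometry, or phylogenetic correlation between sequence
conservation and the species tree. Passing tests therefore demonstrate
the correctness of the algorithms under controlled conditions, not the
robustness of the biological conclusions to real data noise.

## Pipeline determinism and problem sizes

`run_pipeline()` executes the stages through files only, so any stage
can be re-run from the previous outputs. Per-stage seeds are derived
deterministically from the master seed, and a run is byte-reproducible:
wall-clock timings go to a separate log, never into the report. The
default demo sizes (22 taxa, 7 gene families, 100 proteins, 85
structures of ~450 residues per chain, 500 Wilks replicates in the
acceptance analyses) were chosen as the smallest sizes at which each
statistical check is meaningful; a full run completes in well under a
minute on one core.

## Known limitations

* Polytomy resolution is exhaustive and capped; NOTUNG-style heuristic
  rearrangement search at large degree is out of scope.
* The reconciliation assumes a binary, dated-topology species tree and
  unit event costs by default.
* Contact detection approximates surface-probe logic by a distance
  threshold; subtle dot-surface effects (occlusion, aromatic normals)
  are not modelled.
* The conservation scorer's constants (pseudocount, gap handling) match
  the cited scorer's spirit, not a byte-identical reimplementation of
  any particular webserver build.
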