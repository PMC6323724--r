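# septinevo

Septins are GTP-binding cytoskeletal proteins of animals, fungi and their
protist relatives (the opisthokonts). They polymerise into
heterooligomers through two alternating binding surfaces — the **G
interface** around the GTP pocket and the **NC interface** at the
amino/carboxy-terminal face — and the paralog families ("Groups" 1A, 1B,
2A, 2B, 3, 4, 5) that fill the slots of these heteropolymers arose through
gene duplications reaching back more than a billion years.

`septinevo` is an R package for the comparative analysis behind such a
study, aimed at molecular evolutionists who want each stage as a tested,
reusable function rather than a chain of one-off scripts:

1. **Septin identification.** Scan protein sequences for the three G
   boxes of the septin GTPase domain (G1/Walker A `[AG]x4GK[ST]`, G3
   `Dx2G`, G4 `[NT]KxD`) and retain candidates with a recognised septin
   domain (`P-Loop_NTPase`, `CDC3`, `CDC_septin`) *or* at least two of
   the three boxes without a conflicting domain (`LysM`,
   `DNA_binding`).
2. **Group assignment and reconciliation.** Anchor each paralog Group on
   model-organism septins (the largest clade containing an anchor and
   excluding all others), then reconcile gene trees with the species
   tree under duplication–loss parsimony. Nodes with support below 0.90
   are rearranged to minimise duplications + losses; all equally
   parsimonious reconciliations are returned and per-branch gene copy
   numbers are averaged over them.
3. **Ancestral states.** Mk1/Mk2 maximum-likelihood reconstruction of
   Group presence/absence: Felsenstein pruning with
   `P(t) = exp(Qt)`, `Q = [[-q01, q01], [q10, -q10]]`, marginal
   ("proportional") likelihoods at every node, the 95% resolution rule,
   and a Wilks likelihood-ratio test of equal vs independent gain/loss
   rates.
4. **Conservation.** Per-column Jensen-Shannon divergence against a
   BLOSUM62 (or uniform) background,
   `score = (1 - gap_fraction) * JSD(column, background)`, mapped onto a
   CDC3-like reference residue numbering, with motif-overlap counting
   against annotated regions (G boxes, S1–S4, SUE, polybasic).
5. **Interface contacts.** Probe-style contact detection in two-chain
   dimer structures (atoms interact when
   `d <= r_i + r_j + probe_diameter`, probe 0.5 Å, one-way inter-chain
   only, backbone–backbone clashes discarded), deduplicated to residues,
   aggregated across taxa and crystal templates, and called as consensus
   interface positions when they interact in at least 10 of 17 taxa in
   at least one template. Per-Group residue frequency (logo) matrices
   and "interacting group" clusters summarise the result.
6. **Synthetic data.** Seeded generators for every input — ultrametric
   species trees, gene families evolving by branch-wise birth–death,
   2-state Markov characters, proteomes with planted septins and decoys,
   and dimer structures with planted interface contacts — each emitting
   ground truth, so the whole pipeline is testable without external
   data.

## Worked example

```r
library(septinevo)

## duplication-loss reconciliation of a small gene family
species <- ape::read.tree(text = "((A:1,B:1)AB:1,C:2)R;")
genes   <- ape::read.tree(text = "((A|1,B|1),(A|2,C|1));")
rec <- reconcile(genes, species)
rec[[1]]$n_duplications   # 1   (at the species root)
rec[[1]]$n_losses         # 2   (one copy lost on B, one on C)
rec[[1]]$branch_copies
#>  A  B  C AB  R
#>  2  1  1  2  2

## Mk likelihood of a presence/absence character on a cherry
cherry <- ape::read.tree(text = "(A:1,B:1);")
exp(mk_log_likelihood(cherry, c(A = 1, B = 1), mk_model("MK1", 0.5)))
#> 0.2838338

## synthetic proteome: the retention rule recovers the planted septins
prot <- simulate_septin_proteome(simulation_config(seed = 5))
res  <- filter_proteome(prot$records)
nrow(res$retained)        # 20 of 100, exactly the planted septins
table(res$decisions$reason)
#> conflict_fail   domain_pass     gbox_pass insufficient_fail
#>            10            15             5                70

## interface consensus on the synthetic 17-taxon, 5-template panel
sim <- simulation_config(seed = 9)
st  <- simulate_dimer_structures(sim)
cons <- aggregate_interfaces(structure_residue_table(st$structures),
                             st$alignment, "REF",
                             n_taxa = 17, min_taxa = 10)
sum(cons$consensus & cons$interface == "G")    # 29
sum(cons$consensus & cons$interface == "NC")   # 20
```

The reconciliation recovers one duplication at the species root — the
two gene lineages `(A|1,B|1)` and `(A|2,C|1)` both trace to it — with a
copy of the second lineage lost on branch B and a copy of the first lost
on branch C, giving two gene copies along the root and AB branches. The
consensus call recovers exactly the 29 G-interface and 20 NC-interface
positions planted by the generator.

A complete end-to-end run (simulate → filter → groups → reconcile →
ancestral states → conservation → contacts → report) is one call:

```r
report <- run_pipeline(pipeline_config(out_dir = "demo", seed = 1))
```

It writes Newick trees, FASTA/TSV tables, PDB structures, and a
deterministic JSON/text report under `demo/`.

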