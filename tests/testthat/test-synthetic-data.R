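# The generators are the study conditions for every downstream stage:
# they must be deterministic, carry consistent ground truth, and satisfy
# the structural guarantees the analysis relies on.

test_that("species tree simulation is ultrametric, binary and seeded", {
  tr <- simulate_species_tree(22, 0.01, seed = 1)
  expect_equal(ape::Ntip(tr), 22)
  expect_equal(tr$Nnode, 21)          # binary rooted tree arithmetic
  expect_true(is_ultrametric(tr))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1350)

  cherry <- simulate_species_tree(2, 1.0, seed = 7)
  d <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(d[1], d[2])

  a <- ape::write.tree(simulate_species_tree(22, 0.01, seed = 1))
  b <- ape::write.tree(simulate_species_tree(22, 0.01, seed = 1))
  expect_identical(a, b)
  expect_false(identical(
    a, ape::write.tree(simulate_species_tree(22, 0.01, seed = 2))))

  expect_error(simulate_species_tree(1, 1, seed = 1),
               class = "septinevo_invalid_parameter")
  expect_error(simulate_species_tree(5, 0, seed = 1),
               class = "septinevo_invalid_parameter")
})

test_that("gene family simulation without events is congruent", {
  sp <- simulate_species_tree(8, 0.01, seed = 3)
  fam <- simulate_gene_family(sp, dup_rate = 0, loss_rate = 0, seed = 5)
  expect_equal(sort(leaf_taxon(fam$tree$tip.label)), sort(sp$tip.label))
  expect_equal(fam$truth$n_duplications, 0L)
  expect_equal(fam$truth$n_losses, 0L)
  # topology congruent with the species tree
  gt <- fam$tree
  gt$tip.label <- leaf_taxon(gt$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(sp)), 0,
               ignore_attr = TRUE)
})

test_that("gene family truth is consistent with the emitted tree", {
  sp <- simulate_species_tree(10, 0.01, seed = 2)
  for (s in c(11, 12, 13, 14)) {
    fam <- simulate_gene_family(sp, dup_rate = 0.001, loss_rate = 0.0005,
                                seed = s)
    ev <- fam$truth$events
    # every truth event names an internal node of the emitted tree
    expect_true(all(ev$node %in% fam$tree$node.label))
    expect_equal(fam$truth$n_duplications,
                 sum(ev$event == "duplication"))
    expect_equal(fam$truth$n_losses, nrow(fam$truth$losses))
    # duplication-free leaves: each taxon copy count >= 1 unless lost
    expect_true(all(table(leaf_taxon(fam$tree$tip.label)) >= 1))
  }
  # determinism
  f1 <- simulate_gene_family(sp, 0.001, 0.0005, seed = 21)
  f2 <- simulate_gene_family(sp, 0.001, 0.0005, seed = 21)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  expect_identical(f1$truth, f2$truth)
})

test_that("fully extinct families raise an empty-family condition", {
  sp <- simulate_species_tree(4, 0.01, seed = 2)
  expect_error(simulate_gene_family(sp, dup_rate = 0, loss_rate = 1,
                                    seed = 1),
               class = "septinevo_empty_family")
})

test_that("binary characters follow the 2-state chain", {
  sp <- simulate_species_tree(6, 0.01, seed = 4)
  # no transitions possible: every character constant and equal to root
  ch0 <- simulate_binary_characters(sp, 0, 0, 20, seed = 9)
  expect_true(all(apply(ch0$matrix, 2, function(v) length(unique(v)) == 1)))
  # saturation: leaf frequencies near the symmetric stationary 0.5
  sp1 <- simulate_species_tree(6, 1, seed = 4, root_age = 1)
  ch <- simulate_binary_characters(sp1, 10, 10, 1000, seed = 10)
  expect_lt(abs(mean(ch$matrix) - 0.5), 0.05)
  # truth covers every internal node; determinism
  expect_equal(rownames(ch$truth$node_states),
               ensure_node_labels(sp1)$node.label)
  again <- simulate_binary_characters(sp1, 10, 10, 1000, seed = 10)
  expect_identical(ch, again)
  expect_error(simulate_binary_characters(sp, -1, 1, 5, seed = 1),
               class = "septinevo_invalid_parameter")
})

test_that("synthetic proteome categories behave as constructed", {
  out <- simulate_septin_proteome(simulation_config(seed = 5))
  expect_equal(nrow(out$records), 100)
  expect_equal(as.vector(table(out$truth$category)[
    c("genuine", "borderline", "decoy_low", "decoy_conflict")]),
    c(15L, 5L, 70L, 10L))
  # genuine records pass, conflict decoys fail
  rec <- out$records[match(out$truth$id[out$truth$category == "genuine"][1],
                           out$records$id), ]
  expect_true(classify_candidate(rec)$retained)
  rec <- out$records[match(
    out$truth$id[out$truth$category == "decoy_conflict"][1],
    out$records$id), ]
  dec <- classify_candidate(rec)
  expect_false(dec$retained)
  expect_equal(dec$reason, "conflict_fail")
  # determinism
  again <- simulate_septin_proteome(simulation_config(seed = 5))
  expect_identical(out, again)
})

test_that("dimer structures plant contacts with clean geometry", {
  sim <- simulation_config(seed = 6)
  st <- simulate_dimer_structures(sim)
  expect_length(st$structures, 17 * 5)
  s <- st$structures[[1]]
  at <- s$atoms
  A <- at[at$chain == "A", ]
  B <- at[at$chain == "B", ]
  d <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 +
              outer(A$z, B$z, "-")^2)
  planted <- if (startsWith(s$template, "G")) sim$planted_G_positions else
    sim$planted_NC_positions
  refmap <- map_to_reference(st$alignment, "REF")
  cols_tx <- which(strsplit(st$alignment[[s$taxon]], "")[[1]] != "-")
  local_idx <- match(planted, cols_tx)
  near <- d[cbind(local_idx, local_idx)]
  expect_true(all(abs(near - sim$contact_distance) < 1e-9))
  # all non-planted inter-chain pairs clear the 3.9 contact threshold
  d[cbind(local_idx, local_idx)] <- Inf
  expect_gt(min(d), 3.9)
  # determinism
  st2 <- simulate_dimer_structures(sim)
  expect_identical(st$structures[[10]]$atoms, st2$structures[[10]]$atoms)
  # planted position beyond the reference errors
  bad <- simulation_config(seed = 6, ref_length = 300)
  expect_error(simulate_dimer_structures(bad),
               class = "septinevo_invalid_parameter")
})

test_that("proteome and structure writers round-trip through files", {
  out <- simulate_septin_proteome(simulation_config(seed = 8))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_proteome(out$records, fa, tsv)
  back <- read_proteome(fa, tsv)
  expect_equal(back, out$records)

  st <- simulate_dimer_structures(simulation_config(seed = 8,
                                                    n_struct_taxa = 2))
  pdb <- tempfile(fileext = ".pdb")
  s <- st$structures[[1]]
  write_structure_pdb(s, pdb)
  back <- read_structure_pdb(pdb, taxon = s$taxon, template = s$template)
  expect_equal(back$atoms$resno, s$atoms$resno)
  expect_equal(back$atoms$chain, s$atoms$chain)
  expect_equal(back$atoms$x, s$atoms$x, tolerance = 1e-6)
  expect_equal(back$atoms$element, s$atoms$element)
})
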