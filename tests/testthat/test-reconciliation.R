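# LCA mapping and duplication-loss reconciliation, checked against a
# brute-force map-enumeration oracle and against simulator ground truth.

species3 <- ape::read.tree(text = "((A:1,B:1)AB:1,C:2)R;")

test_that("lca_map maps leaves to taxa and internals to LCAs", {
  # congruent gene tree: the natural isomorphism
  gt <- ape::read.tree(text = "((A|1,B|1),C|1);")
  m <- lca_map(gt, species3)
  labs <- names(m)
  expect_equal(labs[1:3], c("A", "B", "C"))
  expect_equal(labs[4:5], c("R", "AB"))
  # same-taxon cherry maps to the leaf
  gt2 <- ape::read.tree(text = "(A|1,A|2);")
  expect_equal(names(lca_map(gt2, species3))[3], "A")
  # the worked quartet
  gt3 <- ape::read.tree(text = "((A|1,B|1),(A|2,C|1));")
  m3 <- names(lca_map(gt3, species3))
  expect_equal(m3[5], "R")    # root
  expect_equal(m3[6], "AB")   # (a1,b1)
  expect_equal(m3[7], "R")    # (a2,c1)
  expect_error(lca_map(ape::read.tree(text = "(A|1,Z|1);"), species3),
               class = "septinevo_mapping_error")
})

test_that("congruent families reconcile with zero events", {
  gt <- ape::read.tree(text = "((A|1,B|1)1.0,C|1)1.0;")
  res <- reconcile(gt, species3)
  expect_length(res, 1)
  expect_equal(res[[1]]$n_duplications, 0L)
  expect_equal(res[[1]]$n_losses, 0L)
  expect_equal(res[[1]]$n_optima, 1L)
  expect_true(all(res[[1]]$branch_copies == 1))
})

test_that("the worked quartet yields one duplication and two losses", {
  gt <- ape::read.tree(text = "((A|1,B|1),(A|2,C|1));")
  res <- reconcile(gt, species3)
  expect_equal(res[[1]]$n_duplications, 1L)
  expect_equal(res[[1]]$n_losses, 2L)
  # the duplication sits at the species root
  ev <- res[[1]]$event_map
  expect_equal(ev$species_branch[ev$event == "duplication"], "R")
  # copy profile: two copies down to A, one on B and C
  bc <- res[[1]]$branch_copies
  expect_equal(unname(bc[c("A", "B", "C", "AB", "R")]), c(2, 1, 1, 2, 2))
  # event count matches the brute-force minimum
  expect_equal(res[[1]]$n_duplications + res[[1]]$n_losses,
               oracle_reconcile_min(gt, species3))
})

test_that("weakly supported nodes are rearranged to minimise events", {
  # both cherries weakly supported: collapsing gives a 4-child polytomy
  # whose optimal resolutions pair each A copy with a B copy (1 dup, 0
  # losses); the input topology would cost 2 dups
  sp <- ape::read.tree(text = "(A:1,B:1)R;")
  gt <- ape::read.tree(text = "((A|1,A|2)0.50,(B|1,B|2)0.50);")
  res <- reconcile(gt, sp, support_threshold = 0.90)
  expect_equal(res[[1]]$n_duplications, 1L)
  expect_equal(res[[1]]$n_losses, 0L)
  expect_equal(res[[1]]$n_optima, 2L)   # the two mixed pairings tie
  # keeping the supported topology: 2 duplications
  res_keep <- reconcile(gt, sp, support_threshold = 0.10)
  expect_equal(res_keep[[1]]$n_duplications, 2L)
  # averaging over co-optima
  prof <- copy_number_profile(res)
  expect_equal(unname(prof[c("A", "B", "R")]), c(2, 2, 2))
})

test_that("reconciliation attains the exhaustive minimum on random families", {
  set.seed(404)
  checked <- 0L
  for (i in 1:40) {
    n_sp <- sample(3:6, 1)
    sp <- simulate_species_tree(n_sp, 0.01, seed = 1000 + i)
    fam <- tryCatch(
      simulate_gene_family(sp, 0.0015, 0.0008, seed = 2000 + i),
      septinevo_empty_family = function(e) NULL)
    if (is.null(fam) || ape::Ntip(fam$tree) > 8 ||
        ape::Ntip(fam$tree) < 2) next
    res <- reconcile(fam$tree, sp)
    score <- res[[1]]$n_duplications + res[[1]]$n_losses
    expect_equal(score, oracle_reconcile_min(fam$tree, sp),
                 info = sprintf("instance %d", i))
    # losses non-negative, totals invariant to leaf order
    expect_true(all(res[[1]]$loss_branches >= 0))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("loss-free families recover the true duplication count", {
  for (i in 1:5) {
    sp <- simulate_species_tree(6, 0.01, seed = 300 + i)
    fam <- simulate_gene_family(sp, 0.0015, 0, seed = 400 + i)
    res <- reconcile(fam$tree, sp)
    expect_equal(res[[1]]$n_duplications, fam$truth$n_duplications)
    expect_equal(res[[1]]$n_losses, 0L)
  }
})

test_that("oversized polytomies raise an explicit error", {
  sp <- ape::read.tree(text = "(A:1,B:1)R;")
  tips <- paste0("A|", 1:9, ":1", collapse = ",")
  gt <- ape::read.tree(text = sprintf("(%s);", tips))
  expect_error(reconcile(gt, sp, max_children = 7),
               class = "septinevo_unresolved_polytomy")
})

test_that("copy_number_profile averages and validates", {
  expect_error(copy_number_profile(list()),
               class = "septinevo_invalid_input")
  fake <- function(v) list(branch_copies = v)
  prof <- copy_number_profile(list(fake(c(A = 1, B = 2)),
                                   fake(c(A = 2, B = 2))))
  expect_equal(unname(prof), c(1.5, 2))
})
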