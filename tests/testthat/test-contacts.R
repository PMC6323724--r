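# Probe-style contact detection, consensus interface calling and logo
# matrices.

atom_row <- function(chain, resno, atom, element, x, y = 0, z = 0) {
  data.frame(chain = chain, resno = resno, resname = "ALA", atom = atom,
             element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

two_atom <- function(d, atom = "CB") {
  septin_structure("s", "tx", "G:1-1",
                   rbind(atom_row("A", 1, atom, "C", 0),
                         atom_row("B", 1, atom, "C", d)))
}

test_that("the contact threshold is boundary inclusive", {
  # carbon-carbon: 1.7 + 1.7 + 0.5 = 3.9
  expect_equal(nrow(detect_contacts(two_atom(3.90))), 1L)
  expect_equal(nrow(detect_contacts(two_atom(3.91))), 0L)
  # raising the probe never removes a contact
  expect_equal(nrow(detect_contacts(two_atom(3.91),
                                    probe_diameter = 0.6)), 1L)
})

test_that("backbone-backbone clashes are discarded, others kept", {
  # both backbone, overlapping (2.0 < 3.4): modelling clash, dropped
  expect_equal(nrow(detect_contacts(two_atom(2.0, atom = "CA"))), 0L)
  # same overlap between side-chain atoms is a (tight) contact
  expect_equal(nrow(detect_contacts(two_atom(2.0, atom = "CB"))), 1L)
  # backbone pair at non-clashing distance is a contact
  expect_equal(nrow(detect_contacts(two_atom(3.5, atom = "CA"))), 1L)
})

test_that("atom pairs collapse to residue pairs with min gap", {
  atoms <- rbind(atom_row("A", 10, "CB", "C", 0),
                 atom_row("A", 10, "CG", "C", 0.5),
                 atom_row("A", 10, "CD", "C", 1.0),
                 atom_row("B", 55, "CB", "C", 3.8))
  s <- septin_structure("s", "tx", "NC:2-2", atoms)
  contacts <- detect_contacts(s)
  expect_equal(nrow(contacts), 1L)
  expect_equal(contacts$n_atom_pairs, 3L)
  expect_equal(contacts$min_gap, 2.8 - 3.4, tolerance = 1e-9)
  expect_equal(contacts$interface, "NC")
  res <- residue_interface_set(contacts)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$resno, c(10L, 55L))
  expect_equal(nrow(residue_interface_set(
    detect_contacts(two_atom(10)))), 0L)
})

test_that("chain relabelling yields the same residue pairs", {
  set.seed(31)
  s <- random_structure(25, seed = 31)
  sw <- s
  sw$atoms$chain <- ifelse(sw$atoms$chain == "A", "B", "A")
  a <- detect_contacts(s)
  b <- detect_contacts(sw)
  norm <- function(d) paste(pmin(d$resno_a, d$resno_b),
                            pmax(d$resno_a, d$resno_b))
  expect_setequal(norm(a), norm(b))
})

test_that("detection agrees exactly with the all-pairs oracle", {
  for (i in 1:25) {
    s <- random_structure(sample(10:40, 1), seed = 5000 + i)
    got <- detect_contacts(s)
    want <- oracle_contacts(s)
    expect_identical(sort(paste(got$resno_a, got$resno_b, sep = "_")),
                     want, info = sprintf("structure %d", i))
  }
  expect_error(detect_contacts(septin_structure(
    "s", "t", "G:1-1", atom_row("A", 1, "CB", "C", 0))),
    class = "septinevo_invalid_input")
})

test_that("consensus calling recovers planted interfaces exactly", {
  sim <- simulation_config(seed = 41)
  st <- simulate_dimer_structures(sim)
  tab <- structure_residue_table(st$structures)
  cons <- aggregate_interfaces(tab, st$alignment, "REF",
                               n_taxa = 17, min_taxa = 10)
  expect_setequal(cons$position[cons$consensus & cons$interface == "G"],
                  sim$planted_G_positions)
  expect_setequal(cons$position[cons$consensus & cons$interface == "NC"],
                  sim$planted_NC_positions)
  expect_true(all(cons$max_count[cons$consensus] == 17L))
  expect_equal(unique(cons$proportion[cons$consensus]), 1)
  # raising min_taxa never adds a consensus position
  cons18 <- aggregate_interfaces(tab, st$alignment, "REF",
                                 n_taxa = 17, min_taxa = 18)
  expect_equal(sum(cons18$consensus), 0L)
})

test_that("a position dropped below threshold leaves the consensus", {
  sim <- simulation_config(seed = 42)
  st <- simulate_dimer_structures(
    sim, dropout = data.frame(interface = "G", position = 129L,
                              n_missing = 8L))
  cons <- aggregate_interfaces(structure_residue_table(st$structures),
                               st$alignment, "REF", n_taxa = 17,
                               min_taxa = 10)
  gpos <- cons$position[cons$consensus & cons$interface == "G"]
  expect_false(129 %in% gpos)
  expect_setequal(gpos, setdiff(sim$planted_G_positions, 129))
  # the dropped position is still seen, at 9 of 17 taxa
  row129 <- cons[cons$position == 129 & cons$interface == "G", ]
  expect_equal(row129$max_count, 9L)
  expect_equal(row129$proportion, 9 / 17)
  # a just-at-threshold dropout keeps the position
  st10 <- simulate_dimer_structures(
    sim, dropout = data.frame(interface = "G", position = 129L,
                              n_missing = 7L))
  cons10 <- aggregate_interfaces(structure_residue_table(st10$structures),
                                 st10$alignment, "REF", n_taxa = 17,
                                 min_taxa = 10)
  expect_true(129 %in% cons10$position[cons10$consensus])
})

test_that("taxa missing from the alignment raise a mapping error", {
  sim <- simulation_config(seed = 43, n_struct_taxa = 3)
  st <- simulate_dimer_structures(sim)
  aln <- st$alignment[names(st$alignment) != "s02"]
  expect_error(
    aggregate_interfaces(structure_residue_table(st$structures), aln,
                         "REF"),
    class = "septinevo_mapping_error")
})

test_that("group frequency profiles give logo matrices", {
  aln <- c(ref = "AVGW", m1 = "AVGW", m2 = "AAGW", n1 = "VVWW",
           n2 = "V-WW")
  groups <- c(m1 = "G1", m2 = "G1", n1 = "G2", n2 = "G2")
  prof <- group_frequency_profiles(aln, groups, positions = c(1, 2, 4),
                                   reference_id = "ref")
  # identical residue: frequency 1, information content 2 bits
  expect_equal(unname(prof$G1$freq["A", "1"]), 1)
  expect_equal(unname(prof$G1$info["1"]), 2)
  # two-member split A/V: (0.5, 0.5) and 1 bit
  expect_equal(unname(prof$G1$freq[c("A", "V"), "2"]), c(0.5, 0.5))
  expect_equal(unname(prof$G1$info["2"]), 1)
  # frequencies sum to 1 over residues + gap, gaps tracked
  expect_equal(unname(colSums(prof$G2$freq)), rep(1, 3))
  expect_equal(unname(prof$G2$freq["-", "2"]), 0.5)
  expect_warning(
    group_frequency_profiles(aln, c(z = "G9"), 1, "ref"),
    "no sequences")
})

test_that("interface_cluster groups nearby positions", {
  expect_equal(interface_cluster(129L)$n_positions, 1L)
  cl <- interface_cluster(c(209L, 210L, 211L, 214L), max_gap = 3)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 209L)
  expect_equal(cl$end, 214L)
  cl2 <- interface_cluster(c(129L, 209L), max_gap = 3)
  expect_equal(nrow(cl2), 2L)
  expect_equal(nrow(interface_cluster(integer(0))), 0L)
})
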