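# Seeded synthetic-data generators. Every generator is a pure function of
# (arguments, seed): random state never leaks, and identical inputs give
# byte-identical outputs. Each generator returns ground truth alongside the
# data so downstream stages can be tested for exact recovery.

#' Default simulation configuration
#'
#' Bundles the knobs of the synthetic study design. Defaults emulate the
#' scale of a comparative opisthokont septin analysis: 22 taxa on an
#' ultrametric species tree with a 1350-Myr-old root, seven paralog
#' Groups, and a 17-taxon, 5-template structure panel with 29 planted
#' G-interface and 20 planted NC-interface reference positions.
#'
#' @param n_taxa number of species-tree leaves
#' @param birth_rate per-lineage speciation rate (events/Myr)
#' @param root_age age of the root in Myr (tree is rescaled to this depth)
#' @param dup_rate,loss_rate gene duplication and loss rates (events/Myr)
#' @param q01,q10 Mk gain (0 to 1) and loss (1 to 0) rates
#' @param n_chars number of binary characters
#' @param n_groups number of septin paralog Groups
#' @param seq_length protein sequence length for the synthetic proteome
#' @param ref_length reference (alignment) length for structures
#' @param n_struct_taxa number of taxa in the structure panel
#' @param planted_G_positions,planted_NC_positions reference residue
#'   numbers planted as G- / NC-interface contacts (must be disjoint)
#' @param contact_distance inter-chain distance (Angstrom) at planted
#'   contact positions
#' @param seed master seed
#' @return a list of class "septin_sim_config"
#' @export
simulation_config <- function(n_taxa = 22L,
                              birth_rate = 0.01,
                              root_age = 1350,
                              dup_rate = 0.0005,
                              loss_rate = 0.0003,
                              q01 = 0.5, q10 = 0.5,
                              n_chars = 7L,
                              n_groups = 7L,
                              seq_length = 300L,
                              ref_length = 450L,
                              n_struct_taxa = 17L,
                              planted_G_positions = default_planted_positions()$G,
                              planted_NC_positions = default_planted_positions()$NC,
                              contact_distance = 3.8,
                              seed = 1L) {
  for (nm in c("birth_rate", "dup_rate", "loss_rate", "q01", "q10")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  check_scalar_number(n_taxa, "n_taxa", lower = 2)
  if (length(intersect(planted_G_positions, planted_NC_positions)) > 0) {
    abort("planted G and NC position lists must be disjoint",
          "septinevo_invalid_parameter")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
    root_age = root_age, dup_rate = dup_rate, loss_rate = loss_rate,
    q01 = q01, q10 = q10, n_chars = as.integer(n_chars),
    n_groups = as.integer(n_groups), seq_length = as.integer(seq_length),
    ref_length = as.integer(ref_length),
    n_struct_taxa = as.integer(n_struct_taxa),
    planted_G_positions = as.integer(planted_G_positions),
    planted_NC_positions = as.integer(planted_NC_positions),
    contact_distance = contact_distance, seed = as.integer(seed)),
    class = "septin_sim_config")
}

#' Default planted interface positions
#'
#' 29 G-interface and 20 NC-interface reference residue numbers, laid out
#' along regions reminiscent of the septin core (G1/G3/G4 boxes, S motifs
#' and SUE for the G interface; polybasic/alpha-0 region, S1 and SUE for
#' the NC interface). The counts mirror the size of interface sets a
#' consensus analysis of this kind reports.
#'
#' @return list with integer vectors `G` (29) and `NC` (20)
#' @export
default_planted_positions <- function() {
  list(
    G = c(129L, 131L, 133L, 182L, 209L, 210L, 211L, 213L, 214L, 216L,
          260L, 262L, 264L, 266L, 268L, 289L, 291L, 330L, 332L, 334L,
          356L, 358L, 360L, 361L, 362L, 364L, 374L, 376L, 378L),
    NC = c(60L, 62L, 64L, 66L, 68L, 70L, 192L, 237L, 239L, 240L,
           241L, 242L, 386L, 388L, 393L, 398L, 401L, 402L, 404L, 406L))
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) simulation conditioned on the requested number of
#' extant taxa, rescaled so the root age equals `root_age` (default 1350
#' Myr, a plausible age for the opisthokont crown group). Tips are named
#' `t01`, `t02`, ... and internal nodes `n1`, `n2`, ...
#'
#' @param n_taxa number of leaves (>= 2)
#' @param birth_rate speciation rate (> 0)
#' @param seed integer seed
#' @param root_age depth of the root (default 1350)
#' @return an ultrametric rooted binary `phylo` tree
#' @export
simulate_species_tree <- function(n_taxa, birth_rate, seed, root_age = 1350) {
  check_scalar_number(n_taxa, "n_taxa", lower = 2)
  check_scalar_number(birth_rate, "birth_rate", lower = 0, strict = TRUE)
  check_scalar_number(root_age, "root_age", lower = 0, strict = TRUE)
  n_taxa <- as.integer(n_taxa)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_age / depth)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$node.label <- NULL
  ensure_node_labels(tr)
}

# ---------------------------------------------------------------------------
# Gene family birth-death simulation along the species tree
# ---------------------------------------------------------------------------

#' Simulate a gene family evolving by duplication and loss
#'
#' A birth-death process runs along every species-tree branch with
#' exponential waiting times: duplications copy the current lineage in
#' place, losses kill it. Surviving lineages speciate at species nodes.
#' Extinct subtrees are pruned from the returned gene tree; the truth
#' records the observable events (duplication nodes that survive pruning,
#' and each pruned lineage as one loss, placed on the species branch where
#' its root event occurred).
#'
#' @param species_tree ultrametric `phylo` species tree with node labels
#' @param dup_rate,loss_rate per-lineage event rates (>= 0)
#' @param seed integer seed
#' @return list with elements `tree` (gene `phylo`; leaves are
#'   `"taxon|copy"`), and `truth` (list: `events` data frame of internal
#'   node events with species branches, `n_duplications`, `losses` data
#'   frame, `n_losses`). Signals a condition of class
#'   "septinevo_empty_family" if every gene copy is lost.
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate, seed) {
  check_scalar_number(dup_rate, "dup_rate", lower = 0)
  check_scalar_number(loss_rate, "loss_rate", lower = 0)
  stopifnot(inherits(species_tree, "phylo"))
  species_tree <- ensure_node_labels(species_tree)
  sp_lab <- node_labels_all(species_tree)
  sp_children <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  sp_elen <- numeric(ape::Ntip(species_tree) + species_tree$Nnode)
  sp_elen[species_tree$edge[, 2]] <- species_tree$edge.length
  sp_times <- ape::node.depth.edgelength(species_tree)  # time from root
  root <- ape::Ntip(species_tree) + 1L
  ntip <- ape::Ntip(species_tree)
  total <- dup_rate + loss_rate

  with_seed(seed, {
    # full process tree incl. extinct lineages
    proc_at_node <- function(sp, time) {
      if (sp <= ntip) {
        return(list(type = "leaf", sp = sp, time = time))
      }
      kids <- lapply(sp_children[[as.character(sp)]], function(child) {
        proc_on_branch(child, 0, time)
      })
      list(type = "speciation", sp = sp, time = time, children = kids)
    }
    # evolve one lineage along the branch leading into species node `sp`,
    # `consumed` time units from the branch top
    proc_on_branch <- function(sp, consumed, entry_time) {
      len <- sp_elen[sp]
      w <- if (total > 0) rexp(1, total) else Inf
      if (consumed + w < len) {
        t_ev <- entry_time + w
        if (runif(1) < (if (total > 0) dup_rate / total else 0)) {
          a <- proc_on_branch(sp, consumed + w, t_ev)
          b <- proc_on_branch(sp, consumed + w, t_ev)
          list(type = "duplication", sp = sp, time = t_ev,
               children = list(a, b))
        } else {
          list(type = "loss", sp = sp, time = t_ev)
        }
      } else {
        proc_at_node(sp, entry_time + (len - consumed))
      }
    }
    full <- proc_at_node(root, 0)

    losses <- list()
    prune <- function(node) {
      if (node$type == "loss") return(NULL)
      if (node$type == "leaf") return(node)
      kids <- lapply(node$children, prune)
      dead <- vapply(kids, is.null, logical(1))
      if (all(dead)) return(NULL)
      if (any(dead)) {
        for (d in node$children[dead]) {
          losses[[length(losses) + 1L]] <<- d$sp
        }
      }
      kids <- kids[!dead]
      if (length(kids) == 1L) return(kids[[1L]])  # collapse unary node
      node$children <- kids
      node
    }
    pruned <- prune(full)
    if (is.null(pruned)) {
      stop(errorCondition("all gene copies were lost",
                          class = c("septinevo_empty_family",
                                    "septinevo_error", "error", "condition")))
    }

    # assign leaf copy indices and internal labels; build newick
    copy_count <- integer(length(sp_lab))
    gidx <- 0L
    events <- list()
    build <- function(node, parent_time) {
      if (node$type == "leaf") {
        copy_count[node$sp] <<- copy_count[node$sp] + 1L
        lab <- sprintf("%s|%d", sp_lab[node$sp], copy_count[node$sp])
        return(sprintf("%s:%.8f", lab, node$time - parent_time))
      }
      gidx <<- gidx + 1L
      lab <- sprintf("g%d", gidx)
      events[[length(events) + 1L]] <<-
        data.frame(node = lab,
                   event = if (node$type == "duplication")
                     "duplication" else "speciation",
                   species_branch = sp_lab[node$sp],
                   time = node$time, stringsAsFactors = FALSE)
      inner <- vapply(node$children, build, character(1),
                      parent_time = node$time)
      sprintf("(%s)%s:%.8f", paste(inner, collapse = ","), lab,
              node$time - parent_time)
    }
    tree <- if (pruned$type == "leaf") {
      # single surviving copy: a one-tip tree, built directly
      structure(list(edge = matrix(c(2L, 1L), 1),
                     tip.label = sprintf("%s|1", sp_lab[pruned$sp]),
                     edge.length = pruned$time, Nnode = 1L),
                class = "phylo")
    } else {
      ape::read.tree(text = paste0(build(pruned, pruned$time), ";"))
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(node = character(), event = character(),
                 species_branch = character(), time = numeric())
    loss_df <- if (length(losses)) {
      data.frame(species_branch = sp_lab[unlist(losses)],
                 stringsAsFactors = FALSE)
    } else data.frame(species_branch = character())
    list(tree = tree,
         truth = list(events = ev,
                      n_duplications = sum(ev$event == "duplication"),
                      losses = loss_df,
                      n_losses = nrow(loss_df)))
  })
}

# ---------------------------------------------------------------------------
# Binary characters under a 2-state Markov process
# ---------------------------------------------------------------------------

# 2-state transition probability matrix (rows: from-state 0,1)
mk_transition <- function(q01, q10, t) {
  s <- q01 + q10
  if (s <= 0) return(diag(2))
  e <- exp(-s * t)
  pi0 <- q10 / s
  pi1 <- q01 / s
  matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
           pi1 * (1 - e), pi1 + pi0 * e), nrow = 2)
}

#' Simulate binary characters on a tree
#'
#' Evolves `n_chars` independent presence/absence characters down the tree
#' under a 2-state Markov process with gain rate `q01` and loss rate
#' `q10`. The root state is drawn from the stationary distribution
#' (uniform when both rates are zero). True states at every internal node
#' are recorded.
#'
#' @param tree a `phylo` tree with branch lengths
#' @param q01,q10 gain and loss rates (>= 0)
#' @param n_chars number of characters
#' @param seed integer seed
#' @return list with `matrix` (taxa x characters 0/1 integer matrix) and
#'   `truth$node_states` (internal-node x characters matrix, rows named by
#'   node labels)
#' @export
simulate_binary_characters <- function(tree, q01, q10, n_chars, seed) {
  check_scalar_number(q01, "q01", lower = 0)
  check_scalar_number(q10, "q10", lower = 0)
  check_scalar_number(n_chars, "n_chars", lower = 1)
  stopifnot(inherits(tree, "phylo"))
  tree <- ensure_node_labels(tree)
  n_chars <- as.integer(n_chars)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  s <- q01 + q10
  pi1 <- if (s > 0) q01 / s else 0.5
  with_seed(seed, {
    states <- matrix(NA_integer_, nnode, n_chars)
    states[root, ] <- as.integer(runif(n_chars) < pi1)
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (k in seq_len(nrow(edges))) {
      p <- states[edges[k, 1], ]
      P <- mk_transition(q01, q10, elen[k])
      # probability of being in state 1 given parent state
      p1 <- ifelse(p == 1L, P[2, 2], P[1, 2])
      states[edges[k, 2], ] <- as.integer(runif(n_chars) < p1)
    }
    m <- states[seq_len(ntip), , drop = FALSE]
    rownames(m) <- tree$tip.label
    colnames(m) <- sprintf("c%d", seq_len(n_chars))
    node_states <- states[(ntip + 1L):nnode, , drop = FALSE]
    rownames(node_states) <- tree$node.label
    colnames(node_states) <- colnames(m)
    list(matrix = m, truth = list(node_states = node_states))
  })
}

# ---------------------------------------------------------------------------
# Synthetic septin proteome
# ---------------------------------------------------------------------------

# canonical G-box instances used when planting motifs; each matches the
# default pattern of its box and none of the others
GBOX_INSTANCES <- c(G1 = "GQSGLGKS", G3 = "DTPG", G4 = "TKLD")

# background alphabet for decoy/linker sequence: the 20 amino acids minus
# D and K, so no G box (all of which need D and/or K) can arise by chance
BG_ALPHABET <- setdiff(AA20, c("D", "K"))

rand_seq <- function(n) paste(sample(BG_ALPHABET, n, replace = TRUE),
                              collapse = "")

# place the given motifs (in order) into a random background sequence
plant_motifs <- function(motifs, seq_length) {
  gaps <- length(motifs) + 1L
  spare <- seq_length - sum(nchar(motifs))
  # fixed comfortable spacing (>= 25 residues) between consecutive motifs
  sep <- max(25L, spare %/% (gaps + 1L))
  parts <- character(0)
  used <- 0L
  for (m in motifs) {
    parts <- c(parts, rand_seq(sep), m)
    used <- used + sep + nchar(m)
  }
  paste0(paste(parts, collapse = ""), rand_seq(max(0L, seq_length - used)))
}

#' Simulate a proteome with planted septins and decoys
#'
#' Emits four record categories: (a) genuine septins with all three G
#' boxes plus a recognised septin domain label; (b) borderline septins
#' with exactly two G boxes and no domain label; (c) decoys with at most
#' one G box; (d) decoys with two G boxes plus a conflicting domain label
#' (LysM or DNA_binding). Categories (a) and (b) are the planted true
#' septins. The background alphabet omits D and K so decoys cannot gain G
#' boxes by chance.
#'
#' @param config a [simulation_config()] (uses `seq_length`, `n_taxa`)
#' @param seed integer seed
#' @param n_genuine,n_borderline,n_decoy_low,n_decoy_conflict category
#'   sizes; defaults give 20 planted septins and 80 decoys
#' @return list with `records` (data frame: id, taxon, sequence,
#'   domain_labels) and `truth` (data frame: id, category, is_septin)
#' @export
simulate_septin_proteome <- function(config = simulation_config(),
                                     seed = config$seed,
                                     n_genuine = 15L, n_borderline = 5L,
                                     n_decoy_low = 70L,
                                     n_decoy_conflict = 10L) {
  if (config$seq_length < 250L) {
    abort("seq_length must be >= 250", "septinevo_invalid_parameter")
  }
  L <- config$seq_length
  taxa <- sprintf("t%02d", seq_len(config$n_taxa))
  septin_domains <- c("P-Loop_NTPase", "CDC3", "CDC_septin")
  conflict_domains <- c("LysM", "DNA_binding")
  two_box_sets <- list(c("G1", "G3"), c("G1", "G4"), c("G3", "G4"))
  with_seed(seed, {
    rec <- function(i, category) {
      switch(category,
        genuine = list(
          sequence = plant_motifs(GBOX_INSTANCES[c("G1", "G3", "G4")], L),
          domains = sample(septin_domains, 1)),
        borderline = list(
          sequence = plant_motifs(
            GBOX_INSTANCES[two_box_sets[[1 + (i %% 3)]]], L),
          domains = ""),
        decoy_low = list(
          sequence = if (i %% 2 == 0) rand_seq(L) else
            plant_motifs(GBOX_INSTANCES[sample(names(GBOX_INSTANCES), 1)], L),
          domains = ""),
        decoy_conflict = list(
          sequence = plant_motifs(
            GBOX_INSTANCES[two_box_sets[[1 + (i %% 3)]]], L),
          domains = sample(conflict_domains, 1)))
    }
    cats <- c(rep("genuine", n_genuine), rep("borderline", n_borderline),
              rep("decoy_low", n_decoy_low),
              rep("decoy_conflict", n_decoy_conflict))
    out <- lapply(seq_along(cats), function(i) rec(i, cats[i]))
    records <- data.frame(
      id = sprintf("p%03d", seq_along(cats)),
      taxon = taxa[1 + (seq_along(cats) - 1L) %% length(taxa)],
      sequence = vapply(out, `[[`, character(1), "sequence"),
      domain_labels = vapply(out, `[[`, character(1), "domains"),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      id = records$id, category = cats,
      is_septin = cats %in% c("genuine", "borderline"),
      stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Toy dimer structures with planted interface contacts
# ---------------------------------------------------------------------------

#' The five dimer template labels
#' @export
DIMER_TEMPLATES <- c("G:1-1", "G:2-2", "G:1-2", "NC:2-2", "NC:1-2")

#' Simulate two-chain dimer structures with planted interface contacts
#'
#' For each structure-panel taxon and each of the five crystal-template
#' labels, builds a two-chain pseudo-atom structure (one carbon atom per
#' residue, van der Waals radius 1.7 Angstrom). Homologous residues of the
#' two chains sit opposite each other; at positions planted for the
#' template's interface type the inter-chain distance is
#' `contact_distance` (default 3.8, inside the 3.9 contact threshold for
#' two carbons with a 0.5 probe), everywhere else it is at least 6.5.
#' Each non-reference taxon has a few residues deleted relative to the
#' reference, so taxon residue numbering differs from reference numbering
#' and must be reconciled through the returned alignment.
#'
#' @param config a [simulation_config()]
#' @param seed integer seed
#' @param dropout optional data frame (interface, position, n_missing):
#'   remove the planted contact at `position` from `n_missing` taxa (in
#'   all templates of that interface), to exercise the consensus
#'   threshold
#' @param n_deletions residues deleted per non-reference taxon
#' @param conserved_fraction fraction of alignment columns that are
#'   globally conserved (identical residue across taxa); planted
#'   interface positions are always conserved, mimicking the
#'   conservation of real interface residues, and further conserved
#'   columns are sampled to reach this fraction. Remaining columns are
#'   free (i.i.d. residues per taxon).
#' @return list with `structures` (list of septin_structure objects),
#'   `alignment` (named gapped strings incl. reference row `"REF"`), and
#'   `truth` (planted positions, dropout, taxa)
#' @export
simulate_dimer_structures <- function(config = simulation_config(),
                                      seed = config$seed,
                                      dropout = NULL,
                                      n_deletions = 2L,
                                      conserved_fraction = 0.3) {
  L <- config$ref_length
  planted <- list(G = config$planted_G_positions,
                  NC = config$planted_NC_positions)
  if (any(unlist(planted) > L)) {
    abort("planted position exceeds reference length",
          "septinevo_invalid_parameter")
  }
  taxa <- sprintf("s%02d", seq_len(config$n_struct_taxa))
  spacing <- 10
  far <- 6.5
  near <- config$contact_distance
  with_seed(seed, {
    ref_letters <- sample(AA20, L, replace = TRUE)
    aln <- c(REF = paste(ref_letters, collapse = ""))
    # column classes: planted positions conserved, plus sampled extras
    n_cons <- max(0L, round(conserved_fraction * L) - length(unlist(planted)))
    conserved <- sort(c(unlist(planted),
                        sample(setdiff(seq_len(L), unlist(planted)),
                               n_cons)))
    deleted <- list()
    for (tx in taxa) {
      letters_tx <- sample(AA20, L, replace = TRUE)
      letters_tx[conserved] <- ref_letters[conserved]
      del <- sort(sample(setdiff(seq_len(L), conserved), n_deletions))
      letters_tx[del] <- "-"
      aln[tx] <- paste(letters_tx, collapse = "")
      deleted[[tx]] <- del
    }
    # taxa lacking the planted contact, per dropped position
    drop_map <- list()
    if (!is.null(dropout) && nrow(dropout) > 0) {
      for (k in seq_len(nrow(dropout))) {
        key <- sprintf("%s:%d", dropout$interface[k], dropout$position[k])
        drop_map[[key]] <- sample(taxa, dropout$n_missing[k])
      }
    }
    structures <- list()
    for (tx in taxa) {
      row <- strsplit(aln[[tx]], "")[[1]]
      cols <- which(row != "-")            # alignment column per residue
      resno <- seq_along(cols)
      resname <- bio3d::aa123(row[cols])
      for (tmpl in DIMER_TEMPLATES) {
        iface <- sub(":.*", "", tmpl)
        yB <- rep(far, length(cols))
        for (p in planted[[iface]]) {
          key <- sprintf("%s:%d", iface, p)
          if (tx %in% (drop_map[[key]] %||% character(0))) next
          hit <- which(cols == p)          # ref row is ungapped: col == pos
          if (length(hit)) yB[hit] <- near
        }
        atoms <- rbind(
          data.frame(chain = "A", resno = resno, resname = resname,
                     atom = "CB", element = "C",
                     x = spacing * cols, y = 0, z = 0,
                     stringsAsFactors = FALSE),
          data.frame(chain = "B", resno = resno, resname = resname,
                     atom = "CB", element = "C",
                     x = spacing * cols, y = yB, z = 0,
                     stringsAsFactors = FALSE))
        structures[[sprintf("%s_%s", tx, tmpl)]] <- septin_structure(
          id = sprintf("%s_%s", tx, tmpl), taxon = tx,
          template = tmpl, atoms = atoms)
      }
    }
    truth_planted <- rbind(
      data.frame(interface = "G", position = planted$G),
      data.frame(interface = "NC", position = planted$NC))
    list(structures = structures, alignment = aln,
         truth = list(planted = truth_planted, dropout = drop_map,
                      taxa = taxa, deleted_columns = deleted))
  })
}

# ---------------------------------------------------------------------------
# Writers for the synthetic dataset (plain-text formats only)
# ---------------------------------------------------------------------------

#' Write a proteome as FASTA plus an annotation TSV
#' @param records proteome records data frame
#' @param fasta,tsv output paths
#' @export
write_proteome <- function(records, fasta, tsv) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, fasta)
  write.table(records[, c("id", "taxon", "domain_labels")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a proteome from FASTA plus an annotation TSV
#' @param fasta,tsv input paths
#' @return records data frame (id, taxon, sequence, domain_labels)
#' @export
read_proteome <- function(fasta, tsv) {
  aa <- Biostrings::readAAStringSet(fasta)
  ann <- read.delim(tsv, stringsAsFactors = FALSE,
                    colClasses = "character")
  ids <- sub("\\s.*$", "", names(aa))
  m <- match(ids, ann$id)
  if (anyNA(m)) abort("annotation TSV is missing ids present in FASTA")
  data.frame(id = ids, taxon = ann$taxon[m],
             sequence = unname(as.character(aa)),
             domain_labels = ann$domain_labels[m],
             stringsAsFactors = FALSE)
}

#' Write a character matrix as TSV (rows = taxa)
#' @param m taxa x characters matrix
#' @param path output path
#' @export
write_character_matrix <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a character matrix TSV
#' @param path input path
#' @return integer matrix with taxa as rownames
#' @export
read_character_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write an alignment (named gapped strings) as aligned FASTA
#' @param aln named character vector of equal-length gapped sequences
#' @param path output path
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln), path)
  invisible(NULL)
}

#' Read an aligned FASTA into a named character vector
#' @param path input path
#' @return named character vector of gapped sequences
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}
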