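# Paralog-Group assignment by anchor taxa, LCA mapping, and
# duplication-loss reconciliation of gene trees with the species tree,
# including support-based rearrangement of weak nodes.

#' Assign gene-tree leaves to paralog Groups by anchor leaves
#'
#' For each Group, the largest clade containing at least one of its
#' anchor leaves and no anchor of any other Group is found; all leaves of
#' that clade are assigned the Group. This anchors "the largest
#' monophyletic group possible" around model-organism septins. Leaves
#' outside every anchored maximal clade are `"UNCLASSIFIED"`.
#'
#' @param gene_tree rooted `phylo` gene tree
#' @param anchors named character vector: anchor leaf label -> Group label
#' @return named character vector over all leaves: Group or
#'   `"UNCLASSIFIED"`
#' @export
assign_groups <- function(gene_tree, anchors) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (!all(names(anchors) %in% gene_tree$tip.label)) {
    abort("anchor leaves missing from the gene tree",
          "septinevo_invalid_anchor")
  }
  tips <- gene_tree$tip.label
  ntip <- length(tips)
  # leaf sets of all clades: singletons plus internal-node bipartitions
  parts <- c(as.list(seq_len(ntip)),
             lapply(ape::prop.part(gene_tree), identity))
  clade_tips <- lapply(parts, function(ix) tips[ix])
  groups <- unique(anchors)
  assignment <- setNames(rep("UNCLASSIFIED", ntip), tips)
  chosen <- list()
  for (g in groups) {
    mine <- names(anchors)[anchors == g]
    others <- names(anchors)[anchors != g]
    ok <- vapply(clade_tips, function(cl) {
      any(mine %in% cl) && !any(others %in% cl)
    }, logical(1))
    if (!any(ok)) next
    sizes <- vapply(clade_tips[ok], length, integer(1))
    best <- clade_tips[ok][[which.max(sizes)]]
    chosen[[g]] <- best
  }
  # the exclusion rule makes overlap impossible; check invariantly
  all_assigned <- unlist(chosen, use.names = FALSE)
  if (anyDuplicated(all_assigned)) {
    abort("internal inconsistency: maximal Group clades overlap",
          "septinevo_internal")
  }
  for (g in names(chosen)) assignment[chosen[[g]]] <- g
  assignment
}

#' Default gene-leaf to taxon parser
#'
#' Gene leaves are conventionally labelled `"taxon|copy"`; everything up
#' to the first `|` is the taxon.
#' @param labels character vector of gene leaf labels
#' @return character vector of taxa
#' @export
leaf_taxon <- function(labels) sub("\\|.*$", "", labels)

resolve_leaf_taxa <- function(gene_leaves, leaf_to_taxon) {
  if (is.null(leaf_to_taxon)) return(leaf_taxon(gene_leaves))
  if (is.function(leaf_to_taxon)) return(leaf_to_taxon(gene_leaves))
  out <- unname(leaf_to_taxon[gene_leaves])
  if (anyNA(out)) {
    abort("leaf_to_taxon map is missing some gene leaves",
          "septinevo_mapping_error")
  }
  out
}

#' Map gene-tree nodes to species-tree nodes by LCA
#'
#' Leaves map to their taxon; every internal gene node maps to the
#' species-tree LCA of its children's images. This is the standard core
#' of parsimony gene-tree/species-tree reconciliation.
#'
#' @param gene_tree rooted `phylo` gene tree
#' @param species_tree rooted `phylo` species tree
#' @param leaf_to_taxon NULL (parse `taxon|copy` labels), a named
#'   character vector, or a function on leaf labels
#' @return integer vector over gene node ids (tips then internals) of
#'   species node ids; names give species node labels
#' @export
lca_map <- function(gene_tree, species_tree, leaf_to_taxon = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  species_tree <- ensure_node_labels(species_tree)
  idx <- species_index(species_tree)
  taxa <- resolve_leaf_taxa(gene_tree$tip.label, leaf_to_taxon)
  tipmatch <- match(taxa, species_tree$tip.label)
  if (anyNA(tipmatch)) {
    abort(sprintf("unknown taxa in gene tree: %s",
                  paste(unique(taxa[is.na(tipmatch)]), collapse = ", ")),
          "septinevo_mapping_error")
  }
  ngt <- ape::Ntip(gene_tree)
  map <- integer(ngt + gene_tree$Nnode)
  map[seq_len(ngt)] <- tipmatch
  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]; ch <- po[k, 2]
    map[p] <- if (map[p] == 0L) map[ch] else lca_pair(idx, map[p], map[ch])
  }
  setNames(map, node_labels_all(species_tree)[map])
}

# --------------------------------------------------------------------------
# nested-list tree representation used during rearrangement
# --------------------------------------------------------------------------

phylo_to_nested <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  sup <- node_supports(tree)
  ntip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) {
      return(list(leaf = tree$tip.label[node], children = NULL))
    }
    ch <- lapply(kids[[as.character(node)]], function(e) {
      build(tree$edge[e, 2])
    })
    list(leaf = NULL, children = ch, support = sup[node - ntip])
  }
  build(ntip + 1L)
}

# contract edges whose (internal) child support falls below the threshold
contract_weak_edges <- function(node, threshold) {
  if (is.null(node$children)) return(node)
  node$children <- lapply(node$children, contract_weak_edges, threshold)
  out <- list()
  for (ch in node$children) {
    weak <- !is.null(ch$children) && !is.na(ch$support %||% NA) &&
      (ch$support < threshold)
    if (weak) out <- c(out, ch$children) else out <- c(out, list(ch))
  }
  node$children <- out
  node
}

nested_newick <- function(node) {
  if (is.null(node$children)) return(node$leaf)
  paste0("(", paste(vapply(node$children, nested_newick, character(1)),
                    collapse = ","), ")")
}

# all rooted binary shapes over k items, as nested pair structures of
# indices; classic leaf-addition enumeration, (2k-3)!! shapes
binary_shapes <- function(k) {
  shapes <- list(1L)
  if (k == 1L) return(shapes)
  for (item in 2:k) {
    nxt <- list()
    for (s in shapes) {
      for (attach in shape_insertions(s, item)) nxt <- c(nxt, list(attach))
    }
    shapes <- nxt
  }
  shapes
}

# insert `item` on every edge of shape `s`, including above the root
shape_insertions <- function(s, item) {
  out <- list(list(s, item))
  if (is.list(s)) {
    for (i in 1:2) {
      for (sub in shape_insertions(s[[i]], item)) {
        s2 <- s
        s2[[i]] <- sub
        out <- c(out, list(s2))
      }
    }
  }
  out
}

# materialise a shape into a nested node over the given child subtrees
shape_to_nested <- function(shape, subtrees) {
  if (!is.list(shape)) return(subtrees[[shape]])
  list(leaf = NULL, support = NA_real_,
       children = list(shape_to_nested(shape[[1]], subtrees),
                       shape_to_nested(shape[[2]], subtrees)))
}

# resolve all polytomies in `node`; returns list of fully binary trees
enumerate_resolutions <- function(node, max_children, limit) {
  if (is.null(node$children)) return(list(node))
  child_sets <- lapply(node$children, enumerate_resolutions,
                       max_children = max_children, limit = limit)
  combos <- Reduce(function(acc, cs) {
    out <- list()
    for (a in acc) for (c in cs) out <- c(out, list(c(a, list(c))))
    if (length(out) > limit) {
      abort("too many candidate rearrangements; raise `resolution_limit`",
            "septinevo_unresolved_polytomy")
    }
    out
  }, child_sets, accumulate = FALSE, init = list(list()))
  k <- length(node$children)
  if (k > max_children) {
    abort(sprintf(
      "polytomy with %d children exceeds the resolution cap of %d",
      k, max_children), "septinevo_unresolved_polytomy")
  }
  shapes <- if (k <= 2L) NULL else binary_shapes(k)
  out <- list()
  for (kids in combos) {
    if (k <= 2L) {
      node2 <- node
      node2$children <- kids
      out <- c(out, list(node2))
    } else {
      for (s in shapes) {
        out <- c(out, list(shape_to_nested(s, kids)))
      }
    }
    if (length(out) > limit) {
      abort("too many candidate rearrangements; raise `resolution_limit`",
            "septinevo_unresolved_polytomy")
    }
  }
  out
}

# --------------------------------------------------------------------------
# LCA reconciliation of a nested gene tree against an indexed species tree
# --------------------------------------------------------------------------

# returns list(sp, n_dup, n_loss, events, losses, copies)
# sp_idx: species_index(); sp_tipmap: taxon -> species tip id;
# labels: species node labels
reconcile_nested <- function(node, sp_idx, sp_tipmap, labels,
                             collect = FALSE) {
  n_dup <- 0L
  n_loss <- 0L
  events <- list()
  loss_branches <- character(0)
  copies <- integer(length(sp_idx$par))

  # path of species nodes from `lo` (exclusive of `hi`) up to `hi`
  # returns nodes bottom-to-top including lo, excluding hi
  path_up <- function(lo, hi) {
    out <- integer(0)
    v <- lo
    while (v != hi) {
      out <- c(out, v)
      v <- sp_idx$par[v]
    }
    out
  }

  # siblings (other children) of `child` under `parent`
  other_children <- local({
    kids <- split(seq_along(sp_idx$par)[sp_idx$par != 0],
                  sp_idx$par[sp_idx$par != 0])
    function(parent, child) setdiff(kids[[as.character(parent)]], child)
  })

  walk <- function(node) {
    if (is.null(node$children)) {
      tx <- leaf_taxon(node$leaf)
      sp <- sp_tipmap[[tx]]
      if (is.null(sp)) {
        abort(sprintf("unknown taxon '%s'", tx), "septinevo_mapping_error")
      }
      return(list(sp = sp, leaves = node$leaf))
    }
    ch <- lapply(node$children, walk)
    ch_sp <- vapply(ch, `[[`, integer(1), "sp")
    sp <- lca_set(sp_idx, ch_sp)
    dup <- any(ch_sp == sp)
    if (dup) n_dup <<- n_dup + 1L
    leaves <- sort(unlist(lapply(ch, `[[`, "leaves")))
    if (collect) {
      events[[length(events) + 1L]] <<- data.frame(
        clade = paste(leaves, collapse = ","),
        event = if (dup) "duplication" else "speciation",
        species_branch = labels[sp], stringsAsFactors = FALSE)
    }
    # losses and copy intervals on each child edge
    for (i in seq_along(ch)) {
      c_sp <- ch[[i]]$sp
      steps <- sp_idx$depth[c_sp] - sp_idx$depth[sp]
      k <- if (dup) steps else steps - 1L
      n_loss <<- n_loss + max(0L, k)
      if (collect) {
        # branch where the lineage exists: from just-below the event down
        # to the child's image; lost siblings recorded along the way
        pu <- path_up(c_sp, sp)      # bottom-to-top, excludes sp
        covered <- if (dup) c(pu, sp) else pu
        copies[covered] <<- copies[covered] + 1L
        # lost sibling branches at every speciation the lineage crosses
        # without populating both sides; chain runs top-to-bottom
        chain <- c(sp, rev(pu))                # sp, ..., c_sp
        # for speciation parent: losses at chain[2..len-1]'s siblings
        # for duplication parent: losses at chain[1..len-1]'s siblings
        from <- if (dup) 1L else 2L
        len <- length(chain)
        if (len >= from + 1L) {
          for (j in from:(len - 1L)) {
            sibs <- other_children(chain[j], chain[j + 1L])
            loss_branches <<- c(loss_branches, labels[sibs])
          }
        }
      }
    }
    list(sp = sp, leaves = leaves)
  }
  res <- walk(node)
  if (collect) {
    # the root lineage occupies the stem branch of its image unless the
    # root is a duplication (whose child edges already cover that branch)
    root_dup <- length(events) > 0 &&
      events[[length(events)]]$event == "duplication" &&
      events[[length(events)]]$clade == paste(res$leaves, collapse = ",")
    if (!root_dup) copies[res$sp] <- copies[res$sp] + 1L
  }
  list(sp = res$sp, n_dup = n_dup, n_loss = n_loss,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(clade = character(0), event = character(0),
                    species_branch = character(0)),
       losses = loss_branches, copies = copies)
}

#' Reconcile a gene tree with the species tree
#'
#' Parsimony duplication-loss reconciliation with rearrangement of weakly
#' supported gene-tree nodes: edges whose child node support falls below
#' `support_threshold` (default 0.90) are contracted into polytomies,
#' every polytomy is exhaustively re-resolved, and the resolutions
#' minimising `dup_cost * duplications + loss_cost * losses` under LCA
#' reconciliation are returned. An internal node is a duplication iff its
#' species image equals the image of at least one child; losses on a gene
#' edge count the species branches skipped between the parent's and
#' child's images. Multiple equally parsimonious reconciliations are all
#' returned (up to `max_optima`, deterministic lexicographic-Newick
#' order) so downstream summaries can average over them.
#'
#' @param gene_tree rooted `phylo` gene tree with supports in node labels
#' @param species_tree rooted `phylo` species tree
#' @param leaf_to_taxon NULL (parse `taxon|copy`), named vector, or
#'   function
#' @param support_threshold nodes below this support are rearranged
#' @param dup_cost,loss_cost event costs (defaults 1/1)
#' @param max_children cap on polytomy degree for exhaustive resolution
#' @param max_optima cap on the number of co-optimal results returned
#' @param resolution_limit cap on enumerated candidate trees
#' @return list of reconciliation results; each has `tree` (resolved
#'   `phylo`), `event_map` (data frame: clade, event, species_branch),
#'   `n_duplications`, `n_losses`, `loss_branches`, `branch_copies`
#'   (named integer vector over species branches, identified by child
#'   node label; the root's stem included), and `n_optima` (number of
#'   co-optimal resolutions before capping)
#' @export
reconcile <- function(gene_tree, species_tree, leaf_to_taxon = NULL,
                      support_threshold = 0.90, dup_cost = 1,
                      loss_cost = 1, max_children = 7L,
                      max_optima = 32L, resolution_limit = 20000L) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  species_tree <- ensure_node_labels(species_tree)
  idx <- species_index(species_tree)
  labels <- node_labels_all(species_tree)
  sp_tipmap <- as.list(setNames(seq_len(ape::Ntip(species_tree)),
                                species_tree$tip.label))

  # relabel leaves through the taxon map so reconcile_nested can parse them
  gt <- gene_tree
  taxa <- resolve_leaf_taxa(gt$tip.label, leaf_to_taxon)
  if (!all(taxa %in% species_tree$tip.label)) {
    abort("gene leaves map to taxa absent from the species tree",
          "septinevo_mapping_error")
  }
  if (ape::Ntip(gt) == 1L) {
    # single surviving copy: no internal nodes, no events; the lineage
    # occupies just its taxon's branch
    copies <- setNames(integer(length(labels)), labels)
    copies[taxa[1]] <- 1L
    return(list(list(
      tree = gt,
      event_map = data.frame(clade = character(0), event = character(0),
                             species_branch = character(0)),
      n_duplications = 0L, n_losses = 0L,
      loss_branches = setNames(integer(0), character(0)),
      branch_copies = copies, n_optima = 1L)))
  }
  orig <- gt$tip.label
  gt$tip.label <- sprintf("%s|%s", taxa, orig)

  nested <- contract_weak_edges(phylo_to_nested(gt), support_threshold)
  candidates <- enumerate_resolutions(nested, max_children,
                                      resolution_limit)
  scores <- vapply(candidates, function(cand) {
    r <- reconcile_nested(cand, idx, sp_tipmap, labels, collect = FALSE)
    dup_cost * r$n_dup + loss_cost * r$n_loss
  }, numeric(1))
  best <- min(scores)
  opt <- candidates[scores == best]
  n_optima <- length(opt)
  ord <- order(vapply(opt, nested_newick, character(1)))
  opt <- opt[ord][seq_len(min(n_optima, max_optima))]

  lapply(opt, function(cand) {
    r <- reconcile_nested(cand, idx, sp_tipmap, labels, collect = TRUE)
    tr <- ape::read.tree(text = paste0(nested_newick(cand), ";"))
    # restore original leaf labels
    tr$tip.label <- orig[match(tr$tip.label, gt$tip.label)]
    copies <- setNames(r$copies, labels)
    loss_tab <- table(r$losses)
    list(tree = tr,
         event_map = r$events,
         n_duplications = r$n_dup,
         n_losses = r$n_loss,
         loss_branches = setNames(as.integer(loss_tab), names(loss_tab)),
         branch_copies = copies,
         n_optima = n_optima)
  })
}

#' Average per-branch gene copy number over co-optimal reconciliations
#'
#' @param results list of reconciliation results from [reconcile()] over
#'   the same species tree
#' @return named numeric vector: species branch (child node label) ->
#'   mean gene copy count
#' @export
copy_number_profile <- function(results) {
  if (length(results) == 0) {
    abort("no reconciliation results supplied")
  }
  mats <- vapply(results, `[[`, results[[1]]$branch_copies, "branch_copies")
  if (is.null(dim(mats))) return(results[[1]]$branch_copies + 0)
  rowMeans(mats)
}
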