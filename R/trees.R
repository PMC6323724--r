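# Tree utilities built on ape's "phylo" container: node labelling, support
# normalisation, depth/LCA bookkeeping and rooting.

#' Ensure a tree carries unique node labels
#'
#' Internal nodes without labels get deterministic labels `n1`, `n2`, ...
#' in node-number order. Existing labels are kept.
#'
#' @param tree an [ape::read.tree()]-style `phylo` object
#' @param prefix label prefix for unlabelled internal nodes
#' @return the tree with a complete `node.label` vector
#' @export
ensure_node_labels <- function(tree, prefix = "n") {
  stopifnot(inherits(tree, "phylo"))
  n <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0(prefix, which(empty))
  tree$node.label <- lab
  tree
}

#' Numeric branch supports from internal node labels
#'
#' Newick files store support values in the internal-node label position.
#' Both the [0,1] and the [0,100] dialects occur in practice; values above
#' 1 are interpreted as percentages and divided by 100. Non-numeric labels
#' yield NA (treated downstream as "no support information").
#'
#' @param tree a `phylo` object
#' @return numeric vector of length `tree$Nnode` in [0,1] (or NA)
#' @export
node_supports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  big <- !is.na(sup) & sup > 1
  sup[big] <- sup[big] / 100
  sup
}

# parent node id for every node (0 for the root)
parent_vector <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  par <- integer(nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# depth in edges from the root (root depth 0)
node_depths_edges <- function(tree) {
  par <- parent_vector(tree)
  root <- ape::Ntip(tree) + 1L
  nnode <- length(par)
  depth <- rep(NA_integer_, nnode)
  depth[root] <- 0L
  # edges in preorder guarantee parents are assigned before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) depth[ord[k, 2]] <- depth[ord[k, 1]] + 1L
  depth
}

# label for every node id: tip labels then node labels
node_labels_all <- function(tree) {
  tree <- ensure_node_labels(tree)
  c(tree$tip.label, tree$node.label)
}

# small-tree LCA by walking ancestors; `spidx` is a precomputed
# list(par=..., depth=...) to avoid recomputation in inner loops
species_index <- function(tree) {
  list(par = parent_vector(tree),
       depth = node_depths_edges(tree),
       root = ape::Ntip(tree) + 1L)
}

lca_pair <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$par[a] else b <- idx$par[b]
  }
  a
}

lca_set <- function(idx, nodes) Reduce(function(a, b) lca_pair(idx, a, b), nodes)

#' Root a tree by outgroup or at the midpoint
#'
#' Outgroup rooting places the root on the edge subtending the given
#' leaves, which must form one side of a split of the unrooted topology.
#' Midpoint rooting places the root halfway along the longest
#' leaf-to-leaf path. With no recognisable protist outgroup, septin gene
#' trees are typically rooted on the branch separating Groups 3 and 5
#' from the rest, a choice consistent with midpoint rooting.
#'
#' @param tree a `phylo` object (rooted or unrooted)
#' @param method `"outgroup"` or `"midpoint"`
#' @param outgroup_leaves character vector of leaf labels (outgroup method)
#' @return a rooted `phylo` object
#' @export
root_tree <- function(tree, method = c("outgroup", "midpoint"),
                      outgroup_leaves = NULL) {
  stopifnot(inherits(tree, "phylo"))
  method <- match.arg(method)
  if (method == "midpoint") {
    return(phangorn::midpoint(tree))
  }
  if (is.null(outgroup_leaves) || !all(outgroup_leaves %in% tree$tip.label)) {
    abort("outgroup leaves must all be present in the tree",
          "septinevo_invalid_input")
  }
  out <- tryCatch(
    ape::root(tree, outgroup = outgroup_leaves, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(out) ||
      !ape::is.monophyletic(out, outgroup_leaves)) {
    abort("outgroup does not form one side of a split of the tree",
          "septinevo_not_a_split")
  }
  out
}

#' Check ultrametricity of a tree
#'
#' @param tree a `phylo` object
#' @param tol relative tolerance on root-to-tip path lengths
#' @return TRUE/FALSE
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}
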