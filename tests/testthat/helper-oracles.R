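# Independent brute-force oracles used to verify the package's
# algorithmic cores. Each oracle enumerates the full state space rather
# than re-using the implementation's recursions.

# ---- 2-state Markov transition probabilities (closed form) ---------------
oracle_P <- function(q01, q10, t) {
  s <- q01 + q10
  if (s <= 0) return(diag(2))
  e <- exp(-s * t)
  pi0 <- q10 / s
  pi1 <- q01 / s
  matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
           pi1 * (1 - e), pi1 + pi0 * e), 2)
}

# ---- Mk likelihood by enumeration over all node state assignments --------
# x: named 0/1/NA vector over tips. Enumerates internal nodes and any
# missing tips; returns the likelihood (not log).
oracle_mk_likelihood <- function(tree, x, q01, q10,
                                 prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- rep(NA_integer_, nnode)
  obs <- x[tree$tip.label]
  states[seq_len(ntip)] <- as.integer(obs)
  free <- which(is.na(states))
  edges <- tree$edge
  elen <- tree$edge.length
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  for (r in seq_len(nrow(grid))) {
    s <- states
    s[free] <- grid[r, ]
    p <- prior[s[root] + 1]
    for (k in seq_len(nrow(edges))) {
      P <- oracle_P(q01, q10, elen[k])
      p <- p * P[s[edges[k, 1]] + 1, s[edges[k, 2]] + 1]
    }
    total <- total + p
  }
  total
}

# ---- marginal state probabilities by joint enumeration -------------------
# returns matrix (internal nodes in node-number order) x 2
oracle_mk_marginals <- function(tree, x, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- rep(NA_integer_, nnode)
  states[seq_len(ntip)] <- as.integer(x[tree$tip.label])
  free <- which(is.na(states))
  edges <- tree$edge
  elen <- tree$edge.length
  internals <- (ntip + 1L):nnode
  acc <- matrix(0, length(internals), 2)
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  for (r in seq_len(nrow(grid))) {
    s <- states
    s[free] <- grid[r, ]
    p <- prior[s[root] + 1]
    for (k in seq_len(nrow(edges))) {
      P <- oracle_P(q01, q10, elen[k])
      p <- p * P[s[edges[k, 1]] + 1, s[edges[k, 2]] + 1]
    }
    for (j in seq_along(internals)) {
      acc[j, s[internals[j]] + 1] <- acc[j, s[internals[j]] + 1] + p
    }
  }
  acc / rowSums(acc)
}

# ---- duplication-loss reconciliation by map enumeration ------------------
# Enumerates every valid gene-node -> species-node map (each internal gene
# node ranges over the ancestors, inclusive, of the LCA of its leaf taxa)
# and returns the minimal duplications + losses.
oracle_reconcile_min <- function(gene_tree, species_tree,
                                 taxa = septinevo::leaf_taxon(gene_tree$tip.label)) {
  sntip <- ape::Ntip(species_tree)
  spar <- integer(sntip + species_tree$Nnode)
  spar[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  sroot <- sntip + 1L
  sdepth <- vapply(seq_along(spar), function(v) {
    d <- 0L
    while (v != sroot) { v <- spar[v]; d <- d + 1L }
    d
  }, integer(1))
  ancestors <- function(v) {
    out <- v
    while (v != sroot) { v <- spar[v]; out <- c(out, v) }
    out
  }
  is_anc <- function(a, d) a %in% ancestors(d)  # a ancestor-or-equal of d
  slca <- function(a, b) {
    while (a != b) if (sdepth[a] >= sdepth[b]) a <- spar[a] else b <- spar[b]
    a
  }

  gntip <- ape::Ntip(gene_tree)
  gnn <- gntip + gene_tree$Nnode
  groot <- gntip + 1L
  gedge <- gene_tree$edge
  kids <- split(gedge[, 2], gedge[, 1])
  leafsets <- vector("list", gnn)
  for (v in seq_len(gntip)) leafsets[[v]] <- match(taxa[v],
                                                   species_tree$tip.label)
  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]
    leafsets[[p]] <- unique(c(leafsets[[p]], leafsets[[po[k, 2]]]))
  }
  internals <- (gntip + 1L):gnn
  lcas <- vapply(internals, function(v) Reduce(slca, leafsets[[v]]),
                 integer(1))
  options <- lapply(lcas, ancestors)
  grid <- expand.grid(lapply(options, identity), KEEP.OUT.ATTRS = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    M <- integer(gnn)
    M[seq_len(gntip)] <- vapply(seq_len(gntip), function(v) leafsets[[v]][1],
                                integer(1))
    M[internals] <- as.integer(grid[r, ])
    ok <- TRUE
    for (v in internals) {
      for (c in kids[[as.character(v)]]) {
        if (!is_anc(M[v], M[c])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    ndup <- 0L
    nloss <- 0L
    event_dup <- logical(gnn)
    for (v in internals) {
      ch <- kids[[as.character(v)]]
      l <- Reduce(slca, M[ch])
      dup <- (M[v] != l) || any(M[ch] == M[v])
      event_dup[v] <- dup
      if (dup) ndup <- ndup + 1L
    }
    for (k in seq_len(nrow(gedge))) {
      p <- gedge[k, 1]; c <- gedge[k, 2]
      steps <- sdepth[M[c]] - sdepth[M[p]]
      nloss <- nloss + max(0L, if (event_dup[p]) steps else steps - 1L)
    }
    best <- min(best, ndup + nloss)
  }
  best
}

# ---- contact detection by scalar double loop -----------------------------
oracle_contacts <- function(structure, probe_diameter = 0.5,
                            radii = vdw_radii(),
                            backbone = c("N", "CA", "C", "O")) {
  at <- structure$atoms
  chains <- sort(unique(at$chain))
  A <- at[at$chain == chains[1], ]
  B <- at[at$chain == chains[2], ]
  pairs <- character(0)
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      rsum <- radii[[A$element[i]]] + radii[[B$element[j]]]
      if (d > rsum + probe_diameter + 1e-9) next
      if (A$atom[i] %in% backbone && B$atom[j] %in% backbone &&
          d < rsum - 1e-9) next
      pairs <- c(pairs, paste(A$resno[i], B$resno[j], sep = "_"))
    }
  }
  sort(unique(pairs))
}

# random two-chain test structure with mixed elements
random_structure <- function(n_per_chain, seed, box = 12) {
  set.seed(seed)
  mk_chain <- function(chain) {
    n <- n_per_chain
    data.frame(chain = chain,
               resno = sort(sample.int(max(3, n %/% 2), n, replace = TRUE)),
               resname = "ALA",
               atom = sample(c("N", "CA", "C", "O", "CB", "CG"), n,
                             replace = TRUE),
               element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
               x = runif(n, 0, box), y = runif(n, 0, box),
               z = runif(n, 0, box), stringsAsFactors = FALSE)
  }
  septin_structure(id = sprintf("rand%d", seed), taxon = "tx",
                   template = "G:1-1",
                   atoms = rbind(mk_chain("A"), mk_chain("B")))
}
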