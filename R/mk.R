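# Mk1/Mk2 maximum-likelihood reconstruction of binary (presence/absence)
# characters on a species tree: Felsenstein pruning, rate fitting,
# marginal ("proportional") likelihoods with the 95% resolution rule, and
# the Wilks likelihood-ratio test between the equal-rates and
# independent-rates models.

#' Construct an Mk model
#'
#' MK1 constrains the gain (0 to 1) and loss (1 to 0) rates to be equal;
#' MK2 leaves them independent.
#'
#' @param kind `"MK1"` or `"MK2"`
#' @param q01 gain rate (>= 0)
#' @param q10 loss rate (>= 0; must equal `q01` for MK1)
#' @return list of class "mk_model"
#' @export
mk_model <- function(kind = c("MK1", "MK2"), q01, q10 = q01) {
  kind <- match.arg(kind)
  check_scalar_number(q01, "q01", lower = 0)
  check_scalar_number(q10, "q10", lower = 0)
  if (kind == "MK1" && q01 != q10) {
    abort("MK1 requires q01 == q10", "septinevo_invalid_parameter")
  }
  structure(list(kind = kind, q01 = q01, q10 = q10), class = "mk_model")
}

root_prior_vec <- function(root_prior, q01, q10) {
  if (identical(root_prior, "uniform")) return(c(0.5, 0.5))
  s <- q01 + q10
  if (s <= 0) return(c(0.5, 0.5))
  c(q10 / s, q01 / s)
}

# character input -> taxa x chars integer matrix (NA = missing '?')
as_char_matrix <- function(x, tip_labels) {
  if (is.matrix(x)) m <- x else m <- matrix(x, ncol = 1,
                                            dimnames = list(names(x), NULL))
  if (is.null(rownames(m))) {
    abort("characters must be named by taxon", "septinevo_invalid_input")
  }
  mm <- match(tip_labels, rownames(m))
  if (anyNA(mm)) {
    abort("character matrix is missing some tree taxa",
          "septinevo_mapping_error")
  }
  m <- m[mm, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# Precompiled likelihood evaluator: fixes the tree traversal and tip
# partials once, so rate optimisation only pays for per-edge arithmetic.
# Returns function(q01, q10, root_prior) -> log-likelihood (summed over
# characters).
mk_likelihood_function <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  m <- as_char_matrix(x, tree$tip.label)
  nch <- ncol(m)
  tip0 <- matrix(1, ntip, nch)
  tip1 <- matrix(1, ntip, nch)
  obs <- !is.na(m)
  tip0[obs] <- as.numeric(m[obs] == 0L)
  tip1[obs] <- as.numeric(m[obs] == 1L)

  function(q01, q10, root_prior = "uniform") {
    if (q01 < 0 || q10 < 0) {
      abort("rates must be non-negative", "septinevo_invalid_parameter")
    }
    s <- q01 + q10
    L0 <- matrix(1, nnode, nch)
    L1 <- matrix(1, nnode, nch)
    L0[seq_len(ntip), ] <- tip0
    L1[seq_len(ntip), ] <- tip1
    if (s > 0) {
      e <- exp(-s * elen)
      pi0 <- q10 / s
      pi1 <- q01 / s
      P00 <- pi0 + pi1 * e
      P01 <- pi1 * (1 - e)
      P10 <- pi0 * (1 - e)
      P11 <- pi1 + pi0 * e
    } else {
      P00 <- P11 <- rep(1, length(elen))
      P01 <- P10 <- rep(0, length(elen))
    }
    for (k in seq_len(nrow(edge))) {
      p <- edge[k, 1]; ch <- edge[k, 2]
      c0 <- L0[ch, ]; c1 <- L1[ch, ]
      L0[p, ] <- L0[p, ] * (P00[k] * c0 + P01[k] * c1)
      L1[p, ] <- L1[p, ] * (P10[k] * c0 + P11[k] * c1)
    }
    prior <- root_prior_vec(root_prior, q01, q10)
    sum(log(prior[1] * L0[root, ] + prior[2] * L1[root, ]))
  }
}

#' Mk log-likelihood of binary characters on a tree
#'
#' Felsenstein pruning with 2-state transition probabilities
#' P(t) = exp(Qt), Q = [[-q01, q01], [q10, -q10]]. Missing states (`NA` /
#' `?`) contribute (1, 1) partials. With several characters the
#' log-likelihoods are summed (characters are independent).
#'
#' @param tree `phylo` tree with branch lengths
#' @param x named 0/1 vector (taxa) or taxa x characters matrix; NA for
#'   missing
#' @param model an [mk_model()]
#' @param root_prior `"uniform"` (default, the convention of standard
#'   Mk ancestral-state software) or `"stationary"`
#' @return log-likelihood (a single number)
#' @export
mk_log_likelihood <- function(tree, x, model,
                              root_prior = c("uniform", "stationary")) {
  root_prior <- match.arg(root_prior)
  f <- mk_likelihood_function(tree, x)
  f(model$q01, model$q10, root_prior)
}

log_spaced <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimised on the log scale within `bounds`. MK1 (one rate)
#' uses a Brent interval search; MK2 (two rates) uses L-BFGS-B from
#' `n_starts` log-spaced starting points, keeping the best optimum.
#'
#' @param tree `phylo` tree
#' @param x character vector/matrix as in [mk_log_likelihood()]
#' @param kind `"MK1"` or `"MK2"`
#' @param root_prior as in [mk_log_likelihood()]
#' @param bounds rate search bounds (default `c(1e-8, 1e3)`)
#' @param n_starts number of multi-start points for MK2
#' @return list with `model` (fitted [mk_model()]) and `logLik`
#' @export
fit_mk <- function(tree, x, kind = c("MK1", "MK2"),
                   root_prior = c("uniform", "stationary"),
                   bounds = c(1e-8, 1e3), n_starts = 5L) {
  kind <- match.arg(kind)
  root_prior <- match.arg(root_prior)
  m <- as_char_matrix(x, tree$tip.label)
  if (all(is.na(m))) {
    abort("at least one observed leaf state is required",
          "septinevo_invalid_input")
  }
  f <- mk_likelihood_function(tree, x)
  lb <- log(bounds[1]); ub <- log(bounds[2])
  if (kind == "MK1") {
    nll <- function(lq) -f(exp(lq), exp(lq), root_prior)
    opt <- optimize(nll, interval = c(lb, ub))
    # a boundary can beat the interior optimum (e.g. constant characters)
    cand <- rbind(c(opt$minimum, opt$objective),
                  c(lb, nll(lb)), c(ub, nll(ub)))
    best <- cand[which.min(cand[, 2]), ]
    q <- exp(best[1])
    return(list(model = mk_model("MK1", q, q), logLik = -best[2]))
  }
  nll2 <- function(lq) -f(exp(lq[1]), exp(lq[2]), root_prior)
  starts <- log(log_spaced(bounds[1] * 10, bounds[2] / 10, n_starts))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(c(s0, s0), nll2, method = "L-BFGS-B", lower = lb, upper = ub),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("MK2 optimisation failed from every start",
          "septinevo_numerical_failure")
  }
  list(model = mk_model("MK2", exp(best$par[1]), exp(best$par[2])),
       logLik = -best$value)
}

#' Marginal (proportional) likelihoods of ancestral states
#'
#' Computes, for every internal node, the marginal posterior probability
#' of states 0 and 1 under the given model, by the standard up-down
#' algorithm (down partials from pruning, up partials from the root).
#' The pair at each node is normalised to sum to one — the "proportional
#' likelihood" displayed as pie charts in ancestral-state plots. A node
#' is `resolved` when one state carries more than 95% of the
#' proportional likelihood.
#'
#' @param tree `phylo` tree
#' @param x named 0/1 vector over taxa (one character); NA for missing
#' @param model an [mk_model()]
#' @param root_prior as in [mk_log_likelihood()]
#' @param resolve_threshold proportional likelihood needed to call a
#'   state resolved (default 0.95)
#' @return data frame (node, p0, p1, resolved) over internal nodes, in
#'   node-number order; `node` uses node labels when present
#' @export
marginal_reconstruction <- function(tree, x, model,
                                    root_prior = c("uniform", "stationary"),
                                    resolve_threshold = 0.95) {
  root_prior <- match.arg(root_prior)
  stopifnot(inherits(tree, "phylo"))
  tree <- ensure_node_labels(tree)
  m <- as_char_matrix(x, tree$tip.label)
  if (ncol(m) != 1L) {
    abort("marginal_reconstruction takes a single character",
          "septinevo_invalid_input")
  }
  q01 <- model$q01; q10 <- model$q10
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  # transition matrix per edge (rows: parent state)
  Pk <- lapply(seq_len(nrow(edge)), function(k) {
    mk_transition(q01, q10, elen[k])
  })
  # down pass: D[v, s] = P(data below v | state s at v)
  D <- matrix(1, nnode, 2)
  obs <- !is.na(m[, 1])
  D[seq_len(ntip), 1][obs] <- as.numeric(m[obs, 1] == 0L)
  D[seq_len(ntip), 2][obs] <- as.numeric(m[obs, 1] == 1L)
  Mdg <- matrix(NA_real_, nnode, 2)  # message child -> parent
  for (k in seq_len(nrow(edge))) {
    ch <- edge[k, 2]
    Mdg[ch, ] <- as.numeric(Pk[[k]] %*% D[ch, ])
    D[edge[k, 1], ] <- D[edge[k, 1], ] * Mdg[ch, ]
  }
  prior <- root_prior_vec(root_prior, q01, q10)
  # up pass: U[v, s] = P(data elsewhere, state s at v) (preorder)
  U <- matrix(NA_real_, nnode, 2)
  U[root, ] <- prior
  kids_of <- split(edge[, 2], edge[, 1])
  edge_of_child <- setNames(seq_len(nrow(edge)), edge[, 2])
  for (k in rev(seq_len(nrow(edge)))) {      # reverse postorder = preorder
    p <- edge[k, 1]; ch <- edge[k, 2]
    sibs <- setdiff(kids_of[[as.character(p)]], ch)
    excl <- U[p, ]
    for (sb in sibs) excl <- excl * Mdg[sb, ]
    U[ch, ] <- as.numeric(excl %*% Pk[[edge_of_child[[as.character(ch)]]]])
  }
  nodes <- (ntip + 1L):nnode
  post <- U[nodes, , drop = FALSE] * D[nodes, , drop = FALSE]
  post <- post / rowSums(post)
  data.frame(node = tree$node.label,
             p0 = post[, 1], p1 = post[, 2],
             resolved = pmax(post[, 1], post[, 2]) > resolve_threshold,
             stringsAsFactors = FALSE)
}

#' Wilks likelihood-ratio test between MK1 and MK2
#'
#' MK1 (equal rates) is nested in MK2 (independent rates) with one
#' constrained parameter; the statistic 2(lnL2 - lnL1) is compared to a
#' chi-square distribution with one degree of freedom. The constrained
#' point is interior to the MK2 parameter space, so no boundary
#' correction is needed.
#'
#' @param lnl_mk1,lnl_mk2 maximised log-likelihoods of the two models
#' @return list (statistic, p_value)
#' @export
wilks_test <- function(lnl_mk1, lnl_mk2) {
  if (lnl_mk2 < lnl_mk1 - 1e-6) {
    abort("MK2 log-likelihood below MK1: the models are nested",
          "septinevo_invalid_input")
  }
  stat <- max(0, 2 * (lnl_mk2 - lnl_mk1))
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
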