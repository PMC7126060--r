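# Independent brute-force oracles and small fixtures.
#
# The oracles deliberately avoid the pruning recursion: genotype
# configurations of the internal nodes are enumerated exhaustively on a
# grid and leaf contributions are direct 10-term sums, so agreement with
# the engine checks the dynamic programme against the model's definition.

GT10 <- genotype_states()

# random rooted tree with branch lengths in metres and k replicates per tip
random_physical_tree <- function(n_tips, k = 2, max_len = 10) {
  ph <- ape::rtree(n_tips, rooted = TRUE)
  ph$tip.label <- paste0("L", seq_len(n_tips))
  ph$edge.length <- stats::runif(nrow(ph$edge), 0.5, max_len)
  physical_tree(ph, n_replicates = k)
}

# random pileup for one site: per replicate, multinomial reads around a
# random "true-ish" base mix so variant-like and boring sites both occur
random_site_pileup <- function(tree, mean_depth = 8) {
  rt <- replicate_table(tree)
  counts <- matrix(0L, 1, 4 * nrow(rt))
  for (r in seq_len(nrow(rt))) {
    d <- stats::rpois(1, mean_depth)
    w <- stats::rexp(4)^2
    counts[1, 4 * (r - 1) + 1:4] <- as.integer(stats::rmultinom(1, d, w / sum(w)))
  }
  site_pileup("chr1", sample(1e6, 1), sample(c("A", "C", "G", "T"), 1),
              counts, rt)
}

# exhaustive-enumeration oracle for the site likelihood and DNP:
# grid over internal-node genotypes, direct sums over leaf genotypes
oracle_site <- function(tree, pileup1, params) {
  ph <- tree$phylo
  n_tip <- length(ph$tip.label)
  n_int <- ph$Nnode
  root <- n_tip + 1L
  P <- log(phylomut:::base_given_genotype(params$epsilon))
  leafLL <- lapply(seq_len(n_tip), function(k) {
    L <- numeric(10)
    for (r in tree$replicate_map[[ph$tip.label[k]]])
      L <- L + as.numeric(phylomut:::replicate_counts(pileup1, r) %*% P)
    L
  })
  Tm <- lapply(ph$edge.length, branch_transition_matrix, params = params)
  prior <- genotype_prior(pileup1$ref, params)
  grid <- as.matrix(expand.grid(rep(list(1:10), n_int)))
  int_node <- function(v) v - n_tip   # column in grid for internal node v
  log_terms <- log(prior)[grid[, int_node(root)]]
  for (e in seq_len(nrow(ph$edge))) {
    par <- ph$edge[e, 1]; chd <- ph$edge[e, 2]
    gp <- grid[, int_node(par)]
    if (chd > n_tip) {
      log_terms <- log_terms + log(Tm[[e]])[cbind(gp, grid[, int_node(chd)])]
    } else {
      # direct 10-term sum over the leaf genotype for each parent state
      m <- max(leafLL[[chd]])
      msg <- m + log(as.numeric(Tm[[e]] %*% exp(leafLL[[chd]] - m)))
      log_terms <- log_terms + msg[gp]
    }
  }
  m <- max(log_terms)
  log_total <- m + log(sum(exp(log_terms - m)))
  # no-mutation configuration: every node (leaves included) carries the
  # root genotype; every edge contributes its diagonal probability
  logdiag <- Reduce(`+`, lapply(Tm, function(M) log(diag(M))))
  S <- Reduce(`+`, leafLL)
  x <- log(prior) + logdiag + S
  mx <- max(x)
  log_nomut <- mx + log(sum(exp(x - mx)))
  list(log_total = log_total, dnp = 1 - exp(log_nomut - log_total))
}

# literal full enumeration including leaf genotypes (3-leaf scale only)
oracle_site_full <- function(tree, pileup1, params) {
  ph <- tree$phylo
  n_tip <- length(ph$tip.label)
  n_node <- n_tip + ph$Nnode
  root <- n_tip + 1L
  P <- log(phylomut:::base_given_genotype(params$epsilon))
  leafLL <- lapply(seq_len(n_tip), function(k) {
    L <- numeric(10)
    for (r in tree$replicate_map[[ph$tip.label[k]]])
      L <- L + as.numeric(phylomut:::replicate_counts(pileup1, r) %*% P)
    L
  })
  Tm <- lapply(ph$edge.length, branch_transition_matrix, params = params)
  prior <- genotype_prior(pileup1$ref, params)
  grid <- as.matrix(expand.grid(rep(list(1:10), n_node)))
  log_terms <- log(prior)[grid[, root]]
  for (e in seq_len(nrow(ph$edge)))
    log_terms <- log_terms +
      log(Tm[[e]])[cbind(grid[, ph$edge[e, 1]], grid[, ph$edge[e, 2]])]
  for (k in seq_len(n_tip))
    log_terms <- log_terms + leafLL[[k]][grid[, k]]
  m <- max(log_terms)
  m + log(sum(exp(log_terms - m)))
}

# brute-force Fitch parsimony: minimise state changes over all internal
# labelings drawn from the observed states
oracle_fitch <- function(tree, alignment) {
  ph <- ape::unroot(tree)
  ph <- ape::multi2di(ph)  # binary; fitch score is invariant to resolution of the root
  n_tip <- length(ph$tip.label)
  total <- 0L
  for (s in seq_len(ncol(alignment))) {
    states <- unique(alignment[, s])
    tipstate <- match(alignment[ph$tip.label, s], states)
    n_int <- ph$Nnode
    grid <- as.matrix(expand.grid(rep(list(seq_along(states)), n_int)))
    best <- Inf
    for (i in seq_len(nrow(grid))) {
      g <- c(tipstate, grid[i, ])
      ch <- sum(g[ph$edge[, 1]] != g[ph$edge[, 2]])
      best <- min(best, ch)
    }
    total <- total + best
  }
  as.integer(total)
}

# BFS oracle for the topological path difference
oracle_pd <- function(t1, t2) {
  leaf_dists <- function(tr) {
    tr <- ape::unroot(tr)
    g <- igraph::graph_from_edgelist(tr$edge, directed = FALSE)
    n <- length(tr$tip.label)
    d <- igraph::distances(g, v = seq_len(n), to = seq_len(n))
    dimnames(d) <- list(tr$tip.label, tr$tip.label)
    ord <- order(rownames(d))
    d[ord, ord]
  }
  d1 <- leaf_dists(t1); d2 <- leaf_dists(t2)
  sqrt(sum((d1 - d2)[upper.tri(d1)]^2))
}

# tiny deterministic pileup builder: named leaf -> named count vectors,
# identical counts across each leaf's replicates
fixed_pileup <- function(tree, ref, leaf_counts, pos = 1000L) {
  rt <- replicate_table(tree)
  counts <- matrix(0L, 1, 4 * nrow(rt))
  for (r in seq_len(nrow(rt))) {
    cv <- leaf_counts[[rt$leaf[r]]]
    idx <- match(names(cv), c("A", "C", "G", "T"))
    counts[1, 4 * (r - 1) + idx] <- as.integer(cv)
  }
  site_pileup("chr1", pos, ref, counts, rt)
}
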