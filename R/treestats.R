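# Positive-control tree statistics --------------------------------------------

#' Enumerate all unrooted binary topologies on n labelled leaves
#'
#' There are `(2n-5)!!` such topologies (10 395 for eight leaves).
#' Enumeration is bounded at `n <= 10` to guard against combinatorial
#' explosion.
#'
#' @param n Number of leaves, 3..10.
#' @param tip_labels Optional leaf labels (default `t1..tn`).
#' @return A `multiPhylo` of all distinct topologies.
#' @export
enumerate_topologies <- function(n, tip_labels = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 3 || n > 10)
    stop("n must be a single integer in 3..10")
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  stopifnot(length(tip_labels) == n)
  phangorn::allTrees(n, rooted = FALSE, tip.label = tip_labels)
}

# alignment (tips x sites character matrix) -> phyDat on its observed states
alignment_phydat <- function(alignment) {
  lev <- sort(unique(as.vector(alignment)))
  phangorn::phyDat(alignment, type = "USER", levels = lev)
}

#' Fitch parsimony score of topologies given a variant alignment
#'
#' Minimum number of discrete state changes over the tree summed across
#' sites, treating each site's genotype strings as unordered discrete
#' states.
#'
#' @param topology A `phylo` or `multiPhylo`; tip labels must match the
#'   alignment rows.
#' @param alignment Character matrix, tips x sites (e.g. the positive
#'   control genotype alignment), or a `phyDat`.
#' @return Integer parsimony score(s), one per topology.
#' @export
fitch_score <- function(topology, alignment) {
  dat <- if (inherits(alignment, "phyDat")) alignment else
    alignment_phydat(alignment)
  labs <- if (inherits(topology, "multiPhylo")) topology[[1]]$tip.label else
    topology$tip.label
  if (!setequal(labs, names(dat)))
    stop("tip labels do not match alignment rows")
  as.integer(phangorn::parsimony(topology, dat, method = "fitch"))
}

#' Topological path-difference distance between two trees
#'
#' Euclidean distance between the vectors of pairwise leaf-to-leaf path
#' lengths, with every branch counted as one edge (topology-only variant).
#' Identical unrooted topologies have distance 0.
#'
#' @param topology_a,topology_b `phylo` objects on the same leaf set.
#' @return Non-negative numeric distance.
#' @export
path_difference <- function(topology_a, topology_b) {
  if (!setequal(topology_a$tip.label, topology_b$tip.label))
    stop("trees must share the same leaf set")
  d1 <- unit_leaf_dists(topology_a)
  d2 <- unit_leaf_dists(topology_b)[rownames(d1), colnames(d1)]
  sqrt(sum((d1 - d2)[upper.tri(d1)]^2))
}

# leaf-to-leaf path lengths in edges, on the unrooted topology
unit_leaf_dists <- function(tree) {
  tr <- ape::unroot(tree)
  tr$edge.length <- rep(1, nrow(tr$edge))
  n <- length(tr$tip.label)
  d <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tr$tip.label, tr$tip.label)
  ord <- order(rownames(d))
  d[ord, ord]
}

#' Path-difference null test of an observed topology
#'
#' Compares the path difference between an observed topology and a
#' reference topology (e.g. the physical tree) to the null distribution of
#' path differences between the reference and every possible topology on
#' the same leaves. The p-value is the fraction of the null at or below
#' the observed distance (ties counted in, conservative).
#'
#' @param observed_topology A `phylo` (e.g. a maximum-parsimony tree).
#' @param reference_topology A `phylo` on the same leaves.
#' @param topologies Optional pre-enumerated `multiPhylo` null set; all
#'   topologies are enumerated when `NULL` (requires <= 10 leaves).
#' @return List: `pd_observed`, `p_value`, `null` (numeric vector of null
#'   path differences), `n_null`.
#' @export
pd_null_test <- function(observed_topology, reference_topology,
                         topologies = NULL) {
  if (is.null(topologies))
    topologies <- enumerate_topologies(length(reference_topology$tip.label),
                                       reference_topology$tip.label)
  null <- vapply(topologies, path_difference,
                 topology_b = reference_topology, numeric(1))
  pd <- path_difference(observed_topology, reference_topology)
  list(pd_observed = pd, p_value = mean(null <= pd), null = null,
       n_null = length(null))
}

#' Maximum-likelihood scan over candidate topologies
#'
#' Scores each candidate topology under an equal-rates (Jukes-Cantor
#' style) substitution model on the alignment's observed states, with
#' per-edge branch-length optimisation, and returns the best topology.
#' Optional nonparametric bootstrap over sites gives split support
#' percentages on the best tree.
#'
#' @param alignment Character matrix (tips x sites) or `phyDat`.
#' @param topologies `multiPhylo` of candidate topologies.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Optional RNG seed for the bootstrap.
#' @return List: `log_lik` (per topology), `best_index`, `best_tree`
#'   (edge lengths in substitutions per site), `ties` (indices within
#'   1e-6 of the maximum), `support` (percent support per internal node of
#'   the best tree, `NULL` without bootstrap).
#' @export
ml_tree_scan <- function(alignment, topologies, bootstrap = 0, seed = NULL) {
  dat <- if (inherits(alignment, "phyDat")) alignment else
    alignment_phydat(alignment)
  chr <- as.character(dat)
  if (all(apply(chr, 2, function(col) length(unique(col)) == 1)))
    stop("alignment is invariant across tips; likelihood scan is degenerate")
  score_all <- function(d) {
    vapply(topologies, function(tr) {
      tr <- ape::unroot(ape::multi2di(tr))
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      fit <- phangorn::pml(tr, d)
      fit <- phangorn::optim.pml(fit, optEdge = TRUE,
                                 control = phangorn::pml.control(trace = 0,
                                                                 maxit = 10))
      fit$logLik
    }, numeric(1))
  }
  ll <- score_all(dat)
  best <- which.max(ll)
  ties <- which(ll >= max(ll) - 1e-6)
  best_tree <- ape::unroot(ape::multi2di(topologies[[best]]))
  best_tree$edge.length <- rep(0.1, nrow(best_tree$edge))
  fit <- phangorn::optim.pml(phangorn::pml(best_tree, dat), optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  support <- NULL
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- if (inherits(alignment, "phyDat")) {
      as.character(alignment)
    } else alignment
    boots <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample(ncol(m), replace = TRUE)
      db <- alignment_phydat(m[, cols, drop = FALSE])
      llb <- score_all(db)
      boots[[b]] <- topologies[[which.max(llb)]]
    }
    class(boots) <- "multiPhylo"
    cl <- ape::prop.clades(fit$tree, boots, rooted = FALSE)
    cl[is.na(cl)] <- 0
    support <- 100 * cl / bootstrap
  }
  list(log_lik = ll, best_index = best, best_tree = fit$tree, ties = ties,
       support = support)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions (splits) present in exactly one of
#' the two trees; at most `2(n-3)` for binary trees on `n` leaves.
#'
#' @param tree_a,tree_b `phylo` objects on the same leaf set.
#' @return Integer distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees must share the same leaf set")
  as.integer(phangorn::RF.dist(tree_a, tree_b))
}

#' Regression of mutation counts on physical branch lengths
#'
#' Least-squares line forced through the origin of per-branch mutation
#' counts on per-branch physical lengths in metres, across the matched
#' edges of two trees with identical topology. Reports the no-intercept
#' R-squared and the slope t-test p-value.
#'
#' @param physical_tree A [physical_tree()] (or `phylo`), lengths in
#'   metres.
#' @param mutation_tree A `phylo` of the same topology with edge lengths
#'   equal to mutation counts.
#' @return List: `slope`, `r_squared`, `p_value`, `n_edges`, `model` (the
#'   `lm` fit).
#' @export
branch_length_regression <- function(physical_tree, mutation_tree) {
  pt <- if (inherits(physical_tree, "physical_tree")) physical_tree$phylo
        else physical_tree
  mt <- mutation_tree
  if (phangorn::RF.dist(ape::unroot(pt), ape::unroot(mt)) != 0)
    stop("trees must have identical topologies")
  # edges matched by the tip set of the child clade (rooted identity, so
  # the two root edges stay distinct)
  key <- function(tr) {
    desc <- phangorn::Descendants(tr, tr$edge[, 2], type = "tips")
    vapply(desc, function(i) paste(sort(tr$tip.label[i]), collapse = ","),
           "")
  }
  kp <- key(pt); km <- key(mt)
  i <- match(kp, km)
  if (anyNA(i) || anyDuplicated(i))
    stop("could not match edges between trees; both must be rooted the same way")
  x <- pt$edge.length
  y <- mt$edge.length[i]
  if (all(y == 0)) stop("all mutation counts are zero; regression undefined")
  fit <- stats::lm(y ~ 0 + x)
  sm <- suppressWarnings(summary(fit))  # exact proportionality is fine
  list(slope = unname(stats::coef(fit)[1]), r_squared = sm$r.squared,
       p_value = sm$coefficients[1, 4], n_edges = length(x), model = fit)
}

#' Per-branch mutation counts as a tree
#'
#' Builds a copy of the physical tree whose edge lengths are the number of
#' filtered calls assigned to each branch, for the branch-length
#' correlation against physical metres.
#'
#' @param calls A `calls` data.frame (with a `branch` column) or
#'   [call_mutations()] result.
#' @param tree The [physical_tree()].
#' @return A `phylo` with counts as edge lengths.
#' @export
mutation_branch_counts <- function(calls, tree) {
  df <- if (inherits(calls, "mutation_calls")) calls$calls else calls
  et <- edge_table(tree)
  counts <- table(factor(df$branch, levels = et$edge))
  out <- tree$phylo
  out$edge.length <- as.numeric(counts)
  out
}
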