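# Phylogenetic likelihood engine ----------------------------------------------
#
# Felsenstein pruning over the physical tree on the 10-genotype state space,
# vectorised across sites. All replicate samples of a tip share the tip's
# genotype; each edge carries the per-metre mutation kernel.

row_max <- function(M) {
  m <- M[, 1]
  for (j in 2:ncol(M)) m <- pmax(m, M[, j])
  m
}

row_logsumexp <- function(M) {
  m <- row_max(M)
  bad <- !is.finite(m)
  m[bad] <- 0
  out <- m + log(rowSums(exp(M - m)))
  out[bad] <- -Inf
  out
}

# Core vectorised peel. Returns per-site quantities; `want_branch` adds the
# single-edge mutation-configuration posteriors, `detail` additionally
# returns the per-edge clade log-likelihood sums (used for allele calls).
peel_engine <- function(tree, pileup, params,
                        want_branch = TRUE, detail = FALSE) {
  ph <- tree$phylo
  n <- n_sites(pileup)
  n_tip <- length(ph$tip.label)
  rt <- replicate_table(tree)
  if (!all(rt$replicate %in% pileup$samples$replicate))
    stop("pileup is missing replicates required by the tree")

  logP <- log(base_given_genotype(params$epsilon))      # 4 x 10
  ref_i <- base_index(pileup$ref)
  logprior <- log(prior_matrix(params$theta, params$kappa))[ref_i, , drop = FALSE]
  dimnames(logprior) <- NULL

  # leaf conditional log-likelihoods: product over the tip's replicates
  leafLL <- vector("list", n_tip)
  for (k in seq_len(n_tip)) {
    tip <- ph$tip.label[k]
    L <- matrix(0, n, 10)
    for (r in tree$replicate_map[[tip]])
      L <- L + replicate_counts(pileup, r) %*% logP
    leafLL[[k]] <- L
  }

  # per-edge transition matrices (cache by branch length)
  el <- ph$edge.length
  uel <- unique(el)
  Tcache <- lapply(uel, branch_transition_matrix, params = params)
  Tm <- Tcache[match(el, uel)]

  # post-order pruning
  ord <- ape::reorder.phylo(ph, "postorder")
  n_node <- n_tip + ph$Nnode
  partial <- vector("list", n_node)
  for (k in seq_len(n_tip)) partial[[k]] <- leafLL[[k]]
  edge_of_child <- match(seq_len(n_node), ph$edge[, 2])
  for (i in seq_len(nrow(ord$edge))) {
    e <- match(paste(ord$edge[i, 1], ord$edge[i, 2]),
               paste(ph$edge[, 1], ph$edge[, 2]))
    par <- ph$edge[e, 1]; chd <- ph$edge[e, 2]
    Lc <- partial[[chd]]
    m <- row_max(Lc)
    msg <- log(pmax(exp(Lc - m) %*% t(Tm[[e]]), 0)) + m
    if (is.null(partial[[par]])) partial[[par]] <- msg
    else partial[[par]] <- partial[[par]] + msg
  }
  root <- n_tip + 1L
  log_total <- row_logsumexp(logprior + partial[[root]])

  # exact no-mutation configuration: all nodes share the root genotype,
  # every edge contributes its diagonal (no-change) probability
  S <- Reduce(`+`, leafLL)                               # N x 10
  logdiag <- Reduce(`+`, lapply(Tm, function(M) log(diag(M))))
  log_nomut <- row_logsumexp(sweep(logprior + S, 2, logdiag, `+`))
  dnp <- 1 - exp(pmin(log_nomut - log_total, 0))
  dnp <- pmin(pmax(dnp, 0), 1)

  depth <- total_depth(pileup)
  lld <- (log_total / log(10)) / pmax(1, depth)

  # root MAP genotype; ties broken toward reference-containing genotypes
  contains <- t(vapply(1:4, gt_contains, logical(10)))   # 4 x 10
  root_post <- logprior + partial[[root]] + 1e-9 * contains[ref_i, , drop = FALSE]
  root_map <- max.col(root_post, ties.method = "first")

  out <- list(log_total = unname(log_total), log_nomut = unname(log_nomut),
              dnp = unname(dnp), lld = unname(lld), depth = depth,
              root_map = GT_NAMES[root_map],
              root_het = gt_is_het()[root_map])

  if (want_branch || detail) {
    # clade leaf-likelihood sums below each edge (post-order accumulation)
    Bnode <- vector("list", n_node)
    for (k in seq_len(n_tip)) Bnode[[k]] <- leafLL[[k]]
    for (i in seq_len(nrow(ord$edge))) {
      par <- ord$edge[i, 1]; chd <- ord$edge[i, 2]
      if (is.null(Bnode[[par]])) Bnode[[par]] <- Bnode[[chd]]
      else Bnode[[par]] <- Bnode[[par]] + Bnode[[chd]]
    }
    et <- edge_table(tree)
    n_edge <- nrow(ph$edge)
    logLe <- matrix(-Inf, n, n_edge)
    for (e in seq_len(n_edge)) {
      Toff <- Tm[[e]]; diag(Toff) <- 0
      if (all(Toff == 0)) next
      B <- Bnode[[ph$edge[e, 2]]]
      A <- logprior + (S - B)
      mA <- row_max(A); mB <- row_max(B)
      M2 <- exp(B - mB) %*% t(Toff)                      # N x 10, index g
      logLe[, e] <- log(pmax(rowSums(exp(A - mA) * M2), 0)) + mA + mB
    }
    log_nomut_id <- row_logsumexp(logprior + S)  # identity on every edge
    denom <- row_logsumexp(cbind(log_nomut_id, logLe))
    post <- exp(logLe - denom)
    colnames(post) <- et$edge
    best <- max.col(post, ties.method = "first")
    out$branch_post <- post
    out$branch <- et$edge[best]
    out$branch_edge_idx <- best
    if (detail) {
      out$clade_sums <- lapply(seq_len(n_edge),
                               function(e) Bnode[[ph$edge[e, 2]]])
      out$logprior <- logprior
      out$S <- S
      out$Tm <- Tm
    }
  }
  out
}

#' Score one site under the phylogenetic mutation model
#'
#' Runs the pruning algorithm at a single site and reports the full site
#' score: total log-likelihood, the de novo mutation probability (DNP,
#' posterior probability that at least one somatic mutation occurred
#' anywhere on the tree), per-branch mutation posteriors from single-edge
#' mutation configurations, the scaled data log-likelihood (LLD,
#' `log10(likelihood)` per read), and maximum a posteriori genotypes for
#' every node.
#'
#' @param tree A [physical_tree()].
#' @param pileup A [site_pileup()] (its `site` row is used).
#' @param params A [model_params()].
#' @param site Site index within `pileup` (default 1).
#' @return An object of class `site_score`: list with `log_likelihood`,
#'   `dnp`, `lld`, `branch_posteriors` (named by edge), `branch` (edge with
#'   maximal posterior), `map_genotypes` (named by node label), `root_map`.
#' @export
site_peel <- function(tree, pileup, params, site = 1) {
  one <- subset_pileup(pileup, site)
  eng <- peel_engine(tree, one, params, want_branch = TRUE)
  ph <- tree$phylo
  n_tip <- length(ph$tip.label)
  n_node <- n_tip + ph$Nnode
  # per-node MAP genotype from clamped marginals
  map <- character(n_node)
  for (v in seq_len(n_node)) {
    lv <- vapply(1:10, function(g) clamped_loglik(tree, one, params, v, g),
                 numeric(1))
    bonus <- 1e-9 * gt_contains(base_index(one$ref))
    map[v] <- GT_NAMES[which.max(lv + bonus)]
  }
  names(map) <- node_label(ph, seq_len(n_node))
  structure(list(
    chrom = one$chrom, pos = one$pos, ref = one$ref,
    log_likelihood = eng$log_total, dnp = eng$dnp, lld = eng$lld,
    branch_posteriors = stats::setNames(as.numeric(eng$branch_post),
                                        colnames(eng$branch_post)),
    branch = eng$branch, map_genotypes = map, root_map = eng$root_map,
    depth = eng$depth), class = "site_score")
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("site_score %s:%d ref %s  depth %d\n", x$chrom, x$pos, x$ref,
              x$depth))
  cat(sprintf("  logL %.3f  DNP %.6g  LLD %.4f  branch %s\n",
              x$log_likelihood, x$dnp, x$lld, x$branch))
  invisible(x)
}

# log-likelihood with node v clamped to genotype g (single-site recursion)
clamped_loglik <- function(tree, pileup1, params, v, g) {
  ph <- tree$phylo
  n_tip <- length(ph$tip.label)
  logP <- log(base_given_genotype(params$epsilon))
  leafL <- lapply(seq_len(n_tip), function(k) {
    L <- numeric(10)
    for (r in tree$replicate_map[[ph$tip.label[k]]])
      L <- L + as.numeric(replicate_counts(pileup1, r) %*% logP)
    L
  })
  Tm <- lapply(ph$edge.length, branch_transition_matrix, params = params)
  down <- function(node) {
    kids <- which(ph$edge[, 1] == node)
    L <- if (node <= n_tip) leafL[[node]] else numeric(10)
    for (e in kids) {
      Lc <- down(ph$edge[e, 2])
      m <- max(Lc)
      L <- L + log(as.numeric(Tm[[e]] %*% exp(Lc - m))) + m
    }
    if (node == v) L[-g] <- -Inf
    L
  }
  root <- n_tip + 1L
  pr <- log(genotype_prior(pileup1$ref, params))
  x <- pr + down(root)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Parameter fitting ------------------------------------------------------------

#' Fit model parameters by maximum likelihood on neutral sites
#'
#' Maximises the summed per-site log-likelihood of the pruning model over
#' `(theta, epsilon, lam)` by the Nelder-Mead simplex (derivative-free), on
#' transformed scales (logit for `theta`, scaled logit for `epsilon`, log
#' for `lam`). `kappa` is fixed by default; pass `fit_kappa = TRUE` to fit
#' it too. Intended for putatively neutral sites such as 3-fold degenerate
#' positions; at least a few hundred sites are recommended.
#'
#' @param pileup A [site_pileup()] of neutral sites.
#' @param tree A [physical_tree()].
#' @param init A [model_params()] with starting values.
#' @param kappa Fixed transition/transversion ratio (ignored if
#'   `fit_kappa`).
#' @param fit_kappa Also fit `kappa` (log scale).
#' @param control Passed to [stats::optim()] (`maxit` default 500).
#' @return List with `params` ([model_params()]), `log_lik`, `convergence`
#'   (0 = converged), `counts` (optimizer evaluations).
#' @export
fit_params <- function(pileup, tree,
                       init = model_params(theta = 0.005, epsilon = 0.01,
                                           lam = 1e-4),
                       kappa = 2, fit_kappa = FALSE,
                       control = list(maxit = 500)) {
  if (n_sites(pileup) < 100)
    warning("fewer than 100 sites; parameter estimates will be unstable")
  pack <- function(p) {
    out <- c(stats::qlogis(p$theta), stats::qlogis(p$epsilon / 0.75),
             log(p$lam))
    if (fit_kappa) out <- c(out, log(p$kappa))
    out
  }
  unpack <- function(x) {
    model_params(theta = stats::plogis(x[1]),
                 epsilon = 0.75 * stats::plogis(x[2]),
                 lam = exp(x[3]),
                 kappa = if (fit_kappa) exp(x[4]) else kappa)
  }
  nll <- function(x) {
    p <- unpack(x)
    eng <- peel_engine(tree, pileup, p, want_branch = FALSE)
    -sum(eng$log_total)
  }
  opt <- stats::optim(pack(init), nll, method = "Nelder-Mead",
                      control = control)
  list(params = unpack(opt$par), log_lik = -opt$value,
       convergence = opt$convergence, counts = opt$counts)
}

# Mutation calling -------------------------------------------------------------

#' Default calling and filtering thresholds
#'
#' @param dnp Minimum de novo mutation probability for a candidate call.
#' @param lld Minimum scaled data log-likelihood; calls below are filtered.
#' @return Named list.
#' @export
call_thresholds <- function(dnp = 0.99999, lld = -5) {
  list(dnp = dnp, lld = lld)
}

#' Call somatic mutations and heterozygous sites on a physical tree
#'
#' Scores sites under the phylogenetic mutation model and reports (i)
#' candidate somatic mutations — sites whose DNP reaches `thresholds$dnp`,
#' with the maximal-posterior branch as the call's branch assignment — and
#' (ii) heterozygous sites (MAP root genotype heterozygous, no mutation
#' signal), for downstream phasing.
#'
#' For speed, sites without at least `min_alt` reads of one non-reference
#' base in some replicate are screened out before exact scoring (such sites
#' cannot approach production DNP thresholds). The screen is disabled when
#' `thresholds$dnp == 0` or `prescreen = FALSE`, in which case every site
#' is scored.
#'
#' @param tree A [physical_tree()].
#' @param pileup A [site_pileup()].
#' @param params A [model_params()] (fitted or user-supplied).
#' @param thresholds See [call_thresholds()].
#' @param prescreen Apply the cheap pre-screen before exact scoring.
#' @param min_alt Pre-screen minimum non-reference read count.
#' @param chunk_size Sites scored per block (memory control).
#' @return List of class `mutation_calls`: `calls` (data.frame: chrom, pos,
#'   ref, alt, root_genotype, mut_genotype, branch, dnp, lld, log_lik,
#'   depth), `het_sites` (data.frame: chrom, pos, ref, genotype, depth),
#'   `n_scored`, `thresholds`.
#' @export
call_mutations <- function(tree, pileup, params,
                           thresholds = call_thresholds(),
                           prescreen = TRUE, min_alt = 2,
                           chunk_size = 100000) {
  if (thresholds$dnp <= 0) prescreen <- FALSE
  idx <- if (prescreen) prescreen_sites(pileup, min_alt) else
    seq_len(n_sites(pileup))
  cand_rows <- list(); het_rows <- list()
  for (start in seq(1, max(length(idx), 1), by = chunk_size)) {
    if (length(idx) == 0) break
    block <- idx[start:min(start + chunk_size - 1, length(idx))]
    sub <- subset_pileup(pileup, block)
    eng <- peel_engine(tree, sub, params, want_branch = TRUE)
    is_cand <- eng$dnp >= thresholds$dnp
    is_het <- eng$root_het & !is_cand
    if (any(is_cand)) {
      alt <- call_alt_alleles(tree, sub, params, which(is_cand), eng)
      cand_rows[[length(cand_rows) + 1]] <- data.frame(
        chrom = sub$chrom[is_cand], pos = sub$pos[is_cand],
        ref = sub$ref[is_cand], alt = alt$alt,
        root_genotype = eng$root_map[is_cand],
        mut_genotype = alt$mut_genotype,
        branch = eng$branch[is_cand], dnp = eng$dnp[is_cand],
        lld = eng$lld[is_cand], log_lik = eng$log_total[is_cand],
        depth = eng$depth[is_cand], stringsAsFactors = FALSE)
    }
    if (any(is_het))
      het_rows[[length(het_rows) + 1]] <- data.frame(
        chrom = sub$chrom[is_het], pos = sub$pos[is_het],
        ref = sub$ref[is_het], genotype = eng$root_map[is_het],
        dnp = eng$dnp[is_het], depth = eng$depth[is_het],
        stringsAsFactors = FALSE)
  }
  empty_calls <- data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            root_genotype = character(),
                            mut_genotype = character(), branch = character(),
                            dnp = numeric(), lld = numeric(),
                            log_lik = numeric(), depth = integer(),
                            stringsAsFactors = FALSE)
  empty_het <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), genotype = character(),
                          dnp = numeric(), depth = integer(),
                          stringsAsFactors = FALSE)
  calls <- if (length(cand_rows)) do.call(rbind, cand_rows) else empty_calls
  het <- if (length(het_rows)) do.call(rbind, het_rows) else empty_het
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, het_sites = het, n_scored = length(idx),
                 thresholds = thresholds), class = "mutation_calls")
}

#' @export
print.mutation_calls <- function(x, ...) {
  cat(sprintf("mutation_calls: %d candidates, %d heterozygous sites (%d sites scored)\n",
              nrow(x$calls), nrow(x$het_sites), x$n_scored))
  invisible(x)
}

# MAP mutant genotype / alt allele for candidate sites: maximise the
# single-edge configuration term over the post-mutation genotype h on the
# assigned branch
call_alt_alleles <- function(tree, pileup, params, cand, eng) {
  det <- peel_engine(tree, subset_pileup(pileup, cand), params,
                     want_branch = TRUE, detail = TRUE)
  nc <- length(cand)
  mutg <- character(nc); alt <- character(nc)
  for (i in seq_len(nc)) {
    e <- det$branch_edge_idx[i]
    Toff <- det$Tm[[e]]; diag(Toff) <- 0
    B <- det$clade_sums[[e]][i, ]
    A <- det$logprior[i, ] + (det$S[i, ] - B)
    wg <- exp(A - max(A))
    term <- log(as.numeric(wg %*% Toff)) + B
    h <- which.max(term)
    mutg[i] <- GT_NAMES[h]
    g0 <- genotype_index(eng$root_map[cand[i]])
    newa <- setdiff(GT_PAIRS[h, ], GT_PAIRS[g0, ])
    alt[i] <- if (length(newa)) BASES[newa[1]] else
      BASES[setdiff(GT_PAIRS[h, ], base_index(pileup$ref[cand[i]]))[1]]
    if (is.na(alt[i])) alt[i] <- BASES[GT_PAIRS[h, 1]]
  }
  list(mut_genotype = mutg, alt = alt)
}
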