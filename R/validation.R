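# False-negative and false-discovery estimation --------------------------------

#' Plan in silico mutation spikes across the branches of the tree
#'
#' Randomly draws sites (without replacement) and assigns `n_per_branch` of
#' them to each branch of the physical tree. For each site the root
#' genotype is estimated by the caller's root MAP genotype; a source allele
#' of that genotype is picked and the mutant allele drawn from the other
#' bases with transition weight `kappa` versus 1 per transversion.
#'
#' @param tree A [physical_tree()].
#' @param pileup A [site_pileup()] covering the candidate sites.
#' @param params A [model_params()] (used for root genotyping and the
#'   transition weighting).
#' @param n_per_branch Spikes per branch (the study design used 1000 on
#'   each of 14 branches).
#' @param seed RNG seed; the plan is reproducible given the seed.
#' @param min_spacing Minimum distance in nucleotides between chosen sites
#'   (0 = unconstrained uniform draws).
#' @param exclude `data.frame` with `chrom`, `pos` of sites to avoid
#'   (e.g. known variants), or `NULL`.
#' @return `data.frame` of class `spike_plan`: `chrom`, `pos`, `ref`,
#'   `edge`, `root_genotype`, `source_allele`, `mutant_allele`.
#' @export
make_spike_plan <- function(tree, pileup, params, n_per_branch,
                            seed = NULL, min_spacing = 0, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  et <- edge_table(tree)
  n_needed <- n_per_branch * nrow(et)
  elig <- seq_len(n_sites(pileup))
  if (!is.null(exclude) && nrow(exclude))
    elig <- elig[!paste(pileup$chrom[elig], pileup$pos[elig]) %in%
                   paste(exclude$chrom, exclude$pos)]
  if (min_spacing > 0) {
    ord <- sample(elig)
    chosen <- integer(0)
    occupied <- data.frame(chrom = character(), pos = integer())
    for (i in ord) {
      if (length(chosen) >= n_needed) break
      near <- abs(pileup$pos[chosen] - pileup$pos[i]) < min_spacing &
        pileup$chrom[chosen] == pileup$chrom[i]
      if (!any(near)) chosen <- c(chosen, i)
    }
    sites <- chosen
  } else {
    if (length(elig) < n_needed)
      stop(sprintf("not enough eligible sites: need %d, found %d",
                   n_needed, length(elig)))
    sites <- sample(elig, n_needed)
  }
  if (length(sites) < n_needed)
    stop(sprintf("not enough eligible sites: need %d, found %d",
                 n_needed, length(sites)))
  sites <- sites[seq_len(n_needed)]
  edge <- rep(et$edge, each = n_per_branch)

  sub <- subset_pileup(pileup, sites)
  eng <- peel_engine(tree, sub, params, want_branch = FALSE)
  rootg <- eng$root_map
  gp <- GT_PAIRS[genotype_index(rootg), , drop = FALSE]
  pick2 <- stats::runif(length(sites)) < 0.5
  src <- ifelse(pick2, gp[, 2], gp[, 1])
  mut <- vapply(src, function(a) {
    w <- rep(1, 4); w[a] <- 0
    w[base_index(TRANSITION[a])] <- params$kappa
    sample(1:4, 1, prob = w)
  }, 1L)
  out <- data.frame(chrom = sub$chrom, pos = sub$pos, ref = sub$ref,
                    edge = edge, root_genotype = rootg,
                    source_allele = BASES[src], mutant_allele = BASES[mut],
                    stringsAsFactors = FALSE)
  class(out) <- c("spike_plan", "data.frame")
  out
}

#' Apply a spike plan to pileup counts
#'
#' Edits the pileups of every replicate of every tip descending from each
#' spike's target branch. At sites with a homozygous root genotype, a
#' binomially distributed number (p = 0.5) of the source-allele reads is
#' flipped to the mutant allele in each affected replicate; at heterozygous
#' sites every source-allele read is flipped. Reads of unaffected samples
#' are untouched.
#'
#' @param pileup A [site_pileup()].
#' @param plan A [make_spike_plan()] result.
#' @param tree The [physical_tree()].
#' @param seed RNG seed for the binomial draws.
#' @return List: `pileup` (edited copy), `plan` (with added
#'   `n_reads_edited` and `covered` columns; a spike with zero covered
#'   reads in every affected sample stays in the plan and the recovery
#'   denominator).
#' @export
spike_pileups <- function(pileup, plan, tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- pileup$counts
  rt <- replicate_table(tree)
  et <- edge_table(tree)
  desc <- edge_descendant_tips(tree)
  names(desc) <- et$edge
  site_of <- match(paste(plan$chrom, plan$pos),
                   paste(pileup$chrom, pileup$pos))
  if (anyNA(site_of)) stop("spike plan contains sites absent from the pileup")
  edited <- integer(nrow(plan)); covered <- logical(nrow(plan))
  het <- substr(plan$root_genotype, 1, 1) != substr(plan$root_genotype, 2, 2)
  for (k in seq_len(nrow(plan))) {
    i <- site_of[k]
    src <- base_index(plan$source_allele[k])
    mut <- base_index(plan$mutant_allele[k])
    reps <- rt$replicate[rt$leaf %in% desc[[plan$edge[k]]]]
    tot <- 0L
    for (r in reps) {
      ci <- match(r, pileup$samples$replicate)
      cs <- 4L * (ci - 1L)
      nsrc <- counts[i, cs + src]
      nmove <- if (het[k]) nsrc else stats::rbinom(1, nsrc, 0.5)
      counts[i, cs + src] <- counts[i, cs + src] - nmove
      counts[i, cs + mut] <- counts[i, cs + mut] + nmove
      tot <- tot + nmove
      covered[k] <- covered[k] || sum(counts[i, cs + 1:4]) > 0
    }
    edited[k] <- tot
  }
  plan$n_reads_edited <- edited
  plan$covered <- covered
  out <- pileup
  out$counts <- counts
  list(pileup = out, plan = plan)
}

#' Estimate the false-negative rate from spiked data
#'
#' Re-runs the calling pipeline (scoring plus the de novo filter cascade)
#' on spiked pileups and reports how many planned spikes were recovered. A
#' spike counts as recovered when a surviving call occurs at its site and
#' (by default) on its target branch; attempted spikes with no coverage
#' stay in the denominator.
#'
#' @param tree A [physical_tree()].
#' @param spiked_pileup The edited [site_pileup()] from [spike_pileups()].
#' @param plan The (annotated) spike plan.
#' @param params A [model_params()].
#' @param thresholds See [call_thresholds()].
#' @param blocks Haplotype blocks passed to [denovo_filter()] (`NULL`
#'   skips the block filter).
#' @param match `"branch"` (default: site and exact branch must match) or
#'   `"site"` (site only).
#' @return List: `n_spiked`, `n_recovered`, `recovery_rate`,
#'   `false_negative_rate`, `per_branch` (data.frame), `calls` (surviving
#'   calls).
#' @export
estimate_fnr <- function(tree, spiked_pileup, plan, params,
                         thresholds = call_thresholds(), blocks = NULL,
                         match = c("branch", "site")) {
  match <- match.arg(match)
  mc <- call_mutations(tree, spiked_pileup, params, thresholds)
  filt <- denovo_filter(mc, blocks = blocks, min_lld = thresholds$lld,
                        min_dnp = thresholds$dnp)
  calls <- filt$calls
  callkey <- paste(calls$chrom, calls$pos)
  plankey <- paste(plan$chrom, plan$pos)
  hit <- plankey %in% callkey
  if (match == "branch") {
    cb <- calls$branch[base::match(plankey, callkey)]
    hit <- hit & !is.na(cb) & cb == plan$edge
  }
  per_branch <- stats::aggregate(hit, by = list(edge = plan$edge), FUN = mean)
  names(per_branch)[2] <- "recovery_rate"
  r <- mean(hit)
  list(n_spiked = nrow(plan), n_recovered = sum(hit), recovery_rate = r,
       false_negative_rate = 1 - r, per_branch = per_branch, calls = calls)
}

#' Shuffle tip labels to maximal Robinson-Foulds distance
#'
#' Permutes the tip labels of a binary tree until the permuted tree shares
#' no non-trivial splits with the original, i.e. reaches the maximal RF
#' distance `2(n-3)`. Used to scramble all phylogenetic information while
#' preserving the tree shape.
#'
#' @param tree A binary `phylo`.
#' @param seed RNG seed.
#' @param max_tries Attempts before giving up.
#' @return The permuted `phylo`, with attribute `tries`.
#' @export
shuffle_maximal_rf <- function(tree, seed = NULL, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::multi2di(tree)
  n <- length(tr$tip.label)
  target <- 2 * (n - 3)
  for (k in seq_len(max_tries)) {
    perm <- tr
    perm$tip.label <- sample(tr$tip.label)
    if (phangorn::RF.dist(perm, tr) == target) {
      attr(perm, "tries") <- k
      return(perm)
    }
  }
  stop(sprintf("no label shuffle reached RF %d in %d tries", target,
               max_tries))
}

# a replicate_map permutation whose induced replicate tree shares no splits
# with the original replicate tree
permute_replicate_map <- function(tree, max_tries = 1000) {
  rt <- replicate_table(tree)
  rtree <- replicate_tree(tree)
  target <- 2 * (length(rtree$tip.label) - 3)
  for (k in seq_len(max_tries)) {
    shuffled <- sample(rt$replicate)
    perm <- rtree
    perm$tip.label <- shuffled[match(rtree$tip.label, rt$replicate)]
    if (phangorn::RF.dist(perm, rtree) == target)
      return(split(shuffled, rt$leaf)[names(tree$replicate_map)])
  }
  stop("no replicate permutation reached maximal RF distance")
}

#' Estimate the false-discovery rate by replicate-label permutation
#'
#' Repeatedly scrambles which replicate samples belong to which branch tip
#' (requiring the induced replicate tree to share no splits with the
#' original, i.e. maximal RF distance), re-runs the full calling pipeline
#' under the scrambled assignment while ignoring previously identified
#' variable sites, and counts every surviving call as a false positive.
#'
#' @param tree A [physical_tree()].
#' @param pileup The (unspiked) [site_pileup()].
#' @param params A [model_params()].
#' @param known_variants `data.frame` with `chrom`, `pos` of previously
#'   called variable sites (somatic candidates and heterozygous sites) to
#'   ignore.
#' @param n_perm Number of permutations (the study design used 100).
#' @param thresholds See [call_thresholds()].
#' @param blocks Optional haplotype blocks for [denovo_filter()].
#' @param n_real_calls Number of calls in the real (unpermuted) run; used
#'   for the FDR denominator. `NA` leaves `false_discovery_rate` as `NA`.
#' @param seed RNG seed.
#' @return List: `n_permutations`, `n_false_calls`, `fp_per_experiment`,
#'   `false_discovery_rate`, `per_permutation` (integer vector).
#' @export
estimate_fdr <- function(tree, pileup, params, known_variants,
                         n_perm = 100, thresholds = call_thresholds(),
                         blocks = NULL, n_real_calls = NA, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  keep <- !(paste(pileup$chrom, pileup$pos) %in%
              paste(known_variants$chrom, known_variants$pos))
  masked <- subset_pileup(pileup, which(keep))
  per_perm <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pmap <- permute_replicate_map(tree)
    ptree <- tree
    ptree$replicate_map <- pmap
    mc <- call_mutations(ptree, masked, params, thresholds)
    filt <- denovo_filter(mc, blocks = blocks, min_lld = thresholds$lld,
                          min_dnp = thresholds$dnp)
    per_perm[b] <- nrow(filt$calls)
  }
  f <- sum(per_perm) / n_perm
  list(n_permutations = n_perm, n_false_calls = sum(per_perm),
       fp_per_experiment = f,
       false_discovery_rate = if (is.na(n_real_calls)) NA else
         f / n_real_calls,
       per_permutation = per_perm)
}
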