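# Site filters: positive-control cascade and de novo call cascade -------------

#' Phred-scaled excess-heterozygosity statistic
#'
#' One-sided exact test for an excess of heterozygous samples under
#' Hardy-Weinberg equilibrium, conditioned on the observed allele counts
#' (Levene's exact distribution): the phred-scaled probability of observing
#' at least the seen number of heterozygotes. High values flag genotyping
#' artefacts such as uniformly heterozygous sites miscalled as variable.
#'
#' @param n_hom_ref,n_het,n_hom_alt Counts of samples by genotype class.
#' @return Non-negative phred score, `-10*log10(p)`; 0 when no
#'   heterozygotes are observed.
#' @export
excess_het_phred <- function(n_hom_ref, n_het, n_hom_alt) {
  N <- n_hom_ref + n_het + n_hom_alt
  if (N == 0) stop("no genotyped samples")
  nA <- 2 * n_hom_ref + n_het
  nB <- 2 * n_hom_alt + n_het
  if (nA == 0 || nB == 0) return(0)  # monomorphic: p(het >= 0 obs het) = 1
  hets <- seq(min(nA, nB), if (nA %% 2 == 0) 0 else 1, by = -2)
  hets <- sort(hets)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(N) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * N)
  }, numeric(1))
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  p_upper <- sum(p[hets >= n_het])
  max(0, -10 * log10(max(p_upper, .Machine$double.xmin)))
}

# Genotype records for the positive control ------------------------------------

#' Per-replicate genotype calls at candidate variable sites
#'
#' Calls the MAP genotype of every replicate sample independently (read
#' likelihood times the reference-conditioned genotype prior), at sites
#' passing the cheap variability pre-screen. Replicates with zero coverage
#' at a site are recorded as missing. This emulates the per-sample
#' genotyping step feeding the positive-control filters.
#'
#' @param tree A [physical_tree()].
#' @param pileup A [site_pileup()].
#' @param params A [model_params()].
#' @param min_alt Pre-screen threshold (see [call_mutations()]).
#' @param chunk_size Sites per processing block.
#' @return Object of class `site_records`: `sites` (data.frame chrom, pos,
#'   ref, total_depth), `genotypes` (character matrix sites x replicates,
#'   `NA` for missing), `samples` (replicate table).
#' @export
genotype_records <- function(tree, pileup, params, min_alt = 2,
                             chunk_size = 200000) {
  idx <- prescreen_sites(pileup, min_alt)
  sub <- subset_pileup(pileup, idx)
  n <- n_sites(sub)
  rt <- replicate_table(tree)
  logP <- log(base_given_genotype(params$epsilon))
  logprior <- log(prior_matrix(params$theta,
                               params$kappa))[base_index(sub$ref), ,
                                              drop = FALSE]
  contains <- t(vapply(1:4, gt_contains, logical(10)))
  bonus <- 1e-9 * contains[base_index(sub$ref), , drop = FALSE]
  G <- matrix(NA_character_, n, nrow(rt),
              dimnames = list(NULL, rt$replicate))
  for (r in rt$replicate) {
    cm <- replicate_counts(sub, r)
    post <- cm %*% logP + logprior + bonus
    g <- GT_NAMES[max.col(post, ties.method = "first")]
    g[rowSums(cm) == 0] <- NA_character_
    G[, r] <- g
  }
  structure(list(
    sites = data.frame(chrom = sub$chrom, pos = sub$pos, ref = sub$ref,
                       total_depth = total_depth(sub),
                       stringsAsFactors = FALSE),
    genotypes = G, samples = rt), class = "site_records")
}

#' @export
print.site_records <- function(x, ...) {
  cat(sprintf("site_records: %d sites x %d replicate samples\n",
              nrow(x$sites), ncol(x$genotypes)))
  invisible(x)
}

# genotype allele membership helpers
gt_alleles <- function(g) strsplit(g, "")[[1]]

#' Positive-control site filters
#'
#' Applies the conservative filter cascade for the phylogenetic positive
#' control, retaining sites where: (i) genotype calls are identical within
#' all replicates of each branch tip; (ii) at least one tip differs from
#' the others; (iii) the site is biallelic (a single non-reference allele);
#' (iv) total depth across samples is at most `max_depth`; (v) the
#' excess-heterozygosity phred score is at most `max_excess_het`; and (vi)
#' the site is outside the repeat mask. Sites with a missing replicate
#' genotype are dropped and counted separately.
#'
#' @param records A [genotype_records()] object.
#' @param tree The [physical_tree()] (defines replicate grouping).
#' @param repeat_mask `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) or `NULL` to skip filter (vi).
#' @param max_depth Depth cap, default 500.
#' @param max_excess_het ExcessHet cap, default 40.
#' @return List: `records` (surviving `site_records`), `alignment`
#'   (character matrix, tips x surviving sites, the per-tip genotypes),
#'   `attrition` (data.frame: filter, n_failed, n_failed_only), `n_input`,
#'   `n_missing`, `n_survivors`, `n_multi_fail`.
#' @export
positive_control_filter <- function(records, tree, repeat_mask = NULL,
                                    max_depth = 500, max_excess_het = 40) {
  G <- records$genotypes
  n <- nrow(records$sites)
  rt <- replicate_table(tree)
  leaves <- unique(rt$leaf)
  missing <- apply(G, 1, anyNA)

  # per-leaf consensus (NA when replicates disagree)
  leafG <- matrix(NA_character_, n, length(leaves),
                  dimnames = list(NULL, leaves))
  concord <- rep(TRUE, n)
  for (l in leaves) {
    cols <- rt$replicate[rt$leaf == l]
    sub <- G[, cols, drop = FALSE]
    same <- rowSums(sub == sub[, 1]) == length(cols)
    same[is.na(same)] <- FALSE
    concord <- concord & same
    leafG[, l] <- ifelse(same, sub[, 1], NA_character_)
  }

  varies <- vapply(seq_len(n), function(i) {
    g <- leafG[i, ]; g <- g[!is.na(g)]
    length(unique(g)) >= 2
  }, logical(1))

  biallelic <- vapply(seq_len(n), function(i) {
    g <- leafG[i, ]; g <- g[!is.na(g)]
    if (!length(g)) return(FALSE)
    al <- unique(unlist(strsplit(g, "")))
    length(setdiff(al, records$sites$ref[i])) == 1
  }, logical(1))

  depth_ok <- records$sites$total_depth <= max_depth

  eh <- vapply(seq_len(n), function(i) {
    g <- G[i, ]; g <- g[!is.na(g)]
    if (!length(g)) return(0)
    het <- substr(g, 1, 1) != substr(g, 2, 2)
    homref <- !het & substr(g, 1, 1) == records$sites$ref[i]
    excess_het_phred(sum(homref), sum(het), sum(!het & !homref))
  }, numeric(1))
  eh_ok <- eh <= max_excess_het

  rep_ok <- if (is.null(repeat_mask)) rep(TRUE, n) else
    !in_mask(records$sites$chrom, records$sites$pos, repeat_mask)

  fails <- cbind(replicate_concordance = !concord,
                 tip_varies = !varies,
                 biallelic = !biallelic,
                 depth = !depth_ok,
                 excess_het = !eh_ok,
                 repeat_region = !rep_ok)
  fails[missing, ] <- FALSE  # missing counted separately
  keep <- !missing & rowSums(fails) == 0
  nf <- rowSums(fails)
  attrition <- data.frame(
    filter = colnames(fails),
    n_failed = colSums(fails),
    n_failed_only = colSums(fails & nf == 1),
    row.names = NULL, stringsAsFactors = FALSE)

  surv <- structure(list(
    sites = records$sites[keep, , drop = FALSE],
    genotypes = records$genotypes[keep, , drop = FALSE],
    samples = records$samples), class = "site_records")
  alignment <- t(leafG[keep, , drop = FALSE])
  colnames(alignment) <- NULL
  list(records = surv, alignment = alignment, attrition = attrition,
       n_input = n, n_missing = sum(missing), n_survivors = sum(keep),
       n_multi_fail = sum(nf > 1))
}

# is each (chrom, pos) inside a 1-based inclusive mask interval?
in_mask <- function(chrom, pos, mask) {
  out <- rep(FALSE, length(pos))
  for (ch in unique(mask$chrom)) {
    m <- mask[mask$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    ord <- order(m$start)
    starts <- m$start[ord]; ends <- m$end[ord]
    j <- findInterval(pos[sel], starts)
    out[sel] <- j >= 1 & pos[sel] <= ends[pmax(j, 1)]
  }
  out
}

# Haplotype blocks --------------------------------------------------------------

#' Build haplotype blocks from read-connected heterozygous sites
#'
#' Union-find over heterozygous sites that share a sequencing fragment: two
#' het sites supported by the same read pair are phased into the same
#' block; connectivity is transitive. The block span runs from its lowest
#' to highest member position.
#'
#' @param het_sites `data.frame` with `chrom` and `pos` of heterozygous
#'   sites.
#' @param fragments `data.frame` with `fragment` (read/pair identifier),
#'   `chrom`, `pos` linking fragments to het sites they cover.
#' @return `data.frame` of blocks: `block`, `chrom`, `start`, `end`,
#'   `size` (`end - start + 1`), `n_sites`.
#' @export
build_blocks <- function(het_sites, fragments = NULL) {
  key <- paste(het_sites$chrom, het_sites$pos)
  n <- length(key)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(fragments) && nrow(fragments)) {
    fkey <- paste(fragments$chrom, fragments$pos)
    idx <- match(fkey, key)
    ok <- !is.na(idx)
    for (grp in split(idx[ok], fragments$fragment[ok])) {
      grp <- unique(grp)
      if (length(grp) < 2) next
      r <- find(grp[1])
      for (j in grp[-1]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  agg <- split(seq_len(n), root)
  blocks <- do.call(rbind, lapply(seq_along(agg), function(b) {
    i <- agg[[b]]
    data.frame(block = b, chrom = het_sites$chrom[i[1]],
               start = min(het_sites$pos[i]), end = max(het_sites$pos[i]),
               n_sites = length(i), stringsAsFactors = FALSE)
  }))
  blocks$size <- blocks$end - blocks$start + 1
  rownames(blocks) <- NULL
  blocks[order(blocks$chrom, blocks$start),
         c("block", "chrom", "start", "end", "size", "n_sites")]
}

# De novo call filters -----------------------------------------------------------

#' Filter de novo mutation candidates
#'
#' Removes candidate calls that (i) sit on a haplotype block spanning fewer
#' than `min_block` nucleotides (calls outside any block count as block
#' size 0), (ii) lie within `proximity` nucleotides of another candidate
#' (both members of a close pair are removed; the rule is evaluated on the
#' full input candidate set), (iii) have `lld < min_lld`, or (iv) have
#' `dnp < min_dnp`. A call at exactly the DNP threshold is kept.
#'
#' @param calls A [call_mutations()] result or its `calls` data.frame.
#' @param blocks Haplotype blocks from [build_blocks()], or `NULL` to skip
#'   the block filter.
#' @param min_block Minimum block span in nucleotides (default 500).
#' @param proximity Exclusion distance: calls with `|pos_i - pos_j| <
#'   proximity` are removed (default 1000; a pair exactly `proximity`
#'   apart is kept).
#' @param min_lld,min_dnp Score thresholds (defaults -5 and 0.99999).
#' @return List: `calls` (surviving data.frame), `attrition` (per-filter
#'   fail counts), `n_input`, `n_survivors`, `n_multi_fail`.
#' @export
denovo_filter <- function(calls, blocks = NULL, min_block = 500,
                          proximity = 1000, min_lld = -5,
                          min_dnp = 0.99999) {
  df <- if (inherits(calls, "mutation_calls")) calls$calls else calls
  n <- nrow(df)
  if (n == 0) {
    return(list(calls = df,
                attrition = data.frame(filter = c("haplotype_block",
                                                  "proximity", "lld", "dnp"),
                                       n_failed = rep(0L, 4),
                                       n_failed_only = rep(0L, 4)),
                n_input = 0L, n_survivors = 0L, n_multi_fail = 0L))
  }
  block_fail <- rep(FALSE, n)
  if (!is.null(blocks)) {
    bsize <- vapply(seq_len(n), function(i) {
      b <- blocks[blocks$chrom == df$chrom[i] &
                  blocks$start <= df$pos[i] & blocks$end >= df$pos[i], ]
      if (nrow(b)) max(b$size) else 0L
    }, numeric(1))
    block_fail <- bsize < min_block
  }
  prox_fail <- vapply(seq_len(n), function(i) {
    d <- abs(df$pos - df$pos[i])
    any(d > 0 & d < proximity & df$chrom == df$chrom[i])
  }, logical(1))
  lld_fail <- df$lld < min_lld
  dnp_fail <- df$dnp < min_dnp
  fails <- cbind(haplotype_block = block_fail, proximity = prox_fail,
                 lld = lld_fail, dnp = dnp_fail)
  nf <- rowSums(fails)
  keep <- nf == 0
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out,
       attrition = data.frame(filter = colnames(fails),
                              n_failed = colSums(fails),
                              n_failed_only = colSums(fails & nf == 1),
                              row.names = NULL, stringsAsFactors = FALSE),
       n_input = n, n_survivors = sum(keep), n_multi_fail = sum(nf > 1))
}
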