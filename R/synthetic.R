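# Synthetic data generator ------------------------------------------------------
#
# Emulates the replicated branch-tip study design: a diploid genome with
# heterozygous sites at density theta, somatic mutations planted on the
# branches of a known physical tree, per-replicate short-read coverage with
# sequencing error, and a repeat mask covering a configurable genome
# fraction.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study conditions scaled to a desk-size genome: the
#' default physical tree, three replicates per tip at mean 10x coverage
#' each (~30x per tip), heterozygosity 0.01/site, error 0.005/base, a
#' repeat mask covering 40% of the genome, and a mutation intensity chosen
#' so the expected number of planted somatic mutations over the whole tree
#' is `n_somatic` (default 300, the study-scale corrected count).
#'
#' @param genome_length Number of reference sites.
#' @param theta Per-site heterozygosity probability.
#' @param kappa Transition/transversion ratio.
#' @param epsilon Per-base sequencing error probability.
#' @param lam Mutation intensity per allele per metre; when `NULL` derived
#'   as `n_somatic / (2 * total_branch_length * genome_length)`.
#' @param n_somatic Expected total planted mutations (used when `lam` is
#'   `NULL`).
#' @param tree A [physical_tree()].
#' @param mean_depth Mean per-replicate coverage (Poisson).
#' @param repeat_fraction Fraction of the genome covered by the repeat
#'   mask, in \[0, 1).
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, theta = 0.01, kappa = 2,
                       epsilon = 0.005, lam = NULL, n_somatic = 300,
                       tree = default_fig1_tree(), mean_depth = 10,
                       repeat_fraction = 0.4, seed = 1) {
  stopifnot(genome_length >= 1, theta > 0, theta < 1, epsilon >= 0,
            epsilon < 0.75, mean_depth > 0,
            repeat_fraction >= 0, repeat_fraction < 1)
  if (is.null(lam))
    lam <- n_somatic / (2 * total_branch_length(tree) * genome_length)
  structure(list(genome_length = as.integer(genome_length), theta = theta,
                 kappa = kappa, epsilon = epsilon, lam = lam,
                 tree = tree, mean_depth = mean_depth,
                 repeat_fraction = repeat_fraction, seed = seed),
            class = "sim_config")
}

# kappa-weighted draw of a different base, vectorised over source alleles
draw_mutant_allele <- function(src_idx, kappa) {
  vapply(src_idx, function(a) {
    w <- rep(1, 4); w[a] <- 0
    w[base_index(TRANSITION[a])] <- kappa
    sample(1:4, 1, prob = w)
  }, 1L)
}

#' Simulate a replicated branch-tip sequencing dataset
#'
#' Generates a random reference, germline heterozygous sites (Bernoulli
#' `theta` with kappa-weighted alternative alleles), somatic mutations
#' planted per edge as Poisson(`2 * lam * edge_metres * genome_length`)
#' at uniform positions, a repeat mask, and per-replicate pileup counts:
#' depth ~ Poisson(`mean_depth`), each read drawing one of the two alleles
#' of its tip's genotype at random and miscalled with probability
#' `epsilon` (uniform over the other three bases).
#'
#' @param config A [sim_config()].
#' @return List of class `phylomut_sim`: `reference` (character vector of
#'   bases), `tree`, `pileup` ([site_pileup()]), `truth` (list:
#'   `het` data.frame, `somatic` data.frame with the planted edge and
#'   alleles, `repeats` data.frame), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  G <- config$genome_length
  tree <- config$tree
  ref_idx <- sample.int(4, G, replace = TRUE)

  # germline variation against the reference: heterozygous sites at rate
  # theta and homozygous-alternative sites at theta/2, mirroring the
  # genotype prior (a pseudo-reference carries hom differences too)
  u <- stats::runif(G)
  het_pos <- which(u < config$theta)
  hom_pos <- which(u >= config$theta & u < 1.5 * config$theta)
  het_alt <- draw_mutant_allele(ref_idx[het_pos], config$kappa)
  hom_alt <- draw_mutant_allele(ref_idx[hom_pos], config$kappa)

  # germline genotype per site as allele pair (a1 = ref, a2 = ref or alt)
  a1 <- ref_idx
  a2 <- ref_idx
  a2[het_pos] <- het_alt
  a1[hom_pos] <- hom_alt
  a2[hom_pos] <- hom_alt

  # somatic mutations per edge
  et <- edge_table(tree)
  n_edge <- nrow(et)
  n_mut <- stats::rpois(n_edge, 2 * config$lam * et$length_m * G)
  avoid <- c(het_pos, hom_pos)
  som <- NULL
  if (sum(n_mut) > 0) {
    pos <- sample(setdiff(seq_len(G), avoid), sum(n_mut))
    edge <- rep(et$edge, n_mut)
    which_allele <- ifelse(stats::runif(length(pos)) < 0.5, 1L, 2L)
    src <- ifelse(which_allele == 1, a1[pos], a2[pos])
    mut <- draw_mutant_allele(src, config$kappa)
    som <- data.frame(chrom = "sim1", pos = pos, edge = edge,
                      ref = BASES[ref_idx[pos]],
                      source_allele = BASES[src],
                      mutant_allele = BASES[mut],
                      allele_slot = which_allele,
                      stringsAsFactors = FALSE)
    som <- som[order(som$pos), , drop = FALSE]
    rownames(som) <- NULL
  } else {
    som <- data.frame(chrom = character(), pos = integer(),
                      edge = character(), ref = character(),
                      source_allele = character(),
                      mutant_allele = character(), allele_slot = integer(),
                      stringsAsFactors = FALSE)
  }

  # repeat mask: non-overlapping intervals until the target fraction
  repeats <- data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  if (config$repeat_fraction > 0) {
    target <- config$repeat_fraction * G
    covered <- 0
    starts <- integer(0); ends <- integer(0)
    guard <- 0
    while (covered < target && guard < 10 * G) {
      len <- min(stats::rgeom(1, 1 / 1500) + 500, G)
      s <- sample.int(max(G - len + 1, 1), 1)
      e <- s + len - 1
      if (!length(starts) || all(e < starts - 1 | s > ends + 1)) {
        starts <- c(starts, s); ends <- c(ends, e)
        covered <- covered + len
      }
      guard <- guard + 1
    }
    ord <- order(starts)
    repeats <- data.frame(chrom = "sim1", start = starts[ord],
                          end = ends[ord], stringsAsFactors = FALSE)
  }

  # per-tip genotypes: germline plus somatic along the root-to-tip path
  tips <- tree$phylo$tip.label
  desc <- edge_descendant_tips(tree)
  names(desc) <- et$edge
  tipA1 <- stats::setNames(rep(list(a1), length(tips)), tips)
  tipA2 <- stats::setNames(rep(list(a2), length(tips)), tips)
  for (k in seq_len(nrow(som))) {
    for (tp in desc[[som$edge[k]]]) {
      if (som$allele_slot[k] == 1)
        tipA1[[tp]][som$pos[k]] <- base_index(som$mutant_allele[k])
      else
        tipA2[[tp]][som$pos[k]] <- base_index(som$mutant_allele[k])
    }
  }

  # pileup counts per replicate
  rt <- replicate_table(tree)
  n_rep <- nrow(rt)
  counts <- matrix(0L, G, 4 * n_rep)
  P <- base_given_genotype(config$epsilon)           # 4 x 10
  gt_code <- function(x1, x2) {
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    match(paste0(BASES[lo], BASES[hi]), GT_NAMES)
  }
  for (r in seq_len(n_rep)) {
    tp <- rt$leaf[r]
    g <- gt_code(tipA1[[tp]], tipA2[[tp]])
    depth <- stats::rpois(G, config$mean_depth)
    remaining <- depth
    pleft <- rep(1, G)
    for (b in 1:3) {
      pb <- P[b, g]
      nb <- stats::rbinom(G, remaining, pmin(pb / pleft, 1))
      counts[, 4 * (r - 1) + b] <- nb
      remaining <- remaining - nb
      pleft <- pleft - pb
    }
    counts[, 4 * (r - 1) + 4] <- remaining
  }

  pileup <- site_pileup("sim1", seq_len(G), BASES[ref_idx], counts, rt)
  het <- data.frame(chrom = "sim1", pos = het_pos,
                    ref = BASES[ref_idx[het_pos]], alt = BASES[het_alt],
                    genotype = GT_NAMES[gt_code(ref_idx[het_pos], het_alt)],
                    stringsAsFactors = FALSE)
  hom <- data.frame(chrom = "sim1", pos = hom_pos,
                    ref = BASES[ref_idx[hom_pos]], alt = BASES[hom_alt],
                    genotype = GT_NAMES[gt_code(hom_alt, hom_alt)],
                    stringsAsFactors = FALSE)
  structure(list(reference = BASES[ref_idx], tree = tree, pileup = pileup,
                 truth = list(het = het, hom_alt = hom, somatic = som,
                              repeats = repeats),
                 config = config), class = "phylomut_sim")
}

#' @export
print.phylomut_sim <- function(x, ...) {
  cat(sprintf("phylomut_sim: %d sites, %d het sites, %d somatic mutations, %d repeat intervals\n",
              x$config$genome_length, nrow(x$truth$het),
              nrow(x$truth$somatic), nrow(x$truth$repeats)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the reference (FASTA), pileups (TSV), physical tree (Newick plus
#' replicate sample map), repeat mask (BED, 0-based half-open) and truth
#' tables (VCF for het and somatic sites).
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             pileup = file.path(dir, "pileup.tsv"),
             tree = file.path(dir, "tree.nwk"),
             sample_map = file.path(dir, "sample_map.tsv"),
             repeats = file.path(dir, "repeats.bed"),
             het = file.path(dir, "truth_het.vcf"),
             somatic = file.path(dir, "truth_somatic.vcf"))
  write_fasta(stats::setNames(paste(sim$reference, collapse = ""), "sim1"),
              paths["reference"])
  write_pileup_tsv(sim$pileup, paths["pileup"])
  write_physical_tree(sim$tree, paths["tree"], paths["sample_map"])
  write_bed_mask(sim$truth$repeats, paths["repeats"])
  write_simple_vcf(data.frame(chrom = sim$truth$het$chrom,
                              pos = sim$truth$het$pos,
                              ref = sim$truth$het$ref,
                              alt = sim$truth$het$alt,
                              info = paste0("GT=", sim$truth$het$genotype)),
                   paths["het"])
  som <- sim$truth$somatic
  write_simple_vcf(data.frame(chrom = som$chrom, pos = som$pos,
                              ref = som$ref, alt = som$mutant_allele,
                              info = paste0("BRANCH=", som$edge)),
                   paths["somatic"])
  invisible(paths)
}
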