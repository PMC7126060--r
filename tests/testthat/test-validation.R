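small_sim <- function(seed = 21, genome = 30000, n_somatic = 0,
                      repeat_fraction = 0) {
  simulate_dataset(sim_config(genome_length = genome, theta = 0.01,
                              epsilon = 0.005, n_somatic = n_somatic,
                              repeat_fraction = repeat_fraction,
                              seed = seed))
}

sim_params <- model_params(theta = 0.01, kappa = 2, epsilon = 0.005,
                           lam = 1e-7)

test_that("spike plans are reproducible, branch-complete and kappa-weighted", {
  sim <- small_sim()
  plan <- make_spike_plan(sim$tree, sim$pileup, sim_params,
                          n_per_branch = 50, seed = 11)
  expect_equal(nrow(plan), 14 * 50)
  expect_equal(as.integer(table(plan$edge)), rep(50L, 14))
  expect_true(all(plan$edge %in% edge_table(sim$tree)$edge))
  expect_false(anyDuplicated(paste(plan$chrom, plan$pos)) > 0)
  plan2 <- make_spike_plan(sim$tree, sim$pileup, sim_params,
                           n_per_branch = 50, seed = 11)
  expect_identical(plan, plan2)
  # mutant allele never equals the source; transitions enriched ~kappa/(kappa+2)
  expect_true(all(plan$mutant_allele != plan$source_allele))
  is_ts <- plan$mutant_allele ==
    c(A = "G", C = "T", G = "A", T = "C")[plan$source_allele]
  chi <- chisq.test(table(is_ts), p = c(1 / 2, 1 / 2))
  expect_gt(chi$p.value, 1e-4)   # 700 draws at expected 50:50 ts:tv
  expect_error(make_spike_plan(sim$tree, subset_pileup(sim$pileup, 1:10),
                               sim_params, n_per_branch = 50, seed = 1),
               "not enough eligible sites")
})

test_that("spiking edits only descendants of the target branch", {
  sim <- small_sim(seed = 22, genome = 5000)
  tr <- sim$tree
  plan <- make_spike_plan(tr, sim$pileup, sim_params, n_per_branch = 2,
                          seed = 5)
  sp <- spike_pileups(sim$pileup, plan, tr, seed = 6)
  rt <- replicate_table(tr)
  et <- edge_table(tr)
  desc <- phylomut:::edge_descendant_tips(tr)
  names(desc) <- et$edge
  diff_sites <- which(rowSums(sp$pileup$counts != sim$pileup$counts) > 0)
  expect_true(all(diff_sites %in%
                    match(paste(plan$chrom, plan$pos),
                          paste(sim$pileup$chrom, sim$pileup$pos))))
  for (k in seq_len(nrow(plan))) {
    i <- match(paste(plan$chrom[k], plan$pos[k]),
               paste(sim$pileup$chrom, sim$pileup$pos))
    affected <- rt$leaf %in% desc[[plan$edge[k]]]
    for (r in seq_len(nrow(rt))) {
      cols <- 4 * (r - 1) + 1:4
      if (!affected[r])
        expect_identical(sp$pileup$counts[i, cols],
                         sim$pileup$counts[i, cols])
      else  # depth conserved under read editing
        expect_equal(sum(sp$pileup$counts[i, cols]),
                     sum(sim$pileup$counts[i, cols]))
    }
  }
})

test_that("heterozygous spikes replace every source read; homozygous spikes flip about half", {
  tr <- default_fig1_tree()
  leaves <- tr$phylo$tip.label
  pu <- fixed_pileup(tr, "A",
                     setNames(rep(list(c(A = 8, C = 8)), 8), leaves),
                     pos = 100L)
  plan_het <- data.frame(chrom = "chr1", pos = 100L, ref = "A",
                         edge = "B->C", root_genotype = "AC",
                         source_allele = "A", mutant_allele = "G",
                         stringsAsFactors = FALSE)
  sp <- spike_pileups(pu, plan_het, tr, seed = 1)
  rt <- replicate_table(tr)
  for (r in which(rt$leaf %in% c("M1", "M2", "M3"))) {
    cols <- 4 * (r - 1) + 1:4
    expect_equal(unname(sp$pileup$counts[1, cols]), c(0L, 8L, 8L, 0L))
  }
  # homozygous case: Binomial(n_src, 0.5) flips, mean about half over spikes
  pu2 <- fixed_pileup(tr, "A",
                      setNames(rep(list(c(A = 20)), 8), leaves), pos = 100L)
  set.seed(99)
  flips <- replicate(300, {
    plan_hom <- data.frame(chrom = "chr1", pos = 100L, ref = "A",
                           edge = "G->M7", root_genotype = "AA",
                           source_allele = "A", mutant_allele = "T",
                           stringsAsFactors = FALSE)
    s <- spike_pileups(pu2, plan_hom, tr)
    r <- which(rt$leaf == "M7")[1]
    s$pileup$counts[1, 4 * (r - 1) + 4]
  })
  expect_equal(mean(flips), 10, tolerance = 0.08)
  expect_gt(stats::var(flips), 2)   # genuinely binomial, not deterministic
})

test_that("fnr estimation recovers cleanly planted spikes and reports arithmetic", {
  sim <- small_sim(seed = 23, genome = 150000)
  tr <- sim$tree
  plan <- make_spike_plan(tr, sim$pileup, sim_params, n_per_branch = 3,
                          seed = 7, min_spacing = 2000,
                          exclude = sim$truth$het)
  sp <- spike_pileups(sim$pileup, plan, tr, seed = 8)
  fnr <- estimate_fnr(tr, sp$pileup, sp$plan, sim_params)
  expect_equal(fnr$n_spiked, 42)
  expect_equal(fnr$recovery_rate, fnr$n_recovered / fnr$n_spiked)
  expect_equal(fnr$false_negative_rate, 1 - fnr$recovery_rate)
  expect_gt(fnr$recovery_rate, 0.8)
  expect_equal(sort(unique(fnr$per_branch$edge)),
               sort(edge_table(tr)$edge))
  # site-only matching can only raise recovery
  fnr_site <- estimate_fnr(tr, sp$pileup, sp$plan, sim_params,
                           match = "site")
  expect_gte(fnr_site$recovery_rate, fnr$recovery_rate)
  # study arithmetic: 4193 of 14000 -> 29.95%
  expect_equal(round(100 * 4193 / 14000, 2), 29.95)
})

test_that("label shuffling reaches maximal RF distance deterministically", {
  tr <- replicate_tree(default_fig1_tree())
  s1 <- shuffle_maximal_rf(tr, seed = 42)
  s2 <- shuffle_maximal_rf(tr, seed = 42)
  expect_equal(rf_distance(s1, tr), 42)
  expect_identical(s1$tip.label, s2$tip.label)
  expect_error(shuffle_maximal_rf(ape::rtree(4), max_tries = 0), "tries")
})

test_that("permutation fdr loop counts false calls against scrambled replicates", {
  sim <- small_sim(seed = 24, genome = 20000)
  mc <- call_mutations(sim$tree, sim$pileup, sim_params)
  known <- rbind(mc$calls[, c("chrom", "pos")],
                 mc$het_sites[, c("chrom", "pos")])
  fdr <- estimate_fdr(sim$tree, sim$pileup, sim_params, known,
                      n_perm = 3, n_real_calls = 90, seed = 31)
  expect_equal(fdr$n_permutations, 3)
  expect_equal(fdr$fp_per_experiment, fdr$n_false_calls / 3)
  expect_length(fdr$per_permutation, 3)
  expect_lte(fdr$fp_per_experiment, 1)  # null data: at most sporadic calls
  expect_error(estimate_fdr(sim$tree, sim$pileup, sim_params, known,
                            n_perm = 0), "at least 1")
  # study arithmetic: 11 false calls over 100 permutations, 90 real calls
  expect_equal(11 / 100, 0.11)
  expect_equal(round(100 * 0.11 / 90, 2), 0.12)
})
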