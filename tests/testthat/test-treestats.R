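test_that("topology enumeration yields the double-factorial counts without duplicates", {
  expect_length(enumerate_topologies(3), 1)
  t5 <- enumerate_topologies(5)
  expect_length(t5, 15)
  # pairwise distinct under label-preserving isomorphism
  for (i in 1:14) for (j in (i + 1):15)
    expect_gt(phangorn::RF.dist(t5[[i]], t5[[j]]), 0)
  expect_length(enumerate_topologies(6), 105)
  expect_error(enumerate_topologies(2), "3..10")
  expect_error(enumerate_topologies(11), "3..10")
})

test_that("fitch score matches brute-force internal labelling minimisation", {
  tr1 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  tr2 <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  al <- matrix(c("A", "A", "B", "B"), 4, 1,
               dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr1, al), 1)
  expect_equal(fitch_score(tr2, al), 2)
  # invariant alignment scores zero
  inv <- matrix("AA", 4, 6, dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr1, inv), 0)
  # random multistate alignments on random 5-6 leaf trees vs brute force
  set.seed(77)
  for (i in 1:6) {
    n <- sample(5:6, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$tip.label <- paste0("t", seq_len(n))
    al <- matrix(sample(c("AA", "AG", "GG", "CC"), n * 8, replace = TRUE),
                 n, 8, dimnames = list(tr$tip.label, NULL))
    expect_equal(fitch_score(tr, al), oracle_fitch(tr, al))
  }
  # score is invariant under site permutation
  perm <- al[, sample(ncol(al))]
  expect_equal(fitch_score(tr, perm), fitch_score(tr, al))
  bad <- al
  rownames(bad) <- paste0("x", seq_len(nrow(al)))
  expect_error(fitch_score(tr, bad), "labels")
})

test_that("path difference matches the BFS oracle and phangorn, and is a metric", {
  tops <- enumerate_topologies(5)
  expect_equal(path_difference(tops[[4]], tops[[4]]), 0)
  set.seed(13)
  for (i in 1:10) {
    a <- tops[[sample(15, 1)]]; b <- tops[[sample(15, 1)]]
    pd <- path_difference(a, b)
    expect_equal(pd, oracle_pd(a, b))
    expect_equal(pd, path_difference(b, a))
    expect_equal(pd,
                 unname(phangorn::treedist(a, b)["path.difference"]),
                 tolerance = 1e-12)
  }
  # larger random trees against the BFS oracle
  for (i in 1:5) {
    a <- ape::rtree(8, rooted = FALSE); b <- ape::rtree(8, rooted = FALSE)
    b$tip.label <- a$tip.label[sample(8)]
    expect_equal(path_difference(a, b), oracle_pd(a, b))
  }
  expect_error(path_difference(tops[[1]], ape::rtree(4)), "leaf set")
})

test_that("pd null test brackets its extremes", {
  ref <- enumerate_topologies(6)[[50]]
  tops <- enumerate_topologies(6, ref$tip.label)
  null <- vapply(tops, path_difference, topology_b = ref, numeric(1))
  same <- pd_null_test(ref, ref, tops)
  expect_equal(same$pd_observed, 0)
  expect_equal(same$p_value, mean(null == 0))
  expect_equal(same$p_value, min(vapply(unique(null), function(q)
    mean(null <= q), numeric(1))))
  worst <- tops[[which.max(null)]]
  expect_equal(pd_null_test(worst, ref, tops)$p_value, 1)
})

test_that("ml scan recovers the generating topology and bounded bootstrap support", {
  set.seed(19)
  tops <- enumerate_topologies(5)
  truth <- tops[[9]]
  # simulate binary states down the tree: flip probability low per edge
  sim_align <- function(tr, m, pflip = 0.15) {
    tr <- ape::multi2di(tr)
    n_tip <- length(tr$tip.label)
    root <- n_tip + 1
    out <- matrix("", n_tip, m)
    for (s in seq_len(m)) {
      g <- integer(n_tip + tr$Nnode)
      g[root] <- sample(0:1, 1)
      for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
        g[chd] <- if (runif(1) < pflip) 1 - g[par] else g[par]
      }
      out[, s] <- c("R", "M")[g[seq_len(n_tip)] + 1]
    }
    rownames(out) <- tr$tip.label
    out
  }
  al <- sim_align(truth, 400, pflip = 0.12)
  scan <- ml_tree_scan(al, tops, bootstrap = 10, seed = 4)
  expect_equal(phangorn::RF.dist(scan$best_tree, truth), 0)
  expect_true(all(scan$support >= 0 & scan$support <= 100))
  expect_true(all(is.finite(scan$log_lik)))
  inv <- matrix("AA", 5, 4, dimnames = list(truth$tip.label, NULL))
  expect_error(ml_tree_scan(inv, tops), "invariant")
})

test_that("rf distance counts splits present in exactly one tree", {
  t5 <- enumerate_topologies(5)
  expect_equal(rf_distance(t5[[1]], t5[[1]]), 0)
  expect_equal(rf_distance(t5[[1]], t5[[2]]), rf_distance(t5[[2]], t5[[1]]))
  big <- ape::rtree(24)
  shuf <- shuffle_maximal_rf(big, seed = 3)
  expect_equal(rf_distance(big, shuf), 2 * (24 - 3))
  # no shared non-trivial splits: verify via split enumeration
  splits <- function(tr) {
    tr <- ape::unroot(tr)
    desc <- phangorn::Descendants(tr, unique(tr$edge[, 1]), type = "tips")
    keys <- lapply(desc, function(i) sort(tr$tip.label[i]))
    all_tips <- sort(tr$tip.label)
    keys <- lapply(keys, function(s)
      if (length(s) <= length(all_tips) / 2) s else setdiff(all_tips, s))
    unique(vapply(keys, paste, "", collapse = ","))
  }
  s1 <- splits(big); s2 <- splits(shuf)
  nontrivial <- function(s) s[vapply(strsplit(s, ","), length, 1L) >= 2]
  expect_length(intersect(nontrivial(s1), nontrivial(s2)), 0)
})

test_that("branch-length regression through the origin behaves on exact and degenerate data", {
  tr <- default_fig1_tree()
  mt <- tr$phylo
  mt$edge.length <- 3 * tr$phylo$edge.length
  fit <- branch_length_regression(tr, mt)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  mt0 <- tr$phylo
  mt0$edge.length <- rep(0, 14)
  expect_error(branch_length_regression(tr, mt0), "zero")
  # Poisson counts proportional to metres recover the rate
  set.seed(8)
  rho <- 3.3
  mt2 <- tr$phylo
  mt2$edge.length <- rpois(14, rho * tr$phylo$edge.length)
  fit2 <- branch_length_regression(tr, mt2)
  expect_gt(fit2$r_squared, 0.7)
  expect_lt(fit2$p_value, 0.001)
  expect_lt(abs(fit2$slope - rho) / rho, 0.35)
})

test_that("mutation branch counts build a count tree aligned to the physical edges", {
  tr <- default_fig1_tree()
  calls <- data.frame(chrom = "c", pos = c(1, 2, 3),
                      branch = c("B->C", "B->C", "G->M7"))
  mt <- mutation_branch_counts(calls, tr)
  et <- edge_table(tr)
  expect_equal(sum(mt$edge.length), 3)
  expect_equal(mt$edge.length[et$edge == "B->C"], 2)
  expect_equal(mt$edge.length[et$edge == "G->M7"], 1)
})
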