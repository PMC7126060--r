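test_that("excess heterozygosity phred score matches exact-test behaviour", {
  expect_equal(excess_het_phred(24, 0, 0), 0)
  expect_lt(excess_het_phred(12, 0, 12), 1e-6)  # p = 1 upward tail... none seen
  expect_gt(excess_het_phred(0, 24, 0), 40)
  # agreement with a permutation oracle at small n: P(het >= obs)
  set.seed(31)
  n_aa <- 3; n_ab <- 4; n_bb <- 1
  alleles <- c(rep("A", 2 * n_aa + n_ab), rep("B", 2 * n_bb + n_ab))
  B <- 40000
  hets <- replicate(B, {
    a <- sample(alleles)
    sum(a[c(TRUE, FALSE)] != a[c(FALSE, TRUE)])
  })
  p_mc <- mean(hets >= n_ab)
  p_exact <- 10^(-excess_het_phred(n_aa, n_ab, n_bb) / 10)
  expect_equal(p_exact, p_mc, tolerance = 0.05)
})

test_that("positive-control cascade removes exactly the offending site per rule", {
  tr <- default_fig1_tree()
  rt <- replicate_table(tr)
  mask <- data.frame(chrom = "chr1", start = 30990, end = 31010)
  # M4 varies cleanly; one M5 replicate disagrees -> only rule (i) fails
  disc <- leafG_uniform(tr, "AA", except = "M4", alt_gt = "AG")
  disc_gt <- unlist(lapply(rt$leaf, function(l) disc[[l]]))
  names(disc_gt) <- rt$replicate
  disc_gt[rt$replicate[rt$leaf == "M5"][1]] <- "AG"  # replicate discordance
  rows <- list(
    list(ref = "A", depth = 240,                     # passes everything
         leafG = leafG_uniform(tr, "AA", "M3", "AG")),
    list(ref = "A", depth = 240, gt = disc_gt),      # (i) discordant reps
    list(ref = "A", depth = 240,                     # (ii) no tip differs
         leafG = leafG_uniform(tr, "GG")),
    list(ref = "A", depth = 240,                     # (iii) two alt alleles
         leafG = leafG_uniform(tr, "AA", c("M1", "M2"), "AC") |>
           modifyList(list(M5 = "AG"))),
    list(ref = "A", depth = 501,                     # (iv) depth > 500
         leafG = leafG_uniform(tr, "AA", "M7", "AG")),
    list(ref = "A", depth = 240,                     # (v) all-sample het
         leafG = leafG_uniform(tr, "AG")),
    list(ref = "A", depth = 240,                     # (vi) repeat region
         leafG = leafG_uniform(tr, "AA", "M2", "AG")))
  rec <- make_records(tr, rows)
  rec$sites$pos <- c(1000, 6000, 11000, 16000, 21000, 26000, 31000)
  out <- positive_control_filter(rec, tr, repeat_mask = mask)
  expect_equal(out$n_survivors, 1)
  expect_equal(out$records$sites$pos, 1000)
  failed <- setNames(out$attrition$n_failed, out$attrition$filter)
  expect_equal(unname(failed["replicate_concordance"]), 1)
  # the uniformly heterozygous artefact site fails both the variation rule
  # and the excess-het rule; every other constructed site fails one rule
  expect_equal(unname(failed["tip_varies"]), 2)
  expect_equal(unname(failed["biallelic"]), 1)
  expect_equal(unname(failed["depth"]), 1)
  expect_equal(unname(failed["excess_het"]), 1)
  expect_equal(unname(failed["repeat_region"]), 1)
  expect_equal(out$n_multi_fail, 1)
  # attrition bookkeeping: input = survivors + exclusive + multi + missing
  expect_equal(out$n_input,
               out$n_survivors + sum(out$attrition$n_failed_only) +
                 out$n_multi_fail + out$n_missing)
  # alignment holds per-tip genotypes of survivors
  expect_equal(dim(out$alignment), c(8, 1))
  expect_equal(unname(out$alignment["M3", 1]), "AG")
})

test_that("excess-het cap is inclusive and binds through the filter argument", {
  # with three concordant replicates per tip, het counts come in multiples
  # of three; the largest score compatible with tip variation is ~37.2
  # (21 het + 3 hom-alt), under the default cap of 40, while a uniformly
  # heterozygous artefact site (24 het) scores ~62.8 and is removed
  expect_lte(excess_het_phred(0, 21, 3), 40)
  expect_gt(excess_het_phred(0, 24, 0), 40)
  tr <- default_fig1_tree()
  rows <- list(list(ref = "A", depth = 240,
                    leafG = leafG_uniform(tr, "AG", "M1", "GG")))
  kept <- positive_control_filter(make_records(tr, rows), tr,
                                  max_excess_het = 40)
  expect_equal(kept$n_survivors, 1)   # 37.2 <= 40: kept
  gone <- positive_control_filter(make_records(tr, rows), tr,
                                  max_excess_het = 35)
  expect_equal(gone$n_survivors, 0)   # cap below the score: removed
})

test_that("depth boundary is inclusive at 500", {
  tr <- default_fig1_tree()
  rows <- list(list(ref = "A", depth = 500,
                    leafG = leafG_uniform(tr, "AA", "M1", "AG")),
               list(ref = "A", depth = 501,
                    leafG = leafG_uniform(tr, "AA", "M1", "AG")))
  out <- positive_control_filter(make_records(tr, rows), tr)
  expect_equal(out$records$sites$total_depth, 500L)
})

test_that("sites with a missing replicate genotype are dropped and counted separately", {
  tr <- default_fig1_tree()
  rt <- replicate_table(tr)
  gt <- setNames(rep("AA", 24), rt$replicate)
  gt[rt$replicate[rt$leaf == "M2"]] <- "AG"
  gt[1] <- NA
  out <- positive_control_filter(
    make_records(tr, list(list(ref = "A", depth = 100, gt = gt))), tr)
  expect_equal(out$n_missing, 1)
  expect_equal(out$n_survivors, 0)
})

test_that("haplotype blocks follow fragment connectivity transitively", {
  het <- data.frame(chrom = "chr1", pos = c(100, 300, 650, 5000))
  # fragment f1 joins 100-300, f2 joins 300-650; 5000 unconnected
  frags <- data.frame(fragment = c("f1", "f1", "f2", "f2"),
                      chrom = "chr1", pos = c(100, 300, 300, 650))
  b <- build_blocks(het, frags)
  expect_equal(nrow(b), 2)
  chain <- b[b$n_sites == 3, ]
  expect_equal(chain$start, 100)
  expect_equal(chain$end, 650)
  expect_equal(chain$size, 551)
  expect_equal(b[b$n_sites == 1, ]$size, 1)
  # no fragments: all singletons
  b0 <- build_blocks(het, NULL)
  expect_equal(nrow(b0), 4)
  expect_true(all(b0$size == 1))
})

test_that("de novo filter boundaries match their printed thresholds", {
  base <- data.frame(chrom = "chr1", ref = "A", alt = "G", dnp = 0.999999,
                     lld = -1, stringsAsFactors = FALSE)
  mk <- function(pos) {
    df <- base[rep(1, length(pos)), ]
    df$pos <- pos
    df
  }
  # proximity: 999 apart -> both removed; 1000 and 1001 apart -> kept
  f999 <- denovo_filter(mk(c(10000, 10999)))
  expect_equal(nrow(f999$calls), 0)
  f1000 <- denovo_filter(mk(c(10000, 11000)))
  expect_equal(nrow(f1000$calls), 2)
  f1001 <- denovo_filter(mk(c(10000, 11001)))
  expect_equal(nrow(f1001$calls), 2)

  # block filter: 499-nt block removed, 500-nt block kept, no block removed
  blocks <- data.frame(block = 1:2, chrom = "chr1",
                       start = c(10000, 20000), end = c(10498, 20499))
  blocks$size <- blocks$end - blocks$start + 1
  fb <- denovo_filter(mk(c(10100, 20100, 30000)), blocks = blocks)
  expect_equal(fb$calls$pos, 20100)

  # DNP exactly at threshold kept; below removed
  df <- mk(c(10000, 50000))
  df$dnp <- c(0.99999, 0.999989)
  fd <- denovo_filter(df)
  expect_equal(fd$calls$pos, 10000)

  # LLD below -5 removed, at -5 kept
  df2 <- mk(c(10000, 50000))
  df2$lld <- c(-5, -5.01)
  fl <- denovo_filter(df2)
  expect_equal(fl$calls$pos, 10000)
})

test_that("de novo filter attrition bookkeeping is consistent", {
  df <- data.frame(chrom = "chr1",
                   pos = c(1000, 1500, 9000, 40000),
                   ref = "A", alt = "G",
                   dnp = c(1, 1, 0.9, 1),
                   lld = c(-1, -6, -1, -1), stringsAsFactors = FALSE)
  out <- denovo_filter(df)
  expect_equal(out$n_input, 4)
  expect_equal(out$n_survivors, 1)
  expect_equal(out$calls$pos, 40000)
  expect_equal(out$n_input,
               out$n_survivors + sum(out$attrition$n_failed_only) +
                 out$n_multi_fail)
  expect_equal(nrow(denovo_filter(df[0, ])$calls), 0)
})
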