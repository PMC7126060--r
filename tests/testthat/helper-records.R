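# fabricate site_records for filter tests --------------------------------------

make_records <- function(tree, rows) {
  # rows: list of list(ref, depth, leafG = named leaf -> genotype (replicated
  # to the leaf's replicates), or gt = full named replicate vector)
  rt <- replicate_table(tree)
  G <- matrix(NA_character_, length(rows), nrow(rt),
              dimnames = list(NULL, rt$replicate))
  sites <- data.frame(chrom = "chr1", pos = seq(1000, by = 5000,
                                                length.out = length(rows)),
                      ref = vapply(rows, `[[`, "", "ref"),
                      total_depth = vapply(rows, function(r)
                        as.integer(r$depth), 1L),
                      stringsAsFactors = FALSE)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (!is.null(r$gt)) {
      G[i, names(r$gt)] <- r$gt
    } else {
      for (l in names(r$leafG))
        G[i, rt$replicate[rt$leaf == l]] <- r$leafG[[l]]
    }
  }
  structure(list(sites = sites, genotypes = G, samples = rt),
            class = "site_records")
}

leafG_uniform <- function(tree, base_gt, except = NULL, alt_gt = NULL) {
  leaves <- tree$phylo$tip.label
  out <- setNames(rep(list(base_gt), length(leaves)), leaves)
  for (l in except) out[[l]] <- alt_gt
  out
}
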