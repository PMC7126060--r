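# Per-site, per-replicate base-count pileups ----------------------------------

#' Construct a site pileup
#'
#' Per-site base counts for every replicate sample, the unit of data the
#' caller consumes. Counts are stored as an integer matrix with four
#' columns (A, C, G, T) per replicate, replicates ordered as in `samples`.
#'
#' @param chrom Chromosome/scaffold names (length 1 or N).
#' @param pos 1-based positions (length N).
#' @param ref Reference base per site.
#' @param counts Integer matrix, N x (4 * n_replicates); the columns of
#'   replicate `i` are `4*(i-1) + 1:4` in A,C,G,T order.
#' @param samples `data.frame` with columns `replicate` and `leaf`, one row
#'   per replicate, in the column-block order of `counts`.
#' @return An object of class `site_pileup`.
#' @export
site_pileup <- function(chrom, pos, ref, counts, samples) {
  n <- length(pos)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(ref) == n)
  stopifnot(is.matrix(counts), nrow(counts) == n,
            ncol(counts) == 4 * nrow(samples))
  if (any(counts < 0)) stop("negative base counts")
  stopifnot(all(c("replicate", "leaf") %in% names(samples)))
  colnames(counts) <- paste(rep(samples$replicate, each = 4), BASES, sep = ".")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = toupper(as.character(ref)), counts = counts,
                 samples = samples[, c("replicate", "leaf")]),
            class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cat(sprintf("site_pileup: %d sites x %d replicates (%d leaves), mean depth %.1f\n",
              length(x$pos), nrow(x$samples), length(unique(x$samples$leaf)),
              mean(rowSums(x$counts))))
  invisible(x)
}

#' Number of sites in a pileup
#' @param pileup A [site_pileup()].
#' @return Integer.
#' @export
n_sites <- function(pileup) length(pileup$pos)

#' Total read depth per site
#' @param pileup A [site_pileup()].
#' @return Integer vector over sites.
#' @export
total_depth <- function(pileup) as.integer(rowSums(pileup$counts))

# N x 4 counts of one replicate
replicate_counts <- function(pileup, replicate) {
  i <- match(replicate, pileup$samples$replicate)
  if (is.na(i)) stop("unknown replicate: ", replicate)
  pileup$counts[, 4 * (i - 1) + 1:4, drop = FALSE]
}

#' Subset a pileup by site index
#' @param pileup A [site_pileup()].
#' @param idx Integer or logical site index.
#' @return A [site_pileup()] restricted to `idx`.
#' @export
subset_pileup <- function(pileup, idx) {
  site_pileup(pileup$chrom[idx], pileup$pos[idx], pileup$ref[idx],
              pileup$counts[idx, , drop = FALSE], pileup$samples)
}

# sites where at least one replicate has >= min_alt reads of one
# non-reference base (cheap screen before exact scoring)
prescreen_sites <- function(pileup, min_alt = 2) {
  n <- n_sites(pileup)
  ref_i <- base_index(pileup$ref)
  keep <- rep(FALSE, n)
  for (r in seq_len(nrow(pileup$samples))) {
    M <- pileup$counts[, 4 * (r - 1) + 1:4, drop = FALSE]
    M[cbind(seq_len(n), ref_i)] <- 0L
    mx <- pmax(M[, 1], M[, 2], M[, 3], M[, 4])
    keep <- keep | (mx >= min_alt)
  }
  which(keep)
}
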