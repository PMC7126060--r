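# Nucleotide and diploid genotype state space ---------------------------------

BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

# the 10 unordered diploid genotypes, lexicographic
GT_PAIRS <- local({
  p <- t(utils::combn(4, 2))
  rbind0 <- rbind(cbind(1:4, 1:4), p)
  m <- rbind0[order(rbind0[, 1], rbind0[, 2]), , drop = FALSE]
  m
})
GT_NAMES <- apply(GT_PAIRS, 1, function(i) paste0(BASES[i[1]], BASES[i[2]]))

#' Diploid genotype state space
#'
#' Names of the 10 unordered diploid genotypes used throughout the package,
#' in the fixed internal order.
#'
#' @return Character vector of length 10 (`"AA"`, `"AC"`, ..., `"TT"`).
#' @export
genotype_states <- function() GT_NAMES

base_index <- function(x) {
  i <- match(toupper(x), BASES)
  if (anyNA(i)) stop("invalid base symbol: ", paste(x[is.na(i)], collapse = ", "))
  i
}

genotype_index <- function(x) {
  i <- match(toupper(x), GT_NAMES)
  if (anyNA(i)) {
    # accept reversed allele order, e.g. "GA"
    flip <- vapply(strsplit(toupper(x[is.na(i)]), ""), function(a)
      paste0(sort(a)[1], sort(a)[2]), "")
    i[is.na(i)] <- match(flip, GT_NAMES)
  }
  if (anyNA(i)) stop("invalid genotype symbol")
  i
}

gt_is_het <- function() GT_PAIRS[, 1] != GT_PAIRS[, 2]

gt_contains <- function(base_idx) {
  GT_PAIRS[, 1] == base_idx | GT_PAIRS[, 2] == base_idx
}

# Model parameters ------------------------------------------------------------

#' Model parameters for the phylogenetic mutation caller
#'
#' Bundles the parameters of the likelihood model: expected per-site
#' heterozygosity `theta`, transition/transversion ratio `kappa`, per-base
#' sequencing error probability `epsilon`, and the somatic mutation
#' intensity `lam` per allele per metre of physical branch.
#'
#' @param theta Expected heterozygosity per site, in (0, 1).
#' @param kappa Transition/transversion ratio, > 0. Default 2, the observed
#'   ratio in eucalypts.
#' @param epsilon Per-base sequencing error probability, in \[0, 0.75).
#' @param lam Mutation intensity per allele per metre of branch, >= 0.
#' @return An object of class `model_params`.
#' @export
model_params <- function(theta, kappa = 2, epsilon, lam) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta > 0, theta < 1)
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0, epsilon < 0.75)
  stopifnot(is.numeric(lam), length(lam) == 1, lam >= 0)
  structure(list(theta = theta, kappa = kappa, epsilon = epsilon, lam = lam),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("phylomut model parameters\n")
  cat(sprintf("  theta   (heterozygosity/site)   %.4g\n", x$theta))
  cat(sprintf("  kappa   (ts/tv ratio)           %.4g\n", x$kappa))
  cat(sprintf("  epsilon (error/base)            %.4g\n", x$epsilon))
  cat(sprintf("  lam     (mutations/allele/m)    %.4g\n", x$lam))
  invisible(x)
}

# Genotype prior --------------------------------------------------------------

#' Diploid genotype prior given the reference base
#'
#' Places mass `1 - 3*theta/2` on the homozygous-reference genotype, `theta`
#' on the three reference/alternative heterozygotes and `theta/2` on the
#' three homozygous-alternative genotypes. Within each alternative class the
#' transition alternative receives weight `kappa` and each transversion
#' weight 1 (normalised). Genotypes carrying two non-reference alleles of
#' different bases get zero prior mass.
#'
#' @param ref_allele Reference base, one of `"A","C","G","T"`.
#' @param params A [model_params()] object (only `theta`, `kappa` used).
#' @return Numeric vector of 10 probabilities over [genotype_states()],
#'   summing to 1.
#' @export
genotype_prior <- function(ref_allele, params) {
  prior_matrix(params$theta, params$kappa)[base_index(ref_allele), ]
}

# 4 x 10 matrix: row r = prior over genotypes when the reference base is r
prior_matrix <- function(theta, kappa) {
  w <- matrix(0, 4, 10, dimnames = list(BASES, GT_NAMES))
  for (r in 1:4) {
    alt_w <- rep(1, 4)
    alt_w[r] <- 0
    alt_w[base_index(TRANSITION[r])] <- kappa
    alt_w <- alt_w / sum(alt_w)
    hom_ref <- which(GT_PAIRS[, 1] == r & GT_PAIRS[, 2] == r)
    w[r, hom_ref] <- 1 - 1.5 * theta
    for (a in setdiff(1:4, r)) {
      het <- which((GT_PAIRS[, 1] == r & GT_PAIRS[, 2] == a) |
                   (GT_PAIRS[, 1] == a & GT_PAIRS[, 2] == r))
      hom <- which(GT_PAIRS[, 1] == a & GT_PAIRS[, 2] == a)
      w[r, het] <- theta * alt_w[a]
      w[r, hom] <- 0.5 * theta * alt_w[a]
    }
  }
  w
}

# Mutation kernel -------------------------------------------------------------

# 4x4 per-allele kernel: stay with 1-mu, move to the transition partner with
# mu*kappa/(kappa+2), to each transversion with mu/(kappa+2)
allele_kernel <- function(mu, kappa) {
  K <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (a in 1:4) {
    K[a, a] <- 1 - mu
    for (b in setdiff(1:4, a)) {
      w <- if (BASES[b] == TRANSITION[a]) kappa else 1
      K[a, b] <- mu * w / (kappa + 2)
    }
  }
  K
}

#' Genotype transition matrix along a physical branch
#'
#' Per-allele mutation probability on a branch of `length_m` metres is
#' `mu = 1 - exp(-lam * length_m)`; a mutating allele moves to its
#' transition partner with probability `mu*kappa/(kappa+2)` and to each
#' transversion with `mu/(kappa+2)`. The two alleles of a diploid genotype
#' mutate independently and the ordered outcome is collapsed onto the 10
#' unordered genotypes.
#'
#' @param length_m Branch length in metres, >= 0.
#' @param params A [model_params()] object (`lam`, `kappa` used).
#' @return 10 x 10 row-stochastic matrix over [genotype_states()].
#' @export
branch_transition_matrix <- function(length_m, params) {
  if (!is.numeric(length_m) || length(length_m) != 1 || length_m < 0)
    stop("branch length must be a single non-negative number of metres")
  mu <- 1 - exp(-params$lam * length_m)
  K <- allele_kernel(mu, params$kappa)
  Tm <- matrix(0, 10, 10, dimnames = list(GT_NAMES, GT_NAMES))
  for (i in 1:10) {
    a1 <- GT_PAIRS[i, 1]; a2 <- GT_PAIRS[i, 2]
    for (j in 1:10) {
      b1 <- GT_PAIRS[j, 1]; b2 <- GT_PAIRS[j, 2]
      p <- K[a1, b1] * K[a2, b2]
      if (b1 != b2) p <- p + K[a1, b2] * K[a2, b1]
      Tm[i, j] <- p
    }
  }
  Tm
}

# Read model ------------------------------------------------------------------

# 4 x 10 matrix: P(read base b | genotype g) = 0.5 p(b|a1) + 0.5 p(b|a2),
# with p(b|a) = 1-eps if b == a else eps/3
base_given_genotype <- function(epsilon) {
  pba <- matrix(epsilon / 3, 4, 4)
  diag(pba) <- 1 - epsilon
  M <- matrix(0, 4, 10, dimnames = list(BASES, GT_NAMES))
  for (g in 1:10)
    M[, g] <- 0.5 * pba[, GT_PAIRS[g, 1]] + 0.5 * pba[, GT_PAIRS[g, 2]]
  M
}

#' Likelihood of one replicate's base counts given a diploid genotype
#'
#' Each read draws one of the two alleles with probability 1/2 and is then
#' observed correctly with probability `1 - epsilon`, or as each of the
#' other three bases with probability `epsilon/3`. The replicate likelihood
#' is the product over reads, computed from the base counts in log space.
#'
#' @param counts Named (or A,C,G,T-ordered) non-negative integer vector of
#'   base counts for one replicate at one site.
#' @param genotype Genotype string, e.g. `"AG"`.
#' @param params A [model_params()] object (`epsilon` used).
#' @param log Return the log-likelihood instead of the likelihood.
#' @return Scalar (log-)likelihood; 1 (or 0) for zero reads.
#' @export
replicate_likelihood <- function(counts, genotype, params, log = FALSE) {
  cv <- normalise_counts(counts)
  g <- genotype_index(genotype)
  ll <- sum(cv * log(base_given_genotype(params$epsilon)[, g, drop = TRUE]))
  if (log) ll else exp(ll)
}

normalise_counts <- function(counts) {
  if (!is.null(names(counts))) {
    cv <- numeric(4); names(cv) <- BASES
    cv[intersect(names(counts), BASES)] <- counts[intersect(names(counts), BASES)]
  } else {
    stopifnot(length(counts) == 4)
    cv <- as.numeric(counts)
  }
  if (any(cv < 0) || anyNA(cv)) stop("malformed base counts")
  cv
}
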