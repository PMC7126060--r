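---
title: "Measuring somatic mutations on the physical tree of a plant"
author: "phylomut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring somatic mutations on the physical tree of a plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomut)
```

## The problem

A mutation in a meristematic cell of a plant is inherited by every tissue
that grows from that meristem, so a whole branch — leaves, flowers, seeds —
can carry a genotype the rest of the plant does not. Counting such somatic
mutations genome-wide in a single individual is hard for two reasons:
sequencing error and library artefacts occur at rates far above the somatic
mutation rate, and there is no pedigree against which to polarise variants.

`phylomut` implements a phylogenomic solution built on three ideas:

1. **Replicates.** Each sampled branch tip is sequenced as several
   independent biological replicates (three by default). Errors introduced
   during extraction, library preparation or sequencing are very unlikely
   to recur at the same site in all replicates, while a true somatic
   mutation is present in all of them.
2. **The plant is its own phylogeny.** The physical branching structure of
   the individual, with branch lengths measured in metres, predicts the
   pattern a real somatic mutation must show: it is shared by exactly the
   tips descending from the branch on which it arose. The caller scores
   sites directly against that expectation.
3. **Internal controls.** The physical tree yields a positive control (do
   mutation-derived phylogenies recover the plant's structure?), a
   false-negative control (spike synthetic mutations into the reads and
   count how many the pipeline recovers) and a false-discovery control
   (scramble the replicate-to-branch assignment so no true phylogenetic
   signal remains, and count the calls that survive anyway).

## The likelihood model

All computations run on the space of the 10 unordered diploid genotypes
$\{AA, AC, \dots, TT\}$.

**Root prior.** Given reference base $r$ and heterozygosity $\theta$, the
root (germline) genotype prior puts mass $1 - \tfrac{3\theta}{2}$ on the
homozygous-reference genotype, $\theta$ spread over the three $r/x$
heterozygotes and $\theta/2$ over the three $x/x$ homozygotes, in both
cases weighting the transition alternative $\kappa$ against 1 for each
transversion. Genotypes with two distinct non-reference alleles get zero
prior mass. With $\theta = 0.01$, $\kappa = 2$ and reference A this gives
$P(AA) = 0.985$, $P(AG) = 0.005$, $P(AC) = P(AT) = 0.0025$.

**Branch kernel.** Along a branch of $\ell$ metres each allele mutates
with probability $\mu = 1 - e^{-\lambda \ell}$, moving to its transition
partner with probability $\mu\kappa/(\kappa+2)$ and to each transversion
with $\mu/(\kappa+2)$. The two alleles mutate independently; the ordered
outcome is collapsed to unordered genotypes. This is a single-jump kernel:
as $\lambda\ell \to \infty$ the no-change probability of a homozygote
goes to zero, but rows do not converge to a common stationary
distribution — the kernel models "did a mutation happen on this branch",
not long-run substitution.

**Read model.** A read drawn from genotype $\{a_1, a_2\}$ reports base $d$
with probability $\tfrac12 p(d|a_1) + \tfrac12 p(d|a_2)$, where
$p(d|a) = 1-\varepsilon$ if $d = a$ and $\varepsilon/3$ otherwise. A
replicate's likelihood is the product over its reads, computed from base
counts in log space. All replicates of a tip share the tip's genotype, so
a tip's conditional likelihood is the product of its replicates'
likelihoods — this is where the replicated design earns its power.

**Pruning and scores.** Felsenstein pruning over the physical tree with
the branch kernel per edge gives the total site likelihood. Three scores
summarise each site:

* **DNP**, the de novo mutation probability: one minus the posterior
  probability that every node of the tree carries the root genotype. The
  no-mutation configuration is computed exactly, including the per-edge
  no-change probabilities, so DNP is always in $[0, 1]$ and agrees with
  exhaustive enumeration over genotype assignments (the test suite checks
  this to $10^{-8}$ on all trees with up to five tips).
* **Per-branch posteriors**: the likelihood of each "exactly one mutation,
  on edge $e$" configuration (identity on every other edge),
  renormalised over the no-mutation and all single-edge configurations.
  Double hits at one site are treated as negligible, consistent with the
  rarity of somatic mutations. The maximal-posterior edge becomes the
  call's branch assignment.
* **LLD**, the scaled data log-likelihood: $\log_{10}$ of the site
  likelihood divided by the read count (at least 1), a per-read model-fit
  score. Sites the model explains poorly have strongly negative LLD.

Ties in MAP genotypes are broken toward reference-containing genotypes; a
site with no reads falls back to the prior, so its DNP is the prior
probability $\approx 2\lambda L_{\text{total}}$ that any mutation occurred.

**Parameter fitting.** `fit_params()` maximises the summed site
log-likelihood over $(\theta, \varepsilon, \lambda)$ with the Nelder–Mead
simplex on transformed scales (logit, scaled logit, log). $\kappa$ is
fixed at 2 by default — the observed transition/transversion ratio of
eucalypts — with `fit_kappa = TRUE` exposed. Fitting is intended for
putatively neutral sites (e.g. 3-fold degenerate positions); a few
thousand sites give $\varepsilon$ to a few percent and $\theta$ to
roughly the Poisson error of the realised number of variant sites
(about 12% relative at 5000 sites with $\theta = 0.01$).

## Filters

Two cascades mirror the two analysis tracks.

The **positive-control filter** consumes per-replicate genotype calls
(each replicate genotyped independently, MAP of read likelihood times the
prior) and keeps sites where (i) all replicates of every tip agree, (ii)
at least one tip differs, (iii) exactly one non-reference allele is
present, (iv) total depth across samples is ≤ 500 (about twice the
expected 240×; excess depth flags collapsed repeats), (v) the
excess-heterozygosity phred score is ≤ 40, and (vi) the site is outside
the repeat mask. ExcessHet is the one-sided Levene exact test of more
heterozygous samples than Hardy–Weinberg predicts, conditioned on allele
counts, computed across all replicate samples (they entered genotyping as
separate samples). A consequence of the concordance rule worth knowing:
with three concordant replicates per tip, het counts come in multiples of
three, so the largest ExcessHet compatible with tip-level variation at 24
samples is ≈ 37.2 — the ≤ 40 rule then fires only together with other
failures, exactly as intended for uniformly-heterozygous artefact sites.

The **de novo filter** removes candidate calls that (i) sit on a
haplotype block spanning < 500 nt (short blocks flag poorly assembled or
repetitive regions; blocks are built by union–find over het sites sharing
a read fragment), (ii) lie within 1000 nt of another candidate — "within"
is interpreted strictly, so a pair exactly 1000 nt apart is kept, and both
members of a close pair are removed, evaluated on the full candidate set
before the other rules; (iii) have LLD < −5; or (iv) have DNP < 0.99999
(a call exactly at a threshold is kept). When no block annotation exists
(e.g. pileup-only simulations), the block filter is skipped by flag.

## Validation loops

**False negatives.** `make_spike_plan()` draws sites without replacement,
assigns an equal quota to every branch (the study design used 1000 ×
14 branches), estimates the root genotype with the caller and draws the
mutant allele with κ-weighting. `spike_pileups()` edits only the
replicates of tips descending from the target branch: at homozygous sites
a Binomial(n, 0.5) number of source-allele reads flips to the mutant
(heterozygous somatic mutation); at heterozygous sites every source read
flips. `estimate_fnr()` re-runs calling plus the de novo filters and
counts a spike as recovered only if the surviving call lands on the
correct branch (site-only matching is a flag). Attempted spikes with no
coverage stay in the denominator. Because this package edits pileups
rather than raw FASTQ, re-alignment effects are outside the loop; the
recovery it measures is the caller-plus-filter power.

**False discoveries.** `estimate_fdr()` repeatedly permutes which
replicates belong to which tip, requiring the induced 24-taxon replicate
tree to share no splits with the original (maximal Robinson–Foulds
distance, $2(n-3) = 42$), re-runs the pipeline ignoring previously
identified variable sites, and counts every surviving call as a false
positive. The FDR is false calls per experiment divided by the number of
calls in the real run (0.11/90 ≈ 0.12% in the study's arithmetic); using
the corrected count instead is exposed as an option.

## Rates

`rate_report()` chains the arithmetic: corrected count
$(n_{\text{called}} - f)/r$; per-genome-per-metre (divide by total
sampled branch length); per-base-per-metre (divide by the callable
diploid genome size — the default $1.21 \times 10^9$ is back-solved so
that 3.33 mutations/genome/m corresponds to $2.75 \times 10^{-9}$/base/m,
since the callable size itself is not printed); a per-year range combining
the shortest/longest root-to-tip path with the oldest/youngest plausible
age; and a per-generation range scaling by adult height. A helper
converts another species' per-generation rate to per-metre by dividing by
its average height, for cross-species comparison.

## The synthetic generator

`simulate_dataset()` emulates the study design: a uniform random
reference; germline heterozygous sites at Bernoulli($\theta$) **and
homozygous-alternative sites at $\theta/2$** — the latter so the genome
is consistent with the genotype prior (a pseudo-reference consensus still
leaves homozygous differences; without them the ML $\hat\theta$ would be
biased to $\approx 2\theta/3$); somatic mutations per edge as
Poisson($2\lambda \ell G$), placed uniformly with κ-weighted alleles; a
repeat mask of non-overlapping geometric-length intervals covering 40% of
the genome by default; and per-replicate depths Poisson(10) with the same
read model the likelihood assumes (about 30× per tip over three
replicates). The default tree has eight tips and 14 edges, 90.1 m of
total branch, root-to-tip paths spanning 8.4–20.3 m, and the
herbivory-relevant clade {M1, M2, M3} under edge B→C; the individual edge
lengths are otherwise a documented choice, since only those aggregate
constraints are known.

What the generator deliberately omits: repeat-like sequence content and
alignment error, indels, structural variation, base-quality variation,
GC-coverage bias and fragment-level phasing information. Passing tests on
synthetic data therefore demonstrate the correctness of the likelihood,
filters and bookkeeping — not robustness to mapping artefacts, which is
what the real study's repeat-region attrition reflects.

## Numerical and design choices

* All likelihoods in log space; pruning vectorised across sites with
  per-chunk processing (`chunk_size`, default $10^5$) to bound memory.
* `call_mutations()` pre-screens sites, requiring some replicate to carry
  ≥ 2 reads of one non-reference base before exact scoring; sites failing
  the screen cannot approach production DNP thresholds. The screen is off
  when the DNP threshold is 0, so "threshold 0 → every site is a
  candidate" holds exactly.
* Spike plans accept a `min_spacing` argument (default 0, i.e. uniform
  draws as in the study, whose density — 14 000 sites on a ~500 Mb
  genome — makes sub-kilobase spike collisions rare). At desk-scale
  genome sizes the same count of uniform spikes would mostly fall within
  the 1000-nt proximity window of one another, so the clean-data
  calibration uses spacing 2000 to measure caller power rather than an
  artefact of compressed spike density.
* Problem sizes used by the bundled checks, chosen to keep a desk-scale
  run meaningful: a 1 Mb genome with ~100 planted mutations for the
  end-to-end positive control (the study-scale density of 300 expected
  mutations is the generator default); 5000 neutral sites for parameter
  recovery; 56 spaced spikes on 300 kb for the recovery calibration; ten
  replicate-label permutations on 100 kb for the false-discovery loop.
* Internal coordinates are 1-based inclusive (VCF convention); BED masks
  are converted at the I/O boundary and nowhere else.

## Limitations

The caller consumes pileup counts, not alignments: mapping quality,
strand bias and indel realignment are upstream concerns. Multi-allelic
somatic calls and indels are out of scope. The per-branch attribution
assumes at most one mutation per site on the tree; under extreme
$\lambda$ that assumption, and the DNP/branch-posterior decomposition
built on it, would understate multiple hits. ExcessHet assumes replicate
samples are exchangeable under Hardy–Weinberg at artefact sites, which is
a heuristic (replicates of one tip are not independent individuals) — it
is used exactly as the study used it, as a conservative artefact screen.
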