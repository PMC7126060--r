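# Mutation-rate arithmetic ------------------------------------------------------

#' Correct a call count for false positives and recovery
#'
#' `n_true = (n_called - f) / r`: subtract the expected number of false
#' positives per experiment and divide by the pipeline recovery rate.
#'
#' @param n_called Number of filtered calls.
#' @param f Expected false-positive calls per experiment.
#' @param r Recovery rate in (0, 1].
#' @return List: `n_true` (raw) and `n_true_rounded`.
#' @export
corrected_count <- function(n_called, f, r) {
  if (r <= 0 || r > 1) stop("recovery rate must be in (0, 1]")
  if (f > n_called) stop("false-positive expectation exceeds the call count")
  n <- (n_called - f) / r
  list(n_true = n, n_true_rounded = round(n))
}

#' Per-metre mutation rates
#'
#' @param n_true Corrected mutation count.
#' @param total_m Total sampled physical branch length, metres.
#' @param diploid_bases Callable diploid genome size in bases. The default
#'   1.21e9 is back-solved from the study's printed per-genome and
#'   per-base rates (the callable size itself is not printed).
#' @return List: `per_genome_per_metre`, `per_base_per_metre`.
#' @export
per_metre_rates <- function(n_true, total_m, diploid_bases = 1.21e9) {
  if (total_m <= 0 || diploid_bases <= 0) stop("denominators must be positive")
  pg <- n_true / total_m
  list(per_genome_per_metre = pg, per_base_per_metre = pg / diploid_bases)
}

#' Per-year mutation-rate range for a single apical meristem
#'
#' Bounds the per-base per-year rate by combining the extremes of the
#' root-to-tip physical path lengths with the extremes of the plant's age:
#' low = shortest path x rate / oldest age, high = longest path x rate /
#' youngest age.
#'
#' @param per_base_per_metre Per-base per-metre rate.
#' @param tip_min_m,tip_max_m Root-to-tip physical path range, metres.
#' @param age_min_yr,age_max_yr Age range, years.
#' @return Numeric `c(low, high)`.
#' @export
per_year_range <- function(per_base_per_metre, tip_min_m, tip_max_m,
                           age_min_yr, age_max_yr) {
  if (age_min_yr <= 0 || age_max_yr <= 0) stop("ages must be positive")
  stopifnot(tip_min_m <= tip_max_m, age_min_yr <= age_max_yr)
  c(low = tip_min_m * per_base_per_metre / age_max_yr,
    high = tip_max_m * per_base_per_metre / age_min_yr)
}

#' Per-generation mutation-rate range
#'
#' Assumes a seed is produced from a branch that has grown the adult
#' height of the species, so the heritable per-generation rate is height
#' times the per-metre rate.
#'
#' @param per_base_per_metre Per-base per-metre rate.
#' @param height_min_m,height_max_m Adult height range, metres.
#' @return Numeric `c(low, high)`.
#' @export
per_generation_range <- function(per_base_per_metre, height_min_m,
                                 height_max_m) {
  if (height_min_m <= 0 || height_max_m <= 0)
    stop("heights must be positive")
  stopifnot(height_min_m <= height_max_m)
  c(low = height_min_m * per_base_per_metre,
    high = height_max_m * per_base_per_metre)
}

#' Convert a per-generation rate to a per-metre rate for cross-species
#' comparison
#'
#' @param per_generation_rate Per-base per-generation mutation rate.
#' @param height_m Average height of the studied individuals, metres.
#' @return Per-base per-metre rate.
#' @export
cross_species_per_metre <- function(per_generation_rate, height_m) {
  if (height_m <= 0) stop("height must be positive")
  per_generation_rate / height_m
}

#' Inputs for the full rate calculation
#'
#' Defaults describe the sequenced yellow-box eucalypt study system:
#' 90 filtered calls, 0.11 false positives per experiment, recovery
#' 0.2995, 90.1 m of sampled branch, tip paths 8.4-20.3 m, age 50-200
#' years, adult height 15-30 m.
#'
#' @param n_called,fp_per_experiment,recovery_rate,total_branch_length_m
#'   See [corrected_count()] and [per_metre_rates()].
#' @param diploid_callable_bases Callable diploid genome size (back-solved
#'   default, see [per_metre_rates()]).
#' @param tip_path_range_m,age_range_yr,generation_height_range_m Ordered
#'   length-2 ranges.
#' @return List of class `rate_inputs`.
#' @export
rate_inputs <- function(n_called = 90, fp_per_experiment = 0.11,
                        recovery_rate = 0.2995,
                        total_branch_length_m = 90.1,
                        diploid_callable_bases = 1.21e9,
                        tip_path_range_m = c(8.4, 20.3),
                        age_range_yr = c(50, 200),
                        generation_height_range_m = c(15, 30)) {
  stopifnot(recovery_rate > 0, recovery_rate <= 1,
            total_branch_length_m > 0,
            diff(tip_path_range_m) >= 0, diff(age_range_yr) >= 0,
            diff(generation_height_range_m) >= 0)
  structure(list(n_called = n_called, fp_per_experiment = fp_per_experiment,
                 recovery_rate = recovery_rate,
                 total_branch_length_m = total_branch_length_m,
                 diploid_callable_bases = diploid_callable_bases,
                 tip_path_range_m = tip_path_range_m,
                 age_range_yr = age_range_yr,
                 generation_height_range_m = generation_height_range_m),
            class = "rate_inputs")
}

#' Full mutation-rate report
#'
#' Chains the correction and scaling arithmetic: corrected count, per-metre
#' rates, per-year range and per-generation range, echoing the inputs.
#'
#' @param inputs A [rate_inputs()] object.
#' @return List of class `rate_estimate` with `inputs`, `n_true`,
#'   `n_true_rounded`, `per_genome_per_metre`, `per_base_per_metre`,
#'   `per_base_per_year_range`, `per_generation_range`.
#' @export
rate_report <- function(inputs = rate_inputs()) {
  cc <- corrected_count(inputs$n_called, inputs$fp_per_experiment,
                        inputs$recovery_rate)
  pm <- per_metre_rates(cc$n_true, inputs$total_branch_length_m,
                        inputs$diploid_callable_bases)
  py <- per_year_range(pm$per_base_per_metre, inputs$tip_path_range_m[1],
                       inputs$tip_path_range_m[2], inputs$age_range_yr[1],
                       inputs$age_range_yr[2])
  pg <- per_generation_range(pm$per_base_per_metre,
                             inputs$generation_height_range_m[1],
                             inputs$generation_height_range_m[2])
  structure(list(inputs = inputs, n_true = cc$n_true,
                 n_true_rounded = cc$n_true_rounded,
                 per_genome_per_metre = pm$per_genome_per_metre,
                 per_base_per_metre = pm$per_base_per_metre,
                 per_base_per_year_range = py,
                 per_generation_range = pg), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("somatic mutation rate estimate\n")
  cat(sprintf("  corrected count        %.2f (~%d)\n", x$n_true,
              x$n_true_rounded))
  cat(sprintf("  per genome per metre   %.2f\n", x$per_genome_per_metre))
  cat(sprintf("  per base per metre     %.3g\n", x$per_base_per_metre))
  cat(sprintf("  per base per year      %.3g - %.3g\n",
              x$per_base_per_year_range[1], x$per_base_per_year_range[2]))
  cat(sprintf("  per generation         %.3g - %.3g\n",
              x$per_generation_range[1], x$per_generation_range[2]))
  invisible(x)
}
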