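# Format readers and writers ---------------------------------------------------
#
# Internal coordinates are 1-based inclusive (VCF convention). BED input is
# 0-based half-open and is converted at this boundary, in both directions.

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings for the reference genome.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA I/O")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read/write pileup tables
#'
#' TSV with columns `chrom`, `pos`, `ref`, then four columns
#' `<replicate>.A/.C/.G/.T` per replicate sample.
#'
#' @param pileup A [site_pileup()].
#' @param path File path.
#' @param samples Optional replicate table (`replicate`, `leaf`); when
#'   `NULL`, leaves are inferred by stripping the final `.suffix` from
#'   replicate names.
#' @return `read_pileup_tsv`: a [site_pileup()].
#' @export
write_pileup_tsv <- function(pileup, path) {
  df <- data.table::data.table(chrom = pileup$chrom, pos = pileup$pos,
                               ref = pileup$ref)
  cn <- colnames(pileup$counts)
  df <- cbind(df, data.table::as.data.table(pileup$counts))
  data.table::setnames(df, c("chrom", "pos", "ref", cn))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path, samples = NULL) {
  df <- data.table::fread(path, sep = "\t")
  cn <- names(df)[-(1:3)]
  reps <- unique(sub("\\.[ACGT]$", "", cn))
  if (is.null(samples))
    samples <- data.frame(replicate = reps,
                          leaf = sub("\\.[^.]*$", "", reps),
                          stringsAsFactors = FALSE)
  want <- paste(rep(samples$replicate, each = 4), BASES, sep = ".")
  if (!all(want %in% cn))
    stop("pileup file is missing expected count columns")
  counts <- as.matrix(df[, want, with = FALSE])
  storage.mode(counts) <- "integer"
  site_pileup(df$chrom, df$pos, df$ref, counts, samples)
}

#' Read/write a repeat mask as BED
#'
#' BED is 0-based half-open on disk; in memory intervals are 1-based
#' inclusive (`start`, `end`).
#'
#' @param path File path.
#' @param mask `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return `read_bed_mask`: `data.frame` with 1-based inclusive `start`,
#'   `end`.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$start <- df$start + 1L   # 0-based half-open -> 1-based inclusive
  df
}

#' @rdname read_bed_mask
#' @export
write_bed_mask <- function(mask, path) {
  df <- data.frame(chrom = mask$chrom, start = mask$start - 1L,
                   end = mask$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Minimal VCF 4.2 writer/reader -------------------------------------------------

vcf_header <- function(info_lines) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=phylomut-%s",
            as.character(utils::packageVersion("phylomut"))),
    info_lines,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

write_simple_vcf <- function(df, path, info_lines = character()) {
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", df$chrom, df$pos, df$ref,
                  df$alt, df$info)
  writeLines(c(vcf_header(info_lines), body), path)
  invisible(path)
}

#' Write somatic mutation calls as VCF 4.2
#'
#' INFO carries `DNP`, `LLD` (full precision) and `BRANCH` (the assigned
#' physical branch).
#'
#' @param calls A [call_mutations()] result or its `calls` data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_calls_vcf <- function(calls, path) {
  df <- if (inherits(calls, "mutation_calls")) calls$calls else calls
  info <- sprintf("DNP=%.17g;LLD=%.17g;BRANCH=%s", df$dnp, df$lld,
                  df$branch)
  write_simple_vcf(
    data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               info = info),
    path,
    info_lines = c(
      '##INFO=<ID=DNP,Number=1,Type=Float,Description="De novo mutation probability">',
      '##INFO=<ID=LLD,Number=1,Type=Float,Description="Scaled data log-likelihood">',
      '##INFO=<ID=BRANCH,Number=1,Type=String,Description="Assigned physical branch">'))
}

#' Write heterozygous sites as VCF 4.2
#'
#' @param het_sites The `het_sites` data.frame of [call_mutations()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_het_vcf <- function(het_sites, path) {
  alt <- vapply(seq_len(nrow(het_sites)), function(i) {
    al <- setdiff(strsplit(het_sites$genotype[i], "")[[1]],
                  het_sites$ref[i])
    if (length(al)) paste(al, collapse = ",") else "."
  }, "")
  write_simple_vcf(
    data.frame(chrom = het_sites$chrom, pos = het_sites$pos,
               ref = het_sites$ref, alt = alt,
               info = paste0("GT=", het_sites$genotype)),
    path,
    info_lines = '##INFO=<ID=GT,Number=1,Type=String,Description="Root MAP genotype">')
}

#' Read a VCF written by this package
#'
#' Minimal parser for the single-sample, INFO-only VCFs the package
#' writes; INFO keys become columns (numeric where possible).
#'
#' @param path File path.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt` and one column
#'   per INFO key.
#' @export
read_simple_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  f <- strsplit(body, "\t")
  bad <- which(vapply(f, length, 1L) < 8)
  if (length(bad))
    stop("malformed VCF record at data line ", bad[1])
  df <- data.frame(chrom = vapply(f, `[`, "", 1),
                   pos = as.integer(vapply(f, `[`, "", 2)),
                   ref = vapply(f, `[`, "", 4),
                   alt = vapply(f, `[`, "", 5), stringsAsFactors = FALSE)
  info <- strsplit(vapply(f, `[`, "", 8), ";")
  keys <- unique(unlist(lapply(info, function(kv) sub("=.*", "", kv))))
  for (k in keys) {
    v <- vapply(info, function(kv) {
      hit <- kv[startsWith(kv, paste0(k, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, "")
    num <- suppressWarnings(as.numeric(v))
    df[[tolower(k)]] <- if (all(is.na(num) == is.na(v))) num else v
  }
  df
}

#' Convert a BAM file to a site pileup
#'
#' Standard pileup semantics via Rsamtools: per-replicate A/C/G/T counts
#' at the requested positions, minimum base and mapping quality
#' configurable. One BAM per replicate sample.
#'
#' @param bam_paths Named character vector: replicate id -> BAM path.
#' @param samples Replicate table (`replicate`, `leaf`).
#' @param reference Named character vector of reference sequences (for
#'   ref alleles).
#' @param which Optional `GRanges` restriction.
#' @param min_base_quality,min_mapq Quality cutoffs.
#' @return A [site_pileup()].
#' @export
pileup_from_bam <- function(bam_paths, samples, reference, which = NULL,
                            min_base_quality = 13, min_mapq = 0) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for BAM input")
  pparam <- Rsamtools::PileupParam(min_base_quality = min_base_quality,
                                   min_mapq = min_mapq,
                                   distinguish_strands = FALSE,
                                   max_depth = 10000)
  sparam <- if (is.null(which)) Rsamtools::ScanBamParam() else
    Rsamtools::ScanBamParam(which = which)
  tabs <- lapply(bam_paths, function(p)
    Rsamtools::pileup(p, scanBamParam = sparam, pileupParam = pparam))
  keys <- unique(do.call(rbind, lapply(tabs, function(t)
    data.frame(chrom = as.character(t$seqnames), pos = t$pos))))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  n <- nrow(keys)
  counts <- matrix(0L, n, 4 * nrow(samples))
  for (i in seq_along(tabs)) {
    t <- tabs[[i]]
    r <- match(names(bam_paths)[i], samples$replicate)
    j <- match(paste(t$seqnames, t$pos), paste(keys$chrom, keys$pos))
    b <- match(as.character(t$nucleotide), BASES)
    ok <- !is.na(b)
    idx <- cbind(j[ok], 4L * (r - 1L) + b[ok])
    for (row in which(ok))
      counts[j[row], 4L * (r - 1L) + b[row]] <-
        counts[j[row], 4L * (r - 1L) + b[row]] + t$count[row]
  }
  ref <- substring(reference[keys$chrom], keys$pos, keys$pos)
  site_pileup(keys$chrom, keys$pos, ref, counts, samples)
}

#' Read a YAML run configuration
#'
#' Fills in default thresholds (`dnp = 0.99999`, `lld = -5`) and seed when
#' absent.
#'
#' @param path YAML file path.
#' @return List with at least `thresholds` and `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$thresholds)) cfg$thresholds <- list()
  if (is.null(cfg$thresholds$dnp)) cfg$thresholds$dnp <- 0.99999
  if (is.null(cfg$thresholds$lld)) cfg$thresholds$lld <- -5
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}
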