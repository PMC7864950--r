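# Readers/writers for pooled allele counts (minimal VCF with DP/AD INFO
# fields, and TSV) and for simulation truth tables used as test oracles.

#' Write pool counts as a minimal VCF
#'
#' One record per site with `INFO DP=<depth>;AD=<alt_count>`. This is the
#' distilled form of a pooled variant call (the information a pooled caller's
#' AD field carries) and round-trips through [read_pool_vcf()].
#'
#' @param counts Pool-counts data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(counts, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nodmap",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Pooled alt allele depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AD=%d",
                  counts$chrom, counts$pos, counts$ref, counts$alt,
                  counts$depth, counts$alt_count)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read pool counts from a VCF
#'
#' Accepts the minimal VCF written by [write_pool_vcf()] (INFO `DP`/`AD`) or
#' any VCF carrying a per-sample `AD` field (ref,alt allele depths) for a
#' single pooled sample, e.g. a pooled-discrete caller's output. Parsing is
#' done with [vcfR::read.vcfR()].
#'
#' @param path Path to a VCF file.
#' @param sample For multi-sample VCFs with FORMAT AD, which sample column to
#'   use (default 1).
#' @return A pool-counts data frame (`chrom, pos, ref, alt, alt_count, depth`).
#' @export
read_pool_vcf <- function(path, sample = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  has_gt <- ncol(v@gt) >= 2L
  if (has_gt && "AD" %in% unlist(strsplit(v@gt[1L, "FORMAT"], ":"))) {
    ad <- vcfR::extract.gt(v, element = "AD")[, sample]
    parts <- strsplit(ad, ",")
    ref_d <- as.integer(vapply(parts, `[`, character(1L), 1L))
    alt_d <- as.integer(vapply(parts, `[`, character(1L), 2L))
    depth <- ref_d + alt_d
    alt_count <- alt_d
  } else {
    depth <- as.integer(vcfR::extract.info(v, element = "DP"))
    alt_count <- as.integer(vcfR::extract.info(v, element = "AD"))
  }
  if (anyNA(depth) || anyNA(alt_count)) {
    stop("VCF lacks usable DP/AD depth information: ", path)
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, alt_count = alt_count, depth = depth,
             stringsAsFactors = FALSE)
}

#' Write/read pool counts as TSV
#'
#' @param counts Pool-counts data frame.
#' @param path File path.
#' @return `path` (write) or the counts data frame (read).
#' @export
write_pool_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", ref = "character",
                                   alt = "character"))
}

#' Write a simulation truth table
#'
#' Per-variant truth (chrom, pos, ref, alt, causal flag, recombination
#' fraction from the causal locus) as TSV, for use as an external oracle.
#'
#' @param variants Variant data frame with a single causal row.
#' @param phys_lengths,genetic_lengths Passed to [recombination_fractions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(variants, phys_lengths, path, genetic_lengths = NULL) {
  truth <- variants
  truth$r <- recombination_fractions(variants, phys_lengths, genetic_lengths)
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
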