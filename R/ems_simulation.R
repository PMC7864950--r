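# EMS mutagenesis, backcross/F2 meiosis under the Haldane map, phenotypic pool
# selection, and pooled allele-count sequencing. This is the generative model
# the mapping analysis is tested against: a mutant line homozygous for
# genome-wide G:C->A:T transitions and one recessive causal lesion, crossed to
# wild type, selfed, and its non-nodulating F2 quarter pooled and sequenced.

#' EMS mutagenesis configuration
#'
#' @param mutation_rate Expected induced SNPs per Mb (default 5). The realized
#'   genome-wide density of an EMS screen depends on dose and is treated as a
#'   tunable; 5/Mb is a typical plant EMS figure.
#' @param spectrum_fraction Fraction of mutations that are G:C->A:T transitions
#'   (default 1: the canonical EMS spectrum).
#' @param seed Optional integer seed.
#' @return A list of class `ems_config`.
#' @export
ems_config <- function(mutation_rate = 5, spectrum_fraction = 1, seed = NULL) {
  stopifnot(mutation_rate >= 0, spectrum_fraction >= 0, spectrum_fraction <= 1)
  structure(list(mutation_rate = mutation_rate,
                 spectrum_fraction = spectrum_fraction, seed = seed),
            class = "ems_config")
}

#' Backcross/F2 configuration
#'
#' @param genetic_lengths Named numeric vector, genetic length in cM per
#'   chromosome (default 100 cM each; names must match the genome's).
#'   `NULL` means "100 cM for every chromosome encountered".
#' @param pool_size Number of phenotype-selected F2 plants pooled (default 110,
#'   the midpoint of the 100-120 plants pooled per mutant in the study design
#'   this emulates).
#' @param seed Optional integer seed.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(genetic_lengths = NULL, pool_size = 110L, seed = NULL) {
  stopifnot(is.null(genetic_lengths) || all(genetic_lengths > 0), pool_size >= 1)
  structure(list(genetic_lengths = genetic_lengths,
                 pool_size = as.integer(pool_size), seed = seed),
            class = "cross_config")
}

#' Pooled sequencing configuration
#'
#' @param mean_depth Mean read depth per site; realized depths are
#'   Poisson(`mean_depth`) (default 50).
#' @param error_rate Per-base substitution probability: with this probability a
#'   read's base is replaced by one of the three other bases uniformly
#'   (default 0, so a fixed mutant pool yields an index of exactly 1).
#' @param seed Optional integer seed.
#' @return A list of class `sequencing_config`.
#' @export
sequencing_config <- function(mean_depth = 50, error_rate = 0, seed = NULL) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, error_rate = error_rate, seed = seed),
            class = "sequencing_config")
}

#' Draw genome-wide EMS mutations
#'
#' The number of mutations is Poisson with mean `mutation_rate` x genome size
#' in Mb. A `spectrum_fraction` share of them are G:C->A:T transitions placed
#' uniformly over G/C sites (G->A, C->T); the remainder are uniform random
#' substitutions at uniform positions. Positions are unique and never fall on
#' N bases.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param config An [ems_config()].
#' @return A variant data frame (see [ems_variants()]), `causal = FALSE`.
#' @export
draw_ems_mutations <- function(genome, config = ems_config()) {
  genome <- validate_genome(genome)
  if (!is.null(config$seed)) set.seed(config$seed)
  lens <- chrom_lengths(genome)
  n_total <- stats::rpois(1L, config$mutation_rate * sum(lens) / 1e6)
  if (n_total == 0L) {
    return(ems_variants(character(0), integer(0), character(0), character(0)))
  }
  n_ems <- stats::rbinom(1L, n_total, config$spectrum_fraction)
  seqs <- vapply(names(lens), function(ch) as.character(genome[[ch]]), character(1L))
  if (n_ems > 0L && sum(Biostrings::letterFrequency(genome, "GC")) == 0L) {
    stop("genome has no G/C bases; cannot draw EMS-spectrum mutations")
  }
  draw_sites <- function(n, eligible_base) {
    out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0))
    while (nrow(out) < n) {
      k <- max(2L * (n - nrow(out)), 16L)
      ch <- sample(names(lens), k, replace = TRUE, prob = lens)
      pos <- floor(stats::runif(k, 1, lens[ch] + 1))
      ref <- substring(seqs[ch], pos, pos)
      keep <- eligible_base(ref)
      out <- unique(rbind(out, data.frame(chrom = ch[keep], pos = as.integer(pos[keep]),
                                          ref = ref[keep])))
    }
    out[seq_len(n), , drop = FALSE]
  }
  ems <- draw_sites(n_ems, function(b) b %in% c("G", "C"))
  ems$alt <- ifelse(ems$ref == "G", "A", "T")
  other <- draw_sites(n_total - n_ems, function(b) b %in% c("A", "C", "G", "T"))
  if (nrow(other)) {
    other$alt <- vapply(other$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1L))
  }
  all <- rbind(ems, other)
  all <- all[!duplicated(all[, c("chrom", "pos")]), , drop = FALSE]
  ems_variants(all$chrom, all$pos, all$ref, all$alt, causal = FALSE)
}

#' Place the recessive causal variant in a gene
#'
#' Returns a single causal EMS-type variant inside `model`:
#' \describe{
#'   \item{`splice_donor`}{the first base of the first intron whose donor
#'     dinucleotide is canonical `GT` on the coding strand, mutated G->A
#'     (genomically G->A on plus-strand genes, C->T on minus-strand genes) --
#'     the canonical splice-boundary lesion.}
#'   \item{`missense`}{the first CDS position whose EMS transition (coding-strand
#'     G->A or C->T) changes the encoded amino acid without creating a stop.}
#' }
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param model A coding [gene_model()].
#' @param site_class `"splice_donor"` or `"missense"`.
#' @param skip Skip the first `skip` eligible sites (distinct alleles of one
#'   gene can be generated by increasing `skip`).
#' @return A one-row variant data frame with `causal = TRUE`.
#' @export
place_causal_variant <- function(genome, model,
                                 site_class = c("splice_donor", "missense"),
                                 skip = 0L) {
  site_class <- match.arg(site_class)
  chr_seq <- as.character(genome[[model$chromosome]])
  n_skipped <- 0L
  if (site_class == "splice_donor") {
    ivs <- introns(model)
    if (nrow(ivs) == 0L) stop("splice_donor requires a gene with >= 2 exons")
    iv_order <- if (model$strand == "+") seq_len(nrow(ivs)) else rev(seq_len(nrow(ivs)))
    for (i in iv_order) {
      if (model$strand == "+") {
        donor_pos <- ivs[i, 1L]
        hit <- substring(chr_seq, donor_pos, donor_pos + 1L) == "GT"
        ref <- "G"; alt <- "A"
      } else {
        donor_pos <- ivs[i, 2L]  # coding-strand intron base 1
        hit <- revcomp(substring(chr_seq, donor_pos - 1L, donor_pos)) == "GT"
        ref <- "C"; alt <- "T"
      }
      if (hit) {
        if (n_skipped < skip) { n_skipped <- n_skipped + 1L; next }
        return(ems_variants(model$chromosome, donor_pos, ref, alt, causal = TRUE))
      }
    }
    stop("no canonical GT donor with a mutable G in gene ", model$gene_id)
  }
  # missense: scan CDS positions in transcription order
  cds <- extract_cds(genome, model)
  if (!model$coding || nchar(cds) == 0L) stop("missense requires a coding gene model")
  gpos <- cds_genomic_positions(model)
  bases <- strsplit(cds, "")[[1L]]
  prot <- translate_cds(cds)
  for (i in seq_along(bases)) {
    if (!bases[i] %in% c("G", "C")) next
    alt_coding <- if (bases[i] == "G") "A" else "T"
    mutant <- bases
    mutant[i] <- alt_coding
    codon_i <- (i - 1L) %/% 3L + 1L
    aa_ref <- substring(prot, codon_i, codon_i)
    aa_alt <- translate_cds(paste(mutant[(3L * codon_i - 2L):(3L * codon_i)], collapse = ""))
    if (aa_alt != aa_ref && aa_alt != "*" && !(codon_i == 1L)) {
      if (n_skipped < skip) { n_skipped <- n_skipped + 1L; next }
      ref_g <- if (model$strand == "+") bases[i] else comp_base(bases[i])
      alt_g <- if (model$strand == "+") alt_coding else comp_base(alt_coding)
      return(ems_variants(model$chromosome, gpos[i], ref_g, alt_g, causal = TRUE))
    }
  }
  stop("no EMS-mutable missense site in gene ", model$gene_id)
}

#' Place EMS SNPs tightly linked to a gene
#'
#' Draws `n` additional G:C->A:T variants from the G/C sites in the `flank_bp`
#' windows immediately up- and downstream of the gene body (outside it), i.e.
#' in near-complete linkage with a lesion inside the gene. These emulate the
#' mutant line's EMS lesions in the immediate neighbourhood of the causal gene
#' that make the linkage cluster visible.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param model The causal [gene_model()].
#' @param n Number of linked SNPs (default 6).
#' @param flank_bp Width of each flanking window (default 500).
#' @param seed Optional integer seed.
#' @return A variant data frame, `causal = FALSE`.
#' @export
place_linked_snps <- function(genome, model, n = 6L, flank_bp = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- gene_span(model)
  chr_seq <- as.character(genome[[model$chromosome]])
  lo <- max(1L, span[1L] - flank_bp):(span[1L] - 1L)
  hi <- (span[2L] + 1L):min(nchar(chr_seq), span[2L] + flank_bp)
  cand <- c(lo, hi)
  base <- substring(chr_seq, cand, cand)
  cand <- cand[base %in% c("G", "C")]
  if (length(cand) < n) stop("not enough G/C sites flanking ", model$gene_id)
  pos <- sort(sample(cand, n))
  ref <- substring(chr_seq, pos, pos)
  ems_variants(model$chromosome, pos, ref, ifelse(ref == "G", "A", "T"))
}

#' Haldane map function and its inverse
#'
#' Under the Haldane (no-interference) model, a genetic distance of `d` cM
#' corresponds to a recombination fraction `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d_cM Genetic distance in centimorgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' @rdname haldane_r
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Genetic distance in cM.
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * r)

genetic_positions <- function(variants, phys_lengths, genetic_lengths = NULL) {
  if (is.null(genetic_lengths)) {
    genetic_lengths <- stats::setNames(rep(100, length(phys_lengths)), names(phys_lengths))
  }
  missing <- setdiff(unique(variants$chrom), names(genetic_lengths))
  if (length(missing)) stop("no genetic length for chromosome(s): ",
                            paste(missing, collapse = ", "))
  variants$pos / phys_lengths[variants$chrom] * genetic_lengths[variants$chrom]
}

#' Simulate selfed backcross-F2 genotypes
#'
#' The mutant line is homozygous alt at every variant, the wild-type parent
#' homozygous ref, so the F1 is uniformly heterozygous with all alt alleles in
#' coupling on one haplotype. Each F2 plant is formed from two independent F1
#' gametes; per chromosome, a gamete's crossover count is Poisson with mean
#' (genetic length)/100 Morgans and breakpoints are uniform (Haldane model, no
#' interference). Variants are mapped to genetic positions by linear scaling of
#' their physical position to the chromosome's cM length.
#'
#' @param variants A variant data frame (sorted; see [ems_variants()]).
#' @param phys_lengths Named vector of chromosome physical lengths in bp.
#' @param n_plants Number of F2 plants.
#' @param cross A [cross_config()].
#' @return Integer matrix `n_plants` x `nrow(variants)` of alt-allele copy
#'   numbers (0/1/2); columns in `variants` order.
#' @export
simulate_f2_plants <- function(variants, phys_lengths, n_plants,
                               cross = cross_config()) {
  if (!is.null(cross$seed)) set.seed(cross$seed)
  stopifnot(n_plants >= 1)
  m <- nrow(variants)
  gl <- cross$genetic_lengths
  if (is.null(gl)) gl <- stats::setNames(rep(100, length(phys_lengths)), names(phys_lengths))
  g_cM <- genetic_positions(variants, phys_lengths, gl)
  n_gam <- 2L * n_plants
  gam <- matrix(0L, nrow = n_gam, ncol = m)
  for (ch in unique(variants$chrom)) {
    cols <- which(variants$chrom == ch)
    gpos <- g_cM[cols]
    L <- gl[[ch]]
    k <- stats::rpois(n_gam, L / 100)
    start <- stats::rbinom(n_gam, 1L, 0.5)
    for (i in seq_len(n_gam)) {
      if (k[i] == 0L) {
        gam[i, cols] <- start[i]
      } else {
        bp <- sort(stats::runif(k[i], 0, L))
        gam[i, cols] <- (start[i] + findInterval(gpos, bp)) %% 2L
      }
    }
  }
  geno <- gam[seq(1L, n_gam, by = 2L), , drop = FALSE] +
    gam[seq(2L, n_gam, by = 2L), , drop = FALSE]
  colnames(geno) <- variant_key(variants)
  geno
}

#' Select the phenotyped mutant pool
#'
#' Keeps plants homozygous for the alt allele at the causal locus (the
#' recessive non-nodulating class, ~1/4 of the F2 in expectation) and samples
#' `pool_size` of them without replacement.
#'
#' @param genotypes Genotype matrix from [simulate_f2_plants()].
#' @param causal_col Column index (or key) of the causal variant.
#' @param pool_size Number of plants to pool.
#' @return Genotype matrix of the selected plants.
#' @export
select_mutant_pool <- function(genotypes, causal_col, pool_size = 110L) {
  hom <- which(genotypes[, causal_col] == 2L)
  if (length(hom) < pool_size) {
    stop("only ", length(hom), " homozygous-mutant plants; need ", pool_size,
         " (simulate a larger F2)")
  }
  genotypes[sample(hom, pool_size), , drop = FALSE]
}

#' Sample pooled sequencing allele counts
#'
#' Per site, depth is Poisson(`mean_depth`); each read samples one of the
#' pool's `2 * n` chromosome copies uniformly, and with probability
#' `error_rate` its base is replaced by one of the three other bases
#' uniformly. The observed alt probability is therefore
#' `p (1 - e) + (1 - p) e / 3` for a pool alt frequency `p`.
#'
#' @param pool Genotype matrix of the pooled plants.
#' @param variants The matching variant data frame.
#' @param config A [sequencing_config()].
#' @return A pool-counts data frame: `chrom, pos, ref, alt, alt_count, depth`.
#' @export
sample_pool_counts <- function(pool, variants, config = sequencing_config()) {
  stopifnot(nrow(pool) >= 1, ncol(pool) == nrow(variants))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- colSums(pool) / (2 * nrow(pool))
  e <- config$error_rate
  p_obs <- p * (1 - e) + (1 - p) * e / 3
  depth <- stats::rpois(length(p), config$mean_depth)
  alt <- stats::rbinom(length(p), depth, p_obs)
  data.frame(chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
             alt = variants$alt, alt_count = alt, depth = depth,
             stringsAsFactors = FALSE)
}

#' Per-variant recombination fraction from the causal locus
#'
#' `r = haldane_r(|genetic distance|)` on the causal chromosome and 0.5 on all
#' others (unlinked).
#'
#' @param variants A variant data frame containing exactly one `causal = TRUE` row.
#' @param phys_lengths Named physical chromosome lengths (bp).
#' @param genetic_lengths Named genetic lengths (cM); `NULL` = 100 cM each.
#' @return Numeric vector of recombination fractions, one per variant.
#' @export
recombination_fractions <- function(variants, phys_lengths, genetic_lengths = NULL) {
  ci <- which(variants$causal)
  if (length(ci) != 1L) stop("variants must contain exactly one causal row")
  g <- genetic_positions(variants, phys_lengths, genetic_lengths)
  r <- rep(0.5, nrow(variants))
  same <- variants$chrom == variants$chrom[ci]
  r[same] <- haldane_r(abs(g[same] - g[ci]))
  r
}
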