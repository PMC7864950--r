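# Synthetic reference genomes and planted gene models. These generators supply
# the study conditions everything downstream is exercised on: a small
# multi-chromosome genome of i.i.d. bases and a protein-coding gene with
# canonical GT..AG introns planted at a chosen location.

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with the given GC content. This deliberately ignores
#' repeat structure, composition heterogeneity and Ns; it provides exactly what
#' the pooled-mapping analysis consumes (positions and base identities).
#'
#' @param lengths Named integer vector of chromosome lengths in bp.
#' @param gc GC content (fraction, default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @return A named [Biostrings::DNAStringSet].
#' @export
random_genome <- function(lengths = c(chr1 = 5e6, chr2 = 5e6), gc = 0.5,
                          seed = NULL) {
  stopifnot(all(lengths >= 1), gc >= 0, gc <= 1, !is.null(names(lengths)))
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1L))
  validate_genome(Biostrings::DNAStringSet(seqs))
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Plant a protein-coding gene into a genome
#'
#' Constructs a coding sequence (ATG start, sense codons, TAA stop), splits it
#' into exons, joins them with canonical `GT..AG` introns, and overwrites the
#' genome at `start` with the resulting gene sequence (reverse-complemented
#' for minus-strand genes, with exon coordinates mirrored so they stay in
#' ascending genomic order). CDS intervals equal exon intervals (no UTRs).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chromosome Chromosome to plant into.
#' @param start 1-based position of the first gene base.
#' @param gene_id Identifier for the new model.
#' @param strand `"+"` or `"-"`.
#' @param exon_lengths Exon lengths in transcription order; their sum must be a
#'   multiple of 3 and at least 6.
#' @param intron_lengths Intron lengths (each >= 4), length one less than
#'   `exon_lengths`.
#' @param seed Optional integer seed.
#' @return A list with elements `genome` (modified) and `model` (a
#'   [gene_model()]).
#' @export
plant_gene <- function(genome, chromosome, start, gene_id = "gene1",
                       strand = "+", exon_lengths = c(120L, 123L),
                       intron_lengths = 90L, seed = NULL) {
  stopifnot(chromosome %in% names(genome),
            sum(exon_lengths) %% 3L == 0L, sum(exon_lengths) >= 6L,
            length(intron_lengths) == length(exon_lengths) - 1L,
            all(intron_lengths >= 4L))
  if (!is.null(seed)) set.seed(seed)
  n_codons <- sum(exon_lengths) %/% 3L
  codons <- c("ATG",
              sample(sense_codons(), n_codons - 2L, replace = TRUE),
              "TAA")
  cds_seq <- paste(codons, collapse = "")
  # split CDS into exon pieces (boundaries need not respect codon frame)
  stops <- cumsum(exon_lengths)
  starts <- c(1L, stops[-length(stops)] + 1L)
  exon_seqs <- substring(cds_seq, starts, stops)
  intron_seqs <- vapply(intron_lengths, function(L) {
    paste0("GT",
           if (L > 4L) paste(sample(c("A", "C", "G", "T"), L - 4L, replace = TRUE),
                             collapse = "") else "",
           "AG")
  }, character(1L))
  pieces <- character(0)
  for (i in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[i])
    if (i < length(exon_seqs)) pieces <- c(pieces, intron_seqs[i])
  }
  gene_seq <- paste(pieces, collapse = "")
  L <- nchar(gene_seq)
  end <- start + L - 1L
  if (start < 1L || end > length(genome[[chromosome]])) {
    stop("gene does not fit on ", chromosome)
  }
  # exon coordinates within the gene (transcription order)
  piece_len <- nchar(pieces)
  piece_end <- cumsum(piece_len)
  piece_start <- piece_end - piece_len + 1L
  is_exon <- rep(c(TRUE, FALSE), length.out = length(pieces))
  ex_local <- cbind(piece_start[is_exon], piece_end[is_exon])
  if (strand == "+") {
    insert <- gene_seq
    ex <- cbind(start + ex_local[, 1L] - 1L, start + ex_local[, 2L] - 1L)
  } else {
    insert <- revcomp(gene_seq)
    ex <- cbind(start + L - ex_local[, 2L], start + L - ex_local[, 1L])
  }
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  chr <- genome[[chromosome]]
  Biostrings::subseq(chr, start, end) <- Biostrings::DNAString(insert)
  genome[[chromosome]] <- chr
  model <- gene_model(gene_id, chromosome, strand, exons = ex, cds = ex)
  list(genome = genome, model = model)
}

#' Generate a small genome carrying one random coding gene
#'
#' Convenience wrapper used for annotation property checks: a short random
#' chromosome with one planted multi-exon gene on either strand.
#'
#' @param seed Integer seed.
#' @param strand `"+"` or `"-"` (default: random).
#' @param n_exons Number of exons (default: 1-3, random).
#' @return A list with `genome` and `model`.
#' @export
random_coding_gene <- function(seed, strand = NULL, n_exons = NULL) {
  set.seed(seed)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  if (is.null(n_exons)) n_exons <- sample(1:3, 1L)
  exon_lengths <- 3L * sample(4:12, n_exons, replace = TRUE)
  intron_lengths <- if (n_exons > 1L) sample(8:40, n_exons - 1L, replace = TRUE) else integer(0)
  total <- sum(exon_lengths) + sum(intron_lengths)
  genome <- random_genome(c(chrT = total + 200L), seed = seed + 1L)
  plant_gene(genome, "chrT", start = 101L, gene_id = sprintf("g%d", seed),
             strand = strand, exon_lengths = exon_lengths,
             intron_lengths = intron_lengths)
}
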