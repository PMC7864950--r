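# Domain types and I/O for reference genomes, gene models and EMS variants.
# All coordinates throughout the package are 1-based inclusive (the GFF3/VCF
# convention); conversions, if any, happen only inside readers/writers.

#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] with the validation the rest of the
#' pipeline relies on: record names are unique (first whitespace-delimited
#' token), sequences are non-empty, and bases are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- validate_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop("all chromosomes must be named")
  }
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  }
  if (any(Biostrings::width(genome) == 0L)) stop("empty chromosome sequence")
  bad <- Biostrings::letterFrequency(genome, letters = "ACGTN")
  if (any(rowSums(bad) != Biostrings::width(genome))) {
    stop("genome contains bases outside {A,C,G,T,N}")
  }
  genome
}

#' Chromosome lengths of a genome
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

genome_base <- function(genome, chromosome, position) {
  as.character(Biostrings::subseq(genome[[chromosome]], position, position))
}

#' Construct a gene model
#'
#' A gene model is one mRNA's exon/CDS structure: non-overlapping exons sorted
#' by genomic start, CDS intervals contained in exons, and (for protein-coding
#' models) a concatenated CDS length divisible by 3. Models whose CDS length is
#' not a multiple of 3 are kept but flagged non-coding with a warning.
#'
#' @param gene_id Identifier (one per mRNA).
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of (start, end), 1-based inclusive.
#' @param cds Two-column matrix or data.frame of CDS (start, end); may be empty.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- as_intervals(exons, "exon")
  cds <- as_intervals(cds, "CDS")
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("exons overlap or are unsorted in gene ", gene_id)
  }
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    if (!inside) {
      stop("CDS interval [", cds[i, 1L], ",", cds[i, 2L],
           "] outside exons in gene ", gene_id)
    }
  }
  cds_len <- if (nrow(cds)) sum(cds[, 2L] - cds[, 1L] + 1L) else 0L
  coding <- nrow(cds) > 0L && cds_len %% 3L == 0L
  if (nrow(cds) > 0L && cds_len %% 3L != 0L) {
    warning("CDS length of ", gene_id, " (", cds_len,
            ") is not a multiple of 3; model flagged non-coding")
  }
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         exons = exons, cds = cds, coding = coding),
    class = "gene_model"
  )
}

as_intervals <- function(x, what) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) ||
      (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  m <- as.matrix(x)
  if (ncol(m) != 2L) stop(what, " intervals must have two columns (start, end)")
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  if (any(m[, 1L] > m[, 2L])) stop(what, " interval with start > end")
  if (any(m[, 1L] < 1L)) stop(what, " interval with start < 1")
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), %d CDS interval(s)%s\n",
              x$gene_id, x$chromosome, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, nrow(x$exons), nrow(x$cds),
              if (x$coding) "" else " [non-coding]"))
  invisible(x)
}

gene_span <- function(model) {
  c(min(model$exons[, 1L]), max(model$exons[, 2L]))
}

#' Intron intervals of a gene model
#' @param model A `gene_model`.
#' @return Matrix of (start, end) intron intervals in ascending genomic order
#'   (zero rows for single-exon genes).
#' @export
introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-nrow(ex), 2L] + 1L, end = ex[-1L, 1L] - 1L)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via [rtracklayer::readGFF()]) into one [gene_model()]
#' per mRNA feature, linking exon and CDS children through their `Parent`
#' attributes. Only gene/mRNA/exon/CDS features are interpreted; other feature
#' types are skipped with a message reporting the count. CDS phases are not
#' trusted (they are recomputed on write).
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects (names are mRNA IDs).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  g <- rtracklayer::readGFF(path)
  g$type <- as.character(g$type)
  known <- c("gene", "mRNA", "exon", "CDS")
  n_other <- sum(!g$type %in% known)
  if (n_other > 0L) message("read_gff: skipped ", n_other, " non gene/mRNA/exon/CDS feature(s)")
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  if (nrow(mrna) == 0L) stop("no mRNA features in ", path)
  parents <- vapply(g$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                    character(1L))
  models <- lapply(seq_len(nrow(mrna)), function(i) {
    id <- mrna$ID[i]
    kids <- g[!is.na(parents) & parents == id, , drop = FALSE]
    gene_model(
      gene_id = id,
      chromosome = as.character(mrna$seqid[i]),
      strand = as.character(mrna$strand[i]),
      exons = kids[kids$type == "exon", c("start", "end"), drop = FALSE],
      cds = kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    )
  })
  stats::setNames(models, mrna$ID)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS lines with `Parent` links and recomputed CDS
#' phases (phase of each CDS piece in transcription order).
#'
#' @param models A list of `gene_model` objects.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path, source = "nodmap") {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- gene_span(m)
    gid <- paste0(m$gene_id, ".gene")
    lines <- c(
      lines,
      gff_line(m$chromosome, source, "gene", span[1L], span[2L], m$strand, ".",
               paste0("ID=", gid)),
      gff_line(m$chromosome, source, "mRNA", span[1L], span[2L], m$strand, ".",
               paste0("ID=", m$gene_id, ";Parent=", gid))
    )
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, gff_line(m$chromosome, source, "exon",
                                 m$exons[i, 1L], m$exons[i, 2L], m$strand, ".",
                                 paste0("Parent=", m$gene_id)))
    }
    cds <- m$cds
    if (nrow(cds)) {
      tx_order <- if (m$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
      before <- 0L
      phase <- integer(nrow(cds))
      for (j in tx_order) {
        phase[j] <- (3L - before %% 3L) %% 3L
        before <- before + (cds[j, 2L] - cds[j, 1L] + 1L)
      }
      for (i in seq_len(nrow(cds))) {
        lines <- c(lines, gff_line(m$chromosome, source, "CDS",
                                   cds[i, 1L], cds[i, 2L], m$strand, phase[i],
                                   paste0("Parent=", m$gene_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gff_line <- function(seqid, source, type, start, end, strand, phase, attrs) {
  paste(seqid, source, type, start, end, ".", strand, phase, attrs, sep = "\t")
}

#' Extract the coding sequence of a gene model
#'
#' CDS intervals are concatenated in ascending genomic order and, for
#' minus-strand genes, the concatenation is reverse-complemented as a whole, so
#' the returned string always reads in transcription order.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param model A `gene_model`.
#' @return The CDS as an upper-case character string.
#' @export
extract_cds <- function(genome, model) {
  if (!model$chromosome %in% names(genome)) {
    stop("chromosome ", model$chromosome, " not in genome")
  }
  chr <- genome[[model$chromosome]]
  if (nrow(model$cds) == 0L) return("")
  if (max(model$cds[, 2L]) > length(chr)) {
    stop("CDS coordinates outside chromosome ", model$chromosome)
  }
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    as.character(Biostrings::subseq(chr, model$cds[i, 1L], model$cds[i, 2L]))
  }, character(1L))
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Reverse-complement a DNA string
#' @param x A character string over the DNA alphabet.
#' @return Its reverse complement.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct an EMS variant table
#'
#' Variants are plain data frames with columns `chrom`, `pos`, `ref`, `alt`
#' and `causal`; this helper validates and normalizes one.
#'
#' @param chrom,pos,ref,alt,causal Vectors of equal length (causal defaults to
#'   `FALSE`).
#' @return A `data.frame` of variants.
#' @export
ems_variants <- function(chrom, pos, ref, alt, causal = FALSE) {
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  causal = rep_len(as.logical(causal), length(chrom)),
                  stringsAsFactors = FALSE)
  if (any(v$ref == v$alt)) stop("variant with ref == alt")
  if (!all(v$ref %in% c("A", "C", "G", "T")) || !all(v$alt %in% c("A", "C", "G", "T"))) {
    stop("variant alleles must be single A/C/G/T bases")
  }
  v[order(v$chrom, v$pos), , drop = FALSE]
}

#' Check variants against a reference genome
#'
#' Verifies that each variant's `ref` allele matches the genome base at its
#' position (and that no variant sits on an N base).
#'
#' @param variants A variant data frame (see [ems_variants()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @return `variants`, invisibly; errors on mismatch.
#' @export
validate_variants <- function(variants, genome) {
  for (chr in unique(variants$chrom)) {
    if (!chr %in% names(genome)) stop("variant chromosome ", chr, " not in genome")
    idx <- variants$chrom == chr
    pos <- variants$pos[idx]
    if (any(pos < 1L | pos > length(genome[[chr]]))) {
      stop("variant position outside chromosome ", chr)
    }
    s <- as.character(genome[[chr]])
    obs <- substring(s, pos, pos)
    if (any(obs != variants$ref[idx])) {
      stop("variant ref allele mismatch on ", chr)
    }
  }
  invisible(variants)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Is a substitution EMS-type?
#'
#' EMS (ethyl methane sulfonate) alkylates guanine and induces G:C->A:T
#' transitions, i.e. G->A on one strand or C->T on the other.
#'
#' @param ref,alt Single-base allele vectors.
#' @return Logical vector.
#' @export
is_ems_type <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}
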