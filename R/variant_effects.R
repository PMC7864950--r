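# Gene-model-aware annotation of candidate EMS SNPs: splice-boundary
# disruption, missense/nonsense/synonymous coding changes, intronic and
# intergenic calls, with protein-change notation and a severity ordering used
# to rank candidate mutations.

EFFECT_SEVERITY <- c(intergenic = 1L, intronic = 2L, synonymous = 3L,
                     missense = 4L, start_loss = 5L, nonsense = 5L,
                     splice_site = 5L)

#' Effect severity ranks
#'
#' Integer severity of each effect class: splice_site, nonsense and start_loss
#' (5) > missense (4) > synonymous (3) > intronic (2) > intergenic (1).
#'
#' @return Named integer vector.
#' @export
effect_severity <- function() EFFECT_SEVERITY

#' Translate a coding sequence
#'
#' Standard genetic code, one letter per codon, stop rendered `"*"`. The codon
#' table is `Biostrings::GENETIC_CODE`; the codon walk is done here so the
#' annotator controls frame and stop handling explicitly.
#'
#' @param cds A DNA string whose length is a multiple of 3 (ACGT only).
#' @param to_first_stop If `TRUE`, truncate the translation at the first stop.
#' @return The protein string (`""` for empty input).
#' @export
translate_cds <- function(cds, to_first_stop = FALSE) {
  n <- nchar(cds)
  if (n == 0L) return("")
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (to_first_stop) {
    s <- which(aa == "*")
    if (length(s)) aa <- aa[seq_len(s[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# Genomic positions of CDS bases in transcription order (reversed for minus
# strand, so element i is the genomic position of CDS base i).
cds_genomic_positions <- function(model) {
  if (nrow(model$cds) == 0L) return(integer(0))
  gpos <- unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    seq.int(model$cds[i, 1L], model$cds[i, 2L])
  }))
  if (model$strand == "-") gpos <- rev(gpos)
  gpos
}

#' Does a variant hit a canonical splice dinucleotide?
#'
#' `TRUE` iff the position falls in the first 2 or last 2 bases of any intron
#' of the model -- the canonical donor (GT) and acceptor (AG) dinucleotides.
#' The check is positional; it does not require the reference bases to be
#' canonical.
#'
#' @param variant A one-row variant data frame.
#' @param model A [gene_model()].
#' @param width Bases at each intron end considered splice site (default 2,
#'   the canonical dinucleotides; widen to flag extended splice regions).
#' @return Logical flag.
#' @export
classify_splice_site <- function(variant, model, width = 2L) {
  if (variant$chrom != model$chromosome) return(FALSE)
  ivs <- introns(model)
  if (nrow(ivs) == 0L) return(FALSE)
  pos <- variant$pos
  any((pos >= ivs[, 1L] & pos <= pmin(ivs[, 1L] + width - 1L, ivs[, 2L])) |
        (pos <= ivs[, 2L] & pos >= pmax(ivs[, 2L] - width + 1L, ivs[, 1L])))
}

classify_cds_change <- function(variant, model, genome) {
  gpos <- cds_genomic_positions(model)
  idx <- match(variant$pos, gpos)
  if (is.na(idx)) return(NULL)
  cds <- extract_cds(genome, model)
  bases <- strsplit(cds, "")[[1L]]
  coding_ref <- if (model$strand == "+") variant$ref else comp_base(variant$ref)
  coding_alt <- if (model$strand == "+") variant$alt else comp_base(variant$alt)
  if (bases[idx] != coding_ref) {
    stop("variant ref disagrees with CDS of ", model$gene_id, " at ", variant$pos)
  }
  codon_i <- (idx - 1L) %/% 3L + 1L
  ref_codon <- paste(bases[(3L * codon_i - 2L):(3L * codon_i)], collapse = "")
  alt_bases <- bases
  alt_bases[idx] <- coding_alt
  alt_codon <- paste(alt_bases[(3L * codon_i - 2L):(3L * codon_i)], collapse = "")
  aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  if (codon_i == 1L && ref_codon == "ATG" && alt_codon != "ATG") {
    list(effect_class = "start_loss", protein_change = "M1?")
  } else if (aa_alt == aa_ref) {
    list(effect_class = "synonymous",
         protein_change = paste0(aa_ref, codon_i, aa_alt))
  } else if (aa_alt == "*") {
    list(effect_class = "nonsense",
         protein_change = paste0(aa_ref, codon_i, "*"))
  } else {
    list(effect_class = "missense",
         protein_change = paste0(aa_ref, codon_i, aa_alt))
  }
}

#' Annotate one variant against gene models
#'
#' Effect precedence within a gene is splice_site > CDS effects (computed by
#' substituting the base in the extracted CDS, strand-aware, and comparing
#' codons) > intronic; variants overlapping no gene are intergenic. Overlap is
#' judged on the gene span (first exon start to last exon end); in-span
#' positions that are neither splice-site nor CDS (introns, and any
#' non-coding exonic sequence) are classed intronic. One row is returned per
#' overlapping gene, most severe first.
#'
#' @param variant A one-row variant data frame.
#' @param models A list of [gene_model()] objects.
#' @param genome The reference [Biostrings::DNAStringSet].
#' @param splice_width Splice-site width passed to [classify_splice_site()].
#' @return Data frame with columns `chrom, pos, ref, alt, gene_id,
#'   effect_class, protein_change, severity` (>= 1 row).
#' @export
annotate_variant <- function(variant, models, genome, splice_width = 2L) {
  stopifnot(nrow(variant) == 1L)
  if (genome_base(genome, variant$chrom, variant$pos) != variant$ref) {
    stop("variant ref allele mismatch with genome at ",
         variant$chrom, ":", variant$pos)
  }
  hits <- list()
  for (m in models) {
    if (m$chromosome != variant$chrom) next
    span <- gene_span(m)
    if (variant$pos < span[1L] || variant$pos > span[2L]) next
    if (classify_splice_site(variant, m, width = splice_width)) {
      eff <- list(effect_class = "splice_site", protein_change = NA_character_)
    } else {
      eff <- if (m$coding) classify_cds_change(variant, m, genome) else NULL
      if (is.null(eff)) {
        eff <- list(effect_class = "intronic", protein_change = NA_character_)
      }
    }
    hits[[length(hits) + 1L]] <- data.frame(
      chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
      alt = variant$alt, gene_id = m$gene_id, effect_class = eff$effect_class,
      protein_change = eff$protein_change,
      severity = EFFECT_SEVERITY[[eff$effect_class]],
      stringsAsFactors = FALSE
    )
  }
  if (!length(hits)) {
    return(data.frame(chrom = variant$chrom, pos = variant$pos,
                      ref = variant$ref, alt = variant$alt,
                      gene_id = NA_character_, effect_class = "intergenic",
                      protein_change = NA_character_,
                      severity = EFFECT_SEVERITY[["intergenic"]],
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(-res$severity, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate a variant table
#'
#' Vectorized wrapper over [annotate_variant()].
#'
#' @param variants A variant data frame.
#' @param models A list of [gene_model()] objects.
#' @param genome The reference genome.
#' @param best_only If `TRUE` (default), keep only the most severe effect per
#'   variant; otherwise one row per (variant, gene) pair.
#' @param splice_width Splice-site width.
#' @return Annotation data frame (see [annotate_variant()]).
#' @export
annotate_variants <- function(variants, models, genome, best_only = TRUE,
                              splice_width = 2L) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    eff <- annotate_variant(variants[i, , drop = FALSE], models, genome,
                            splice_width = splice_width)
    if (best_only) eff[1L, , drop = FALSE] else eff
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rank candidate mutations within a region
#'
#' Restricts effects to the candidate region, keeps EMS-type substitutions
#' only, joins each variant's SNP index from the track, and orders by severity
#' (descending) then SNP index (descending) then position (the documented
#' tie-break).
#'
#' @param effects Annotation data frame from [annotate_variants()].
#' @param region One-row region data frame (`chrom, start, end`).
#' @param track Optional SNP-index track to supply `snp_index`.
#' @return Ranked candidate data frame (possibly empty).
#' @export
rank_candidates <- function(effects, region, track = NULL) {
  keep <- effects$chrom == region$chrom & effects$pos >= region$start &
    effects$pos <= region$end & is_ems_type(effects$ref, effects$alt)
  cand <- effects[keep, , drop = FALSE]
  if (!is.null(track)) {
    key <- paste(cand$chrom, cand$pos)
    cand$snp_index <- track$snp_index[match(key, paste(track$chrom, track$pos))]
  } else {
    cand$snp_index <- NA_real_
  }
  idx <- ifelse(is.na(cand$snp_index), -1, cand$snp_index)
  cand <- cand[order(-cand$severity, -idx, cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
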