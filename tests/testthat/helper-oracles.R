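# Independent oracles and small fixture builders shared across test files.

# Brute-force cluster enumerator: every maximal contiguous run of qualifying
# records, checked by explicit scan, ranked by the documented rule.
brute_force_clusters <- function(track, index_threshold = 0.95, min_snps = 3L,
                                 max_gap_bp = 2e6) {
  rows <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    n <- nrow(t)
    qualifies <- function(i, j) {
      idx <- t$snp_index[i:j]
      if (any(is.na(idx)) || any(idx < index_threshold)) return(FALSE)
      if (j > i && any(diff(t$pos[i:j]) > max_gap_bp)) return(FALSE)
      TRUE
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!qualifies(i, j)) next
        # maximal: cannot extend left or right
        if (i > 1L && qualifies(i - 1L, j)) next
        if (j < n && qualifies(i, j + 1L)) next
        if (j - i + 1L < min_snps) next
        cl <- data.frame(chrom = ch, start = t$pos[i], end = t$pos[j],
                         n_snps = j - i + 1L,
                         min_index = min(t$snp_index[i:j]),
                         mean_index = mean(t$snp_index[i:j]))
        rows[[length(rows) + 1L]] <- cl
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_snps = integer(0), min_index = numeric(0),
                      mean_index = numeric(0)))
  }
  res <- unique(do.call(rbind, rows))
  res <- res[order(-res$n_snps, -res$mean_index, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random SNP-index track over one or two chromosomes, with indexes spread so
# both sides of the detection threshold occur often.
random_track <- function(seed, max_sites = 50L) {
  set.seed(seed)
  n <- sample.int(max_sites, 1L)
  chrom <- sort(sample(c("cA", "cB"), n, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    sort(sample.int(5e6, sum(chrom == ch)))
  }))
  depth <- stats::rpois(n, 40) + 10L
  idx <- sample(c(stats::runif(n), rep(1, n), stats::runif(n, 0.9, 1)), n)
  alt <- round(idx * depth)
  ref <- sample(c("G", "C"), n, replace = TRUE)
  tr <- data.frame(chrom = chrom, pos = pos, ref = ref,
                   alt = ifelse(ref == "G", "A", "T"),
                   alt_count = alt, depth = depth)
  tr$snp_index <- tr$alt_count / tr$depth
  tr
}

# Retranslation oracle for coding variants: rebuild the mutant genome, extract
# the mutant CDS, translate both CDSs with Biostrings::translate, and classify
# from the protein diff. Independent of the annotator's CDS-position walk.
oracle_cds_effect <- function(variant, model, genome) {
  chr <- genome[[model$chromosome]]
  stopifnot(as.character(Biostrings::subseq(chr, variant$pos, variant$pos)) == variant$ref)
  Biostrings::subseq(chr, variant$pos, variant$pos) <- Biostrings::DNAString(variant$alt)
  mut_genome <- genome
  mut_genome[[model$chromosome]] <- chr
  ref_cds <- Biostrings::DNAString(extract_cds(genome, model))
  mut_cds <- Biostrings::DNAString(extract_cds(mut_genome, model))
  ref_prot <- as.character(Biostrings::translate(ref_cds, no.init.codon = TRUE))
  mut_prot <- as.character(Biostrings::translate(mut_cds, no.init.codon = TRUE))
  if (ref_prot == mut_prot) {
    diff_pos <- which(strsplit(as.character(ref_cds), "")[[1L]] !=
                        strsplit(as.character(mut_cds), "")[[1L]])
    codon <- (diff_pos - 1L) %/% 3L + 1L
    aa <- substring(ref_prot, codon, codon)
    return(list(effect_class = "synonymous",
                protein_change = paste0(aa, codon, aa)))
  }
  codon <- which(strsplit(ref_prot, "")[[1L]] != strsplit(mut_prot, "")[[1L]])
  stopifnot(length(codon) == 1L)
  aa_ref <- substring(ref_prot, codon, codon)
  aa_mut <- substring(mut_prot, codon, codon)
  ref_start <- as.character(Biostrings::subseq(ref_cds, 1L, 3L))
  mut_start <- as.character(Biostrings::subseq(mut_cds, 1L, 3L))
  if (codon == 1L && ref_start == "ATG" && mut_start != "ATG") {
    list(effect_class = "start_loss", protein_change = "M1?")
  } else if (aa_mut == "*") {
    list(effect_class = "nonsense", protein_change = paste0(aa_ref, codon, "*"))
  } else {
    list(effect_class = "missense", protein_change = paste0(aa_ref, codon, aa_mut))
  }
}

# All-pairs single-linkage sibling closure by explicit fixpoint iteration
# (no graph library): merge any two groups sharing a linked pair until stable.
brute_force_siblings <- function(profiles, min_jaccard) {
  ids <- vapply(profiles, `[[`, character(1L), "mutant_id")
  groups <- as.list(ids)
  linked <- function(a, b) {
    any(outer(a, b, Vectorize(function(x, y) {
      fingerprint_jaccard(profiles[[x]]$snps, profiles[[y]]$snps) >= min_jaccard
    })))
  }
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (merged) break
      for (j in seq_along(groups)) {
        if (j <= i) next
        if (linked(groups[[i]], groups[[j]])) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- groups[vapply(groups, length, integer(1L)) >= 2L]
  sort(unname(vapply(keep, function(g) paste(sort(g), collapse = ","),
                     character(1L))))
}

# Small two-exon plus-strand gene planted in a short genome; shared fixture.
toy_gene_fixture <- function(seed = 7L, strand = "+") {
  genome <- random_genome(c(chrF = 2000L), seed = seed)
  plant_gene(genome, "chrF", start = 501L, gene_id = "toy", strand = strand,
             exon_lengths = c(60L, 60L), intron_lengths = 40L, seed = seed + 1L)
}
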