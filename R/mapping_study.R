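# End-to-end drivers: simulate one complete pooled mapping study, run the
# mapping analysis on its counts, and simulate a multi-mutant capture-panel
# collection for the sibling/allelic-series stage.

#' Simulate a complete pooled mapping study
#'
#' Builds (or reuses) a toy reference genome, plants a two-exon causal gene
#' mid-chromosome, draws genome-wide EMS mutations, places the recessive
#' causal lesion (splice-donor by default) plus `n_linked` tightly linked
#' flanking EMS SNPs, simulates the selfed backcross-F2, selects the
#' homozygous-mutant (non-nodulating) pool, and samples pooled allele counts.
#' All randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @param genome Optional pre-built genome; by default a `random_genome()` of
#'   `lengths`.
#' @param lengths Chromosome lengths for the default genome
#'   (default two 5-Mb chromosomes).
#' @param mutation_rate EMS mutations per Mb (default 5).
#' @param site_class Causal lesion class (`"splice_donor"` or `"missense"`).
#' @param n_linked Linked flanking EMS SNPs around the causal gene (default 6).
#' @param linked_flank_bp Width of each flanking window (default 500).
#' @param n_f2 Number of F2 plants (default 1000).
#' @param pool_size Selected pool size (default 110).
#' @param mean_depth Mean sequencing depth (default 50).
#' @param error_rate Per-base sequencing error rate (default 0).
#' @param genetic_lengths Named cM lengths (default 100 cM per chromosome).
#' @return A list: `genome`, `model` (causal gene), `variants` (with `causal`
#'   flag), `causal` (one-row variant), `pool` (genotype matrix), `counts`
#'   (pool-counts data frame), `truth` (variants + recombination fraction
#'   `r`), and the configuration actually used.
#' @export
simulate_mapping_study <- function(seed,
                                   genome = NULL,
                                   lengths = c(chr1 = 5e6, chr2 = 5e6),
                                   mutation_rate = 5,
                                   site_class = "splice_donor",
                                   n_linked = 6L,
                                   linked_flank_bp = 500L,
                                   n_f2 = 1000L,
                                   pool_size = 110L,
                                   mean_depth = 50,
                                   error_rate = 0,
                                   genetic_lengths = NULL) {
  set.seed(seed)
  if (is.null(genome)) genome <- random_genome(lengths)
  phys <- chrom_lengths(genome)
  gene_start <- as.integer(phys[[1L]] %/% 2L)
  planted <- plant_gene(genome, names(phys)[1L], gene_start, gene_id = "causal_gene")
  genome <- planted$genome
  model <- planted$model
  background <- draw_ems_mutations(genome, ems_config(mutation_rate = mutation_rate))
  causal <- place_causal_variant(genome, model, site_class)
  linked <- place_linked_snps(genome, model, n = n_linked,
                              flank_bp = linked_flank_bp)
  span <- gene_span(model)
  in_gene_region <- background$chrom == model$chromosome &
    background$pos >= span[1L] - linked_flank_bp &
    background$pos <= span[2L] + linked_flank_bp
  variants <- rbind(background[!in_gene_region, , drop = FALSE], causal, linked)
  variants <- variants[!duplicated(paste(variants$chrom, variants$pos)), , drop = FALSE]
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  validate_variants(variants, genome)
  cross <- cross_config(genetic_lengths = genetic_lengths, pool_size = pool_size)
  geno <- simulate_f2_plants(variants, phys, n_f2, cross)
  pool <- select_mutant_pool(geno, which(variants$causal), pool_size)
  counts <- sample_pool_counts(pool, variants,
                               sequencing_config(mean_depth = mean_depth,
                                                 error_rate = error_rate))
  truth <- variants
  truth$r <- recombination_fractions(variants, phys, cross$genetic_lengths)
  list(genome = genome, model = model, variants = variants, causal = causal,
       pool = pool, counts = counts, truth = truth,
       config = list(seed = seed, lengths = phys, mutation_rate = mutation_rate,
                     site_class = site_class, n_linked = n_linked,
                     linked_flank_bp = linked_flank_bp, n_f2 = n_f2,
                     pool_size = pool_size, mean_depth = mean_depth,
                     error_rate = error_rate))
}

#' Run the mapping-by-sequencing analysis
#'
#' Counts -> SNP-index track -> EMS-type filter -> linkage clusters ->
#' candidate region, and (when gene models and the genome are supplied)
#' annotation and severity ranking of the region's variants.
#'
#' @param counts Pool-counts data frame (simulated or imported from VCF/TSV).
#' @param min_depth Minimum depth per site (default 10).
#' @param index_threshold Cluster membership threshold (default 0.95).
#' @param min_snps Minimum cluster size (default 3).
#' @param max_gap_bp Maximum intra-cluster gap (default 2 Mb).
#' @param margin_bp Candidate-region padding (default 10 kb).
#' @param models Optional list of [gene_model()] objects for annotation.
#' @param genome Optional reference genome for annotation.
#' @return A list: `track`, `clusters`, `region` (`NULL` when no cluster) and
#'   `candidates` (`NULL` unless models and genome are given).
#' @export
run_mapping_analysis <- function(counts, min_depth = 10L, index_threshold = 0.95,
                                 min_snps = 3L, max_gap_bp = 2e6,
                                 margin_bp = 10000L, models = NULL, genome = NULL) {
  track <- filter_ems_type(compute_snp_index(counts, min_depth = min_depth))
  clusters <- detect_linkage_clusters(track, index_threshold = index_threshold,
                                      min_snps = min_snps, max_gap_bp = max_gap_bp)
  region <- NULL
  candidates <- NULL
  if (nrow(clusters)) {
    lens <- if (!is.null(genome)) chrom_lengths(genome) else NULL
    region <- candidate_region(clusters, margin_bp = margin_bp, lengths = lens)
    if (!is.null(models) && !is.null(genome)) {
      in_region <- track$chrom == region$chrom & track$pos >= region$start &
        track$pos <= region$end
      if (any(in_region)) {
        v <- track[in_region, c("chrom", "pos", "ref", "alt"), drop = FALSE]
        effects <- annotate_variants(v, models, genome)
        candidates <- rank_candidates(effects, region, track)
      }
    }
  }
  list(track = track, clusters = clusters, region = region,
       candidates = candidates)
}

#' Simulate a targeted-capture mutant collection
#'
#' Emulates the capture-panel stage: a panel of `n_genes` planted genes, a set
#' of mutants each carrying one causal-grade lesion in an assigned panel gene
#' plus a genome-wide EMS fingerprint, and sibling pairs that duplicate
#' another mutant's fingerprint within the same screening bulk.
#'
#' @param seed Integer seed.
#' @param n_genes Number of panel genes (default 5).
#' @param alleles_per_gene Independent mutants per gene (default 2 each).
#' @param n_sibling_pairs Number of mutants duplicated as siblings (default 2).
#' @param fingerprint_size EMS SNPs per mutant fingerprint outside the causal
#'   lesion (default 25).
#' @param chrom_length Length of the single toy chromosome (default 2 Mb).
#' @return A list: `genome`, `models`, `panel` (gene intervals), `calls`
#'   (per-mutant variant calls), and `truth` (mutant_id, bulk_id, gene_id,
#'   sibling_of).
#' @export
simulate_mutant_collection <- function(seed, n_genes = 5L,
                                       alleles_per_gene = rep(2L, n_genes),
                                       n_sibling_pairs = 2L,
                                       fingerprint_size = 25L,
                                       chrom_length = 2e6) {
  set.seed(seed)
  stopifnot(length(alleles_per_gene) == n_genes)
  genome <- random_genome(c(chrP = chrom_length))
  models <- list()
  spacing <- chrom_length %/% (n_genes + 1L)
  for (i in seq_len(n_genes)) {
    planted <- plant_gene(genome, "chrP", start = i * spacing,
                          gene_id = sprintf("panel_g%02d", i),
                          strand = if (i %% 2L) "+" else "-",
                          exon_lengths = c(90L, 90L, 63L),
                          intron_lengths = c(60L, 60L))
    genome <- planted$genome
    models[[planted$model$gene_id]] <- planted$model
  }
  # capture intervals tile 400 bp beyond each gene (bait design reaches into
  # the flanks), so fingerprint SNPs in the flanks are captured too
  panel <- do.call(rbind, lapply(models, function(m) {
    s <- gene_span(m)
    data.frame(gene_id = m$gene_id, chrom = m$chromosome,
               start = max(1L, s[1L] - 400L),
               end = min(as.integer(chrom_length), s[2L] + 400L))
  }))
  rownames(panel) <- NULL
  chr_seq <- as.character(genome[["chrP"]])
  in_panel <- unlist(lapply(seq_len(nrow(panel)), function(i) {
    seq.int(panel$start[i], panel$end[i])
  }))
  in_gene <- unlist(lapply(models, function(m) {
    s <- gene_span(m)
    seq.int(s[1L], s[2L])
  }))
  flank_sites <- setdiff(in_panel, in_gene)  # captured but outside gene bodies
  base_at <- substring(chr_seq, flank_sites, flank_sites)
  gc_sites <- flank_sites[base_at %in% c("G", "C")]
  draw_fingerprint <- function() {
    pos <- sort(sample(gc_sites, fingerprint_size))
    ref <- substring(chr_seq, pos, pos)
    ems_variants("chrP", pos, ref, ifelse(ref == "G", "A", "T"))
  }
  calls <- list()
  truth <- list()
  k <- 0L
  for (i in seq_len(n_genes)) {
    site_classes <- rep(c("splice_donor", "missense"), length.out = alleles_per_gene[i])
    for (a in seq_len(alleles_per_gene[i])) {
      k <- k + 1L
      id <- sprintf("M%03d", k)
      bulk <- sprintf("bulk%02d", ((k - 1L) %% 4L) + 1L)
      lesion <- place_causal_variant(genome, models[[i]], site_classes[a],
                                     skip = (a - 1L) %/% 2L)
      snps <- rbind(draw_fingerprint(), lesion)
      snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), , drop = FALSE]
      calls[[id]] <- data.frame(mutant_id = id, bulk_id = bulk,
                                chrom = snps$chrom, pos = snps$pos,
                                ref = snps$ref, alt = snps$alt)
      truth[[id]] <- data.frame(mutant_id = id, bulk_id = bulk,
                                gene_id = models[[i]]$gene_id,
                                sibling_of = NA_character_)
    }
  }
  base_ids <- names(calls)
  for (s in seq_len(n_sibling_pairs)) {
    k <- k + 1L
    id <- sprintf("M%03d", k)
    src <- base_ids[s]
    sib <- calls[[src]]
    sib$mutant_id <- id
    calls[[id]] <- sib
    truth[[id]] <- data.frame(mutant_id = id, bulk_id = sib$bulk_id[1L],
                              gene_id = truth[[src]]$gene_id, sibling_of = src)
  }
  list(genome = genome, models = models, panel = panel,
       calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
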