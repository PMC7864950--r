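#!/usr/bin/env Rscript
# Stage 2 -- mapping-by-sequencing: read the pooled allele counts produced by
# stage 1, compute SNP indexes (mutant allele frequencies), filter to the EMS
# transition spectrum, detect linkage clusters of index~1 SNPs, and derive
# the candidate region. Writes the index track, the clusters, a sliding-
# window profile, the region, and (if ggplot2 is available) the index plot.

suppressPackageStartupMessages(library(nodmap))

counts <- read_pool_vcf("results/pool_counts.vcf")
message("Read ", nrow(counts), " pooled count records")

track <- filter_ems_type(compute_snp_index(counts, min_depth = 10))
clusters <- detect_linkage_clusters(track, index_threshold = 0.95,
                                    min_snps = 3, max_gap_bp = 2e6)
message("Detected ", nrow(clusters), " linkage cluster(s)")
if (nrow(clusters) == 0) stop("mapping failed: no cluster of high-index SNPs")

top <- clusters[1, ]
message(sprintf("Top cluster: %s:%d-%d with %d SNPs (min index %.3f, mean %.3f)",
                top$chrom, top$start, top$end, top$n_snps, top$min_index,
                top$mean_index))

genome <- read_fasta("results/reference.fa")
region <- candidate_region(clusters, margin_bp = 10000,
                           lengths = chrom_lengths(genome))
message(sprintf("Candidate region: %s:%d-%d", region$chrom, region$start,
                region$end))

profile <- sliding_window_profile(track, window_bp = 5e5, step_bp = 1e5,
                                  lengths = chrom_lengths(genome))

flat <- function(d) { d$positions <- NULL; d }
utils::write.table(track, "results/snp_index_track.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(flat(clusters), "results/linkage_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(profile, "results/window_profile.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(region, "results/candidate_region.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- plot_snp_index(track, clusters)
  ggplot2::ggsave("results/snp_index_plot.pdf", p, width = 9, height = 3.2)
  message("Wrote results/snp_index_plot.pdf")
}
message("Stage 2 outputs written under results/")
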