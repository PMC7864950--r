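#!/usr/bin/env Rscript
# Stage 1 -- simulate the forward-genetics material: a 10-Mb two-chromosome
# reference, an EMS mutant line (5 G:C->A:T SNPs/Mb) carrying a recessive
# splice-donor lesion in a planted two-exon gene, the mutant x WT backcross,
# 1000 selfed F2 plants, selection of a 110-plant non-nodulating pool, and
# pooled sequencing at Poisson(50) depth with zero error.
#
# Writes to results/: reference FASTA, gene model GFF3, pooled counts
# (VCF + TSV), and the simulation truth table (per-variant recombination
# fraction from the causal locus).

suppressPackageStartupMessages(library(nodmap))

dir.create("results", showWarnings = FALSE)
seed <- 20210205

message("Simulating mapping study (seed ", seed, ") ...")
study <- simulate_mapping_study(seed = seed)

write_fasta(study$genome, "results/reference.fa")
write_gff(list(study$model), "results/genes.gff3")
write_pool_vcf(study$counts, "results/pool_counts.vcf")
write_pool_tsv(study$counts, "results/pool_counts.tsv")
write_truth_tsv(study$variants, chrom_lengths(study$genome),
                "results/truth.tsv")

n_linked <- sum(study$truth$r < 0.001) - 1L
message(sprintf("EMS variants: %d total, causal splice-donor lesion at %s:%d",
                nrow(study$variants), study$causal$chrom, study$causal$pos))
message(sprintf("%d linked flanking SNPs (r < 0.001); pool of %d plants, all homozygous mutant",
                n_linked, nrow(study$pool)))

# the F2 itself segregates ~3:1 wild:mutant -- record the segregation test
geno <- simulate_f2_plants(study$variants, chrom_lengths(study$genome),
                           n_plants = 1000)
n_mut <- sum(geno[, which(study$variants$causal)] == 2)
seg <- segregation_test(1000 - n_mut, n_mut, ratio = c(3, 1))
print(seg)
utils::write.table(
  data.frame(n_wild = seg$n_wild, n_mutant = seg$n_mutant,
             chi_square = seg$chi_square, p_value = seg$p_value),
  "results/f2_segregation.tsv", sep = "\t", quote = FALSE, row.names = FALSE
)
message("Stage 1 outputs written under results/")
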