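test_that("EMS mutation draws respect rate, spectrum and determinism", {
  genome <- random_genome(c(g1 = 1e6), seed = 5)
  expect_equal(nrow(draw_ems_mutations(genome, ems_config(mutation_rate = 0))), 0)

  v1 <- draw_ems_mutations(genome, ems_config(mutation_rate = 5, seed = 9))
  v2 <- draw_ems_mutations(genome, ems_config(mutation_rate = 5, seed = 9))
  expect_identical(v1, v2)
  v3 <- draw_ems_mutations(genome, ems_config(mutation_rate = 5, seed = 10))
  expect_false(identical(v1, v3))

  expect_true(all(is_ems_type(v1$ref, v1$alt)))
  expect_false(anyDuplicated(paste(v1$chrom, v1$pos)) > 0)
  expect_silent(validate_variants(v1, genome))

  # at a high rate the Poisson count concentrates near rate * Mb
  v4 <- draw_ems_mutations(genome, ems_config(mutation_rate = 1000, seed = 2))
  expect_lt(abs(nrow(v4) - 1000), 3 * sqrt(1000))

  gonly <- Biostrings::DNAStringSet(c(x = "ATATATATAT"))
  expect_error(draw_ems_mutations(gonly, ems_config(mutation_rate = 1e6, seed = 1)),
               "no G/C")
})

test_that("causal variant placement hits the donor dinucleotide and a missense site", {
  for (strand in c("+", "-")) {
    fx <- toy_gene_fixture(seed = 31, strand = strand)
    donor <- place_causal_variant(fx$genome, fx$model, "splice_donor")
    expect_true(donor$causal)
    expect_true(is_ems_type(donor$ref, donor$alt))
    expect_true(classify_splice_site(donor, fx$model))
    # the donor base is intron position 1 on the coding strand
    iv <- introns(fx$model)
    expected_pos <- if (strand == "+") iv[1, 1] else iv[1, 2]
    expect_equal(donor$pos, expected_pos)

    mis <- place_causal_variant(fx$genome, fx$model, "missense")
    eff <- annotate_variant(mis, list(fx$model), fx$genome)
    expect_equal(eff$effect_class[1], "missense")
    expect_true(is_ems_type(mis$ref, mis$alt))
  }
  # single-exon gene has no donor
  genome <- random_genome(c(s = 1000L), seed = 40)
  single <- plant_gene(genome, "s", 101, exon_lengths = 120L,
                       intron_lengths = integer(0))
  expect_error(place_causal_variant(single$genome, single$model, "splice_donor"),
               ">= 2 exons")
})

test_that("a Gly codon's middle G mutates to Glu, as the annotator confirms", {
  # construct a plus-strand gene and force a GGA codon at a known spot
  genome <- Biostrings::DNAStringSet(
    c(cM = paste0(strrep("A", 100), "ATGGGATTATTGTAA", strrep("A", 100)))
  )
  m <- gene_model("gly", "cM", "+", exons = rbind(c(101, 115)),
                  cds = rbind(c(101, 115)))
  v <- ems_variants("cM", 105, "G", "A")  # middle G of GGA -> GAA
  eff <- annotate_variant(v, list(m), genome)
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$protein_change, "G2E")
})

test_that("F2 genotypes follow Mendelian and Haldane expectations", {
  # single unlinked-ish variant: 1:2:1 within 3 sigma
  v <- ems_variants("c1", 5e5, "G", "A", causal = TRUE)
  set.seed(101)
  geno <- simulate_f2_plants(v, c(c1 = 1e6), n_plants = 2000)
  n_het <- sum(geno == 1)
  expect_lt(abs(n_het - 1000), 3 * sqrt(2000 * 0.5 * 0.5))
  n_hom <- sum(geno == 2)
  expect_lt(abs(n_hom - 500), 3 * sqrt(2000 * 0.25 * 0.75))

  # complete linkage: adjacent base pairs co-segregate
  v2 <- ems_variants(c("c1", "c1"), c(5e5, 5e5 + 1), c("G", "C"), c("A", "T"),
                     causal = c(TRUE, FALSE))
  set.seed(102)
  g2 <- simulate_f2_plants(v2, c(c1 = 1e6), n_plants = 200)
  expect_true(all(g2[, 1] == g2[, 2]))

  # 50 cM apart (Haldane): selected-gamete alt frequency = 1 - r, r = (1-e^-1)/2
  d <- 50
  v3 <- ems_variants(c("c1", "c1"), c(1, 1 + round(1e6 * d / 100)),
                     c("G", "G"), c("A", "A"), causal = c(TRUE, FALSE))
  set.seed(103)
  g3 <- simulate_f2_plants(v3, c(c1 = 1e6), n_plants = 4000)
  sel <- g3[g3[, 1] == 2, , drop = FALSE]
  r <- (1 - exp(-1)) / 2
  freq <- mean(sel[, 2]) / 2
  n_gam <- 2 * nrow(sel)
  expect_lt(abs(freq - (1 - r)), 3 * sqrt(r * (1 - r) / n_gam))
  expect_equal(haldane_r(d), r)
  expect_equal(haldane_d(haldane_r(17)), 17)
})

test_that("pool selection keeps only homozygous mutants at ~1/4 frequency", {
  v <- ems_variants("c1", 5e5, "G", "A", causal = TRUE)
  set.seed(104)
  geno <- simulate_f2_plants(v, c(c1 = 1e6), n_plants = 1000)
  eligible <- sum(geno[, 1] == 2)
  expect_lt(abs(eligible - 250), 3 * sqrt(1000 * 0.25 * 0.75))
  pool <- select_mutant_pool(geno, 1, pool_size = 110)
  expect_equal(nrow(pool), 110)
  expect_true(all(pool[, 1] == 2))
  expect_error(select_mutant_pool(geno, 1, pool_size = eligible + 1),
               "homozygous-mutant")
})

test_that("pooled counts are forced at fixed pools and Poisson in depth", {
  v <- ems_variants(c("c1", "c1"), c(100, 200), c("G", "C"), c("A", "T"),
                    causal = c(TRUE, FALSE))
  pool_hom <- matrix(2L, nrow = 20, ncol = 2)
  pool_wt <- matrix(0L, nrow = 20, ncol = 2)
  set.seed(105)
  cnt <- sample_pool_counts(pool_hom, v, sequencing_config(error_rate = 0))
  expect_equal(cnt$alt_count, cnt$depth)
  cnt0 <- sample_pool_counts(pool_wt, v, sequencing_config(error_rate = 0))
  expect_equal(cnt0$alt_count, rep(0L, 2))

  many <- ems_variants("c1", seq(1, 5e5, by = 500), "G", "A",
                       causal = c(TRUE, rep(FALSE, 999)))
  pool1k <- matrix(1L, nrow = 20, ncol = nrow(many))
  set.seed(106)
  c2 <- sample_pool_counts(pool1k, many, sequencing_config(mean_depth = 50))
  expect_lt(abs(mean(c2$depth) - 50), 3 * sqrt(50 / nrow(many)))
})

test_that("simulated studies are reproducible and seed-sensitive", {
  a <- simulate_mapping_study(seed = 77, lengths = c(chr1 = 4e5, chr2 = 4e5),
                              n_f2 = 200, pool_size = 30)
  b <- simulate_mapping_study(seed = 77, lengths = c(chr1 = 4e5, chr2 = 4e5),
                              n_f2 = 200, pool_size = 30)
  expect_identical(a$counts, b$counts)
  expect_identical(a$causal, b$causal)
  d <- simulate_mapping_study(seed = 78, lengths = c(chr1 = 4e5, chr2 = 4e5),
                              n_f2 = 200, pool_size = 30)
  expect_false(identical(a$counts, d$counts))
  # every pooled plant is homozygous mutant at the causal locus
  expect_true(all(a$pool[, which(a$variants$causal)] == 2))
  # truth table recombination fractions: 0 at causal, 0.5 off-chromosome
  expect_equal(a$truth$r[a$truth$causal], 0)
  expect_true(all(a$truth$r[a$truth$chrom != a$causal$chrom] == 0.5))
})

test_that("pool counts round-trip through minimal VCF and TSV", {
  st <- simulate_mapping_study(seed = 12, lengths = c(chr1 = 3e5, chr2 = 3e5),
                               n_f2 = 150, pool_size = 25, mutation_rate = 20)
  fv <- withr::local_tempfile(fileext = ".vcf")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_pool_vcf(st$counts, fv)
  write_pool_tsv(st$counts, ft)
  from_vcf <- read_pool_vcf(fv)
  from_tsv <- read_pool_tsv(ft)
  expect_equal(from_vcf, st$counts, ignore_attr = TRUE)
  expect_equal(from_tsv, st$counts, ignore_attr = TRUE)
})
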