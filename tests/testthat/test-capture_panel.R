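panel_fixture <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = c("c1", "c1"),
             start = c(1000, 5000), end = c(1999, 5999))
}

calls_row <- function(id, bulk, pos, ref = "G", alt = "A", chrom = "c1") {
  data.frame(mutant_id = id, bulk_id = bulk, chrom = chrom, pos = pos,
             ref = ref, alt = alt)
}

test_that("profiles restrict to the panel, filter to EMS type, and dedupe", {
  calls <- rbind(
    calls_row("m1", "b1", c(1100, 1200, 1200)),           # dup collapses
    calls_row("m1", "b1", 1300, ref = "T", alt = "A"),    # transversion out
    calls_row("m1", "b1", 9000),                          # off panel
    calls_row("m2", "b1", c(5100, 5200), ref = "C", alt = "T")
  )
  profiles <- build_profiles(calls, panel_fixture())
  expect_length(profiles, 2)
  expect_equal(nrow(profiles[["m1"]]$snps), 2)
  expect_equal(nrow(profiles[["m2"]]$snps), 2)
  expect_warning(build_profiles(calls_row("m3", "b9", 9999), panel_fixture()),
                 "empty panel profile")
})

test_that("identical fingerprints group; disjoint ones do not", {
  calls <- rbind(calls_row("m1", "b1", c(1100, 1200, 1300)),
                 calls_row("m2", "b1", c(1100, 1200, 1300)),
                 calls_row("m3", "b2", c(5100, 5300)))
  profiles <- build_profiles(calls, panel_fixture())
  sib <- find_siblings(profiles, min_jaccard = 0.5)
  expect_equal(nrow(sib), 1)
  expect_equal(sib$members, "m1,m2")
  expect_false(sib$cross_bulk)
  # jaccard is symmetric
  expect_equal(fingerprint_jaccard(profiles[["m1"]]$snps, profiles[["m3"]]$snps),
               fingerprint_jaccard(profiles[["m3"]]$snps, profiles[["m1"]]$snps))
  # cross-bulk sharing is reported but flagged
  calls2 <- rbind(calls_row("x1", "b1", c(1100, 1200)),
                  calls_row("x2", "b2", c(1100, 1200)))
  expect_warning(sib2 <- find_siblings(build_profiles(calls2, panel_fixture())),
                 "spans bulks")
  expect_true(sib2$cross_bulk)
})

test_that("sibling grouping matches brute-force closure and refines monotonically", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    profiles <- lapply(seq_len(n), function(i) {
      pos <- sort(sample(seq(1000, 1995, by = 5), sample(3:8, 1)))
      list(mutant_id = sprintf("m%02d", i), bulk_id = "b1",
           snps = ems_variants("c1", pos, "G", "A"))
    })
    names(profiles) <- vapply(profiles, `[[`, character(1), "mutant_id")
    for (thr in c(0.2, 0.5)) {
      got <- suppressWarnings(find_siblings(profiles, min_jaccard = thr))
      got_sets <- sort(got$members)
      want_sets <- brute_force_siblings(profiles, min_jaccard = thr)
      expect_equal(got_sets, want_sets)
    }
    # raising the threshold never merges groups: every high-threshold group is
    # contained in a low-threshold group
    lo <- suppressWarnings(find_siblings(profiles, min_jaccard = 0.2))
    hi <- suppressWarnings(find_siblings(profiles, min_jaccard = 0.6))
    lo_sets <- strsplit(lo$members, ",")
    for (h in strsplit(hi$members, ",")) {
      expect_true(any(vapply(lo_sets, function(l) all(h %in% l), logical(1))))
    }
  }
})

test_that("candidate identification keeps severe effects in panel genes only", {
  profile <- list(mutant_id = "m1", bulk_id = "b1",
                  snps = ems_variants("c1", c(1100, 1200, 1300), "G", "A"))
  effects <- data.frame(
    chrom = "c1", pos = c(1100, 1200, 1300), ref = "G", alt = "A",
    gene_id = c("gA", "gA", "gA"),
    effect_class = c("splice_site", "synonymous", "synonymous"),
    protein_change = c(NA, "G2G", "K9K"), severity = c(5, 3, 3)
  )
  cand <- identify_candidates(profile, effects)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$effect_class, "splice_site")
  # all synonymous -> unexplained mutant
  effects$effect_class <- "synonymous"
  effects$severity <- 3
  expect_equal(nrow(identify_candidates(profile, effects)), 0)
  # two missense in different genes: both retained, stable severity order
  eff2 <- data.frame(chrom = "c1", pos = c(1100, 5100), ref = "G", alt = "A",
                     gene_id = c("gA", "gB"),
                     effect_class = "missense",
                     protein_change = c("G2E", "P7L"), severity = 4)
  prof2 <- list(mutant_id = "m2", bulk_id = "b1",
                snps = ems_variants("c1", c(1100, 5100), "G", "A"))
  expect_equal(identify_candidates(prof2, eff2)$gene_id, c("gA", "gB"))
})

test_that("allelic series count distinct variants with siblings collapsed", {
  cand <- function(id, gene, pos) {
    data.frame(mutant_id = id, chrom = "c1", pos = pos, ref = "G", alt = "A",
               gene_id = gene, effect_class = "missense",
               protein_change = "X1Y", severity = 4)
  }
  no_sibs <- data.frame(group = integer(0), members = character(0),
                        n_members = integer(0), bulk_id = character(0),
                        cross_bulk = logical(0), min_pair_jaccard = numeric(0))
  # 3 mutants, distinct variants, same gene -> 3 alleles
  s1 <- group_allelic_series(rbind(cand("m1", "gA", 10), cand("m2", "gA", 20),
                                   cand("m3", "gA", 30)), no_sibs)
  expect_equal(s1$n_alleles, 3)
  # 2 siblings sharing a variant + 1 independent -> 2 alleles
  sibs <- data.frame(group = 1, members = "m1,m2", n_members = 2,
                     bulk_id = "b1", cross_bulk = FALSE, min_pair_jaccard = 1)
  s2 <- group_allelic_series(rbind(cand("m1", "gA", 10), cand("m2", "gA", 10),
                                   cand("m3", "gA", 30)), sibs)
  expect_equal(s2$n_alleles, 2)
  # toy 6 mutants over 2 genes vs hand enumeration
  cands <- rbind(cand("m1", "gA", 10), cand("m2", "gA", 20),
                 cand("m3", "gB", 100), cand("m4", "gB", 110),
                 cand("m5", "gB", 120), cand("m6", "gB", 100))
  s3 <- group_allelic_series(cands, no_sibs)
  expect_equal(s3$gene_id, c("gB", "gA"))
  expect_equal(s3$n_alleles, c(3, 2))   # gB: 100,110,120 distinct; gA: 10,20
  expect_equal(s3$n_mutants, c(4, 2))
  # input order invariance
  s4 <- group_allelic_series(cands[sample(nrow(cands)), ], no_sibs)
  expect_equal(s4, s3)
})

test_that("segregation chi-square matches the direct formula", {
  exact <- segregation_test(75, 25)
  expect_equal(exact$chi_square, 0)
  expect_equal(exact$p_value, 1)
  expect_equal(segregation_test(300, 100)$chi_square, 0)  # scale invariance
  skew <- segregation_test(90, 10)
  expect_equal(skew$chi_square, 12)  # (90-75)^2/75 + (10-25)^2/25
  expect_equal(skew$p_value, stats::pchisq(12, 1, lower.tail = FALSE))
  # agrees with stats::chisq.test as an independent reference
  ref <- stats::chisq.test(c(90, 10), p = c(3, 1) / 4)
  expect_equal(skew$chi_square, unname(ref$statistic))
  expect_equal(skew$p_value, unname(ref$p.value))
  # exact k:1 scaling gives 0 for all k
  for (k in c(1, 2, 7, 40)) {
    expect_equal(segregation_test(3 * k, k)$chi_square, 0)
  }
  # Yates correction shrinks the statistic
  expect_lt(segregation_test(90, 10, correct = TRUE)$chi_square, 12)
  expect_error(segregation_test(0, 0), "zero total")
})

test_that("a simulated mutant collection recovers its truth", {
  coll <- simulate_mutant_collection(seed = 5)
  profiles <- build_profiles(coll$calls, coll$panel)
  sibs <- find_siblings(profiles, min_jaccard = 0.5)
  # every truth sibling pair is grouped together
  tr <- coll$truth[!is.na(coll$truth$sibling_of), ]
  for (i in seq_len(nrow(tr))) {
    hit <- vapply(strsplit(sibs$members, ","), function(m) {
      all(c(tr$mutant_id[i], tr$sibling_of[i]) %in% m)
    }, logical(1))
    expect_true(any(hit))
  }
  # candidates point at the assigned genes and series counts match truth
  effects <- annotate_variants(
    unique(coll$calls[, c("chrom", "pos", "ref", "alt")]),
    coll$models, coll$genome
  )
  cands <- do.call(rbind, lapply(profiles, identify_candidates, effects = effects))
  series <- group_allelic_series(cands, sibs)
  truth_rep <- coll$truth[is.na(coll$truth$sibling_of), ]
  want <- table(truth_rep$gene_id)
  for (g in names(want)) {
    expect_equal(series$n_alleles[series$gene_id == g], unname(want[[g]]),
                 ignore_attr = TRUE)
  }
})
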