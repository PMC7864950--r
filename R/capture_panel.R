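# Targeted-capture panel analysis: per-mutant EMS SNP fingerprints over a
# gene panel, sibling filtering by fingerprint sharing, candidate-mutation
# identification by effect severity, allelic-series grouping, and Mendelian
# segregation testing.

#' Build per-mutant panel profiles
#'
#' Restricts each mutant's variant calls to the panel intervals, applies the
#' EMS-spectrum filter, and collapses duplicates to a set. A mutant's profile
#' is its EMS SNP fingerprint over the capture panel.
#'
#' @param calls Data frame of per-mutant calls with columns `mutant_id,
#'   bulk_id, chrom, pos, ref, alt` and optionally `phenotype`.
#' @param panel Data frame of panel intervals: `gene_id, chrom, start, end`.
#' @return A named list of profiles, each a list with `mutant_id`, `bulk_id`,
#'   `phenotype`, and `snps` (a variant data frame).
#' @export
build_profiles <- function(calls, panel) {
  stopifnot(all(c("mutant_id", "bulk_id", "chrom", "pos", "ref", "alt") %in% names(calls)))
  in_panel <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(panel))) {
    in_panel <- in_panel | (calls$chrom == panel$chrom[i] &
                              calls$pos >= panel$start[i] &
                              calls$pos <= panel$end[i])
  }
  ids <- unique(calls$mutant_id)
  bulk_of <- calls$bulk_id[match(ids, calls$mutant_id)]
  pheno_of <- if ("phenotype" %in% names(calls)) {
    calls$phenotype[match(ids, calls$mutant_id)]
  } else {
    rep(NA_character_, length(ids))
  }
  calls <- calls[in_panel & is_ems_type(calls$ref, calls$alt), , drop = FALSE]
  profiles <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    m <- calls[calls$mutant_id == id, , drop = FALSE]
    m <- m[!duplicated(variant_key(m)), , drop = FALSE]
    if (nrow(m) == 0L) warning("mutant ", id, " has an empty panel profile")
    list(mutant_id = id, bulk_id = bulk_of[i], phenotype = pheno_of[i],
         snps = ems_variants(m$chrom, m$pos, m$ref, m$alt))
  })
  stats::setNames(profiles, ids)
}

#' Jaccard similarity of two SNP fingerprints
#' @param a,b Variant data frames.
#' @return `|a intersect b| / |a union b|` (0 when both empty).
#' @export
fingerprint_jaccard <- function(a, b) {
  ka <- variant_key(a)
  kb <- variant_key(b)
  u <- length(union(ka, kb))
  if (u == 0L) return(0)
  length(intersect(ka, kb)) / u
}

#' Find sibling groups among mutant profiles
#'
#' Siblings are independent-looking isolates descending from the same
#' mutagenized M1 plant; they share most of their genome-wide EMS fingerprint.
#' Pairs with Jaccard similarity >= `min_jaccard` are linked and groups are
#' the connected components of that graph (single-linkage closure, since
#' siblings share an M1 parent transitively). Groups whose members span more
#' than one screening bulk are reported but flagged: true siblings come from
#' the same bulk.
#'
#' @param profiles Profile list from [build_profiles()] (>= 2 profiles).
#' @param min_jaccard Similarity threshold (default 0.5).
#' @return Data frame with one row per group of >= 2 members: `group`,
#'   `members` (comma-separated ids), `n_members`, `bulk_id`,
#'   `cross_bulk` flag, and `min_pair_jaccard` within the group's linked pairs.
#' @export
find_siblings <- function(profiles, min_jaccard = 0.5) {
  stopifnot(length(profiles) >= 2L)
  ids <- vapply(profiles, `[[`, character(1L), "mutant_id")
  n <- length(profiles)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      jac <- fingerprint_jaccard(profiles[[i]]$snps, profiles[[j]]$snps)
      if (jac >= min_jaccard) {
        edges[[length(edges) + 1L]] <- data.frame(from = ids[i], to = ids[j],
                                                  jaccard = jac)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(group = integer(0), members = character(0),
                      n_members = integer(0), bulk_id = character(0),
                      cross_bulk = logical(0), min_pair_jaccard = numeric(0)))
  }
  ed <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = ids)
  comp <- igraph::components(g)
  grp_ids <- which(tabulate(comp$membership) >= 2L)
  rows <- lapply(seq_along(grp_ids), function(k) {
    members <- ids[comp$membership == grp_ids[k]]
    bulks <- unique(vapply(profiles[members], `[[`, character(1L), "bulk_id"))
    in_grp <- ed$from %in% members & ed$to %in% members
    cross <- length(bulks) > 1L
    if (cross) {
      warning("sibling group {", paste(members, collapse = ","),
              "} spans bulks ", paste(bulks, collapse = ","))
    }
    data.frame(group = k, members = paste(sort(members), collapse = ","),
               n_members = length(members),
               bulk_id = paste(bulks, collapse = ","),
               cross_bulk = cross,
               min_pair_jaccard = min(ed$jaccard[in_grp]))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Identify candidate mutations in a profile
#'
#' Formalizes the manual search for "the variation able to explain the
#' phenotype": keeps the profile's SNPs whose annotated effect is splice_site,
#' nonsense, start_loss or missense in a panel gene, ordered by severity
#' (descending) then position -- synonymous and non-splice intronic changes
#' cannot explain a loss of function and are dropped.
#'
#' @param profile One profile from [build_profiles()].
#' @param effects Annotation data frame (from [annotate_variants()]) covering
#'   the profile's SNPs.
#' @return Candidate data frame (possibly empty) with the profile's
#'   `mutant_id` attached.
#' @export
identify_candidates <- function(profile, effects) {
  key <- variant_key(profile$snps)
  eff <- effects[paste(effects$chrom, effects$pos, effects$ref, effects$alt,
                       sep = ":") %in% key, , drop = FALSE]
  eff <- eff[eff$effect_class %in% c("splice_site", "nonsense", "start_loss",
                                     "missense") & !is.na(eff$gene_id), , drop = FALSE]
  eff <- eff[order(-eff$severity, eff$chrom, eff$pos), , drop = FALSE]
  if (nrow(eff)) eff <- cbind(mutant_id = profile$mutant_id, eff)
  rownames(eff) <- NULL
  eff
}

#' Group candidate mutations into allelic series
#'
#' One series per gene hit by at least one non-sibling mutant. Each sibling
#' group is counted once (represented by its first member in sorted id
#' order); the allele count of a series is the number of distinct candidate
#' variants among the retained mutants.
#'
#' @param candidates Data frame of candidates across mutants (rows as from
#'   [identify_candidates()], with `mutant_id` and `gene_id`).
#' @param siblings Sibling-group data frame from [find_siblings()] (may have
#'   zero rows).
#' @return Data frame `gene_id, n_alleles, n_mutants, mutant_ids, variants`
#'   sorted by allele count (descending) then gene id.
#' @export
group_allelic_series <- function(candidates, siblings) {
  if (nrow(candidates) == 0L) {
    return(data.frame(gene_id = character(0), n_alleles = integer(0),
                      n_mutants = integer(0), mutant_ids = character(0),
                      variants = character(0)))
  }
  drop <- character(0)
  for (members in strsplit(siblings$members, ",")) {
    members <- sort(members)
    drop <- c(drop, members[-1L])  # keep first member as representative
  }
  cand <- candidates[!candidates$mutant_id %in% drop, , drop = FALSE]
  rows <- lapply(sort(unique(cand$gene_id)), function(g) {
    cg <- cand[cand$gene_id == g, , drop = FALSE]
    keys <- sort(unique(variant_key(cg)))
    data.frame(gene_id = g, n_alleles = length(keys),
               n_mutants = length(unique(cg$mutant_id)),
               mutant_ids = paste(sort(unique(cg$mutant_id)), collapse = ","),
               variants = paste(keys, collapse = ","))
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$n_alleles, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chi-square test of Mendelian segregation
#'
#' Pearson goodness-of-fit of observed (wild-type, mutant) plant counts
#' against an expected ratio (default 3:1, the selfed-F2 expectation for a
#' single recessive gene), with 1 degree of freedom. Yates continuity
#' correction is off by default.
#'
#' @param n_wild,n_mutant Observed plant counts.
#' @param ratio Expected wild:mutant ratio as a length-2 vector (default `c(3, 1)`).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list of class `segregation_result`: counts, expected ratio,
#'   `chi_square`, `df` and `p_value`.
#' @export
segregation_test <- function(n_wild, n_mutant, ratio = c(3, 1), correct = FALSE) {
  stopifnot(n_wild >= 0, n_mutant >= 0, length(ratio) == 2L, all(ratio > 0))
  n <- n_wild + n_mutant
  if (n == 0) stop("zero total plant count")
  expected <- n * ratio / sum(ratio)
  obs <- c(n_wild, n_mutant)
  dev <- abs(obs - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi <- sum(dev^2 / expected)
  structure(list(n_wild = n_wild, n_mutant = n_mutant, expected_ratio = ratio,
                 chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation %d:%d vs %s:%s expected -- chi-square = %.4g (df = %d), p = %.4g\n",
              x$n_wild, x$n_mutant, x$expected_ratio[1L], x$expected_ratio[2L],
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
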