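# Mapping-by-sequencing: SNP indexes from pooled allele counts, EMS-spectrum
# filtering, and detection of the linkage cluster of index~1 SNPs that
# localizes a recessive causal gene.

#' Compute the SNP-index track
#'
#' The SNP index at a site is the fraction of reads carrying the mutant (alt)
#' allele, `alt_count / depth` -- the pool's mutant allele frequency. Sites
#' with depth below `min_depth` are dropped before any clustering.
#'
#' @param counts Pool-counts data frame (`chrom, pos, ref, alt, alt_count, depth`).
#' @param min_depth Minimum depth for a site to be retained (default 10).
#' @return The track: `counts` restricted to retained sites, sorted by
#'   (chrom, pos), with an added `snp_index` column in `[0, 1]`.
#' @export
compute_snp_index <- function(counts, min_depth = 10L) {
  stopifnot(all(counts$alt_count >= 0), all(counts$alt_count <= counts$depth))
  keep <- counts$depth >= min_depth
  if (!any(keep)) warning("all sites filtered out at min_depth = ", min_depth)
  track <- counts[keep, , drop = FALSE]
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  track$snp_index <- ifelse(track$depth > 0, track$alt_count / track$depth, NA_real_)
  rownames(track) <- NULL
  track
}

#' Restrict a track to EMS-type substitutions
#'
#' Keeps only G->A and C->T records (the G:C->A:T EMS transition spectrum);
#' everything else is background variation or artifact for this design.
#'
#' @param track A SNP-index track (or any variant-keyed data frame with
#'   `ref`/`alt` columns).
#' @return The filtered track.
#' @export
filter_ems_type <- function(track) {
  out <- track[is_ems_type(track$ref, track$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect linkage clusters of high-index SNPs
#'
#' A cluster is a maximal run of consecutive track records on one chromosome
#' whose indexes all reach `index_threshold`, with adjacent members at most
#' `max_gap_bp` apart and at least `min_snps` members. Clusters are ranked by
#' member count (descending), then mean index (descending), then chromosome
#' and start position (ascending) to break ties.
#'
#' @param track A sorted SNP-index track.
#' @param index_threshold Minimum index for cluster membership (default 0.95;
#'   slightly below 1 so finite depth and nonzero error still recover the
#'   cluster of allele frequencies that "reach 100%").
#' @param min_snps Minimum run length (default 3).
#' @param max_gap_bp Maximum distance between adjacent members (default 2e6).
#' @return A data frame, one row per cluster in rank order: `chrom, start,
#'   end, n_snps, min_index, mean_index` plus a `positions` list-column of
#'   member positions. Zero rows when nothing qualifies.
#' @export
detect_linkage_clusters <- function(track, index_threshold = 0.95, min_snps = 3L,
                                    max_gap_bp = 2e6) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_snps = integer(0), min_index = numeric(0),
                      mean_index = numeric(0))
  empty$positions <- list()
  if (nrow(track) == 0L) return(empty)
  stopifnot(!is.unsorted(order(track$chrom, track$pos)))
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    hi <- !is.na(t$snp_index) & t$snp_index >= index_threshold
    # split qualifying records into runs broken by failures or large gaps
    new_run <- c(TRUE, diff(t$pos) > max_gap_bp | !hi[-length(hi)] | !hi[-1L])
    run_id <- cumsum(new_run)
    for (id in unique(run_id[hi])) {
      m <- t[run_id == id & hi, , drop = FALSE]
      if (nrow(m) < min_snps) next
      cl <- data.frame(chrom = ch, start = min(m$pos), end = max(m$pos),
                       n_snps = nrow(m), min_index = min(m$snp_index),
                       mean_index = mean(m$snp_index))
      cl$positions <- list(m$pos)
      out[[length(out) + 1L]] <- cl
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$n_snps, -res$mean_index, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sliding-window mean SNP index
#'
#' Tiles each chromosome with windows of `window_bp` every `step_bp` and
#' reports the mean index and SNP count per window (the classic SNP-index
#' plot). Empty windows are reported with `n_snps = 0` and `mean_index = NA`.
#'
#' @param track A SNP-index track.
#' @param window_bp Window width (must be >= `step_bp`).
#' @param step_bp Step between window starts.
#' @param lengths Optional named chromosome lengths; defaults to the last SNP
#'   position per chromosome.
#' @return Data frame `chrom, start, end, n_snps, mean_index`.
#' @export
sliding_window_profile <- function(track, window_bp, step_bp, lengths = NULL) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    L <- if (!is.null(lengths)) lengths[[ch]] else max(t$pos)
    starts <- seq(1L, max(1L, L), by = step_bp)
    ends <- pmin(starts + window_bp - 1L, L)
    n <- vapply(seq_along(starts), function(i) {
      sum(t$pos >= starts[i] & t$pos <= ends[i])
    }, integer(1L))
    mu <- vapply(seq_along(starts), function(i) {
      v <- t$snp_index[t$pos >= starts[i] & t$pos <= ends[i]]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1L))
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_snps = n, mean_index = mu)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate region from detected clusters
#'
#' Takes the top-ranked cluster's interval, padded by `margin_bp` on each side
#' (clipped at 1 and, when chromosome lengths are supplied, at the chromosome
#' end).
#'
#' @param clusters Cluster data frame from [detect_linkage_clusters()].
#' @param margin_bp Padding on each side (default 10 kb).
#' @param lengths Optional named chromosome lengths for right-clipping.
#' @return A one-row data frame `chrom, start, end`.
#' @export
candidate_region <- function(clusters, margin_bp = 10000L, lengths = NULL) {
  if (nrow(clusters) == 0L) stop("no linkage clusters: mapping failed")
  top <- clusters[1L, ]
  start <- max(1L, top$start - margin_bp)
  end <- top$end + margin_bp
  if (!is.null(lengths) && top$chrom %in% names(lengths)) {
    end <- min(end, lengths[[top$chrom]])
  }
  data.frame(chrom = top$chrom, start = as.integer(start), end = as.integer(end))
}

#' Plot the SNP-index track
#'
#' Position-vs-index scatter per chromosome with detected clusters shaded;
#' requires ggplot2.
#'
#' @param track A SNP-index track.
#' @param clusters Optional cluster data frame to highlight.
#' @return A ggplot object.
#' @export
plot_snp_index <- function(track, clusters = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_snp_index requires ggplot2")
  }
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos / 1e6, y = .data$snp_index)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Position (Mb)", y = "SNP index") +
    ggplot2::ylim(0, 1)
  if (!is.null(clusters) && nrow(clusters)) {
    p <- p + ggplot2::geom_rect(
      data = clusters,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.2, inherit.aes = FALSE
    )
  }
  p
}
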