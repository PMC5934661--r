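#' Detect clusters of predicted-functional mutations
#'
#' Finds genomic runs of significant mutations: within each chromosome,
#' variants are sorted by position and chained greedily while the gap to the
#' previous member (the inter-distance between consecutive positions) is
#' strictly below `max_gap`; chains with at least `min_size` members are
#' reported. With the defaults this is the "at least 3 predicted-functional
#' mutations, consecutive inter-distances < 10 kb" rule used to flag
#' recurrently mutated noncoding regions.
#'
#' Pass the already-thresholded set (see [significant_variants()]); the
#' function does not filter by p-value itself. Clusters never span
#' chromosomes, and the output is invariant to input row order.
#'
#' @param scored Data frame with at least `chrom` and `pos`; `p_value` and
#'   `iw_score` are summarized when present.
#' @param max_gap Maximum allowed inter-distance between consecutive members,
#'   exclusive (default 10 000).
#' @param min_size Minimum cluster size (default 3).
#' @return Tibble of class `iw_clusters`, one row per cluster: `chrom`,
#'   `start`, `end` (1-based inclusive span of member positions), `size`,
#'   `min_p`, `mean_iw`, and `members` (list-column of the member rows,
#'   sorted by position).
#' @export
detect_clusters <- function(scored, max_gap = 10000, min_size = 3) {
  scored <- tibble::as_tibble(scored)
  if (!all(c("chrom", "pos") %in% names(scored))) {
    abort("cluster detection needs 'chrom' and 'pos' columns")
  }
  sorted <- dplyr::arrange(scored, .data$chrom, .data$pos)
  grouped <- dplyr::group_by(sorted, .data$chrom)
  chained <- dplyr::mutate(
    grouped,
    gap = .data$pos - dplyr::lag(.data$pos),
    chain = cumsum(is.na(.data$gap) | .data$gap >= max_gap)
  )
  chains <- dplyr::group_split(dplyr::group_by(chained, .data$chrom, .data$chain))
  keep <- chains[vapply(chains, nrow, integer(1)) >= min_size]
  if (length(keep) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      size = integer(), min_p = numeric(), mean_iw = numeric(),
      members = list()
    )
  } else {
    out <- dplyr::bind_rows(lapply(keep, function(ch) {
      tibble::tibble(
        chrom = ch$chrom[1],
        start = min(ch$pos), end = max(ch$pos),
        size = nrow(ch),
        min_p = if ("p_value" %in% names(ch)) min(ch$p_value) else NA_real_,
        mean_iw = if ("iw_score" %in% names(ch)) mean(ch$iw_score) else NA_real_,
        members = list(dplyr::select(ch, -dplyr::any_of(c("gap", "chain"))))
      )
    }))
    out <- dplyr::arrange(out, .data$chrom, .data$start)
  }
  class(out) <- c("iw_clusters", class(out))
  out
}

#' Annotate clusters with overlapping regions
#'
#' Labels each cluster with every BED region its `[start, end]` span
#' intersects (BED intervals are 0-based half-open).
#'
#' @param clusters Result of [detect_clusters()].
#' @param regions Tibble as returned by [read_bed()].
#' @param normalize_chrom Strip a leading `"chr"` prefix before matching.
#' @return `clusters` with a list-column `region_labels`.
#' @export
cluster_overlap <- function(clusters, regions, normalize_chrom = FALSE) {
  labels <- rep(list(character()), nrow(clusters))
  if (nrow(clusters) > 0 && nrow(regions) > 0) {
    cchrom <- clusters$chrom
    rchrom <- regions$chrom
    if (normalize_chrom) {
      cchrom <- sub("^chr", "", cchrom)
      rchrom <- sub("^chr", "", rchrom)
    }
    gc <- GenomicRanges::GRanges(
      cchrom, IRanges::IRanges(start = clusters$start, end = clusters$end))
    gr <- regions_to_granges(tibble::tibble(chrom = rchrom,
                                            start = regions$start,
                                            end = regions$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gc, gr))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    hit_labels <- split(regions$label[sh],
                        factor(qh, levels = seq_len(nrow(clusters))))
    labels <- lapply(hit_labels, as.character)
  }
  clusters$region_labels <- unname(labels)
  clusters
}
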