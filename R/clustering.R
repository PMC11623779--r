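#' Cluster adjacent CpGs into candidate regions
#'
#' Two consecutive probes share a cluster iff they sit on the same
#' chromosome and their positions differ by at most `max_gap` bp. Clusters
#' never span chromosomes and cluster ids increase along the genome. The
#' manifest must already be sorted (no silent sorting).
#'
#' @param manifest Tibble with `probe_id`, `chrom`, `pos` sorted by
#'   (chromosome, position), positions strictly increasing within
#'   chromosome.
#' @param max_gap Maximum gap in bp between probes of one cluster (> 0).
#'   Default 300, the usual bump-hunting convention.
#' @return The manifest with an integer `cluster_id` column appended.
#' @export
#' @examples
#' mf <- tibble::tibble(probe_id = paste0("cg", 1:3), chrom = "chr1",
#'                      pos = c(100L, 200L, 900L))
#' make_clusters(mf, max_gap = 300)
make_clusters <- function(manifest, max_gap = 300) {
  if (max_gap <= 0) stop_config("max_gap must be > 0")
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(manifest))) {
    stop_data(paste("manifest needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(manifest$probe_id)) stop_data("probe ids must be unique")
  same_chrom <- manifest$chrom[-1] == manifest$chrom[-nrow(manifest)]
  gap <- diff(manifest$pos)
  if (any(same_chrom & gap <= 0)) {
    stop_data("manifest is not sorted: positions must strictly increase within chromosome")
  }
  if (anyDuplicated(rle(manifest$chrom)$values)) {
    stop_data("manifest is not sorted: chromosomes must form contiguous blocks")
  }
  new_cluster <- c(TRUE, !same_chrom | gap > max_gap)
  out <- manifest
  out$cluster_id <- cumsum(new_cluster)
  out
}

#' Drop clusters below a minimum probe count
#'
#' Clusters with fewer than `min_probes` members are removed; surviving
#' clusters are unchanged (ids kept stable). The default of 7 probes is the
#' minimum cluster size used throughout the pipeline.
#'
#' @param clusters Output of [make_clusters()].
#' @param min_probes Minimum probes per surviving cluster (>= 1). Default 7.
#' @return Filtered cluster assignment.
#' @export
filter_clusters <- function(clusters, min_probes = 7) {
  if (min_probes < 1) stop_config("min_probes must be >= 1")
  clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::filter(dplyr::n() >= min_probes) |>
    dplyr::ungroup()
}

#' Summarise clusters
#'
#' One row per cluster: chromosome, inclusive 1-based span of first/last
#' probe positions, and member count.
#'
#' @param clusters Output of [make_clusters()] or [filter_clusters()].
#' @return Tibble `cluster_id`, `chrom`, `start`, `end`, `n_probes`.
#' @export
cluster_summary <- function(clusters) {
  clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$pos), end = max(.data$pos),
                     n_probes = dplyr::n(), .groups = "drop")
}
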