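#' Ranked gene list from annotated DMRs
#'
#' Orders records by `fwer` ascending, then `area` descending, then genomic
#' position (the table ordering used for "top-k" comparisons throughout),
#' and keeps the first occurrence of each gene symbol.
#'
#' @param annotated Output of [annotate_dmrs()]; rows without a gene symbol
#'   are ignored.
#' @return Tibble `rank`, `gene_symbol`.
#' @export
ranked_genes <- function(annotated) {
  annotated |>
    dplyr::filter(!is.na(.data$gene_symbol)) |>
    dplyr::arrange(.data$fwer, dplyr::desc(.data$area), .data$chrom, .data$start) |>
    dplyr::distinct(.data$gene_symbol) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "gene_symbol")
}

#' Top-k gene overlap between two ranked lists
#'
#' Intersects the top-k prefixes of two ranked gene lists (the whole lists
#' when `top_k = NULL`). Symmetric in its arguments.
#'
#' @param a,b Ranked gene tibbles from [ranked_genes()] or character
#'   vectors of unique symbols in rank order.
#' @param top_k Prefix length, or `NULL` for the full lists.
#' @return List with `shared` (character), `n_shared`, `n_a_only`,
#'   `n_b_only`.
#' @export
overlap_genes <- function(a, b, top_k = NULL) {
  as_genes <- function(x) {
    if (is.data.frame(x)) x$gene_symbol else as.character(x)
  }
  ga <- as_genes(a)
  gb <- as_genes(b)
  if (anyDuplicated(ga) || anyDuplicated(gb)) {
    stop_data("gene lists must contain unique symbols")
  }
  if (!is.null(top_k)) {
    if (top_k > min(length(ga), length(gb))) {
      stop_config("top_k exceeds the length of a gene list")
    }
    ga <- ga[seq_len(top_k)]
    gb <- gb[seq_len(top_k)]
  }
  shared <- intersect(ga, gb)
  list(shared = shared, n_shared = length(shared),
       n_a_only = length(setdiff(ga, gb)), n_b_only = length(setdiff(gb, ga)))
}

#' Hyper/Hypo composition of a DMR result
#'
#' Fraction of Hyper- and Hypo-methylated regions among the top-k records
#' (whole set when `top_k = NULL`); fractions sum to 1 and counts are
#' reported alongside.
#'
#' @param results A `psdmr_result` or region tibble with a `state` column
#'   (already sorted if a plain tibble).
#' @param top_k Number of leading records to summarise, or `NULL` for all.
#' @return Tibble `state`, `n`, `fraction`.
#' @export
state_composition <- function(results, top_k = NULL) {
  regions <- if (inherits(results, "psdmr_result")) results$regions else as_tibble(results)
  if (nrow(regions) == 0) stop_data("empty result set")
  if (!is.null(top_k)) regions <- head(regions, top_k)
  tibble(state = c("Hyper", "Hypo")) |>
    dplyr::left_join(dplyr::count(regions, .data$state), by = "state") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = .data$n / sum(.data$n))
}

#' Tally gene symbols by family prefix
#'
#' Counts symbols starting with each prefix (case sensitive); a symbol
#' matches at most one prefix, with the longest matching prefix winning.
#'
#' @param genes Character vector of gene symbols, or a ranked gene tibble.
#' @param family_prefixes Non-empty character vector of prefixes (e.g.
#'   `c("ZNF", "HOX", "NKX2", "MIR")`).
#' @return Tibble `prefix`, `n` (zeros included).
#' @export
family_tally <- function(genes, family_prefixes) {
  if (length(family_prefixes) == 0) stop_config("family_prefixes must be non-empty")
  if (is.data.frame(genes)) genes <- genes$gene_symbol
  ord <- family_prefixes[order(nchar(family_prefixes), decreasing = TRUE)]
  assigned <- vapply(genes, function(g) {
    hit <- ord[startsWith(g, ord)]
    if (length(hit) > 0) hit[1] else NA_character_
  }, character(1))
  tibble(prefix = family_prefixes) |>
    dplyr::left_join(dplyr::count(tibble(prefix = assigned[!is.na(assigned)]),
                                  .data$prefix),
                     by = "prefix") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Multi-group methylation-level comparison for a targeted panel
#'
#' Computes per-gene group means on a gene-by-sample methylation panel,
#' excludes genes whose maximum group mean falls below
#' `low_signal_threshold` (low signal in every group), and reports Wilcoxon
#' rank-sum p-values for case vs healthy and case vs other on the retained
#' genes. Rank-sum tests are used because targeted-panel levels are bounded
#' and non-Gaussian.
#'
#' @param panel Wide tibble: `gene` plus one numeric column per sample.
#' @param groups Tibble `sample_id`, `group` with groups among
#'   `case`, `other`, `healthy` (at least two present, none empty).
#' @param low_signal_threshold Exclusion threshold on the panel's
#'   normalized scale. Default 0.1.
#' @return Tibble: `gene`, one `mean_<group>` column per group, `retained`,
#'   and rank-sum p-values (`NA` for excluded genes or absent groups).
#' @export
group_level_comparison <- function(panel, groups, low_signal_threshold = 0.1) {
  m <- wide_to_matrix(panel, "gene")
  if (!all(colnames(m) %in% groups$sample_id)) {
    stop_data("groups table must cover every panel sample")
  }
  grp <- groups$group[match(colnames(m), groups$sample_id)]
  present <- unique(grp)
  if (length(present) < 2) stop_data("need at least 2 groups")
  if (any(!groups$group %in% grp)) stop_data("a declared group has 0 samples")

  means <- sapply(present, function(g) rowMeans(m[, grp == g, drop = FALSE]))
  colnames(means) <- paste0("mean_", present)
  retained <- apply(means, 1, max) >= low_signal_threshold

  test_p <- function(i, g1, g2) {
    if (!all(c(g1, g2) %in% present)) return(NA_real_)
    suppressWarnings(
      wilcox.test(m[i, grp == g1], m[i, grp == g2], exact = FALSE)$p.value)
  }
  p_ch <- p_co <- rep(NA_real_, nrow(m))
  for (i in which(retained)) {
    p_ch[i] <- test_p(i, "case", "healthy")
    p_co[i] <- test_p(i, "case", "other")
  }
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(means),
                   tibble(retained = unname(retained),
                          p_case_vs_healthy = p_ch,
                          p_case_vs_other = p_co))
}
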