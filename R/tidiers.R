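#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired DMR result
#'
#' @param x A `psdmr_result`.
#' @param ... Unused.
#' @return The region tibble, sorted by `fwer` then `area`.
#' @export
tidy.psdmr_result <- function(x, ...) x$regions

#' One-row summary of a paired DMR run
#'
#' @param x A `psdmr_result`.
#' @param fwer_threshold Threshold for the significant-region count.
#' @param ... Unused.
#' @return One-row tibble: engine, probe/cluster/region counts, significant
#'   regions, hypermethylated fraction, B and seed.
#' @export
glance.psdmr_result <- function(x, fwer_threshold = 0.05, ...) {
  md <- x$metadata
  sig <- x$regions[x$regions$fwer < fwer_threshold, ]
  tibble(engine = md$engine,
         n_probes = md$n_probes_analyzed,
         n_clusters = md$n_clusters,
         n_regions = nrow(x$regions),
         n_significant = nrow(sig),
         frac_hyper = if (nrow(x$regions) > 0)
           mean(x$regions$state == "Hyper") else NA_real_,
         B = md$B, seed = md$seed)
}

#' Tidy a cfDNA NB-stage result
#'
#' @param x A `psdmr_cfdna`.
#' @param ... Unused.
#' @return Per-ROI tibble (`roi`, `logFC`, `p`, `flagged`, RPKM means).
#' @export
tidy.psdmr_cfdna <- function(x, ...) x$results

#' One-row summary of the cfDNA NB stage
#'
#' @param x A `psdmr_cfdna`.
#' @param alpha Unadjusted-p threshold for the significant count.
#' @param ... Unused.
#' @return One-row tibble: ROI count, significant windows, dispersion,
#'   group sizes.
#' @export
glance.psdmr_cfdna <- function(x, alpha = 0.05, ...) {
  tibble(n_rois = nrow(x$results),
         n_significant = sum(x$results$p < alpha),
         dispersion = x$metadata$dispersion,
         n_case = x$metadata$n_case,
         n_control = x$metadata$n_control)
}
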