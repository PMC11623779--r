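#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_hline
#'   geom_density facet_wrap labs scale_color_manual theme_minimal
#' @export
ggplot2::autoplot

state_colors <- c(Hyper = "#c0392b", Hypo = "#2471a3")

#' Plot DMRs along the genome
#'
#' Region area against genomic position, faceted by chromosome, colored by
#' Hyper/Hypo state; significant regions (FWER below the threshold) are
#' drawn solid, the rest hollow.
#'
#' @param object A `psdmr_result`.
#' @param fwer_threshold Significance threshold. Default 0.05.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psdmr_result <- function(object, fwer_threshold = 0.05, ...) {
  df <- dplyr::mutate(object$regions,
                      significant = .data$fwer < fwer_threshold)
  ggplot(df, aes(x = (.data$start + .data$end) / 2, y = .data$area,
                 color = .data$state, shape = .data$significant)) +
    geom_point(size = 2) +
    facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    scale_color_manual(values = state_colors) +
    labs(x = "position (bp)", y = "region area (sum |smoothed t|)",
         color = "state", shape = sprintf("FWER < %.2g", fwer_threshold)) +
    theme_minimal()
}

#' Volcano plot of the cfDNA NB stage
#'
#' log2 fold change against -log10 unadjusted p per ROI, with the
#' significance level marked.
#'
#' @param object A `psdmr_cfdna`.
#' @param alpha Unadjusted-p threshold. Default 0.05.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psdmr_cfdna <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(object$results,
                      significant = .data$p < alpha)
  ggplot(df, aes(x = .data$logFC, y = -log10(.data$p),
                 color = .data$significant)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(alpha), linetype = 2) +
    scale_color_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    labs(x = "log2 fold change (case / reference)",
         y = "-log10 p (unadjusted)", color = sprintf("p < %.2g", alpha)) +
    theme_minimal()
}

#' Beta-value distributions of a simulated methylome
#'
#' Density of beta values by phenotype over a probe subsample — a sanity
#' view of the bimodal marginal distribution the generator emulates.
#'
#' @param object A `psdmr_sim`.
#' @param max_probes Probe subsample size for the density. Default 2000.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psdmr_sim <- function(object, max_probes = 2000, ...) {
  b <- object$betas
  if (nrow(b) > max_probes) {
    b <- b[round(seq(1, nrow(b), length.out = max_probes)), ]
  }
  long <- tidyr::pivot_longer(b, -"probe_id", names_to = "sample_id",
                              values_to = "beta") |>
    dplyr::left_join(object$design, by = "sample_id")
  ggplot(long, aes(x = .data$beta, color = .data$phenotype)) +
    geom_density() +
    labs(x = "beta value", y = "density", color = NULL) +
    theme_minimal()
}
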