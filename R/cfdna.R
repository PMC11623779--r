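#' RPKM normalization of ROI counts
#'
#' `rpkm[r, s] = count[r, s] * 1e9 / (length_bp[r] * library_size[s])` —
#' exactly linear in counts and inverse-linear in region length and library
#' size. Library size is the sample's total sequenced fragments and may
#' exceed the on-target column sum.
#'
#' @param counts Wide tibble: `roi` plus one integer column per sample.
#' @param rois ROI tibble with `name`, `start`, `end` (1-based inclusive).
#' @param samples Sample tibble with `sample_id`, `library_size` (> 0).
#' @return Wide tibble of RPKM values, same shape as `counts`.
#' @export
normalize_rpkm <- function(counts, rois, samples) {
  m <- wide_to_matrix(counts, "roi")
  len <- (rois$end - rois$start + 1)[match(rownames(m), rois$name)]
  if (anyNA(len) || any(len <= 0)) stop_data("every ROI needs a positive length")
  lib <- samples$library_size[match(colnames(m), samples$sample_id)]
  if (anyNA(lib) || any(lib <= 0)) stop_data("every sample needs a positive library size")
  matrix_to_wide(m * 1e9 / outer(len, lib), "roi")
}

#' Method-of-moments NB dispersion, per ROI and common
#'
#' Counts are first scaled to a common library size; within each group the
#' moment estimator `(var - mean) / mean^2` is formed and averaged across
#' groups with degrees-of-freedom weights. The common dispersion is the
#' median of the positive per-ROI estimates — robust at targeted-panel ROI
#' counts, at the cost of ignoring genuine dispersion heterogeneity.
#'
#' @inheritParams normalize_rpkm
#' @return List with `per_roi` (tibble `roi`, `phi`) and `common` (scalar).
#' @export
estimate_dispersion <- function(counts, samples) {
  m <- wide_to_matrix(counts, "roi")
  lib <- samples$library_size[match(colnames(m), samples$sample_id)]
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  y <- sweep(m, 2, mean(lib) / lib, `*`)
  phis <- sapply(unique(grp), function(g) {
    yg <- y[, grp == g, drop = FALSE]
    mu <- rowMeans(yg)
    v <- apply(yg, 1, stats::var)
    (v - mu) / mu^2
  })
  w <- vapply(unique(grp), function(g) sum(grp == g) - 1, numeric(1))
  phi <- as.vector(phis %*% w) / sum(w)
  common <- stats::median(phi[is.finite(phi) & phi > 0])
  if (!is.finite(common)) stop_data("could not estimate a positive common dispersion")
  list(per_roi = tibble(roi = rownames(m), phi = phi), common = common)
}

## NB GLM with log link, library-size offset and a group term, dispersion
## held fixed; returns log2 fold change and LRT p-value
nb_fit_one <- function(y, is_case, offset_log, phi) {
  if (all(y == 0)) {
    return(list(logFC = 0, p = 1, flagged = TRUE))
  }
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  full <- stats::glm(y ~ is_case + offset(offset_log), family = fam)
  null <- stats::glm(y ~ 1 + offset(offset_log), family = fam)
  lr <- max(null$deviance - full$deviance, 0)
  list(logFC = unname(coef(full)["is_caseTRUE"]) / log(2),
       p = pchisq(lr, df = 1, lower.tail = FALSE),
       flagged = FALSE)
}

#' Negative-binomial differential test for one ROI
#'
#' Fits a NB log-linear model with a log library-size offset and a group
#' coefficient at a fixed dispersion, and compares it to the no-group null
#' by a likelihood-ratio test (chi-square, 1 df). The fold change is the
#' fitted group coefficient in log2 units (case over reference). An
#' all-zero ROI is flagged and returned with `logFC = 0`, `p = 1`.
#'
#' @inheritParams normalize_rpkm
#' @param samples Sample tibble with `sample_id`, `group` (exactly two
#'   groups, each with >= 2 samples), `library_size`.
#' @param roi ROI name to test.
#' @param dispersion NB dispersion phi; `NULL` estimates the common
#'   dispersion from all ROIs via [estimate_dispersion()].
#' @param reference Reference group level; defaults to `"control"` when
#'   present, otherwise the alphabetically first group.
#' @return Tibble `roi`, `logFC`, `p`, `flagged`.
#' @export
nb_glm_test <- function(counts, samples, roi, dispersion = NULL,
                        reference = NULL) {
  res <- cfdna_test(counts, rois = NULL, samples = samples,
                    dispersion = dispersion, reference = reference,
                    which_rois = roi)
  dplyr::select(tidy(res), "roi", "logFC", "p", "flagged")
}

#' Targeted cfDNA differential-coverage stage
#'
#' Runs the per-ROI negative-binomial likelihood-ratio test across a
#' targeted panel: common dispersion by method of moments (unless supplied),
#' then one NB GLM with library-size offsets per ROI. Group RPKM means are
#' attached when ROI intervals are provided.
#'
#' @inheritParams nb_glm_test
#' @param rois ROI tibble (`name`, `start`, `end`) for RPKM means, or
#'   `NULL` to skip them.
#' @param which_rois Optional subset of ROI names to test.
#' @return A `psdmr_cfdna` object; `tidy()` returns the per-ROI table
#'   (`roi`, `logFC`, `p`, `flagged`, and `rpkm_<group>` columns when ROI
#'   lengths are available).
#' @export
cfdna_test <- function(counts, rois, samples, dispersion = NULL,
                       reference = NULL, which_rois = NULL) {
  m <- wide_to_matrix(counts, "roi")
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  lib <- samples$library_size[match(colnames(m), samples$sample_id)]
  if (anyNA(grp) || anyNA(lib)) stop_data("samples table must cover every count column")
  lev <- sort(unique(grp))
  if (length(lev) != 2) stop_data("exactly two groups are required")
  if (any(table(grp) < 2)) stop_data("both groups need >= 2 samples")
  if (is.null(reference)) reference <- if ("control" %in% lev) "control" else lev[1]
  if (!reference %in% lev) stop_config("reference group not present")
  is_case <- grp != reference

  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, samples)$common
  if (dispersion <= 0) stop_config("dispersion must be > 0")

  test_names <- if (is.null(which_rois)) rownames(m) else {
    missing <- setdiff(which_rois, rownames(m))
    if (length(missing) > 0) stop_data(paste("unknown ROI:", missing[1]))
    which_rois
  }
  off <- log(lib)
  fits <- purrr::map(test_names, function(r) {
    nb_fit_one(m[r, ], is_case, off, dispersion)
  })
  out <- tibble(roi = test_names,
                logFC = vapply(fits, `[[`, numeric(1), "logFC"),
                p = vapply(fits, `[[`, numeric(1), "p"),
                flagged = vapply(fits, `[[`, logical(1), "flagged"))
  if (!is.null(rois)) {
    rpkm <- wide_to_matrix(normalize_rpkm(counts, rois, samples), "roi")
    rpkm <- rpkm[match(test_names, rownames(rpkm)), , drop = FALSE]
    case_lab <- setdiff(lev, reference)
    out[[paste0("rpkm_", case_lab)]] <- rowMeans(rpkm[, is_case, drop = FALSE])
    out[[paste0("rpkm_", reference)]] <- rowMeans(rpkm[, !is_case, drop = FALSE])
  }
  structure(list(results = out,
                 metadata = list(dispersion = dispersion, reference = reference,
                                 n_case = sum(is_case), n_control = sum(!is_case))),
            class = "psdmr_cfdna")
}

#' Prioritize significant cfDNA windows
#'
#' Keeps windows with unadjusted `p` strictly below `alpha`, sorted by `p`
#' ascending — unadjusted p-values are the prioritization criterion in the
#' validation-oriented targeted stage.
#'
#' @param results A `psdmr_cfdna` object or tidy per-ROI tibble.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return Tibble of significant windows sorted by `p`.
#' @export
prioritize_windows <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  tbl <- if (inherits(results, "psdmr_cfdna")) results$results else as_tibble(results)
  tbl |>
    dplyr::filter(.data$p < alpha) |>
    dplyr::arrange(.data$p)
}

#' @export
print.psdmr_cfdna <- function(x, ...) {
  cat(sprintf("psdmr cfDNA NB stage: %d ROI(s), dispersion %.4g, %d case vs %d %s\n",
              nrow(x$results), x$metadata$dispersion, x$metadata$n_case,
              x$metadata$n_control, x$metadata$reference))
  cat(sprintf("  %d window(s) with p < 0.05\n", sum(x$results$p < 0.05)))
  invisible(x)
}
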