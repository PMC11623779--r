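#' Beta to M-value transform
#'
#' `M = log2(b / (1 - b))` with `b` clipped into `[epsilon, 1 - epsilon]`, so
#' the transform is finite for betas of exactly 0 or 1 and strictly
#' increasing on the clipped range. Testing is done on M values (variance
#' stabilized); effect directions and reported deltas stay on the beta scale.
#'
#' @param beta Numeric vector/matrix of beta values in `[0, 1]`.
#' @param epsilon Clipping bound, in `(0, 0.5)`. Default 1e-3.
#' @return M values, same shape as the input.
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0, 2
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (epsilon <= 0 || epsilon >= 0.5) stop_config("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' M-value to beta transform
#'
#' Inverse logit2; exact inverse of [beta_to_m()] on the clipped range.
#'
#' @param m Numeric M values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  ## 2^m / (1 + 2^m), computed stably for large |m|
  1 / (1 + 2^(-m))
}

#' Impute missing beta values by probe means
#'
#' Probes whose missing fraction exceeds `max_missing_frac` are dropped
#' (logged via a message); remaining missing entries are replaced by the
#' probe's mean over observed samples. Deterministic, seed-free, idempotent;
#' probe order is preserved.
#'
#' @param betas Wide tibble: `probe_id` plus one numeric column per sample.
#' @param max_missing_frac Maximum tolerated missing fraction per probe, in
#'   `[0, 1)`. Default 0.2.
#' @return Wide tibble with no missing values.
#' @export
impute_missing <- function(betas, max_missing_frac = 0.2) {
  if (max_missing_frac < 0 || max_missing_frac >= 1) {
    stop_config("max_missing_frac must be in [0, 1)")
  }
  m <- wide_to_matrix(betas, "probe_id")
  frac <- rowMeans(is.na(m))
  drop <- frac > max_missing_frac
  if (any(drop)) {
    inform(sprintf("impute_missing: dropped %d probe(s) with > %.0f%% missing",
                   sum(drop), 100 * max_missing_frac))
    m <- m[!drop, , drop = FALSE]
  }
  if (anyNA(m)) {
    means <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- means[idx[, 1]]
  }
  matrix_to_wide(m, "probe_id")
}

#' Validate a paired design table
#'
#' Checks that every `pair_id` occurs exactly twice, once per phenotype, and
#' that phenotypes use the Tumor/Normal vocabulary.
#'
#' @param design Tibble with `sample_id`, `pair_id`, `phenotype`.
#' @return The design, invisibly, or an error.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "pair_id", "phenotype")
  if (!all(need %in% names(design))) {
    stop_data(paste("design needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(design$phenotype %in% c("Tumor", "Normal"))) {
    stop_data("phenotype must be 'Tumor' or 'Normal'")
  }
  if (anyDuplicated(design$sample_id)) stop_data("duplicate sample ids in design")
  chk <- design |>
    dplyr::count(.data$pair_id, .data$phenotype) |>
    tidyr::pivot_wider(names_from = "phenotype", values_from = "n", values_fill = 0L)
  if (!all(c("Tumor", "Normal") %in% names(chk)) ||
      any(chk$Tumor != 1L) || any(chk$Normal != 1L)) {
    stop_data("every pair_id must occur exactly twice, once per phenotype")
  }
  if (nrow(chk) < 2) stop_data("need at least 2 pairs")
  invisible(design)
}
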