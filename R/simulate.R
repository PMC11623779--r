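#' Simulation settings for paired methylome generation
#'
#' Bundles every knob of the synthetic paired tumor/normal methylome
#' generator. Effects are simulated additively on the M (logit2) scale and
#' transformed to beta values, so betas always fall inside (0, 1); each
#' patient pair shares a random per-probe baseline (a random intercept),
#' which is the inter-patient heterogeneity that motivates paired testing.
#' Per-probe mean methylation is drawn from a two-component Gaussian mixture
#' on the M scale to mimic the bimodal marginal distribution of array betas.
#'
#' The single `seed` is expanded into per-stage substreams (manifest uses
#' `seed`, betas use `seed + 1`), so stages can be re-run independently and a
#' fixed seed yields byte-identical output. R's default Mersenne-Twister
#' generator is used throughout.
#'
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param cpgs_per_chromosome CpG probes per chromosome.
#' @param spacing_model `"geometric"` (gaps of `1 + Geometric`, mean
#'   `spacing_bp`) or `"fixed"` (every gap exactly `spacing_bp`).
#' @param spacing_bp Mean (geometric) or exact (fixed) gap between adjacent
#'   probes, in bp.
#' @param n_pairs Number of tumor/normal pairs (at least 2).
#' @param baseline_sd_m SD of the per-pair shared baseline shift, M units.
#' @param noise_sd_m SD of per-sample technical noise, M units.
#' @param mix_weights Length-2 mixture weights (low, high methylation).
#' @param mix_means Length-2 component means on the M scale.
#' @param mix_sd Within-component SD of per-probe mean methylation.
#' @param spikes Tibble of spiked differential regions with columns
#'   `chromosome`, `start_probe_index` (1-based within chromosome),
#'   `n_probes`, `delta_m` (signed tumor-minus-normal effect on the M scale;
#'   positive means hypermethylated in tumor). `NULL` for a pure null.
#' @param seed Integer seed; required for reproducibility.
#' @return A `psdmr_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 50,
#'                   n_pairs = 4, seed = 1)
sim_config <- function(n_chromosomes = 4,
                       cpgs_per_chromosome = 5000,
                       spacing_model = c("geometric", "fixed"),
                       spacing_bp = 100,
                       n_pairs = 20,
                       baseline_sd_m = 1.5,
                       noise_sd_m = 0.5,
                       mix_weights = c(0.6, 0.4),
                       mix_means = c(-3, 2.5),
                       mix_sd = 0.5,
                       spikes = NULL,
                       seed = 1L) {
  spacing_model <- match.arg(spacing_model)
  if (n_chromosomes < 1 || cpgs_per_chromosome < 1 || spacing_bp < 1) {
    stop_config("chromosome, probe and spacing counts must be positive")
  }
  if (n_pairs < 2) stop_config("n_pairs must be at least 2")
  if (baseline_sd_m < 0 || noise_sd_m < 0 || mix_sd < 0) {
    stop_config("standard deviations must be non-negative")
  }
  if (length(mix_weights) != 2 || any(mix_weights < 0) || sum(mix_weights) <= 0) {
    stop_config("mix_weights must be two non-negative weights")
  }
  if (!is.null(spikes)) {
    spikes <- as_tibble(spikes)
    need <- c("chromosome", "start_probe_index", "n_probes", "delta_m")
    if (!all(need %in% names(spikes))) {
      stop_config(paste("spikes must have columns:", paste(need, collapse = ", ")))
    }
    if (any(spikes$n_probes < 1)) stop_config("spike n_probes must be >= 1")
  }
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         cpgs_per_chromosome = as.integer(cpgs_per_chromosome),
         spacing_model = spacing_model,
         spacing_bp = spacing_bp,
         n_pairs = as.integer(n_pairs),
         baseline_sd_m = baseline_sd_m,
         noise_sd_m = noise_sd_m,
         mix_weights = mix_weights / sum(mix_weights),
         mix_means = mix_means,
         mix_sd = mix_sd,
         spikes = spikes,
         seed = as.integer(seed)),
    class = "psdmr_config")
}

#' Simulate a CpG probe manifest
#'
#' Lays probes along each chromosome with strictly increasing 1-based
#' positions. Gaps are either fixed or `1 + Geometric(1 / spacing_bp)`, whose
#' mean equals `spacing_bp`.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with `probe_id`, `chrom`, `pos`, sorted by (chrom, pos).
#' @export
simulate_manifest <- function(config) {
  if (!inherits(config, "psdmr_config")) stop_config("config must come from sim_config()")
  set.seed(config$seed)
  n <- config$cpgs_per_chromosome
  pieces <- lapply(seq_len(config$n_chromosomes), function(ch) {
    gaps <- if (config$spacing_model == "fixed") {
      rep(config$spacing_bp, n - 1)
    } else {
      1 + rgeom(n - 1, prob = 1 / config$spacing_bp)
    }
    tibble(chrom = sprintf("chr%d", ch),
           pos = as.integer(cumsum(c(1, gaps))))
  })
  out <- dplyr::bind_rows(pieces)
  out$probe_id <- sprintf("cg%07d", seq_len(nrow(out)))
  dplyr::relocate(out, "probe_id")
}

## validate spike table against a manifest; returns per-chromosome global
## row ranges of each spike
resolve_spikes <- function(manifest, spikes) {
  if (is.null(spikes) || nrow(spikes) == 0) {
    return(tibble(chromosome = character(), first = integer(), last = integer(),
                  delta_m = numeric()))
  }
  chrom_offset <- manifest |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(offset = min(.data$.row) - 1L, n = dplyr::n())
  sp <- dplyr::left_join(spikes, chrom_offset,
                         by = c(chromosome = "chrom"))
  if (anyNA(sp$offset)) stop_config("spike chromosome absent from manifest")
  if (any(sp$start_probe_index < 1 |
          sp$start_probe_index + sp$n_probes - 1 > sp$n)) {
    stop_config("spiked window extends beyond chromosome bounds")
  }
  out <- tibble(chromosome = sp$chromosome,
                first = as.integer(sp$offset + sp$start_probe_index),
                last = as.integer(sp$offset + sp$start_probe_index + sp$n_probes - 1L),
                delta_m = sp$delta_m)
  ord <- order(out$first)
  out <- out[ord, ]
  if (nrow(out) > 1 && any(out$first[-1] <= out$last[-nrow(out)])) {
    stop_config("spiked regions overlap on the same probes")
  }
  out
}

#' Simulate paired tumor/normal beta values with ground truth
#'
#' For probe i and pair j, a shared baseline `b_ij ~ N(mu_i, baseline_sd_m)`
#' is drawn once per pair; normal-tissue M is `b_ij + noise`, tumor M is
#' `b_ij + delta_m * spiked(i) + noise`, and betas are the inverse logit2 of
#' M (guaranteed inside (0, 1)).
#'
#' @param manifest Output of [simulate_manifest()].
#' @param config The same [sim_config()] object.
#' @return List with `betas` (wide tibble, `probe_id` plus one column per
#'   sample), `design` (tibble `sample_id`, `pair_id`, `phenotype`), and
#'   `truth` (one row per spiked region: `chrom`, `start`, `end`, `n_probes`,
#'   `true_state`, `delta_m`).
#' @export
simulate_paired_betas <- function(manifest, config) {
  if (!inherits(config, "psdmr_config")) stop_config("config must come from sim_config()")
  sp <- resolve_spikes(manifest, config$spikes)
  n <- nrow(manifest)
  np <- config$n_pairs
  set.seed(config$seed + 1L)

  comp <- rbinom(n, 1, config$mix_weights[2])
  mu <- rnorm(n, mean = ifelse(comp == 1, config$mix_means[2], config$mix_means[1]),
              sd = config$mix_sd)
  baseline <- mu + matrix(rnorm(n * np, sd = config$baseline_sd_m), n, np)
  delta <- numeric(n)
  if (nrow(sp) > 0) {
    for (k in seq_len(nrow(sp))) delta[sp$first[k]:sp$last[k]] <- sp$delta_m[k]
  }
  m_normal <- baseline + matrix(rnorm(n * np, sd = config$noise_sd_m), n, np)
  m_tumor <- baseline + delta + matrix(rnorm(n * np, sd = config$noise_sd_m), n, np)

  pair_ids <- sprintf("P%02d", seq_len(np))
  betas <- cbind(m_to_beta(m_tumor), m_to_beta(m_normal))
  colnames(betas) <- c(paste0(pair_ids, "_T"), paste0(pair_ids, "_N"))
  rownames(betas) <- manifest$probe_id

  design <- tibble(
    sample_id = colnames(betas),
    pair_id = rep(pair_ids, 2),
    phenotype = rep(c("Tumor", "Normal"), each = np))

  truth <- tibble(
    chrom = sp$chromosome,
    start = manifest$pos[sp$first],
    end = manifest$pos[sp$last],
    n_probes = sp$last - sp$first + 1L,
    true_state = ifelse(sp$delta_m > 0, "Hyper", "Hypo"),
    delta_m = sp$delta_m)

  list(betas = matrix_to_wide(betas, "probe_id"), design = design, truth = truth)
}

#' One-call paired methylome simulation
#'
#' Convenience wrapper running [simulate_manifest()] and
#' [simulate_paired_betas()].
#'
#' @inheritParams simulate_paired_betas
#' @return A `psdmr_sim` list: `manifest`, `betas`, `design`, `truth`,
#'   `config`.
#' @export
simulate_psdmr <- function(config) {
  manifest <- simulate_manifest(config)
  sim <- simulate_paired_betas(manifest, config)
  structure(c(list(manifest = manifest), sim, list(config = config)),
            class = "psdmr_sim")
}

#' @export
print.psdmr_sim <- function(x, ...) {
  cat(sprintf("psdmr simulation: %d probes on %d chromosome(s), %d pairs, %d spiked region(s)\n",
              nrow(x$manifest), length(unique(x$manifest$chrom)),
              x$config$n_pairs, nrow(x$truth)))
  invisible(x)
}

#' Place spiked regions inside CpG clusters
#'
#' Deterministically selects `n_spikes` windows of `n_probes` adjacent probes
#' whose internal gaps never exceed `max_gap` (so each spike sits inside one
#' cluster), spread evenly across the eligible clusters, centred within each
#' chosen cluster, with alternating hyper/hypo signs unless `delta_m` gives
#' explicit signed effects.
#'
#' @param manifest A probe manifest.
#' @param n_spikes Number of regions to spike.
#' @param n_probes Probes per spiked region.
#' @param delta_m Effect size(s) on the M scale; a scalar is alternated in
#'   sign across spikes, a vector is recycled as given.
#' @param max_gap Maximum intra-cluster gap in bp (must match the analysis
#'   gap so spikes do not straddle cluster breaks).
#' @return A spikes tibble suitable for [sim_config()].
#' @export
place_spikes <- function(manifest, n_spikes, n_probes, delta_m, max_gap = 300) {
  cl <- make_clusters(manifest, max_gap = max_gap)
  sizes <- cl |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     first = min(.data$.row), n = dplyr::n()) |>
    dplyr::filter(.data$n >= n_probes)
  if (nrow(sizes) < n_spikes) {
    stop_config(sprintf("only %d clusters can hold %d probes; %d spikes requested",
                        nrow(sizes), n_probes, n_spikes))
  }
  pick <- sizes[round(seq(1, nrow(sizes), length.out = n_spikes)), ]
  chrom_first <- manifest |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(offset = min(.data$.row) - 1L)
  pick <- dplyr::left_join(pick, chrom_first, by = "chrom")
  start_global <- pick$first + floor((pick$n - n_probes) / 2)
  effects <- if (length(delta_m) == 1) {
    delta_m * rep_len(c(1, -1), n_spikes)
  } else {
    rep_len(delta_m, n_spikes)
  }
  tibble(chromosome = pick$chrom,
         start_probe_index = as.integer(start_global - pick$offset),
         n_probes = as.integer(n_probes),
         delta_m = effects)
}

#' Simulate targeted cfDNA ROI fragment counts
#'
#' Counts follow a negative binomial with per-ROI baseline means (lognormal
#' spread around `base_mean`), per-sample library-size scaling, and group
#' fold changes on selected ROIs; truth log2 fold changes and library sizes
#' are emitted alongside.
#'
#' @param n_rois Number of regions of interest.
#' @param n_case,n_control Samples per group (case carries the fold change).
#' @param base_mean Expected baseline fragment count at the reference
#'   library size.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); > 0.
#' @param effect_rois Named numeric of log2 fold changes keyed by ROI name
#'   (e.g. `c(ROI_0001 = 1)`); empty for a global null.
#' @param seed Integer seed.
#' @param roi_length_bp ROI width in bp.
#' @param roi_mean_log_sd SD of the lognormal per-ROI baseline spread.
#' @param libsize_log_sd SD of lognormal library-size variation.
#' @return A `psdmr_roi_sim` list: `counts` (wide tibble), `rois` (1-based
#'   intervals), `samples` (`sample_id`, `group`, `library_size`), `truth`
#'   (`roi`, `log2fc`).
#' @export
simulate_roi_counts <- function(n_rois, n_case, n_control,
                                base_mean = 100, dispersion = 0.1,
                                effect_rois = numeric(), seed = 1L,
                                roi_length_bp = 300,
                                roi_mean_log_sd = 0.5,
                                libsize_log_sd = 0.2) {
  if (dispersion <= 0) stop_config("dispersion must be > 0")
  if (base_mean <= 0) stop_config("base_mean must be > 0")
  if (n_case < 2 || n_control < 2) stop_config("both groups need >= 2 samples")
  set.seed(as.integer(seed))

  roi_names <- sprintf("ROI_%04d", seq_len(n_rois))
  bad <- setdiff(names(effect_rois), roi_names)
  if (length(bad) > 0) stop_config(paste("unknown effect ROI:", bad[1]))
  lfc <- setNames(numeric(n_rois), roi_names)
  lfc[names(effect_rois)] <- effect_rois

  roi_mean <- base_mean * exp(rnorm(n_rois, -roi_mean_log_sd^2 / 2, roi_mean_log_sd))
  ns <- n_case + n_control
  lib <- round(1e6 * exp(rnorm(ns, -libsize_log_sd^2 / 2, libsize_log_sd)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  sample_id <- sprintf("S%03d", seq_len(ns))

  mu <- outer(roi_mean, lib / 1e6) * 2^outer(lfc, as.integer(group == "case"))
  counts <- matrix(rnbinom(n_rois * ns, mu = mu, size = 1 / dispersion),
                   n_rois, ns, dimnames = list(roi_names, sample_id))

  start <- as.integer((seq_len(n_rois) - 1L) * (roi_length_bp + 1000L) + 1L)
  structure(
    list(counts = matrix_to_wide(counts, "roi"),
         rois = tibble(chrom = "chr1", start = start,
                       end = start + as.integer(roi_length_bp) - 1L,
                       name = roi_names),
         samples = tibble(sample_id = sample_id, group = group,
                          library_size = as.numeric(lib)),
         truth = tibble(roi = roi_names, log2fc = unname(lfc))),
    class = "psdmr_roi_sim")
}
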