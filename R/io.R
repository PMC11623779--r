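## ---- headers and primitive readers/writers -------------------------------

## every emitted file opens with tool version, config hash and seed
file_header <- function(seed, config_hash) {
  c(sprintf("#psdmr %s", packageVersion("psdmr")),
    sprintf("#config_hash=%s", config_hash),
    sprintf("#seed=%s", seed))
}

write_tsv_stamped <- function(df, path, seed, config_hash) {
  writeLines(file_header(seed, config_hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a probe manifest TSV
#'
#' Columns `probe_id`, `chrom`, `pos` (1-based); `#` lines are headers.
#'
#' @param path File path.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  out <- read_tsv_quiet(path)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(out))) stop_data("manifest file lacks required columns")
  out
}

#' Read a beta-value matrix TSV
#'
#' Wide layout: `probe_id` plus one numeric column per sample.
#'
#' @param path File path.
#' @return Wide beta tibble.
#' @export
read_beta_matrix <- function(path) {
  out <- read_tsv_quiet(path)
  if (names(out)[1] != "probe_id") stop_data("beta matrix must start with probe_id")
  out
}

#' Read a pairing sidecar TSV
#'
#' Columns `sample_id`, `pair_id`, `phenotype` (Tumor/Normal).
#'
#' @param path File path.
#' @return Design tibble (validated).
#' @export
read_pairing <- function(path) {
  out <- read_tsv_quiet(path)
  validate_design(out)
  out
}

#' Read ROI intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the internal
#' 1-based inclusive convention on input.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @export
read_roi_bed <- function(path) {
  out <- read_tsv_quiet(path, col_names = c("chrom", "start", "end", "name"))
  if (any(out$start >= out$end)) stop_data("BED intervals must satisfy start < end")
  if (anyDuplicated(out$name)) stop_data("ROI names must be unique")
  dplyr::mutate(out, start = .data$start + 1L)
}

## 1-based inclusive intervals -> BED lines (0-based half-open)
write_bed <- function(df, path, names, scores = 0) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", df$chrom, df$start - 1L,
                     df$end, names, format(scores, trim = TRUE)), path)
  invisible(path)
}

check_outputs <- function(paths, force) {
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !force) {
    stop_config(paste0("output exists (use force = TRUE to overwrite): ",
                       existing[1]))
  }
  invisible(paths)
}

## ---- orchestration over the library functions ----------------------------

#' Write simulated fixtures to disk
#'
#' Emits the paired-methylome fixture set (manifest, betas, pairing, truth)
#' and, when `roi_sim` is given, the cfDNA fixture set (ROI counts TSV, BED
#' intervals, sample sidecar, truth). Refuses to overwrite existing files
#' unless `force = TRUE`; every file carries a header with tool version,
#' config hash and seed, and a fixed seed reproduces the files
#' byte-identically.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @param roi_sim Optional [simulate_roi_counts()] result.
#' @param force Overwrite existing outputs. Default `FALSE`.
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_fixture_files <- function(config, dir, roi_sim = NULL, force = FALSE) {
  sim <- simulate_psdmr(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             betas = file.path(dir, "betas.tsv"),
             pairing = file.path(dir, "pairing.tsv"),
             truth = file.path(dir, "truth.tsv"))
  if (!is.null(roi_sim)) {
    paths <- c(paths,
               roi_counts = file.path(dir, "roi_counts.tsv"),
               rois = file.path(dir, "rois.bed"),
               roi_samples = file.path(dir, "roi_samples.tsv"),
               roi_truth = file.path(dir, "roi_truth.tsv"))
  }
  check_outputs(paths, force)
  h <- hash(unclass(config))
  write_tsv_stamped(sim$manifest, paths["manifest"], config$seed, h)
  write_tsv_stamped(sim$betas, paths["betas"], config$seed, h)
  write_tsv_stamped(sim$design, paths["pairing"], config$seed, h)
  write_tsv_stamped(sim$truth, paths["truth"], config$seed, h)
  if (!is.null(roi_sim)) {
    write_tsv_stamped(roi_sim$counts, paths["roi_counts"], config$seed, h)
    write_bed(roi_sim$rois, paths["rois"], roi_sim$rois$name)
    write_tsv_stamped(roi_sim$samples, paths["roi_samples"], config$seed, h)
    write_tsv_stamped(roi_sim$truth, paths["roi_truth"], config$seed, h)
  }
  invisible(paths)
}

#' Run the paired DMR pipeline on fixture files
#'
#' Reads the fixture set written by [simulate_fixture_files()] (or files in
#' the same formats), runs [run_paired_dmr()], optionally annotates against
#' gene models, and writes `dmrs.tsv`, `dmrs.bed`, a key/value `report.tsv`
#' (parameters, counts of significant DMRs, Hyper/Hypo fractions) and —
#' with gene models — `annotated.tsv` plus a BED of significant promoter
#' DMRs.
#'
#' @param input_dir Directory holding `manifest.tsv`, `betas.tsv`,
#'   `pairing.tsv`.
#' @param out_dir Output directory.
#' @param gene_models Optional path to a BED/GFF3 gene-model file.
#' @param fwer_threshold Significance threshold for the report. Default
#'   0.05.
#' @param upstream,downstream Promoter window, bp. Defaults 2000/500.
#' @param force Overwrite existing outputs.
#' @param ... Passed to [run_paired_dmr()] (e.g. `B`, `seed`, `min_probes`).
#' @return The `psdmr_result`, invisibly, with written paths in attribute
#'   `paths`.
#' @export
run_psdmr_files <- function(input_dir, out_dir, gene_models = NULL,
                            fwer_threshold = 0.05, upstream = 2000,
                            downstream = 500, force = FALSE, ...) {
  manifest <- read_manifest(file.path(input_dir, "manifest.tsv"))
  betas <- read_beta_matrix(file.path(input_dir, "betas.tsv"))
  design <- read_pairing(file.path(input_dir, "pairing.tsv"))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dmrs = file.path(out_dir, "dmrs.tsv"),
             bed = file.path(out_dir, "dmrs.bed"),
             report = file.path(out_dir, "report.tsv"))
  if (!is.null(gene_models)) {
    paths <- c(paths, annotated = file.path(out_dir, "annotated.tsv"),
               promoter_bed = file.path(out_dir, "significant_promoter_dmrs.bed"))
  }
  check_outputs(paths, force)

  res <- run_paired_dmr(betas, design, manifest, ...)
  md <- res$metadata
  write_tsv_stamped(res$regions, paths["dmrs"], md$seed, md$config_hash)
  if (nrow(res$regions) > 0) {
    write_bed(res$regions, paths["bed"],
              sprintf("DMR_%04d", seq_len(nrow(res$regions))),
              res$regions$n_cpgs)
  } else {
    writeLines(character(), paths["bed"])
  }

  comp <- if (nrow(res$regions) > 0) state_composition(res) else
    tibble(state = c("Hyper", "Hypo"), n = 0L, fraction = NA_real_)
  report <- tibble(
    key = c("engine", "min_probes", "max_gap", "span", "cutoff_quantile",
            "B", "seed", "scale", "null_method", "fwer_threshold",
            "n_regions", "n_significant", "frac_hyper", "frac_hypo"),
    value = as.character(c(md$engine, md$min_probes, md$max_gap, md$span,
                           md$cutoff_quantile, md$B, md$seed, md$scale,
                           md$null_method, fwer_threshold,
                           nrow(res$regions),
                           sum(res$regions$fwer < fwer_threshold),
                           comp$fraction[comp$state == "Hyper"],
                           comp$fraction[comp$state == "Hypo"])))
  write_tsv_stamped(report, paths["report"], md$seed, md$config_hash)

  if (!is.null(gene_models)) {
    models <- load_gene_models(gene_models)
    ann <- annotate_dmrs(res, promoter_regions(models, upstream, downstream),
                         models)
    write_tsv_stamped(ann, paths["annotated"], md$seed, md$config_hash)
    sig <- filter_significant(ann, fwer_threshold, promoter_only = TRUE)
    if (nrow(sig) > 0) {
      write_bed(sig, paths["promoter_bed"], sig$gene_symbol, sig$n_cpgs)
    } else {
      writeLines(character(), paths["promoter_bed"])
    }
  }
  attr(res, "paths") <- paths
  invisible(res)
}

#' Compare two DMR result files
#'
#' Reads two annotated DMR TSVs (as written by [run_psdmr_files()]), ranks
#' genes in each, and reports the top-k overlap plus the Hyper/Hypo
#' composition of each input.
#'
#' @param path_a,path_b Annotated DMR TSV paths.
#' @param top_k Prefix length for the overlap (`NULL` = full lists).
#' @param out_file Optional path for a TSV overlap report.
#' @return List with `overlap` (see [overlap_genes()]), `composition_a`,
#'   `composition_b`.
#' @export
compare_result_files <- function(path_a, path_b, top_k = NULL,
                                 out_file = NULL) {
  a <- read_tsv_quiet(path_a)
  b <- read_tsv_quiet(path_b)
  ov <- overlap_genes(ranked_genes(a), ranked_genes(b), top_k)
  out <- list(overlap = ov,
              composition_a = state_composition(dplyr::distinct(a, .data$dmr_id,
                                                                .keep_all = TRUE)),
              composition_b = state_composition(dplyr::distinct(b, .data$dmr_id,
                                                                .keep_all = TRUE)))
  if (!is.null(out_file)) {
    readr::write_tsv(tibble(
      key = c("n_shared", "n_a_only", "n_b_only", "shared"),
      value = c(ov$n_shared, ov$n_a_only, ov$n_b_only,
                paste(ov$shared, collapse = ","))), out_file, progress = FALSE)
  }
  out
}

#' Run the targeted cfDNA stage on fixture files
#'
#' Reads ROI counts, BED intervals and the sample sidecar, runs
#' [cfdna_test()], and writes the per-ROI table plus the prioritized
#' significant windows.
#'
#' @param counts_path ROI count TSV (wide, `roi` first).
#' @param rois_bed ROI BED path.
#' @param samples_path Sample sidecar TSV (`sample_id`, `group`,
#'   `library_size`).
#' @param out_dir Output directory.
#' @param alpha Unadjusted-p threshold. Default 0.05.
#' @param force Overwrite existing outputs.
#' @param ... Passed to [cfdna_test()].
#' @return The `psdmr_cfdna` object, invisibly.
#' @export
run_cfdna_files <- function(counts_path, rois_bed, samples_path, out_dir,
                            alpha = 0.05, force = FALSE, ...) {
  counts <- read_tsv_quiet(counts_path)
  rois <- read_roi_bed(rois_bed)
  samples <- read_tsv_quiet(samples_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(out_dir, "cfdna_results.tsv"),
             significant = file.path(out_dir, "cfdna_significant.tsv"))
  check_outputs(paths, force)
  res <- cfdna_test(counts, rois, samples, ...)
  h <- hash(res$metadata)
  write_tsv_stamped(res$results, paths["results"], "NA", h)
  write_tsv_stamped(prioritize_windows(res, alpha), paths["significant"], "NA", h)
  attr(res, "paths") <- paths
  invisible(res)
}
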