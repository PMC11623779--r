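#' Load gene models from BED6 or GFF3
#'
#' Files are parsed with rtracklayer and normalized to the internal 1-based
#' inclusive convention (BED input is 0-based half-open and converted on
#' import). The TSS is the span start on the + strand and the span end on
#' the - strand. Duplicate models by (symbol, tss) are collapsed.
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file of gene intervals.
#' @return Tibble `gene_symbol`, `entrez_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss` (all coordinates 1-based inclusive).
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop_config(paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop_data(paste0("failed to parse ", path, ": ",
                                         conditionMessage(e))))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ext %in% c("gff", "gff3")) {
    keep <- mc$type == "gene"
    gr <- gr[keep]
    mc <- mc[keep, , drop = FALSE]
    symbol <- if (!is.null(mc$Name)) as.character(mc$Name) else
      if (!is.null(mc$gene_name)) as.character(mc$gene_name) else
        as.character(mc$ID)
    entrez <- if (!is.null(mc$entrez_id)) as.character(mc$entrez_id) else NA_character_
  } else {
    symbol <- as.character(mc$name)
    entrez <- NA_character_
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop_data("gene models must carry an explicit +/- strand")
  }
  out <- tibble(
    gene_symbol = symbol,
    entrez_id = entrez,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr))
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  dplyr::distinct(out, .data$gene_symbol, .data$tss, .keep_all = TRUE)
}

#' Write gene models to BED6 or GFF3
#'
#' The exact inverse of [load_gene_models()]'s coordinate normalization:
#' BED output converts to 0-based half-open, GFF3 keeps 1-based inclusive.
#'
#' @param models Gene-model tibble from [load_gene_models()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     models$chrom, models$start - 1L, models$end,
                     models$gene_symbol, models$strand)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tpsdmr\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       models$chrom, models$start, models$end, models$strand,
                       models$gene_symbol, models$gene_symbol))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive promoter windows around transcription start sites
#'
#' On the + strand a promoter is `[tss - upstream, tss + downstream]`; on
#' the - strand the window is mirrored. Windows are clipped at position 1.
#' The defaults (2000 bp upstream, 500 bp downstream) follow common
#' promoter-annotation convention and are configurable.
#'
#' @param models Gene-model tibble.
#' @param upstream,downstream Window extents in bp (both >= 0, not both 0).
#' @return Tibble `gene_symbol`, `chrom`, `strand`, `start`, `end`, `tss`.
#' @export
promoter_regions <- function(models, upstream = 2000, downstream = 500) {
  if (upstream < 0 || downstream < 0) stop_config("window extents must be >= 0")
  if (upstream == 0 && downstream == 0) stop_config("promoter window cannot be empty")
  tibble(
    gene_symbol = models$gene_symbol,
    chrom = models$chrom,
    strand = models$strand,
    start = pmax(1L, as.integer(ifelse(models$strand == "+",
                                       models$tss - upstream,
                                       models$tss - downstream))),
    end = as.integer(ifelse(models$strand == "+",
                            models$tss + downstream,
                            models$tss + upstream)),
    tss = models$tss)
}

#' Annotate DMRs with genes and promoters
#'
#' Each DMR is labeled with every promoter it overlaps by at least 1 bp
#' (all reported, one row per gene); DMRs without a promoter hit that
#' overlap a gene span are labeled `gene_body` (again per gene); remaining
#' DMRs are `intergenic`. Chromosomes absent from the annotation fall
#' through to `intergenic`.
#'
#' @param dmrs A `psdmr_result` or a region tibble with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param promoters Promoter tibble from [promoter_regions()].
#' @param models Gene-model tibble (for gene-body spans).
#' @return Tibble: the DMR columns plus `dmr_id`, `gene_symbol`,
#'   `relation` (promoter / gene_body / intergenic).
#' @export
annotate_dmrs <- function(dmrs, promoters, models) {
  regions <- if (inherits(dmrs, "psdmr_result")) dmrs$regions else as_tibble(dmrs)
  if (nrow(regions) == 0) {
    return(dplyr::mutate(regions, dmr_id = integer(),
                         gene_symbol = character(), relation = character()))
  }
  regions <- dplyr::mutate(regions, dmr_id = dplyr::row_number())
  gr_dmr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
  overlap_pairs <- function(tbl) {
    gr <- GenomicRanges::GRanges(tbl$chrom, IRanges::IRanges(tbl$start, tbl$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_dmr, gr))
    tibble(dmr_id = S4Vectors::queryHits(hits),
           gene_symbol = tbl$gene_symbol[S4Vectors::subjectHits(hits)])
  }
  prom_hits <- dplyr::mutate(overlap_pairs(promoters), relation = "promoter")
  body_hits <- overlap_pairs(models) |>
    dplyr::filter(!.data$dmr_id %in% prom_hits$dmr_id) |>
    dplyr::mutate(relation = "gene_body")
  hit <- dplyr::bind_rows(prom_hits, body_hits) |> dplyr::distinct()
  inter <- tibble(dmr_id = setdiff(regions$dmr_id, hit$dmr_id),
                  gene_symbol = NA_character_, relation = "intergenic")
  dplyr::left_join(regions, dplyr::bind_rows(hit, inter), by = "dmr_id") |>
    dplyr::arrange(.data$dmr_id)
}

#' Prioritize significant (promoter) DMRs
#'
#' Keeps records with `fwer` strictly below the threshold; with
#' `promoter_only = TRUE` a promoter relation is additionally required.
#' A record with `fwer` exactly at the threshold is dropped.
#'
#' @param annotated Output of [annotate_dmrs()] (or any tibble with `fwer`).
#' @param fwer_threshold Significance threshold in (0, 1]. Default 0.05.
#' @param promoter_only Require a promoter relation. Default `FALSE`.
#' @return The filtered tibble (a subset of the input rows).
#' @export
filter_significant <- function(annotated, fwer_threshold = 0.05,
                               promoter_only = FALSE) {
  if (fwer_threshold <= 0 || fwer_threshold > 1) {
    stop_config("fwer_threshold must be in (0, 1]")
  }
  out <- dplyr::filter(annotated, .data$fwer < fwer_threshold)
  if (promoter_only) out <- dplyr::filter(out, .data$relation == "promoter")
  out
}
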