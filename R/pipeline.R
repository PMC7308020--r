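#' Stage 0: linker filtering of a paired FASTQ library
#'
#' Thin driver over [process_fastq_pair()]: classifies read pairs by
#' half-linker combination, trims non-chimeric pairs to tags, and writes the
#' trimmed FASTQ pair plus a classification summary (TSV and JSON) into
#' `outdir`.
#'
#' @param fastq_1,fastq_2 input FASTQ paths.
#' @param outdir output directory (created if absent).
#' @param config a [linker_config()].
#' @return (invisibly) the summary list.
#' @export
run_stage0 <- function(fastq_1, fastq_2, outdir, config = linker_config()) {
  if (!file.exists(fastq_1) || !file.exists(fastq_2)) {
    stop("stage0: input FASTQ not found")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- process_fastq_pair(
    fastq_1, fastq_2,
    file.path(outdir, "tags_1.fastq"), file.path(outdir, "tags_2.fastq"),
    config)
  cls <- data.frame(class = names(res$counts),
                    count = unlist(res$counts, use.names = FALSE))
  utils::write.table(cls, file.path(outdir, "linker_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res, file.path(outdir, "stage0_summary.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Stage 2: PET classification
#'
#' Reads mapped PETs, optionally removes blacklist overlaps, removes PCR
#' duplicates, finds the self/intra length cut-off by the elbow method, and
#' writes the self-ligated / intra / inter partition, the length histogram
#' and a summary JSON into `outdir`.
#'
#' @param pets PET input: a path (TSV or BAM per `format`) or a data.frame
#'   from [read_pets()].
#' @param outdir output directory.
#' @param format,point_rule,tag_length passed to [read_pets()] when `pets`
#'   is a path.
#' @param blacklist optional BED path or `GRanges`.
#' @param bin_width histogram bin width (bp).
#' @param dedup_tol duplicate-matching tolerance (bp).
#' @param cutoff optional manual cut-off overriding the elbow.
#' @return (invisibly) the `pet_partition`.
#' @export
run_stage2 <- function(pets, outdir, format = "tsv",
                       point_rule = "midpoint", tag_length = 20L,
                       blacklist = NULL, bin_width = 100L,
                       dedup_tol = 1L, cutoff = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(pets)) {
    pets <- read_pets(pets, format = format, point_rule = point_rule,
                      tag_length = tag_length)
  }
  n_in <- nrow(pets)
  if (!is.null(blacklist)) pets <- filter_blacklist(pets, blacklist)
  n_blacklisted <- n_in - nrow(pets)
  pets <- dedup_pets(pets, tol = dedup_tol)
  n_dedup <- nrow(pets)
  part <- classify_pets(pets, bin_width = bin_width, cutoff = cutoff)
  utils::write.table(part$self_ligated,
                     file.path(outdir, "self_ligated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wr <- function(df, nm) {
    utils::write.table(df, file.path(outdir, nm), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(part$intra, "intra.tsv")
  wr(part$inter, "inter.tsv")
  if (!is.null(part$histogram)) {
    h <- part$histogram
    wr(data.frame(bin_start = h$edges[-length(h$edges)],
                  bin_end = h$edges[-1], count = h$counts,
                  log10_mid = h$log_mid), "length_histogram.tsv")
  }
  jsonlite::write_json(
    list(n_input = n_in, n_blacklisted = n_blacklisted,
         n_after_dedup = n_dedup, cutoff = part$cutoff,
         n_self = nrow(part$self_ligated), n_intra = nrow(part$intra),
         n_inter = nrow(part$inter), n_dropped_xy = part$n_dropped_xy),
    file.path(outdir, "stage2_summary.json"), auto_unbox = TRUE)
  invisible(part)
}

#' Stage 3: peak calling on self-ligated PETs
#'
#' Segments the self-ligated PETs into regions of mutual overlap, fits each
#' region's SGT mixture with BIC model selection (regions are independent,
#' so results do not depend on processing order), calls significant binding
#' sites against local Poisson backgrounds with one genome-wide BH
#' correction, and writes narrowPeak, a detailed peak TSV, a region BED and
#' a summary JSON.
#'
#' @param self_pets data.frame `chrom`, `x`, `y`, or a path to a TSV with
#'   those columns (the stage-2 output).
#' @param chrom_sizes data.frame from [read_chrom_sizes()], or a path.
#' @param outdir output directory.
#' @param fdr FDR threshold.
#' @param G_max largest cluster count per region.
#' @param use_lambda include the Lambda normalizer during fitting.
#' @param ... passed to [ecme_fit()] via [select_model()].
#' @return (invisibly) the peak-call data.frame.
#' @export
run_stage3 <- function(self_pets, chrom_sizes, outdir, fdr = 0.05,
                       G_max = 3L, use_lambda = TRUE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(self_pets)) {
    self_pets <- utils::read.table(self_pets, header = TRUE,
                                   stringsAsFactors = FALSE)
  }
  if (is.character(chrom_sizes)) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  regions <- segment_regions(self_pets)
  fits <- lapply(regions, function(r) {
    list(region = r,
         fit = select_model(r, G_max = G_max, use_lambda = use_lambda, ...))
  })
  calls <- call_peaks(fits, chrom_sizes, self_pets, fdr = fdr)
  write_peaks(calls, file.path(outdir, "peaks.narrowPeak"),
              format = "narrowPeak")
  write_peaks(calls, file.path(outdir, "peaks.tsv"), format = "tsv")
  if (length(regions) > 0) {
    bed <- data.frame(
      chrom = vapply(regions, `[[`, "", "chrom"),
      start = vapply(regions, function(r) r$start - 1L, 0),
      end = vapply(regions, `[[`, 0, "end"))
    utils::write.table(bed, file.path(outdir, "regions.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(n_self_pets = nrow(self_pets), n_regions = length(regions),
         n_candidates = nrow(calls),
         n_significant = sum(calls$significant), fdr = fdr),
    file.path(outdir, "stage3_summary.json"), auto_unbox = TRUE)
  invisible(calls)
}
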