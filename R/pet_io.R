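#' Read mapped PETs from a TSV or paired-end BAM
#'
#' A PET (paired-end tag) is a pair of short aligned tags. The TSV dialect has
#' a header `chrom1 pos1 strand1 chrom2 pos2 strand2` where `pos` is the
#' 5'-end coordinate of each tag (1-based); the aligned span is reconstructed
#' from `tag_length`. BAM input is read with Rsamtools and mates are paired by
#' read name; records without a mapped mate are skipped (count reported via a
#' message).
#'
#' Each tag is reduced to a single `point` coordinate by `point_rule`:
#' `"midpoint"` (default) takes the floor of the span midpoint and is
#' strand-neutral, matching a model that ignores strand; `"five_prime"` keeps
#' the 5' end.
#'
#' @param path input file.
#' @param format `"tsv"` or `"bam"`.
#' @param point_rule `"midpoint"` or `"five_prime"`.
#' @param tag_length aligned tag length in bp used to reconstruct TSV spans.
#' @return a data.frame with one row per PET: `chrom1,start1,end1,strand1,
#'   point1,chrom2,start2,end2,strand2,point2,read_id`.
#' @export
read_pets <- function(path, format = c("tsv", "bam"),
                      point_rule = c("midpoint", "five_prime"),
                      tag_length = 20L) {
  format <- match.arg(format)
  point_rule <- match.arg(point_rule)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "tsv") {
    read_pets_tsv(path, point_rule, tag_length)
  } else {
    read_pets_bam(path, point_rule)
  }
}

read_pets_tsv <- function(path, point_rule, tag_length) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_pets())
  first <- tolower(gsub("\\s+", " ", trimws(lines[1])))
  has_header <- startsWith(first, "chrom1")
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0) return(empty_pets())
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(trimws(body), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields != 6L)) {
    bad <- which(n_fields != 6L)[1]
    stop(sprintf("malformed PET TSV row at line %d: expected 6 fields, got %d",
                 bad + offset, n_fields[bad]))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  # tolerate both ASCII '-' and typographic minus for the minus strand
  norm_strand <- function(s) ifelse(s %in% c("-", "−"), "-", s)
  s1 <- norm_strand(m[, 3]); s2 <- norm_strand(m[, 6])
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  pos2 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos1) | is.na(pos2) | !(s1 %in% c("+", "-")) |
                 !(s2 %in% c("+", "-")))
  if (length(bad) > 0) {
    stop(sprintf("malformed PET TSV row at line %d: bad position or strand",
                 bad[1] + offset))
  }
  span <- function(pos, strand) {
    start <- ifelse(strand == "+", pos, pos - tag_length + 1L)
    cbind(start, start + tag_length - 1L)
  }
  sp1 <- span(pos1, s1); sp2 <- span(pos2, s2)
  pets <- data.frame(
    chrom1 = m[, 1], start1 = sp1[, 1], end1 = sp1[, 2], strand1 = s1,
    point1 = tag_point(sp1[, 1], sp1[, 2], s1, point_rule),
    chrom2 = m[, 4], start2 = sp2[, 1], end2 = sp2[, 2], strand2 = s2,
    point2 = tag_point(sp2[, 1], sp2[, 2], s2, point_rule),
    read_id = sprintf("pet%07d", seq_along(pos1)),
    stringsAsFactors = FALSE)
  pets
}

tag_point <- function(start, end, strand, point_rule) {
  if (point_rule == "midpoint") {
    as.integer(floor((start + end) / 2))
  } else {
    as.integer(ifelse(strand == "+", start, end))
  }
}

read_pets_bam <- function(path, point_rule) {
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth"),
    flag = flag)
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  if (length(b$qname) == 0) return(empty_pets())
  first <- bitwAnd(b$flag, 64L) > 0L
  df <- data.frame(qname = b$qname, first = first,
                   chrom = as.character(b$rname),
                   strand = as.character(b$strand),
                   start = b$pos, end = b$pos + b$qwidth - 1L,
                   stringsAsFactors = FALSE)
  m1 <- df[df$first, ]; m2 <- df[!df$first, ]
  idx <- match(m1$qname, m2$qname)
  n_unpaired <- sum(is.na(idx)) + (nrow(m2) - sum(!is.na(idx)))
  if (n_unpaired > 0) {
    message(sprintf("read_pets: skipped %d unpaired BAM records", n_unpaired))
  }
  keep <- !is.na(idx)
  m1 <- m1[keep, ]; m2 <- m2[idx[keep], ]
  if (nrow(m1) == 0) return(empty_pets())
  data.frame(
    chrom1 = m1$chrom, start1 = m1$start, end1 = m1$end, strand1 = m1$strand,
    point1 = tag_point(m1$start, m1$end, m1$strand, point_rule),
    chrom2 = m2$chrom, start2 = m2$start, end2 = m2$end, strand2 = m2$strand,
    point2 = tag_point(m2$start, m2$end, m2$strand, point_rule),
    read_id = m1$qname, stringsAsFactors = FALSE)
}

empty_pets <- function() {
  data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
             strand1 = character(), point1 = integer(),
             chrom2 = character(), start2 = integer(), end2 = integer(),
             strand2 = character(), point2 = integer(),
             read_id = character(), stringsAsFactors = FALSE)
}

#' Read a UCSC chrom.sizes table
#'
#' @param path two-column whitespace-separated text: chromosome name, size.
#' @return data.frame with `name` and `size`; duplicate names are an error.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(name = character(), size = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 2L)) {
    stop("chrom.sizes rows must have at least two fields")
  }
  name <- vapply(fields, `[[`, "", 1L)
  size_chr <- vapply(fields, `[[`, "", 2L)
  size <- suppressWarnings(as.numeric(size_chr))
  if (any(is.na(size) | size != floor(size))) {
    stop("non-integer chromosome size in chrom.sizes")
  }
  if (anyDuplicated(name)) {
    stop(sprintf("duplicate chromosome name '%s' in chrom.sizes",
                 name[duplicated(name)][1]))
  }
  if (any(size <= 0)) stop("chromosome sizes must be > 0")
  data.frame(name = name, size = size, stringsAsFactors = FALSE)
}

#' Remove PETs overlapping blacklisted regions
#'
#' A PET is removed when either tag's aligned span intersects any blacklist
#' interval on the same chromosome. The blacklist is BED (0-based half-open)
#' when given as a path, or a `GRanges` already in 1-based coordinates.
#'
#' @param pets data.frame from [read_pets()].
#' @param blacklist path to a BED3 file, or a `GenomicRanges::GRanges`.
#' @return the filtered data.frame, input order preserved.
#' @export
filter_blacklist <- function(pets, blacklist) {
  if (is.character(blacklist)) {
    blacklist <- rtracklayer::import(blacklist, format = "BED")
  }
  if (length(blacklist) == 0 || nrow(pets) == 0) return(pets)
  hit <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    GenomicRanges::countOverlaps(gr, blacklist) > 0
  }
  drop <- hit(pets$chrom1, pets$start1, pets$end1) |
    hit(pets$chrom2, pets$start2, pets$end2)
  pets[!drop, , drop = FALSE]
}

#' Write peak calls to narrowPeak or TSV
#'
#' narrowPeak uses BED conventions: `chromStart = interval_start - 1`
#' (0-based), `chromEnd = interval_end`, `signalValue` = PETs in the cluster,
#' `pValue`/`qValue` = -log10 of the combined p-value / q-value (capped at
#' `log_cap` when the probability underflows to 0), and `peak` = summit offset
#' from `chromStart` relative to the 1-based interval start.
#'
#' @param calls data.frame of peak calls from [call_peaks()], sorted by
#'   (chrom, interval_start).
#' @param path output file.
#' @param format `"narrowPeak"` or `"tsv"`.
#' @param log_cap value written for -log10(0).
#' @export
write_peaks <- function(calls, path, format = c("narrowPeak", "tsv"),
                        log_cap = 330) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  neglog10 <- function(p) ifelse(p <= 0, log_cap, pmin(log_cap, -log10(p)))
  np <- data.frame(
    chrom = calls$chrom,
    chromStart = as.integer(calls$interval_start - 1L),
    chromEnd = as.integer(calls$interval_end),
    name = sprintf("peak_%d", seq_len(nrow(calls))),
    score = pmin(1000L, as.integer(round(10 * neglog10(calls$q_value)))),
    strand = rep(".", nrow(calls)),
    signalValue = calls$n_pets,
    pValue = neglog10(calls$p_combined),
    qValue = neglog10(calls$q_value),
    peak = as.integer(calls$summit - calls$interval_start),
    stringsAsFactors = FALSE)
  utils::write.table(np, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
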