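#' Half-linker configuration for stage 0
#'
#' ChIA-PET reads have the layout `[tag][half-linker][rest]`: the restriction
#' enzyme cuts `tag_length` bp (default 20, the MmeI distance) from its site,
#' so the genomic tag precedes the half-linker barcode. The default barcodes
#' are TAAG (linker A) and ATGT (linker B).
#'
#' @param half_a,half_b half-linker barcode sequences.
#' @param tag_length tag length in bp.
#' @param max_mismatch mismatches tolerated when matching a barcode.
#' @return a list of class `linker_config`.
#' @export
linker_config <- function(half_a = "TAAG", half_b = "ATGT",
                          tag_length = 20L, max_mismatch = 0L) {
  half_a <- toupper(half_a); half_b <- toupper(half_b)
  if (identical(half_a, half_b)) stop("half_a and half_b must differ")
  if (tag_length <= 0) stop("tag_length must be > 0")
  if (nchar(half_a) != nchar(half_b)) {
    stop("half-linkers must have equal length")
  }
  structure(list(half_a = half_a, half_b = half_b,
                 tag_length = as.integer(tag_length),
                 max_mismatch = as.integer(max_mismatch)),
            class = "linker_config")
}

n_mismatch <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Identify the half-linker of one read
#'
#' Looks at the subsequence immediately after the tag (offset `tag_length`)
#' and compares it to both barcodes within `max_mismatch`. If both match, the
#' fewer-mismatch barcode wins; an exact tie, or a read too short to carry a
#' barcode, yields `"none"`.
#'
#' @param read_seq read sequence (character).
#' @param config a [linker_config()].
#' @return `"A"`, `"B"` or `"none"` (vectorized over reads).
#' @export
detect_half_linker <- function(read_seq, config = linker_config()) {
  read_seq <- toupper(read_seq)
  L <- nchar(config$half_a)
  vapply(read_seq, function(s) {
    if (nchar(s) < config$tag_length + L) return("none")
    probe <- substr(s, config$tag_length + 1L, config$tag_length + L)
    ma <- n_mismatch(probe, config$half_a)
    mb <- n_mismatch(probe, config$half_b)
    ok_a <- ma <= config$max_mismatch
    ok_b <- mb <= config$max_mismatch
    if (ok_a && (!ok_b || ma < mb)) "A"
    else if (ok_b && (!ok_a || mb < ma)) "B"
    else "none"
  }, "", USE.NAMES = FALSE)
}

#' Classify a read pair by its half-linker combination
#'
#' A/A and B/B pairs are non-chimeric (genuine proximity-ligation products);
#' A/B and B/A are chimeric (random inter-complex ligations); a pair missing
#' either half-linker is ambiguous. Only non-chimeric pairs proceed to
#' trimming and mapping.
#'
#' @param read_1,read_2 read sequences (character vectors, parallel).
#' @param config a [linker_config()].
#' @return character vector with values in
#'   `c("ambiguous", "chimeric", "non_chimeric_AA", "non_chimeric_BB")`.
#' @export
classify_pair <- function(read_1, read_2, config = linker_config()) {
  h1 <- detect_half_linker(read_1, config)
  h2 <- detect_half_linker(read_2, config)
  out <- rep("ambiguous", length(h1))
  out[h1 == "A" & h2 == "A"] <- "non_chimeric_AA"
  out[h1 == "B" & h2 == "B"] <- "non_chimeric_BB"
  out[(h1 == "A" & h2 == "B") | (h1 == "B" & h2 == "A")] <- "chimeric"
  out
}

#' Trim the half-linkers off a non-chimeric pair
#'
#' @param read_1,read_2 read sequences of a pair classified non-chimeric.
#' @param config a [linker_config()].
#' @return list of `tag_1` and `tag_2`, each the first `tag_length` bases.
#' @export
trim_pair <- function(read_1, read_2, config = linker_config()) {
  cls <- classify_pair(read_1, read_2, config)
  if (any(!startsWith(cls, "non_chimeric"))) {
    stop("trim_pair called on a pair that is not non-chimeric")
  }
  list(tag_1 = substr(read_1, 1L, config$tag_length),
       tag_2 = substr(read_2, 1L, config$tag_length))
}

#' Keep only tags made of standard residues
#'
#' @param tag_seq character vector of tag sequences.
#' @return logical: `TRUE` iff every character is A/C/G/T (case-insensitive).
#' @export
drop_nonstandard <- function(tag_seq) {
  grepl("^[ACGTacgt]+$", tag_seq)
}

#' Stage 0: filter and trim a paired FASTQ library
#'
#' Reads two FASTQ files (mates matched by record order), classifies every
#' pair by half-linker combination, trims the non-chimeric pairs to their
#' `tag_length` nt tags, drops pairs whose tags contain non-standard residues,
#' and writes two trimmed FASTQ files.
#'
#' @param fastq_1,fastq_2 input FASTQ paths (gzip allowed).
#' @param out_1,out_2 output FASTQ paths for the trimmed tags.
#' @param config a [linker_config()].
#' @return (invisibly) a list with the classification `counts` (one per
#'   class), `n_nonstandard` dropped pairs and `n_written`.
#' @export
process_fastq_pair <- function(fastq_1, fastq_2, out_1, out_2,
                               config = linker_config()) {
  r1 <- Biostrings::readDNAStringSet(fastq_1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq_2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop("FASTQ mates differ in record count")
  }
  s1 <- as.character(r1); s2 <- as.character(r2)
  cls <- classify_pair(s1, s2, config)
  counts <- table(factor(cls, levels = c("ambiguous", "chimeric",
                                         "non_chimeric_AA",
                                         "non_chimeric_BB")))
  keep <- startsWith(cls, "non_chimeric")
  t1 <- substr(s1[keep], 1L, config$tag_length)
  t2 <- substr(s2[keep], 1L, config$tag_length)
  std <- drop_nonstandard(t1) & drop_nonstandard(t2)
  n_nonstandard <- sum(!std)
  idx <- which(keep)[std]
  tl <- config$tag_length
  write_tags <- function(reads, tags, idx, path) {
    out <- Biostrings::DNAStringSet(tags)
    names(out) <- names(reads)[idx]
    quals <- Biostrings::BStringSet(
      substr(as.character(S4Vectors::mcols(reads)$qualities[idx]), 1L, tl))
    Biostrings::writeXStringSet(out, path, format = "fastq",
                                qualities = quals)
  }
  write_tags(r1, t1[std], idx, out_1)
  write_tags(r2, t2[std], idx, out_2)
  invisible(list(counts = as.list(counts),
                 n_nonstandard = n_nonstandard,
                 n_written = length(idx)))
}
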