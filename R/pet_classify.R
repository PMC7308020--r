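#' Length of a same-chromosome PET
#'
#' The length of a PET is the distance between its two tag points.
#'
#' @param pets data.frame from [read_pets()] with both tags on one chromosome.
#' @return integer vector of |point2 - point1|.
#' @export
pet_length <- function(pets) {
  if (any(pets$chrom1 != pets$chrom2)) {
    stop("pet_length requires both tags on the same chromosome")
  }
  abs(pets$point2 - pets$point1)
}

#' Remove PCR duplicates
#'
#' PETs whose two tag points both lie within `tol` bp (default 1) of an
#' already-kept PET's tag points, on the same chromosomes, are removed;
#' scanning is over PETs sorted by (chrom1, chrom2, point1, point2) and the
#' first-kept PET wins. Tags are first ordered within each PET so that
#' point1 <= point2 (chromosome name order breaks inter-chromosomal ties).
#'
#' @param pets data.frame from [read_pets()].
#' @param tol matching tolerance in bp.
#' @return the deduplicated data.frame.
#' @export
dedup_pets <- function(pets, tol = 1L) {
  if (nrow(pets) == 0) return(pets)
  pets <- canonicalize_pets(pets)
  key <- paste(pets$chrom1, pets$chrom2)
  ord <- order(key, pets$point1, pets$point2)
  out_keep <- logical(nrow(pets))
  for (grp in split(ord, key[ord])) {
    kept_p1 <- numeric(0); kept_p2 <- numeric(0)
    for (i in grp) {
      p1 <- pets$point1[i]; p2 <- pets$point2[i]
      dup <- FALSE
      j <- length(kept_p1)
      while (j >= 1 && p1 - kept_p1[j] <= tol) {
        if (abs(p2 - kept_p2[j]) <= tol) { dup <- TRUE; break }
        j <- j - 1
      }
      if (!dup) {
        kept_p1 <- c(kept_p1, p1); kept_p2 <- c(kept_p2, p2)
        out_keep[i] <- TRUE
      }
    }
  }
  pets[sort(which(out_keep)), , drop = FALSE]
}

canonicalize_pets <- function(pets) {
  swap <- (pets$chrom2 < pets$chrom1) |
    (pets$chrom1 == pets$chrom2 & pets$point2 < pets$point1)
  if (any(swap)) {
    cols1 <- c("chrom1", "start1", "end1", "strand1", "point1")
    cols2 <- c("chrom2", "start2", "end2", "strand2", "point2")
    tmp <- pets[swap, cols1]
    pets[swap, cols1] <- pets[swap, cols2]
    pets[swap, cols2] <- tmp
  }
  pets
}

#' Histogram of PET lengths
#'
#' Uniform bins of `bin_width` bp spanning the minimum to the maximum length.
#' Bins are left-closed/right-open except the last, which is closed. The
#' log10 bin midpoints are carried along for the elbow construction, whose
#' x-axis is the log-length.
#'
#' @param lengths PET lengths (bp), nonempty.
#' @param bin_width bin width in bp.
#' @return a list of class `length_histogram` with `edges`, `counts`,
#'   `log_mid`.
#' @export
length_histogram <- function(lengths, bin_width = 100L) {
  if (length(lengths) == 0) stop("length_histogram needs a nonempty input")
  lo <- min(lengths); hi <- max(lengths)
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / bin_width)))
  edges <- lo + bin_width * (0:n_bins)
  bin <- findInterval(lengths, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(edges = edges, counts = counts, log_mid = log10(mids)),
            class = "length_histogram")
}

#' Elbow cut-off between self-ligated and intra-chromosomal lengths
#'
#' On the (log10 midpoint, count) points scaled to the unit square, draws the
#' chord from the highest-count bin (the self-ligated peak) to the rightmost
#' bin and returns the upper edge (bp) of the bin — at or right of the peak —
#' with the largest perpendicular distance to that chord. Ties break leftmost.
#'
#' @param hist a [length_histogram()].
#' @return the cut-off in bp.
#' @export
elbow_cutoff <- function(hist) {
  counts <- hist$counts
  n <- length(counts)
  if (sum(counts > 0) < 3) {
    stop("elbow_cutoff needs at least 3 nonzero bins")
  }
  peak <- which.max(counts)
  if (peak == n) stop("elbow_cutoff: histogram peak is the rightmost bin")
  xs <- unit_scale(hist$log_mid)
  ys <- unit_scale(counts)
  p1 <- c(xs[peak], ys[peak])
  p2 <- c(xs[n], ys[n])
  v <- p2 - p1
  nv <- sqrt(sum(v * v))
  idx <- peak:n
  d <- abs(v[1] * (p1[2] - ys[idx]) - (p1[1] - xs[idx]) * v[2]) / nv
  best <- idx[which.max(d)]
  hist$edges[best + 1L]
}

unit_scale <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

#' Partition PETs into self-ligated, intra- and inter-chromosomal
#'
#' Inter-chromosomal PETs have tags on different chromosomes. Same-chromosome
#' PETs are split by a length cut-off — found by [elbow_cutoff()] on the
#' length histogram unless supplied — into self-ligated (length <= cutoff)
#' and intra-chromosomal (length > cutoff). Self-ligated PETs are reduced to
#' ordered coordinate pairs (x, y) with x < y; pairs whose points coincide
#' are dropped (count reported).
#'
#' @param pets deduplicated data.frame from [read_pets()].
#' @param bin_width histogram bin width (bp).
#' @param cutoff optional manual cut-off (bp) overriding the elbow.
#' @return a list of class `pet_partition`: `self_ligated` (data.frame
#'   `chrom`, `x`, `y`), `intra`, `inter` (PET data.frames), `cutoff`,
#'   `histogram`, `n_dropped_xy`.
#' @export
classify_pets <- function(pets, bin_width = 100L, cutoff = NULL) {
  inter <- pets[pets$chrom1 != pets$chrom2, , drop = FALSE]
  same <- pets[pets$chrom1 == pets$chrom2, , drop = FALSE]
  hist <- NULL
  if (nrow(same) == 0) {
    part <- list(self_ligated = data.frame(chrom = character(),
                                           x = integer(), y = integer(),
                                           stringsAsFactors = FALSE),
                 intra = same, inter = inter, cutoff = NA_real_,
                 histogram = NULL, n_dropped_xy = 0L)
    return(structure(part, class = "pet_partition"))
  }
  len <- pet_length(same)
  if (is.null(cutoff)) {
    hist <- length_histogram(len, bin_width)
    cutoff <- elbow_cutoff(hist)
  }
  is_self <- len <= cutoff
  selfp <- same[is_self, , drop = FALSE]
  x <- pmin(selfp$point1, selfp$point2)
  y <- pmax(selfp$point1, selfp$point2)
  ok <- x < y
  self_df <- data.frame(chrom = selfp$chrom1[ok], x = x[ok], y = y[ok],
                        stringsAsFactors = FALSE)
  self_df <- self_df[order(self_df$chrom, self_df$x, self_df$y), ,
                     drop = FALSE]
  rownames(self_df) <- NULL
  structure(list(self_ligated = self_df,
                 intra = same[!is_self, , drop = FALSE],
                 inter = inter,
                 cutoff = cutoff,
                 histogram = hist,
                 n_dropped_xy = sum(!ok)),
            class = "pet_partition")
}

#' @export
print.pet_partition <- function(x, ...) {
  cat(sprintf(
    "<pet_partition> %d self-ligated / %d intra / %d inter (cutoff %s bp)\n",
    nrow(x$self_ligated), nrow(x$intra), nrow(x$inter),
    format(x$cutoff)))
  invisible(x)
}
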