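#' Sample from the SGT distribution
#'
#' Inverse-CDF sampling on uniforms from the current RNG stream; seed with
#' `set.seed()` for reproducibility. Note the q = 1 tails are cubic, so the
#' distribution has no finite variance — summaries of draws should use
#' quantiles, never moments beyond the first.
#'
#' @param n number of draws.
#' @param mu,lam,sigma SGT parameters.
#' @return numeric vector of n positions.
#' @export
sample_sgt <- function(n, mu, lam = 0, sigma = 1) {
  if (n == 0) return(numeric(0))
  sgt_quantile(stats::runif(n), mu, lam, sigma)
}

#' Simulate the self-ligated PETs of one binding site
#'
#' Upstream coordinates are drawn from the upstream SGT marginal and
#' downstream from the downstream marginal; pairs are accepted only when
#' x < y (the support of the joint density), so the reciprocal of the
#' acceptance rate is a Monte-Carlo estimate of the Lambda normalizer.
#' Coordinates are rounded to integer bp (pairs that collide after rounding
#' are re-drawn).
#'
#' @param pair a [peak_pair()].
#' @param n_pets number of PETs to emit (>= 2).
#' @param chrom chromosome name attached to the output.
#' @return data.frame `chrom`, `x`, `y` with attributes `acceptance_rate`
#'   and `n_proposed`.
#' @export
simulate_site <- function(pair, n_pets, chrom = "chrSim") {
  stopifnot(n_pets >= 2)
  xs <- integer(0); ys <- integer(0)
  n_prop <- 0L; n_acc <- 0L
  while (length(xs) < n_pets) {
    m <- max(2L * (n_pets - length(xs)), 100L)
    x <- sample_sgt(m, pair$mu_x, pair$lam_x, pair$sigma_x)
    y <- sample_sgt(m, pair$mu_y, pair$lam_y, pair$sigma_y)
    ok <- x < y
    n_prop <- n_prop + m
    n_acc <- n_acc + sum(ok)
    xi <- as.integer(round(x[ok])); yi <- as.integer(round(y[ok]))
    keep <- xi < yi
    xs <- c(xs, xi[keep]); ys <- c(ys, yi[keep])
    if (n_prop > 1000L && n_acc / n_prop < 1e-3) {
      stop("simulate_site: acceptance rate below 1e-3; pathological site")
    }
  }
  out <- data.frame(chrom = chrom, x = xs[seq_len(n_pets)],
                    y = ys[seq_len(n_pets)], stringsAsFactors = FALSE)
  attr(out, "acceptance_rate") <- n_acc / n_prop
  attr(out, "n_proposed") <- n_prop
  out
}

#' Configuration for a simulated PET dataset
#'
#' Describes one or more chromosomes carrying planted binding sites,
#' triangle-uniform noise spans (noise is placed around declared spans, not
#' genome-wide, so segmentation produces realistic mixed regions),
#' long-range intra-chromosomal PETs (lognormal lengths) and
#' inter-chromosomal PETs.
#'
#' @param chrom_sizes data.frame `name`, `size`.
#' @param sites list of `list(chrom, pair, n_pets)` entries.
#' @param noise list of `list(chrom, start, end, n)` spans on which noise
#'   PETs are uniform over \{x < y\}.
#' @param n_intra,n_inter counts of long-range PETs.
#' @param intra_meanlog,intra_sdlog lognormal length law of intra PETs
#'   (defaults: median 200 kb).
#' @param tag_length tag length used when emitting TSV rows.
#' @param dup_rate fraction of emitted PETs duplicated exactly (PCR clones).
#' @param seed mandatory RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes, sites = list(), noise = list(),
                       n_intra = 0L, n_inter = 0L,
                       intra_meanlog = log(2e5), intra_sdlog = 0.5,
                       tag_length = 20L, dup_rate = 0, seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must be in [0, 1)")
  for (s in sites) {
    if (!s$chrom %in% chrom_sizes$name) {
      stop(sprintf("site chromosome '%s' not in chrom_sizes", s$chrom))
    }
    if (s$n_pets < 2) stop("each site needs n_pets >= 2")
  }
  structure(list(chrom_sizes = chrom_sizes, sites = sites, noise = noise,
                 n_intra = as.integer(n_intra),
                 n_inter = as.integer(n_inter),
                 intra_meanlog = intra_meanlog, intra_sdlog = intra_sdlog,
                 tag_length = as.integer(tag_length),
                 dup_rate = dup_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a PET dataset with a truth table
#'
#' Emits site PETs (SGT pairs), noise PETs (uniform on the triangle
#' \{x < y\} of each noise span), intra-chromosomal PETs with long lognormal
#' lengths, and inter-chromosomal PETs; optionally appends exact duplicates.
#' PET rows are in the six-column TSV dialect of [read_pets()] with tag 5'
#' positions placed so that the midpoint rule recovers the planted points
#' exactly. Fully reproducible from `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @return list: `pets` (TSV-dialect data.frame), `truth` (per-row `origin`
#'   in site:<i>/noise/intra/inter/duplicate and planted points), `sites`
#'   (per-site truth: chromosome, summit, parameters, n_pets).
#' @export
simulate_chromosome <- function(config) {
  set.seed(config$seed)
  cs <- config$chrom_sizes
  pts <- list(); origin <- character(0)
  for (i in seq_along(config$sites)) {
    s <- config$sites[[i]]
    d <- simulate_site(s$pair, s$n_pets, s$chrom)
    pts[[length(pts) + 1L]] <- d
    origin <- c(origin, rep(sprintf("site:%d", i), nrow(d)))
  }
  for (nz in config$noise) {
    if (nz$n == 0) next
    x <- floor(stats::runif(nz$n, nz$start, nz$end))
    y <- floor(stats::runif(nz$n, nz$start, nz$end))
    lo <- pmin(x, y); hi <- pmax(x, y)
    eq <- lo >= hi
    while (any(eq)) {
      x2 <- floor(stats::runif(sum(eq), nz$start, nz$end))
      y2 <- floor(stats::runif(sum(eq), nz$start, nz$end))
      lo[eq] <- pmin(x2, y2); hi[eq] <- pmax(x2, y2)
      eq <- lo >= hi
    }
    pts[[length(pts) + 1L]] <- data.frame(chrom = nz$chrom, x = lo, y = hi,
                                          stringsAsFactors = FALSE)
    origin <- c(origin, rep("noise", nz$n))
  }
  self_like <- if (length(pts)) do.call(rbind, pts) else
    data.frame(chrom = character(), x = integer(), y = integer())
  rows <- list()
  if (nrow(self_like) > 0) {
    rows[[1]] <- points_to_tsv(self_like$chrom, self_like$x,
                               self_like$chrom, self_like$y,
                               config$tag_length)
  }
  if (config$n_intra > 0) {
    ch <- sample(cs$name, config$n_intra, replace = TRUE)
    size <- cs$size[match(ch, cs$name)]
    len <- pmax(config$tag_length * 4,
                round(stats::rlnorm(config$n_intra, config$intra_meanlog,
                                    config$intra_sdlog)))
    len <- pmin(len, size - 100)
    x <- floor(stats::runif(config$n_intra, 50, size - len - 50))
    rows[[length(rows) + 1L]] <- points_to_tsv(ch, x, ch, x + len,
                                               config$tag_length)
    origin <- c(origin, rep("intra", config$n_intra))
  }
  if (config$n_inter > 0) {
    if (nrow(cs) < 2) stop("inter-chromosomal PETs need >= 2 chromosomes")
    c1 <- sample(cs$name, config$n_inter, replace = TRUE)
    c2 <- vapply(c1, function(a) sample(setdiff(cs$name, a), 1L), "")
    p1 <- floor(stats::runif(config$n_inter, 50,
                             cs$size[match(c1, cs$name)] - 50))
    p2 <- floor(stats::runif(config$n_inter, 50,
                             cs$size[match(c2, cs$name)] - 50))
    rows[[length(rows) + 1L]] <- points_to_tsv(c1, p1, c2, p2,
                                               config$tag_length)
    origin <- c(origin, rep("inter", config$n_inter))
  }
  pets <- do.call(rbind, rows)
  rownames(pets) <- NULL
  truth_pts <- data.frame(
    chrom1 = pets$chrom1, point1 = point_of(pets$pos1, pets$strand1,
                                            config$tag_length),
    chrom2 = pets$chrom2, point2 = point_of(pets$pos2, pets$strand2,
                                            config$tag_length),
    stringsAsFactors = FALSE)
  if (config$dup_rate > 0 && nrow(pets) > 0) {
    dup <- which(stats::runif(nrow(pets)) < config$dup_rate)
    if (length(dup) > 0) {
      pets <- rbind(pets, pets[dup, , drop = FALSE])
      truth_pts <- rbind(truth_pts, truth_pts[dup, , drop = FALSE])
      origin <- c(origin, rep("duplicate", length(dup)))
    }
  }
  rownames(pets) <- NULL
  rownames(truth_pts) <- NULL
  sites_truth <- do.call(rbind, lapply(seq_along(config$sites), function(i) {
    s <- config$sites[[i]]
    data.frame(site = i, chrom = s$chrom,
               summit = binding_summit(s$pair),
               mu_x = s$pair$mu_x, mu_y = s$pair$mu_y, k = s$pair$k,
               lam_x = s$pair$lam_x, lam_y = s$pair$lam_y,
               sigma_x = s$pair$sigma_x, sigma_y = s$pair$sigma_y,
               n_pets = s$n_pets, stringsAsFactors = FALSE)
  }))
  list(pets = pets,
       truth = cbind(data.frame(origin = origin, stringsAsFactors = FALSE),
                     truth_pts),
       sites = sites_truth)
}

# the tag point a midpoint-rule reader recovers from a 5'-position record
point_of <- function(pos, strand, tag_length) {
  off_plus <- floor((tag_length - 1) / 2)
  ifelse(strand == "+", pos + off_plus, pos - (tag_length - 1L - off_plus))
}

# emit a 6-column PET TSV row set whose midpoint-rule points equal the
# requested coordinates, with random strands
points_to_tsv <- function(chrom1, point1, chrom2, point2, tag_length) {
  n <- length(point1)
  mk <- function(point, strand) {
    # midpoint of [pos, pos+L-1] is pos + floor((L-1)/2); of [pos-L+1, pos]
    # it is pos - ceil((L-1)/2). Invert so the midpoint rule recovers point.
    off_plus <- floor((tag_length - 1) / 2)
    off_minus <- tag_length - 1L - off_plus
    ifelse(strand == "+", point - off_plus, point + off_minus)
  }
  s1 <- sample(c("+", "-"), n, replace = TRUE)
  s2 <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(chrom1 = chrom1, pos1 = mk(point1, s1), strand1 = s1,
             chrom2 = chrom2, pos2 = mk(point2, s2), strand2 = s2,
             stringsAsFactors = FALSE)
}

#' Write a simulated PET set as a TSV consumable by [read_pets()]
#'
#' @param sim result of [simulate_chromosome()].
#' @param path output path.
#' @export
write_pet_tsv <- function(sim, path) {
  utils::write.table(sim$pets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("chrom1", "pos1", "strand1",
                                   "chrom2", "pos2", "strand2"))
  invisible(path)
}

#' Simulate a paired FASTQ library with planted half-linkers
#'
#' Every read is a random `tag_length` nt tag followed by a half-linker and
#' filler up to `read_length`. Class counts (AA, BB, chimeric AB/BA,
#' ambiguous) are planted exactly; ambiguous reads carry a barcode that
#' mismatches both half-linkers at every position. Optionally a fraction of
#' pairs is duplicated exactly.
#'
#' @param n_aa,n_bb,n_chimeric,n_ambiguous planted pair counts.
#' @param config a [linker_config()].
#' @param read_length total read length (nt).
#' @param seed RNG seed (mandatory).
#' @return list: `reads_1`, `reads_2` (character), `truth` (data.frame with
#'   planted class and tag sequences per pair).
#' @export
simulate_library <- function(n_aa = 100L, n_bb = 100L, n_chimeric = 50L,
                             n_ambiguous = 20L, config = linker_config(),
                             read_length = 46L, seed) {
  if (missing(seed)) stop("simulate_library: a seed is mandatory")
  set.seed(seed)
  n <- n_aa + n_bb + n_chimeric + n_ambiguous
  classes <- c(rep("non_chimeric_AA", n_aa), rep("non_chimeric_BB", n_bb),
               rep("chimeric", n_chimeric), rep("ambiguous", n_ambiguous))
  rand_seq <- function(n, len) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, "")
  }
  # a barcode differing from both half-linkers at every position
  bases <- c("A", "C", "G", "T")
  la <- strsplit(config$half_a, "")[[1]]
  lb <- strsplit(config$half_b, "")[[1]]
  none_linker <- function() {
    paste(vapply(seq_along(la), function(i) {
      sample(setdiff(bases, c(la[i], lb[i])), 1L)
    }, ""), collapse = "")
  }
  L <- nchar(config$half_a)
  filler_len <- read_length - config$tag_length - L
  if (filler_len < 0) stop("read_length too short for tag + linker")
  tag1 <- rand_seq(n, config$tag_length)
  tag2 <- rand_seq(n, config$tag_length)
  half <- function(cls, mate) {
    switch(cls,
           non_chimeric_AA = config$half_a,
           non_chimeric_BB = config$half_b,
           chimeric = if (mate == 1L) config$half_a else config$half_b,
           ambiguous = if (mate == 1L) none_linker() else config$half_a)
  }
  mk_read <- function(tag, cls, mate) {
    filler <- if (filler_len > 0) rand_seq(1L, filler_len) else ""
    paste0(tag, half(cls, mate), filler)
  }
  reads_1 <- vapply(seq_len(n),
                    function(i) mk_read(tag1[i], classes[i], 1L), "")
  reads_2 <- vapply(seq_len(n),
                    function(i) mk_read(tag2[i], classes[i], 2L), "")
  ord <- sample.int(n)
  list(reads_1 = reads_1[ord], reads_2 = reads_2[ord],
       truth = data.frame(class = classes[ord], tag_1 = tag1[ord],
                          tag_2 = tag2[ord], stringsAsFactors = FALSE))
}

#' Write a simulated library as two FASTQ files
#'
#' @param lib result of [simulate_library()].
#' @param path_1,path_2 output FASTQ paths.
#' @export
write_library_fastq <- function(lib, path_1, path_2) {
  wr <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("read%06d", seq_along(reads))
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = quals)
  }
  wr(lib$reads_1, path_1)
  wr(lib$reads_2, path_2)
  invisible(c(path_1, path_2))
}
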