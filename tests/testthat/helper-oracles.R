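# Independent brute-force oracles and small fixture builders shared by the
# suite. The oracles deliberately avoid the package's own code paths.

# quadratic all-pairs blacklist filter: drop a PET when either tag span
# intersects any interval
oracle_blacklist <- function(pets, bl_df) {
  overlaps <- function(chrom, s, e) {
    any(bl_df$chrom == chrom & s <= bl_df$end & e >= bl_df$start)
  }
  keep <- vapply(seq_len(nrow(pets)), function(i) {
    !(overlaps(pets$chrom1[i], pets$start1[i], pets$end1[i]) ||
        overlaps(pets$chrom2[i], pets$start2[i], pets$end2[i]))
  }, TRUE)
  pets[keep, , drop = FALSE]
}

# quadratic connected components of the closed-interval overlap graph
oracle_segment <- function(self_pets) {
  n <- nrow(self_pets)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (self_pets$chrom[i] == self_pets$chrom[j] &&
            self_pets$x[i] <= self_pets$y[j] &&
            self_pets$y[i] >= self_pets$x[j] &&
            comp[i] != comp[j]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# textbook BH step-up, written independently of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# SGT left-tail mass up to `x` by piecewise quadrature of the density only
# (independent of the closed-form CDF); pieces keep each panel smooth so the
# adaptive rule never stalls on the cubic tails
oracle_sgt_cdf <- function(x, mu, lam, sigma) {
  ub <- (x - mu) / sigma
  f_std <- function(u) sigma * sgt_pdf(mu + sigma * u, mu, lam, sigma)
  cuts <- c(-1e3, -100, -10, 0, 10, 100, 1e3, 1e4)
  if (ub < -1e4) return(0)
  total <- integrate(f_std, -Inf, min(ub, cuts[1]), rel.tol = 1e-10,
                     abs.tol = 1e-14)$value
  for (i in seq_along(cuts)[-1]) {
    if (ub <= cuts[i - 1]) break
    total <- total + integrate(f_std, cuts[i - 1], min(ub, cuts[i]),
                               rel.tol = 1e-10, abs.tol = 1e-14)$value
  }
  total
}

# uniform noise PETs on the triangle {x < y} of [a, b]
make_noise_pets <- function(n, a, b, chrom = "chr1") {
  xs <- integer(0); ys <- integer(0)
  while (length(xs) < n) {
    x <- floor(stats::runif(n, a, b))
    y <- floor(stats::runif(n, a, b))
    lo <- pmin(x, y); hi <- pmax(x, y)
    ok <- lo < hi
    xs <- c(xs, lo[ok]); ys <- c(ys, hi[ok])
  }
  data.frame(chrom = chrom, x = xs[seq_len(n)], y = ys[seq_len(n)],
             stringsAsFactors = FALSE)
}

# random valid peak-pair parameters for property sweeps
random_pair <- function() {
  peak_pair(mu_y = stats::runif(1, 500, 5000),
            k = stats::runif(1, 10, 600),
            lam_x = -stats::runif(1, 0.05, 0.97),
            lam_y = stats::runif(1, 0.05, 0.97),
            sigma_x = stats::runif(1, 5, 100),
            sigma_y = stats::runif(1, 5, 100))
}

random_sgt <- function() {
  list(mu = stats::runif(1, -100, 100),
       lam = stats::runif(1, -0.95, 0.95),
       sigma = stats::runif(1, 0.2, 50))
}

# minimal raw-PET data.frame from point coordinates (20 bp spans on +)
make_raw_pets <- function(chrom1, point1, chrom2, point2, tag_length = 20L) {
  half <- floor((tag_length - 1) / 2)
  data.frame(
    chrom1 = chrom1, start1 = point1 - half,
    end1 = point1 - half + tag_length - 1L, strand1 = "+", point1 = point1,
    chrom2 = chrom2, start2 = point2 - half,
    end2 = point2 - half + tag_length - 1L, strand2 = "+", point2 = point2,
    read_id = sprintf("r%04d", seq_along(point1)),
    stringsAsFactors = FALSE)
}
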