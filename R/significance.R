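#' Count tags inside a closed interval
#'
#' @param tags sorted numeric vector of tag coordinates.
#' @param a,b interval bounds, `a <= b`; the interval is closed.
#' @return the number of tags in `[a, b]`.
#' @export
count_tags <- function(tags, a, b) {
  if (a > b) stop("count_tags: interval start exceeds end")
  if (length(tags) == 0) return(0L)
  findInterval(b, tags, left.open = FALSE) -
    findInterval(a, tags, left.open = TRUE)
}

#' Local Poisson background intensity
#'
#' The null intensity for the tag count in a peak interval of length
#' `s_peak` is the largest of: 2 (so at least two tags are required for
#' significance), the chromosome-wide expectation `n_chrom * s_peak /
#' chrom_size`, and the expectations from windows 10 and 15 times the peak
#' size (`n_w10 / 10`, `n_w15 / 15`; the peak length cancels).
#'
#' @param n_chrom total same-side tags on the chromosome.
#' @param chrom_size chromosome size (bp).
#' @param s_peak peak interval length (bp), > 0.
#' @param n_w10,n_w15 tag counts in the 10x and 15x windows.
#' @return the Poisson intensity.
#' @export
local_lambda <- function(n_chrom, chrom_size, s_peak, n_w10, n_w15) {
  if (s_peak <= 0 || chrom_size <= 0) {
    stop("local_lambda: s_peak and chrom_size must be > 0")
  }
  max(2, n_chrom * s_peak / chrom_size, n_w10 / 10, n_w15 / 15)
}

#' Upper-tail Poisson probability
#'
#' @param n_obs observed count (>= 0).
#' @param lam Poisson intensity (> 0).
#' @return P(X >= n_obs) for X ~ Poisson(lam).
#' @export
poisson_sf <- function(n_obs, lam) {
  if (any(n_obs < 0)) stop("poisson_sf: n_obs must be >= 0")
  if (any(lam <= 0)) stop("poisson_sf: lam must be > 0")
  stats::ppois(n_obs - 1, lam, lower.tail = FALSE)
}

#' Combine the two per-side p-values of a peak
#'
#' Under the null the upstream and downstream counts are independent, so a
#' candidate site is non-significant only if both sides are; the combined
#' p-value is the product.
#'
#' @param p_x,p_y per-side p-values in [0, 1].
#' @return `p_x * p_y`.
#' @export
combine_pvalues <- function(p_x, p_y) {
  stopifnot(all(p_x >= 0 & p_x <= 1), all(p_y >= 0 & p_y <= 1))
  p_x * p_y
}

#' Benjamini-Hochberg adjustment
#'
#' @param pvals p-values in [0, 1].
#' @param threshold FDR threshold carried along for reporting.
#' @return list with `q_values` (aligned to input order) and `threshold`.
#' @export
bh_adjust <- function(pvals, threshold = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  list(q_values = stats::p.adjust(pvals, method = "BH"),
       threshold = threshold)
}

#' Call significant binding sites from fitted regions
#'
#' For every candidate site of every fitted region, computes the per-side
#' 95% quantile intervals from the independent marginals (Lambda = 1),
#' counts the chromosome-wide upstream (x) tags in the upstream interval and
#' in mode-centered windows of 10 and 15 times its length — likewise
#' downstream — forms per-side Poisson p-values against
#' [local_lambda()], combines them by product, and applies one genome-wide
#' Benjamini-Hochberg correction. A site is significant when its q-value is
#' at most `fdr`.
#'
#' @param region_fits list of `list(region, fit)` entries (a fitted
#'   `pet_region` with its `sgt_mixture_fit`).
#' @param chrom_sizes data.frame from [read_chrom_sizes()].
#' @param self_pets all self-ligated PETs genome-wide (data.frame `chrom`,
#'   `x`, `y`); supplies the chromosome tag indexes and totals.
#' @param fdr FDR threshold.
#' @param level interval level for the quantile intervals.
#' @return data.frame of peak calls sorted by (chrom, interval_start):
#'   summit, binding interval, per-side intervals/counts/p-values, combined
#'   p-value, q-value, `significant` flag and the cluster parameters.
#' @export
call_peaks <- function(region_fits, chrom_sizes, self_pets, fdr = 0.05,
                       level = 0.95) {
  x_tags <- lapply(split(self_pets$x, self_pets$chrom), sort)
  y_tags <- lapply(split(self_pets$y, self_pets$chrom), sort)
  rows <- list()
  for (rf in region_fits) {
    region <- rf$region; fit <- rf$fit
    cands <- candidate_peaks(fit, region)
    if (length(cands) == 0) next
    ch <- region$chrom
    if (!ch %in% chrom_sizes$name) {
      stop(sprintf("chromosome '%s' missing from chrom_sizes", ch))
    }
    S_C <- chrom_sizes$size[match(ch, chrom_sizes$name)]
    tx <- x_tags[[ch]]; ty <- y_tags[[ch]]
    n_cx <- length(tx)
    for (cand in cands) {
      pair <- cand$pair
      iv <- binding_interval(pair, level)
      side_test <- function(tags, interval, mu) {
        s <- interval[2] - interval[1]
        n <- count_tags(tags, interval[1], interval[2])
        n_w10 <- count_tags(tags, mu - 5 * s, mu + 5 * s)
        n_w15 <- count_tags(tags, mu - 7.5 * s, mu + 7.5 * s)
        lam <- local_lambda(n_cx, S_C, s, n_w10, n_w15)
        list(n = n, lam = lam, p = poisson_sf(n, lam))
      }
      up <- side_test(tx, iv$up, pair$mu_x)
      down <- side_test(ty, iv$down, pair$mu_y)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        summit = round(binding_summit(pair)),
        interval_start = max(1, floor(iv$start)),
        interval_end = min(S_C, ceiling(iv$end)),
        up_start = iv$up[1], up_end = iv$up[2],
        down_start = iv$down[1], down_end = iv$down[2],
        n_up = up$n, n_down = down$n,
        lambda_up = up$lam, lambda_down = down$lam,
        p_up = up$p, p_down = down$p,
        p_combined = combine_pvalues(up$p, down$p),
        n_pets = cand$n_pets,
        mu_x = pair$mu_x, mu_y = pair$mu_y, k = pair$k,
        lam_x = pair$lam_x, lam_y = pair$lam_y,
        sigma_x = pair$sigma_x, sigma_y = pair$sigma_y,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(empty_peak_calls())
  }
  calls <- do.call(rbind, rows)
  adj <- bh_adjust(calls$p_combined, fdr)
  calls$q_value <- adj$q_values
  calls$significant <- calls$q_value <= fdr
  calls <- calls[order(calls$chrom, calls$interval_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_peak_calls <- function() {
  data.frame(chrom = character(), summit = numeric(),
             interval_start = numeric(), interval_end = numeric(),
             up_start = numeric(), up_end = numeric(),
             down_start = numeric(), down_end = numeric(),
             n_up = integer(), n_down = integer(),
             lambda_up = numeric(), lambda_down = numeric(),
             p_up = numeric(), p_down = numeric(),
             p_combined = numeric(), n_pets = integer(),
             mu_x = numeric(), mu_y = numeric(), k = numeric(),
             lam_x = numeric(), lam_y = numeric(),
             sigma_x = numeric(), sigma_y = numeric(),
             q_value = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}
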