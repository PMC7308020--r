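region_from <- function(x, y, chrom = "chr1") {
  segment_regions(data.frame(chrom = chrom, x = x, y = y,
                             stringsAsFactors = FALSE))
}

test_that("segmentation finds overlap components and drops singletons", {
  regs <- region_from(c(100, 150, 500, 550, 900),
                      c(200, 300, 600, 700, 950))
  expect_length(regs, 2)
  expect_equal(regs[[1]]$start, 100); expect_equal(regs[[1]]$end, 300)
  expect_equal(regs[[2]]$start, 500); expect_equal(regs[[2]]$end, 700)
  # all-disjoint spans: nothing survives
  expect_length(region_from(c(1, 100, 200), c(50, 150, 250)), 0)
  # one span containing all others: one region
  expect_length(region_from(c(1, 10, 20), c(1000, 15, 25)), 1)
  # a shared endpoint connects (closed spans)
  expect_length(region_from(c(100, 200), c(200, 300)), 1)
  expect_length(segment_regions(data.frame(chrom = character(),
                                           x = integer(), y = integer())),
                0)
})

test_that("segmentation equals the quadratic connected-components oracle", {
  set.seed(501)
  for (rep in 1:5) {
    n <- 120
    x <- sample.int(5000, n, replace = TRUE)
    y <- x + sample.int(400, n, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    sp <- data.frame(chrom = chrom, x = x, y = y, stringsAsFactors = FALSE)
    comp <- oracle_segment(sp)
    keep <- comp %in% names(which(table(comp) >= 2))
    want <- split(seq_len(n)[keep], comp[keep])
    want_spans <- sort(vapply(want, function(i) {
      paste0(sp$chrom[i[1]], ":", min(sp$x[i]), "-", max(sp$y[i]))
    }, ""))
    regs <- segment_regions(sp)
    got_spans <- sort(vapply(regs, function(r) {
      paste0(r$chrom, ":", r$start, "-", r$end)
    }, ""))
    expect_equal(unname(got_spans), unname(want_spans))
    expect_equal(sum(vapply(regs, `[[`, 0L, "n")), sum(keep))
  }
})

test_that("region volume is the ordered-pair triangle area", {
  r <- region_from(c(100, 120), c(150, 200))[[1]]  # span L = 100
  expect_equal(region_volume(r), 5000)
  r2 <- region_from(c(100, 120), c(250, 300))[[1]]  # span L = 200
  expect_equal(region_volume(r2), 20000)  # L doubles, V quadruples
  # noise density 1/(2.5 V)
  expect_equal(noise_logpdf(110, 140, r), log(8e-5))
  expect_identical(noise_logpdf(140, 110, r), -Inf)
  expect_equal(noise_logpdf(c(101, 110), c(149, 150), r),
               rep(log(8e-5), 2))
})

test_that("penalized log-likelihood composes noise, clusters and priors", {
  r <- region_from(c(100, 120, 130, 140, 110), c(150, 200, 190, 180, 170))[[1]]
  # noise-only reduction
  expect_equal(penalized_loglik(r, 1, list()),
               5 * -log(2.5 * region_volume(r)))
  # G = 1: matches an independent composition from the SGT layer
  p <- peak_pair(180, 50, -0.6, 0.6, 20, 20)
  ll <- penalized_loglik(r, c(0.2, 0.8), list(p))
  lam <- lambda_norm(p)
  per_pet <- log(0.2 / (2.5 * region_volume(r)) +
                   0.8 * lam *
                     sgt_pdf(r$pets$x, p$mu_x, p$lam_x, p$sigma_x) *
                     sgt_pdf(r$pets$y, p$mu_y, p$lam_y, p$sigma_y))
  want <- sum(per_pet) + lambda_prior_logpdf(p$lam_x, "up") +
    lambda_prior_logpdf(p$lam_y, "down")
  expect_equal(ll, want, tolerance = 1e-10)
  # a cluster with lam_x = 0 hits the prior endpoint
  p0 <- peak_pair(180, 50, 0, 0.6, 20, 20)
  expect_identical(penalized_loglik(r, c(0.2, 0.8), list(p0)), -Inf)
})

test_that("ECME ascends the penalized likelihood and recovers a planted site", {
  set.seed(502)
  pair <- peak_pair(mu_y = 10600, k = 200, lam_x = -0.9, lam_y = 0.9,
                    sigma_x = 35, sigma_y = 35)
  site <- simulate_site(pair, 500, "chr1")
  noise <- make_noise_pets(56, 10000, 11200)
  regs <- segment_regions(rbind(site, noise))
  expect_length(regs, 1)
  fit <- ecme_fit(regs[[1]], G = 1)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  expect_lt(abs(binding_summit(fit$clusters[[1]]) - 10500), 5)
  expect_lt(abs(fit$weights[1] - 0.1), 0.05)
  # structural contracts
  expect_equal(rowSums(fit$responsibilities), rep(1, regs[[1]]$n))
  expect_equal(sum(fit$weights), 1)
  expect_lte(fit$clusters[[1]]$lam_x, 0)
  expect_gte(fit$clusters[[1]]$lam_y, 0)
})

test_that("fits with and without the Lambda normalizer nearly coincide", {
  set.seed(503)
  pair <- peak_pair(5600, 180, -0.9, 0.9, 30, 30)
  site <- simulate_site(pair, 300, "chr1")
  noise <- make_noise_pets(30, 5000, 6200)
  reg <- segment_regions(rbind(site, noise))[[1]]
  f_with <- ecme_fit(reg, 1, use_lambda = TRUE)
  f_without <- ecme_fit(reg, 1, use_lambda = FALSE)
  expect_lt(abs(binding_summit(f_with$clusters[[1]]) -
                  binding_summit(f_without$clusters[[1]])), 2)
})

test_that("two well-separated planted sites are both recovered", {
  set.seed(504)
  p1 <- peak_pair(10600, 200, -0.9, 0.9, 35, 35)
  p2 <- peak_pair(11200, 200, -0.9, 0.9, 35, 35)  # 600 bp > 10 sigma apart
  self <- rbind(simulate_site(p1, 250, "chr1"),
                simulate_site(p2, 250, "chr1"),
                make_noise_pets(50, 10000, 11800))
  reg <- segment_regions(self)[[1]]
  fit <- ecme_fit(reg, 2)
  summits <- sort(vapply(fit$clusters, binding_summit, 0))
  expect_lt(abs(summits[1] - 10500), 10)
  expect_lt(abs(summits[2] - 11100), 10)
})

test_that("BIC model selection separates noise-only from single-site data", {
  set.seed(505)
  reg_noise <- segment_regions(make_noise_pets(40, 5000, 7000))[[1]]
  best <- select_model(reg_noise, G_max = 2)
  expect_equal(best$G, 0)
  bt <- attr(best, "bic_table")
  expect_true(all(bt$bic >= bt$bic[bt$G == best$G]))
  pair <- peak_pair(5600, 200, -0.9, 0.9, 35, 35)
  reg_sig <- segment_regions(rbind(simulate_site(pair, 200, "chr1"),
                                   make_noise_pets(20, 5000, 6200)))[[1]]
  best_sig <- select_model(reg_sig, G_max = 2)
  expect_equal(best_sig$G, 1)
})

test_that("candidate peaks follow max-responsibility assignment", {
  set.seed(506)
  reg <- segment_regions(make_noise_pets(10, 100, 400))[[1]]
  g0 <- petpeaks:::noise_only_fit(reg)
  expect_length(candidate_peaks(g0, reg), 0)
  # hand-built responsibilities: 6 PETs to cluster 1, 3 to cluster 2, 1 noise
  fake <- structure(list(
    G = 2L, weights = c(0.1, 0.6, 0.3),
    clusters = list(peak_pair(300, 50), peak_pair(200, 50)),
    responsibilities = rbind(
      matrix(rep(c(0.05, 0.9, 0.05), 6), ncol = 3, byrow = TRUE),
      matrix(rep(c(0.05, 0.05, 0.9), 3), ncol = 3, byrow = TRUE),
      c(0.8, 0.1, 0.1)),
    converged = TRUE), class = "sgt_mixture_fit")
  cands <- candidate_peaks(fake, reg)
  expect_length(cands, 2)
  expect_equal(vapply(cands, `[[`, 0L, "n_pets"), c(6L, 3L))
  # a cluster holding one PET is dropped
  fake$responsibilities[7:8, ] <- rep(c(0.05, 0.9, 0.05), each = 2) |>
    matrix(ncol = 3)
  cands2 <- candidate_peaks(fake, reg)
  expect_length(cands2, 1)
})
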