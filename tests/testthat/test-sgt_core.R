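test_that("SGT density has the closed form at and near the mode", {
  expect_equal(sgt_pdf(0, mu = 0, lam = 0, sigma = 0.5), 1)
  expect_equal(sgt_pdf(1, mu = 0, lam = 0, sigma = 1), 2^(-1.5) / 2,
               tolerance = 1e-12)
  # mode is the maximum and both skew branches agree there
  for (lam in c(-0.8, -0.3, 0, 0.4, 0.9)) {
    grid <- seq(-50, 50, by = 0.5)
    vals <- sgt_pdf(grid, mu = 3, lam = lam, sigma = 7)
    expect_equal(grid[which.max(vals)], 3)
    expect_equal(sgt_pdf(3 - 1e-9, 3, lam, 7), sgt_pdf(3 + 1e-9, 3, lam, 7),
                 tolerance = 1e-6)
  }
})

test_that("SGT density integrates to one over random parameter sets", {
  set.seed(101)
  for (i in 1:100) {
    th <- random_sgt()
    total <- integrate(function(x) sgt_pdf(x, th$mu, th$lam, th$sigma),
                       -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-8)
  }
})

test_that("closed-form CDF matches quadrature and has the mode mass", {
  expect_equal(sgt_cdf(0, mu = 0, lam = -0.5), 0.75)
  expect_equal(sgt_cdf(1, mu = 0, lam = 0, sigma = 1), 0.5 + 0.5 / sqrt(2),
               tolerance = 1e-12)
  set.seed(102)
  for (i in 1:50) {
    th <- random_sgt()
    x <- th$mu + stats::runif(1, -5, 5) * th$sigma
    quad <- integrate(function(t) sgt_pdf(t, th$mu, th$lam, th$sigma),
                      -Inf, x, rel.tol = 1e-11)$value
    expect_lt(abs(sgt_cdf(x, th$mu, th$lam, th$sigma) - quad), 1e-8)
    expect_equal(sgt_cdf(th$mu, th$mu, th$lam, th$sigma),
                 (1 - th$lam) / 2)
  }
  # symmetry when lam = 0
  expect_equal(sgt_cdf(-3, 0, 0, 2), 1 - sgt_cdf(3, 0, 0, 2))
})

test_that("quantile is the exact inverse of the CDF", {
  expect_equal(sgt_quantile(0.5, mu = 100, lam = 0, sigma = 9), 100)
  for (lam in c(-0.9, -0.2, 0.3, 0.8)) {
    expect_equal(sgt_quantile((1 - lam) / 2, 7, lam, 3), 7)
  }
  set.seed(103)
  for (i in 1:1000) {
    th <- random_sgt()
    q <- stats::runif(1, 1e-4, 1 - 1e-4)
    x <- sgt_quantile(q, th$mu, th$lam, th$sigma)
    expect_lt(abs(sgt_cdf(x, th$mu, th$lam, th$sigma) - q), 1e-10)
  }
  expect_error(sgt_quantile(0, 0), "strictly")
  expect_error(sgt_quantile(1.2, 0), "strictly")
})

test_that("skewness prior is maximized at -alpha/(alpha+1) and mirrors", {
  expect_identical(lambda_prior_logpdf(0, "up"), -Inf)
  expect_identical(lambda_prior_logpdf(0, "down"), -Inf)
  grid <- seq(-0.999, -0.001, by = 0.001)
  argmax <- grid[which.max(lambda_prior_logpdf(grid, "up", alpha = 39))]
  expect_equal(argmax, -39 / 40, tolerance = 1e-3)
  lam <- seq(0.01, 0.99, by = 0.01)
  expect_equal(lambda_prior_logpdf(-lam, "up", 39),
               lambda_prior_logpdf(lam, "down", 39))
  expect_error(lambda_prior_logpdf(0.5, "up"), "must lie")
  expect_error(lambda_prior_logpdf(-0.5, "down"), "must lie")
})

test_that("Lambda normalizer has the limit values and the 2D-mass identity", {
  # identical marginals: integral of F dF = 1/2, Lambda = 2
  near0 <- peak_pair(1000, 1e-3, 0, 0, 30, 30)
  expect_equal(lambda_norm(near0), 2, tolerance = 1e-4)
  # wide separation under the skew regime the priors enforce
  sep <- peak_pair(1000, 50 * 30, -0.975, 0.975, 30, 30)
  expect_lt(abs(lambda_norm(sep) - 1), 1e-6)
  # Lambda times the 2D mass over {x < y} is 1; the mass is computed by
  # nested quadrature using only the density (no closed-form CDF)
  set.seed(104)
  for (i in 1:10) {
    p <- random_pair()
    # inner CDF by quadrature of the density only (no closed form); the
    # far-left truncation loses O(1e-11) of cubic-tail mass
    # bounds capped at +-1e4 standard units: the cubic tails hold O(1e-8)
    # mass beyond, inside the assertion budget
    f_std <- function(u) {
      p$sigma_x * sgt_pdf(p$mu_x + p$sigma_x * u,
                          p$mu_x, p$lam_x, p$sigma_x)
    }
    inner <- function(y) {
      vapply(y, function(yy) {
        ub <- (yy - p$mu_x) / p$sigma_x
        if (ub < -1e4) return(0)
        # split at the mode: the half-infinite piece keeps its peak at the
        # boundary, the finite piece is a plain decaying tail
        left <- integrate(f_std, -Inf, min(ub, 0), rel.tol = 1e-9,
                          abs.tol = 1e-13)$value
        right <- if (ub > 0) {
          integrate(f_std, 0, min(ub, 1e4), rel.tol = 1e-9,
                    abs.tol = 1e-13)$value
        } else 0
        left + right
      }, 0)
    }
    # outer integral in the downstream peak's standardized coordinates
    mass <- integrate(function(t) {
      y <- p$mu_y + p$sigma_y * t
      p$sigma_y * sgt_pdf(y, p$mu_y, p$lam_y, p$sigma_y) * inner(y)
    }, -Inf, Inf, rel.tol = 1e-7)$value
    expect_lt(abs(lambda_norm(p) * mass - 1), 1e-6)
    expect_gte(lambda_norm(p), 1 - 1e-9)
  }
})

test_that("fast fixed-node Lambda agrees with the adaptive quadrature", {
  set.seed(105)
  for (i in 1:50) {
    p <- random_pair()
    expect_equal(petpeaks:::lambda_norm_fast(p), lambda_norm(p),
                 tolerance = 2e-3)
  }
})

test_that("joint PET density is zero on x >= y and normalized on x < y", {
  p <- peak_pair(1000, 150, -0.7, 0.7, 25, 25)
  expect_identical(pet_logpdf(1200, 1100, p), -Inf)
  expect_identical(pet_logpdf(1000, 1000, p), -Inf)
  # without Lambda the log density is exactly the sum of marginals
  expect_equal(pet_logpdf(900, 1100, p, use_lambda = FALSE),
               log(sgt_pdf(900, p$mu_x, p$lam_x, p$sigma_x)) +
                 log(sgt_pdf(1100, p$mu_y, p$lam_y, p$sigma_y)))
  # with Lambda the joint density integrates to 1 over {x < y}
  llam <- log(lambda_norm(p))
  mass <- integrate(function(t) {
    y <- p$mu_y + p$sigma_y * t
    p$sigma_y * vapply(y, function(yy) {
      ub <- (yy - p$mu_x) / p$sigma_x
      if (ub < -1e4) return(0)
      g <- function(u) {
        p$sigma_x * exp(pet_logpdf(p$mu_x + p$sigma_x * u, yy, p,
                                   log_lambda = llam))
      }
      left <- integrate(g, -Inf, min(ub, 0), rel.tol = 1e-9,
                        abs.tol = 1e-13)$value
      right <- if (ub > 0) {
        integrate(g, 0, min(ub, 1e4), rel.tol = 1e-9,
                  abs.tol = 1e-13)$value
      } else 0
      left + right
    }, 0)
  }, -Inf, Inf, rel.tol = 1e-7)$value
  expect_lt(abs(mass - 1), 1e-6)
})

test_that("summit and binding interval geometry", {
  p <- peak_pair(1200, 200, 0, 0, 30, 30)
  expect_equal(binding_summit(p), 1100)
  expect_equal(binding_summit(p) - p$mu_x, p$mu_y - binding_summit(p))
  iv <- binding_interval(p)
  # symmetric case: interval symmetric about the summit, containing it
  expect_equal(binding_summit(p) - iv$start, iv$end - binding_summit(p),
               tolerance = 1e-9)
  expect_lt(iv$start, binding_summit(p))
  expect_gt(iv$end, binding_summit(p))
  # endpoints equal numerically inverted CDF values
  inv <- function(q, mu, lam, sigma) {
    uniroot(function(x) sgt_cdf(x, mu, lam, sigma) - q,
            c(mu - 1e5 * sigma, mu + 1e5 * sigma), tol = 1e-8)$root
  }
  p2 <- peak_pair(1200, 200, -0.6, 0.4, 20, 35)
  iv2 <- binding_interval(p2)
  expect_equal(iv2$start, inv(0.05, p2$mu_x, p2$lam_x, p2$sigma_x),
               tolerance = 1e-6)
  expect_equal(iv2$end, inv(0.95, p2$mu_y, p2$lam_y, p2$sigma_y),
               tolerance = 1e-6)
  expect_equal(iv2$S_x, iv2$up[2] - iv2$up[1])
})

test_that("peak_pair validates its constraints", {
  expect_error(peak_pair(100, -5), "k must be > 0")
  expect_error(peak_pair(100, 10, lam_x = 0.2), "lam_x")
  expect_error(peak_pair(100, 10, lam_y = -0.2), "lam_y")
  expect_error(peak_pair(100, 10, sigma_x = 0), "sigmas")
  p <- peak_pair(100, 10)
  expect_equal(p$mu_x, 90)
})
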