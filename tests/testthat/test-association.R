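test_that("the whitening transformer turns the model covariance into I", {
  set.seed(50)
  kin <- toy_kinship(6, 200, seed = 50)

  # s_lambda = 0 reduces to the orthogonal rotation Uk'
  W0 <- whiten_transform(kin, 0)
  v <- rnorm(6)
  expect_equal(drop(W0(v)), drop(crossprod(kin$vectors, v)))
  expect_equal(sum(W0(v)^2), sum(v^2), tolerance = 1e-10)

  # Monte-Carlo covariance of the whitened vector is the identity
  s <- 1.4
  W <- whiten_transform(kin, s)
  Lk <- kin$vectors %*% diag(sqrt(kin$values), 6)
  draws <- vapply(1:5e4, function(b) {
    y <- sqrt(s) * drop(Lk %*% rnorm(6)) + rnorm(6)
    drop(W(y))
  }, numeric(6))
  expect_equal(cov(t(draws)), diag(6), tolerance = 0.06, ignore_attr = TRUE)

  # composing with the explicit inverse recovers the input
  scale <- 1 / sqrt(s * kin$values + 1)
  inv <- function(u) kin$vectors %*% (u / scale)
  expect_equal(drop(inv(W(v))), v, tolerance = 1e-10)

  expect_error(whiten_transform(kin, -0.1), "non-negative")
})

test_that("marker scoring is least squares with unit residual variance", {
  set.seed(3)
  z <- rnorm(30)
  y <- rnorm(30)
  y_perp <- y - z * sum(z * y) / sum(z^2)
  expect_equal(score_marker(y_perp, z)$chi2, 0, tolerance = 1e-20)

  deg <- score_marker(y, rep(0, 30))
  expect_true(deg$degenerate)
  expect_equal(deg$chi2, 0)

  sm <- score_marker(y, z)
  expect_equal(sm$effect, sum(z * y) / sum(z^2))
  expect_equal(sm$chi2, sm$effect^2 / sm$variance)
})

test_that("the scan statistic equals brute-force GLS on a small fixture", {
  set.seed(5)
  n <- 30; d <- 3
  geno <- filter_markers(toy_genotypes(n, 60, seed = 5), 0.05, 1)
  kin <- compute_grm(geno)
  P <- matrix(rnorm(n * d), n) + 2
  rownames(P) <- rownames(geno$matrix)
  # plant an effect of the first marker on every trait
  P <- P + 0.6 * geno$matrix[, 1]
  null <- estimate_null_mvlmm(P, kin, compute_se = FALSE)
  scan <- hirrm_scan(P, geno, kin = kin, null = null, refine = FALSE)

  ct <- canonical_transform(null)
  Ps <- transform_phenotypes(P, ct)
  K <- kin$matrix
  Zc <- sweep(geno$matrix, 2, colMeans(geno$matrix), "-")
  chi_bf <- vapply(seq_len(ncol(Zc)), function(j) {
    sum(vapply(seq_len(d), function(l) {
      V <- ct$s_lambda[l] * K + diag(n)
      Vi <- solve(V)
      X <- cbind(1, Zc[, j])
      XtVX <- t(X) %*% Vi %*% X
      b <- solve(XtVX, t(X) %*% Vi %*% Ps[, l])
      b[2]^2 / solve(XtVX)[2, 2]
    }, 0))
  }, 0)
  expect_lt(max(abs(scan$records$chi2_sum - chi_bf)), 1e-6)
})

test_that("null statistics follow the reference chi-square distribution", {
  set.seed(60)
  n <- 80
  kin <- toy_kinship(n, 400, seed = 60)
  s <- 0.8
  W <- whiten_transform(kin, s)
  Lk <- kin$vectors %*% diag(sqrt(kin$values), n)
  Xw <- W(matrix(1, n, 1))
  proj <- function(M) M - Xw %*% solve(crossprod(Xw), crossprod(Xw, M))
  # fresh phenotype draw for each block of null markers
  chi2 <- unlist(lapply(1:50, function(b) {
    Z <- matrix(rbinom(n * 100, 2, 0.3), n)
    Zc <- sweep(Z, 2, colMeans(Z), "-")
    y <- sqrt(s) * drop(Lk %*% rnorm(n)) + rnorm(n)
    yw <- drop(proj(W(y)))
    Zw <- proj(W(Zc))
    colSums(Zw * yw)^2 / colSums(Zw^2)
  }))
  ks <- ks.test(chi2, pchisq, df = 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("the summed pleiotropy statistic uses the chi-square upper tail", {
  z <- pleiotropy_test(c(0, 0, 0))
  expect_equal(z$chi2_sum, 0)
  expect_equal(z$neglog10_p, 0, tolerance = 1e-12)   # p = 1

  # quadrature oracle for the chi-square_3 upper tail at 6
  pt <- pleiotropy_test(c(1, 2, 3))
  tail_quad <- integrate(dchisq, 6, Inf, df = 3, rel.tol = 1e-12)$value
  expect_equal(pt$chi2_sum, 6)
  expect_equal(pt$neglog10_p, -log10(tail_quad), tolerance = 1e-8)

  # extreme statistics stay finite on the -log10 scale, capped at 320
  expect_lte(pleiotropy_test(c(3000, 0, 0))$neglog10_p, 320)

  set.seed(1)
  draws <- matrix(rchisq(3e4, 1), ncol = 3)
  expect_equal(mean(pleiotropy_test(draws)$chi2_sum), 3, tolerance = 0.05)
})

test_that("multiple-testing threshold matches the closed form", {
  expect_equal(round(bonferroni_threshold(11833, 0.05), 3), 5.374)
  expect_equal(bonferroni_threshold(1, 0.05), -log10(0.05))
  expect_equal(round(bonferroni_threshold(1, 0.05), 3), 1.301)
  expect_equal(bonferroni_threshold(100, 1e-2), 4)
  expect_error(bonferroni_threshold(0, 0.05), ">= 1")
  expect_error(bonferroni_threshold(10, 1.2), "alpha")
})

test_that("genomic control is the median ratio and scales accordingly", {
  set.seed(2)
  chi2 <- rchisq(20000, 3)
  lam <- genomic_control(chi2, 3)
  expect_equal(lam, 1, tolerance = 0.03)
  expect_equal(genomic_control(2 * chi2, 3), 2 * lam, tolerance = 1e-12)
  expect_error(genomic_control(rchisq(50, 3), 3), "at least 100")
})

test_that("effects planted on one curve parameter stay on that parameter", {
  set.seed(71)
  n <- 300; d <- 3
  reps <- 8
  eff <- matrix(0, reps, d)
  for (b in seq_len(reps)) {
    geno <- filter_markers(toy_genotypes(n, 150, seed = 700 + b), 0.05, 1)
    kin <- compute_grm(geno)
    P <- draw_mvlmm(kin, rand_pd(d, seed = 1), rand_pd(d, seed = 2))
    P[, 1] <- P[, 1] + 0.9 * geno$matrix[, 5]   # effect on trait 1 only
    null <- estimate_null_mvlmm(P, kin, compute_se = FALSE)
    scan <- hirrm_scan(P, geno, kin = kin, null = null, refine = FALSE)
    eff[b, ] <- as.numeric(scan$records[5, grep("^effect_",
                                                names(scan$records))])
  }
  m_eff <- colMeans(eff)
  se <- apply(eff, 2, sd) / sqrt(reps)
  expect_gt(m_eff[1], 0.6)
  expect_lt(abs(m_eff[2]), 3 * se[2] + 0.05)
  expect_lt(abs(m_eff[3]), 3 * se[3] + 0.05)
})

test_that("refinement reruns only flagged markers, caching duplicates", {
  set.seed(90)
  n <- 150
  geno <- filter_markers(toy_genotypes(n, 120, seed = 90), 0.05, 1)
  # duplicate a marker column to exercise the cache
  G <- geno$matrix
  G[, 7] <- G[, 6]
  geno <- genotype_matrix(G, geno$markers)
  kin <- compute_grm(geno)
  P <- draw_mvlmm(kin, diag(2), diag(2))
  P <- P + outer(G[, 6], c(1.0, 0.8))          # strong planted QTL
  null <- estimate_null_mvlmm(P, kin, compute_se = FALSE)
  scan <- hirrm_scan(P, geno, kin = kin, null = null, refine = TRUE,
                     suggestive_p = 1e-4)
  expect_equal(scan$rounds_used, 2L)
  r <- scan$records
  expect_true(any(r$refined))
  expect_equal(r$chi2_sum[6], r$chi2_sum[7], tolerance = 1e-10)

  # with an unreachable suggestive level nothing is refined
  scan1 <- hirrm_scan(P, geno, kin = kin, null = null, refine = TRUE,
                      suggestive_p = 1e-300, top_frac = 0)
  expect_equal(scan1$rounds_used, 1L)
  expect_false(any(scan1$records$refined))
})

test_that("refinement does not lose the planted signal on average", {
  set.seed(91)
  n <- 150
  diffs <- replicate(10, {
    geno <- filter_markers(toy_genotypes(n, 100,
                                         seed = sample.int(1e6, 1)), 0.05, 1)
    kin <- compute_grm(geno)
    P <- draw_mvlmm(kin, diag(2) * 2, diag(2))
    P <- P + outer(geno$matrix[, 10], c(0.7, 0.5))
    null <- estimate_null_mvlmm(P, kin, compute_se = FALSE)
    s_ref <- hirrm_scan(P, geno, kin = kin, null = null, refine = TRUE)
    s_one <- hirrm_scan(P, geno, kin = kin, null = null, refine = FALSE)
    s_ref$records$chi2_sum[10] - s_one$records$chi2_sum[10]
  })
  expect_gt(mean(diffs), -0.5)
})
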