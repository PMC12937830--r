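test_that("curve evaluation matches the closed forms and family reductions", {
  t <- c(0.5, 1, 2, 5, 9, 16)

  # asymptote of the logistic curve
  log10p <- growth_params("logistic", c(10, 1, 1))
  expect_equal(evaluate_curve(log10p, 1e6), 10, tolerance = 1e-12)

  # shape parameter k = 2 reduces the four-parameter family to the logistic
  rich2 <- growth_params("richards", c(10, 1, 1, 2))
  expect_equal(evaluate_curve(rich2, t), evaluate_curve(log10p, t),
               tolerance = 1e-12)

  # k = 0 gives the linear-in-exp(-rt) form, i.e. Bertalanffy with b
  # sign-flipped under the a(1 - b e^-rt) convention
  rich0 <- growth_params("richards", c(12, -0.7, 0.3, 0))
  bert <- growth_params("bertalanffy", c(12, 0.7, 0.3))
  expect_equal(evaluate_curve(rich0, t), evaluate_curve(bert, t),
               tolerance = 1e-12)

  # population-scale Bertalanffy curve against direct scalar arithmetic
  pb <- growth_params("bertalanffy", c(21.428, 0.948, 0.234))
  expect_equal(evaluate_curve(pb, 1),
               21.428 * (1 - 0.948 * exp(-0.234 * 1)), tolerance = 1e-12)
  expect_equal(evaluate_curve(pb, 16),
               21.428 * (1 - 0.948 * exp(-0.234 * 16)), tolerance = 1e-12)

  # gompertz closed form
  pg <- growth_params("gompertz", c(20, 2, 0.3))
  expect_equal(evaluate_curve(pg, 3), 20 * exp(-2 * exp(-0.9)),
               tolerance = 1e-12)

  # legendre evaluation equals the basis expansion
  pl <- growth_params("legendre", c(1, 0.5, -0.2), t_range = c(1, 16))
  B <- legendre_basis(t, 2, c(1, 16))
  expect_equal(evaluate_curve(pl, t), drop(B %*% c(1, 0.5, -0.2)))
})

test_that("invalid parameters are rejected", {
  expect_error(growth_params("richards", c(10, 1, 1, 1)), "k must stay away")
  expect_error(growth_params("logistic", c(-3, 1, 1)), "positive")
  p <- growth_params("richards", c(10, -2, 0.5, 1.5))
  expect_error(evaluate_curve(p, 0.1), "positive")
  expect_error(growth_params("legendre", c(1, 2)), "t_range")
})

test_that("normalized Legendre basis is orthonormal under quadrature", {
  h <- 2 / 20000
  x <- seq(-1 + h / 2, 1 - h / 2, by = h)   # midpoint quadrature
  B <- legendre_basis(x, 6, c(-1, 1))
  G <- crossprod(B) * h
  expect_lt(max(abs(G - diag(7))), 1e-3)
})

test_that("noiseless data are recovered to high relative accuracy", {
  t <- 1:16
  cases <- list(
    list(family = "logistic", cf = c(20, 9, 0.5)),
    list(family = "bertalanffy", cf = c(21.428, 0.948, 0.234)),
    list(family = "gompertz", cf = c(20, 2.5, 0.3)),
    list(family = "richards", cf = c(21.4, 0.95, 0.23, 1.5))
  )
  for (cs in cases) {
    y <- evaluate_curve(growth_params(cs$family, cs$cf), t)
    fit <- fit_growth_curve(t, y, cs$family)
    expect_true(fit$converged, info = cs$family)
    expect_equal(unname(coef(fit)), cs$cf, tolerance = 1e-6,
                 info = cs$family)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("order-1 Legendre fit of a straight line is exact least squares", {
  t <- 1:10
  y <- 2 + 3 * t
  fit <- fit_growth_curve(t, y, "legendre", order = 1L)
  expect_equal(predict(fit), y, tolerance = 1e-10)
  # coefficients equal the OLS solution re-expressed in the basis
  B <- legendre_basis(t, 1)
  expect_equal(unname(coef(fit)), unname(qr.solve(B, y)), tolerance = 1e-10)
  expect_equal(sum(residuals(fit)^2), 0, tolerance = 1e-18)
})

test_that("fit reporting contracts hold", {
  t <- 1:8
  y <- evaluate_curve(growth_params("logistic", c(15, 4, 0.6)), t) +
    c(0.1, -0.2, 0.05, 0, 0.1, -0.1, 0.2, -0.05)
  fit <- fit_growth_curve(t, y, "logistic")
  n <- fit$n_obs; d <- fit$params$d
  rss <- sum(residuals(fit)^2)
  # information criteria and residual variance recomputed from RSS, n, d
  expect_equal(fit$aic, n * log(rss / n) + 2 * (d + 1))
  expect_equal(fit$bic, n * log(rss / n) + (d + 1) * log(n))
  expect_equal(fit$residual_variance, rss / (n - d))
  expect_error(fit_growth_curve(1:3, c(1, 2, 3), "logistic"), "at least")
})

test_that("residual-variance estimator is unbiased on linear fits", {
  set.seed(42)
  sims <- 400
  t <- seq(1, 16, length.out = 10)
  B <- legendre_basis(t, 1)
  truth <- 2.25
  rv <- replicate(sims, {
    y <- drop(B %*% c(5, 1)) + rnorm(10, 0, sqrt(truth))
    fit_growth_curve(t, y, "legendre", order = 1L)$residual_variance
  })
  mc_se <- sd(rv) / sqrt(sims)
  expect_lt(abs(mean(rv) - truth), 3 * mc_se)
})

test_that("coefficient sampling covariance matches the design-based formula", {
  set.seed(7)
  t <- 1:16
  y <- drop(legendre_basis(t, 2) %*% c(16, 6, -3)) + rnorm(16, 0, 2)
  fit <- fit_growth_curve(t, y, "legendre", order = 2L)
  B <- legendre_basis(t, 2)
  expect_equal(vcov(fit), fit$residual_variance * solve(crossprod(B)),
               tolerance = 1e-10)
})

test_that("model selection ranks by BIC with a fewest-parameter tie rule", {
  mk <- function(bic, d, fam = "logistic") {
    structure(list(params = list(family = fam, d = d), bic = bic,
                   aic = bic - 1, r_squared = 0.9, residual_variance = 0.2),
              class = "growth_fit")
  }
  tab <- select_growth_model(list(mk(30.597, 3), mk(38.731, 3),
                                  mk(19.058, 7)))
  expect_equal(tab$bic, c(19.058, 30.597, 38.731))
  tie <- select_growth_model(list(mk(25, 4), mk(25, 3)))
  expect_equal(tie$n_params, c(3, 4))
  expect_error(select_growth_model(list(mk(1, 2))), "at least two")
})

test_that("BIC ranking of nested OLS fits matches direct recomputation", {
  set.seed(11)
  t <- 1:16
  y <- drop(legendre_basis(t, 2) %*% c(16, 6, -3)) + rnorm(16, 0, 0.7)
  fits <- lapply(1:4, function(o) fit_growth_curve(t, y, "legendre",
                                                   order = o))
  tab <- select_growth_model(fits)
  bic_direct <- vapply(fits, function(f) {
    rss <- sum(residuals(f)^2)
    16 * log(rss / 16) + (f$params$d + 1) * log(16)
  }, 0)
  expect_equal(sort(bic_direct), tab$bic)
})

test_that("population curve fitting averages ages then delegates", {
  t <- 1:12
  y <- evaluate_curve(growth_params("logistic", c(18, 5, 0.5)), t)
  pheno <- data.frame(id = rep(c("a", "b"), each = 12), time = rep(t, 2),
                      value = rep(y, 2))
  popfit <- fit_population_curve(pheno, "logistic")
  indfit <- fit_growth_curve(t, y, "logistic")
  expect_equal(coef(popfit), coef(indfit), tolerance = 1e-8)

  single <- fit_population_curve(pheno[pheno$id == "a", ], "logistic")
  expect_equal(coef(single), coef(indfit), tolerance = 1e-8)

  # a merged age group containing two records of one individual is not
  # alignable
  bad <- data.frame(id = "a", time = c(1, 1 + 1e-9, 3), value = c(1, 2, 3))
  expect_error(fit_population_curve(bad, "logistic", tol = 1e-6),
               "not alignable")
})

test_that("population fit recovers the mean asymptote of a noisy cohort", {
  set.seed(3)
  t <- 1:16
  n <- 100
  a_i <- rnorm(n, 20, 1)
  pheno <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = sprintf("m%03d", i), time = t,
               value = evaluate_curve(growth_params("logistic",
                                                    c(a_i[i], 9, 0.5)), t))
  }))
  fit <- fit_population_curve(pheno, "logistic")
  expect_lt(abs(coef(fit)["a"] - mean(a_i)), 2 * sd(a_i) / sqrt(n) + 0.05)
})

test_that("genetic-effect trajectories difference the shifted curve", {
  pop <- growth_params("bertalanffy", c(21.428, 0.948, 0.234))
  tg <- 0:16

  expect_equal(genetic_effect_trajectory(pop, c(0, 0, 0), tg),
               rep(0, 17))

  # per-parameter QTL effects, checked at t = 0 by scalar arithmetic
  eff <- c(0.638, 0.021, 0.012)
  g <- genetic_effect_trajectory(pop, eff, tg)
  g0 <- (21.428 + 0.638) * (1 - (0.948 + 0.021)) - 21.428 * (1 - 0.948)
  expect_equal(g[1], g0, tolerance = 1e-12)

  # an asymptote-only effect scales the population shape
  da <- 0.5
  g_a <- genetic_effect_trajectory(pop, c(da, 0, 0), tg)
  expect_equal(g_a, da * (1 - 0.948 * exp(-0.234 * tg)), tolerance = 1e-12)

  expect_error(genetic_effect_trajectory(pop, c(1, 2), tg), "length")
})

test_that("cohort fitting drops short or unidentifiable series with warning", {
  t <- 1:16
  y <- evaluate_curve(growth_params("logistic", c(18, 5, 0.5)), t)
  pheno <- rbind(
    data.frame(id = "ok", time = t, value = y + rnorm(16, 0, 0.2)),
    data.frame(id = "short", time = 1:3, value = y[1:3])
  )
  set.seed(1)
  expect_warning(fits <- fit_growth_curves(pheno, "logistic"), "dropped")
  expect_named(fits, "ok")
  P <- regression_phenotypes(fits)
  expect_equal(rownames(P), "ok")
  expect_equal(dim(attr(P, "meas_cov")), c(3L, 3L, 1L))
})
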