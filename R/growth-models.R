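#' Growth-curve families
#'
#' Supported trajectory models for the first hierarchy. The four biological
#' families derive from the Richards growth function
#' \deqn{y(t) = a (1 + b e^{-rt})^{1/(1-k)},}
#' where \eqn{a} is the asymptotic (mature) size, \eqn{b} an integration
#' constant fixing the initial condition, \eqn{r} the intrinsic growth rate
#' and \eqn{k} a shape parameter moving the inflection point. Setting
#' \eqn{k = 2} gives the Logistic curve \eqn{a/(1 + b e^{-rt})}; the limit
#' \eqn{k \to 1} gives the Gompertz curve \eqn{a \exp(-b e^{-rt})}, which is
#' treated as its own family because the Richards exponent is undefined at
#' \eqn{k = 1}; \eqn{k = 0} gives the linear-in-\eqn{e^{-rt}} Bertalanffy
#' form, parameterized here as \eqn{a (1 - b e^{-rt})} with \eqn{b > 0} for a
#' growing trajectory (so Richards at \eqn{k = 0} equals Bertalanffy with the
#' sign of \eqn{b} flipped). The \code{legendre} family is an orthogonal
#' polynomial regression on age affinely mapped to \eqn{[-1, 1]}.
#'
#' @name growth_families
#' @keywords internal
NULL

GROWTH_FAMILIES <- c("richards", "bertalanffy", "gompertz", "logistic", "legendre")

family_coef_names <- function(family, order = 2L) {
  switch(family,
    richards    = c("a", "b", "r", "k"),
    bertalanffy = ,
    gompertz    = ,
    logistic    = c("a", "b", "r"),
    legendre    = paste0("c", 0:order),
    stop("unknown growth-curve family: ", family)
  )
}

#' Construct growth-curve parameters
#'
#' @param family One of \code{"richards"}, \code{"bertalanffy"},
#'   \code{"gompertz"}, \code{"logistic"}, \code{"legendre"}.
#' @param coefficients Named or ordered numeric vector: \code{a, b, r, k} for
#'   Richards; \code{a, b, r} for Bertalanffy/Gompertz/Logistic;
#'   \code{c0 .. c_order} for Legendre.
#' @param t_range Length-2 numeric giving the age interval mapped to
#'   \eqn{[-1, 1]} (Legendre only).
#' @return An object of class \code{"growth_params"} with elements
#'   \code{family}, \code{coefficients}, \code{d} (parameter count) and, for
#'   Legendre, \code{t_range}.
#' @export
growth_params <- function(family, coefficients, t_range = NULL) {
  family <- match.arg(family, GROWTH_FAMILIES)
  coefficients <- as.numeric(coefficients)
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  if (family == "legendre") {
    if (is.null(t_range)) stop("legendre parameters require t_range")
    if (length(coefficients) < 1L) stop("legendre needs at least c0")
    names(coefficients) <- paste0("c", seq_along(coefficients) - 1L)
  } else {
    nm <- family_coef_names(family)
    if (length(coefficients) != length(nm))
      stop(family, " takes ", length(nm), " coefficients")
    names(coefficients) <- nm
    if (coefficients["a"] <= 0)
      stop("asymptote a must be positive for the ", family, " family")
    if (family == "richards" && abs(coefficients["k"] - 1) < 1e-4)
      stop("richards shape k must stay away from 1 (|k - 1| > 1e-4); ",
           "use the gompertz family for the k = 1 limit")
  }
  structure(
    list(family = family, coefficients = coefficients,
         d = length(coefficients),
         t_range = if (family == "legendre") as.numeric(t_range)),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, digits = 4, ...) {
  cat(sprintf("<growth_params: %s, d = %d>\n", x$family, x$d))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Normalized Legendre basis
#'
#' Evaluates the normalized Legendre polynomials
#' \eqn{\psi_j(x) = \sqrt{(2j+1)/2}\, P_j(x)} (orthonormal on \eqn{[-1,1]}
#' with unit weight), the basis conventional in random-regression test-day
#' models, at ages affinely mapped from \code{t_range} to \eqn{[-1, 1]}.
#'
#' @param t Numeric vector of ages.
#' @param order Highest polynomial degree.
#' @param t_range Interval mapped to \eqn{[-1, 1]}; defaults to
#'   \code{range(t)}.
#' @return Matrix with \code{length(t)} rows and \code{order + 1} columns
#'   \eqn{\psi_0, \ldots, \psi_{order}}.
#' @export
legendre_basis <- function(t, order, t_range = range(t)) {
  t_range <- as.numeric(t_range)
  if (diff(t_range) <= 0) stop("t_range must have positive width")
  x <- 2 * (t - t_range[1]) / (t_range[2] - t_range[1]) - 1
  P <- matrix(0, length(x), order + 1L)
  P[, 1] <- 1
  if (order >= 1L) P[, 2] <- x
  if (order >= 2L) {
    for (j in 2:order) {
      # Bonnet recurrence: j P_j = (2j-1) x P_{j-1} - (j-1) P_{j-2}
      P[, j + 1] <- ((2 * j - 1) * x * P[, j] - (j - 1) * P[, j - 1]) / j
    }
  }
  norm <- sqrt((2 * (0:order) + 1) / 2)
  sweep(P, 2, norm, "*")
}

#' Evaluate a growth curve
#'
#' @param params A \code{\link{growth_params}} object.
#' @param t Numeric vector of ages.
#' @return Numeric vector of trajectory values at \code{t}.
#' @export
evaluate_curve <- function(params, t) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(t))) stop("t must be finite")
  cf <- params$coefficients
  switch(params$family,
    richards = {
      base <- 1 + cf["b"] * exp(-cf["r"] * t)
      if (any(base <= 0))
        stop("richards base 1 + b*exp(-r*t) must be positive on t")
      unname(cf["a"] * base^(1 / (1 - cf["k"])))
    },
    bertalanffy = unname(cf["a"] * (1 - cf["b"] * exp(-cf["r"] * t))),
    gompertz    = unname(cf["a"] * exp(-cf["b"] * exp(-cf["r"] * t))),
    logistic    = unname(cf["a"] / (1 + cf["b"] * exp(-cf["r"] * t))),
    legendre    = {
      B <- legendre_basis(t, params$d - 1L, params$t_range)
      drop(B %*% cf)
    }
  )
}

## residual-based fit statistics shared by all families; the +1 in the
## parameter count is the residual variance of the Gaussian likelihood
fit_stats <- function(values, fitted, d) {
  n <- length(values)
  rss <- sum((values - fitted)^2)
  tss <- sum((values - mean(values))^2)
  rss_ic <- max(rss, n * .Machine$double.xmin)   # keep IC finite at RSS = 0
  list(
    rss = rss,
    residual_variance = rss / (n - d),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    aic = n * log(rss_ic / n) + 2 * (d + 1),
    bic = n * log(rss_ic / n) + (d + 1) * log(n)
  )
}

## self-starting heuristics; returns a list of candidate start vectors
nls_starts <- function(times, values, family, k0 = 1.5) {
  a0 <- 1.05 * max(abs(values))
  eps <- 1e-8
  ratio <- pmin(pmax(values / a0, eps), 1 - eps)
  z <- switch(family,
    bertalanffy = log(1 - ratio),
    gompertz    = log(-log(ratio)),
    logistic    = log(1 / ratio - 1),
    richards    = log(pmax(ratio^(1 - k0) - 1, eps))
  )
  ok <- is.finite(z)
  sl <- if (sum(ok) >= 2) stats::coef(stats::lm(z[ok] ~ times[ok])) else c(0, -0.2)
  r0 <- max(-sl[2], 1e-3)
  b0 <- exp(min(sl[1], 20))
  base <- switch(family,
    bertalanffy = c(a = a0, b = b0, r = r0),
    gompertz    = c(a = a0, b = b0, r = r0),
    logistic    = c(a = a0, b = b0, r = r0),
    richards    = c(a = a0, b = b0, r = r0, k = k0)
  )
  alt <- lapply(c(0.3, 3), function(f) { s <- base; s["r"] <- r0 * f; s })
  # trajectories decaying toward the asymptote (b < 0, or r < 0 in
  # simulation extremes) need sign-flipped starts
  flip_b <- base; flip_b["b"] <- -b0
  flip_r <- base; flip_r["r"] <- -r0
  c(list(base), alt, list(flip_b, flip_r))
}

## analytic Jacobian of the curve w.r.t. its coefficients
family_jacobian <- function(family, cf, t) {
  a <- cf[1]; b <- cf[2]; r <- cf[3]
  ert <- exp(-r * t)
  switch(family,
    bertalanffy = cbind(1 - b * ert, -a * ert, a * b * t * ert),
    gompertz = {
      y <- a * exp(-b * ert)
      cbind(y / a, -y * ert, y * b * t * ert)
    },
    logistic = {
      den <- 1 + b * ert
      cbind(1 / den, -a * ert / den^2, a * b * t * ert / den^2)
    },
    richards = {
      k <- cf[4]
      base <- 1 + b * ert
      ex <- 1 / (1 - k)
      y <- a * base^ex
      cbind(base^ex, a * ex * base^(ex - 1) * ert,
            -a * ex * base^(ex - 1) * b * t * ert,
            y * log(base) * ex^2)
    })
}

## sampling covariance of the fitted coefficients, sigma2 * (J'J)^{-1}
coef_sampling_cov <- function(family, params, times, sigma2, order = NULL,
                              t_range = NULL) {
  J <- if (family == "legendre")
    legendre_basis(times, order, t_range)
  else family_jacobian(family, params, times)
  V <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  d <- length(params)
  if (is.null(V) || any(!is.finite(V)))
    V <- diag(Inf, d)
  (V + t(V)) / 2
}

## profiled-rate starts: for fixed r the Bertalanffy curve is linear in
## (a, a*b), so a coarse grid over r with exact linear LS locates the global
## basin cheaply; Gompertz and Logistic use their log/reciprocal
## linearizations on admissible points. Returns a list of start vectors.
profile_starts <- function(times, values, family, n_keep = 3L) {
  r_grid <- c(seq(-0.8, -0.02, by = 0.06), seq(0.02, 1.6, by = 0.04))
  cand <- list()
  if (family %in% c("bertalanffy", "richards")) {
    rss <- vapply(r_grid, function(r) {
      X <- cbind(1, exp(-r * times))
      sum(stats::lm.fit(X, values)$residuals^2)
    }, 0)
    best <- r_grid[order(rss)[seq_len(n_keep)]]
    cand <- lapply(best, function(r) {
      cf <- stats::lm.fit(cbind(1, exp(-r * times)), values)$coefficients
      a <- cf[1]
      if (!is.finite(a) || a <= 0) return(NULL)
      if (family == "bertalanffy")
        c(a = unname(a), b = unname(-cf[2] / a), r = r)
      else
        c(a = unname(a), b = unname(cf[2] / a), r = r, k = 1e-3)
    })
  } else if (family == "gompertz") {
    ok <- values > 0
    if (sum(ok) >= 4) {
      ly <- log(values[ok]); tt <- times[ok]
      rss <- vapply(r_grid, function(r) {
        X <- cbind(1, exp(-r * tt))
        sum(stats::lm.fit(X, ly)$residuals^2)
      }, 0)
      best <- r_grid[order(rss)[seq_len(n_keep)]]
      cand <- lapply(best, function(r) {
        cf <- stats::lm.fit(cbind(1, exp(-r * tt)), ly)$coefficients
        if (!is.finite(cf[1])) return(NULL)
        c(a = unname(exp(cf[1])), b = unname(-cf[2]), r = r)
      })
    }
  } else if (family == "logistic") {
    ok <- values > 0
    if (sum(ok) >= 4) {
      iy <- 1 / values[ok]; tt <- times[ok]
      rss <- vapply(r_grid, function(r) {
        X <- cbind(1, exp(-r * tt))
        sum(stats::lm.fit(X, iy)$residuals^2)
      }, 0)
      best <- r_grid[order(rss)[seq_len(n_keep)]]
      cand <- lapply(best, function(r) {
        cf <- stats::lm.fit(cbind(1, exp(-r * tt)), iy)$coefficients
        if (!is.finite(cf[1]) || cf[1] <= 0) return(NULL)
        c(a = unname(1 / cf[1]), b = unname(cf[2] / cf[1]), r = r)
      })
    }
  }
  Filter(Negate(is.null), cand)
}

nls_formula <- function(family) {
  switch(family,
    richards    = values ~ a * (1 + b * exp(-r * times))^(1 / (1 - k)),
    bertalanffy = values ~ a * (1 - b * exp(-r * times)),
    gompertz    = values ~ a * exp(-b * exp(-r * times)),
    logistic    = values ~ a / (1 + b * exp(-r * times))
  )
}

try_nls <- function(form, dat, start, lower, upper) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      form, data = dat, start = as.list(start),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(coef = stats::coef(fit), rss = sum(stats::resid(fit)^2),
       converged = isTRUE(fit$convInfo$isConv))
}

#' Fit a growth curve to one longitudinal series
#'
#' Non-linear least squares (Levenberg--Marquardt, multi-start) for the
#' biological families; ordinary least squares on the normalized Legendre
#' basis for \code{family = "legendre"}. Non-convergence is reported through
#' \code{converged = FALSE} with the best parameters found, never silently.
#'
#' @param times,values Numeric vectors of ages and measurements (equal
#'   length, \code{times} strictly increasing).
#' @param family Growth-curve family (see \code{\link{growth_params}}).
#' @param order Polynomial degree for \code{family = "legendre"}.
#' @param t_range Age interval mapped to \eqn{[-1,1]} for Legendre fits;
#'   defaults to \code{range(times)}.
#' @param id Optional individual identifier carried into the result.
#' @return An object of class \code{"growth_fit"}: a list with
#'   \code{params} (\code{growth_params}), \code{n_obs},
#'   \code{residual_variance} (\eqn{RSS/(n-d)}), \code{r_squared},
#'   \code{aic}, \code{bic} (Gaussian forms with \eqn{d+1} parameters
#'   counting the residual variance), \code{converged}, \code{fitted},
#'   \code{residuals} and \code{id}.
#' @examples
#' t <- 1:16
#' y <- evaluate_curve(growth_params("logistic", c(20, 9, 0.5)), t)
#' fit <- fit_growth_curve(t, y, "logistic")
#' coef(fit)
#' @export
fit_growth_curve <- function(times, values, family = GROWTH_FAMILIES,
                             order = 2L, t_range = range(times), id = NULL) {
  family <- match.arg(family)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  d <- if (family == "legendre") order + 1L else length(family_coef_names(family))
  if (n < d + 1L)
    stop("need at least d + 1 = ", d + 1L, " observations to fit ", family)

  if (family == "legendre") {
    B <- legendre_basis(times, order, t_range)
    beta <- stats::lm.fit(B, values)$coefficients
    params <- growth_params("legendre", beta, t_range = t_range)
    fitted <- drop(B %*% beta)
    converged <- TRUE
  } else {
    form <- nls_formula(family)
    dat <- data.frame(times = times, values = values)
    nm <- family_coef_names(family)
    lower <- stats::setNames(rep(-Inf, length(nm)), nm); lower["a"] <- 1e-8
    upper <- stats::setNames(rep(Inf, length(nm)), nm)
    if (family == "richards") {
      # seed from the heuristic, the profiled near-Bertalanffy (k ~ 0) and
      # the logistic-equivalent (k = 2) shapes, and fit each side of the
      # k = 1 exclusion band so the shape parameter never crosses the
      # singularity
      log_start <- lapply(profile_starts(times, values, "logistic"),
                          function(s) c(s, k = 2))
      starts <- c(nls_starts(times, values, "richards"),
                  profile_starts(times, values, "richards"), log_start)
      starts <- lapply(starts, function(s) {
        names(s) <- c("a", "b", "r", "k"); s
      })
      lo_hi <- lower; lo_hi["k"] <- 1 + 2e-4
      up_lo <- upper; up_lo["k"] <- 1 - 2e-4
      starts <- c(
        lapply(starts, function(s) { s["k"] <- max(s["k"], 1.5); s }),
        lapply(starts, function(s) { s["k"] <- min(s["k"], 0.5); s })
      )
      # rank candidate starts by their own RSS and polish only the best few
      rss0 <- vapply(starts, function(s) {
        y0 <- eval_family("richards", s, times)
        if (any(!is.finite(y0))) Inf else sum((values - y0)^2)
      }, 0)
      starts <- starts[order(rss0)[seq_len(min(6L, length(starts)))]]
      cands <- lapply(starts, function(s)
        if (s["k"] > 1) try_nls(form, dat, s, lo_hi, upper)
        else try_nls(form, dat, s, lower, up_lo))
    } else {
      starts <- c(nls_starts(times, values, family),
                  profile_starts(times, values, family))
      cands <- lapply(starts, function(s) try_nls(form, dat, s, lower, upper))
    }
    cands <- Filter(Negate(is.null), cands)
    if (family == "richards")
      # enforce the domain constraint 1 + b*exp(-r*t) > 0 on the data grid
      cands <- Filter(function(cn) {
        all(1 + cn$coef["b"] * exp(-cn$coef["r"] * times) > 0)
      }, cands)
    if (length(cands) == 0L) {
      # no optimizer run succeeded: report the best domain-valid start,
      # unconverged (never silently)
      ok <- Filter(function(s) {
        s["a"] > 0 && (family != "richards" ||
          (abs(s["k"] - 1) > 1e-4 &&
           all(1 + s["b"] * exp(-s["r"] * times) > 0)))
      }, starts)
      if (length(ok) == 0L)
        ok <- list(switch(family,
          richards = c(a = max(abs(values)), b = 0.5, r = 0.1, k = 1.5),
          c(a = max(abs(values)), b = 0.5, r = 0.1)))
      rss_ok <- vapply(ok, function(s)
        sum((values - eval_family(family, s, times))^2), 0)
      params <- growth_params(family, ok[[which.min(rss_ok)]])
      fitted <- evaluate_curve(params, times)
      converged <- FALSE
    } else {
      rss_all <- vapply(cands, `[[`, 0, "rss")
      best <- cands[[which.min(rss_all)]]
      # prefer a cleanly converged candidate over an equal-RSS wanderer
      # that stopped on the iteration cap (common on flat shape ridges)
      if (!best$converged) {
        near <- which(rss_all <= min(rss_all) * (1 + 1e-4) &
                        vapply(cands, `[[`, TRUE, "converged"))
        if (length(near)) best <- cands[[near[which.min(rss_all[near])]]]
      }
      params <- growth_params(family, best$coef)
      fitted <- evaluate_curve(params, times)
      converged <- best$converged
    }
  }

  st <- fit_stats(values, fitted, d)
  structure(
    list(params = params, id = id, n_obs = n, times = times, values = values,
         fitted = fitted, residuals = values - fitted,
         residual_variance = st$residual_variance, r_squared = st$r_squared,
         aic = st$aic, bic = st$bic, converged = converged,
         vcov = coef_sampling_cov(family, params$coefficients, times,
                                  st$residual_variance,
                                  order = if (family == "legendre") order,
                                  t_range = t_range)),
    class = "growth_fit"
  )
}

#' @export
vcov.growth_fit <- function(object, ...) object$vcov

#' @export
coef.growth_fit <- function(object, ...) object$params$coefficients

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @export
fitted.growth_fit <- function(object, ...) object$fitted

#' @export
predict.growth_fit <- function(object, newtimes = object$times, ...) {
  evaluate_curve(object$params, newtimes)
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Growth-curve fit (%s)%s: n = %d, converged = %s\n",
              x$params$family,
              if (!is.null(x$id)) paste0(" for ", x$id) else "",
              x$n_obs, x$converged))
  print(round(x$params$coefficients, digits))
  cat(sprintf("residual variance %.4g, R2 %.4f, AIC %.3f, BIC %.3f\n",
              x$residual_variance, x$r_squared, x$aic, x$bic))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Fit growth curves for all individuals in a long-format table
#'
#' @param pheno Data frame with columns \code{id}, \code{time}, \code{value}
#'   (see \code{\link{read_phenotypes}}).
#' @param family,order,t_range Passed to \code{\link{fit_growth_curve}};
#'   \code{t_range} defaults to the pooled age range so every individual uses
#'   the same Legendre scaling.
#' @param min_obs Individuals with fewer observations than \code{d + 1} are
#'   skipped with a warning naming how many were dropped.
#' @return A list of \code{growth_fit} objects (class
#'   \code{"growth_fit_list"}), named by individual id.
#' @export
fit_growth_curves <- function(pheno, family = GROWTH_FAMILIES, order = 2L,
                              t_range = range(pheno$time), min_obs = NULL) {
  family <- match.arg(family)
  d <- if (family == "legendre") order + 1L else length(family_coef_names(family))
  if (is.null(min_obs)) min_obs <- d + 1L
  sp <- split(pheno[c("time", "value")], pheno$id)
  short <- vapply(sp, nrow, 0L) < min_obs
  if (any(short)) {
    warning(sum(short), " individual(s) dropped with fewer than ",
            min_obs, " records")
    sp <- sp[!short]
  }
  fits <- lapply(names(sp), function(id) {
    s <- sp[[id]]
    o <- order(s$time)
    fit_growth_curve(s$time[o], s$value[o], family, order = order,
                     t_range = t_range, id = id)
  })
  names(fits) <- names(sp)
  structure(fits, class = c("growth_fit_list", "list"))
}

#' @export
print.growth_fit_list <- function(x, ...) {
  cat(sprintf("<%d growth-curve fits (%s); %d converged>\n", length(x),
              x[[1]]$params$family, sum(vapply(x, `[[`, TRUE, "converged"))))
  invisible(x)
}

#' Extract the regression-phenotype matrix from a set of curve fits
#'
#' Rows are individuals, columns the fitted curve parameters: the
#' second-hierarchy traits taken into the multivariate mixed model.
#' Unconverged fits are dropped with a warning.
#'
#' @param fits A \code{growth_fit_list}.
#' @param drop_unconverged Drop fits with \code{converged = FALSE}
#'   (default TRUE).
#' @param max_vcov_factor Fits whose coefficient-sampling-covariance trace
#'   exceeds this multiple of the cohort median are treated as failed
#'   (effectively unidentifiable trajectories) and dropped; \code{Inf}
#'   disables the filter.
#' @return Numeric matrix (individuals x parameters) with row names the
#'   ids and attribute \code{"meas_cov"}: a d x d x n array of the
#'   coefficient sampling covariances \eqn{\hat\sigma^2 (J^T J)^{-1}} of the
#'   retained fits.
#' @export
regression_phenotypes <- function(fits, drop_unconverged = TRUE,
                                  max_vcov_factor = 10) {
  conv <- vapply(fits, `[[`, TRUE, "converged")
  keep <- conv | !drop_unconverged
  tr <- vapply(fits, function(f) sum(diag(f$vcov)), 0)
  if (is.finite(max_vcov_factor)) {
    med <- stats::median(tr[keep & is.finite(tr)])
    keep <- keep & is.finite(tr) & tr <= max_vcov_factor * med
  }
  if (any(!keep)) {
    warning(sum(!keep), " failed fit(s) (unconverged or unidentifiable) ",
            "dropped from the phenotype matrix")
    fits <- fits[keep]
  }
  d <- fits[[1]]$params$d
  P <- t(vapply(fits, function(f) f$params$coefficients, numeric(d)))
  rownames(P) <- names(fits)
  mc <- vapply(fits, `[[`, matrix(0, d, d), "vcov")
  attr(P, "meas_cov") <- array(mc, dim = c(d, d, length(fits)))
  P
}

#' Fit the population mean growth curve
#'
#' Averages measurements at each shared age across individuals, then fits the
#' requested family to the age-specific means.
#'
#' @param pheno Long-format data frame (\code{id}, \code{time}, \code{value}).
#' @param family,order Passed to \code{\link{fit_growth_curve}}.
#' @param tol Ages closer than \code{tol} are treated as the same time point;
#'   an error is raised if a single individual has two records inside one
#'   merged age group (grids not alignable).
#' @return A \code{growth_fit} for the mean trajectory (\code{id = "population"}).
#' @export
fit_population_curve <- function(pheno, family = GROWTH_FAMILIES, order = 2L,
                                 tol = 1e-6) {
  family <- match.arg(family)
  ut <- sort(unique(pheno$time))
  grp <- cumsum(c(TRUE, diff(ut) > tol))
  key <- grp[match(pheno$time, ut)]
  if (anyDuplicated(paste(pheno$id, key)))
    stop("time grids not alignable within tol = ", tol,
         ": an individual has two records at one merged age")
  mean_t <- tapply(pheno$time, key, mean)
  mean_y <- tapply(pheno$value, key, mean)
  o <- order(mean_t)
  fit_growth_curve(as.numeric(mean_t[o]), as.numeric(mean_y[o]), family,
                   order = order, id = "population")
}

#' Rank growth-curve fits by goodness of fit
#'
#' @param fits List of \code{growth_fit} objects fitted to the same data.
#' @return Data frame with one row per fit, columns \code{family},
#'   \code{n_params}, \code{bic}, \code{aic}, \code{r_squared},
#'   \code{residual_variance}, sorted by BIC ascending; equal BIC is broken
#'   in favour of fewer parameters.
#' @export
select_growth_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to rank")
  tab <- data.frame(
    family = vapply(fits, function(f) f$params$family, ""),
    n_params = vapply(fits, function(f) as.integer(f$params$d), 0L),
    bic = vapply(fits, `[[`, 0, "bic"),
    aic = vapply(fits, `[[`, 0, "aic"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    residual_variance = vapply(fits, `[[`, 0, "residual_variance"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$bic, tab$n_params), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Time-dependent genetic effect of a QTL on the trajectory
#'
#' The trajectory-level effect of a QTL is the difference between the
#' population curve shifted by the QTL's per-parameter effects and the
#' population curve itself:
#' \eqn{g(t) = f(p_{pop} + \alpha, t) - f(p_{pop}, t)}.
#'
#' @param pop Population \code{\link{growth_params}} (Bertalanffy or
#'   Richards).
#' @param effects Numeric vector of per-parameter QTL effects, aligned with
#'   \code{pop$coefficients}.
#' @param t_grid Ages at which to evaluate the effect curve.
#' @return Numeric vector \eqn{g(t)} over \code{t_grid}.
#' @export
genetic_effect_trajectory <- function(pop, effects, t_grid) {
  stopifnot(inherits(pop, "growth_params"))
  if (!pop$family %in% c("bertalanffy", "richards"))
    stop("population curve must be bertalanffy or richards")
  if (length(effects) != pop$d)
    stop("effects length must match the ", pop$d, " population coefficients")
  shifted <- growth_params(pop$family, pop$coefficients + effects)
  evaluate_curve(shifted, t_grid) - evaluate_curve(pop, t_grid)
}
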