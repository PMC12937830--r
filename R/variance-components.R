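#' Rotate phenotypes and fixed effects by the kinship eigenvectors
#'
#' With \eqn{K = U_k S_k U_k^T}, premultiplying the regression-phenotype
#' matrix and the fixed-effect design by \eqn{U_k^T} turns the matrix-normal
#' null model \eqn{P = X B + G + E}, \eqn{G \sim MN(0, V_g, K)},
#' \eqn{E \sim MN(0, V_{pe}, I_n)} into one with independent rows: row
#' \eqn{i} of the rotated phenotypes has covariance
#' \eqn{s_{k,i} V_g + V_{pe}}.
#'
#' @param P n x d regression-phenotype matrix (row names = ids).
#' @param X n x c fixed-effect design matrix.
#' @param kin A \code{\link{kinship}} object with ids aligned to \code{P}.
#' @return List with rotated \code{P}, \code{X} and the eigenvalues
#'   \code{values}.
#' @export
rotate_by_kinship <- function(P, X, kin) {
  stopifnot(inherits(kin, "kinship"))
  if (nrow(P) != nrow(kin$matrix)) stop("P and kinship dimensions disagree")
  if (!is.null(rownames(P)) && !is.null(kin$ids) &&
      !identical(rownames(P), as.character(kin$ids)))
    stop("P rows and kinship ids are not aligned")
  if (nrow(X) != nrow(P)) stop("X and P dimensions disagree")
  list(P = crossprod(kin$vectors, P), X = crossprod(kin$vectors, X),
       values = kin$values)
}

## T such that T Vpe T' = I and T Vg T' = diag(dvals); NULL if Vpe not PD
simdiag_pair <- function(Vg, Vpe) {
  Rl <- tryCatch(t(chol(Vpe)), error = function(e) NULL)
  if (is.null(Rl)) return(NULL)
  W <- forwardsolve(Rl, t(forwardsolve(Rl, Vg)))
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  Tm <- t(e$vectors) %*% forwardsolve(Rl, diag(nrow(Vg)))
  list(T = Tm, dvals = e$values, logdet_vpe = 2 * sum(log(diag(Rl))))
}

## -2 x REML log-likelihood of the rotated independent-row model, with the
## Gaussian constant included. Returns Inf outside the feasible region.
reml_neg2 <- function(Vg, Vpe, Ptil, Xtil, sk) {
  n <- nrow(Ptil); d <- ncol(Ptil); cc <- ncol(Xtil)
  sd_ <- simdiag_pair(Vg, Vpe)
  if (is.null(sd_)) return(Inf)
  w <- outer(sk, sd_$dvals) + 1            # n x d weights
  if (any(w <= 1e-12)) return(Inf)
  Q <- Ptil %*% t(sd_$T)
  crit <- (n - cc) * sd_$logdet_vpe + sum(log(w))
  for (l in seq_len(d)) {
    Xw <- Xtil / w[, l]
    A <- crossprod(Xtil, Xw)
    b <- tryCatch(solve(A, crossprod(Xw, Q[, l])), error = function(e) NULL)
    if (is.null(b)) return(Inf)
    r <- Q[, l] - Xtil %*% b
    crit <- crit + sum(r^2 / w[, l]) + determinant(A)$modulus[1]
  }
  crit + (n - cc) * d * log(2 * pi)
}

## GLS fixed effects B (c x d, original trait scale) at given components
gls_fixed_effects <- function(Vg, Vpe, Ptil, Xtil, sk) {
  sd_ <- simdiag_pair(Vg, Vpe)
  w <- outer(sk, sd_$dvals) + 1
  Q <- Ptil %*% t(sd_$T)
  Cm <- sapply(seq_len(ncol(Q)), function(l) {
    Xw <- Xtil / w[, l]
    solve(crossprod(Xtil, Xw), crossprod(Xw, Q[, l]))
  })
  Cm <- matrix(Cm, ncol = ncol(Q))
  # q-space coefficients back to original traits: C = B T' => B = C (T')^{-1}
  Cm %*% t(solve(sd_$T))
}

vech_index <- function(d) which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)

theta_to_chol <- function(theta, d) {
  L <- matrix(0, d, d)
  idx <- vech_index(d)
  diag_pos <- idx[, 1] == idx[, 2]
  v <- theta
  v[diag_pos] <- exp(pmin(v[diag_pos], 30))
  L[idx] <- v
  L
}

chol_to_theta <- function(V, d) {
  L <- t(chol(V + diag(1e-10 * mean(diag(V)) + 1e-12, d)))
  idx <- vech_index(d)
  v <- L[idx]
  diag_pos <- idx[, 1] == idx[, 2]
  v[diag_pos] <- log(pmax(v[diag_pos], 1e-12))
  v
}

## one EM sweep for (Vg, Vpe) in the rotated model (ML flavour, used only to
## warm-start the quasi-Newton REML maximization)
em_step <- function(Vg, Vpe, Ptil, Xtil, sk) {
  n <- nrow(Ptil); d <- ncol(Ptil)
  B <- gls_fixed_effects(Vg, Vpe, Ptil, Xtil, sk)
  R <- Ptil - Xtil %*% B
  Sg <- matrix(0, d, d); Sp <- matrix(0, d, d); ng <- 0L
  for (i in seq_len(n)) {
    Sig <- sk[i] * Vg + Vpe
    Sinv <- solve(Sig)
    r <- R[i, ]
    Ee <- Vpe %*% Sinv %*% r
    Ve <- Vpe - Vpe %*% Sinv %*% Vpe
    Sp <- Sp + tcrossprod(Ee) + Ve
    if (sk[i] > 1e-10) {
      Gg <- sk[i] * Vg
      Eg <- Gg %*% Sinv %*% r
      Vgp <- Gg - Gg %*% Sinv %*% Gg
      Sg <- Sg + (tcrossprod(Eg) + Vgp) / sk[i]
      ng <- ng + 1L
    }
  }
  list(Vg = (Sg + t(Sg)) / (2 * max(ng, 1L)), Vpe = (Sp + t(Sp)) / (2 * n))
}

#' REML estimation of the null multivariate mixed model
#'
#' Estimates the genetic and permanent-environmental covariance matrices
#' \eqn{(V_g, V_{pe})} of the regression phenotypes under the no-QTL model
#' \eqn{P = X B + G + E} with \eqn{G \sim MN(0, V_g, K)} and
#' \eqn{E \sim MN(0, V_{pe}, I_n)}. The kinship rotation makes rows
#' independent; the likelihood is maximized by quasi-Newton iteration on an
#' unconstrained log-Cholesky parameterization (which enforces positive
#' semi-definiteness), warm-started by a few EM sweeps. Standard deviations
#' of all components come from the central-difference observed information of
#' the REML log-likelihood in the original (co)variance coordinates.
#'
#' @param P n x d matrix of fitted curve parameters (rows = individuals
#'   aligned with \code{kin}).
#' @param kin A \code{\link{kinship}} object.
#' @param covariates Optional n x q matrix of fixed covariates; a per-trait
#'   intercept is always included.
#' @param meas_cov Optional first-hierarchy measurement covariances of the
#'   rows of \code{P}: a d x d x n array (e.g. \code{attr(P, "meas_cov")}
#'   from \code{\link{regression_phenotypes}}) or a single d x d matrix.
#'   When supplied, the REML fit estimates the total independent covariance
#'   and reports \code{Vpe} with the mean measurement covariance subtracted
#'   (floored to positive semi-definite), so that it captures only
#'   permanent-environmental variation; the uncorrected total is kept in
#'   \code{Vpe_total} and is what association scans should whiten against.
#' @param em_iter Number of EM warm-start sweeps (default 5).
#' @param max_iter Iteration cap for the quasi-Newton stage (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8);
#'   the gradient max-norm must also fall below \code{grad_tol}.
#' @param grad_tol Gradient tolerance (default 1e-5), applied to the\n#'   max-norm relative to the criterion magnitude.
#' @param compute_se Compute standard deviations (default TRUE; the Hessian
#'   costs a few hundred likelihood evaluations).
#' @return An object of class \code{"null_mvlmm"}: \code{Vg}, \code{Vpe},
#'   \code{se_Vg}, \code{se_Vpe}, \code{B} (fixed effects), \code{loglik_reml},
#'   \code{loglik_trace}, \code{converged}, \code{n_iter}, plus the rotated
#'   data needed by the downstream scan.
#' @export
estimate_null_mvlmm <- function(P, kin, covariates = NULL, meas_cov = NULL,
                                em_iter = 5L, max_iter = 500L, tol = 1e-8,
                                grad_tol = 1e-5, compute_se = TRUE) {
  if (is.null(meas_cov)) meas_cov <- attr(P, "meas_cov")
  P <- as.matrix(P)
  n <- nrow(P); d <- ncol(P)
  X <- cbind(intercept = rep(1, n), covariates)
  if (n <= d + ncol(X)) stop("too few individuals for ", d, " traits")
  if (any(!is.finite(P))) stop("P contains non-finite values")
  rot <- rotate_by_kinship(P, X, kin)
  Ptil <- rot$P; Xtil <- rot$X; sk <- rot$values
  if (max(sk) - min(sk) < 0.05)
    warning("kinship eigenvalue spread < 0.05: Vg and Vpe nearly confounded")

  ## moment start: residual covariance split evenly
  S0 <- stats::cov(as.matrix(stats::lm.fit(X, P)$residuals)) *
    (n - 1) / (n - ncol(X))
  Vg <- S0 / 2; Vpe <- S0 / 2
  for (it in seq_len(em_iter)) {
    upd <- em_step(Vg, Vpe, Ptil, Xtil, sk)
    Vg <- upd$Vg; Vpe <- upd$Vpe
  }
  Vpe <- Vpe + diag(1e-8 * mean(diag(Vpe)) + 1e-12, d)

  np <- d * (d + 1) / 2
  obj <- function(theta) {
    Lg <- theta_to_chol(theta[1:np], d)
    Lp <- theta_to_chol(theta[np + 1:np], d)
    v <- reml_neg2(tcrossprod(Lg), tcrossprod(Lp), Ptil, Xtil, sk)
    if (!is.finite(v)) 1e10 else v
  }
  theta <- c(chol_to_theta(Vg, d), chol_to_theta(Vpe, d))
  val <- obj(theta)
  trace <- -val / 2
  iter_used <- 0L
  converged <- FALSE
  while (iter_used < max_iter) {
    op <- stats::optim(theta, obj, method = "BFGS",
                       control = list(maxit = 25, reltol = 1e-12))
    iter_used <- iter_used + 25L
    theta <- op$par
    improved <- val - op$value
    val <- op$value
    trace <- c(trace, -val / 2)
    if (improved < tol * (abs(val) + 1)) {
      g <- numeric(length(theta))
      h <- 1e-4
      for (j in seq_along(theta)) {
        tp <- theta; tp[j] <- tp[j] + h
        tm <- theta; tm[j] <- tm[j] - h
        g[j] <- (obj(tp) - obj(tm)) / (2 * h)
      }
      # gradient norm relative to the criterion magnitude: an absolute
      # norm is below the resolution of central differences here
      if (max(abs(g)) / 2 < grad_tol * (1 + abs(val))) converged <- TRUE
      if (converged || improved <= 0) break
    }
  }
  Vg <- tcrossprod(theta_to_chol(theta[1:np], d))
  Vpe_total <- tcrossprod(theta_to_chol(theta[np + 1:np], d))
  tn <- colnames(P)
  if (is.null(tn)) tn <- paste0("trait", seq_len(d))
  B <- gls_fixed_effects(Vg, Vpe_total, Ptil, Xtil, sk)
  dimnames(B) <- list(colnames(X), tn)

  ## subtract the known first-hierarchy measurement covariance (if any)
  ## from the total independent component, flooring at PSD
  M_bar <- NULL
  Vpe <- Vpe_total
  if (!is.null(meas_cov)) {
    M_bar <- if (length(dim(meas_cov)) == 3L)
      apply(meas_cov, c(1, 2), mean) else as.matrix(meas_cov)
    if (!all(dim(M_bar) == d)) stop("meas_cov must be d x d (x n)")
    Vpe <- Vpe_total - M_bar
    ev <- eigen((Vpe + t(Vpe)) / 2, symmetric = TRUE)
    Vpe <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  }
  dimnames(Vg) <- dimnames(Vpe) <- dimnames(Vpe_total) <- list(tn, tn)

  se <- if (compute_se) information_se(Vg, Vpe_total, Ptil, Xtil, sk) else NULL
  structure(
    list(Vg = Vg, Vpe = Vpe, Vpe_total = Vpe_total, meas_cov_mean = M_bar,
         se_Vg = se$se_Vg, se_Vpe = se$se_Vpe, se_available = !is.null(se),
         B = B, loglik_reml = -val / 2, loglik_trace = trace,
         converged = converged, n_iter = iter_used,
         n = n, d = d, traits = tn,
         rotated = list(P = Ptil, X = Xtil, values = sk)),
    class = "null_mvlmm"
  )
}

## central-difference observed information in vech(Vg), vech(Vpe) coordinates
information_se <- function(Vg, Vpe, Ptil, Xtil, sk, rel_step = 1e-4) {
  d <- ncol(Vg)
  idx <- vech_index(d)
  np <- nrow(idx)
  pack <- function(V1, V2) c(V1[idx], V2[idx])
  unpack <- function(v) {
    mk <- function(x) {
      M <- matrix(0, d, d); M[idx] <- x; M[upper.tri(M)] <- t(M)[upper.tri(M)]
      M
    }
    list(Vg = mk(v[1:np]), Vpe = mk(v[np + 1:np]))
  }
  f <- function(v) {
    V <- unpack(v)
    -0.5 * reml_neg2(V$Vg, V$Vpe, Ptil, Xtil, sk)
  }
  v0 <- pack(Vg, Vpe)
  h <- rel_step * pmax(abs(v0), mean(abs(v0)))
  p <- length(v0)
  H <- matrix(NA_real_, p, p)
  f0 <- f(v0)
  if (!is.finite(f0)) return(NULL)
  for (i in seq_len(p)) for (j in i:p) {
    vpp <- v0; vpp[i] <- vpp[i] + h[i]; vpp[j] <- vpp[j] + h[j]
    vpm <- v0; vpm[i] <- vpm[i] + h[i]; vpm[j] <- vpm[j] - h[j]
    vmp <- v0; vmp[i] <- vmp[i] - h[i]; vmp[j] <- vmp[j] + h[j]
    vmm <- v0; vmm[i] <- vmm[i] - h[i]; vmm[j] <- vmm[j] - h[j]
    H[i, j] <- H[j, i] <-
      (f(vpp) - f(vpm) - f(vmp) + f(vmm)) / (4 * h[i] * h[j])
  }
  if (any(!is.finite(H))) return(NULL)
  Cv <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(Cv) || any(diag(Cv) <= 0)) return(NULL)
  se <- sqrt(diag(Cv))
  mk <- function(x) {
    M <- matrix(0, d, d); M[idx] <- x; M[upper.tri(M)] <- t(M)[upper.tri(M)]
    dimnames(M) <- dimnames(Vg)
    M
  }
  list(se_Vg = mk(se[1:np]), se_Vpe = mk(se[np + 1:np]))
}

#' @export
print.null_mvlmm <- function(x, digits = 3, ...) {
  cat(sprintf("Null multivariate mixed model: n = %d, d = %d, REML loglik %.3f (%s)\n",
              x$n, x$d, x$loglik_reml,
              if (x$converged) "converged" else "NOT converged"))
  cat("Vg:\n"); print(round(x$Vg, digits))
  cat("Vpe:\n"); print(round(x$Vpe, digits))
  invisible(x)
}

#' @export
summary.null_mvlmm <- function(object, ...) {
  print(object)
  if (object$se_available) {
    cat("\nWald tests on (co)variance components:\n")
    print(wald_components(object), digits = 3)
  } else {
    cat("\nstandard deviations unavailable (singular information matrix)\n")
  }
  invisible(object)
}

#' Wald-type tests on estimated (co)variance components
#'
#' Each component is compared with its standard deviation: \eqn{z =}
#' estimate / sd, with a one-sided normal p-value for variances (diagonals)
#' and a two-sided one for covariances.
#'
#' @param object A \code{\link{estimate_null_mvlmm}} result.
#' @return Data frame with columns \code{component}, \code{row}, \code{col},
#'   \code{estimate}, \code{sd}, \code{z}, \code{p}.
#' @export
wald_components <- function(object) {
  if (!isTRUE(object$se_available))
    stop("standard deviations unavailable for this fit")
  d <- object$d
  idx <- vech_index(d)
  one <- function(V, S, label) {
    est <- V[idx]; sd_ <- S[idx]
    z <- ifelse(sd_ > 0, est / sd_, ifelse(est == 0, 0, NA_real_))
    diag_pos <- idx[, 1] == idx[, 2]
    p <- ifelse(diag_pos, stats::pnorm(z, lower.tail = FALSE),
                2 * stats::pnorm(-abs(z)))
    p[!is.na(z) & z == 0 & !diag_pos] <- 1
    data.frame(component = label,
               row = object$traits[idx[, 1]], col = object$traits[idx[, 2]],
               estimate = est, sd = sd_, z = z, p = p,
               stringsAsFactors = FALSE)
  }
  rbind(one(object$Vg, object$se_Vg, "Vg"),
        one(object$Vpe, object$se_Vpe, "Vpe"))
}
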