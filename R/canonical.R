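#' Canonical transformation of the multivariate mixed model
#'
#' Builds the d x d matrix \eqn{L} that simultaneously whitens the
#' permanent-environmental covariance and diagonalizes the genetic
#' covariance: \eqn{L V_{pe} L^T = I_d} and \eqn{L V_g L^T = S_\lambda}.
#' With \eqn{V_{pe} = U_{pe} S_{pe} U_{pe}^T}, set
#' \eqn{A = S_{pe}^{-1/2} U_{pe}^T}; eigen-decomposing
#' \eqn{A V_g A^T = U_\lambda S_\lambda U_\lambda^T} gives
#' \eqn{L = U_\lambda^T A}. Applying \eqn{P^* = P L^T} turns the d
#' correlated traits into d independent pseudo-traits, the l-th with
#' covariance \eqn{s_{\lambda l} K + I_n}.
#'
#' Canonical values are returned in descending order; each row of \eqn{L} is
#' sign-fixed so its largest-magnitude entry is positive. A nearly singular
#' \eqn{V_{pe}} is repaired by a small ridge (1e-8 of the mean diagonal) with
#' a warning; repair is refused if the condition number still exceeds 1e12.
#'
#' @param x A \code{null_mvlmm} fit, or a list with elements \code{Vg} and
#'   \code{Vpe}.
#' @return An object of class \code{"canonical_transform"}: list with
#'   \code{L}, \code{s_lambda}, and \code{Vg}, \code{Vpe} used.
#' @export
canonical_transform <- function(x) {
  Vg <- x$Vg
  # scans whiten against the total independent component (which includes
  # any first-hierarchy measurement variance), not the corrected Vpe
  Vpe <- if (!is.null(x$Vpe_total)) x$Vpe_total else x$Vpe
  d <- ncol(Vpe)
  ep <- eigen((Vpe + t(Vpe)) / 2, symmetric = TRUE)
  if (max(ep$values) <= 0)
    stop("Vpe singular beyond repair: eigenvalue ",
         signif(max(ep$values), 3))
  if (min(ep$values) < 1e-10 * max(ep$values)) {
    warning("Vpe nearly singular (smallest eigenvalue ",
            signif(min(ep$values), 3), "); applying ridge repair")
    Vpe <- Vpe + diag(1e-8 * mean(diag(Vpe)) + 1e-300, d)
    ep <- eigen((Vpe + t(Vpe)) / 2, symmetric = TRUE)
    if (min(ep$values) <= 0 || max(ep$values) / min(ep$values) > 1e12)
      stop("Vpe singular beyond repair: eigenvalue ", signif(min(ep$values), 3))
  }
  A <- diag(1 / sqrt(ep$values), d) %*% t(ep$vectors)
  M <- A %*% Vg %*% t(A)
  el <- eigen((M + t(M)) / 2, symmetric = TRUE)   # values descending
  L <- t(el$vectors) %*% A
  sgn <- apply(L, 1, function(r) sign(r[which.max(abs(r))]))
  L <- L * sgn
  rownames(L) <- paste0("canon", seq_len(d))
  colnames(L) <- colnames(Vpe)
  structure(list(L = L, s_lambda = pmax(el$values, 0), Vg = Vg, Vpe = Vpe),
            class = "canonical_transform")
}

#' @export
print.canonical_transform <- function(x, digits = 4, ...) {
  cat("<canonical_transform>\ns_lambda:", signif(x$s_lambda, digits), "\nL:\n")
  print(round(x$L, digits))
  invisible(x)
}

#' Apply the canonical transformation to the phenotype matrix
#'
#' @param P n x d regression-phenotype matrix.
#' @param ct A \code{\link{canonical_transform}}.
#' @return n x d matrix \eqn{P^* = P L^T} of independent pseudo-traits
#'   (column l has covariance \eqn{s_{\lambda l} K + I_n} under the fitted
#'   components).
#' @export
transform_phenotypes <- function(P, ct) {
  stopifnot(inherits(ct, "canonical_transform"))
  P <- as.matrix(P)
  if (ncol(P) != ncol(ct$L)) stop("P has ", ncol(P),
                                  " columns but L expects ", ncol(ct$L))
  Ps <- P %*% t(ct$L)
  colnames(Ps) <- rownames(ct$L)
  Ps
}

#' Back-transform canonical-scale effects to the curve-parameter scale
#'
#' Marker effects estimated on the pseudo-traits satisfy
#' \eqn{\hat a^* = \hat a L^T}; the original-scale effects are
#' \eqn{\hat a = \hat a^* (L^T)^{-1}}, and (by independence of the
#' pseudo-traits) their variances map through the squared entries of
#' \eqn{(L^T)^{-1}}.
#'
#' @param effects_star m x d matrix of canonical-scale effects.
#' @param var_star m x d matrix of their variances.
#' @param ct A \code{\link{canonical_transform}}.
#' @return List with \code{effects} and \code{se} (both m x d, original
#'   scale).
#' @export
backtransform_effects <- function(effects_star, var_star, ct) {
  Minv <- solve(t(ct$L))                     # (L^T)^{-1}
  eff <- effects_star %*% Minv
  se <- sqrt(var_star %*% Minv^2)
  colnames(eff) <- colnames(se) <- colnames(ct$L)
  list(effects = eff, se = se)
}
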