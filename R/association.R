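#' Whitening transformer for one canonical trait
#'
#' For a pseudo-trait with covariance \eqn{\sigma^2 (s_\lambda K + I_n)} and
#' \eqn{K = U_k S_k U_k^T}, the map
#' \eqn{V^{-1/2} = (s_\lambda S_k + I)^{-1/2} U_k^T} turns the covariance
#' into the identity; applying it to the phenotype and every design column
#' reduces the mixed model to ordinary least squares.
#'
#' @param kin A \code{\link{kinship}} object.
#' @param s_lambda Non-negative variance ratio of the pseudo-trait.
#' @return A function that premultiplies a vector or matrix by
#'   \eqn{V^{-1/2}}.
#' @export
whiten_transform <- function(kin, s_lambda) {
  stopifnot(inherits(kin, "kinship"))
  if (s_lambda < 0) stop("s_lambda must be non-negative")
  scale <- 1 / sqrt(s_lambda * kin$values + 1)
  U <- kin$vectors
  function(M) {
    M <- as.matrix(M)
    crossprod(U, M) * scale
  }
}

#' Score test for one marker on a whitened trait
#'
#' Ordinary least squares on the whitened scale with unit residual variance
#' (the EMMAX convention): \eqn{\hat a = (z'^T z')^{-1} z'^T p'},
#' \eqn{V(\hat a) = 1 / (z'^T z')}, \eqn{\chi^2 = \hat a^2 / V(\hat a)}.
#'
#' @param y_w Whitened (and fixed-effect-residualized) phenotype vector.
#' @param z_w Whitened, centered (and residualized) genotype column.
#' @return List with \code{effect}, \code{variance}, \code{chi2} and
#'   \code{degenerate} (TRUE when the marker carries no variance after
#'   whitening, in which case \code{chi2 = 0}).
#' @export
score_marker <- function(y_w, z_w) {
  zz <- sum(z_w^2)
  if (zz < 1e-12)
    return(list(effect = 0, variance = Inf, chi2 = 0, degenerate = TRUE))
  a <- sum(z_w * y_w) / zz
  list(effect = a, variance = 1 / zz, chi2 = a^2 * zz, degenerate = FALSE)
}

#' Summed pleiotropy test across canonical traits
#'
#' Adds the per-trait chi-square statistics; under the null the sum follows a
#' chi-square distribution with d degrees of freedom (d = number of curve
#' parameters).
#'
#' @param chi2_per_trait Numeric vector (one marker) or m x d matrix.
#' @return List with \code{chi2_sum} and \code{neglog10_p} (computed on the
#'   log scale and capped at 320 to avoid underflow).
#' @export
pleiotropy_test <- function(chi2_per_trait) {
  M <- rbind(chi2_per_trait)
  if (any(!is.finite(M))) stop("chi2 values must be finite")
  s <- rowSums(M)
  lp <- -stats::pchisq(s, df = ncol(M), lower.tail = FALSE, log.p = TRUE) /
    log(10)
  list(chi2_sum = unname(s), neglog10_p = unname(pmin(lp, 320)))
}

#' Bonferroni genome-wide threshold
#'
#' @param m_markers Number of tested markers.
#' @param alpha Family-wise significance level.
#' @return \eqn{-\log_{10}(\alpha / m)}.
#' @export
bonferroni_threshold <- function(m_markers, alpha = 0.05) {
  if (m_markers < 1) stop("m_markers must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  -log10(alpha / m_markers)
}

#' Genomic-control inflation factor
#'
#' @param chi2 Vector of summed test statistics (>= 100 markers).
#' @param df Degrees of freedom of the reference chi-square.
#' @return \code{median(chi2) / qchisq(0.5, df)}.
#' @export
genomic_control <- function(chi2, df) {
  if (length(chi2) < 100) stop("genomic control needs at least 100 markers")
  stats::median(chi2) / stats::qchisq(0.5, df)
}

## center genotype columns at twice the allele frequency; mean-impute NA
center_genotypes <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  if (anyNA(G)) {
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- (2 * p)[idx[, 2]]
  }
  list(Z = sweep(G, 2, 2 * p, "-"), freq = p)
}

## residualize columns of M on the columns of Xw (whitened design)
residualize <- function(M, Xw) {
  M - Xw %*% solve(crossprod(Xw), crossprod(Xw, M))
}

#' Genome scan with the canonically transformed mixed model
#'
#' Runs the EMMAX-style association scan: the fitted curve parameters are
#' canonically transformed into independent pseudo-traits, each pseudo-trait
#' is whitened by its own variance ratio, every centered marker is tested by
#' least squares on the whitened scale, and the per-trait chi-squares are
#' summed into the pleiotropy statistic with d degrees of freedom. Effects
#' and standard errors are reported back on the curve-parameter scale (per
#' copy of the counted allele).
#'
#' When \code{refine = TRUE}, markers passing the suggestive filter
#' (p below \code{suggestive_p} or in the top \code{top_frac} fraction)
#' get a second, exact round: the per-trait variance ratio is re-estimated by
#' univariate REML with the marker as a fixed covariate (started from the
#' genomic value) and the marker is re-tested with the residual variance
#' re-estimated, for at most one refinement pass (two rounds in total).
#'
#' @param P n x d regression-phenotype matrix (ids in row names, aligned
#'   with \code{geno} and \code{kin}).
#' @param geno A \code{genotype_matrix}.
#' @param kin A \code{\link{kinship}}; computed from \code{geno} if missing.
#' @param null A \code{null_mvlmm}; fitted if missing.
#' @param covariates Optional fixed covariates (n x q).
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param refine Run the refinement round (default TRUE).
#' @param suggestive_p P-value bound flagging markers for refinement.
#' @param top_frac Fraction of top markers always flagged.
#' @return Object of class \code{"hirrm_scan"}: \code{records} (per-marker
#'   data frame), \code{lambda_gc}, \code{threshold_neglog10},
#'   \code{rounds_used}, \code{s_lambda}, \code{null}, \code{transform}.
#' @export
hirrm_scan <- function(P, geno, kin = NULL, null = NULL, covariates = NULL,
                       alpha = 0.05, refine = TRUE, suggestive_p = 1e-4,
                       top_frac = 0.001) {
  P <- as.matrix(P)
  if (is.null(kin)) kin <- compute_grm(geno)
  G <- geno$matrix
  if (nrow(G) != nrow(P)) stop("genotype and phenotype row counts disagree")
  if (!is.null(rownames(P)) && !is.null(rownames(G)) &&
      !identical(rownames(P), rownames(G))) {
    common <- intersect(rownames(P), rownames(G))
    stop("phenotype/genotype ids are not aligned (", length(common),
         " ids in common); reorder upstream")
  }
  if (is.null(null)) null <- estimate_null_mvlmm(P, kin,
                                                 covariates = covariates,
                                                 compute_se = FALSE)
  d <- ncol(P); n <- nrow(P); m <- ncol(G)
  ct <- canonical_transform(null)
  Ps <- transform_phenotypes(P, ct)
  X <- cbind(intercept = rep(1, n), covariates)
  cg <- center_genotypes(G)

  chi2 <- matrix(0, m, d)
  eff_star <- matrix(0, m, d)
  var_star <- matrix(Inf, m, d)
  for (l in seq_len(d)) {
    Wl <- whiten_transform(kin, ct$s_lambda[l])
    Xw <- Wl(X)
    yw <- residualize(Wl(Ps[, l, drop = FALSE]), Xw)
    Zw <- residualize(Wl(cg$Z), Xw)
    zz <- colSums(Zw^2)
    ok <- zz > 1e-12
    a <- numeric(m)
    a[ok] <- colSums(Zw[, ok, drop = FALSE] * as.vector(yw)) / zz[ok]
    eff_star[, l] <- a
    var_star[ok, l] <- 1 / zz[ok]
    chi2[, l] <- a^2 * zz
  }
  pt <- pleiotropy_test(chi2)
  rounds_used <- 1L
  refined <- logical(m)

  if (refine && m > 0) {
    pval <- 10^(-pt$neglog10_p)
    flag <- pval < suggestive_p
    n_top <- max(0L, ceiling(top_frac * m))
    if (n_top > 0)
      flag[order(pt$chi2_sum, decreasing = TRUE)[seq_len(n_top)]] <- TRUE
    if (any(flag)) {
      rounds_used <- 2L
      idx <- which(flag)
      key <- apply(cg$Z[, idx, drop = FALSE], 2, paste, collapse = "\r")
      cache <- new.env(parent = emptyenv())
      Ut <- t(kin$vectors)
      Pt <- Ut %*% Ps
      Xt <- Ut %*% X
      Zt <- Ut %*% cg$Z[, idx, drop = FALSE]
      for (j in seq_along(idx)) {
        if (!is.null(cache[[key[j]]])) {
          res <- cache[[key[j]]]
        } else {
          res <- refine_marker(Pt, Xt, Zt[, j], kin$values, ct$s_lambda)
          cache[[key[j]]] <- res
        }
        if (!is.null(res)) {
          i <- idx[j]
          chi2[i, ] <- res$chi2
          eff_star[i, ] <- res$effect
          var_star[i, ] <- res$variance
          refined[i] <- TRUE
        }
      }
      pt <- pleiotropy_test(chi2)
    }
  }

  bt <- backtransform_effects(eff_star, var_star, ct)
  st <- marker_stats(geno)
  records <- data.frame(
    chr = geno$markers$chr, snp = geno$markers$id, pos = geno$markers$pos,
    maf = st$maf, stringsAsFactors = FALSE
  )
  tn <- colnames(ct$L)
  if (is.null(tn)) tn <- paste0("trait", seq_len(d))
  colnames(bt$effects) <- paste0("effect_", tn)
  colnames(bt$se) <- paste0("se_", tn)
  colnames(chi2) <- paste0("chi2_canon", seq_len(d))
  records <- cbind(records, bt$effects, bt$se, chi2,
                   chi2_sum = pt$chi2_sum, df = d,
                   neglog10_p = pt$neglog10_p, refined = refined)
  structure(
    list(records = records,
         lambda_gc = if (m >= 100) genomic_control(pt$chi2_sum, d) else NA_real_,
         threshold_neglog10 = bonferroni_threshold(m, alpha),
         alpha = alpha, rounds_used = rounds_used,
         s_lambda = ct$s_lambda, null = null, transform = ct),
    class = "hirrm_scan"
  )
}

## exact second-round test of one marker: per pseudo-trait, re-estimate the
## variance ratio by univariate REML with the marker in the design (started
## from the genomic value), then a Wald test with re-estimated residual
## variance. Inputs are already rotated by Uk'. Returns NULL on failure.
refine_marker <- function(Pt, Xt, zt, sk, s_lambda) {
  n <- nrow(Pt); d <- ncol(Pt)
  Xz <- cbind(Xt, marker = zt)
  cc <- ncol(Xz)
  out <- list(chi2 = numeric(d), effect = numeric(d), variance = numeric(d))
  for (l in seq_len(d)) {
    y <- Pt[, l]
    neg2remlp <- function(loglam) {
      w <- exp(loglam) * sk + 1
      Xw <- Xz / w
      A <- crossprod(Xz, Xw)
      b <- tryCatch(solve(A, crossprod(Xw, y)), error = function(e) NULL)
      if (is.null(b)) return(1e10)
      rss <- sum((y - Xz %*% b)^2 / w)
      sum(log(w)) + (n - cc) * log(rss) + determinant(A)$modulus[1]
    }
    o <- tryCatch(
      stats::optimize(neg2remlp,
                      interval = log(s_lambda[l] + 1e-6) + c(-8, 8)),
      error = function(e) NULL)
    if (is.null(o)) return(NULL)
    lam <- exp(o$minimum)
    w <- lam * sk + 1
    Xw <- Xz / w
    A <- crossprod(Xz, Xw)
    b <- solve(A, crossprod(Xw, y))
    rss <- sum((y - Xz %*% b)^2 / w)
    sigma2 <- rss / (n - cc)
    va <- sigma2 * solve(A)[cc, cc]
    out$effect[l] <- b[cc]
    out$variance[l] <- va
    out$chi2[l] <- b[cc]^2 / va
  }
  out
}

#' @export
print.hirrm_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("Genome scan: %d markers, %d pseudo-traits, %d round(s)\n",
              nrow(r), length(x$s_lambda), x$rounds_used))
  cat(sprintf("lambda_gc = %.3f; Bonferroni -log10(p) threshold = %.3f (alpha = %g)\n",
              x$lambda_gc, x$threshold_neglog10, x$alpha))
  cat(sprintf("%d marker(s) above the threshold\n",
              sum(r$neglog10_p > x$threshold_neglog10)))
  invisible(x)
}

#' @export
summary.hirrm_scan <- function(object, n_top = 10, ...) {
  print(object)
  r <- object$records
  top <- r[order(r$neglog10_p, decreasing = TRUE), ]
  cat("\nTop markers:\n")
  print(utils::head(top[c("chr", "snp", "pos", "maf", "chi2_sum",
                          "neglog10_p")], n_top),
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' Manhattan-style plot of a genome scan
#'
#' @param x A \code{hirrm_scan}.
#' @param ... Passed to \code{plot}.
#' @export
plot.hirrm_scan <- function(x, ...) {
  r <- x$records
  chr <- factor(r$chr, levels = unique(r$chr))
  offset <- c(0, cumsum(tapply(r$pos, chr, max)))[as.integer(chr)]
  graphics::plot(offset + r$pos, r$neglog10_p,
                 col = as.integer(chr) %% 2 + 1, pch = 20,
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = x$threshold_neglog10, lty = 2)
  invisible(x)
}
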