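#' Per-marker minor-allele frequency and missingness
#'
#' @param g A \code{genotype_matrix}.
#' @return Data frame with columns \code{maf} (frequency of the less common
#'   allele after dropping missing entries; NA when a marker is entirely
#'   missing) and \code{missing} (missing rate).
#' @export
marker_stats <- function(g) {
  G <- g$matrix
  miss <- colMeans(is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[miss == 1] <- NA_real_
  data.frame(maf = maf, missing = miss, row.names = NULL)
}

#' Filter markers on MAF and missingness
#'
#' @param g A \code{genotype_matrix}.
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param missing_max Maximum missing rate (default 0.1).
#' @return A \code{genotype_matrix} keeping the passing markers in their
#'   original order.
#' @export
filter_markers <- function(g, maf_min = 0.01, missing_max = 0.1) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  st <- marker_stats(g)
  # maf_min = 0 imposes no frequency condition, so markers with undefined
  # MAF (all missing) survive there and are removed by any positive maf_min
  maf_ok <- if (maf_min > 0) !is.na(st$maf) & st$maf >= maf_min else TRUE
  keep <- maf_ok & st$missing <= missing_max
  genotype_matrix(g$matrix[, keep, drop = FALSE],
                  g$markers[keep, , drop = FALSE])
}

#' Genomic relationship matrix
#'
#' Standardized (VanRaden method 2) GRM: missing genotypes are mean-imputed
#' per marker, each marker column is centered at twice its allele frequency
#' and scaled by \eqn{\sqrt{2p(1-p)}}, and \eqn{K = W W^T / m}. The spectral
#' decomposition \eqn{K = U_k S_k U_k^T} is computed once and cached;
#' eigenvalues below zero (numerical) are floored at zero, bending K to
#' positive semi-definite.
#'
#' @param g A \code{genotype_matrix} (at least two polymorphic markers).
#' @param ridge Optional non-negative value added to the diagonal (stabilizes
#'   downstream REML when K is near-singular).
#' @return An object of class \code{"kinship"}: list with \code{matrix}
#'   (n x n), \code{ids}, \code{values} (eigenvalues, descending) and
#'   \code{vectors} (eigenvectors, columns aligned with \code{values}).
#' @export
compute_grm <- function(g, ridge = 0) {
  G <- g$matrix
  p <- colMeans(G, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono))
    stop(sum(mono), " monomorphic or all-missing marker(s); ",
         "run filter_markers() first")
  if (ncol(G) < 2L) stop("need at least two polymorphic markers")
  W <- G
  if (anyNA(W)) {
    mu <- 2 * p
    idx <- which(is.na(W), arr.ind = TRUE)
    W[idx] <- mu[idx[, 2]]
  }
  W <- sweep(W, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(W) / ncol(W)
  K <- (K + t(K)) / 2
  if (ridge > 0) diag(K) <- diag(K) + ridge
  kinship(K, rownames(G))
}

#' Construct a kinship object from a relationship matrix
#'
#' @param K Symmetric n x n relationship matrix.
#' @param ids Individual identifiers (defaults to row names).
#' @return A \code{"kinship"} object with the eigen-decomposition cached and
#'   negative eigenvalues floored at zero.
#' @export
kinship <- function(K, ids = rownames(K)) {
  if (max(abs(K - t(K))) > 1e-10) stop("K is not symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    warning("K has markedly negative eigenvalues; flooring at zero")
  e$values <- pmax(e$values, 0)
  structure(list(matrix = K, ids = ids, values = e$values,
                 vectors = e$vectors),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship: %d individuals, mean diagonal %.3f, eigenvalue range [%.3g, %.3g]>\n",
              nrow(x$matrix), mean(diag(x$matrix)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.kinship <- function(x) dim(x$matrix)
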