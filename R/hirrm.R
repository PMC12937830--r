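#' Hierarchical growth-trajectory GWAS: the full pipeline
#'
#' Runs both hierarchies end to end: fits the chosen growth-curve family to
#' every individual's trajectory, takes the fitted coefficients as
#' correlated quantitative traits, estimates their genetic and
#' permanent-environmental covariance matrices under the null multivariate
#' mixed model, and scans every marker with the canonically transformed
#' EMMAX-style tests.
#'
#' @param pheno Long-format phenotype data frame (\code{id}, \code{time},
#'   \code{value}) or a file path readable by \code{\link{read_phenotypes}}.
#' @param geno A \code{genotype_matrix} or a PLINK prefix for
#'   \code{\link{read_plink}}.
#' @param family Growth-curve family for the first hierarchy.
#' @param order Legendre order when \code{family = "legendre"}.
#' @param covariates Optional covariate matrix (rows named by individual id).
#' @param maf_min,missing_max Marker QC thresholds
#'   (\code{\link{filter_markers}}).
#' @param alpha Family-wise significance level.
#' @param refine Run the second EMMAX round on suggestive markers.
#' @param ... Further arguments to \code{\link{hirrm_scan}}.
#' @return Object of class \code{"hirrm"}: list with \code{fits},
#'   \code{population_fit}, \code{P}, \code{null}, \code{scan},
#'   \code{kinship}, \code{genotypes}.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_individuals = 150, n_markers = 300, n_qtls = 2,
#'                   family = "bertalanffy", seed = 7)
#' dat <- simulate_dataset(cfg)
#' res <- hirrm(dat$pheno, dat$genotypes, family = "bertalanffy")
#' print(res)
#' }
#' @export
hirrm <- function(pheno, geno, family = "bertalanffy", order = 2L,
                  covariates = NULL, maf_min = 0.01, missing_max = 0.1,
                  alpha = 0.05, refine = TRUE, ...) {
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  if (is.character(geno)) geno <- read_plink(geno)
  geno <- filter_markers(geno, maf_min = maf_min, missing_max = missing_max)
  fits <- fit_growth_curves(pheno, family = family, order = order)
  P <- regression_phenotypes(fits)
  gid <- rownames(geno$matrix)
  common <- intersect(rownames(P), gid)
  n_miss <- (nrow(P) - length(common)) + (length(gid) - length(common))
  if (length(common) == 0)
    stop("no individual ids shared between phenotypes and genotypes")
  if (n_miss > 0)
    message(nrow(P) - length(common), " phenotyped and ",
            length(gid) - length(common),
            " genotyped individual(s) without a match were dropped")
  P <- P[common, , drop = FALSE]
  geno <- genotype_matrix(geno$matrix[common, , drop = FALSE], geno$markers)
  rownames(geno$matrix) <- common
  if (!is.null(covariates)) covariates <- covariates[common, , drop = FALSE]
  kin <- compute_grm(geno)
  null <- estimate_null_mvlmm(P, kin, covariates = covariates)
  scan <- hirrm_scan(P, geno, kin = kin, null = null,
                     covariates = covariates, alpha = alpha,
                     refine = refine, ...)
  structure(list(fits = fits,
                 population_fit = fit_population_curve(pheno, family = family,
                                                       order = order),
                 P = P, null = null, scan = scan, kinship = kin,
                 genotypes = geno, family = family),
            class = "hirrm")
}

#' @export
print.hirrm <- function(x, ...) {
  cat(sprintf("Hierarchical growth-trajectory GWAS (%s curve)\n", x$family))
  cat(sprintf("First hierarchy: %d individuals fitted, population curve:\n",
              nrow(x$P)))
  print(round(x$population_fit$params$coefficients, 4))
  cat("Second hierarchy:\n")
  print(x$null)
  print(x$scan)
  invisible(x)
}

#' @export
summary.hirrm <- function(object, ...) {
  print(object)
  summary(object$scan)
  invisible(object)
}

#' @export
plot.hirrm <- function(x, ...) plot(x$scan, ...)

#' @export
coef.hirrm <- function(object, ...) object$P
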