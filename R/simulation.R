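#' Simulation configuration for longitudinal GWAS data
#'
#' Collects the generative settings of the simulation design emulated by the
#' simulator: an LD-structured SNP panel, QTLs placed at random among the
#' markers, correlated genetic and permanent-environmental deviations of the
#' growth-curve parameters (all pairwise correlations 0.5, permanent
#' environmental regression variances 4.0, regression heritability 0.5 by
#' default), trajectories observed at 16 time points with Gaussian
#' measurement error of variance 4.0.
#'
#' By default the deviations act on the coefficients of a normalized
#' Legendre basis over the time grid (the random-regression convention), so
#' they are directly on the phenotype scale and a regression variance of
#' 4.0 is commensurate with the measurement-error variance of 4.0. With
#' \code{deviation_basis = "curve"} the deviations instead perturb the
#' growth-curve parameters themselves; those are then specified in
#' trajectory-normalized units (one unit of parameter j perturbs the
#' trajectory by one phenotype unit root-mean-square over the grid), which
#' keeps a common variance meaningful across parameters of very different
#' magnitude and the trajectories biologically plausible. Set
#' \code{scale = "raw"} to apply curve-parameter variances on the raw
#' coefficient scale instead.
#'
#' @param n_individuals,n_markers Panel size.
#' @param n_qtls Number of QTLs placed uniformly among the markers
#'   (default 500).
#' @param times Measurement ages (default 1:16).
#' @param regression_heritability Per-parameter \eqn{V_g/(V_g+V_{pe})}
#'   (default 0.5).
#' @param pe_variance Permanent-environmental variance per parameter
#'   (default 4.0, normalized units).
#' @param effect_correlation Common pairwise correlation of genetic and of
#'   permanent-environmental deviations (default 0.5).
#' @param residual_variance Measurement-error variance (default 4.0).
#' @param qtl_variance_fraction Fraction of the genetic variance explained
#'   jointly by the QTLs (default 0.3); the rest is polygenic.
#' @param family,pop_coefficients Population growth curve (default Richards
#'   a = 21.4, b = 0.95, r = 0.23, k = 1.5; use Bertalanffy
#'   c(21.4, 0.95, 0.23) for a three-parameter scan).
#' @param deviation_basis Basis carrying the individual genetic and
#'   permanent-environmental deviations: \code{"legendre"} (default) places
#'   them on the coefficients of a normalized Legendre basis over the time
#'   grid, the random-regression convention, so deviations are directly on
#'   the phenotype scale; \code{"curve"} places them on the growth-curve
#'   parameters themselves in trajectory-normalized units (see
#'   \code{scale}).
#' @param deviation_order Legendre order of the deviation basis (default 2,
#'   i.e. d = 3 regression coefficients per individual).
#' @param ld_block_length Markers per LD block.
#' @param ld_copy_prob Within-block haplotype copying probability of the
#'   first-order Markov LD model (default 0.8).
#' @param n_chromosomes Markers are split evenly over this many chromosomes.
#' @param scale \code{"trajectory"} (default) or \code{"raw"} (see Details).
#' @param seed Integer seed; every generator call is deterministic given the
#'   config.
#' @return A \code{"sim_config"} list.
#' @export
sim_config <- function(n_individuals = 500, n_markers = 2000, n_qtls = 500,
                       times = 1:16, regression_heritability = 0.5,
                       pe_variance = 4.0, effect_correlation = 0.5,
                       residual_variance = 4.0, qtl_variance_fraction = 0.3,
                       family = "richards",
                       pop_coefficients = NULL,
                       deviation_basis = c("legendre", "curve"),
                       deviation_order = 2L,
                       ld_block_length = 20, ld_copy_prob = 0.8,
                       n_chromosomes = 5, scale = c("trajectory", "raw"),
                       seed = 1L) {
  family <- match.arg(family, setdiff(GROWTH_FAMILIES, "legendre"))
  if (is.null(pop_coefficients))
    pop_coefficients <- switch(family,
      richards = c(a = 21.4, b = 0.95, r = 0.23, k = 1.5),
      bertalanffy = c(a = 21.4, b = 0.95, r = 0.23),
      gompertz = c(a = 21.4, b = 1.2, r = 0.23),
      logistic = c(a = 21.4, b = 3.0, r = 0.3))
  h2 <- regression_heritability
  if (h2 <= 0 || h2 >= 1) stop("heritability must lie in (0, 1)")
  if (pe_variance <= 0 || residual_variance <= 0) stop("variances must be > 0")
  if (n_qtls > n_markers) stop("n_qtls cannot exceed n_markers")
  if (qtl_variance_fraction < 0 || qtl_variance_fraction > 1)
    stop("qtl_variance_fraction must lie in [0, 1]")
  structure(list(
    n_individuals = n_individuals, n_markers = n_markers, n_qtls = n_qtls,
    times = times, regression_heritability = h2, pe_variance = pe_variance,
    effect_correlation = effect_correlation,
    residual_variance = residual_variance,
    qtl_variance_fraction = qtl_variance_fraction,
    family = family, pop_coefficients = pop_coefficients,
    deviation_basis = match.arg(deviation_basis),
    deviation_order = as.integer(deviation_order),
    ld_block_length = ld_block_length, ld_copy_prob = ld_copy_prob,
    n_chromosomes = n_chromosomes, scale = match.arg(scale),
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate an LD-structured SNP panel
#'
#' Haplotypes follow a first-order Markov copying model inside blocks of
#' \code{ld_block_length} markers: each allele copies its left neighbour
#' with probability \code{ld_copy_prob} and is otherwise drawn fresh at the
#' marker's allele frequency (Uniform(0.05, 0.5)). Blocks and chromosomes
#' are independent; positions are evenly spaced along each chromosome.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{genotype_matrix}.
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_individuals; m <- config$n_markers
  freq <- stats::runif(m, 0.05, 0.5)
  chr <- rep(seq_len(config$n_chromosomes), length.out = m)
  chr <- sort(chr)
  within <- stats::ave(seq_len(m), chr, FUN = seq_along)
  new_block <- within == 1L | ((within - 1L) %% config$ld_block_length) == 0L
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    f1 <- stats::rbinom(n, 1L, freq[j]); f2 <- stats::rbinom(n, 1L, freq[j])
    if (new_block[j]) {
      H1[, j] <- f1; H2[, j] <- f2
    } else {
      c1 <- stats::rbinom(n, 1L, config$ld_copy_prob)
      c2 <- stats::rbinom(n, 1L, config$ld_copy_prob)
      H1[, j] <- ifelse(c1 == 1L, H1[, j - 1L], f1)
      H2[, j] <- ifelse(c2 == 1L, H2[, j - 1L], f2)
    }
  }
  G <- H1 + H2
  rownames(G) <- sprintf("ind%04d", seq_len(n))
  markers <- data.frame(
    chr = as.character(chr),
    id = sprintf("snp%05d", seq_len(m)),
    pos = as.integer(within * 10000L),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  genotype_matrix(G, markers)
}

## RMS sensitivity of the trajectory to each curve parameter at the
## population coefficients (numerical derivative over the time grid)
trajectory_sensitivity <- function(family, pop, times) {
  d <- length(pop)
  vapply(seq_len(d), function(j) {
    h <- 1e-6 * max(abs(pop[j]), 1e-3)
    up <- pop; up[j] <- up[j] + h
    dn <- pop; dn[j] <- dn[j] - h
    g <- (eval_family(family, up, times) - eval_family(family, dn, times)) /
      (2 * h)
    sqrt(mean(g^2))
  }, 0)
}

## vectorized family evaluation without growth_params validation (used on
## simulated parameter matrices, where extreme draws must still evaluate)
eval_family <- function(family, cf, t) {
  a <- cf[1]; b <- cf[2]; r <- cf[3]
  switch(family,
    richards = {
      base <- 1 + b * exp(-r * t)
      a * base^(1 / (1 - cf[4]))
    },
    bertalanffy = a * (1 - b * exp(-r * t)),
    gompertz = a * exp(-b * exp(-r * t)),
    logistic = a / (1 + b * exp(-r * t)))
}

## TRUE when the parameter vector yields a finite, biologically plausible
## trajectory: the curve must stay inside a generous envelope around the
## population curve (10x its largest absolute value), which also rejects
## Richards curves whose base term approaches zero
params_valid <- function(family, cf, t, y_max = Inf) {
  if (cf[1] <= 0) return(FALSE)
  if (family == "richards") {
    if (abs(cf[4] - 1) < 1e-3) return(FALSE)
    if (any(1 + cf[2] * exp(-cf[3] * t) <= 0)) return(FALSE)
  }
  y <- eval_family(family, cf, t)
  all(is.finite(y)) && max(abs(y)) <= y_max
}

#' Simulate QTL effects, curve parameters and longitudinal phenotypes
#'
#' Places \code{n_qtls} QTLs uniformly among the markers, draws their
#' per-parameter effects from a multivariate normal with the configured
#' correlation and rescales them so that the QTLs jointly explain
#' \code{qtl_variance_fraction} of the genetic variance; completes the
#' genetic deviations with a polygenic term drawn matrix-normal against the
#' realized genomic relationship matrix and adds permanent-environmental
#' deviations. Each individual's trajectory is its population curve shifted
#' by its deviations, observed at the time grid with Gaussian error.
#'
#' Deviations that would push an individual's Richards curve out of its
#' domain (non-positive base) are halved until valid; the affected count is
#' reported as an attribute.
#'
#' @param geno A \code{genotype_matrix} from \code{\link{simulate_genotypes}}.
#' @param config The same \code{\link{sim_config}}.
#' @return A \code{"sim_dataset"}: list with \code{genotypes}, \code{pheno}
#'   (long-format data frame), \code{P_true} (true parameter matrix),
#'   \code{qtl_indices}, \code{qtl_effects} (raw scale), \code{Vg}, \code{Vpe}
#'   (normalized units), \code{param_scale} (per-parameter unit), and
#'   \code{config}.
#' @export
simulate_effects_and_phenotypes <- function(geno, config) {
  set.seed(config$seed + 999983L)
  G <- geno$matrix
  n <- nrow(G); m <- ncol(G)
  pop <- config$pop_coefficients
  times <- config$times
  legendre_dev <- config$deviation_basis == "legendre"
  d <- if (legendre_dev) config$deviation_order + 1L else length(pop)
  rho <- config$effect_correlation
  C <- matrix(rho, d, d); diag(C) <- 1
  h2 <- config$regression_heritability
  sg2 <- config$pe_variance * h2 / (1 - h2)   # genetic variance per parameter
  Vg <- sg2 * C; Vpe <- config$pe_variance * C
  if (config$qtl_variance_fraction > 1)
    stop("QTL variance exceeds the total genetic variance")
  s_unit <- if (!legendre_dev && config$scale == "trajectory")
    1 / trajectory_sensitivity(config$family, pop, times)
  else rep(1, d)

  cg <- center_genotypes(G)
  qtl <- sort(sample.int(m, config$n_qtls))
  Rc <- chol(C)
  A <- matrix(stats::rnorm(config$n_qtls * d), nrow = config$n_qtls,
              ncol = d) %*% Rc
  Q <- cg$Z[, qtl, drop = FALSE] %*% A
  f <- config$qtl_variance_fraction
  if (config$n_qtls > 0 && f > 0) {
    sc <- sqrt(f * sg2 / mean(apply(Q, 2, stats::var)))
    A <- A * sc; Q <- Q * sc
  } else {
    A <- A * 0; Q <- Q * 0
  }
  ## polygenic completion of the genetic covariance against the GRM
  kin <- compute_grm(filter_markers(geno, maf_min = 1e-6, missing_max = 1))
  Vres <- Vg - stats::cov(Q)
  er <- eigen((Vres + t(Vres)) / 2, symmetric = TRUE)
  Rres <- diag(sqrt(pmax(er$values, 0)), d) %*% t(er$vectors)
  Lk <- kin$vectors %*% diag(sqrt(kin$values), n)
  Upoly <- Lk %*% matrix(stats::rnorm(n * d), n) %*% Rres
  Ugen <- Q + Upoly
  Upe <- matrix(stats::rnorm(n * d), n) %*% (sqrt(config$pe_variance) * Rc)

  n_shrunk <- 0L
  if (legendre_dev) {
    ## deviations enter the trajectory through the normalized Legendre
    ## basis; the true regression phenotypes are the basis coefficients
    P_true <- Ugen + Upe
    colnames(P_true) <- paste0("c", seq_len(d) - 1L)
    rownames(P_true) <- rownames(G)
    Phi <- legendre_basis(times, config$deviation_order, range(times))
    pop_traj <- eval_family(config$family, pop, times)
    Y <- matrix(pop_traj, n, length(times), byrow = TRUE) +
      P_true %*% t(Phi)
  } else {
    dev <- sweep(Ugen + Upe, 2, s_unit, "*")
    P_true <- sweep(dev, 2, pop, "+")
    y_max <- 10 * max(abs(eval_family(config$family, pop, times)))
    for (i in seq_len(n)) {
      k <- 0L
      while (!params_valid(config$family, P_true[i, ], times, y_max) &&
             k < 12L) {
        dev[i, ] <- dev[i, ] / 2
        P_true[i, ] <- pop + dev[i, ]
        k <- k + 1L
      }
      if (k > 0L) n_shrunk <- n_shrunk + 1L
    }
    colnames(P_true) <- names(pop)
    rownames(P_true) <- rownames(G)
    Y <- t(apply(P_true, 1,
                 function(cf) eval_family(config$family, cf, times)))
  }
  Y <- Y + stats::rnorm(length(Y), 0, sqrt(config$residual_variance))
  pheno <- data.frame(
    id = rep(rownames(G), each = length(times)),
    time = rep(times, n),
    value = as.vector(t(Y)), stringsAsFactors = FALSE)

  eff_raw <- sweep(A, 2, s_unit, "*")
  colnames(eff_raw) <- colnames(P_true)
  structure(list(genotypes = geno, pheno = pheno, P_true = P_true,
                 qtl_indices = qtl, qtl_effects = eff_raw,
                 Vg = Vg, Vpe = Vpe, param_scale = s_unit,
                 u_genetic = Ugen, u_pe = Upe,
                 n_shrunk = n_shrunk, config = config),
            class = "sim_dataset")
}

#' Simulate a complete longitudinal GWAS dataset
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{sim_dataset} (see
#'   \code{\link{simulate_effects_and_phenotypes}}).
#' @export
simulate_dataset <- function(config) {
  simulate_effects_and_phenotypes(simulate_genotypes(config), config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset: %d individuals x %d markers, %d QTL(s), %s curve, seed %d>\n",
              nrow(x$P_true), ncol(x$genotypes$matrix),
              length(x$qtl_indices), x$config$family, x$config$seed))
  invisible(x)
}

#' Call QTLs from a genome scan
#'
#' A marker is called a QTL when its -log10(p) exceeds the threshold and its
#' summed chi-square is the largest among its \code{window} closest
#' positional neighbours (half on each side, truncated at chromosome ends);
#' on a plateau of tied statistics only the leftmost marker is called.
#'
#' @param scan A \code{\link{hirrm_scan}} result (markers in genome order).
#' @param window Neighbourhood size (default 20).
#' @param threshold -log10(p) threshold; defaults to the scan's Bonferroni
#'   bound.
#' @return Integer vector of called marker indices (rows of
#'   \code{scan$records}).
#' @export
call_qtls <- function(scan, window = 20, threshold = scan$threshold_neglog10) {
  r <- scan$records
  sig <- which(r$neglog10_p > threshold)
  half <- window %/% 2
  called <- integer(0)
  for (i in sig) {
    nb <- neighbour_window(r$chr, i, half)
    if (length(nb) == 0) { called <- c(called, i); next }
    stat <- r$chi2_sum
    if (any(stat[nb] > stat[i])) next
    left_tie <- nb[nb < i & stat[nb] == stat[i]]
    if (length(left_tie) == 0) called <- c(called, i)
  }
  called
}

neighbour_window <- function(chr, i, half) {
  j <- seq(max(1, i - half), min(length(chr), i + half))
  j <- j[chr[j] == chr[i]]
  setdiff(j, i)
}

#' Power and type-I error over a threshold grid
#'
#' A simulated QTL counts as identified when a called marker falls inside
#' its neighbour window; the type-I error is the fraction of markers outside
#' every QTL window that are called.
#'
#' @param dataset A \code{sim_dataset} (the truth).
#' @param scan The \code{\link{hirrm_scan}} of that dataset.
#' @param thresholds Vector of -log10(p) thresholds; defaults to the scan's
#'   Bonferroni bound.
#' @param window Neighbourhood size used both for calling and matching.
#' @return Data frame with columns \code{threshold}, \code{power},
#'   \code{fpr}, \code{n_called}.
#' @export
evaluate_power_roc <- function(dataset, scan,
                               thresholds = scan$threshold_neglog10,
                               window = 20) {
  r <- scan$records
  half <- window %/% 2
  qtl <- dataset$qtl_indices
  windows <- lapply(qtl, function(q)
    c(q, neighbour_window(r$chr, q, half)))
  in_window <- sort(unique(unlist(windows)))
  n_null <- nrow(r) - length(in_window)
  out <- lapply(thresholds, function(th) {
    called <- call_qtls(scan, window = window, threshold = th)
    hit <- vapply(windows, function(w) any(called %in% w), TRUE)
    fp <- sum(!(called %in% in_window))
    data.frame(threshold = th,
               power = if (length(qtl)) mean(hit) else NA_real_,
               fpr = if (n_null > 0) fp / n_null else NA_real_,
               n_called = length(called))
  })
  do.call(rbind, out)
}
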