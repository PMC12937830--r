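# shared fixture builders; everything is generated in code at test time

toy_genotypes <- function(n, m, seed = 1, maf = c(0.1, 0.5), chr = "1") {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(G) <- sprintf("i%03d", seq_len(n))
  genotype_matrix(G, data.frame(chr = chr, id = sprintf("s%04d", seq_len(m)),
                                pos = seq_len(m) * 1000L,
                                stringsAsFactors = FALSE))
}

toy_kinship <- function(n, m = 200, seed = 1) {
  compute_grm(filter_markers(toy_genotypes(n, m, seed = seed),
                             maf_min = 0.02, missing_max = 1))
}

# random positive-definite matrix
rand_pd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(0.2, d)
}

# matrix-normal phenotypes P = 1 mu' + G + E with G ~ MN(0, Vg, K),
# E ~ MN(0, Vpe, I)
draw_mvlmm <- function(kin, Vg, Vpe, mu = NULL) {
  n <- nrow(kin$matrix); d <- ncol(Vg)
  if (is.null(mu)) mu <- rep(0, d)
  Lk <- kin$vectors %*% diag(sqrt(kin$values), n)
  P <- Lk %*% matrix(rnorm(n * d), n) %*% chol(Vg) +
    matrix(rnorm(n * d), n) %*% chol(Vpe)
  P <- sweep(P, 2, mu, "+")
  rownames(P) <- kin$ids
  P
}
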