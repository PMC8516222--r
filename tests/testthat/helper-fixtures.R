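# Shared fixtures and independent oracles. Oracles deliberately use naive
# dense algebra (solve/determinant/double loops) so they stay independent of
# the package's optimized code paths.

# dense full-inversion GLS oracle: beta and var for X1 = [X, x_snp, x_inter]
oracle_gls <- function(y, X1, V) {
  Vi <- solve(V)
  A <- t(X1) %*% Vi %*% X1
  Ainv <- solve(A)
  beta <- Ainv %*% t(X1) %*% Vi %*% y
  list(beta = as.vector(beta), var = Ainv)
}

# direct dense restricted log-likelihood (determinants + inverses)
oracle_reml_ll <- function(theta, y, X, G, exposed = NULL) {
  n <- length(y)
  V <- theta[["g"]] * G + diag(theta[["e"]], n)
  if ("ghs" %in% names(theta)) {
    V <- V + theta[["ghs"]] * (G * tcrossprod(as.numeric(exposed)))
  }
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(A) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(A)$modulus +
                       t(y) %*% P %*% y))
}

# brute-force double-loop VanRaden GRM
oracle_grm <- function(doses) {
  n <- nrow(doses)
  p <- colMeans(doses) / 2
  M <- sweep(doses, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- sum(M[i, ] * M[j, ]) / denom
  }
  G
}

# small complete synthetic dataset built through the public generator
make_small_dataset <- function(n = 200, m = 300, seed = 1,
                               vc = c(g = 0.3, ghs = 0.1, e = 0.6),
                               prevalence = 0.5, week = 1,
                               missing_rate = 0, g_method = "eigen",
                               causal = NULL) {
  cfg <- sim_config(n_animals = n, n_snps = m, n_chromosomes = 5,
                    missing_rate = missing_rate,
                    variance_components = vc, causal_spec = causal,
                    hs_target_prevalence = prevalence, seed = seed)
  markers <- simulate_markers(cfg)
  geno <- simulate_genotypes(cfg, markers)
  if (missing_rate > 0) geno <- mean_impute(geno)
  grm <- vanraden_grm(geno)
  exposure <- simulate_exposure_flags(cfg, geno$animal_ids, weeks = week)
  ph <- simulate_phenotypes(geno, grm, exposure, week, cfg,
                            g_method = g_method)
  list(cfg = cfg, geno = geno, grm = grm, exposure = exposure,
       y = ph$phenotypes$y, truth = ph$truth,
       exposed = ph$truth$exposed,
       X = cbind(`(Intercept)` = 1, hs = as.numeric(ph$truth$exposed)))
}

# the QC toy matrix: 10 animals x 6 markers with one non-autosomal marker,
# one marker failing the strict MAF rule and one all-heterozygous marker
make_qc_toy <- function() {
  good1 <- c(0, 1, 1, 2, 0, 1, 2, 1, 0, 2) # p = 0.5, near HWE
  good2 <- c(0, 0, 1, 1, 0, 1, 0, 1, 2, 0) # p = 0.3
  good3 <- c(2, 2, 1, 2, 2, 1, 2, 1, 2, 2) # p high but MAF 0.25... see below
  nonauto <- c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1) # chromosome 30 (not an autosome)
  lowmaf <- rep(0, 10)                       # monomorphic: MAF 0 <= 0.01
  allhet <- rep(1, 10)                       # H_obs 1, expected 0.5
  doses <- cbind(good1, good2, good3, nonauto, lowmaf, allhet)
  map <- data.frame(
    snp_id = c("g1", "g2", "g3", "x1", "m1", "h1"),
    chr = c(1L, 1L, 2L, 30L, 2L, 3L),
    pos_bp = c(100L, 200L, 100L, 100L, 300L, 100L))
  genotype_matrix(doses, map, animal_ids = sprintf("A%02d", 1:10))
}

# random positive-definite covariance with unit-scale diagonal
random_psd <- function(n, seed) {
  set.seed(seed)
  B <- matrix(rnorm(n * n), n)
  V <- crossprod(B) / n + diag(n) * 0.5
  V
}
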