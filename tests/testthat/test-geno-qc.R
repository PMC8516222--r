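# genotype QC, imputation, VanRaden GRM, relationship pruning

test_that("allele_frequency and hwe_het_deviation on hand-counted columns", {
  expect_equal(allele_frequency(c(0, 1, 1, 2, 2, 2)), 8 / 12)
  expect_equal(allele_frequency(rep(2, 5)), 1)
  expect_equal(allele_frequency(c(1, 1, 1, 1)), 0.5)
  expect_equal(allele_frequency(c(0, NA, 2)), 0.5) # missing excluded
  expect_error(allele_frequency(c(NA, NA)), "missing")

  expect_equal(hwe_het_deviation(rep(1, 100)), 0.5) # all het, p = 0.5
  expect_equal(hwe_het_deviation(c(rep(0, 25), rep(1, 50), rep(2, 25))), 0)
  expect_equal(hwe_het_deviation(rep(0, 10)), 0) # monomorphic
})

test_that("call_rates computes row and column non-missing fractions", {
  toy <- make_qc_toy()
  cr <- call_rates(toy)
  expect_true(all(cr$marker == 1) && all(cr$animal == 1))
  doses <- toy$doses
  doses[1, 2] <- NA
  toy2 <- genotype_matrix(doses, toy$map, toy$animal_ids)
  cr2 <- call_rates(toy2)
  expect_equal(cr2$marker[[2]], 0.9)
  expect_equal(cr2$animal[[1]], 5 / 6)
})

test_that("apply_qc removes exactly the three bad toy markers, each by its rule", {
  res <- apply_qc(make_qc_toy())
  expect_equal(ncol(res$genotypes$doses), 3)
  expect_setequal(colnames(res$genotypes$doses), c("g1", "g2", "g3"))
  expect_equal(res$report$removed$non_autosomal, "x1")
  expect_equal(res$report$removed$maf, "m1")
  expect_equal(res$report$removed$hwe, "h1")
  expect_equal(sum(res$report$n_removed), 3)
  # idempotence: QC of a QC-passing matrix is the identity
  res2 <- apply_qc(res$genotypes)
  expect_equal(res2$genotypes$doses, res$genotypes$doses)
  expect_equal(sum(res2$report$n_removed), 0)
})

test_that("QC boundaries: call rate 0.95 inclusive, MAF 0.01 strict", {
  set.seed(42)
  doses <- matrix(rbinom(100 * 3, 2, 0.4), 100, 3)
  doses[1:5, 1] <- NA  # call rate 0.95: kept
  doses[1:6, 2] <- NA  # call rate 0.94: removed
  map <- data.frame(snp_id = c("a", "b", "c"), chr = 1L, pos_bp = 1:3 * 100L)
  res <- apply_qc(genotype_matrix(doses, map))
  expect_equal(res$report$removed$marker_call_rate, "b")
  expect_true("a" %in% colnames(res$genotypes$doses))
  # MAF exactly 0.01 is removed ("larger than 0.01" is strict)
  doses2 <- cbind(c(1, rep(0, 49)), rbinom(50, 2, 0.5)) # p = 0.01 exactly
  map2 <- data.frame(snp_id = c("edge", "ok"), chr = 1L, pos_bp = c(10L, 20L))
  res2 <- apply_qc(genotype_matrix(doses2, map2))
  expect_equal(res2$report$removed$maf, "edge")
})

test_that("mean_impute fills 2p and preserves column means", {
  set.seed(3)
  doses <- matrix(rbinom(40 * 8, 2, 0.3), 40, 8)
  map <- data.frame(snp_id = paste0("s", 1:8), chr = 1L,
                    pos_bp = 1:8 * 100L)
  doses[2, 3] <- NA
  geno <- genotype_matrix(doses, map)
  p3 <- allele_frequency(doses[, 3])
  imp <- mean_impute(geno)
  expect_equal(imp$doses[2, 3], 2 * p3)
  expect_equal(colMeans(imp$doses), colMeans(doses, na.rm = TRUE),
               ignore_attr = TRUE)
  # no missingness: identity
  full <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2),
                          data.frame(snp_id = c("a", "b"), chr = 1L,
                                     pos_bp = c(1L, 2L)))
  expect_identical(mean_impute(full)$doses, full$doses)
})

test_that("vanraden_grm: 2-animal hand case and double-loop oracle", {
  g <- genotype_matrix(matrix(c(0, 2), 2, 1),
                       data.frame(snp_id = "s", chr = 1L, pos_bp = 1L))
  G <- vanraden_grm(g)
  expect_equal(G$values, matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  expect_equal(G$denominator, 0.5)

  set.seed(9)
  for (dims in list(c(8, 20), c(20, 50))) {
    doses <- matrix(rbinom(dims[1] * dims[2], 2, runif(dims[2], 0.1, 0.5)),
                    dims[1], dims[2], byrow = TRUE)
    map <- data.frame(snp_id = paste0("s", seq_len(dims[2])), chr = 1L,
                      pos_bp = seq_len(dims[2]))
    G <- vanraden_grm(genotype_matrix(doses, map))$values
    expect_lt(max(abs(G - oracle_grm(doses))), 1e-10)
    expect_equal(G, t(G))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  mono <- genotype_matrix(matrix(2, 3, 1),
                          data.frame(snp_id = "s", chr = 1L, pos_bp = 1L))
  expect_error(vanraden_grm(mono), "monomorphic")
})

test_that("GRM diagonal is near 1 and off-diagonal near 0 under HWE", {
  cfg <- sim_config(n_animals = 500, n_snps = 10000, n_chromosomes = 10,
                    missing_rate = 0, seed = 21)
  geno <- simulate_genotypes(cfg, simulate_markers(cfg))
  G <- vanraden_grm(geno)$values
  expect_gt(mean(diag(G)), 0.98)
  expect_lt(mean(diag(G)), 1.02)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.01)
})

test_that("prune_related removes duplicates deterministically", {
  set.seed(14)
  n <- 30
  doses <- matrix(rbinom(n * 400, 2, 0.4), n, 400)
  doses[2, ] <- doses[1, ] # duplicate pair
  map <- data.frame(snp_id = paste0("s", 1:400), chr = 1L, pos_bp = 1:400)
  grm <- vanraden_grm(genotype_matrix(doses, map,
                                      sprintf("A%02d", 1:n)))
  # the duplicate pair's relationship equals the shared diagonal (~1 with
  # sampling noise at m = 400); test the rule with a cutoff well between
  # duplicate (~0.9) and unrelated (~0.2) levels
  expect_gt(grm$values[1, 2], 0.8)
  kept <- prune_related(grm, cutoff = 0.8)
  expect_length(kept, n - 1)
  expect_true("A01" %in% kept) # larger-id member of the pair removed
  expect_false("A02" %in% kept)
  # triple duplicate: one survivor
  doses3 <- doses
  doses3[3, ] <- doses3[1, ]
  grm3 <- vanraden_grm(genotype_matrix(doses3, map, sprintf("A%02d", 1:n)))
  kept3 <- prune_related(grm3, cutoff = 0.8)
  expect_length(kept3, n - 2)
  expect_equal(sum(c("A01", "A02", "A03") %in% kept3), 1)
  expect_true("A01" %in% kept3) # ties resolved against larger ids
  # nothing above cutoff: all retained
  grm_ok <- vanraden_grm(genotype_matrix(
    matrix(rbinom(n * 500, 2, 0.4), n, 500),
    data.frame(snp_id = paste0("q", 1:500), chr = 1L, pos_bp = 1:500),
    sprintf("A%02d", 1:n)))
  expect_length(prune_related(grm_ok), n)
})

test_that("subset_grm is a principal submatrix and PSD", {
  d <- make_small_dataset(n = 30, m = 100, seed = 4)
  ids <- d$grm$animal_ids
  sub <- subset_grm(d$grm, ids[c(3, 7, 11)])
  expect_equal(sub$values, d$grm$values[c(3, 7, 11), c(3, 7, 11)],
               ignore_attr = TRUE)
  expect_equal(sub$kind, "G_hs")
  expect_gte(min(eigen(sub$values, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  # full subset reproduces G; singleton gives the diagonal entry
  expect_equal(subset_grm(d$grm, ids)$values, d$grm$values)
  expect_equal(subset_grm(d$grm, ids[5])$values,
               d$grm$values[5, 5, drop = FALSE])
  expect_error(subset_grm(d$grm, character(0)), "empty")
})
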