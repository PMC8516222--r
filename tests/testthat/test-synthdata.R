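# synthetic-data generator: determinism, marginal laws, generative structure

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_animals = 1), "n_animals")
  expect_error(sim_config(maf_range = c(0, 0.5)))
  expect_error(sim_config(variance_components = c(g = 0.1, ghs = 0, e = 0)))
  expect_error(sim_config(date_range = as.Date(c("2015-01-01", "2010-01-01"))),
               "date range")
})

test_that("simulate_markers: sorted positions, degenerate maf interval, determinism", {
  cfg <- sim_config(n_animals = 10, n_snps = 10, n_chromosomes = 2, seed = 2)
  mk <- simulate_markers(cfg)
  expect_equal(nrow(mk), 10)
  expect_setequal(unique(mk$chr), 1:2)
  for (ch in 1:2) {
    expect_true(all(diff(mk$pos_bp[mk$chr == ch]) > 0))
  }
  expect_identical(mk, simulate_markers(cfg))
  cfg3 <- sim_config(n_animals = 10, n_snps = 25, maf_range = c(0.3, 0.3),
                     seed = 2)
  expect_true(all(simulate_markers(cfg3)$true_p == 0.3))
})

test_that("simulate_genotypes: codomain, missingness, frequency convergence", {
  cfg <- sim_config(n_animals = 50, n_snps = 40, missing_rate = 0, seed = 3)
  geno <- simulate_genotypes(cfg, simulate_markers(cfg))
  expect_true(all(geno$doses %in% c(0, 1, 2)))
  expect_identical(geno$doses,
                   simulate_genotypes(cfg, simulate_markers(cfg))$doses)

  cfg_m <- sim_config(n_animals = 200, n_snps = 50, missing_rate = 0.1,
                      seed = 3)
  geno_m <- simulate_genotypes(cfg_m, simulate_markers(cfg_m))
  expect_gt(mean(is.na(geno_m$doses)), 0.07)
  expect_lt(mean(is.na(geno_m$doses)), 0.13)

  # n = 10,000 at true p = 0.3: empirical frequency within +/- 0.02
  cfg_big <- sim_config(n_animals = 10000, n_snps = 5, missing_rate = 0,
                        maf_range = c(0.3, 0.3), seed = 4)
  geno_big <- simulate_genotypes(cfg_big, simulate_markers(cfg_big))
  p_hat <- allele_frequencies(geno_big)
  expect_true(all(abs(p_hat - 0.3) < 0.02))
  # Hardy-Weinberg heterozygosity: H -> 2 p (1 - p)
  het <- colMeans(geno_big$doses == 1)
  expect_true(all(abs(het - 2 * 0.3 * 0.7) < 0.02))
})

test_that("simulate_weather: clamping, seasonality and target prevalence", {
  cfg <- sim_config(n_animals = 10, n_snps = 10, n_stations = 2,
                    date_range = as.Date(c("2011-01-01", "2012-12-31")),
                    hs_target_prevalence = 0.16, seed = 6)
  w <- simulate_weather(cfg)
  expect_true(all(w$rh_pct >= 0 & w$rh_pct <= 100))
  expect_identical(w$temp_c, simulate_weather(cfg)$temp_c)
  # zero noise: exact sum of the two sinusoids (up to station offset)
  w0 <- simulate_weather(cfg, noise_sd = 0)
  one <- w0[w0$station_id == "S001" & as.Date(w0$timestamp) == "2011-06-15", ]
  hours <- as.numeric(strftime(one$timestamp, "%H", tz = "UTC"))
  resid <- one$temp_c - 4 * cos(2 * pi * (hours - 14) / 24)
  expect_lt(diff(range(resid)), 0.05) # seasonal part ~constant within a day
  # weekly THI spans both sides of 60 and hits the target prevalence
  daily <- daily_thi(w)
  d1 <- daily[daily$station_id == "S001", ]
  wk <- vapply(seq(8, nrow(d1) - 7, by = 7),
               function(i) mean(d1$thi[i:(i + 6)]), 0)
  expect_gt(max(wk), 60)
  expect_lt(min(wk), 60)
  frac <- mean(wk >= 60)
  expect_lt(abs(frac - cfg$hs_target_prevalence), 0.1)
})

test_that("simulate_population conserves herd sizes and is deterministic", {
  cfg <- sim_config(n_animals = 120, n_snps = 10, n_herds = 4,
                    n_stations = 3, seed = 8)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$animals), 120)
  expect_true(all(pop$animals$herd_id %in% pop$herds$herd_id))
  expect_equal(sum(table(pop$animals$herd_id)), 120)
  bb <- cfg$bounding_box
  expect_true(all(pop$herds$lat >= bb$lat[1] & pop$herds$lat <= bb$lat[2]))
  expect_identical(pop, simulate_population(cfg))
  cfg1 <- sim_config(n_animals = 15, n_snps = 10, n_herds = 1, seed = 8)
  expect_equal(unique(simulate_population(cfg1)$animals$herd_id), "H001")
})

test_that("psd_sqrt factors PSD matrices and rejects indefinite ones", {
  set.seed(11)
  B <- matrix(rnorm(25), 5)
  A <- crossprod(B)
  L <- psd_sqrt(A)
  expect_equal(L %*% t(L), A, tolerance = 1e-10)
  expect_error(psd_sqrt(diag(c(1, -1))), "positive semi-definite")
})

test_that("simulate_phenotypes: zero-variance degenerate case and determinism", {
  cfg0 <- sim_config(n_animals = 40, n_snps = 60, missing_rate = 0,
                     variance_components = c(g = 0, ghs = 0, e = 1e-12),
                     fixed_effect_spec = list(), seed = 12,
                     hs_target_prevalence = 0.5)
  # note: sigma2_e must be > 0 by config contract; 1e-12 makes y ~ 0
  mk <- simulate_markers(cfg0)
  geno <- simulate_genotypes(cfg0, mk)
  grm <- vanraden_grm(geno)
  ex <- simulate_exposure_flags(cfg0, geno$animal_ids, weeks = 1)
  ph <- simulate_phenotypes(geno, grm, ex, 1, cfg0)
  expect_lt(max(abs(ph$phenotypes$y)), 1e-4)
  ph2 <- simulate_phenotypes(geno, grm, ex, 1, cfg0)
  expect_identical(ph$phenotypes$y, ph2$phenotypes$y)
})

test_that("polygenic variance matches mean(diag(G)) * sigma2_g across replicates", {
  # law of total variance under the generator, checked by Monte Carlo
  cfg <- sim_config(n_animals = 500, n_snps = 800, missing_rate = 0,
                    variance_components = c(g = 1, ghs = 0, e = 1e-12),
                    fixed_effect_spec = list(), hs_target_prevalence = 0.5,
                    seed = 13)
  geno <- simulate_genotypes(cfg, simulate_markers(cfg))
  grm <- vanraden_grm(geno)
  ex <- simulate_exposure_flags(cfg, geno$animal_ids, weeks = 1)
  vars <- vapply(1:200, function(r) {
    cfg_r <- cfg
    cfg_r$seed <- 1000L + r
    ph <- simulate_phenotypes(geno, grm, ex, 1, cfg_r, g_method = "marker")
    mean(ph$truth$g^2)
  }, 0)
  expect_lt(abs(mean(vars) / mean(diag(grm$values)) - 1), 0.1)
})

test_that("with sigma2_ghs = 0 exposed and unexposed phenotypes agree in law", {
  cfg <- sim_config(n_animals = 300, n_snps = 300, missing_rate = 0,
                    variance_components = c(g = 0.3, ghs = 0, e = 0.7),
                    fixed_effect_spec = list(), hs_target_prevalence = 0.5,
                    seed = 14)
  geno <- simulate_genotypes(cfg, simulate_markers(cfg))
  grm <- vanraden_grm(geno)
  ex <- simulate_exposure_flags(cfg, geno$animal_ids, weeks = 1)
  pvals <- vapply(1:50, function(r) {
    cfg_r <- cfg
    cfg_r$seed <- 2000L + r
    ph <- simulate_phenotypes(geno, grm, ex, 1, cfg_r, g_method = "marker")
    stats::ks.test(ph$phenotypes$y[ph$truth$exposed],
                   ph$phenotypes$y[!ph$truth$exposed])$p.value
  }, 0)
  # pooled uniformity check at alpha = 0.01: Fisher combination
  fisher <- -2 * sum(log(pvals))
  expect_gt(stats::pchisq(fisher, df = 2 * length(pvals),
                          lower.tail = FALSE), 0.01)
})

test_that("causal_spec markers contribute their fixed substitution effects", {
  causal <- data.frame(marker = 5L, beta_main = 2, beta_inter = 1)
  cfg <- sim_config(n_animals = 150, n_snps = 50, missing_rate = 0,
                    variance_components = c(g = 0, ghs = 0, e = 1e-12),
                    causal_spec = causal, fixed_effect_spec = list(),
                    hs_target_prevalence = 0.5, seed = 15)
  geno <- simulate_genotypes(cfg, simulate_markers(cfg))
  grm <- vanraden_grm(geno)
  ex <- simulate_exposure_flags(cfg, geno$animal_ids, weeks = 1)
  ph <- simulate_phenotypes(geno, grm, ex, 1, cfg)
  p5 <- allele_frequency(geno$doses[, 5])
  cols <- snp_columns(geno$doses[, 5], p5, ph$truth$exposed)
  expect_equal(ph$phenotypes$y, 2 * cols$x_snp + 1 * cols$x_inter,
               tolerance = 1e-4, ignore_attr = TRUE)
})
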