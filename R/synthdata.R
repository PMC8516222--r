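# Synthetic-data generator: genotypes, herd/station geography, seasonal
# hourly weather, in-utero heat-stress exposures and phenotypes with the
# statistical structure the downstream analysis assumes, so the whole
# pipeline is testable with known ground truth and no external download.

# evaluate expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults emulate the study system this package targets: a German
#' Holstein population of 14,188 genotyped cows in 53 large herds served by
#' 32 weather stations, 41,139 autosomal SNPs on 29 chromosomes, calving
#' years 2010-2015, and weekly THI whose exceedance of the heat-stress
#' threshold (60) has probability about 0.16 (a normal tail estimate from a
#' weekly THI mean near 48 and SD near 12). Tests and examples pass smaller
#' sizes explicitly.
#'
#' @param n_animals,n_snps,n_chromosomes,n_herds,n_stations Counts.
#' @param maf_range Interval in (0, 0.5] for true allele frequencies.
#' @param missing_rate Per-entry genotype missingness probability.
#' @param bounding_box List with `lat` and `lon` ranges (decimal degrees).
#' @param date_range Two dates bounding birth dates.
#' @param variance_components Named vector `c(g=, ghs=, e=)`.
#' @param causal_spec Data frame `marker`, `beta_main`, `beta_inter` of
#'   explicit causal markers (default none).
#' @param fixed_effect_spec Named list; each element
#'   `list(n_levels=, effect_sd=)`.
#' @param hs_target_prevalence Target fraction of animal-weeks with
#'   THI >= 60.
#' @param seed Integer master seed; identical configurations produce
#'   bit-identical data.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_animals = 14188, n_snps = 41139, n_chromosomes = 29,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       n_herds = 53, n_stations = 32,
                       bounding_box = list(lat = c(51.3, 54.7),
                                           lon = c(11.2, 14.8)),
                       date_range = as.Date(c("2010-01-01", "2015-12-31")),
                       variance_components = c(g = 0.3, ghs = 0.05, e = 0.65),
                       causal_spec = NULL,
                       fixed_effect_spec = list(
                         calving_year = list(n_levels = 6, effect_sd = 0.1),
                         calving_month = list(n_levels = 12, effect_sd = 0.1)),
                       hs_target_prevalence = 0.16,
                       seed = 1L) {
  stopifnot(n_animals >= 2, n_snps >= 1, n_chromosomes >= 1,
            n_herds >= 1, n_stations >= 1)
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  stopifnot(missing_rate >= 0, missing_rate < 1)
  vc <- variance_components
  stopifnot(all(c("g", "ghs", "e") %in% names(vc)), all(vc >= 0), vc[["e"]] > 0)
  date_range <- as.Date(date_range)
  if (diff(as.numeric(date_range)) < 0) stop("empty date range")
  stopifnot(hs_target_prevalence > 0, hs_target_prevalence < 1)
  structure(list(n_animals = n_animals, n_snps = n_snps,
                 n_chromosomes = n_chromosomes, maf_range = maf_range,
                 missing_rate = missing_rate, n_herds = n_herds,
                 n_stations = n_stations, bounding_box = bounding_box,
                 date_range = date_range, variance_components = vc,
                 causal_spec = causal_spec,
                 fixed_effect_spec = fixed_effect_spec,
                 hs_target_prevalence = hs_target_prevalence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an autosomal marker map
#'
#' Markers are spread over `n_chromosomes` autosomes (balanced counts) with
#' strictly increasing base-pair positions within each chromosome and true
#' allele frequencies drawn uniformly from `maf_range`.
#'
#' @param config A `sim_config`.
#' @return Data frame `snp_id`, `chr`, `pos_bp`, `true_p`.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    per_chr <- rep(config$n_snps %/% config$n_chromosomes, config$n_chromosomes)
    extra <- config$n_snps %% config$n_chromosomes
    if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
    chr <- rep(seq_len(config$n_chromosomes), per_chr)
    pos <- unlist(lapply(per_chr, function(k) {
      if (k == 0) return(integer(0))
      # strictly increasing: sorted draws without replacement
      sort(sample.int(1.1e8, k))
    }))
    data.frame(snp_id = sprintf("snp%06d", seq_len(config$n_snps)),
               chr = chr, pos_bp = pos,
               true_p = stats::runif(config$n_snps, config$maf_range[1],
                                     config$maf_range[2]),
               stringsAsFactors = FALSE)
  })
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Doses are binomial(2, true frequency) per marker, independently across
#' animals (no linkage disequilibrium); entries are masked missing with
#' probability `missing_rate`.
#'
#' @param config A `sim_config`.
#' @param markers Marker map from [simulate_markers()].
#' @return A `genotype_matrix`.
#' @export
simulate_genotypes <- function(config, markers) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(markers))
  with_seed(config$seed + 2L, {
    n <- config$n_animals
    m <- nrow(markers)
    doses <- matrix(stats::rbinom(n * m, 2L, rep(markers$true_p, each = n)),
                    nrow = n, ncol = m)
    if (config$missing_rate > 0) {
      doses[stats::runif(n * m) < config$missing_rate] <- NA
    }
    genotype_matrix(doses, markers,
                    animal_ids = sprintf("A%05d", seq_len(n)))
  })
}

# Deterministic calibration of the seasonal baseline temperature: bisect the
# annual-mean temperature so that the fraction of noiseless weekly THI
# values exceeding 60 matches the target prevalence. The seasonal curve is
# evaluated on a one-year daily grid, aggregated to weeks.
calibrate_baseline_temp <- function(target, annual_amplitude = 9,
                                    rh_mean = 75) {
  frac_above <- function(t0) {
    doy <- 1:364
    tday <- t0 + annual_amplitude * cos(2 * pi * (doy - 196) / 365.25)
    wk <- colMeans(matrix(tday, nrow = 7))
    mean(thi_hourly(wk, rh_mean) >= 60)
  }
  lo <- -20; hi <- 40
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac_above(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate hourly station weather
#'
#' Per station, hourly temperature is an annual sinusoid (peak in mid July)
#' plus a diurnal sinusoid (peak at 14:00) plus Gaussian noise; relative
#' humidity moves against temperature and is clamped to \[0, 100\]. The
#' seasonal baseline is calibrated deterministically so the fraction of
#' weekly THI values at or above 60 approximates `hs_target_prevalence`.
#' The series starts 70 days before `date_range[1]` so every gestation
#' week of the earliest birth date is covered.
#'
#' @param config A `sim_config`.
#' @param stations Optional station table (from [simulate_population()]);
#'   defaults to `n_stations` anonymous stations.
#' @param noise_sd Hourly temperature noise SD in deg C (default 2).
#' @param annual_amplitude,diurnal_amplitude Sinusoid amplitudes in deg C.
#' @param rh_mean Mean relative humidity in percent (default 75).
#' @return Data frame `station_id`, `timestamp` (POSIXct UTC), `temp_c`,
#'   `rh_pct`.
#' @export
simulate_weather <- function(config, stations = NULL, noise_sd = 2,
                             annual_amplitude = 9, diurnal_amplitude = 4,
                             rh_mean = 75) {
  stopifnot(inherits(config, "sim_config"))
  station_ids <- if (is.null(stations)) {
    sprintf("S%03d", seq_len(config$n_stations))
  } else as.character(stations$station_id)
  t0 <- calibrate_baseline_temp(config$hs_target_prevalence,
                                annual_amplitude, rh_mean)
  start <- config$date_range[1] - 70L
  end <- config$date_range[2]
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:00:00"), tz = "UTC"), by = "hour")
  doy <- as.numeric(strftime(ts, "%j", tz = "UTC"))
  hour <- as.numeric(strftime(ts, "%H", tz = "UTC"))
  seasonal <- t0 + annual_amplitude * cos(2 * pi * (doy - 196) / 365.25) +
    diurnal_amplitude * cos(2 * pi * (hour - 14) / 24)
  with_seed(config$seed + 3L, {
    out <- lapply(seq_along(station_ids), function(s) {
      st_off <- stats::rnorm(1, 0, 0.5) # persistent station microclimate
      temp <- seasonal + st_off +
        if (noise_sd > 0) stats::rnorm(length(ts), 0, noise_sd) else 0
      rh <- rh_mean - 1.5 * (temp - t0) + stats::rnorm(length(ts), 0, 5)
      data.frame(station_id = station_ids[s], timestamp = ts,
                 temp_c = temp, rh_pct = pmin(100, pmax(0, rh)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate herds, stations and animal records
#'
#' Herd and station coordinates are uniform in the bounding box; each animal
#' gets a uniformly drawn herd, a uniform birth date in `date_range`, and
#' one level per factor of `fixed_effect_spec` (levels sampled independently
#' and uniformly, so no confounding between herd and exposure is induced).
#'
#' @param config A `sim_config`.
#' @return List with data frames `herds` (`herd_id`, `lat`, `lon`),
#'   `stations` (`station_id`, `lat`, `lon`) and `animals`
#'   (`animal_id`, `herd_id`, `birth_date`, one column per factor).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bb <- config$bounding_box
  with_seed(config$seed + 4L, {
    herds <- data.frame(
      herd_id = sprintf("H%03d", seq_len(config$n_herds)),
      lat = stats::runif(config$n_herds, bb$lat[1], bb$lat[2]),
      lon = stats::runif(config$n_herds, bb$lon[1], bb$lon[2]),
      stringsAsFactors = FALSE)
    stations <- data.frame(
      station_id = sprintf("S%03d", seq_len(config$n_stations)),
      lat = stats::runif(config$n_stations, bb$lat[1], bb$lat[2]),
      lon = stats::runif(config$n_stations, bb$lon[1], bb$lon[2]),
      stringsAsFactors = FALSE)
    span <- as.numeric(diff(config$date_range))
    animals <- data.frame(
      animal_id = sprintf("A%05d", seq_len(config$n_animals)),
      herd_id = herds$herd_id[sample.int(config$n_herds, config$n_animals,
                                         replace = TRUE)],
      birth_date = config$date_range[1] +
        sample.int(span + 1L, config$n_animals, replace = TRUE) - 1L,
      stringsAsFactors = FALSE)
    for (f in names(config$fixed_effect_spec)) {
      k <- config$fixed_effect_spec[[f]]$n_levels
      animals[[f]] <- sample.int(k, config$n_animals, replace = TRUE)
    }
    list(herds = herds, stations = stations, animals = animals)
  })
}

#' Shortcut exposure flags (no weather path)
#'
#' Draws the binary heat-stress flag directly as Bernoulli with the target
#' prevalence and fills in weekly THI values consistent with the flag
#' (above/below 60). Used for fast unit tests; the full path goes through
#' [simulate_weather()] and [build_exposure()].
#'
#' @param config A `sim_config`.
#' @param animal_ids Animal identifiers (default those of
#'   [simulate_genotypes()]).
#' @param weeks Gestation weeks to cover (default 1:8).
#' @return Exposure table `animal_id`, `week`, `weekly_thi`, `hs_flag`.
#' @export
simulate_exposure_flags <- function(config,
                                    animal_ids = sprintf("A%05d",
                                                         seq_len(config$n_animals)),
                                    weeks = 1:8) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 5L, {
    grid <- expand.grid(animal_id = animal_ids, week = weeks,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    flag <- stats::rbinom(nrow(grid), 1L, config$hs_target_prevalence)
    dev <- abs(stats::rnorm(nrow(grid), 0, 5))
    grid$weekly_thi <- ifelse(flag == 1L, 60 + dev, 60 - dev - 1e-6)
    grid$hs_flag <- as.integer(flag)
    grid[order(grid$animal_id, grid$week), ]
  })
}

#' Symmetric square-root factor of a PSD matrix
#'
#' Eigendecomposition with negative eigenvalues clipped at zero (a numerical
#' guard: Gram-constructed relationship matrices are PSD up to rounding).
#' Errors if clipping removes more than `tol` of the spectrum.
#'
#' @param A Symmetric matrix.
#' @param tol Relative tolerance on admissible negative eigenvalues.
#' @return Matrix `L` with `L %*% t(L) = A` (up to clipping).
#' @export
psd_sqrt <- function(A, tol = 1e-6) {
  e <- eigen(A, symmetric = TRUE)
  lmax <- max(abs(e$values))
  if (lmax > 0 && min(e$values) < -tol * lmax) {
    stop("matrix is not positive semi-definite within tolerance")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate phenotypes from the interaction animal model
#'
#' Generates `y = Xb + Zg + W g_hs + e`: polygenic effects `g` drawn
#' multivariate normal with covariance `G sigma2_g`, interaction effects
#' `g_hs` with covariance `G_hs sigma2_ghs` mapped onto exposed animals
#' only, i.i.d. residuals, optional categorical fixed effects, and optional
#' explicit causal-marker effects (main on all animals, interaction on
#' exposed animals only, doses centered at the observed frequency).
#'
#' Two equivalent-in-law samplers for `g` are available: `"eigen"` uses the
#' clipped symmetric square root of `G`; `"marker"` draws i.i.d. effects for
#' the centered marker columns (exact for a VanRaden `G` built from the same
#' genotypes, and much cheaper at large n).
#'
#' @param genotypes Complete `genotype_matrix` (imputed).
#' @param grm The `grm` built from `genotypes`.
#' @param exposure Exposure table covering `week` for all animals.
#' @param week Gestation week whose flag defines exposure.
#' @param config A `sim_config` (variance components, causal spec, fixed
#'   effects, seed).
#' @param animals Optional animal records carrying fixed-effect levels;
#'   levels are drawn fresh when absent.
#' @param g_method `"eigen"` (default) or `"marker"`.
#' @return List: `phenotypes` (data frame `animal_id`, `y`) and `truth`
#'   (`g`, `g_hs`, `b` per factor, `causal`, `exposed`, components).
#' @export
simulate_phenotypes <- function(genotypes, grm, exposure, week, config,
                                animals = NULL,
                                g_method = c("eigen", "marker")) {
  g_method <- match.arg(g_method)
  stopifnot(inherits(config, "sim_config"))
  doses <- genotypes$doses
  if (anyNA(doses)) stop("phenotype simulation needs complete doses")
  n <- nrow(doses)
  ids <- genotypes$animal_ids
  ex <- exposure[exposure$week == week, ]
  exposed <- ex$hs_flag[match(ids, ex$animal_id)] == 1L
  if (anyNA(exposed)) stop("exposure table does not cover every animal")
  vc <- config$variance_components
  G <- if (inherits(grm, "grm")) grm$values else grm

  with_seed(config$seed + 10L + week, {
    # polygenic and interaction effects
    if (g_method == "eigen") {
      L <- psd_sqrt(G)
      g <- sqrt(vc[["g"]]) * as.vector(L %*% stats::rnorm(n))
      g_hs <- numeric(n)
      if (vc[["ghs"]] > 0 && any(exposed)) {
        Lh <- psd_sqrt(G[exposed, exposed, drop = FALSE])
        g_hs[exposed] <- sqrt(vc[["ghs"]]) *
          as.vector(Lh %*% stats::rnorm(sum(exposed)))
      }
    } else {
      p <- colMeans(doses) / 2
      denom <- 2 * sum(p * (1 - p))
      M <- sweep(doses, 2, 2 * p, "-")
      g <- sqrt(vc[["g"]] / denom) * as.vector(M %*% stats::rnorm(ncol(M)))
      g_hs <- numeric(n)
      if (vc[["ghs"]] > 0 && any(exposed)) {
        g_hs[exposed] <- sqrt(vc[["ghs"]] / denom) *
          as.vector(M[exposed, , drop = FALSE] %*% stats::rnorm(ncol(M)))
      }
    }

    # categorical fixed effects
    xb <- numeric(n)
    b <- list()
    levels_used <- list()
    for (f in names(config$fixed_effect_spec)) {
      spec_f <- config$fixed_effect_spec[[f]]
      lev <- if (!is.null(animals) && f %in% names(animals)) {
        animals[[f]][match(ids, animals$animal_id)]
      } else {
        sample.int(spec_f$n_levels, n, replace = TRUE)
      }
      eff <- stats::rnorm(spec_f$n_levels, 0, spec_f$effect_sd)
      xb <- xb + eff[lev]
      b[[f]] <- eff
      levels_used[[f]] <- lev
    }

    # explicit causal markers
    causal <- config$causal_spec
    if (!is.null(causal) && nrow(causal) > 0) {
      p <- colMeans(doses) / 2
      for (r in seq_len(nrow(causal))) {
        j <- causal$marker[r]
        cols <- snp_columns(doses[, j], p[j], exposed)
        xb <- xb + cols$x_snp * causal$beta_main[r] +
          cols$x_inter * causal$beta_inter[r]
      }
    }

    e <- stats::rnorm(n, 0, sqrt(vc[["e"]]))
    y <- xb + g + g_hs + e
    list(phenotypes = data.frame(animal_id = ids, y = y,
                                 stringsAsFactors = FALSE),
         truth = list(g = g, g_hs = g_hs, b = b, levels = levels_used,
                      causal = causal, exposed = exposed,
                      variance_components = vc))
  })
}
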