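# Pipeline orchestration: simulate -> thi -> qc -> grm -> reml -> scan ->
# annotate across traits and gestation weeks, with a JSON manifest and
# deterministic seeding. Every (trait, week) cell is an independent unit of
# work; results are byte-identical regardless of evaluation order.

#' Run the full analysis pipeline
#'
#' Executes, per configured trait and gestation week: exposure lookup,
#' variance-component estimation (no-interaction and interaction models),
#' the GLS genome scan and optional gene annotation. Inputs can come from
#' the synthetic generator (`config$simulate = TRUE`) or from files.
#' Weeks with no exposed animal degrade gracefully: the interaction model
#' is skipped, the no-interaction model is reported, and the manifest notes
#' the downgrade.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created).}
#'     \item{sim}{a [sim_config()] when simulating, else `NULL`.}
#'     \item{genotypes,exposure,phenotypes}{pre-built objects or paths;
#'       required when not simulating.}
#'     \item{weeks}{integer vector of gestation weeks (default 1:8).}
#'     \item{traits}{trait column names (default "y").}
#'     \item{genes}{optional gene table for annotation.}
#'     \item{qc}{named list of [apply_qc()] thresholds overrides.}
#'     \item{ld}{list(r2_cutoff, window) for the independent-SNP count;
#'       `compute = FALSE` skips it.}
#'   }
#' @return The run manifest (list), invisibly; artifacts under `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  weeks <- if (is.null(config$weeks)) 1:8 else config$weeks
  stopifnot(length(weeks) >= 1)
  traits <- if (is.null(config$traits)) "y" else config$traits
  manifest <- list(started = format(Sys.time(), tz = "UTC"),
                   weeks = weeks, traits = traits, stages = list())

  if (isTRUE(config$simulate)) {
    sim <- config$sim
    stopifnot(inherits(sim, "sim_config"))
    markers <- simulate_markers(sim)
    geno_raw <- simulate_genotypes(sim, markers)
    pop <- simulate_population(sim)
    if (isTRUE(config$use_weather)) {
      weather <- simulate_weather(sim, pop$stations)
      daily <- daily_thi(weather)
      assign <- assign_stations(pop$herds, pop$stations)
      exposure <- build_exposure(pop$animals, daily, assign, weeks = weeks)
    } else {
      exposure <- simulate_exposure_flags(sim, geno_raw$animal_ids,
                                          weeks = weeks)
    }
    manifest$stages$simulate <- list(n_animals = sim$n_animals,
                                     n_snps = sim$n_snps, seed = sim$seed)
  } else {
    geno_raw <- config$genotypes
    exposure <- config$exposure
  }

  qc_args <- c(list(geno = geno_raw), config$qc)
  qc <- do.call(apply_qc, qc_args)
  geno <- mean_impute(qc$genotypes)
  grm <- vanraden_grm(geno)
  n_before_prune <- length(grm$animal_ids)
  keep <- prune_related(grm, cutoff = if (is.null(config$rel_cutoff)) 0.95
                        else config$rel_cutoff)
  if (length(keep) < n_before_prune) {
    idx <- match(keep, geno$animal_ids)
    geno <- genotype_matrix_subset(geno, idx)
    grm <- structure(list(values = grm$values[idx, idx],
                          animal_ids = keep, denominator = grm$denominator,
                          kind = "G"), class = "grm")
  }
  manifest$stages$qc <- list(report = unclass(qc$report)[
    c("n_markers_in", "n_markers_out", "n_animals_in", "n_animals_out",
      "n_removed")],
    n_pruned_related = n_before_prune - length(keep),
    n_retained = length(keep))
  jsonlite::write_json(manifest$stages$qc,
                       file.path(config$out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  n_independent <- NULL
  if (!isFALSE(config$ld$compute)) {
    ld <- config$ld
    n_independent <- count_independent(
      geno,
      r2_cutoff = if (is.null(ld$r2_cutoff)) 0.15 else ld$r2_cutoff,
      window = if (is.null(ld$window)) 500 else ld$window)
  }

  ids <- geno$animal_ids
  for (trait in traits) {
    for (wk in weeks) {
      cell <- sprintf("%s_wk%d", trait, wk)
      res <- tryCatch(
        run_cell(config, trait, wk, geno, grm, exposure, n_independent,
                 ids),
        error = function(e) list(error = conditionMessage(e)))
      manifest$stages[[cell]] <- res$summary %||% res
      if (!is.null(res$scan)) {
        utils::write.table(
          res$scan$fits, file.path(config$out_dir, paste0("scan_", cell, ".tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
      if (!is.null(res$vc_report)) {
        jsonlite::write_json(res$vc_report,
                             file.path(config$out_dir,
                                       paste0("varcomp_", cell, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(res$candidates)) {
        utils::write.csv(res$candidates,
                         file.path(config$out_dir,
                                   paste0("candidates_", cell, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one (trait, week) unit of work
run_cell <- function(config, trait, wk, geno, grm, exposure, n_independent,
                     ids) {
  if (isTRUE(config$simulate)) {
    ph <- simulate_phenotypes(geno, grm, exposure, wk, config$sim,
                              g_method = config$g_method %||% "eigen")
    pheno <- ph$phenotypes
    names(pheno)[names(pheno) == "y"] <- trait
  } else {
    pheno <- config$phenotypes
  }
  pheno <- pheno[match(ids, pheno$animal_id), , drop = FALSE]
  ex <- exposure[exposure$week == wk & exposure$animal_id %in% ids, ]
  exposed <- ex$hs_flag[match(ids, ex$animal_id)] == 1L
  y <- pheno[[trait]]
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- cbind(X, hs = as.numeric(exposed))
  if (!any(exposed)) X <- X[, 1, drop = FALSE]

  vc_nhs <- reml_fit(y, X, grm, model = "nhs")
  degenerate <- !any(exposed)
  vc_whs <- if (degenerate) NULL else
    reml_fit(y, X, grm, exposed = exposed, model = "whs")
  vc_use <- if (degenerate) vc_nhs else vc_whs
  scan <- gls_scan(y, X, vc_use, grm, geno, exposed,
                   model = if (degenerate) "nhs" else "whs",
                   n_independent = n_independent)
  candidates <- NULL
  if (!is.null(config$genes) && !is.null(scan$thresholds)) {
    hits <- scan$fits[scan$fits$label_main != "none" |
                        (!is.na(scan$fits$label_inter) &
                           scan$fits$label_inter != "none"), , drop = FALSE]
    candidates <- window_genes(hits, config$genes,
                               flank = config$flank %||% 1e5)
  }
  vc_report <- list(
    trait = trait, week = wk,
    nhs = varcomp_report(vc_nhs),
    whs = if (degenerate) "skipped: no exposed animals" else
      varcomp_report(vc_whs))
  list(summary = list(trait = trait, week = wk,
                      n_exposed = sum(exposed),
                      degenerate_exposure = degenerate,
                      lambda_main = scan$lambda_main,
                      lambda_inter = scan$lambda_inter),
       scan = scan, vc_report = vc_report, candidates = candidates)
}

varcomp_report <- function(vc) {
  out <- unclass(vc)[c("sigma2_g", "sigma2_ghs", "sigma2_e", "loglik",
                       "n_iter", "converged", "model")]
  out <- c(out, ratios(vc))
  out$se <- as.list(vc$se)
  out
}

# subset a genotype_matrix to given row indices (animals)
genotype_matrix_subset <- function(geno, idx) {
  out <- geno
  out$doses <- geno$doses[idx, , drop = FALSE]
  out$animal_ids <- geno$animal_ids[idx]
  out
}
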