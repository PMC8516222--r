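# Genotype QC and genomic relationship matrices (VanRaden construction).

#' Construct a genotype matrix object
#'
#' Thin S3 container for allele-dose genotypes: an `n x m` matrix of codes
#' in \{0, 1, 2, NA\} (counts of the reference allele) plus the marker map.
#'
#' @param doses Numeric matrix, animals in rows, markers in columns; missing
#'   genotypes as `NA`.
#' @param map Data frame with columns `snp_id`, `chr`, `pos_bp` (and
#'   optionally `a1`, `a2`), one row per marker column.
#' @param animal_ids Character vector of row identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(doses, map, animal_ids = rownames(doses)) {
  doses <- as.matrix(doses)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(doses)))
  stopifnot(nrow(map) == ncol(doses), length(animal_ids) == nrow(doses))
  bad <- !is.na(doses) & !(doses %in% c(0, 1, 2))
  if (any(bad)) stop("dose codes must be 0, 1, 2 or NA")
  dimnames(doses) <- list(animal_ids, map$snp_id)
  structure(list(doses = doses, map = as.data.frame(map),
                 animal_ids = as.character(animal_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d markers (%.2f%% missing)\n",
              nrow(x$doses), ncol(x$doses),
              100 * mean(is.na(x$doses))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$doses)

#' Observed allele frequency of one marker
#'
#' `p` is the frequency of the counted allele among non-missing doses:
#' `sum(doses) / (2 * n_obs)`.
#'
#' @param doses Numeric vector of doses in \{0, 1, 2, NA\}.
#' @return Scalar frequency in \[0, 1\].
#' @export
allele_frequency <- function(doses) {
  obs <- doses[!is.na(doses)]
  if (length(obs) == 0L) stop("allele frequency undefined: all doses missing")
  sum(obs) / (2 * length(obs))
}

#' Observed allele frequencies for every marker
#' @param geno A `genotype_matrix`.
#' @return Numeric vector, one frequency per marker.
#' @export
allele_frequencies <- function(geno) {
  n_obs <- colSums(!is.na(geno$doses))
  if (any(n_obs == 0L)) stop("markers with no observed doses present")
  colSums(geno$doses, na.rm = TRUE) / (2 * n_obs)
}

#' Marker and animal call rates
#' @param geno A `genotype_matrix`.
#' @return List with `marker` and `animal` fractions of non-missing entries.
#' @export
call_rates <- function(geno) {
  miss <- is.na(geno$doses)
  list(marker = 1 - colMeans(miss), animal = 1 - rowMeans(miss))
}

#' Deviation of observed from expected heterozygosity
#'
#' A cheap Hardy-Weinberg screen: `|H_obs - 2 p (1 - p)|` where `H_obs` is
#' the fraction of heterozygous (dose 1) calls among non-missing doses.
#'
#' @param doses Numeric vector of doses in \{0, 1, 2, NA\}.
#' @return Absolute deviation in \[0, 1\].
#' @export
hwe_het_deviation <- function(doses) {
  obs <- doses[!is.na(doses)]
  if (length(obs) == 0L) stop("HWE deviation undefined: all doses missing")
  p <- sum(obs) / (2 * length(obs))
  abs(mean(obs == 1) - 2 * p * (1 - p))
}

#' Apply marker and animal quality control
#'
#' Filters in a fixed order: non-autosomal markers, marker call rate,
#' animal call rate, minor allele frequency (strict: MAF must exceed the
#' threshold), and heterozygosity deviation from Hardy-Weinberg
#' expectations. Frequencies are recomputed after the call-rate removals.
#'
#' @param geno A `genotype_matrix`.
#' @param autosomes Integer vector of autosome codes (default 1:29, cattle).
#' @param maf Minimum minor allele frequency, exclusive bound (default 0.01).
#' @param marker_call_rate Minimum marker call rate, inclusive (default 0.95).
#' @param animal_call_rate Minimum animal call rate, inclusive (default 0.95).
#' @param hwe_dev Maximum heterozygosity deviation, exclusive (default 0.15).
#' @return List with the filtered `genotypes` and a `report` (class
#'   `qc_report`) of per-rule removal counts.
#' @export
apply_qc <- function(geno, autosomes = 1:29, maf = 0.01,
                     marker_call_rate = 0.95, animal_call_rate = 0.95,
                     hwe_dev = 0.15) {
  report <- list(thresholds = list(autosomes = autosomes, maf = maf,
                                   marker_call_rate = marker_call_rate,
                                   animal_call_rate = animal_call_rate,
                                   hwe_dev = hwe_dev),
                 n_markers_in = ncol(geno$doses),
                 n_animals_in = nrow(geno$doses))
  removed <- list()

  keep_m <- geno$map$chr %in% autosomes
  removed$non_autosomal <- geno$map$snp_id[!keep_m]
  doses <- geno$doses[, keep_m, drop = FALSE]
  map <- geno$map[keep_m, , drop = FALSE]

  cr_m <- 1 - colMeans(is.na(doses))
  keep_m <- cr_m >= marker_call_rate
  removed$marker_call_rate <- map$snp_id[!keep_m]
  doses <- doses[, keep_m, drop = FALSE]
  map <- map[keep_m, , drop = FALSE]

  cr_a <- 1 - rowMeans(is.na(doses))
  keep_a <- cr_a >= animal_call_rate
  removed$animal_call_rate <- geno$animal_ids[!keep_a]
  doses <- doses[keep_a, , drop = FALSE]

  # frequencies recomputed on the surviving animals
  n_obs <- colSums(!is.na(doses))
  p <- ifelse(n_obs > 0, colSums(doses, na.rm = TRUE) / (2 * pmax(n_obs, 1)), NA)
  maf_vec <- pmin(p, 1 - p)
  keep_m <- !is.na(maf_vec) & maf_vec > maf
  removed$maf <- map$snp_id[!keep_m]
  doses <- doses[, keep_m, drop = FALSE]
  map <- map[keep_m, , drop = FALSE]

  hdev <- apply(doses, 2, hwe_het_deviation)
  keep_m <- hdev < hwe_dev
  removed$hwe <- map$snp_id[!keep_m]
  doses <- doses[, keep_m, drop = FALSE]
  map <- map[keep_m, , drop = FALSE]

  if (ncol(doses) == 0L) stop("quality control removed every marker")

  report$removed <- removed
  report$n_removed <- vapply(removed, length, integer(1))
  report$n_markers_out <- ncol(doses)
  report$n_animals_out <- nrow(doses)
  class(report) <- "qc_report"
  list(genotypes = genotype_matrix(doses, map, rownames(doses)),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d markers, %d -> %d animals\n",
              x$n_markers_in, x$n_markers_out,
              x$n_animals_in, x$n_animals_out))
  for (rule in names(x$n_removed)) {
    cat(sprintf("  %-18s removed %d\n", rule, x$n_removed[[rule]]))
  }
  invisible(x)
}

#' Replace missing doses by their marker mean
#'
#' Missing doses are filled with `2 p` of their marker (the column mean of
#' the observed doses), the standard pre-GRM imputation.
#'
#' @param geno A `genotype_matrix`.
#' @return A `genotype_matrix` without missingness (doses may be fractional).
#' @export
mean_impute <- function(geno) {
  doses <- geno$doses
  if (!anyNA(doses)) return(geno)
  p <- allele_frequencies(geno)
  idx <- which(is.na(doses), arr.ind = TRUE)
  doses[idx] <- 2 * p[idx[, 2]]
  out <- geno
  out$doses <- doses
  out
}

#' VanRaden genomic relationship matrix
#'
#' Centers each marker column by twice its observed allele frequency to form
#' `M`, then `G = M M' / (2 sum p_j (1 - p_j))`. Requires imputed (complete)
#' doses and at least one polymorphic marker.
#'
#' @param geno A complete `genotype_matrix` (run [mean_impute()] first).
#' @return An object of class `grm`: list with `values` (symmetric n x n),
#'   `animal_ids`, `denominator`, `kind`.
#' @export
vanraden_grm <- function(geno) {
  doses <- geno$doses
  if (anyNA(doses)) stop("GRM requires complete doses; run mean_impute() first")
  p <- colMeans(doses) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: GRM denominator is zero")
  M <- sweep(doses, 2, 2 * p, "-")
  G <- tcrossprod(M) / denom
  structure(list(values = G, animal_ids = geno$animal_ids,
                 denominator = denom, kind = "G"),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d animals, mean diagonal %.3f\n",
              x$kind, nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Prune animals with extreme pairwise genomic relationships
#'
#' While any off-diagonal relationship exceeds `cutoff`, the member of the
#' worst-connected pair with the larger number of super-cutoff partners is
#' removed (ties broken by the larger animal id). Deterministic and greedy;
#' retains the maximal number of animals for duplicate clusters.
#'
#' @param grm A full-kind `grm`.
#' @param cutoff Relationship threshold (default 0.95, exclusive).
#' @return Character vector of retained animal ids.
#' @export
prune_related <- function(grm, cutoff = 0.95) {
  G <- grm$values
  ids <- grm$animal_ids
  active <- rep(TRUE, length(ids))
  adj <- G > cutoff
  diag(adj) <- FALSE
  repeat {
    deg <- rowSums(adj[, active, drop = FALSE]) * active
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    victim <- worst[which.max(xtfrm(ids[worst]))] # larger id loses on ties
    active[victim] <- FALSE
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
  }
  ids[active]
}

#' Principal submatrix of a GRM
#'
#' Restricts `G` to a subset of animals (e.g. those exposed to in-utero heat
#' stress in a given gestation week). Allele frequencies — and hence the
#' scale of the matrix — are inherited from the parent `G`, keeping the
#' common and interaction variance components comparable.
#'
#' @param grm A `grm`.
#' @param animals Character vector of animal ids to keep.
#' @return A `grm` of kind `G_hs`.
#' @export
subset_grm <- function(grm, animals) {
  if (length(animals) == 0L) stop("empty animal subset for GRM")
  idx <- match(animals, grm$animal_ids)
  if (anyNA(idx)) stop("unknown animal ids in GRM subset")
  structure(list(values = grm$values[idx, idx, drop = FALSE],
                 animal_ids = grm$animal_ids[idx],
                 denominator = grm$denominator, kind = "G_hs"),
            class = "grm")
}
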