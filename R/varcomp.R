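# Variance components by restricted maximum likelihood for the genomic
# animal model with an optional genotype-by-heat-stress interaction term:
#   y = Xb + Zg + e                    (model "nhs")
#   y = Xb + Zg + W g_hs + e           (model "whs")
# with g ~ N(0, G sigma2_g), g_hs ~ N(0, G_hs sigma2_ghs), e ~ N(0, I sigma2_e),
# Z = I (every phenotyped animal genotyped), and W allocating records of
# exposed animals to the interaction effects.

# ---- fixed-effect class binning -------------------------------------------

#' Age-at-first-calving class (6 classes)
#'
#' Class 1: <= 22 months, 2: 23-24, 3: 25-26, 4: 27-28, 5: 29-30,
#' 6: >= 31 months.
#' @param months Age at first calving in months (vectorised).
#' @return Integer class 1..6.
#' @export
afc_class <- function(months) {
  stopifnot(all(months > 0))
  pmin(pmax(ceiling((months - 22) / 2) + 1, 1), 6)
}

#' Combined dam lactation x calving-age class (21 classes)
#'
#' Lactation 1 reuses the six age-at-first-calving classes; lactations 2-5
#' each get their own age bins; every dam in lactation 6 or later falls in
#' class 21.
#' @param lactation Dam lactation number (1, 2, ...).
#' @param months Dam calving age in months.
#' @return Integer class 1..21.
#' @export
dam_lact_age_class <- function(lactation, months) {
  if (length(lactation) == 1L) lactation <- rep(lactation, length(months))
  stopifnot(length(lactation) == length(months), all(lactation >= 1))
  cls <- integer(length(lactation))
  l1 <- lactation == 1
  cls[l1] <- afc_class(months[l1])
  l2 <- lactation == 2
  cls[l2] <- 7L + findInterval(months[l2], c(36, 38, 40, 43))
  l3 <- lactation == 3
  cls[l3] <- 12L + findInterval(months[l3], c(49, 52, 55))
  l4 <- lactation == 4
  cls[l4] <- 16L + findInterval(months[l4], c(62, 67))
  l5 <- lactation == 5
  cls[l5] <- 19L + findInterval(months[l5], 78)
  cls[lactation >= 6] <- 21L
  cls
}

#' Days-in-milk class for test-day traits (6 classes)
#'
#' Class 1: <= 10 days, 2: 11-15, 3: 16-20, 4: 21-25, 5: 26-30,
#' 6: >= 31 days.
#' @param days Days in milk at the first test-day.
#' @return Integer class 1..6.
#' @export
dim_class <- function(days) {
  stopifnot(all(days >= 0))
  1L + findInterval(days, c(11, 16, 21, 26, 31))
}

#' Lactation-length class for lactation traits (16 classes)
#'
#' Sixteen equal intervals spanning 275 to 305 days:
#' `class = min(16, floor((len - 275) * 16 / 31) + 1)`.
#' @param days Lactation length in days (275..305).
#' @return Integer class 1..16.
#' @export
lactation_length_class <- function(days) {
  stopifnot(all(days >= 275), all(days <= 305))
  pmin(16L, as.integer(floor((days - 275) * 16 / 31)) + 1L)
}

# ---- design construction ---------------------------------------------------

#' Build the mixed-model design for one trait and gestation week
#'
#' Assembles `y`, the fixed-effects matrix `X` (intercept, dummy-coded herd,
#' calving year, calving month, age-at-first-calving class, dam
#' lactation-age class, days-in-milk class for test-day traits or
#' lactation-length class for lactation traits, and the week's binary
#' heat-stress dummy) and the exposure indicator used to construct `W`.
#' Factors with a single level are dropped with a warning; aliased columns
#' are removed by a rank-revealing QR and logged.
#'
#' @param pheno Data frame with `animal_id`, the trait column, and raw
#'   covariates `herd`, `calving_year`, `calving_month`, `afc_months`,
#'   `dam_lactation`, `dam_age_months`, plus `dim_days` (test-day traits)
#'   or `lact_length_days` (lactation traits). Missing covariate columns
#'   are skipped silently, so desk-scale designs remain usable.
#' @param trait Name of the trait column.
#' @param week Gestation week 1..8.
#' @param exposure Exposure table from [build_exposure()] covering `week`.
#' @param trait_type `"testday"` or `"lactation"`, controls the length/DIM
#'   factor.
#' @return List of class `mixed_model_spec`: `y`, `X`, `exposed` (logical),
#'   `animal_ids`, `week`, `trait`, `dropped` (aliased column names).
#' @export
build_design <- function(pheno, trait, week, exposure,
                         trait_type = c("testday", "lactation")) {
  trait_type <- match.arg(trait_type)
  stopifnot(trait %in% names(pheno))
  ex <- exposure[exposure$week == week, ]
  idx <- match(pheno$animal_id, ex$animal_id)
  if (anyNA(idx)) stop("exposure table does not cover every phenotyped animal")
  exposed <- ex$hs_flag[idx] == 1L

  fac <- list()
  add_factor <- function(fac, name, values) {
    f <- factor(values)
    if (nlevels(f) < 2L) {
      warning(sprintf("factor '%s' has a single level; dropped", name))
      return(fac)
    }
    fac[[name]] <- f
    fac
  }
  if ("herd" %in% names(pheno)) fac <- add_factor(fac, "herd", pheno$herd)
  if ("calving_year" %in% names(pheno))
    fac <- add_factor(fac, "calving_year", pheno$calving_year)
  if ("calving_month" %in% names(pheno))
    fac <- add_factor(fac, "calving_month", pheno$calving_month)
  if ("afc_months" %in% names(pheno))
    fac <- add_factor(fac, "afc", afc_class(pheno$afc_months))
  if (all(c("dam_lactation", "dam_age_months") %in% names(pheno)))
    fac <- add_factor(fac, "dam_lact_age",
                      dam_lact_age_class(pheno$dam_lactation,
                                         pheno$dam_age_months))
  if (trait_type == "testday" && "dim_days" %in% names(pheno))
    fac <- add_factor(fac, "dim", dim_class(pheno$dim_days))
  if (trait_type == "lactation" && "lact_length_days" %in% names(pheno))
    fac <- add_factor(fac, "lact_len",
                      lactation_length_class(pheno$lact_length_days))

  df <- if (length(fac)) as.data.frame(fac) else
    data.frame(row.names = seq_len(nrow(pheno)))
  df$hs <- exposed * 1
  X <- stats::model.matrix(~ ., data = df)

  # drop aliased columns (rank-revealing QR with pivoting)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, sort(keep), drop = FALSE]
  }

  structure(list(y = pheno[[trait]], X = X, exposed = exposed,
                 animal_ids = as.character(pheno$animal_id),
                 week = week, trait = trait, dropped = dropped),
            class = "mixed_model_spec")
}

# ---- REML ------------------------------------------------------------------

# One evaluation of the restricted log-likelihood and its ingredients.
# theta: named vector with g, (ghs), e. mats: list(G, M or NULL).
reml_eval <- function(theta, y, X, G, M = NULL) {
  n <- length(y)
  V <- theta[["g"]] * G + diag(theta[["e"]], n)
  if (!is.null(M)) V <- V + theta[["ghs"]] * M
  cV <- chol(V)
  Vi <- chol2inv(cV)
  T_ <- Vi %*% X
  A <- crossprod(X, T_)
  cA <- chol(A)
  Ainv <- chol2inv(cA)
  Viy <- Vi %*% y
  Py <- Viy - T_ %*% (Ainv %*% crossprod(X, Viy))
  yPy <- sum(y * Py)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cA))) + yPy)
  list(ll = ll, Vi = Vi, T_ = T_, Ainv = Ainv, Py = Py)
}

#' Restricted log-likelihood of the genomic animal model
#'
#' Direct dense evaluation of
#' `-1/2 (log|V| + log|X'V^-1 X| + y'Py)` for given variance components;
#' used both inside [reml_fit()] and as a reference for its iterates.
#'
#' @param theta Named numeric vector with elements `g`, `e` and optionally
#'   `ghs`.
#' @param y,X Response and fixed-effects design.
#' @param G Genomic relationship matrix (plain matrix or `grm`).
#' @param exposed Logical exposure vector (needed when `ghs` is present).
#' @return Scalar restricted log-likelihood (constant terms omitted).
#' @export
reml_loglik <- function(theta, y, X, G, exposed = NULL) {
  if (inherits(G, "grm")) G <- G$values
  M <- NULL
  if ("ghs" %in% names(theta)) {
    stopifnot(!is.null(exposed))
    M <- G * tcrossprod(as.numeric(exposed))
  }
  reml_eval(theta, y, X, G, M)$ll
}

#' Estimate variance components by AI-REML with EM fallback
#'
#' Maximizes the restricted log-likelihood over
#' `(sigma2_g, sigma2_e)` (model `"nhs"`) or
#' `(sigma2_g, sigma2_ghs, sigma2_e)` (model `"whs"`) for
#' `V = G sigma2_g + I sigma2_e (+ W G_hs sigma2_ghs W')`. Average-information
#' updates are taken when they keep the iterate feasible and do not decrease
#' the log-likelihood; otherwise an expectation-maximization step (which
#' guarantees ascent) is used. Components are floored at
#' `1e-6 * var(y)` so boundary solutions (e.g. a zero interaction
#' variance) remain representable.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix (full column rank).
#' @param G Genomic relationship matrix (`grm` object or plain matrix) for
#'   all phenotyped animals.
#' @param exposed Logical vector flagging in-utero heat-stress exposure; the
#'   interaction covariance is `G` restricted to exposed pairs (rows/columns
#'   of unexposed animals zeroed), i.e. `W G_hs W'` with `G_hs` the
#'   principal submatrix of `G`.
#' @param model `"nhs"` (no interaction) or `"whs"` (with interaction). A
#'   `"whs"` fit with no exposed animals degrades to `"nhs"` with
#'   `sigma2_ghs = 0`.
#' @param start Optional named starting values; defaults to
#'   `sigma2_e = sigma2_g = var(y)/2` and `sigma2_ghs = 0.1 var(y)`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol_loglik Convergence tolerance on the log-likelihood change.
#' @param tol_param Convergence tolerance on relative parameter change.
#' @return Object of class `varcomp`: `sigma2_g`, `sigma2_ghs` (or `NA`),
#'   `sigma2_e`, `se` (AI-based standard errors), ratio estimates, `loglik`,
#'   `n_iter`, `converged`, `model`.
#' @export
reml_fit <- function(y, X, G, exposed = NULL, model = c("nhs", "whs"),
                     start = NULL, max_iter = 200, tol_loglik = 1e-8,
                     tol_param = 1e-6) {
  model <- match.arg(model)
  if (inherits(G, "grm")) G <- G$values
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(G) == n, nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient; drop aliased columns")

  degenerate_whs <- FALSE
  if (model == "whs") {
    stopifnot(!is.null(exposed), length(exposed) == n)
    if (!any(exposed)) {
      degenerate_whs <- TRUE
      model <- "nhs"
    }
  }

  vy <- stats::var(y)
  if (vy <= 0) stop("response has zero variance")
  floor_ <- 1e-6 * vy
  M <- NULL
  if (model == "whs") M <- G * tcrossprod(as.numeric(exposed))

  nm <- if (model == "whs") c("g", "ghs", "e") else c("g", "e")
  theta <- if (is.null(start)) {
    stats::setNames(c(0.5 * vy,
                      if (model == "whs") 0.1 * vy,
                      0.5 * vy), nm)
  } else {
    stopifnot(all(nm %in% names(start)))
    pmax(start[nm], floor_)
  }
  mats <- c(list(g = G), if (model == "whs") list(ghs = M), list(e = NULL))

  ev <- reml_eval(theta, y, X, G, M)
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  repeat {
    iter <- iter + 1L
    Py <- ev$Py
    Vi <- ev$Vi
    T_ <- ev$T_
    Ainv <- ev$Ainv

    v <- lapply(nm, function(k) {
      if (k == "e") Py else mats[[k]] %*% Py
    })
    yPAPy <- vapply(v, function(vi) sum(Py * vi), numeric(1))
    trPA <- vapply(nm, function(k) {
      if (k == "e") {
        sum(diag(Vi)) - sum(Ainv * crossprod(T_))
      } else {
        sum(Vi * mats[[k]]) - sum(Ainv * crossprod(T_, mats[[k]] %*% T_))
      }
    }, numeric(1))
    grad <- -0.5 * (trPA - yPAPy)

    Pv <- lapply(v, function(vi) {
      u <- Vi %*% vi
      u - T_ %*% (Ainv %*% crossprod(X, u))
    })
    k <- length(nm)
    AI <- matrix(0, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k)) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(v[[i]] * Pv[[j]])
    }

    # candidate AI (quasi-Newton) step, clamped to the feasible region
    cand <- NULL
    delta <- tryCatch(solve(AI, grad), error = function(e) NULL)
    if (!is.null(delta)) {
      cand <- pmax(theta + delta, floor_)
      ev_cand <- tryCatch(reml_eval(cand, y, X, G, M), error = function(e) NULL)
      if (is.null(ev_cand) || ev_cand$ll < ev$ll - 1e-10) cand <- NULL
    }
    if (is.null(cand)) {
      # EM step: theta_i + 2 theta_i^2 / n * gradient_i; monotone ascent
      cand <- pmax(theta + 2 * theta^2 / n * grad, floor_)
      ev_cand <- reml_eval(cand, y, X, G, M)
    }

    dll <- ev_cand$ll - ev$ll
    dpar <- max(abs(cand - theta) / pmax(abs(theta), floor_))
    theta <- cand
    ev <- ev_cand
    if (abs(dll) < tol_loglik || dpar < tol_param) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, length(nm)))
  names(se) <- nm
  out <- list(
    sigma2_g = theta[["g"]],
    sigma2_ghs = if (degenerate_whs) 0 else
      if ("ghs" %in% nm) theta[["ghs"]] else NA_real_,
    sigma2_e = theta[["e"]],
    se = se,
    loglik = ev$ll,
    n_iter = iter,
    converged = converged,
    model = if (degenerate_whs) "whs" else model,
    degenerate_exposure = degenerate_whs,
    floor = floor_
  )
  class(out) <- "varcomp"
  c2 <- ratios(out)
  out[names(c2)] <- c2
  out
}

#' Variance ratios: heritability and interaction proportion
#'
#' For the no-interaction model, `h2_g = s2g / (s2g + s2e)`. For the
#' interaction model, `h2_c = s2g / (s2g + s2ghs + s2e)` and
#' `r_hs = s2ghs / (s2g + s2ghs + s2e)`.
#'
#' @param vc A `varcomp` object (or list with the `sigma2_*` fields).
#' @return Named list of ratios.
#' @export
ratios <- function(vc) {
  s2g <- vc$sigma2_g
  s2e <- vc$sigma2_e
  s2i <- vc$sigma2_ghs
  with_inter <- !is.null(s2i) && !is.na(s2i)
  tot <- s2g + s2e + if (with_inter) s2i else 0
  if (tot <= 0) stop("total variance is zero; ratios undefined")
  if (with_inter) {
    list(h2_c = s2g / tot, r_hs = s2i / tot)
  } else {
    list(h2_g = s2g / tot)
  }
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp [%s]%s: loglik %.4f after %d iter (%s)\n",
              x$model, if (isTRUE(x$degenerate_exposure)) " (no exposed animals)" else "",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  sigma2_g   = %.6g (se %.3g)\n", x$sigma2_g, x$se[["g"]]))
  if (!is.na(x$sigma2_ghs) && "ghs" %in% names(x$se)) {
    cat(sprintf("  sigma2_ghs = %.6g (se %.3g)\n", x$sigma2_ghs, x$se[["ghs"]]))
  }
  cat(sprintf("  sigma2_e   = %.6g (se %.3g)\n", x$sigma2_e, x$se[["e"]]))
  r <- ratios(x)
  cat("  ", paste(names(r), "=", vapply(r, function(z) sprintf("%.4f", z), ""),
                  collapse = ", "), "\n")
  invisible(x)
}
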