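## BLUPs, heritability, extreme-strain flagging, cross-phenotype correlations

#' Best linear unbiased predictors of the random effects
#'
#' Predicts every random-effect level by
#' \eqn{\hat\gamma = \hat G Z' \hat V^{-1} (Y - X\hat\beta)}, solved through
#' Henderson's mixed-model equations for numerical stability.  The
#' prediction standard error of \eqn{\hat\gamma - \gamma} comes from the
#' corresponding diagonal block of the inverse mixed-model-equations
#' coefficient matrix.  Components estimated at exactly zero produce zero
#' predictions with zero standard error and are flagged in the result.
#'
#' @param fit A [reml_fit()] result.
#' @param level Coverage probability of the prediction intervals (normal
#'   quantile).
#' @return An object of class `blup_result`: a data frame with columns
#'   `effect`, `level` (the random-effect level label), `blup`, `se`,
#'   `lower`, `upper`, `at_zero_variance`; attributes carry the interval
#'   level, endpoint and model class.
#' @export
compute_blups <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rix_fit"))
  frame <- fit$frame
  s2e <- fit$sigma2[["residual"]]
  active <- fit$effects[fit$sigma2[fit$effects] > 0]
  inactive <- setdiff(fit$effects, active)

  rows <- list()
  if (length(active) > 0L) {
    Zlist <- frame$design$Z[active]
    Z <- do.call(cbind, Zlist)
    q_each <- vapply(Zlist, ncol, integer(1L))
    blocks <- rep(active, times = q_each)
    ginv <- rep(s2e / fit$sigma2[active], times = q_each)  # sigma2_e * G^-1

    X <- frame$X
    Y <- frame$Y
    p <- ncol(X)
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + diag(ginv, length(ginv))))
    rhs <- c(drop(crossprod(X, Y)), drop(crossprod(Z, Y)))
    Cinv <- solve(C)
    sol <- drop(Cinv %*% rhs)
    gamma_hat <- sol[-(1:p)]
    pev <- s2e * diag(Cinv)[-(1:p)]   # prediction error variance of gamma_hat - gamma
    pev[pev < 0] <- 0
    se <- sqrt(pev)
    zc <- stats::qnorm(1 - (1 - level) / 2)
    rows[[1L]] <- data.frame(
      effect = blocks,
      level = unlist(lapply(Zlist, colnames), use.names = FALSE),
      blup = gamma_hat, se = se,
      lower = gamma_hat - zc * se, upper = gamma_hat + zc * se,
      at_zero_variance = FALSE, stringsAsFactors = FALSE)
  }
  if (length(inactive) > 0L) {
    rows[[2L]] <- do.call(rbind, lapply(inactive, function(e) {
      lev <- colnames(frame$design$Z[[e]])
      data.frame(effect = e, level = lev, blup = 0, se = 0,
                 lower = 0, upper = 0, at_zero_variance = TRUE,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$effect, fit$effects), out$level), ]
  rownames(out) <- NULL
  structure(out, class = c("blup_result", "data.frame"),
            interval_level = level,
            endpoint = frame$endpoint, model_class = frame$model_class)
}

#' Recompute prediction intervals at another coverage level
#'
#' @param blups A [compute_blups()] result.
#' @param level Coverage probability in (0, 1).
#' @return The `blup_result` with `lower`/`upper` recomputed as
#'   `blup +/- z * se`; levels with `se = 0` get degenerate intervals.
#' @export
prediction_intervals <- function(blups, level = 0.95) {
  stopifnot(inherits(blups, "blup_result"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    rix_abort("interval level must be a single probability in (0, 1)",
              "rixmm_range_error")
  }
  zc <- stats::qnorm(1 - (1 - level) / 2)
  blups$lower <- blups$blup - zc * blups$se
  blups$upper <- blups$blup + zc * blups$se
  attr(blups, "interval_level") <- level
  blups
}

#' Heritability partition from fitted variance components
#'
#' Overall heritability is the fraction of phenotypic variance attributable
#' to strain-containing components,
#' \deqn{h^2 = \frac{\kappa \sum_{s} \sigma^2_s}
#'   {\kappa \sum_{s} \sigma^2_s + \sigma^2_{batch} + \sigma^2_\epsilon}}
#' where the sum runs over strain, strain-by-treatment, strain-by-sex and
#' strain-by-sex-by-treatment (as present in the fit), and the parental
#' multiplier \eqn{\kappa} accounts for each animal carrying two parental
#' strain contributions (\eqn{\kappa = 1} treats each component as the
#' variance attributable to the pair, \eqn{\kappa = 2} doubles per-parent
#' components).  Treatment-effect heritability replaces the numerator with
#' \eqn{\kappa\,\sigma^2_{strain \times tmt}} alone.
#'
#' @param fit A [reml_fit()] result.
#' @param kappa Parental multiplier, 1 (default) or 2.
#' @return An object of class `heritability_result`: list with `overall`,
#'   `treatment`, `kappa`, the component values and a text echo of the
#'   definition used.
#' @export
heritability <- function(fit, kappa = 1) {
  stopifnot(inherits(fit, "rix_fit"))
  strain_comps <- intersect(fit$effects,
                            c("strain", "strain_x_tmt", "strain_x_sex",
                              "strain_x_sex_x_tmt"))
  s_strain <- sum(fit$sigma2[strain_comps])
  s_batch <- if ("batch" %in% fit$effects) fit$sigma2[["batch"]] else 0
  denom <- kappa * s_strain + s_batch + fit$sigma2[["residual"]]
  if (denom <= 0) rix_abort("zero phenotypic variance", "rixmm_range_error")
  tx <- if ("strain_x_tmt" %in% fit$effects) fit$sigma2[["strain_x_tmt"]] else 0
  structure(
    list(overall = kappa * s_strain / denom,
         treatment = kappa * tx / denom,
         kappa = kappa,
         components = fit$sigma2,
         definition = sprintf(
           paste0("overall = %g*(%s) / (%g*sum + batch + residual); ",
                  "treatment = %g*strain_x_tmt / same denominator"),
           kappa, paste(strain_comps, collapse = " + "), kappa, kappa)),
    class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("heritability: overall = %.3f, treatment-effect = %.3f (kappa = %g)\n",
              x$overall, x$treatment, x$kappa))
  invisible(x)
}

#' Per-strain treatment-response deviation from strain-by-treatment BLUPs
#'
#' Under level-expansion coding the strain-by-treatment effect has one
#' predicted level per (strain, arm) pair; the quantity of interest for a
#' strain is its haloperidol-arm level minus its placebo-arm level.  For a
#' class C fit (plasma: haloperidol arm only), the plain strain BLUPs are
#' returned instead, since those effects are predicted in treated animals
#' only.
#'
#' @param blups A [compute_blups()] result.
#' @return Named numeric vector, one value per strain.
#' @export
strain_treatment_deltas <- function(blups) {
  stopifnot(inherits(blups, "blup_result"))
  if (identical(attr(blups, "model_class"), "C")) {
    b <- blups[blups$effect == "strain", ]
    return(stats::setNames(b$blup, b$level))
  }
  b <- blups[blups$effect == "strain_x_tmt", ]
  if (nrow(b) == 0L) {
    rix_abort("no strain_x_tmt predictions in this blup_result",
              "rixmm_schema_error")
  }
  parts <- do.call(rbind, strsplit(b$level, ":", fixed = TRUE))
  strains <- sort(unique(parts[, 1L]))
  halo <- stats::setNames(rep(0, length(strains)), strains)
  plac <- halo
  sel_h <- parts[, 2L] == "haloperidol"
  halo[parts[sel_h, 1L]] <- b$blup[sel_h]
  plac[parts[!sel_h, 1L]] <- b$blup[!sel_h]
  halo - plac
}

#' Flag strains with extreme treatment-response predictions
#'
#' For each endpoint with a direction of interest, flags the strains whose
#' strain-by-treatment prediction lies strictly beyond the stated empirical
#' quantile in that direction (e.g. `quantile = 0.10`, `direction = -1`
#' flags strains in the most extreme 10% of treatment-induced decreases).
#' Ties at the threshold are not flagged, so a constant prediction vector
#' yields an empty set.
#'
#' @param blup_map Named list of [compute_blups()] results, one per endpoint.
#' @param quantile Fraction in (0, 0.5] defining "extreme".
#' @param directions Named numeric vector (+1 or -1) per endpoint: the sign
#'   of the mean treatment shift whose extreme responders are sought.
#'   Endpoints absent from `directions` are skipped.
#' @return List with `per_endpoint` (named list of flagged strain vectors),
#'   `any` (strains extreme for >= 1 endpoint), `multiple` (strains extreme
#'   for > 1 endpoint), and a `summary` data frame.
#' @export
flag_extreme_strains <- function(blup_map, quantile = 0.10, directions) {
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 0.5) {
    rix_abort("quantile must lie in (0, 0.5]", "rixmm_range_error")
  }
  endpoints <- intersect(names(blup_map), names(directions))
  per <- stats::setNames(vector("list", length(endpoints)), endpoints)
  for (ep in endpoints) {
    delta <- strain_treatment_deltas(blup_map[[ep]])
    dir <- sign(directions[[ep]])
    ns <- length(delta)
    if (ns < ceiling(1 / quantile)) {
      warning(sprintf("endpoint %s: only %d strains, need >= %d for the %g quantile; nothing flagged",
                      ep, ns, ceiling(1 / quantile), quantile))
      per[[ep]] <- character(0L)
      next
    }
    k <- floor(quantile * ns)
    if (k == 0L) { per[[ep]] <- character(0L); next }
    v <- sort(dir * delta, decreasing = TRUE)
    threshold <- v[k + 1L]
    per[[ep]] <- sort(names(delta)[dir * delta > threshold])
  }
  counts <- table(unlist(per, use.names = FALSE))
  any_s <- sort(names(counts))
  mult_s <- sort(names(counts)[counts > 1L])
  list(per_endpoint = per,
       any = any_s, multiple = mult_s,
       summary = data.frame(strain = any_s,
                            n_endpoints = as.integer(counts[any_s]),
                            stringsAsFactors = FALSE))
}

#' Pearson correlations of strain-level predictions across endpoints
#'
#' Aligns predictions by parental-strain label and computes the Pearson
#' correlation for every endpoint pair.  With `effect = "strain"` the plain
#' strain BLUPs are correlated; with `effect = "strain_x_tmt"` the
#' per-strain treatment-response deviations ([strain_treatment_deltas()])
#' are used, and an endpoint fit on the treated arm only (class C) enters
#' through its strain effect.  Pairs sharing fewer than `min_shared`
#' strains get a missing entry.
#'
#' @param blup_map Named list of [compute_blups()] results.
#' @param effect `"strain"` or `"strain_x_tmt"`.
#' @param min_shared Minimum shared strain count per pair (default 3).
#' @return An object of class `rix_corr`: list with `correlation`
#'   (endpoint x endpoint matrix, unit diagonal), `n_shared`, and `effect`.
#' @export
strain_effect_correlations <- function(blup_map,
                                       effect = c("strain", "strain_x_tmt"),
                                       min_shared = 3L) {
  effect <- match.arg(effect)
  vals <- list()
  for (ep in names(blup_map)) {
    b <- blup_map[[ep]]
    is_c <- identical(attr(b, "model_class"), "C")
    if (effect == "strain") {
      if (is_c) next  # treated-arm-only strain effects belong to the interaction panel
      sb <- b[b$effect == "strain", ]
      if (nrow(sb) == 0L) next
      vals[[ep]] <- stats::setNames(sb$blup, sb$level)
    } else {
      vals[[ep]] <- tryCatch(strain_treatment_deltas(b), error = function(e) NULL)
    }
  }
  vals <- Filter(Negate(is.null), vals)
  eps <- names(vals)
  if (length(eps) < 2L) {
    rix_abort("need at least two endpoints with the requested effect",
              "rixmm_data_error")
  }
  m <- length(eps)
  cm <- matrix(NA_real_, m, m, dimnames = list(eps, eps))
  ns <- matrix(0L, m, m, dimnames = list(eps, eps))
  diag(cm) <- 1
  for (i in seq_len(m)) ns[i, i] <- length(vals[[i]])
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      shared <- intersect(names(vals[[i]]), names(vals[[j]]))
      ns[i, j] <- ns[j, i] <- length(shared)
      if (length(shared) < min_shared) next
      xi <- vals[[i]][shared]; xj <- vals[[j]][shared]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # degenerate (e.g. zero-variance component)
      cm[i, j] <- cm[j, i] <- stats::cor(xi, xj)
    }
  }
  structure(list(correlation = cm, n_shared = ns, effect = effect),
            class = "rix_corr")
}

#' @export
print.rix_corr <- function(x, ...) {
  cat(sprintf("strain-effect correlations (%s):\n", x$effect))
  print(round(x$correlation, 3))
  invisible(x)
}
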