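## One-shot analysis of all endpoints with the hypothesis-test layout

testable_components <- function(effects) {
  ## batch is always retained and never tested
  intersect(effects, c("strain", "strain_x_tmt", "strain_x_sex",
                       "strain_x_sex_x_tmt"))
}

#' Fit every endpoint and run its hypothesis tests
#'
#' For each endpoint in the registry: assembles the model frame, fits the
#' full REML model, runs a boundary-corrected likelihood ratio test for
#' each strain-containing variance component (batch is always retained and
#' never tested), Wald F tests for the fixed treatment, sex, and
#' sex-by-treatment effects (and the pre covariate where present), and the
#' heritability partition.  A failure for one endpoint is caught and
#' recorded without aborting the others.
#'
#' @param table An [as_animal_table()] object.
#' @param endpoints Endpoints to analyse (default: all in `registry`).
#' @param registry Endpoint registry ([phenotype_registry()]).
#' @param effects Random effects of the full model.
#' @param kappa Parental multiplier for [heritability()].
#' @param n_starts,seed Optimizer settings passed to [reml_fit()].
#' @return An object of class `rix_analysis`: named list per endpoint with
#'   `frame`, `fit`, `fixed_tests`, `variance_tests`, `heritability`,
#'   `blups`, or an `error` field for failed endpoints.
#' @export
fit_all_phenotypes <- function(table, endpoints = NULL,
                               registry = phenotype_registry(),
                               effects = rix_effects(), kappa = 1,
                               n_starts = 5L, seed = 1L) {
  stopifnot(inherits(table, "animal_table"))
  if (is.null(endpoints)) endpoints <- registry$endpoint
  unknown <- setdiff(endpoints, registry$endpoint)
  if (length(unknown) > 0L) {
    rix_abort(sprintf("unknown endpoint(s): %s", paste(unknown, collapse = ", ")),
              "rixmm_schema_error")
  }
  out <- stats::setNames(vector("list", length(endpoints)), endpoints)
  for (ep in endpoints) {
    out[[ep]] <- tryCatch({
      frame <- assemble_model_frame(table, ep, effects = effects,
                                    registry = registry)
      fit <- reml_fit(frame, n_starts = n_starts, seed = seed)

      vt <- list()
      for (comp in testable_components(frame$effects)) {
        red <- reml_fit(drop_effect(frame, comp), n_starts = n_starts,
                        seed = seed)
        vt[[comp]] <- lrt_variance_component(fit, red)
      }

      ft <- list()
      for (coefn in intersect(c("pre", "tmt", "sex", "sex_tmt"),
                              names(fit$beta))) {
        ft[[coefn]] <- wald_f_fixed(fit, coefn)
      }

      list(frame = frame, fit = fit,
           fixed_tests = ft, variance_tests = vt,
           heritability = heritability(fit, kappa = kappa),
           blups = compute_blups(fit))
    }, error = function(e) {
      warning(sprintf("endpoint %s failed: %s", ep, conditionMessage(e)))
      list(error = conditionMessage(e))
    })
  }
  structure(out, class = "rix_analysis")
}

fmt_est_p <- function(est, p) {
  if (is.null(est) || is.null(p)) return(NA_character_)
  sprintf("%.4g (%.3g)", est, p)
}

#' Hypothesis-test report across endpoints
#'
#' Arranges the results of [fit_all_phenotypes()] into the standard layout:
#' rows for the fixed-effect estimates with p-values, the strain-containing
#' variance components with boundary-corrected LRT p-values, the F and LRT
#' statistics for the treatment and sex effects, and the heritability
#' partition; one column per endpoint.
#'
#' @param analysis A [fit_all_phenotypes()] result.
#' @param digits Significant digits for the formatted entries.
#' @return Data frame with a `row` label column and one column per
#'   endpoint; entries are `"estimate (p)"` strings, `NA` where a term is
#'   absent from an endpoint's model.
#' @export
table2_report <- function(analysis, digits = 4L) {
  stopifnot(inherits(analysis, "rix_analysis"))
  eps <- names(analysis)
  row_labels <- c("fixed_pre", "fixed_sex", "fixed_tmt", "fixed_sex_tmt",
                  "vc_strain", "vc_strain_x_tmt", "vc_strain_x_sex",
                  "vc_strain_x_sex_x_tmt",
                  "F_fixed_tmt", "F_fixed_sex",
                  "LRT_strain_x_tmt", "LRT_strain_x_sex",
                  "overall_heritability", "treatment_heritability")
  M <- matrix(NA_character_, length(row_labels), length(eps),
              dimnames = list(row_labels, eps))
  for (ep in eps) {
    res <- analysis[[ep]]
    if (!is.null(res$error)) { M[, ep] <- "error"; next }
    fit <- res$fit
    for (coefn in c("pre", "sex", "tmt", "sex_tmt")) {
      if (coefn %in% names(fit$beta)) {
        M[paste0("fixed_", coefn), ep] <-
          fmt_est_p(fit$beta[[coefn]], res$fixed_tests[[coefn]]$p_value)
      }
    }
    for (comp in names(res$variance_tests)) {
      M[paste0("vc_", comp), ep] <-
        fmt_est_p(fit$sigma2[[comp]], res$variance_tests[[comp]]$p_value)
    }
    for (coefn in c("tmt", "sex")) {
      t <- res$fixed_tests[[coefn]]
      if (!is.null(t)) {
        M[paste0("F_fixed_", coefn), ep] <- fmt_est_p(t$statistic, t$p_value)
      }
    }
    for (comp in c("strain_x_tmt", "strain_x_sex")) {
      t <- res$variance_tests[[comp]]
      if (!is.null(t)) {
        M[paste0("LRT_", comp), ep] <- fmt_est_p(t$statistic, t$p_value)
      }
    }
    M["overall_heritability", ep] <- sprintf("%.*g", digits,
                                             res$heritability$overall)
    M["treatment_heritability", ep] <- sprintf("%.*g", digits,
                                               res$heritability$treatment)
  }
  data.frame(row = row_labels, M, stringsAsFactors = FALSE,
             check.names = FALSE, row.names = NULL)
}
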