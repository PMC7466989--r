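## Endpoint registry and model-frame assembly ------------------------------

#' The eight study endpoints and their model classes
#'
#' Model classes follow how each outcome was ascertained:
#' * class `A` — measured pre- and post-treatment in both arms; the response
#'   is the pre/post change score and the pre-treatment value enters as a
#'   fixed covariate (open-field distance, vertical activity, stereotypy,
#'   centroid time, EPS latency, body weight);
#' * class `B` — measured once post-treatment in both arms, no pre covariate
#'   (total VCM count);
#' * class `C` — measured once, haloperidol arm only (log plasma drug
#'   concentration), with random effects batch, strain and strain-by-sex.
#'
#' Transforms: `identity` (change = post - pre), `log_ratio`
#' (change = log(post) - log(pre); used for body weight so the response is a
#' relative change), `log` (plasma).
#'
#' @return Data frame with columns `endpoint`, `model_class`, `transform`,
#'   `pre_col`, `post_col`, `unit`.
#' @export
phenotype_registry <- function() {
  data.frame(
    endpoint    = c("distance", "vertical", "stereotypy", "centroid",
                    "eps", "weight", "vcm", "plasma"),
    model_class = c("A", "A", "A", "A", "A", "A", "B", "C"),
    transform   = c("identity", "identity", "identity", "identity",
                    "identity", "log_ratio", "identity", "log"),
    pre_col     = c("distance_pre", "vertical_pre", "stereotypy_pre",
                    "centroid_pre", "eps_pre", "weight_pre", NA, NA),
    post_col    = c("distance_post", "vertical_post", "stereotypy_post",
                    "centroid_post", "eps_post", "weight_post", NA, NA),
    unit        = c("cm", "beam breaks", "beam breaks", "s", "s",
                    "log g ratio", "count", "log ng/ml"),
    stringsAsFactors = FALSE)
}

registry_row <- function(endpoint, registry = phenotype_registry()) {
  i <- match(endpoint, registry$endpoint)
  if (is.na(i)) {
    rix_abort(sprintf("unknown endpoint: %s (known: %s)", endpoint,
                      paste(registry$endpoint, collapse = ", ")),
              "rixmm_schema_error")
  }
  registry[i, , drop = FALSE]
}

#' Pre/post change score
#'
#' `identity` returns `post - pre`; `log_ratio` returns
#' `log(post) - log(pre)`, i.e. the difference on the log scale (used for
#' body weight, where a raw difference can be negative and a log of the
#' difference would be ill-defined).  Missing inputs give missing outputs so
#' the row can be dropped later.
#'
#' @param pre,post Numeric vectors of pre- and post-treatment measurements.
#' @param transform `"identity"` or `"log_ratio"`.
#' @return Numeric vector of change scores.
#' @export
derive_change_score <- function(pre, post, transform = c("identity", "log_ratio")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(post - pre)
  bad <- (!is.na(pre) & pre <= 0) | (!is.na(post) & post <= 0)
  if (any(bad)) {
    rix_abort("log_ratio change score requires positive pre and post values",
              "rixmm_range_error")
  }
  log(post) - log(pre)
}

#' Total VCM score
#'
#' Sums the four orofacial movement counts (subtle and overt chewing
#' movements, tongue protrusions, jaw tremors) with equal weight.
#'
#' @param subtle,overt,tongue,tremor Non-negative integer count vectors.
#' @return Numeric vector of total counts (`NA` where any input is missing).
#' @export
total_vcm <- function(subtle, overt, tongue, tremor) {
  counts <- cbind(subtle, overt, tongue, tremor)
  if (any(counts < 0, na.rm = TRUE)) {
    rix_abort("VCM counts must be non-negative", "rixmm_range_error")
  }
  as.numeric(subtle + overt + tongue + tremor)
}

#' Log-transform a plasma drug concentration
#'
#' @param conc Positive concentration (ng/ml).
#' @return Natural log of `conc`.
#' @export
transform_plasma <- function(conc) {
  if (any(conc <= 0, na.rm = TRUE)) {
    rix_abort("plasma concentration must be positive", "rixmm_range_error")
  }
  log(conc)
}

model_class_effects <- function(model_class, effects) {
  if (model_class == "C") {
    ## plasma model: batch, strain, strain-by-sex only (haloperidol arm has
    ## no treatment contrast, so treatment interactions drop out)
    intersect(effects, c("batch", "strain", "strain_x_sex"))
  } else {
    effects
  }
}

#' Assemble the complete-case model frame for one endpoint
#'
#' Derives the modeled response, builds the fixed-effect matrix for the
#' endpoint's model class, drops rows with any required value missing, and
#' rebuilds the random-effect design on the surviving rows.  Coding:
#' sex female = 0, male = 1; treatment placebo = 0, haloperidol = 1; the
#' pre covariate is the raw pre value under `identity` and `log(pre)` under
#' `log_ratio`.
#'
#' Fixed effects by class: A uses intercept, pre, treatment, sex, sex:tmt;
#' B omits the pre covariate; C (haloperidol arm only) uses intercept and
#' sex, with random effects restricted to batch, strain, strain-by-sex.
#'
#' @param table An [as_animal_table()] object.
#' @param endpoint Endpoint name from [phenotype_registry()].
#' @param effects Random effects requested for the full model (class C
#'   automatically keeps only its three).
#' @param registry Endpoint registry, by default [phenotype_registry()].
#' @param ... Passed to [build_random_design()].
#' @return An object of class `model_frame`: list with `Y`, `X` (named
#'   columns), `design`, `animal_id`, `n`, `endpoint`, `model_class`,
#'   `transform`, `effects`, and complete-case `counts`.
#' @export
assemble_model_frame <- function(table, endpoint, effects = rix_effects(),
                                 registry = phenotype_registry(), ...) {
  stopifnot(inherits(table, "animal_table"))
  spec <- registry_row(endpoint, registry)
  df <- table$records
  n_input <- nrow(df)

  if (spec$model_class == "C") df <- df[df$treatment == "haloperidol", , drop = FALSE]

  x_tmt <- as.numeric(df$treatment == "haloperidol")
  x_sex <- as.numeric(df$sex == "male")

  if (spec$model_class == "A") {
    pre <- df[[spec$pre_col]]
    post <- df[[spec$post_col]]
    ok_pair <- !is.na(pre) & !is.na(post)
    Y <- rep(NA_real_, nrow(df))
    Y[ok_pair] <- derive_change_score(pre[ok_pair], post[ok_pair], spec$transform)
    x_pre <- if (spec$transform == "log_ratio") suppressWarnings(log(pre)) else pre
    X <- cbind(`(Intercept)` = 1, pre = x_pre, tmt = x_tmt, sex = x_sex,
               sex_tmt = x_sex * x_tmt)
  } else if (spec$model_class == "B") {
    Y <- total_vcm(df$vcm_subtle, df$vcm_overt, df$vcm_tongue, df$vcm_tremor)
    X <- cbind(`(Intercept)` = 1, tmt = x_tmt, sex = x_sex,
               sex_tmt = x_sex * x_tmt)
  } else {
    Y <- rep(NA_real_, nrow(df))
    ok <- !is.na(df$plasma)
    Y[ok] <- transform_plasma(df$plasma[ok])
    X <- cbind(`(Intercept)` = 1, sex = x_sex)
  }

  keep <- stats::complete.cases(cbind(Y, X))
  df_cc <- df[keep, , drop = FALSE]
  if (nrow(df_cc) < 2L) {
    rix_abort(sprintf("endpoint %s: fewer than 2 complete-case rows", endpoint),
              "rixmm_data_error")
  }

  sub_table <- as_animal_table(df_cc, source = paste0(table$metadata$source,
                                                      " [", endpoint, " complete cases]"))
  use_effects <- model_class_effects(spec$model_class, effects)
  design <- build_random_design(sub_table, effects = use_effects, ...)

  counts <- list(
    n_input = n_input,
    n_used = nrow(df_cc),
    n_dropped = n_input - nrow(df_cc),
    by_arm = table(df_cc$treatment),
    by_sex = table(df_cc$sex))

  structure(
    list(Y = as.numeric(Y[keep]), X = X[keep, , drop = FALSE],
         design = design, table = sub_table,
         animal_id = df_cc$animal_id, n = nrow(df_cc),
         endpoint = endpoint, model_class = spec$model_class,
         transform = spec$transform, effects = use_effects,
         counts = counts),
    class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf("model_frame '%s' (class %s, %s): n = %d (of %d input rows)\n",
              x$endpoint, x$model_class, x$transform, x$n, x$counts$n_input))
  cat("  fixed effects:", paste(colnames(x$X), collapse = ", "), "\n")
  cat("  random effects:", paste(x$effects, collapse = ", "), "\n")
  invisible(x)
}

#' Remove one random effect from a model frame
#'
#' Returns the frame with the named effect's incidence matrix removed, for
#' fitting the reduced model of a variance-component likelihood ratio test.
#'
#' @param frame A [assemble_model_frame()] object.
#' @param effect One of the frame's random-effect names.
#' @return The reduced `model_frame`.
#' @export
drop_effect <- function(frame, effect) {
  stopifnot(inherits(frame, "model_frame"))
  if (!effect %in% frame$effects) {
    rix_abort(sprintf("effect '%s' is not in the frame", effect),
              "rixmm_schema_error")
  }
  out <- frame
  out$effects <- setdiff(frame$effects, effect)
  out$design$Z[[effect]] <- NULL
  out$design$q <- out$design$q[names(out$design$q) != effect]
  out$design$effects <- setdiff(frame$design$effects, effect)
  out
}
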