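## Synthetic CC-RIX-like study designs and phenotypes with known truth ----

#' Generating parameters for a synthetic study
#'
#' Bundles, for each endpoint, the fixed effects, the six variance
#' components (batch, strain, strain-by-treatment, strain-by-sex,
#' strain-by-sex-by-treatment, residual), the transform, and the baseline
#' (pre-treatment) distribution, plus a cross-endpoint correlation matrix
#' for the strain effects.  `default_truth()` supplies a full
#' eight-endpoint configuration whose fixed effects and strain-containing
#' variance components follow the magnitudes reported for a chronic
#' haloperidol CC-RIX study; batch and residual variances (never reported
#' there) are chosen so that the generating overall heritability matches
#' the reported values, with the batch variance set to one ninth of the
#' residual variance.
#'
#' @param endpoints Named list: each element a list with `beta` (named:
#'   `intercept`, and as applicable `pre`, `tmt`, `sex`, `sex_tmt`),
#'   `sigma2` (named: `batch`, `strain`, `strain_x_tmt`, `strain_x_sex`,
#'   `strain_x_sex_x_tmt`, `residual`), `model_class` (`"A"`, `"B"`,
#'   `"C"`), `transform`, and for class A `pre_mean`, `pre_sd`.
#' @param strain_cor Correlation matrix of the strain effects across
#'   endpoints (dimnames = endpoint names; endpoints omitted are treated as
#'   independent).  Must be symmetric with unit diagonal and positive
#'   semidefinite.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(endpoints, strain_cor = NULL) {
  stopifnot(is.list(endpoints), length(endpoints) > 0L,
            !is.null(names(endpoints)))
  for (ep in names(endpoints)) {
    e <- endpoints[[ep]]
    if (any(e$sigma2 < 0)) {
      rix_abort(sprintf("endpoint %s: negative variance component", ep),
                "rixmm_range_error")
    }
    need <- c("batch", "strain", "strain_x_tmt", "strain_x_sex",
              "strain_x_sex_x_tmt", "residual")
    missing <- setdiff(need, names(e$sigma2))
    if (length(missing) > 0L) {
      rix_abort(sprintf("endpoint %s: sigma2 missing %s", ep,
                        paste(missing, collapse = ", ")), "rixmm_schema_error")
    }
  }
  if (!is.null(strain_cor)) {
    if (!isTRUE(all.equal(strain_cor, t(strain_cor))) ||
        any(abs(diag(strain_cor) - 1) > 1e-8)) {
      rix_abort("strain_cor must be symmetric with unit diagonal",
                "rixmm_schema_error")
    }
    ev <- eigen(strain_cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      rix_abort("strain_cor must be positive semidefinite", "rixmm_schema_error")
    }
  }
  structure(list(endpoints = endpoints, strain_cor = strain_cor),
            class = "simulation_truth")
}

truth_endpoint <- function(model_class, transform, beta, sigma2,
                           pre_mean = NA, pre_sd = NA) {
  list(model_class = model_class, transform = transform, beta = beta,
       sigma2 = sigma2, pre_mean = pre_mean, pre_sd = pre_sd)
}

## split (total - strainsum/h2 remainder) into batch : residual = 1 : 9
split_env <- function(strain_sum, h2) {
  rem <- strain_sum / h2 - strain_sum
  c(batch = rem / 10, residual = 9 * rem / 10)
}

#' @rdname simulation_truth
#' @export
default_truth <- function() {
  mk <- function(class, transform, beta, strain, s_tmt, s_sex, s_s_t, h2,
                 pre_mean = NA, pre_sd = NA) {
    env <- split_env(strain + s_tmt + s_sex + s_s_t, h2)
    truth_endpoint(class, transform, beta,
                   c(batch = unname(env["batch"]), strain = strain,
                     strain_x_tmt = s_tmt, strain_x_sex = s_sex,
                     strain_x_sex_x_tmt = s_s_t,
                     residual = unname(env["residual"])),
                   pre_mean, pre_sd)
  }
  endpoints <- list(
    distance = mk("A", "identity",
                  c(intercept = 2450, pre = -0.65, tmt = -911.69,
                    sex = -112.74, sex_tmt = 208.26),
                  300278, 86343, 22771, 4618, 0.40, 5000, 1500),
    vertical = mk("A", "identity",
                  c(intercept = 450, pre = -0.69, tmt = -165.80,
                    sex = -0.94, sex_tmt = -3.18),
                  7032.48, 3005, 19910, 242, 0.33, 800, 250),
    stereotypy = mk("A", "identity",
                    c(intercept = 1300, pre = -0.65, tmt = -13.34,
                      sex = 2.84, sex_tmt = 3.38),
                    2599.73, 451.66, 199.56, 47.68, 0.24, 2000, 600),
    centroid = mk("A", "identity",
                  c(intercept = 215, pre = -0.70, tmt = 1.27,
                    sex = 3.23, sex_tmt = -8.46),
                  1020.47, 114.54, 3.72, 0, 0.24, 350, 120),
    eps = mk("A", "identity",
             c(intercept = 3.7, pre = -0.7391, tmt = 10.4421,
               sex = 0.8715, sex_tmt = -2.6416),
             19.760, 21.948, 0, 0.1648, 0.28, 5, 4),
    weight = mk("A", "log_ratio",
                c(intercept = 0.4, pre = -0.1181, tmt = 0.0104,
                  sex = 0.0092, sex_tmt = -0.043),
                8.4e-4, 2.9e-5, 2.1e-4, 0, 0.21, 25, 4),
    vcm = mk("B", "identity",
             c(intercept = 10, tmt = 18.4336, sex = 8.0108,
               sex_tmt = 4.9340),
             611.53, 61.24, 3.57, 26.61, 0.40),
    plasma = mk("C", "log",
                c(intercept = 2, sex = 0.03297),
                0.04127, 0, 0.01105, 0, 0.31))
  simulation_truth(endpoints)
}

#' Simulate a quasi-loop RIX study design
#'
#' Arranges `n_strains` parental strains in a loop: line i crosses strain i
#' (dam) with strain i+1 (sire, wrapping around), so each strain parents
#' exactly two lines.  When `n_lines > n_strains`, additional lines are
#' chords of the loop (strain j crossed with strain j+2, then j+3, ...),
#' mirroring a quasi-loop in which some strains serve extra crosses.  Each
#' line is filled with `per_cell` animals per sex-by-arm cell (the full
#' factorial of female/male by placebo/haloperidol); cagemates are one
#' haloperidol and one placebo animal of the same line and sex; cages are
#' assigned to batches by a seeded random round-robin.
#'
#' @param n_strains Number of parental strains (>= 3).
#' @param per_cell Animals per sex-by-arm cell within each line (study
#'   default 3, i.e. 12 animals per line).
#' @param n_lines Number of RIX lines (default `n_strains`; must be >=
#'   `n_strains` and < `2 * n_strains`).
#' @param n_batches Number of batches; default places about 16 animals per
#'   batch.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return An [as_animal_table()] object with empty phenotype columns.
#' @export
simulate_design <- function(n_strains, per_cell = 3L, n_lines = n_strains,
                            n_batches = NULL, seed = 1L) {
  if (n_strains < 3L) rix_abort("need at least 3 strains", "rixmm_range_error")
  if (per_cell < 1L) rix_abort("per_cell must be >= 1", "rixmm_range_error")
  if (n_lines < n_strains || n_lines >= 2L * n_strains) {
    rix_abort("n_lines must be in [n_strains, 2*n_strains)", "rixmm_range_error")
  }
  strains <- sprintf("CC%03d", seq_len(n_strains))
  dam <- strains[seq_len(n_strains)]
  sire <- strains[c(seq_len(n_strains - 1L) + 1L, 1L)]
  extra <- n_lines - n_strains
  off <- 2L
  j <- 1L
  while (length(dam) < n_lines) {
    dam <- c(dam, strains[j])
    sire <- c(sire, strains[(j + off - 1L) %% n_strains + 1L])
    j <- j + 1L
    if (j > n_strains) { j <- 1L; off <- off + 1L }
  }

  grid <- expand.grid(rep = seq_len(per_cell),
                      treatment = c("placebo", "haloperidol"),
                      sex = c("female", "male"),
                      line = seq_len(n_lines),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  df <- data.frame(
    animal_id = sprintf("A%05d", seq_len(n)),
    dam_strain = dam[grid$line],
    sire_strain = sire[grid$line],
    sex = grid$sex,
    treatment = grid$treatment,
    batch = NA_character_,
    cage = sprintf("C%05d", grid$line * 1000L +
                     match(grid$sex, c("female", "male")) * 100L + grid$rep),
    stringsAsFactors = FALSE)

  n_cages <- length(unique(df$cage))
  if (is.null(n_batches)) n_batches <- max(1L, round(n / 16))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  cage_ids <- sort(unique(df$cage))
  cage_batch <- stats::setNames(
    sprintf("B%03d", sample(rep(seq_len(n_batches), length.out = n_cages))),
    cage_ids)
  df$batch <- unname(cage_batch[df$cage])
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())

  as_animal_table(df, source = sprintf("simulate_design(seed=%d)", seed))
}

## draw one random-effect vector per endpoint; strain effects are drawn
## jointly across endpoints with the truth's correlation matrix
draw_strain_effects <- function(q, truth, eps) {
  sds <- vapply(eps, function(ep) sqrt(truth$endpoints[[ep]]$sigma2[["strain"]]),
                numeric(1L))
  R <- diag(length(eps))
  dimnames(R) <- list(eps, eps)
  if (!is.null(truth$strain_cor)) {
    shared <- intersect(eps, rownames(truth$strain_cor))
    R[shared, shared] <- truth$strain_cor[shared, shared]
  }
  Lt <- chol(R + diag(1e-12, nrow(R)))
  Zn <- matrix(stats::rnorm(q * length(eps)), q)
  G <- Zn %*% Lt
  sweep(G, 2L, sds, `*`)   # q x n_endpoints, column ep ~ N(0, sigma2_strain_ep)
}

#' Simulate phenotypes on a study design under known truth
#'
#' Draws every random effect and residual exactly under the generating
#' model, builds the modeled response, and writes raw phenotype columns so
#' that the preparation module reconstructs the modeled response: for class
#' A endpoints the pre value is drawn from the baseline distribution and
#' the post value is `pre + Y` (or `pre * exp(Y)` under `log_ratio`), so
#' the change score recovers Y; the VCM total is rounded, floored at zero,
#' and split multinomially across the four movement types; plasma is
#' `exp(Y)` for haloperidol animals only.  EPS pre/post values are clipped
#' to \[0, 60\] (the clipped fraction is recorded in the `clipping`
#' attribute).  The exact generating draws are stored in the
#' `truth_draws` attribute for recovery testing.
#'
#' @param design An [simulate_design()] (or loaded) animal table.
#' @param truth A [simulation_truth()] object.
#' @param seed Integer seed.
#' @return The animal table with phenotype columns filled; attributes
#'   `truth_draws` (per endpoint: the gamma vectors, residuals, and modeled
#'   response) and `clipping` (per endpoint clipped fraction).
#' @export
simulate_phenotypes <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "animal_table"),
            inherits(truth, "simulation_truth"))
  df <- design$records
  n <- nrow(df)
  full_design <- build_random_design(design, rix_effects())
  eps_names <- names(truth$endpoints)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  strain_mat <- draw_strain_effects(ncol(full_design$Z$strain), truth, eps_names)
  rownames(strain_mat) <- colnames(full_design$Z$strain)

  x_tmt <- as.numeric(df$treatment == "haloperidol")
  x_sex <- as.numeric(df$sex == "male")
  draws <- list()
  clipping <- list()

  for (ei in seq_along(eps_names)) {
    ep <- eps_names[ei]
    e <- truth$endpoints[[ep]]
    use_effects <- model_class_effects(e$model_class, rix_effects())

    gamma <- list()
    eta <- numeric(n)
    for (eff in use_effects) {
      Zj <- full_design$Z[[eff]]
      if (eff == "strain") {
        g <- strain_mat[colnames(Zj), ei]
      } else {
        g <- stats::rnorm(ncol(Zj), 0, sqrt(e$sigma2[[eff]]))
        names(g) <- colnames(Zj)
      }
      gamma[[eff]] <- g
      eta <- eta + drop(Zj %*% g)
    }
    resid <- stats::rnorm(n, 0, sqrt(e$sigma2[["residual"]]))

    clip <- 0
    if (e$model_class == "A") {
      pre <- stats::rnorm(n, e$pre_mean, e$pre_sd)
      if (ep == "eps") {
        pre_clipped <- pmin(pmax(pre, 0), 60)
        clip <- clip + mean(pre != pre_clipped)
        pre <- pre_clipped
      }
      if (e$transform == "log_ratio") pre <- pmax(pre, 0.05 * e$pre_mean)
      x_pre <- if (e$transform == "log_ratio") log(pre) else pre
      Y <- e$beta[["intercept"]] + e$beta[["pre"]] * x_pre +
        e$beta[["tmt"]] * x_tmt + e$beta[["sex"]] * x_sex +
        e$beta[["sex_tmt"]] * x_sex * x_tmt + eta + resid
      post <- if (e$transform == "log_ratio") pre * exp(Y) else pre + Y
      if (ep == "eps") {
        post_clipped <- pmin(pmax(post, 0), 60)
        clip <- clip + mean(post != post_clipped)
        post <- post_clipped
        Y <- post - pre   # the response the analysis will actually see
      }
      pre_col <- phenotype_registry()$pre_col[phenotype_registry()$endpoint == ep]
      post_col <- phenotype_registry()$post_col[phenotype_registry()$endpoint == ep]
      df[[pre_col]] <- pre
      df[[post_col]] <- post
    } else if (e$model_class == "B") {
      Y <- e$beta[["intercept"]] + e$beta[["tmt"]] * x_tmt +
        e$beta[["sex"]] * x_sex + e$beta[["sex_tmt"]] * x_sex * x_tmt +
        eta + resid
      total <- round(pmax(Y, 0))
      clip <- mean(total != Y)
      share <- c(0.35, 0.30, 0.20, 0.15)  # subtle, overt, tongue, tremor
      counts <- vapply(total, function(tt) {
        if (tt == 0) return(c(0, 0, 0, 0))
        drop(stats::rmultinom(1L, tt, share))
      }, numeric(4L))
      df$vcm_subtle <- counts[1L, ]
      df$vcm_overt <- counts[2L, ]
      df$vcm_tongue <- counts[3L, ]
      df$vcm_tremor <- counts[4L, ]
      Y <- total
    } else {
      Y <- e$beta[["intercept"]] + e$beta[["sex"]] * x_sex + eta + resid
      plasma <- rep(NA_real_, n)
      halo <- df$treatment == "haloperidol"
      plasma[halo] <- exp(Y[halo])
      df$plasma <- plasma
      Y[!halo] <- NA_real_
    }
    draws[[ep]] <- list(gamma = gamma, resid = resid, Y = Y)
    clipping[[ep]] <- clip
  }

  out <- as_animal_table(df, source = sprintf("%s + simulate_phenotypes(seed=%d)",
                                              design$metadata$source, seed))
  attr(out, "truth_draws") <- draws
  attr(out, "clipping") <- clipping
  out
}
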