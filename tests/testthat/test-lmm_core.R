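test_that("restricted log-likelihood matches a dense explicit-inverse evaluation", {
  tab <- small_sim_table(5, seed = 41)
  fr <- assemble_model_frame(tab, "distance")
  sigma2 <- c(batch = 2e5, strain = 1e5, strain_x_tmt = 5e4,
              strain_x_sex = 1e4, strain_x_sex_x_tmt = 2e4, residual = 6e5)
  ll <- reml_loglik(sigma2, fr)
  ll_dense <- dense_reml_loglik(sigma2, fr$Y, fr$X, fr$design$Z)
  expect_equal(ll, ll_dense, tolerance = 1e-10)

  # a second point, including exact zeros
  sigma2["strain_x_sex"] <- 0
  expect_equal(reml_loglik(sigma2, fr),
               dense_reml_loglik(sigma2, fr$Y, fr$X, fr$design$Z),
               tolerance = 1e-10)
})

test_that("with all genetic variances at zero the REML loglik equals the OLS value", {
  tab <- small_sim_table(4, seed = 43)
  fr <- assemble_model_frame(tab, "distance")
  n <- fr$n; p <- ncol(fr$X)
  sigma2 <- c(batch = 0, strain = 0, strain_x_tmt = 0, strain_x_sex = 0,
              strain_x_sex_x_tmt = 0, residual = 1)
  # independent OLS computation of the restricted likelihood at sigma2_e = 1
  ols <- lm.fit(fr$X, fr$Y)
  rss <- sum(ols$residuals^2)
  ll_ols <- -0.5 * (as.numeric(determinant(crossprod(fr$X))$modulus) +
                      rss + (n - p) * log(2 * pi))
  expect_equal(reml_loglik(sigma2, fr), ll_ols, tolerance = 1e-10)
})

test_that("the restricted log-likelihood is invariant to row permutation", {
  tab <- small_sim_table(4, seed = 47)
  fr <- assemble_model_frame(tab, "distance")
  sigma2 <- c(batch = 1e4, strain = 2e5, strain_x_tmt = 3e4,
              strain_x_sex = 0, strain_x_sex_x_tmt = 0, residual = 5e5)
  perm <- sample(seq_len(nrow(tab$records)))
  tab_p <- as_animal_table(tab$records[perm, ])
  fr_p <- assemble_model_frame(tab_p, "distance")
  expect_equal(reml_loglik(sigma2, fr), reml_loglik(sigma2, fr_p),
               tolerance = 1e-9)
})

test_that("balanced one-way REML reproduces the ANOVA closed form", {
  for (seed in c(1, 2, 3)) {
    ow <- one_way_frame(k = 12, m = 5, s2g = 2, s2e = 1, seed = seed)
    fit <- reml_fit(ow$frame, n_starts = 3)
    want <- one_way_anova_est(ow$y, ow$g, ow$m)
    expect_equal(fit$sigma2[["batch"]], want[["group"]], tolerance = 1e-6)
    expect_equal(fit$sigma2[["residual"]], want[["residual"]], tolerance = 1e-6)
  }
})

test_that("REML fit agrees with lme4 on a random-intercept model", {
  skip_if_not_installed("lme4")
  ow <- one_way_frame(k = 15, m = 4, s2g = 3, s2e = 1.5, seed = 7)
  fit <- reml_fit(ow$frame, n_starts = 3)
  g <- factor(ow$g)
  lf <- lme4::lmer(ow$y ~ 1 + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma2[["batch"]], vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2[["residual"]], vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$beta[1]), unname(lme4::fixef(lf)[1]), tolerance = 1e-5)
})

test_that("small-frame optima match a dense grid search to grid resolution", {
  # n <= 12, two random effects; oracle scans a (ratio1, ratio2, s2e) grid
  set.seed(101)
  for (case in 1:3) {
    df <- toy_df(12,
                 dam = rep(c("A", "B", "C"), each = 4),
                 sire = rep(c("B", "C", "A"), each = 4),
                 sex = rep(c("female", "male"), 6),
                 treatment = rep(c("placebo", "haloperidol"), each = 2,
                                 length.out = 12),
                 batch = rep(c("B1", "B2"), 6))
    df$vcm_subtle <- 0; df$vcm_overt <- 0; df$vcm_tongue <- 0; df$vcm_tremor <- 0
    tab <- as_animal_table(df)
    fr <- assemble_model_frame(tab, "vcm", effects = c("batch", "strain"))
    fr$Y <- rnorm(12) + rep(rnorm(3, sd = 1.2), each = 4)
    fr$X <- fr$X[, c("(Intercept)", "tmt"), drop = FALSE]
    fit <- reml_fit(fr, n_starts = 3)
    oracle <- grid_reml_oracle(fr$Y, fr$X, fr$design$Z,
                               grid_ratio = seq(0, 4, by = 0.2),
                               grid_s2e = seq(0.2, 3, by = 0.1))
    # the optimizer must do at least as well as the oracle grid, and the
    # oracle's best point must not beat the optimizer beyond grid resolution
    expect_gte(fit$loglik, oracle$ll - 1e-6)
    expect_lte(fit$loglik - oracle$ll, 0.2)
  }
})

test_that("objective consistency: reported optimum reproduces reml_loglik", {
  tab <- small_sim_table(5, seed = 53)
  fr <- assemble_model_frame(tab, "distance")
  fit <- reml_fit(fr, n_starts = 2)
  sig <- fit$sigma2
  names(sig)[names(sig) == "residual"] <- "residual"
  expect_equal(fit$loglik, reml_loglik(sig, fr), tolerance = 1e-8)
})

test_that("scale equivariance: rescaling Y rescales components, not tests", {
  tab <- small_sim_table(5, seed = 59)
  fr <- assemble_model_frame(tab, "distance")
  fit1 <- reml_fit(fr, n_starts = 2)
  red1 <- reml_fit(drop_effect(fr, "strain"), n_starts = 2)
  t1 <- lrt_variance_component(fit1, red1)

  frc <- fr
  cscale <- 3.7
  frc$Y <- fr$Y * cscale
  fit2 <- reml_fit(frc, n_starts = 2)
  red2 <- reml_fit(drop_effect(frc, "strain"), n_starts = 2)
  t2 <- lrt_variance_component(fit2, red2)

  expect_equal(fit2$sigma2, fit1$sigma2 * cscale^2, tolerance = 1e-3)
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-4)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-4)
})

test_that("null-model recovery: all-zero genetic variances estimated at zero", {
  tr <- default_truth()
  for (comp in c("batch", "strain", "strain_x_tmt", "strain_x_sex",
                 "strain_x_sex_x_tmt")) {
    tr$endpoints$distance$sigma2[[comp]] <- 0
  }
  tr$endpoints$distance$sigma2[["residual"]] <- 1e5
  tab <- simulate_phenotypes(simulate_design(10, seed = 61), tr, seed = 62)
  fit <- reml_fit(assemble_model_frame(tab, "distance"), n_starts = 2)
  # each component should be (near) zero; residual near truth
  for (comp in c("strain", "strain_x_tmt", "strain_x_sex")) {
    expect_lte(fit$sigma2[[comp]], 0.2 * fit$sigma2[["residual"]])
  }
  expect_equal(fit$sigma2[["residual"]], 1e5, tolerance = 0.3)
})

test_that("monotone LRT: the full model never has lower restricted likelihood", {
  tab <- small_sim_table(6, seed = 67)
  fr <- assemble_model_frame(tab, "distance")
  fit <- reml_fit(fr, n_starts = 2)
  for (comp in c("strain", "strain_x_tmt", "strain_x_sex")) {
    red <- reml_fit(drop_effect(fr, comp), n_starts = 2)
    expect_gte(fit$loglik, red$loglik - 1e-6)
  }
})

test_that("LRT boundary arithmetic: zero statistic and the 2.706 threshold", {
  tab <- small_sim_table(4, seed = 71)
  fr <- assemble_model_frame(tab, "distance")
  fit <- reml_fit(fr, n_starts = 2)
  red <- reml_fit(drop_effect(fr, "strain_x_sex_x_tmt"), n_starts = 2)
  t <- lrt_variance_component(fit, red)
  expect_gte(t$statistic, 0)
  expect_true(t$p_value >= 0 && t$p_value <= 1)
  # identical likelihoods -> statistic 0 -> mixture p exactly 0.5
  red0 <- red; red0$loglik <- fit$loglik
  red0$effects <- setdiff(fit$effects, "strain_x_sex_x_tmt")
  t0 <- lrt_variance_component(fit, red0)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 0.5)
  # the analytic mixture quantile: LR = 2.706 gives p = 0.05
  p_mix <- 0.5 * pchisq(2.706, df = 1, lower.tail = FALSE)
  expect_equal(p_mix, 0.05, tolerance = 1e-3)
})

test_that("mismatched frames and wrong nesting are rejected", {
  tab <- small_sim_table(4, seed = 73)
  fr <- assemble_model_frame(tab, "distance")
  fit <- reml_fit(fr, n_starts = 2)
  red2 <- reml_fit(drop_effect(drop_effect(fr, "strain_x_tmt"),
                                       "strain_x_sex"), n_starts = 2)
  expect_error(lrt_variance_component(fit, red2), class = "rixmm_schema_error")
  fr_v <- assemble_model_frame(tab, "vertical")
  fit_v <- reml_fit(fr_v, n_starts = 2)
  expect_error(lrt_variance_component(fit, fit_v), class = "rixmm_integrity_error")
})

test_that("fixed-effect F test: exact residual df without random effects", {
  # fixed-effects-only frame: the Satterthwaite machinery must reduce to n - p
  ow <- one_way_frame(k = 6, m = 4, seed = 3)
  fr <- ow$frame
  fr$design$Z <- list()
  fr$design$q <- integer(0)
  fr$design$effects <- character(0)
  fr$effects <- character(0)
  fr$X <- cbind(fr$X, x1 = rnorm(24))
  fit <- reml_fit(fr)
  t <- wald_f_fixed(fit, "x1")
  expect_equal(unname(t$df["den"]), 24 - 2)
  # and the F equals the squared t of lm
  lmfit <- summary(lm(fr$Y ~ fr$X - 1))
  expect_equal(t$statistic, lmfit$coefficients["fr$Xx1", "t value"]^2,
               tolerance = 1e-8)
})

test_that("duplicated contrast rows are rejected", {
  tab <- small_sim_table(4, seed = 79)
  fr <- assemble_model_frame(tab, "distance")
  fit <- reml_fit(fr, n_starts = 2)
  L <- matrix(0, 2, length(fit$beta))
  L[1, 3] <- 1
  L[2, 3] <- 1
  expect_error(wald_f_fixed(fit, L), class = "rixmm_rank_error")
  expect_error(wald_f_fixed(fit, "not_a_coef"), class = "rixmm_schema_error")
})

test_that("rank-deficient fixed effects are reported with the offending column", {
  tab <- small_sim_table(4, seed = 83)
  fr <- assemble_model_frame(tab, "distance")
  fr$X <- cbind(fr$X, tmt_copy = fr$X[, "tmt"])
  expect_error(reml_fit(fr), class = "rixmm_rank_error", regexp = "tmt")
})

test_that("fit_all_phenotypes produces the full hypothesis-test report shape", {
  tab <- small_sim_table(8, seed = 89)
  an <- fit_all_phenotypes(tab, n_starts = 2)
  expect_s3_class(an, "rix_analysis")
  expect_named(an, phenotype_registry()$endpoint)
  rep <- table2_report(an)
  expect_equal(ncol(rep), 9L)   # row label + 8 endpoints
  expect_equal(nrow(rep), 14L)
  # class-specific absences: vcm has no pre row, plasma no treatment rows
  expect_true(is.na(rep[rep$row == "fixed_pre", "vcm"]))
  expect_true(is.na(rep[rep$row == "fixed_tmt", "plasma"]))
  expect_true(is.na(rep[rep$row == "vc_strain_x_tmt", "plasma"]))
  # every endpoint has a strain variance-component entry
  expect_true(all(!is.na(rep[rep$row == "vc_strain", -1])))
})

test_that("an endpoint failure is contained, others still fit", {
  tab <- small_sim_table(4, seed = 97)
  df <- tab$records
  df$plasma <- NA_real_   # plasma unmeasured -> endpoint must fail cleanly
  tab2 <- as_animal_table(df)
  expect_warning(an <- fit_all_phenotypes(tab2, endpoints = c("distance", "plasma"),
                                          n_starts = 2),
                 regexp = "plasma")
  expect_null(an$distance$error)
  expect_false(is.null(an$plasma$error))
  rep <- table2_report(an)
  expect_true(all(rep$plasma == "error"))
})

test_that("Wald F p-values are approximately uniform under a null coefficient", {
  # generator with a zero sex effect; fitted model matches the generator
  tr <- default_truth()
  e <- tr$endpoints$distance
  e$beta[c("sex", "sex_tmt")] <- 0
  e$sigma2[c("strain_x_sex", "strain_x_sex_x_tmt")] <- 0
  tr2 <- simulation_truth(list(distance = e))
  d <- simulate_design(8, seed = 107)
  set.seed(107)
  seeds <- sample.int(.Machine$integer.max - 1L, 300)
  pv <- vapply(seeds, function(s) {
    sim <- simulate_phenotypes(d, tr2, seed = s)
    fr <- assemble_model_frame(sim, "distance",
                               effects = c("batch", "strain", "strain_x_tmt"))
    fit <- reml_fit(fr, n_starts = 1, seed = s)
    wald_f_fixed(fit, "sex")$p_value
  }, numeric(1L))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the rejection rate at 0.05 is near nominal
  expect_equal(mean(pv < 0.05), 0.05, tolerance = 0.6)
})
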