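# Fixtures built in code and independent oracles used across test files.

# minimal valid animal-level data frame; phenotype values optional
toy_df <- function(n = 4L,
                   dam = rep(c("CCA", "CCB"), length.out = n),
                   sire = rep(c("CCB", "CCC"), length.out = n),
                   sex = rep(c("female", "male"), length.out = n),
                   treatment = rep(c("placebo", "haloperidol"), length.out = n),
                   batch = rep("B1", n),
                   cage = paste0("K", ceiling(seq_len(n) / 2))) {
  data.frame(animal_id = paste0("id", seq_len(n)),
             dam_strain = dam, sire_strain = sire, sex = sex,
             treatment = treatment, batch = batch, cage = cage,
             stringsAsFactors = FALSE)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force per-row membership oracle: which column labels must carry a 1
# for animal r under each effect, straight from the definitions
oracle_row_membership <- function(rec, effect) {
  both <- c(rec$dam_strain, rec$sire_strain)
  switch(effect,
    batch = rec$batch,
    strain = both,
    strain_x_tmt = paste(both, rec$treatment, sep = ":"),
    strain_x_sex = paste(both, rec$sex, sep = ":"),
    strain_x_sex_x_tmt = paste(both, rec$sex, rec$treatment, sep = ":"))
}

# dense REML log-likelihood with explicit inverses (never used by the package)
dense_reml_loglik <- function(sigma2, Y, X, Zlist) {
  n <- length(Y); p <- ncol(X)
  V <- diag(sigma2[["residual"]], n)
  for (e in names(Zlist)) V <- V + sigma2[[e]] * tcrossprod(Zlist[[e]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% Y)
  r <- Y - X %*% beta
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(r) %*% Vi %*% r) + (n - p) * log(2 * pi))
}

# grid-search REML oracle over variance components (small frames only)
grid_reml_oracle <- function(Y, X, Zlist, grid_ratio, grid_s2e) {
  best <- list(ll = -Inf)
  k <- length(Zlist)
  ratios <- as.matrix(expand.grid(rep(list(grid_ratio), k)))
  for (s2e in grid_s2e) {
    for (i in seq_len(nrow(ratios))) {
      sig <- c(stats::setNames(ratios[i, ] * s2e, names(Zlist)), residual = s2e)
      ll <- dense_reml_loglik(sig, Y, X, Zlist)
      if (ll > best$ll) best <- list(ll = ll, sigma2 = sig)
    }
  }
  best
}

# balanced one-way layout: k groups, m observations per group
one_way_frame <- function(k, m, mu = 0, s2g = 2, s2e = 1, seed = 1L) {
  set.seed(seed)
  g <- rep(seq_len(k), each = m)
  y <- mu + rnorm(k)[g] * sqrt(s2g) + rnorm(k * m) * sqrt(s2e)
  # encode the grouping as the batch effect of a degenerate animal table
  df <- toy_df(k * m,
               dam = rep("CCX", k * m), sire = rep("CCY", k * m),
               sex = rep("female", k * m), treatment = rep("placebo", k * m),
               batch = paste0("G", sprintf("%02d", g)),
               cage = paste0("K", seq_len(k * m)))
  df$vcm_subtle <- 0; df$vcm_overt <- 0; df$vcm_tongue <- 0; df$vcm_tremor <- 0
  tab <- as_animal_table(df)
  fr <- assemble_model_frame(tab, "vcm", effects = "batch")
  fr$Y <- y
  fr$X <- fr$X[, "(Intercept)", drop = FALSE]
  list(frame = fr, y = y, g = g, k = k, m = m)
}

# closed-form balanced one-way REML estimates (ANOVA method coincides with
# REML when the between-group estimate is non-negative)
one_way_anova_est <- function(y, g, m) {
  ybar_g <- tapply(y, g, mean)
  ybar <- mean(y)
  k <- length(ybar_g)
  msb <- m * sum((ybar_g - ybar)^2) / (k - 1)
  mse <- sum((y - ybar_g[g])^2) / (k * (m - 1))
  c(group = max((msb - mse) / m, 0), residual = mse)
}

# small simulated study table for fit-level tests
small_sim_table <- function(n_strains = 8L, seed = 1L, truth = default_truth()) {
  d <- simulate_design(n_strains, seed = seed)
  simulate_phenotypes(d, truth, seed = seed + 100L)
}
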