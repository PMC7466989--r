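## Parameter-recovery and calibration studies ------------------------------

#' Simulate-fit-compare study for one endpoint
#'
#' Repeatedly simulates phenotypes on a fixed quasi-loop design under the
#' supplied truth, runs the full preparation and REML fitting path, and
#' compares estimates to the generating values.  Reports per-parameter
#' bias, Monte-Carlo standard error and RMSE, the coverage of the
#' strain-effect prediction intervals against the stored generating
#' draws, and (optionally) the rejection rate of the boundary-corrected
#' LRT for one component, giving the empirical type-I error when that
#' component's generating variance is zero and power otherwise.
#'
#' @param truth A [simulation_truth()] object containing `endpoint`.
#' @param reps Number of simulation replicates.
#' @param endpoint Which endpoint of the truth to study.
#' @param n_strains,n_lines,per_cell,n_batches,design_seed Design size
#'   passed to [simulate_design()]; the design is fixed across replicates,
#'   as in a real study.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param lrt_component Optional variance component to test each replicate
#'   with [lrt_variance_component()].
#' @param alpha Significance level for the rejection-rate summary.
#' @param interval_level Prediction-interval coverage level to assess.
#' @param effects Random effects of the fitted model (default: all five; a
#'   calibration study of one component should fit a model whose other
#'   components are interior, i.e. truly positive in the generator, so the
#'   boundary null distribution applies to the tested component alone).
#' @param n_starts Optimizer starts per fit (fewer than the fitting default
#'   keeps large studies affordable; the objective is smooth in these
#'   designs).
#' @return An object of class `recovery_report`: `parameters` data frame
#'   (truth, mean estimate, bias, MC SE, RMSE per component and fixed
#'   effect), `coverage` (strain-effect interval coverage), `lrt`
#'   (rejection rate and p-values, if requested), `n_fail`, `reps`, `seed`.
#' @export
parameter_recovery_study <- function(truth, reps, endpoint = "distance",
                                     n_strains = 62L, n_lines = 73L,
                                     per_cell = 3L, n_batches = NULL,
                                     seed = 1L, design_seed = seed,
                                     lrt_component = NULL, alpha = 0.05,
                                     interval_level = 0.95,
                                     effects = rix_effects(),
                                     n_starts = 2L) {
  stopifnot(inherits(truth, "simulation_truth"),
            endpoint %in% names(truth$endpoints))
  design <- simulate_design(n_strains, per_cell = per_cell,
                            n_lines = n_lines, n_batches = n_batches,
                            seed = design_seed)
  e <- truth$endpoints[[endpoint]]
  use_effects <- model_class_effects(e$model_class, effects)
  comp_names <- c(use_effects, "residual")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())

  est <- matrix(NA_real_, reps, length(comp_names),
                dimnames = list(NULL, comp_names))
  beta_est <- NULL
  covered <- total_levels <- 0L
  pvals <- rep(NA_real_, reps)
  n_fail <- 0L
  failures <- character(0L)

  for (i in seq_len(reps)) {
    res <- tryCatch({
      sim <- simulate_phenotypes(design, truth, seed = rep_seeds[i])
      frame <- assemble_model_frame(sim, endpoint, effects = effects)
      fit <- reml_fit(frame, n_starts = n_starts, seed = rep_seeds[i])
      out <- list(sigma2 = fit$sigma2, beta = fit$beta)

      blups <- compute_blups(fit, level = interval_level)
      sb <- blups[blups$effect == "strain", ]
      g_true <- attr(sim, "truth_draws")[[endpoint]]$gamma$strain
      g_true <- g_true[sb$level]
      out$covered <- sum(g_true >= sb$lower & g_true <= sb$upper)
      out$n_levels <- nrow(sb)

      if (!is.null(lrt_component)) {
        red <- reml_fit(drop_effect(frame, lrt_component),
                        n_starts = n_starts, seed = rep_seeds[i])
        out$p <- lrt_variance_component(fit, red)$p_value
      }
      out
    }, error = function(err) err)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      failures <- c(failures, conditionMessage(res))
      next
    }
    est[i, names(res$sigma2)] <- res$sigma2
    if (is.null(beta_est)) {
      beta_est <- matrix(NA_real_, reps, length(res$beta),
                         dimnames = list(NULL, names(res$beta)))
    }
    beta_est[i, ] <- res$beta
    covered <- covered + res$covered
    total_levels <- total_levels + res$n_levels
    if (!is.null(lrt_component)) pvals[i] <- res$p
  }

  truth_sigma <- e$sigma2[comp_names]
  ok <- stats::complete.cases(est)
  params <- data.frame(
    parameter = paste0("sigma2_", comp_names),
    truth = as.numeric(truth_sigma),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    stringsAsFactors = FALSE)
  params$bias <- params$mean_estimate - params$truth
  params$mc_se <- apply(est[ok, , drop = FALSE], 2L, stats::sd) / sqrt(sum(ok))
  params$rmse <- sqrt(colMeans((est[ok, , drop = FALSE] -
                                  rep(params$truth, each = sum(ok)))^2))
  if (!is.null(beta_est)) {
    bt <- e$beta
    bmap <- c(intercept = "(Intercept)", pre = "pre", tmt = "tmt",
              sex = "sex", sex_tmt = "sex_tmt")
    for (b in names(bt)) {
      col <- bmap[[b]]
      if (!col %in% colnames(beta_est)) next
      v <- beta_est[ok, col]
      params <- rbind(params, data.frame(
        parameter = paste0("beta_", b), truth = bt[[b]],
        mean_estimate = mean(v), bias = mean(v) - bt[[b]],
        mc_se = stats::sd(v) / sqrt(sum(ok)),
        rmse = sqrt(mean((v - bt[[b]])^2)), stringsAsFactors = FALSE))
    }
  }
  rownames(params) <- NULL

  lrt <- NULL
  if (!is.null(lrt_component)) {
    pv <- pvals[!is.na(pvals)]
    lrt <- list(component = lrt_component,
                truth = e$sigma2[[lrt_component]],
                alpha = alpha,
                rejection_rate = mean(pv < alpha),
                n = length(pv), p_values = pv)
  }

  structure(
    list(parameters = params,
         coverage = list(level = interval_level,
                         covered = covered, total = total_levels,
                         rate = if (total_levels > 0L) covered / total_levels else NA_real_),
         lrt = lrt,
         endpoint = endpoint,
         design = list(n_strains = n_strains, n_lines = n_lines,
                       per_cell = per_cell,
                       n_animals = nrow(design$records)),
         reps = reps, n_fail = n_fail, failures = utils::head(failures, 10L),
         seed = seed),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: endpoint '%s', %d reps (%d failed), %d strains / %d lines / n = %d\n",
              x$endpoint, x$reps, x$n_fail, x$design$n_strains,
              x$design$n_lines, x$design$n_animals))
  print(cbind(x$parameters[, "parameter", drop = FALSE],
              round(x$parameters[, -1L], 5)))
  cat(sprintf("strain-effect %g%% interval coverage: %.3f (%d/%d levels)\n",
              100 * x$coverage$level, x$coverage$rate,
              x$coverage$covered, x$coverage$total))
  if (!is.null(x$lrt)) {
    cat(sprintf("LRT %s (truth %.4g): rejection rate %.3f at alpha = %g over %d reps\n",
                x$lrt$component, x$lrt$truth, x$lrt$rejection_rate,
                x$lrt$alpha, x$lrt$n))
  }
  invisible(x)
}
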