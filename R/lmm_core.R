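## REML estimation of variance components for multiple-membership models --
##
## Model: Y = X beta + sum_j Z_j gamma_j + eps,
##        gamma_j ~ N(0, sigma2_j I), eps ~ N(0, sigma2_e I), independent.
## V = sum_j sigma2_j Z_j Z_j' + sigma2_e I.
##
## All likelihood work is done in crossproduct space.  With variance ratios
## lambda_j = sigma2_j / sigma2_e and Z the column-concatenation of the Z_j,
## V = sigma2_e (I + Z D Z') with D = blockdiag(lambda_j I).  The Woodbury
## identity reduces every n x n operation to a q x q Cholesky of
## M = I_q + A Z'Z A, A = D^(1/2), so an objective evaluation costs O(q^3)
## regardless of n.  sigma2_e is profiled out analytically.

## precompute crossproducts for a model frame
reml_cross <- function(frame) {
  X <- frame$X
  Y <- frame$Y
  Zlist <- frame$design$Z
  k <- length(Zlist)
  if (k > 0L) {
    Z <- do.call(cbind, Zlist)
    blocks <- rep(seq_len(k), times = vapply(Zlist, ncol, integer(1L)))
  } else {
    Z <- matrix(0, nrow(X), 0L)
    blocks <- integer(0L)
  }
  list(X = X, Y = Y, Z = Z, blocks = blocks, k = k,
       effects = names(Zlist),
       q_per_effect = vapply(Zlist, ncol, integer(1L)),
       Czz = crossprod(Z), Czx = crossprod(Z, X), Czy = drop(crossprod(Z, Y)),
       Cxx = crossprod(X), Cxy = drop(crossprod(X, Y)), Cyy = sum(Y^2),
       n = length(Y), p = ncol(X))
}

## core evaluation at variance ratios lambda (length k, >= 0).
## Returns the profiled REML deviance (-2 loglik with sigma2_e at its
## profile optimum), the profiled sigma2_e, GLS beta, and (if gradient)
## d(-2l)/d lambda.
reml_eval <- function(lambda, cr, gradient = FALSE) {
  n <- cr$n; p <- cr$p
  if (cr$k == 0L) {
    ## no random effects: ordinary least squares
    K <- chol(cr$Cxx)
    beta <- backsolve(K, backsolve(K, cr$Cxy, transpose = TRUE))
    rss <- cr$Cyy - sum(cr$Cxy * beta)
    s2e <- rss / (n - p)
    m2ll <- (n - p) * log(s2e) + 2 * sum(log(diag(K))) + (n - p) * (1 + log(2 * pi))
    return(list(m2ll = m2ll, sigma2_eps = s2e, beta = drop(beta),
                XtViX_chol = K, grad = numeric(0L)))
  }
  lambda <- pmax(lambda, 0)   # optimizer line searches can round below the bound
  a <- sqrt(lambda)[cr$blocks]
  M <- cr$Czz * tcrossprod(a)
  diag(M) <- diag(M) + 1
  U <- chol(M)
  SzX <- a * cr$Czx
  SzY <- a * cr$Czy
  Wx <- backsolve(U, SzX, transpose = TRUE)
  Wy <- drop(backsolve(U, SzY, transpose = TRUE))
  XtViX <- cr$Cxx - crossprod(Wx)
  XtViy <- cr$Cxy - drop(crossprod(Wx, Wy))
  ytViy <- cr$Cyy - sum(Wy^2)
  K <- tryCatch(chol(XtViX), error = function(e) {
    rix_abort(sprintf("X'V^-1X not positive definite (collinear fixed effects among: %s)",
                      paste(colnames(cr$X), collapse = ", ")),
              "rixmm_rank_error")
  })
  beta <- backsolve(K, backsolve(K, XtViy, transpose = TRUE))
  rss <- ytViy - sum(XtViy * beta)          # r' V*^-1 r at GLS beta
  rss <- max(rss, .Machine$double.xmin)
  s2e <- rss / (n - p)
  ldV <- 2 * sum(log(diag(U)))
  ldX <- 2 * sum(log(diag(K)))
  m2ll <- (n - p) * log(s2e) + ldV + ldX + (n - p) * (1 + log(2 * pi))
  out <- list(m2ll = m2ll, sigma2_eps = s2e, beta = drop(beta),
              XtViX_chol = K, U = U)
  if (gradient) {
    ## d(-2l)/d lambda_j = tr(Zj' P* Zj) - (n-p) ||Zj' P* y||^2 / (y' P* y)
    Wz <- backsolve(U, a * cr$Czz, transpose = TRUE)      # U' Wz = A Z'Z
    H <- t(cr$Czx) - crossprod(Wx, Wz)                    # X' V*^-1 Z
    Hs <- backsolve(K, H, transpose = TRUE)
    ZtViy <- cr$Czy - drop(crossprod(Wz, Wy))
    ZtPy <- ZtViy - drop(crossprod(H, beta))
    tr_col <- diag(cr$Czz) - colSums(Wz^2) - colSums(Hs^2)
    tr_j <- as.numeric(rowsum(tr_col, cr$blocks))
    quad_j <- as.numeric(rowsum(ZtPy^2, cr$blocks))
    out$grad <- tr_j - quad_j / s2e
  }
  out
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood
#' \deqn{\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| +
#'   (Y-X\hat\beta)'V^{-1}(Y-X\hat\beta) + (n-p)\log 2\pi\right]}
#' with \eqn{\hat\beta} the GLS solution at the supplied components.  The
#' computation goes through a Cholesky factorization of a q x q capacitance
#' matrix (Woodbury identity); the n x n covariance matrix V is never
#' inverted explicitly.
#'
#' @param sigma2 Named numeric vector: one non-negative entry per random
#'   effect in the frame (names matching `frame$effects`) plus a positive
#'   `"residual"` entry.
#' @param frame A [assemble_model_frame()] object.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(sigma2, frame) {
  stopifnot(inherits(frame, "model_frame"))
  if (!"residual" %in% names(sigma2)) {
    rix_abort("sigma2 must contain a 'residual' entry", "rixmm_schema_error")
  }
  s2e <- sigma2[["residual"]]
  if (s2e <= 0) rix_abort("residual variance must be > 0", "rixmm_range_error")
  comps <- sigma2[names(sigma2) != "residual"]
  missing <- setdiff(frame$effects, names(comps))
  if (length(missing) > 0L) {
    rix_abort(sprintf("sigma2 missing component(s): %s",
                      paste(missing, collapse = ", ")), "rixmm_schema_error")
  }
  if (any(comps < 0)) rix_abort("variance components must be >= 0", "rixmm_range_error")
  cr <- reml_cross(frame)
  lambda <- as.numeric(comps[cr$effects]) / s2e
  ev <- reml_eval(lambda, cr)
  n <- cr$n; p <- cr$p
  ## un-profile: replace (n-p) log(s2e_hat) + (n-p) with the value at s2e
  m2ll <- ev$m2ll - (n - p) * (1 + log(ev$sigma2_eps)) +
    (n - p) * log(s2e) + ev$sigma2_eps * (n - p) / s2e
  -0.5 * m2ll
}

## deterministic-but-seeded start values without touching the global RNG
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' REML fit of a variance-components model
#'
#' Maximizes the restricted likelihood over the non-negative orthant of
#' variance components.  The residual variance is profiled out analytically
#' and the remaining variance ratios are optimized by bounded quasi-Newton
#' (`optim` L-BFGS-B, lower bound 0) with an analytic gradient, from one
#' deterministic start plus `n_starts - 1` seeded random starts; the best
#' optimum is kept.  Ratios below `1e-10` at the optimum are snapped to an
#' exact 0, so boundary estimates are reported as exactly zero.
#'
#' @param frame A [assemble_model_frame()] object.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the random starts (does not touch the
#'   global RNG stream).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return An object of class `rix_fit`: fixed-effect estimates and
#'   standard errors, named variance components (`$sigma2`, including
#'   `residual`), the restricted log-likelihood (`$loglik`), and a
#'   convergence record.
#' @export
reml_fit <- function(frame, n_starts = 5L, seed = 1L, maxit = 500L) {
  stopifnot(inherits(frame, "model_frame"))
  cr <- reml_cross(frame)
  n <- cr$n; p <- cr$p; k <- cr$k
  if (n <= p) {
    rix_abort(sprintf("n = %d rows cannot identify %d fixed effects", n, p),
              "rixmm_data_error")
  }
  qrX <- qr(cr$X)
  if (qrX$rank < p) {
    bad <- colnames(cr$X)[qrX$pivot[(qrX$rank + 1L):p]]
    rix_abort(sprintf("fixed-effect matrix is rank deficient; collinear column(s): %s",
                      paste(bad, collapse = ", ")), "rixmm_rank_error")
  }

  if (k == 0L) {
    ev <- reml_eval(numeric(0L), cr)
    fit <- build_fit(frame, cr, numeric(0L), ev,
                     convergence = list(code = 0L, n_starts = 0L,
                                        message = "closed form (no random effects)"))
    return(fit)
  }

  ## objective/gradient with a one-slot cache (optim calls fn and gr
  ## separately at the same parameter value)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(lambda) {
    key <- paste(format(lambda, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- reml_eval(lambda, cr, gradient = TRUE)
      cache$key <- key
    }
    cache$val
  }
  fn <- function(l) eval_at(l)$m2ll
  gr <- function(l) eval_at(l)$grad

  starts <- matrix(0.2, k, 1L)
  if (n_starts > 1L) {
    u <- matrix(local_runif(k * (n_starts - 1L), seed), k)
    starts <- cbind(starts, 10^(u * 2.5 - 2))  # ratios in [1e-2, 10^0.5]
  }

  best <- NULL
  records <- vector("list", ncol(starts))
  for (s in seq_len(ncol(starts))) {
    opt <- tryCatch(
      stats::optim(starts[, s], fn, gr, method = "L-BFGS-B",
                   lower = rep(0, k),
                   control = list(maxit = maxit, factr = 1e4, pgtol = 1e-7)),
      error = function(e) NULL)
    records[[s]] <- opt
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) {
    rix_abort("REML optimization failed from every start", "rixmm_fit_error")
  }

  lambda <- best$par
  lambda[lambda < 1e-10] <- 0
  ev <- eval_at(lambda)

  ## projected gradient at the reported optimum (boundary components with an
  ## inward-pointing gradient do not count against convergence)
  g <- ev$grad
  g[lambda == 0 & g > 0] <- 0
  conv <- list(
    code = best$convergence,
    message = best$message,
    n_starts = ncol(starts),
    start_values = vapply(records, function(r) if (is.null(r)) NA_real_ else r$value,
                          numeric(1L)),
    iterations = best$counts[["function"]],
    projected_gradient_norm = sqrt(sum(g^2)),
    active_bounds = cr$effects[lambda == 0])
  if (best$convergence != 0L && conv$projected_gradient_norm > 1e-3) {
    rix_abort(sprintf("REML did not converge (code %d, |proj grad| = %.3g); best deviance %.6f",
                      best$convergence, conv$projected_gradient_norm, best$value),
              "rixmm_fit_error")
  }

  if (ev$sigma2_eps < 1e-8 * stats::var(frame$Y)) {
    rix_abort(sprintf("degenerate fit: residual variance estimated at %.3g (response variance %.3g)",
                      ev$sigma2_eps, stats::var(frame$Y)), "rixmm_fit_error")
  }

  build_fit(frame, cr, lambda, ev, conv)
}

build_fit <- function(frame, cr, lambda, ev, convergence) {
  s2e <- ev$sigma2_eps
  sigma2 <- stats::setNames(c(lambda * s2e, s2e), c(cr$effects, "residual"))
  K <- ev$XtViX_chol
  Kinv <- backsolve(K, diag(cr$p))
  vcov_beta <- s2e * tcrossprod(Kinv)    # (X'V^-1X)^-1 on the absolute scale
  dimnames(vcov_beta) <- list(colnames(cr$X), colnames(cr$X))
  beta <- stats::setNames(ev$beta, colnames(cr$X))
  structure(
    list(frame = frame, effects = cr$effects,
         lambda = stats::setNames(lambda, cr$effects),
         sigma2 = sigma2,
         beta = beta, se_beta = sqrt(diag(vcov_beta)), vcov_beta = vcov_beta,
         loglik = -0.5 * ev$m2ll,
         n = cr$n, p = cr$p,
         convergence = convergence),
    class = "rix_fit")
}

#' @export
print.rix_fit <- function(x, ...) {
  cat(sprintf("REML fit: endpoint '%s', n = %d, restricted logLik = %.4f\n",
              x$frame$endpoint, x$n, x$loglik))
  cat("Fixed effects:\n")
  print(round(cbind(estimate = x$beta, se = x$se_beta), 5))
  cat("Variance components:\n")
  print(signif(x$sigma2, 5))
  invisible(x)
}

#' Assemble the fitted random-effect covariance G
#'
#' @param fit A [reml_fit()] result.
#' @return Block-diagonal matrix `diag(sigma2_j)` over all random-effect
#'   columns, with column labels.
#' @export
get_G <- function(fit) {
  stopifnot(inherits(fit, "rix_fit"))
  Zlist <- fit$frame$design$Z
  v <- unlist(lapply(fit$effects, function(e) {
    rep(fit$sigma2[[e]], ncol(Zlist[[e]]))
  }))
  labels <- unlist(lapply(fit$effects, function(e) {
    paste(e, colnames(Zlist[[e]]), sep = ".")
  }))
  G <- diag(v, nrow = length(v))
  dimnames(G) <- list(labels, labels)
  G
}

#' Assemble the fitted marginal covariance V of the response
#'
#' @param fit A [reml_fit()] result.
#' @return Dense n x n matrix `sum_j sigma2_j Z_j Z_j' + sigma2_e I`.
#' @export
get_V <- function(fit) {
  stopifnot(inherits(fit, "rix_fit"))
  n <- fit$n
  V <- diag(fit$sigma2[["residual"]], n)
  for (e in fit$effects) {
    Zj <- fit$frame$design$Z[[e]]
    V <- V + fit$sigma2[[e]] * tcrossprod(Zj)
  }
  V
}

## ------------------------------------------------------------------------
## Hypothesis tests

#' Boundary-corrected likelihood ratio test of one variance component
#'
#' The null value of a variance component lies on the boundary of the
#' parameter space, so the usual chi-square(1) reference distribution is
#' wrong; the asymptotic null is the 50:50 mixture of a point mass at zero
#' and chi-square(1).  Both the mixture p-value and the naive chi-square(1)
#' p-value are reported.  The statistic is floored at zero (numerical
#' optimization can leave a tiny negative difference).
#'
#' @param full,reduced [reml_fit()] results on the same frame; `reduced`
#'   must omit exactly one random effect of `full`.
#' @return An object of class `rix_test` with the statistic, the tested
#'   component, and `p_value` (mixture) / `p_naive` (chi-square(1)).
#' @export
lrt_variance_component <- function(full, reduced) {
  stopifnot(inherits(full, "rix_fit"), inherits(reduced, "rix_fit"))
  if (!isTRUE(all.equal(full$frame$Y, reduced$frame$Y)) ||
      full$n != reduced$n) {
    rix_abort("full and reduced fits are not on the same model frame",
              "rixmm_integrity_error")
  }
  dropped <- setdiff(full$effects, reduced$effects)
  if (length(dropped) != 1L || length(full$effects) != length(reduced$effects) + 1L) {
    rix_abort("reduced model must omit exactly one random effect of the full model",
              "rixmm_schema_error")
  }
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6) {
    warning(sprintf("LRT statistic %.3g < 0; full-model optimum may be suboptimal", stat))
  }
  stat <- max(stat, 0)
  structure(
    list(kind = "LRT", statistic = stat, df = 1L,
         component = dropped,
         p_value = 0.5 * stats::pchisq(stat, df = 1L, lower.tail = FALSE),
         p_naive = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
         null = sprintf("sigma2_%s = 0 (boundary; 50:50 mixture of chi^2_0 and chi^2_1)",
                        dropped)),
    class = "rix_test")
}

#' @export
print.rix_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$kind,
              x$statistic,
              if (x$kind == "F") sprintf("(%d, %.1f)", x$df[1L], x$df[2L])
              else as.character(x$df),
              x$p_value))
  cat("  null:", x$null, "\n")
  invisible(x)
}

## Vbeta(theta) = sigma2_e * (X' V*(lambda)^-1 X)^-1 at absolute components
vbeta_at <- function(sigma2_comps, s2e, cr) {
  lambda <- sigma2_comps / s2e
  ev <- reml_eval(lambda, cr)
  K <- ev$XtViX_chol
  Kinv <- backsolve(K, diag(cr$p))
  s2e * tcrossprod(Kinv)
}

## -2 restricted loglik on the absolute sigma2 scale (for the observed
## information used by the Satterthwaite step)
m2ll_abs <- function(theta, cr) {
  s2e <- theta[length(theta)]
  comps <- theta[-length(theta)]
  ev <- reml_eval(comps / s2e, cr)
  n <- cr$n; p <- cr$p
  ev$m2ll - (n - p) * (1 + log(ev$sigma2_eps)) +
    (n - p) * log(s2e) + ev$sigma2_eps * (n - p) / s2e
}

## central-difference Hessian; callers guarantee x - h > 0 elementwise
numeric_hessian <- function(f, x, h) {
  m <- length(x)
  H <- matrix(NA_real_, m, m)
  f0 <- f(x)
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Wald F test of fixed-effect contrasts
#'
#' Tests `L beta = 0` with the F statistic
#' `(L b)' (L Vb L')^-1 (L b) / r` from the GLS coefficient covariance.
#' The denominator degrees of freedom use a Satterthwaite-style
#' approximation: for each contrast row, `ddf = 2 (l'Vb l)^2 / Var(l'Vb l)`,
#' with the variance obtained from the delta method using the observed REML
#' information of the variance components (variance components estimated at
#' zero are held fixed).  With no random effects in the model this reduces
#' to the classical residual degrees of freedom `n - p` exactly.  Multi-row
#' contrasts use the mean of the per-row degrees of freedom.
#'
#' @param fit A [reml_fit()] result.
#' @param contrast Either a coefficient name, or an `r x p` numeric matrix
#'   of contrast rows (columns ordered as `fit$beta`).
#' @return An object of class `rix_test` with the F statistic,
#'   `(num df, denom df)`, the p-value, and (for single rows) the signed
#'   t statistic.
#' @export
wald_f_fixed <- function(fit, contrast) {
  stopifnot(inherits(fit, "rix_fit"))
  p <- fit$p
  if (is.character(contrast)) {
    idx <- match(contrast, names(fit$beta))
    if (anyNA(idx)) {
      rix_abort(sprintf("unknown coefficient(s): %s",
                        paste(contrast[is.na(idx)], collapse = ", ")),
                "rixmm_schema_error")
    }
    L <- matrix(0, length(idx), p)
    L[cbind(seq_along(idx), idx)] <- 1
  } else {
    L <- rbind(contrast)
    if (ncol(L) != p) {
      rix_abort(sprintf("contrast has %d columns; model has %d coefficients",
                        ncol(L), p), "rixmm_schema_error")
    }
  }
  r <- nrow(L)
  if (qr(L)$rank < r) {
    rix_abort("contrast rows are linearly dependent (duplicated or redundant rows)",
              "rixmm_rank_error")
  }

  Vb <- fit$vcov_beta
  Lb <- drop(L %*% fit$beta)
  LVbL <- L %*% Vb %*% t(L)
  Fstat <- drop(crossprod(Lb, solve(LVbL, Lb))) / r

  k <- length(fit$effects)
  n <- fit$n
  if (k == 0L) {
    ddf <- n - p
  } else {
    cr <- reml_cross(fit$frame)
    active <- fit$lambda > 0
    s2e <- fit$sigma2[["residual"]]
    theta_hat <- c(fit$sigma2[fit$effects][active], residual = s2e)
    m <- length(theta_hat)
    vb_fun <- function(theta) {
      comps <- fit$sigma2[fit$effects]
      comps[active] <- theta[-m]
      vbeta_at(comps, theta[m], cr)
    }
    h <- pmin(pmax(abs(theta_hat) * 1e-4, 1e-10), theta_hat / 2)
    ## observed information of -2 loglik wrt the active components
    m2_fun <- function(theta) {
      comps <- fit$sigma2[fit$effects]
      comps[active] <- theta[-m]
      m2ll_abs(c(comps, theta[m]), cr)
    }
    A <- 0.5 * numeric_hessian(m2_fun, theta_hat, h)  # information of loglik
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    ddf_rows <- rep(NA_real_, r)
    if (!is.null(Ainv)) {
      for (i in seq_len(r)) {
        li <- L[i, ]
        gfun <- function(theta) drop(t(li) %*% vb_fun(theta) %*% li)
        g0 <- gfun(theta_hat)
        grad <- vapply(seq_len(m), function(j) {
          tp <- theta_hat; tp[j] <- theta_hat[j] + h[j]
          tm <- theta_hat; tm[j] <- max(theta_hat[j] - h[j], 1e-300)
          (gfun(tp) - gfun(tm)) / (tp[j] - tm[j])
        }, numeric(1L))
        varg <- drop(t(grad) %*% Ainv %*% grad)
        if (is.finite(varg) && varg > 0) ddf_rows[i] <- 2 * g0^2 / varg
      }
    }
    ddf <- mean(ddf_rows, na.rm = TRUE)
    if (!is.finite(ddf)) ddf <- n - p
    ddf <- min(max(ddf, 1), n - p)
  }

  pval <- stats::pf(Fstat, r, ddf, lower.tail = FALSE)
  out <- list(kind = "F", statistic = Fstat, df = c(num = r, den = ddf),
              p_value = pval,
              null = sprintf("L beta = 0 (%d contrast row%s)", r,
                             if (r > 1L) "s" else ""))
  if (r == 1L) out$t <- sign(Lb) * sqrt(Fstat)
  structure(out, class = "rix_test")
}
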