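#' Restricted log-likelihood of the multi-environment model
#'
#' Evaluates the REML log-likelihood of the model y = mu_env + g + e for a
#' training design, with fixed per-environment means, genetic covariance
#' given by the compound-symmetry structure over the kinship, and
#' heteroscedastic independent residuals.
#'
#' @param K A `genomic_relationship` (or symmetric matrix).
#' @param design A [training_design].
#' @param y A [phenotype_set] or flat numeric vector (environment-major).
#' @param vc A [variance_components].
#' @return The restricted log-likelihood (scalar, includes constants).
#' @export
restricted_loglik <- function(K, design, y, vc) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  yv <- flatten_phenotypes(y, design)
  env <- rep(seq_along(design$subsets), design$sizes)
  tt <- length(design$subsets)
  ntr <- length(yv)
  X <- matrix(0, ntr, tt)
  X[cbind(seq_len(ntr), env)] <- 1
  V <- gtr_matrix(Km, design$subsets, vc) + diag(vc$sigma_e[env], ntr)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), yv))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(-Inf)
  logdetX <- 2 * sum(log(diag(chx)))
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Vi_y)))
  yPy <- sum(yv * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  -0.5 * ((ntr - tt) * log(2 * pi) + logdetV + logdetX + yPy)
}

#' Convergence settings for [fit_reml()]
#'
#' @param tol Relative tolerance on the log-likelihood improvement.
#' @param max_iter Iteration cap for the optimizer.
#' @param floor_frac Variance floor as a fraction of the phenotypic variance;
#'   estimates below it are pinned at the floor.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(tol = 1e-6, max_iter = 200L, floor_frac = 1e-6) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 floor_frac = floor_frac),
            class = "reml_control")
}

#' REML estimation of the variance components
#'
#' Maximizes the restricted log-likelihood over the per-environment genetic
#' variances, the common genetic covariance tau0 and the per-environment
#' residual variances (2T + 1 parameters). Variances are optimized on the
#' log scale; tau0 is parameterized as tanh(z) times the geometric mean of
#' the two smallest genetic variances, which keeps the genetic covariance
#' matrix positive semidefinite for two environments (a numerical check
#' rejects non-PSD proposals for three or more). A Nelder-Mead pass from a
#' method-of-moments start is polished by BFGS.
#'
#' @inheritParams restricted_loglik
#' @param opts A [reml_control].
#' @return An object of class `reml_fit` with `vc` (the estimates),
#'   `env_means`, `loglik`, `converged` and `n_iter`.
#' @export
fit_reml <- function(K, design, y, opts = reml_control()) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  yv <- flatten_phenotypes(y, design)
  tt <- length(design$subsets)
  sizes <- design$sizes
  if (any(sizes < 2L)) stop("each environment needs at least 2 records", call. = FALSE)
  if (sum(sizes) <= tt + 2L) stop("too few records for REML", call. = FALSE)
  env <- rep(seq_len(tt), sizes)

  vfloor <- opts$floor_frac * stats::var(yv)
  unpack <- function(par) {
    sg <- exp(par[seq_len(tt)])
    # tanh keeps |tau0| below the geometric mean of the two smallest genetic
    # variances: the exact PSD boundary for T = 2
    cap <- sqrt(prod(sort(sg)[seq_len(min(2L, tt))]))
    tau0 <- tanh(par[tt + 1L]) * cap
    se <- exp(par[tt + 1L + seq_len(tt)])
    omega <- matrix(tau0, tt, tt); diag(omega) <- sg
    if (tt > 2L &&
        min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) < 0) {
      return(NULL)
    }
    list(sg = sg, tau0 = tau0, se = se)
  }
  nll <- function(par) {
    th <- unpack(par)
    if (is.null(th)) return(1e10)
    vc <- tryCatch(variance_components(th$sg, th$tau0, th$se),
                   error = function(e) NULL)
    if (is.null(vc)) return(1e10)
    ll <- restricted_loglik(Km, design, yv, vc)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # method-of-moments start: split each environment's phenotypic variance
  # half genetic, half residual; moderate positive genetic correlation
  vy <- vapply(split(yv, env), stats::var, numeric(1))
  vy[!is.finite(vy) | vy <= 0] <- stats::var(yv)
  par0 <- c(log(0.5 * vy), atanh(0.5), log(0.5 * vy))

  fit1 <- stats::optim(par0, nll, method = "Nelder-Mead",
                       control = list(maxit = max(500L, 50L * opts$max_iter %/% 10L),
                                      reltol = opts$tol))
  fit2 <- stats::optim(fit1$par, nll, method = "BFGS",
                       control = list(maxit = opts$max_iter, reltol = opts$tol))
  best <- if (fit2$value <= fit1$value) fit2 else fit1
  th <- unpack(best$par)
  sg <- pmax(th$sg, vfloor)
  se <- pmax(th$se, vfloor)
  vc <- variance_components(sg, th$tau0, se)

  bundle <- build_covariances(Km, design, vc)
  ghat <- blup_training(bundle, yv)
  env_means <- vapply(seq_len(tt), function(j) {
    mean(yv[env == j]) - mean(ghat[env == j])
  }, numeric(1))

  structure(list(vc = vc, env_means = env_means,
                 loglik = restricted_loglik(Km, design, yv, vc),
                 converged = fit2$convergence == 0 || fit1$convergence == 0,
                 n_iter = sum(fit1$counts[1], fit2$counts[1], na.rm = TRUE)),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit: loglik =", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$vc)
  cat("env_means:", paste(format(x$env_means, digits = 5), collapse = ", "), "\n")
  invisible(x)
}
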