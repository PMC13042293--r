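#' Configuration of a simulation experiment
#'
#' Defines the generative truth for phenotype simulation under the
#' multi-environment model: fixed environment means, compound-symmetry
#' genetic (co)variances and residual variances. Residual variances may be
#' given directly or derived from a genomic heritability as
#' sigma2_E = sigma2_G * (1 - h2) / h2 per environment.
#'
#' @param env_means Numeric vector mu_1..mu_T of environment means (trait
#'   units).
#' @param sigma_gxe Per-environment genetic variances.
#' @param tau0 Common genetic covariance between environments.
#' @param heritability Genomic heritability in (0, 1); used to derive the
#'   residual variances when `sigma_e` is not supplied.
#' @param sigma_e Optional per-environment residual variances (overrides
#'   `heritability`).
#' @param n_replicates Number of simulated datasets.
#' @param master_seed Integer master seed; replicate r uses seed
#'   master_seed + r.
#' @param prediction_mode `"known_vc"` (BLUP under the true variance
#'   components) or `"reml"` (re-estimate them per replicate).
#' @return An object of class `simulation_config` (with the truth as a
#'   [variance_components] in `$vc`).
#' @export
simulation_config <- function(env_means, sigma_gxe, tau0, heritability = NULL,
                              sigma_e = NULL, n_replicates = 2000L,
                              master_seed,
                              prediction_mode = c("known_vc", "reml")) {
  prediction_mode <- match.arg(prediction_mode)
  tt <- length(env_means)
  if (length(sigma_gxe) != tt) {
    stop("env_means and sigma_gxe must have the same length", call. = FALSE)
  }
  if (is.null(sigma_e)) {
    if (is.null(heritability) || heritability <= 0 || heritability >= 1) {
      stop("supply sigma_e, or heritability in (0, 1)", call. = FALSE)
    }
    sigma_e <- sigma_gxe * (1 - heritability) / heritability
  }
  if (!is_count(n_replicates, 1L)) stop("n_replicates must be >= 1", call. = FALSE)
  if (missing(master_seed)) stop("master_seed is required", call. = FALSE)
  structure(list(env_means = as.numeric(env_means),
                 vc = variance_components(sigma_gxe, tau0, sigma_e),
                 heritability = heritability,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 prediction_mode = prediction_mode),
            class = "simulation_config")
}

#' Simulate true breeding values and phenotypes for one replicate
#'
#' Draws candidate genotypic values h ~ MVN(0, omega_g Kronecker K) through a
#' positive-semidefinite square root (negative eigenvalues clipped at zero)
#' and independent residuals per environment. TBV = mu_j + h_ij and
#' phenotype = TBV + e_ij. The replicate seed is `master_seed + replicate`,
#' so any replicate can be regenerated in isolation.
#'
#' @param K A `genomic_relationship` (or symmetric matrix).
#' @param cfg A [simulation_config].
#' @param replicate Replicate index (>= 1).
#' @param root_g Optional cached PSD square root of omega_g Kronecker K
#'   (avoids re-factorizing across replicates).
#' @return An object of class `simulated_trial` with `tbv` and `phenotypes`
#'   (both ncp x T matrices), `h` (genotypic values, ncp x T) and
#'   `replicate_seed`.
#' @export
simulate_truth <- function(K, cfg, replicate, root_g = NULL) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  stopifnot(inherits(cfg, "simulation_config"), is_count(replicate, 1L))
  ncp <- nrow(Km)
  tt <- length(cfg$env_means)
  if (is.null(root_g)) root_g <- psd_sqrt(kronecker(cfg$vc$omega_g, Km))
  seed <- (cfg$master_seed + replicate) %% .Machine$integer.max
  draws <- with_seed(seed, {
    z <- stats::rnorm(tt * ncp)
    e <- matrix(stats::rnorm(ncp * tt, sd = rep(sqrt(cfg$vc$sigma_e), each = ncp)),
                ncp, tt)
    list(h = matrix(drop(root_g %*% z), ncp, tt), e = e)
  })
  tbv <- sweep(draws$h, 2L, cfg$env_means, `+`)
  structure(list(tbv = tbv, phenotypes = tbv + draws$e, h = draws$h,
                 replicate_seed = seed),
            class = "simulated_trial")
}

# Training phenotype vector (environment-major) for a design from an
# ncp x T phenotype matrix.
design_phenotypes <- function(pheno, design) {
  unlist(lapply(seq_along(design$subsets), function(j) {
    pheno[design$subsets[[j]], j]
  }), use.names = FALSE)
}

# Ranking + correlation metrics for one context.
context_metrics <- function(tbv, gebv, k) {
  pi <- rank_permutation(tbv, gebv)
  c(ndcg = ndcg_at_k(tbv, pi, k),
    src = if (k >= 2L) src_at_k(pi, k) else NA_real_,
    rs_ratio = rs_ratio_at_k(pi, k),
    pearson = stats::cor(tbv, gebv))
}

#' Run a simulation experiment comparing training designs
#'
#' The full evaluation loop: for each replicate, simulate genotypic values
#' and phenotypes from the model truth, extract each design's training
#' records, predict every candidate's genotypic value in every environment
#' (BLUP under the true variance components, or REML-estimated ones), and
#' score the predicted rankings against the true ones at k = the top
#' `fraction` of candidates. Contexts are each environment plus "overall"
#' (environment-averaged values). REML replicates that fail to converge fall
#' back to the known-truth BLUP and are counted. The rank correlation needs
#' at least two selected candidates and is reported as NA when k = 1.
#'
#' @param K A `genomic_relationship` (or symmetric matrix).
#' @param designs Named list of [training_design] objects.
#' @param cfg A [simulation_config].
#' @param fraction Selected top fraction defining k (default 0.05).
#' @return A data frame of class `metric_report` with columns `design`,
#'   `context`, `metric`, `mean`, `sd`, `k`, `n_replicates`; the number of
#'   REML fallbacks is attached as attribute `"n_fallback"`.
#' @export
run_experiment <- function(K, designs, cfg, fraction = 0.05) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(names(designs)) || any(names(designs) == "")) {
    stop("designs must be a named list", call. = FALSE)
  }
  ncp <- nrow(Km)
  tt <- length(cfg$env_means)
  k <- top_k(ncp, fraction)
  contexts <- c(paste0("env", seq_len(tt)), "overall")
  metrics <- c("ndcg", "src", "rs_ratio", "pearson")

  root_g <- psd_sqrt(kronecker(cfg$vc$omega_g, Km))
  # data-free BLUP kernels under the truth: h_hat = H %*% y_tr
  kernels <- lapply(designs, function(d) {
    b <- build_covariances(Km, d, cfg$vc)
    b$G_cp_tr %*% qkernel(b$G_tr, b$M_tr)
  })

  res <- array(NA_real_,
               dim = c(cfg$n_replicates, length(designs), length(contexts),
                       length(metrics)),
               dimnames = list(NULL, names(designs), contexts, metrics))
  n_fallback <- 0L

  for (r in seq_len(cfg$n_replicates)) {
    trial <- simulate_truth(Km, cfg, r, root_g = root_g)
    for (d in seq_along(designs)) {
      des <- designs[[d]]
      ytr <- design_phenotypes(trial$phenotypes, des)
      if (cfg$prediction_mode == "reml") {
        fit <- tryCatch(fit_reml(Km, des, ytr), error = function(e) NULL)
        if (!is.null(fit) && fit$converged) {
          b <- build_covariances(Km, des, fit$vc)
          hmat <- matrix(drop(b$G_cp_tr %*% (qkernel(b$G_tr, b$M_tr) %*% ytr)),
                         ncp, tt)
        } else {
          n_fallback <- n_fallback + 1L
          hmat <- matrix(drop(kernels[[d]] %*% ytr), ncp, tt)
        }
      } else {
        hmat <- matrix(drop(kernels[[d]] %*% ytr), ncp, tt)
      }
      for (j in seq_len(tt)) {
        res[r, d, j, ] <- context_metrics(trial$tbv[, j], hmat[, j], k)
      }
      res[r, d, tt + 1L, ] <- context_metrics(rowMeans(trial$tbv),
                                              rowMeans(hmat), k)
    }
  }

  out <- expand.grid(design = names(designs), context = contexts,
                     metric = metrics, stringsAsFactors = FALSE)
  out$mean <- mapply(function(d, cx, m) mean(res[, d, cx, m]),
                     out$design, out$context, out$metric)
  out$sd <- mapply(function(d, cx, m) stats::sd(res[, d, cx, m]),
                   out$design, out$context, out$metric)
  out$k <- k
  out$n_replicates <- cfg$n_replicates
  attr(out, "n_fallback") <- n_fallback
  class(out) <- c("metric_report", class(out))
  out
}
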