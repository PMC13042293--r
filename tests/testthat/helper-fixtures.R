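# Shared fixtures: small synthetic panels and kinships built in code.

# Kinship from a simulated inbred panel; cached per (ncp, p, seed) within a
# test run.
panel_grm <- local({
  cache <- new.env(parent = emptyenv())
  function(ncp, p = 50 * ncp %/% 4, seed = 42) {
    key <- paste(ncp, p, seed, sep = "_")
    if (is.null(cache[[key]])) {
      m <- simulate_marker_matrix(ncp = ncp, p = p, seed = seed)
      cache[[key]] <- compute_grm(standardize_markers(filter_maf(m, 0.05)))
    }
    cache[[key]]
  }
})

# Direct solve of Henderson's mixed-model equations with explicit fixed
# effects: independent oracle for the absorbed-projection BLUP.
henderson_solve <- function(K, design, vc, y) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else K
  env <- rep(seq_along(design$subsets), design$sizes)
  ntr <- sum(design$sizes)
  tt <- length(design$subsets)
  X <- stats::model.matrix(~ 0 + factor(env, levels = seq_len(tt)))
  Rinv <- diag(1 / vc$sigma_e[env], ntr)
  G <- metgs:::gtr_matrix(Km, design$subsets, vc)
  Ginv <- solve(G + diag(1e-10, ntr))
  lhs <- rbind(cbind(crossprod(X, Rinv) %*% X, crossprod(X, Rinv)),
               cbind(Rinv %*% X, Rinv + Ginv))
  rhs <- c(crossprod(X, Rinv %*% y), Rinv %*% y)
  sol <- unname(solve(lhs, rhs))
  list(beta = sol[seq_len(tt)], g = sol[-seq_len(tt)])
}

# Vectorized model draws for Monte-Carlo oracles: returns H (N x n draws of
# true genotypic values, environment-major) and Hhat (their BLUPs from
# phenotypes simulated under the same variance components).
mc_draws <- function(K, design, vc, n, seed = 99) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else K
  ncp <- nrow(Km)
  tt <- length(design$subsets)
  b <- build_covariances(Km, design, vc)
  Lg <- metgs:::psd_sqrt(b$G_cp)
  env <- rep(seq_len(tt), design$sizes)
  tr_rows <- (env - 1L) * ncp + unlist(design$subsets)
  Hker <- b$G_cp_tr %*% metgs:::qkernel(b$G_tr, b$M_tr)
  withr_seed <- function(expr) metgs:::with_seed(seed, expr)
  withr_seed({
    H <- Lg %*% matrix(stats::rnorm(tt * ncp * n), tt * ncp, n)
    E <- matrix(stats::rnorm(length(tr_rows) * n,
                             sd = rep(sqrt(vc$sigma_e[env]), n)),
                length(tr_rows), n)
    list(H = H, Hhat = Hker %*% (H[tr_rows, , drop = FALSE] + E),
         A = prediction_covariance(b), B = b$G_cp)
  })
}
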