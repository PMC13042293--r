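# Covariance assembly, BLUP and the prediction covariance.

vc2 <- variance_components(c(1, 1), tau0 = 0.5, sigma_e = c(1, 1))

test_that("covariance blocks match their definitions", {
  K <- panel_grm(8)
  # single environment: no cross-covariance blocks
  vc1 <- variance_components(2, tau0 = 0, sigma_e = 1.5)
  d1 <- training_design(list(c(1, 3, 5)), ncp = 8)
  b1 <- build_covariances(K, d1, vc1)
  expect_equal(b1$G_tr, 2 * K$K[c(1, 3, 5), c(1, 3, 5)], ignore_attr = TRUE)

  # two environments: Kronecker structure of the candidate covariance
  ncp <- 3
  K3 <- structure(list(K = K$K[1:3, 1:3] + diag(0.5, 3),
                       genotype_ids = K$genotype_ids[1:3]),
                  class = "genomic_relationship")
  d <- training_design(list(1:2, 2:3), ncp = 3)
  b <- build_covariances(K3, d, vc2)
  expect_equal(b$G_cp,
               rbind(cbind(K3$K, 0.5 * K3$K), cbind(0.5 * K3$K, K3$K)),
               ignore_attr = TRUE)
  expect_equal(b$G_tr[1:2, 3:4], 0.5 * K3$K[1:2, 2:3], ignore_attr = TRUE)
  expect_equal(b$G_cp_tr[4:6, 1:2], 0.5 * K3$K[, 1:2], ignore_attr = TRUE)

  # the centering projection annihilates per-environment constants and is
  # idempotent up to the residual-precision factor
  ones <- c(rep(1, 2), rep(0, 2))
  expect_equal(drop(b$M_tr %*% ones), rep(0, 4))
  expect_equal(b$M_tr %*% b$M_tr, b$M_tr / vc2$sigma_e[1], tolerance = 1e-12)
})

test_that("mismatched dimensions and invalid components are rejected", {
  K <- panel_grm(8)
  d <- training_design(list(1:3, 4:6), ncp = 8)
  expect_error(build_covariances(K, d, variance_components(1, 0, 1)), "environments")
  expect_error(variance_components(c(1, 1), tau0 = 1.5, sigma_e = c(1, 1)),
               "positive semidefinite")
  b <- build_covariances(K, d, vc2)
  expect_error(blup_training(b, rnorm(5)), "length")
})

test_that("BLUP matches a direct Henderson solve and its invariances", {
  K <- panel_grm(8)
  vc <- variance_components(c(1.3, 0.8), tau0 = 0.4, sigma_e = c(0.9, 1.1))
  d <- training_design(list(c(1, 2, 5, 7), c(2, 3, 6, 8)), ncp = 8)
  b <- build_covariances(K, d, vc)
  y <- metgs:::with_seed(21, rnorm(8, mean = 50))

  g <- blup_training(b, y)
  oracle <- henderson_solve(K, d, vc, y)
  expect_equal(unname(g), oracle$g, tolerance = 1e-6)

  # constant phenotypes within environments carry no genetic signal
  expect_equal(unname(blup_training(b, c(rep(3, 4), rep(-7, 4)))), rep(0, 8),
               tolerance = 1e-10)
  # environment-wise shifts are absorbed
  y2 <- y + rep(c(100, -40), each = 4)
  expect_equal(blup_training(b, y2), g, tolerance = 1e-8)
  pr <- predict_candidates(b, y, covariance = FALSE)
  pr2 <- predict_candidates(b, y2, covariance = FALSE)
  expect_equal(pr2$h_hat_cp, pr$h_hat_cp, tolerance = 1e-8)
  # jointly rescaling all variance components leaves the BLUP unchanged
  vcs <- variance_components(2 * vc$sigma_gxe, 2 * vc$tau0, 2 * vc$sigma_e)
  bs <- build_covariances(K, d, vcs)
  expect_equal(blup_training(bs, y), g, tolerance = 1e-8)
})

test_that("the two candidate-BLUP formulas agree", {
  K <- panel_grm(8)
  d <- training_design(list(c(1, 4, 6), c(2, 4, 7, 8)), ncp = 8)
  b <- build_covariances(K, d, vc2)
  y <- metgs:::with_seed(5, rnorm(7))
  pr <- predict_candidates(b, y)
  via_gtr <- drop(b$G_cp_tr %*% solve(b$G_tr + diag(1e-10, 7),
                                      blup_training(b, y)))
  expect_lt(max(abs(pr$h_hat_cp - via_gtr)), 1e-8)
  expect_equal(unname(pr$h_hat_mat[, 1]), unname(pr$h_hat_cp[1:8]))
})

test_that("singleton environments yield a zero prediction covariance", {
  K <- panel_grm(8)
  d <- training_design(list(3, 6), ncp = 8)
  b <- build_covariances(K, d, vc2)
  expect_equal(prediction_covariance(b), matrix(0, 16, 16), ignore_attr = TRUE)
  pr <- predict_candidates(b, c(1.7, -2.2))
  expect_equal(unname(pr$h_hat_cp), rep(0, 16))
})

test_that("prediction covariance is a shrunken PSD part of the prior", {
  K <- panel_grm(8)
  vc <- variance_components(c(1, 1.4), tau0 = 0.6, sigma_e = c(1, 0.7))
  for (seed in 1:3) {
    d <- random_design(8, c(4, 4), seed = seed)
    b <- build_covariances(K, d, vc)
    A <- prediction_covariance(b)
    expect_equal(A, t(A))
    expect_true(all(diag(A) <= diag(b$G_cp) + 1e-8))
    gap <- eigen(b$G_cp - A, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(gap), -1e-6)
    ratio <- diag(A) / diag(b$G_cp)
    expect_true(all(ratio >= -1e-10 & ratio < 1))
  }
})

test_that("Monte-Carlo moments reproduce the closed-form covariance", {
  K <- panel_grm(8)
  d <- training_design(list(c(1, 2, 5, 7), c(2, 3, 6, 8)), ncp = 8)
  n <- 50000
  mc <- mc_draws(K, d, vc2, n)
  var_hat <- tcrossprod(mc$Hhat) / n
  cov_cross <- mc$H %*% t(mc$Hhat) / n
  se_var <- sqrt((outer(diag(mc$A), diag(mc$A)) + mc$A^2) / n)
  se_cross <- sqrt((outer(diag(mc$B), diag(mc$A)) + mc$A^2) / n)
  # 5 SE: 256 (correlated) entries are compared simultaneously
  expect_true(all(abs(var_hat - mc$A) <= 5 * se_var + 1e-12))
  expect_true(all(abs(cov_cross - mc$A) <= 5 * se_cross + 1e-12))
})
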