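# CDmean(v2) and CDmean.MET design criteria.

test_that("degenerate all-singleton designs score zero with a warning", {
  K <- panel_grm(8)
  d <- training_design(list(2, 5), ncp = 8)
  expect_warning(s <- cdmean_v2(K, d), "single record")
  expect_equal(s, 0)
  expect_warning(sm <- cdmean_met(K, d), "single record")
  expect_equal(sm, 0)
})

test_that("criteria reduce to each other for one environment", {
  K <- panel_grm(8)
  vc1 <- variance_components(1, tau0 = 0, sigma_e = 1)
  spec_v <- criterion_spec("cdmean_v2", criterion_vc = vc1)
  spec_m <- criterion_spec("cdmean_met", criterion_vc = vc1)
  for (seed in 1:3) {
    d <- random_design(8, 4, seed = seed)
    expect_equal(cdmean_v2(K, d, spec_v), cdmean_met(K, d, spec_m),
                 tolerance = 1e-12)
  }
})

test_that("criterion scores match the generic prediction-covariance path", {
  K <- panel_grm(10)
  vc <- variance_components(c(1, 1), 0.5, c(1, 1))
  d <- random_design(10, c(5, 4), seed = 8)
  b <- build_covariances(K, d, vc)
  A <- prediction_covariance(b)
  B <- b$G_cp
  expect_equal(cdmean_v2(K, d), sum(diag(A) / diag(B)), tolerance = 1e-10)
  ncp <- 10
  ai <- vapply(seq_len(ncp), function(i) {
    pos <- c(i, ncp + i)
    sum(A[pos, pos])
  }, numeric(1))
  bi <- vapply(seq_len(ncp), function(i) {
    pos <- c(i, ncp + i)
    sum(B[pos, pos])
  }, numeric(1))
  expect_equal(cdmean_met(K, d), sum(ai / bi), tolerance = 1e-10)
})

test_that("adding an informative record strictly improves the score", {
  K <- panel_grm(8)
  d0 <- training_design(list(c(1, 2), 3), ncp = 8)
  d1 <- training_design(list(c(1, 2), c(3, 1)), ncp = 8)
  expect_gt(cdmean_v2(K, d1), cdmean_v2(K, d0))
  expect_gt(cdmean_met(K, d1), cdmean_met(K, d0))
})

test_that("environment order is exchangeable under exchangeable components", {
  K <- panel_grm(8)
  d <- training_design(list(c(1, 2, 5), c(3, 6, 7, 8)), ncp = 8)
  drev <- training_design(rev(d$subsets), ncp = 8)
  expect_equal(cdmean_v2(K, d), cdmean_v2(K, drev), tolerance = 1e-10)
  expect_equal(cdmean_met(K, d), cdmean_met(K, drev), tolerance = 1e-10)
})

test_that("sum and mean reporting rank designs identically", {
  K <- panel_grm(12)
  designs <- lapply(1:6, function(s) random_design(12, c(4, 4), seed = s))
  sums <- vapply(designs, function(d) cdmean_v2(K, d), numeric(1))
  means <- vapply(designs, function(d) {
    cdmean_v2(K, d, criterion_spec("cdmean_v2", report_mean = TRUE))
  }, numeric(1))
  expect_equal(order(sums), order(means))
  expect_equal(means, sums / 24, tolerance = 1e-12)
})

test_that("Monte-Carlo squared correlations reproduce both criteria", {
  K <- panel_grm(8)
  vc <- variance_components(c(1, 1), 0.5, c(1, 1))
  d <- training_design(list(c(1, 2, 5, 7), c(2, 3, 6, 8)), ncp = 8)
  n <- 50000
  mc <- mc_draws(K, d, vc, n)
  emp_v2 <- mean(vapply(1:16, function(l) {
    stats::cor(mc$H[l, ], mc$Hhat[l, ])^2
  }, numeric(1)))
  expect_lt(abs(emp_v2 - cdmean_v2(K, d) / 16), 0.01)
  Hbar <- (mc$H[1:8, ] + mc$H[9:16, ]) / 2
  Hhatbar <- (mc$Hhat[1:8, ] + mc$Hhat[9:16, ]) / 2
  emp_met <- mean(vapply(1:8, function(i) {
    stats::cor(Hbar[i, ], Hhatbar[i, ])^2
  }, numeric(1)))
  expect_lt(abs(emp_met - cdmean_met(K, d) / 8), 0.01)
})

test_that("design rankings are robust to the nominal variance setting", {
  K <- panel_grm(60, p = 600, seed = 17)
  designs <- lapply(1:20, function(s) random_design(60, c(15, 15), seed = 100 + s))
  base <- vapply(designs, function(d) cdmean_v2(K, d), numeric(1))
  variants <- list(
    variance_components(c(1, 1), 0.2, c(1, 1)),
    variance_components(c(1, 1), 0.8, c(1, 1)),
    variance_components(c(1, 2), 0.5, c(1, 1)),
    variance_components(c(1, 5), 0.5, c(1, 2)),
    variance_components(c(1, 1), 0.5, c(1, 5))
  )
  for (vc in variants) {
    alt <- vapply(designs, function(d) {
      cdmean_v2(K, d, criterion_spec("cdmean_v2", criterion_vc = vc))
    }, numeric(1))
    expect_gt(stats::cor(base, alt, method = "spearman"), 0.9)
  }
})
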