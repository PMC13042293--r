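#' Phenotypes aligned with a training design
#'
#' @param values List of numeric vectors y1..yT, one per environment, each
#'   aligned with the corresponding subset of the training design.
#' @param environment_labels Optional labels, length T.
#' @return An object of class `phenotype_set`.
#' @export
phenotype_set <- function(values, environment_labels = NULL) {
  if (!is.list(values)) values <- list(values)
  values <- lapply(values, as.numeric)
  labs <- environment_labels %||% paste0("E", seq_along(values))
  structure(list(values = values, environment_labels = labs),
            class = "phenotype_set")
}

# Concatenate a phenotype_set (or numeric vector) into the flat training
# vector, checking block lengths against the design.
flatten_phenotypes <- function(y, design) {
  if (inherits(y, "phenotype_set")) {
    if (length(y$values) != length(design$subsets) ||
        !all(lengths(y$values) == design$sizes)) {
      stop("phenotype blocks do not match the design sizes", call. = FALSE)
    }
    return(unlist(y$values, use.names = FALSE))
  }
  y <- as.numeric(y)
  if (length(y) != sum(design$sizes)) {
    stop("phenotype vector length does not match the design", call. = FALSE)
  }
  y
}

# --- internal model algebra -------------------------------------------------
#
# Flat ordering is environment-major throughout: candidate i in environment j
# sits at position (j-1)*ncp + i of any length-N vector, N = T*ncp.

# Training covariance G_tr: block (j,j') = omega_g[j,j'] * K[Sj, Sj'].
gtr_matrix <- function(K, subsets, vc) {
  idx <- unlist(subsets, use.names = FALSE)
  env <- rep(seq_along(subsets), lengths(subsets))
  vc$omega_g[env, env] * K[idx, idx, drop = FALSE]
}

# Residual precision projection M_tr: block diagonal with jth block
# (1/sigma_e[j]) * (I - J/nj); annihilates per-environment constants.
mtr_matrix <- function(sizes, sigma_e) {
  blocks <- lapply(seq_along(sizes), function(j) {
    n <- sizes[j]
    (diag(n) - matrix(1 / n, n, n)) / sigma_e[j]
  })
  ntr <- sum(sizes)
  M <- matrix(0, ntr, ntr)
  at <- 0L
  for (j in seq_along(sizes)) {
    rng <- at + seq_len(sizes[j])
    M[rng, rng] <- blocks[[j]]
    at <- at + sizes[j]
  }
  M
}

# Candidate-to-training cross covariance G_cp.tr (N x ntr): rows are the
# candidates in environment j, columns the training records; the scale on
# column c is omega_g[j, env(c)].
gcptr_matrix <- function(K, subsets, vc) {
  idx <- unlist(subsets, use.names = FALSE)
  env <- rep(seq_along(subsets), lengths(subsets))
  Kc <- K[, idx, drop = FALSE]
  do.call(rbind, lapply(seq_along(subsets), function(j) {
    Kc * rep(vc$omega_g[j, env], each = nrow(Kc))
  }))
}

# Q = (M_tr G_tr + I)^-1 M_tr, the data-to-BLUP kernel shared by the BLUP,
# the prediction covariance and both CD criteria. Symmetric in exact
# arithmetic; symmetrized here.
qkernel <- function(Gtr, Mtr) {
  ntr <- nrow(Gtr)
  Q <- solve(Mtr %*% Gtr + diag(ntr), Mtr)
  (Q + t(Q)) / 2
}

# --- exported surface -------------------------------------------------------

#' Assemble the covariance structure of a training design
#'
#' Builds the pieces of the multi-environment genomic BLUP: the training
#' covariance `G_tr` (compound-symmetry blocks of the kinship), the candidate
#' covariance `G_cp` = omega_g Kronecker K, the cross covariance `G_cp_tr`
#' and the residual precision projection `M_tr`. The flat candidate ordering
#' is environment-major: candidate i in environment j is entry
#' (j-1)*ncp + i.
#'
#' @param K A `genomic_relationship` (or plain symmetric matrix).
#' @param design A [training_design].
#' @param vc A [variance_components] with T matching the design.
#' @return An object of class `covariance_bundle` with elements `G_tr`,
#'   `G_cp`, `G_cp_tr`, `M_tr`, `design`, `vc` and `ncp`.
#' @export
build_covariances <- function(K, design, vc) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  stopifnot(inherits(design, "training_design"), inherits(vc, "variance_components"))
  tt <- length(design$subsets)
  if (length(vc$sigma_gxe) != tt) {
    stop("variance components have ", length(vc$sigma_gxe),
         " environments but the design has ", tt, call. = FALSE)
  }
  if (max(unlist(design$subsets)) > nrow(Km)) {
    stop("design indices exceed the candidate population size", call. = FALSE)
  }
  structure(list(G_tr = gtr_matrix(Km, design$subsets, vc),
                 G_cp = kronecker(vc$omega_g, Km),
                 G_cp_tr = gcptr_matrix(Km, design$subsets, vc),
                 M_tr = mtr_matrix(design$sizes, vc$sigma_e),
                 design = design, vc = vc, ncp = nrow(Km)),
            class = "covariance_bundle")
}

#' BLUP of the training genotypic values
#'
#' Henderson's mixed-model solution g_hat = (M_tr + G_tr^-1)^-1 M_tr y,
#' computed through the equivalent inversion-free form
#' G_tr (M_tr G_tr + I)^-1 M_tr y. Per-environment means are absorbed by the
#' centering projection in M_tr, so adding a constant to any environment's
#' phenotypes leaves the BLUP unchanged.
#'
#' @param bundle A `covariance_bundle` from [build_covariances()].
#' @param y A [phenotype_set] or flat numeric vector of length ntr
#'   (environment-major).
#' @return Numeric vector g_hat of length ntr.
#' @export
blup_training <- function(bundle, y) {
  stopifnot(inherits(bundle, "covariance_bundle"))
  yv <- flatten_phenotypes(y, bundle$design)
  Q <- qkernel(bundle$G_tr, bundle$M_tr)
  drop(bundle$G_tr %*% (Q %*% yv))
}

#' Predict candidate genotypic values and their covariance
#'
#' Computes h_hat_cp = G_cp.tr (M_tr G_tr + I)^-1 M_tr y, the BLUP of every
#' candidate's genotypic value in every environment, together with the
#' training BLUP and the prediction covariance A = Var(h_hat_cp).
#'
#' @inheritParams blup_training
#' @param covariance If `FALSE`, skip the N x N prediction covariance (cheaper
#'   when only point predictions are needed).
#' @return An object of class `prediction_result` with `g_hat_tr` (length
#'   ntr), `h_hat_cp` (length N, environment-major), `h_hat_mat` (ncp x T
#'   convenience layout) and `A` (N x N, or NULL).
#' @export
predict_candidates <- function(bundle, y, covariance = TRUE) {
  stopifnot(inherits(bundle, "covariance_bundle"))
  yv <- flatten_phenotypes(y, bundle$design)
  Q <- qkernel(bundle$G_tr, bundle$M_tr)
  Qy <- Q %*% yv
  h <- drop(bundle$G_cp_tr %*% Qy)
  g <- drop(bundle$G_tr %*% Qy)
  A <- NULL
  if (covariance) {
    CQ <- bundle$G_cp_tr %*% Q
    A <- CQ %*% t(bundle$G_cp_tr)
    A <- (A + t(A)) / 2
  }
  tt <- length(bundle$design$subsets)
  structure(list(g_hat_tr = g, h_hat_cp = h,
                 h_hat_mat = matrix(h, nrow = bundle$ncp, ncol = tt),
                 A = A),
            class = "prediction_result")
}

#' Prediction covariance of the candidate BLUPs
#'
#' A = G_cp.tr (M_tr G_tr + I)^-1 M_tr G_cp.tr', which equals both
#' Var(h_hat_cp) and Cov(h_cp, h_hat_cp). It depends only on the design, the
#' kinship and the variance components, never on phenotypes — this is what
#' makes CD-based design optimization possible before any phenotyping.
#'
#' @param bundle A `covariance_bundle`.
#' @return Symmetric N x N matrix.
#' @export
prediction_covariance <- function(bundle) {
  stopifnot(inherits(bundle, "covariance_bundle"))
  Q <- qkernel(bundle$G_tr, bundle$M_tr)
  A <- bundle$G_cp_tr %*% Q %*% t(bundle$G_cp_tr)
  (A + t(A)) / 2
}
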