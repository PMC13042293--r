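#' Specification of a CD design criterion
#'
#' The generalized coefficient of determination (CD) of a candidate's
#' genotypic value is the squared correlation between its true and BLUP-
#' predicted value; summed (or averaged) over candidates it scores how
#' informative a training design is for the whole population. The criterion
#' is evaluated under fixed nominal variance components — by default unit
#' genetic and residual variances in every environment and a common genetic
#' covariance of 0.5 — because CD-based design selection is insensitive to
#' their exact values.
#'
#' @param name `"cdmean_v2"` (per genotype-environment values) or
#'   `"cdmean_met"` (environment-averaged values).
#' @param criterion_vc Optional [variance_components] overriding the
#'   defaults; must match the number of environments of the designs scored.
#' @param report_mean If `TRUE`, scores are divided by the number of summed
#'   terms (N = T*ncp for cdmean_v2, ncp for cdmean_met). Ranking of designs
#'   is unaffected.
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(name = c("cdmean_v2", "cdmean_met"),
                           criterion_vc = NULL, report_mean = FALSE) {
  name <- match.arg(name)
  if (!is.null(criterion_vc)) stopifnot(inherits(criterion_vc, "variance_components"))
  structure(list(name = name, criterion_vc = criterion_vc,
                 report_mean = report_mean),
            class = "criterion_spec")
}

# Default nominal variance components for a T-environment criterion.
default_criterion_vc <- function(tt) {
  variance_components(sigma_gxe = rep(1, tt), tau0 = 0.5, sigma_e = rep(1, tt))
}

criterion_vc_for <- function(spec, tt) {
  vc <- spec$criterion_vc %||% default_criterion_vc(tt)
  if (length(vc$sigma_gxe) != tt) {
    stop("criterion variance components are for ", length(vc$sigma_gxe),
         " environments, design has ", tt, call. = FALSE)
  }
  vc
}

# Fast criterion evaluator on raw pieces (used by the GA inner loop).
# Returns the raw sum; callers divide for mean reporting.
cd_score <- function(K, subsets, vc, type = c("cdmean_v2", "cdmean_met"),
                     warn = TRUE) {
  type <- match.arg(type)
  tt <- length(subsets)
  sizes <- lengths(subsets)
  ncp <- nrow(K)
  if (all(sizes == 1L)) {
    # a single record per environment is annihilated by centering: no signal
    if (warn) warning("all environments have a single record; CD is 0")
    return(0)
  }
  env <- rep(seq_len(tt), sizes)
  idx <- unlist(subsets, use.names = FALSE)
  Gtr <- vc$omega_g[env, env] * K[idx, idx, drop = FALSE]
  Q <- qkernel(Gtr, mtr_matrix(sizes, vc$sigma_e))
  Kc <- K[, idx, drop = FALSE]
  dK <- diag(K)

  if (type == "cdmean_v2") {
    total <- 0
    skipped <- 0L
    for (j in seq_len(tt)) {
      Cj <- Kc * rep(vc$omega_g[j, env], each = ncp)
      a <- rowSums((Cj %*% Q) * Cj)      # diag of A for environment j
      b <- vc$omega_g[j, j] * dK         # diag of G_cp for environment j
      ok <- b > 0
      skipped <- skipped + sum(!ok)
      total <- total + sum(a[ok] / b[ok])
    }
    if (skipped > 0L && warn) {
      warning(skipped, " zero-variance candidate term(s) excluded")
    }
    total
  } else {
    # environment-averaged values: row sums of the per-environment blocks
    U <- Kc * rep(colSums(vc$omega_g)[env], each = ncp)
    a <- rowSums((U %*% Q) * U)          # A_i* summed over environment pairs
    b <- sum(vc$omega_g) * dK            # B_i* likewise
    ok <- b > 0
    if (any(!ok) && warn) {
      warning(sum(!ok), " zero-variance candidate term(s) excluded")
    }
    sum(a[ok] / b[ok])
  }
}

cd_eval <- function(K, design, spec) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  stopifnot(inherits(design, "training_design"), inherits(spec, "criterion_spec"))
  tt <- length(design$subsets)
  vc <- criterion_vc_for(spec, tt)
  s <- cd_score(Km, design$subsets, vc, spec$name)
  if (spec$report_mean) {
    s <- s / if (spec$name == "cdmean_v2") tt * nrow(Km) else nrow(Km)
  }
  s
}

#' CDmean(v2): expected squared accuracy over genotypes and environments
#'
#' Sum over all N = T*ncp candidate-environment pairs of
#' A(l,l) / B(l,l), where A is the prediction covariance of the candidate
#' BLUPs and B the diagonal of the candidate genetic covariance. Each term
#' is the squared correlation between a candidate's true and predicted
#' genotypic value in one environment, so the (mean) score estimates how
#' accurately the design will rank every candidate everywhere.
#'
#' @param K A `genomic_relationship` (or symmetric matrix).
#' @param design A [training_design].
#' @param spec A [criterion_spec]; defaults to the nominal unit-variance
#'   setting with tau0 = 0.5.
#' @return The criterion score (sum, or mean if `spec$report_mean`).
#' @export
cdmean_v2 <- function(K, design, spec = criterion_spec("cdmean_v2")) {
  spec$name <- "cdmean_v2"
  cd_eval(K, design, spec)
}

#' CDmean.MET: expected squared accuracy of environment-averaged values
#'
#' Sum over candidates of A_i* / B_i*, where A_i* and B_i* aggregate the
#' prediction and genetic covariances of candidate i over all environment
#' pairs (the 1/T^2 averaging factors cancel in the ratio). Scores how well
#' the design identifies genotypes with the best average performance across
#' environments. For a single environment it coincides with [cdmean_v2()].
#'
#' @inheritParams cdmean_v2
#' @return The criterion score (sum, or mean if `spec$report_mean`).
#' @export
cdmean_met <- function(K, design, spec = criterion_spec("cdmean_met")) {
  spec$name <- "cdmean_met"
  cd_eval(K, design, spec)
}
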