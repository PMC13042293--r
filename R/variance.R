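#' Variance components of the multi-environment genetic model
#'
#' The genetic covariance across environments is compound-symmetric: the
#' pooled genetic variance in environment j is `sigma_gxe[j]` (the sum of the
#' homogeneous additive variance and the environment-specific
#' genotype-by-environment variance) and every pair of environments shares
#' the common genetic covariance `tau0`. Residuals are independent within
#' environments with heteroscedastic variances `sigma_e`.
#'
#' @param sigma_gxe Numeric vector of per-environment genetic variances
#'   (all > 0), length T.
#' @param tau0 Common genetic covariance between any two environments.
#' @param sigma_e Numeric vector of per-environment residual variances
#'   (all > 0), length T.
#' @return An object of class `variance_components` with elements
#'   `sigma_gxe`, `tau0`, `sigma_e`, `omega_g` (T x T genetic covariance
#'   matrix) and `omega_e` (diagonal residual covariance matrix).
#' @export
variance_components <- function(sigma_gxe, tau0, sigma_e) {
  tt <- length(sigma_gxe)
  if (length(sigma_e) != tt) {
    stop("sigma_gxe and sigma_e must have the same length", call. = FALSE)
  }
  if (any(sigma_gxe <= 0) || any(sigma_e <= 0)) {
    stop("all variances must be > 0", call. = FALSE)
  }
  if (!is.numeric(tau0) || length(tau0) != 1L) {
    stop("tau0 must be a single number", call. = FALSE)
  }
  omega_g <- matrix(tau0, tt, tt)
  diag(omega_g) <- sigma_gxe
  if (tt > 1L && min(eigen(omega_g, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(sigma_gxe)) {
    stop("genetic covariance matrix is not positive semidefinite", call. = FALSE)
  }
  structure(list(sigma_gxe = as.numeric(sigma_gxe), tau0 = as.numeric(tau0),
                 sigma_e = as.numeric(sigma_e),
                 omega_g = omega_g, omega_e = diag(sigma_e, tt)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components: T =", length(x$sigma_gxe),
      "| sigma2_GxE =", paste(format(x$sigma_gxe), collapse = ", "),
      "| tau0 =", format(x$tau0),
      "| sigma2_E =", paste(format(x$sigma_e), collapse = ", "), "\n")
  invisible(x)
}

#' Genetic correlation between two environments
#'
#' rho = tau0 / sqrt(sigma2_GxE\[j\] * sigma2_GxE\[j'\]) under the
#' compound-symmetry genetic covariance. rho = 1 means genotype rankings are
#' identical across the two environments (no genotype-by-environment
#' interaction); low rho means strong interaction.
#'
#' @param vc A [variance_components] object.
#' @param j,j2 Environment indices.
#' @return The genetic correlation (scalar).
#' @export
genetic_correlation <- function(vc, j = 1L, j2 = 2L) {
  stopifnot(inherits(vc, "variance_components"))
  vc$tau0 / sqrt(vc$sigma_gxe[j] * vc$sigma_gxe[j2])
}
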