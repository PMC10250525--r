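#' Kullback-Leibler divergence between two multivariate Gaussians
#'
#' Closed-form KL divergence \eqn{D(N_0 \| N_1)} between
#' \eqn{N(\mu_0, \Sigma_0)} and \eqn{N(\mu_1, \Sigma_1)}:
#' \deqn{\tfrac12\left[\mathrm{tr}(\Sigma_1^{-1}\Sigma_0) +
#'   (\mu_1-\mu_0)^\top \Sigma_1^{-1}(\mu_1-\mu_0) - p +
#'   \ln\frac{\det\Sigma_1}{\det\Sigma_0}\right].}
#'
#' @param mean0,mean1 Numeric mean vectors of equal length `p`.
#' @param cov0,cov1 Covariance matrices (`p` by `p`, symmetric positive
#'   definite). A single positive number is expanded to `sigma2 * I_p`.
#' @return Nonnegative scalar, in nats.
#' @seealso [kl_symmetric()] for the symmetrized version used to calibrate
#'   component separation.
#' @examples
#' kl_mvn(0, 0.5, 1, 0.5)        # 1/(2 * 0.5) = 1
#' kl_mvn(c(0, 0), diag(2), c(0, 0), 2 * diag(2))
#' @export
kl_mvn <- function(mean0, cov0, mean1, cov1) {
  mean0 <- as.numeric(mean0)
  mean1 <- as.numeric(mean1)
  if (length(mean0) != length(mean1)) {
    stop("mean vectors must have the same length", call. = FALSE)
  }
  p <- length(mean0)
  cov0 <- expand_cov(cov0, p)
  cov1 <- expand_cov(cov1, p)
  L0 <- chol_spd(cov0)
  L1 <- chol_spd(cov1)
  # log-determinants from the Cholesky factors
  logdet0 <- 2 * sum(log(diag(L0)))
  logdet1 <- 2 * sum(log(diag(L1)))
  # tr(Sigma1^{-1} Sigma0) = || L1^{-T} L0^T ||_F^2 with upper factors
  A <- backsolve(L1, t(L0), transpose = TRUE)
  tr <- sum(A^2)
  d <- mean1 - mean0
  quad <- sum(backsolve(L1, d, transpose = TRUE)^2)
  0.5 * (tr + quad - p + logdet1 - logdet0)
}

#' Symmetrized Kullback-Leibler divergence
#'
#' The average of the two one-directional divergences,
#' \eqn{\tfrac12[D(N_0\|N_1) + D(N_1\|N_0)]}. When the two covariance
#' matrices are equal both directions coincide, and the value reduces to
#' \eqn{\|\mu_1-\mu_0\|^2 / (2\sigma^2)} for spherical covariance
#' \eqn{\sigma^2 I}; this is the pairwise separation measure used to build
#' the simulation designs.
#'
#' @inheritParams kl_mvn
#' @return Nonnegative scalar, in nats.
#' @examples
#' kl_symmetric(c(0, 0), 0.5, c(1, 1), 0.5)  # ||delta||^2 / (2 * 0.5) = 2
#' @export
kl_symmetric <- function(mean0, cov0, mean1, cov1) {
  0.5 * (kl_mvn(mean0, cov0, mean1, cov1) + kl_mvn(mean1, cov1, mean0, cov0))
}

# Expand scalar variance to sigma2 * I_p; validate dimensions.
expand_cov <- function(cov, p) {
  if (is.numeric(cov) && length(cov) == 1L && !is.matrix(cov)) {
    return(diag(as.numeric(cov), p))
  }
  cov <- as.matrix(cov)
  if (nrow(cov) != p || ncol(cov) != p) {
    stop("covariance dimensions do not match the mean vector", call. = FALSE)
  }
  cov
}

# Upper Cholesky factor with an SPD check and a clear error.
chol_spd <- function(cov) {
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance matrix must be symmetric positive definite", call. = FALSE)
  }
  tryCatch(
    chol(cov),
    error = function(e) {
      stop("covariance matrix must be symmetric positive definite", call. = FALSE)
    }
  )
}
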