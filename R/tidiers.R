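#' Tidy a fitted Gaussian mixture
#'
#' One row per component: weight, variance (spherical families) and the
#' mean coordinates as columns `mean_1 ... mean_p`.
#'
#' @param x A [fit_gmm()] result.
#' @param ... Unused.
#' @return A tibble with `k` rows.
#' @export
tidy.gmm_fit <- function(x, ...) {
  if (x$failed) {
    return(tibble::tibble(component = integer(0), weight = numeric(0)))
  }
  means <- x$means
  colnames(means) <- paste0("mean_", seq_len(ncol(means)))
  out <- tibble::tibble(
    component = seq_len(x$k),
    weight = x$weights,
    variance = vapply(x$covariances, function(S) mean(diag(S)), numeric(1))
  )
  dplyr::bind_cols(out, tibble::as_tibble(means))
}

#' Fit-level summary of a Gaussian mixture
#'
#' @param x A [fit_gmm()] result.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `family`, `loglik`, `n_params`, `bic`,
#'   `converged`, `failed`, `n_iter`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, family = x$family, loglik = x$loglik, n_params = x$n_params,
    bic = x$bic, converged = x$converged, failed = x$failed,
    n_iter = length(x$loglik_trace)
  )
}

#' Per-k table of a BIC model selection
#'
#' @param x A [select_k()] result.
#' @param ... Unused.
#' @return The per-`k` tibble of log-likelihoods, parameter counts, BIC
#'   values and failure flags.
#' @export
tidy.gmm_selection <- function(x, ...) {
  x$table
}

#' @export
glance.gmm_selection <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(k_hat = x$k_hat), glance(x$selected)[-1])
}
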