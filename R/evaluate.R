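#' Match estimated components to true components
#'
#' Mixture component labels are not identified (label switching), so
#' estimated components are mapped to the data-generating ones by
#' exhaustive search over all `K!` assignments, choosing the one that
#' minimizes the mean absolute difference between matched mean vectors
#' (`criterion = "means"`, the default) or between all matched
#' parameters (means, covariance entries and weights,
#' `criterion = "all"`). Ties break toward the lexicographically
#' smallest permutation.
#'
#' @param truth A [mixture_design()].
#' @param fit A non-failed [fit_gmm()] with `fit$k == truth$K`.
#' @param criterion Matching criterion, `"means"` or `"all"`.
#' @return An integer permutation `perm`: estimated component `perm[j]`
#'   corresponds to true component `j`.
#' @export
match_components <- function(truth, fit, criterion = c("means", "all")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(truth, "mixture_design"), inherits(fit, "gmm_fit"))
  if (fit$failed) stop("cannot match a failed fit", call. = FALSE)
  K <- truth$K
  if (fit$k != K) {
    stop(sprintf("component counts differ (truth %d, fit %d)", K, fit$k),
         call. = FALSE)
  }
  perms <- permutations(K)
  err <- apply(perms, 1, function(pm) {
    e <- mean(abs(truth$means - fit$means[pm, , drop = FALSE]))
    if (criterion == "all") {
      tc <- unlist(truth$covariances)
      fc <- unlist(fit$covariances[pm])
      e <- e + mean(abs(tc - fc)) + mean(abs(truth$weights - fit$weights[pm]))
    }
    e
  })
  perms[which.min(err), ]   # first minimum: lexicographically smallest
}

#' Parameter errors of a matched fit
#'
#' Mean absolute differences between true and estimated parameters after
#' component matching: over all `K * p` mean entries, the `K * p`
#' diagonal covariance entries (variances), the `K * p (p - 1) / 2`
#' unique off-diagonal covariance entries, and the `K` mixing weights.
#' For spherical truth and fit the off-diagonal error is exactly zero.
#'
#' @inheritParams match_components
#' @param permutation Matching from [match_components()]; computed when
#'   missing.
#' @return A one-row tibble with columns `mae_means`, `mae_variances`,
#'   `mae_covariances`, `mae_weights`.
#' @export
parameter_errors <- function(truth, fit, permutation = NULL) {
  permutation <- permutation %||% match_components(truth, fit)
  K <- truth$K
  p <- truth$p
  mu_err <- abs(truth$means - fit$means[permutation, , drop = FALSE])
  lower <- lower.tri(matrix(0, p, p))
  var_err <- cov_err <- numeric(0)
  for (j in seq_len(K)) {
    St <- truth$covariances[[j]]
    Sf <- fit$covariances[[permutation[j]]]
    var_err <- c(var_err, abs(diag(St) - diag(Sf)))
    if (p > 1) cov_err <- c(cov_err, abs(St[lower] - Sf[lower]))
  }
  tibble::tibble(
    mae_means = mean(mu_err),
    mae_variances = mean(var_err),
    mae_covariances = if (p > 1) mean(cov_err) else 0,
    mae_weights = mean(abs(truth$weights - fit$weights[permutation]))
  )
}

#' Score one repetition's recovery
#'
#' Compares the BIC-selected number of components with the truth and,
#' when the selection is correct, computes matched parameter errors.
#' Parameter errors are only defined (non-`NA`) for correctly selected
#' repetitions, following the convention that estimation error is
#' reported conditionally on recovering `K`.
#'
#' @param truth A [mixture_design()].
#' @param selection A [select_k()] result (or a single `gmm_fit`).
#' @param criterion Matching criterion, see [match_components()].
#' @return A one-row tibble: `k_true`, `k_hat`, `correct`, `mae_means`,
#'   `mae_variances`, `mae_covariances`, `mae_weights`.
#' @export
evaluate_recovery <- function(truth, selection, criterion = c("means", "all")) {
  criterion <- match.arg(criterion)
  fit <- if (inherits(selection, "gmm_selection")) selection$selected else selection
  k_hat <- fit$k
  correct <- !fit$failed && k_hat == truth$K
  base <- tibble::tibble(
    k_true = truth$K, k_hat = as.integer(k_hat), correct = correct
  )
  if (!correct) {
    return(dplyr::bind_cols(base, tibble::tibble(
      mae_means = NA_real_, mae_variances = NA_real_,
      mae_covariances = NA_real_, mae_weights = NA_real_
    )))
  }
  pm <- match_components(truth, fit, criterion)
  dplyr::bind_cols(base, parameter_errors(truth, fit, pm))
}

#' Aggregate repetition-level recovery into cell summaries
#'
#' @param results Tibble of repetition rows (e.g. from [run_grid()]),
#'   holding at least `correct`, `k_hat` and the `mae_*` columns.
#' @param ... Grouping columns (tidy-select), e.g. `p, n_categories`.
#' @return A tibble with one row per group: `n_reps`, `accuracy`, the
#'   `mae_*` means over the correct repetitions only (`NA` when no
#'   repetition recovered `K` — reported as missing cells), and the mean
#'   selected `k_hat`.
#' @export
summarize_cells <- function(results, ...) {
  results |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n_reps = dplyr::n(),
      accuracy = mean(.data$correct),
      mae_means = mean_or_na(.data$mae_means[.data$correct]),
      mae_variances = mean_or_na(.data$mae_variances[.data$correct]),
      mae_covariances = mean_or_na(.data$mae_covariances[.data$correct]),
      mae_weights = mean_or_na(.data$mae_weights[.data$correct]),
      mean_k_hat = mean(.data$k_hat),
      .groups = "drop"
    )
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}

#' Distribution of the selected number of components
#'
#' @inheritParams summarize_cells
#' @param k_max Largest count in the tabulation.
#' @return A tibble with the grouping columns plus `k_hat` and `n`
#'   (counts summing to the group's repetition count).
#' @export
khat_distribution <- function(results, ..., k_max = 7) {
  results |>
    dplyr::count(..., k_hat = factor(.data$k_hat, levels = seq_len(k_max))) |>
    tidyr::complete(..., .data$k_hat, fill = list(n = 0L)) |>
    dplyr::mutate(k_hat = as.integer(as.character(.data$k_hat)))
}
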