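#' Control settings for the EM fits
#'
#' @param init Initialization of the EM runs. `"hc"` (default) derives a
#'   hard partition from model-based hierarchical agglomeration
#'   ([mclust::hc()]) on a random subsample of at most `hc_subset` rows —
#'   the initialization the study's estimation procedure relies on, and
#'   the one whose zero-variance partitions on heavily tied ordinal data
#'   produce the degenerate fits that drive the binary-category results.
#'   `"kmeans"` and `"random"` are alternatives with `n_init` restarts.
#' @param n_init Number of initializations (restarts) per fit. With
#'   `"hc"` the first initialization is the agglomeration partition and
#'   any further ones use fresh subsamples.
#' @param hc_subset Largest subsample size handed to the agglomeration.
#' @param max_iter Maximum EM iterations per run.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param eig_tol Degeneracy threshold: a run whose smallest
#'   variance/covariance eigenvalue drops below this value is marked
#'   failed (no variance priors or ridge regularization are applied, so
#'   singular solutions can and should surface).
#' @param seed Optional integer seed for subsampling/restarts; `NULL`
#'   uses the ambient RNG state.
#' @return A list of class `gmm_control`.
#' @export
gmm_control <- function(init = c("hc", "kmeans", "random"), n_init = 1,
                        hc_subset = 1000, max_iter = 500, tol = 1e-8,
                        eig_tol = 1e-10, seed = NULL) {
  init <- match.arg(init)
  stopifnot(n_init >= 1, max_iter >= 1, tol > 0, eig_tol >= 0)
  structure(
    list(init = init, n_init = n_init, hc_subset = hc_subset,
         max_iter = max_iter, tol = tol, eig_tol = eig_tol, seed = seed),
    class = "gmm_control"
  )
}

family_code <- function(family) {
  switch(family, spherical = 0L, shared_spherical = 1L, full = 2L,
         stop("unknown model family: ", family, call. = FALSE))
}

#' Number of free parameters of a Gaussian mixture family
#'
#' * `"spherical"`: per-component spherical covariances
#'   \eqn{\sigma_k^2 I} — `K * p` means, `K` variances and `K - 1`
#'   weights, i.e. `K * (p + 1) + (K - 1)`. This is the constrained
#'   ("isomorphic", latent-profile-analysis-like) family used in the main
#'   study.
#' * `"shared_spherical"`: one variance pooled across components,
#'   `K * p + 1 + (K - 1)`.
#' * `"full"`: unconstrained SPD covariance per component,
#'   `K * p + K * p * (p + 1) / 2 + (K - 1)`.
#'
#' @param k Number of components.
#' @param p Number of variables.
#' @param family One of `"spherical"`, `"shared_spherical"`, `"full"`.
#' @return Integer parameter count.
#' @examples
#' n_params(2, 4, "spherical")         # 13
#' n_params(2, 4, "shared_spherical")  # 10
#' n_params(2, 2, "full")              # 11
#' @export
n_params <- function(k, p, family = c("spherical", "shared_spherical", "full")) {
  family <- match.arg(family)
  stopifnot(k >= 1, p >= 1)
  as.integer(switch(family,
    spherical = k * (p + 1) + (k - 1),
    shared_spherical = k * p + 1 + (k - 1),
    full = k * p + k * p * (p + 1) / 2 + (k - 1)
  ))
}

#' BIC on the maximize-is-better convention
#'
#' `2 * loglik - m * log(n)`: larger values indicate better models, the
#' convention of the mclust family of packages. Selection outcomes are
#' invariant to the sign convention.
#'
#' @param loglik Maximized log-likelihood.
#' @param m Number of free parameters (see [n_params()]).
#' @param n Sample size.
#' @return Scalar BIC value.
#' @export
bic_score <- function(loglik, m, n) {
  stopifnot(n >= 1)
  2 * loglik - m * log(n)
}

#' Fit a Gaussian mixture by EM
#'
#' Runs the EM algorithm for a `k`-component Gaussian mixture under one
#' of the covariance families of [n_params()]. `k = 1` is the closed-form
#' maximum-likelihood fit. Runs in which a component empties or a
#' variance collapses below `eig_tol` are *failed*, not errors: the
#' returned object carries `failed = TRUE` and a reason, and such fits
#' are excluded from model selection, mirroring how degenerate solutions
#' behave in practice. When every initialization fails the whole fit is
#' failed.
#'
#' @param data Data frame or matrix; all numeric columns except a column
#'   named `component` (the true simulation labels) are used.
#' @param k Number of mixture components.
#' @param family Covariance family, see [n_params()]. The default
#'   `"spherical"` is the study's constrained estimation.
#' @param control A [gmm_control()].
#' @return An object of class `gmm_fit`: weights, means (`k` by `p`),
#'   covariances (list of `k` matrices), `loglik`, `n_params`, `bic`,
#'   `converged`, `failed`, `reason` and the per-iteration
#'   `loglik_trace` of the winning run.
#' @examples
#' d <- build_design(2, 3, 5, seed = 1)
#' smp <- sample_mixture(d, 500, seed = 2)
#' fit <- fit_gmm(smp, 2, control = gmm_control(seed = 3))
#' glance(fit)
#' @export
fit_gmm <- function(data, k, family = c("spherical", "shared_spherical", "full"),
                    control = gmm_control()) {
  family <- match.arg(family)
  X <- data_matrix(data)
  N <- nrow(X)
  p <- ncol(X)
  stopifnot(k >= 1, N > k)
  m <- n_params(k, p, family)

  if (k == 1L) {
    return(fit_k1(X, family, m))
  }

  with_seed(control$seed, {
    best <- NULL
    reasons <- character(0)
    for (i in seq_len(control$n_init)) {
      control_i <- control
      if (i > 1) control_i$hc_cache <- NULL   # restarts use fresh subsamples
      init <- init_params(X, k, family, control_i)
      if (is.character(init)) {
        reasons <- c(reasons, init)
        next
      }
      res <- em_core(X, init$mu, init$w, init$s2, init$Sigma,
                     family_code(family), control$max_iter, control$tol,
                     control$eig_tol)
      if (res$failed) {
        reasons <- c(reasons, res$reason)
        next
      }
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    if (is.null(best)) {
      new_gmm_fit(
        k = k, p = p, n = N, family = family, n_params = m,
        failed = TRUE,
        reason = paste(unique(reasons), collapse = "; ")
      )
    } else {
      new_gmm_fit(
        k = k, p = p, n = N, family = family, n_params = m,
        weights = as.numeric(best$weights),
        means = matrix(best$means, k, p, dimnames = list(NULL, colnames(X))),
        covariances = fitted_covariances(best, family, p, k),
        loglik = best$loglik,
        bic = bic_score(best$loglik, m, N),
        converged = best$converged,
        loglik_trace = as.numeric(best$trace),
        failed = FALSE, reason = NA_character_
      )
    }
  })
}

fit_k1 <- function(X, family, m) {
  N <- nrow(X)
  p <- ncol(X)
  mu <- colMeans(X)
  D <- sweep(X, 2, mu)
  if (family == "full") {
    S <- crossprod(D) / N
    covs <- list(S)
    ll <- estep_core(X, matrix(mu, 1, p), 1, 1, array(S, c(p, p, 1)), 2L)$loglik
  } else {
    s2 <- sum(D^2) / (N * p)
    covs <- list(diag(s2, p))
    ll <- sum(-p / 2 * log(2 * pi * s2) - rowSums(D^2) / (2 * s2))
  }
  new_gmm_fit(
    k = 1L, p = p, n = N, family = family, n_params = m,
    weights = 1, means = matrix(mu, 1, p, dimnames = list(NULL, colnames(X))),
    covariances = covs, loglik = ll, bic = bic_score(ll, m, N),
    converged = TRUE, loglik_trace = ll, failed = FALSE,
    reason = NA_character_
  )
}

# Initial parameters from a hard partition (or NULL + reason string).
# Returns a character reason when the initialization itself is degenerate
# (e.g. a pure tied cluster with exactly zero variance), which counts as
# a failed run.
init_params <- function(X, k, family, control) {
  N <- nrow(X)
  p <- ncol(X)
  cl <- switch(control$init,
    hc = {
      cache <- control$hc_cache %||% make_hc_cache(X, control)
      list(X = cache$X, cl = as.vector(mclust::hclass(cache$tree, k)))
    },
    kmeans = {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, k, iter.max = 30, nstart = 1)),
        error = function(e) NULL
      )
      if (is.null(km)) return("k-means initialization failed (too few distinct points)")
      list(X = X, cl = km$cluster)
    },
    random = {
      list(X = X, cl = sample.int(k, N, replace = TRUE))
    }
  )
  Xs <- cl$X
  cl <- cl$cl
  sizes <- tabulate(cl, k)
  if (any(sizes == 0)) return("empty cluster in initialization partition")
  mu <- t(vapply(seq_len(k), function(g) colMeans(Xs[cl == g, , drop = FALSE]),
                 numeric(p)))
  w <- sizes / length(cl)
  s2 <- rep(1, k)
  Sigma <- array(diag(p), c(p, p, k))
  if (family == "full") {
    for (g in seq_len(k)) {
      D <- sweep(Xs[cl == g, , drop = FALSE], 2, mu[g, ])
      S <- crossprod(D) / sizes[g]
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < control$eig_tol) {
        return("singular covariance in initialization partition")
      }
      Sigma[, , g] <- S
    }
  } else {
    s2 <- vapply(seq_len(k), function(g) {
      D <- sweep(Xs[cl == g, , drop = FALSE], 2, mu[g, ])
      sum(D^2) / (sizes[g] * p)
    }, numeric(1))
    if (family == "shared_spherical") s2 <- rep(sum(s2 * sizes) / length(cl), k)
    if (min(s2) < control$eig_tol) {
      return("singular covariance in initialization partition")
    }
  }
  list(mu = mu, w = w, s2 = s2, Sigma = Sigma)
}

# Agglomeration tree on a (sub)sample, reused by every k of a selection
# run: the tree is cut at each k, exactly how a single model-based
# hierarchical initialization serves the whole k-sequence.
make_hc_cache <- function(X, control) {
  N <- nrow(X)
  idx <- if (N > control$hc_subset) sample.int(N, control$hc_subset) else seq_len(N)
  Xs <- X[idx, , drop = FALSE]
  list(X = Xs, tree = mclust::hc(Xs, use = "SVD"))
}

fitted_covariances <- function(res, family, p, k) {
  if (family == "full") {
    lapply(seq_len(k), function(g) res$Sigma[, , g])
  } else {
    lapply(res$s2, function(s) diag(s, p))
  }
}

new_gmm_fit <- function(k, p, n, family, n_params, weights = NULL,
                        means = NULL, covariances = NULL,
                        loglik = NA_real_, bic = NA_real_,
                        converged = FALSE, loglik_trace = numeric(0),
                        failed, reason) {
  structure(
    list(k = k, p = p, n = n, family = family, n_params = n_params,
         weights = weights, means = means, covariances = covariances,
         loglik = loglik, bic = bic, converged = converged,
         loglik_trace = loglik_trace, failed = failed, reason = reason),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<gmm_fit> k = %d (%s): FAILED — %s\n", x$k, x$family, x$reason))
  } else {
    cat(sprintf("<gmm_fit> k = %d (%s): loglik = %.2f, BIC = %.2f%s\n",
                x$k, x$family, x$loglik, x$bic,
                if (x$converged) "" else " (not converged)"))
  }
  invisible(x)
}

#' Posterior responsibilities of a fitted mixture
#'
#' @param fit A non-failed [fit_gmm()] result.
#' @param data Data on the same variables the mixture was fitted to.
#' @return An `n` by `k` matrix of posterior component probabilities;
#'   rows sum to one.
#' @export
responsibilities <- function(fit, data) {
  stopifnot(inherits(fit, "gmm_fit"), !fit$failed)
  X <- data_matrix(data)
  p <- fit$p
  if (fit$family == "full") {
    Sigma <- array(unlist(fit$covariances), c(p, p, fit$k))
    s2 <- rep(1, fit$k)
  } else {
    Sigma <- array(diag(p), c(p, p, fit$k))
    s2 <- vapply(fit$covariances, function(S) S[1, 1], numeric(1))
  }
  estep_core(X, fit$means, fit$weights, s2, Sigma,
             family_code(fit$family))$responsibilities
}

#' Select the number of components by BIC
#'
#' Fits mixtures for `k = 1, ..., k_max` and selects the non-failed fit
#' with the largest BIC; ties break toward the smaller `k` (parsimony).
#' Failed (degenerate) fits are excluded from the comparison, so when
#' every `k > 1` collapses — as happens for binary ordinal data — the
#' selection falls back to `k = 1`, which never fails.
#'
#' @inheritParams fit_gmm
#' @param k_max Largest number of components considered; default 7.
#' @return An object of class `gmm_selection`: `k_hat`, `selected` (the
#'   winning `gmm_fit`), `fits` (all of them) and a per-`k` summary
#'   tibble `table`.
#' @examples
#' d <- build_design(2, 3, 5, seed = 1)
#' smp <- sample_mixture(d, 1000, seed = 2)
#' sel <- select_k(smp, control = gmm_control(seed = 3))
#' sel$k_hat
#' @export
select_k <- function(data, family = c("spherical", "shared_spherical", "full"),
                     k_max = 7, control = gmm_control()) {
  family <- match.arg(family)
  X <- data_matrix(data)
  stopifnot(nrow(X) > k_max)
  if (control$init == "hc" && is.null(control$hc_cache)) {
    # one agglomeration tree serves the whole k-sequence
    control$hc_cache <- with_seed(control$seed, make_hc_cache(X, control))
  }
  fits <- lapply(seq_len(k_max), function(k) fit_gmm(X, k, family, control))
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(k = f$k, loglik = f$loglik, n_params = f$n_params,
                   bic = f$bic, converged = f$converged, failed = f$failed,
                   reason = f$reason)
  })
  ok <- which(!tab$failed)
  k_hat <- ok[which.max(tab$bic[ok])]   # first max: ties favor smaller k
  structure(
    list(k_hat = as.integer(k_hat), selected = fits[[k_hat]], fits = fits,
         table = tab, family = family),
    class = "gmm_selection"
  )
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("<gmm_selection> family = %s, k_hat = %d\n", x$family, x$k_hat))
  print(x$table)
  invisible(x)
}
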