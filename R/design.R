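#' Construct a mixture design object
#'
#' A `mixture_design` bundles the parameters of a data-generating Gaussian
#' mixture: component means, covariances and mixing weights, together with
#' the pairwise separation (symmetrized KL divergence) the design was built
#' to achieve. Designs are usually created with [build_design()]; this
#' constructor validates an explicit specification.
#'
#' @param means Numeric `K` by `p` matrix of component means (rows).
#' @param covariances List of `K` symmetric positive-definite `p` by `p`
#'   matrices, or a single matrix / scalar variance shared by all
#'   components.
#' @param weights Mixing weights; default equal weights `1/K`.
#' @param target_kl Pairwise symmetrized KL divergence the design targets
#'   (nats), or `NA` when not applicable.
#' @param kl_tolerance Largest tolerated deviation of any pairwise
#'   divergence from `target_kl`.
#' @return An object of class `mixture_design` with fields `K`, `p`,
#'   `means`, `covariances`, `weights`, `target_kl`, `kl_tolerance`.
#' @examples
#' d <- mixture_design(rbind(c(0, 0), c(1, 1)), 0.5)
#' pairwise_kl(d)
#' @export
mixture_design <- function(means, covariances, weights = NULL,
                           target_kl = NA_real_, kl_tolerance = 1e-8) {
  means <- as.matrix(means)
  K <- nrow(means)
  p <- ncol(means)
  if (!is.list(covariances)) {
    covariances <- replicate(K, expand_cov(covariances, p), simplify = FALSE)
  }
  covariances <- lapply(covariances, expand_cov, p = p)
  if (length(covariances) != K) {
    stop("need one covariance per component", call. = FALSE)
  }
  lapply(covariances, chol_spd)
  weights <- weights %||% rep(1 / K, K)
  if (length(weights) != K || any(weights <= 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be positive and sum to 1", call. = FALSE)
  }
  structure(
    list(K = K, p = p, means = means, covariances = covariances,
         weights = as.numeric(weights), target_kl = target_kl,
         kl_tolerance = kl_tolerance),
    class = "mixture_design"
  )
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> K = %d components, p = %d dimensions\n", x$K, x$p))
  if (is.finite(x$target_kl)) {
    cat(sprintf("  target pairwise symmetrized KL: %g nats\n", x$target_kl))
  }
  shared <- length(unique(lapply(x$covariances, function(s) round(s, 12)))) == 1L
  cat(sprintf("  covariances: %s\n",
              if (shared) "shared across components" else "component-specific"))
  invisible(x)
}

#' Pairwise symmetrized KL divergences of a design
#'
#' @param design A [mixture_design()].
#' @return A `K` by `K` symmetric matrix with zero diagonal.
#' @export
pairwise_kl <- function(design) {
  K <- design$K
  out <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      out[i, j] <- out[j, i] <- kl_symmetric(
        design$means[i, ], design$covariances[[i]],
        design$means[j, ], design$covariances[[j]]
      )
    }
  }
  out
}

#' Validate a mixture design against its declared invariants
#'
#' Checks that weights are equal and sum to one, covariances are symmetric
#' positive definite, and (when `target_kl` is set) that every pairwise
#' symmetrized KL divergence lies within `kl_tolerance` of the target.
#'
#' @param design A [mixture_design()].
#' @return `design`, invisibly; errors describe the violated invariant.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  if (abs(sum(design$weights) - 1) > 1e-10) {
    stop("design weights do not sum to 1", call. = FALSE)
  }
  lapply(design$covariances, chol_spd)
  if (is.finite(design$target_kl) && design$K > 1) {
    dev <- abs(pairwise_kl(design) - design$target_kl)
    diag(dev) <- 0
    if (max(dev) > design$kl_tolerance) {
      stop(sprintf(
        "pairwise KL deviates from target by %.3g (tolerance %.3g)",
        max(dev), design$kl_tolerance
      ), call. = FALSE)
    }
  }
  invisible(design)
}

#' Place component means as a regular simplex with fixed pairwise KL
#'
#' For components sharing a spherical covariance `variance * I`, the
#' symmetrized KL divergence between two components at Euclidean distance
#' `d` is `d^2 / (2 * variance)`. Placing the `K` means at the vertices of
#' a regular simplex with edge length `sqrt(2 * variance * target_kl)`
#' therefore makes all `K (K - 1) / 2` pairwise divergences equal to
#' `target_kl` exactly. The simplex is randomly rotated (Haar-distributed
#' rotation from the ambient RNG, or from `seed`) and translated so its
#' centroid sits at `(0.5, ..., 0.5)`, which puts the per-coordinate means
#' roughly between -0.5 and 1.5 for the separations studied here.
#'
#' @param K Number of components, `2 <= K`.
#' @param p Number of dimensions; the simplex requires `K - 1 <= p`.
#' @param target_kl Desired pairwise symmetrized KL divergence (nats).
#' @param variance Shared spherical variance; default `sqrt(0.25)`.
#' @param seed Optional integer seed for the random rotation.
#' @return A `K` by `p` matrix of means.
#' @export
place_equidistant_means <- function(K, p, target_kl, variance = sqrt(0.25),
                                    seed = NULL) {
  stopifnot(K >= 2, p >= 1, target_kl > 0, variance > 0)
  if (K - 1 > p) {
    stop(sprintf(paste0(
      "cannot place %d pairwise-equidistant means in %d dimensions ",
      "(a regular simplex needs K - 1 <= p); the K = 4, p = 2 case is ",
      "handled by solve_k4p2_design()"), K, p), call. = FALSE)
  }
  d <- sqrt(2 * variance * target_kl)
  with_seed(seed, {
    S <- regular_simplex(K) * d       # K x (K-1), edge length d, centered
    M <- cbind(S, matrix(0, K, p - (K - 1)))
    M <- M %*% t(random_rotation(p))
    sweep(M, 2, colMeans(M) - 0.5)    # centroid at (0.5, ..., 0.5)
  })
}

# Vertices of a regular (K-1)-simplex in K-1 dimensions, centered at the
# origin, edge length 1. Derived from the spectral factorization of the
# centering matrix I - J/K, whose Gram structure has pairwise distances
# sqrt(2).
regular_simplex <- function(K) {
  G <- diag(K) - 1 / K
  ev <- eigen(G, symmetric = TRUE)
  V <- ev$vectors[, seq_len(K - 1), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(K - 1)], 0)), K - 1)
  V / sqrt(2)
}

# Haar-distributed random rotation (det +1) via QR of a Gaussian matrix
# with the sign convention R_ii > 0.
random_rotation <- function(p) {
  qr_ <- qr(matrix(stats::rnorm(p * p), p, p))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), p)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Equal-KL design for four components in two dimensions
#'
#' Four pairwise-equidistant means cannot be placed in the plane, so this
#' design fixes the means on a square centered at `(0.5, 0.5)` and finds
#' component-specific covariances by numeric least squares such that all
#' six pairwise symmetrized KL divergences equal `target_kl`. Covariances
#' are parameterized through their Cholesky factors (log-diagonal), which
#' keeps them symmetric positive definite throughout the optimization.
#' The solved configuration is randomly rotated as a whole (means about
#' the centroid, covariances conjugated), which preserves every pairwise
#' divergence.
#'
#' @param target_kl Desired pairwise symmetrized KL divergence (nats).
#' @param variance Baseline spherical variance used to scale the square
#'   and initialize the optimizer; default `sqrt(0.25)`.
#' @param kl_tolerance Acceptance tolerance on the largest absolute
#'   deviation of a pairwise divergence from `target_kl`.
#' @param n_restarts Random restarts of the local optimizer.
#' @param seed Optional integer seed (restart jitter and final rotation).
#' @return A [mixture_design()] with `K = 4`, `p = 2` and non-identical
#'   covariances.
#' @export
solve_k4p2_design <- function(target_kl, variance = sqrt(0.25),
                              kl_tolerance = 1e-4, n_restarts = 20,
                              seed = NULL) {
  stopifnot(target_kl > 0)
  base <- k4p2_cached(target_kl, variance, kl_tolerance, n_restarts)
  with_seed(seed, {
    Q <- random_rotation(2)
    means <- sweep(base$means, 2, c(0.5, 0.5)) %*% t(Q)
    means <- sweep(means, 2, c(0.5, 0.5), "+")
    covs <- lapply(base$covariances, function(S) Q %*% S %*% t(Q))
    mixture_design(means, covs, target_kl = target_kl,
                   kl_tolerance = kl_tolerance)
  })
}

# Cache the (deterministic) optimization result per (target_kl, variance):
# the per-repetition randomness is only the rotation applied afterwards.
k4p2_env <- new.env(parent = emptyenv())

k4p2_cached <- function(target_kl, variance, kl_tolerance, n_restarts) {
  key <- sprintf("%.12g|%.12g", target_kl, variance)
  if (!is.null(k4p2_env[[key]])) return(k4p2_env[[key]])
  res <- k4p2_solve(target_kl, variance, kl_tolerance, n_restarts)
  k4p2_env[[key]] <- res
  res
}

k4p2_solve <- function(target_kl, variance, kl_tolerance, n_restarts) {
  s <- sqrt(2 * variance * target_kl)       # square side
  means <- 0.5 + s / 2 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  pairs <- utils::combn(4, 2)

  unpack <- function(theta) {
    lapply(seq_len(4), function(k) {
      v <- theta[(3 * k - 2):(3 * k)]
      L <- matrix(c(exp(v[1]), v[3], 0, exp(v[2])), 2, 2)
      L %*% t(L)
    })
  }
  objective <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 10)) return(1e6)
    covs <- unpack(theta)
    dev <- apply(pairs, 2, function(ij) {
      kl_symmetric(means[ij[1], ], covs[[ij[1]]],
                   means[ij[2], ], covs[[ij[2]]]) - target_kl
    })
    sum(dev^2)
  }
  max_dev <- function(theta) {
    covs <- unpack(theta)
    max(abs(apply(pairs, 2, function(ij) {
      kl_symmetric(means[ij[1], ], covs[[ij[1]]],
                   means[ij[2], ], covs[[ij[2]]]) - target_kl
    })))
  }

  # Start from alternating elongated components (orientation flipping
  # around the square, correlations of alternating sign). The KL system is
  # underdetermined, and this branch yields covariances that differ
  # strongly across components — the point of the K = 4, p = 2 design is
  # that a spherical-covariance estimator cannot match it.
  sd0 <- sqrt(variance)
  theta0 <- rep(c(log(4 * sd0), log(sd0 / 4), 0.8,
                  log(sd0 / 4), log(4 * sd0), -0.8), 2)
  best <- NULL
  # deterministic restart jitter so the cached solution is reproducible
  jitter_rng <- local({
    set.seed(20220713)
    lapply(seq_len(n_restarts), function(i) stats::rnorm(12, sd = 0.3))
  })
  for (r in seq_len(n_restarts)) {
    start <- theta0 + if (r == 1) 0 else jitter_rng[[r]]
    fit <- tryCatch(
      stats::optim(start, objective, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (max_dev(best$par) < kl_tolerance) break
  }
  if (is.null(best) || max_dev(best$par) >= kl_tolerance) {
    achieved <- if (is.null(best)) Inf else max_dev(best$par)
    stop(sprintf(paste0(
      "K = 4, p = 2 covariance optimization did not reach tolerance %.1e ",
      "(largest pairwise KL residual %.3e)"), kl_tolerance, achieved),
      call. = FALSE)
  }
  list(means = means, covariances = unpack(best$par))
}

#' Build a data-generating mixture design for one simulation condition
#'
#' Dispatches between the regular-simplex construction (shared spherical
#' covariance `variance * I`, equal weights `1/K`) and the special
#' `K = 4, p = 2` design in which the covariances vary across components
#' to achieve the common pairwise divergence. A fresh random
#' mean configuration (rotation) is drawn on each call, so repeated calls
#' emulate the study's independently regenerated configurations.
#'
#' @param K Number of components (2, 3 or 4 in the study grid).
#' @param p Number of dimensions (2 to 10 in the study grid).
#' @param target_kl Pairwise symmetrized KL divergence: 2, 3.5 or 5 in the
#'   study grid.
#' @param variance Shared spherical variance of the components; the study
#'   fixes `sigma^2 = sqrt(0.25)`.
#' @param seed Optional integer seed for the random configuration.
#' @return A validated [mixture_design()].
#' @examples
#' d <- build_design(3, 2, 5, seed = 1)
#' round(pairwise_kl(d), 6)
#' @export
build_design <- function(K, p, target_kl, variance = sqrt(0.25), seed = NULL) {
  stopifnot(K >= 1, p >= 1, target_kl > 0)
  if (K == 1) {
    return(mixture_design(matrix(0.5, 1, p), variance * diag(p),
                          target_kl = NA_real_))
  }
  design <- if (K == 4 && p == 2) {
    solve_k4p2_design(target_kl, variance, seed = seed)
  } else {
    means <- place_equidistant_means(K, p, target_kl, variance, seed = seed)
    mixture_design(means, variance * diag(p), target_kl = target_kl,
                   kl_tolerance = 1e-8)
  }
  validate_design(design)
}

#' Write or read a mixture design as JSON
#'
#' Serialization keeps full double precision, so a write/read round trip
#' reproduces the design to at least 15 significant digits.
#'
#' @param design A [mixture_design()].
#' @param path File path of the JSON document.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns the reconstructed [mixture_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mixture_design"))
  payload <- list(
    K = design$K,
    p = design$p,
    target_kl = design$target_kl,
    kl_tolerance = design$kl_tolerance,
    weights = design$weights,
    means = apply(design$means, 1, identity, simplify = FALSE),
    covariances = lapply(design$covariances, function(S) {
      apply(S, 1, identity, simplify = FALSE)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  means <- do.call(rbind, lapply(x$means, unlist))
  covs <- lapply(x$covariances, function(S) do.call(rbind, lapply(S, unlist)))
  mixture_design(means, covs, weights = unlist(x$weights),
                 target_kl = x$target_kl %||% NA_real_,
                 kl_tolerance = x$kl_tolerance %||% 1e-8)
}

#' @export
tidy.mixture_design <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    weight = x$weights,
    mean = apply(x$means, 1, identity, simplify = FALSE),
    covariance = x$covariances
  )
}
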