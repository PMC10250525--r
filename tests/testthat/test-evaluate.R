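make_fit <- function(means, covs = NULL, weights = NULL) {
  K <- nrow(means); p <- ncol(means)
  covs <- covs %||% replicate(K, diag(0.5, p), simplify = FALSE)
  ordgmm:::new_gmm_fit(
    k = K, p = p, n = 100L, family = "spherical",
    n_params = n_params(K, p, "spherical"),
    weights = weights %||% rep(1 / K, K), means = means,
    covariances = covs, loglik = 0, bic = 0, converged = TRUE,
    failed = FALSE, reason = NA_character_
  )
}
`%||%` <- ordgmm:::`%||%`

test_that("matching recovers identity and label-switched assignments", {
  d <- build_design(3, 2, 3.5, seed = 1)
  fit_id <- make_fit(d$means, d$covariances)
  expect_identical(match_components(d, fit_id), c(1L, 2L, 3L))
  expect_equal(parameter_errors(d, fit_id)$mae_means, 0)

  fit_rev <- make_fit(d$means[3:1, ], d$covariances[3:1])
  expect_identical(match_components(d, fit_rev), c(3L, 2L, 1L))
  expect_equal(parameter_errors(d, fit_rev)$mae_means, 0)
})

test_that("matching equals the brute-force oracle on random instances", {
  set.seed(2)
  for (i in 1:100) {
    K <- sample(2:4, 1); p <- sample(2:3, 1)
    truth <- mixture_design(matrix(rnorm(K * p), K, p), 0.5)
    est <- matrix(rnorm(K * p), K, p)
    fit <- make_fit(est)
    pm <- match_components(truth, fit)
    oracle <- brute_force_match(truth$means, est)
    got <- mean(abs(truth$means - est[pm, , drop = FALSE]))
    expect_equal(got, oracle$err, tolerance = 1e-12)
  }
})

test_that("component-count mismatches are rejected", {
  d <- build_design(3, 2, 2, seed = 3)
  expect_error(match_components(d, make_fit(matrix(0, 2, 2))), "differ")
})

test_that("parameter errors follow their definitions", {
  truth <- mixture_design(matrix(0, 2, 2), 0.5)
  fit <- make_fit(matrix(0.2, 2, 2))
  pe <- parameter_errors(truth, fit, c(1L, 2L))
  expect_equal(pe$mae_means, 0.2)
  expect_equal(pe$mae_variances, 0)
  # spherical truth and fit: off-diagonals are identically zero
  expect_identical(pe$mae_covariances, 0)
})

test_that("errors are invariant to a common permutation of truth and fit", {
  set.seed(4)
  d <- build_design(3, 3, 3.5, seed = 4)
  est <- d$means + matrix(rnorm(9, sd = 0.1), 3, 3)
  f1 <- make_fit(est)
  pm <- sample(3)
  d2 <- mixture_design(d$means[pm, ], d$covariances[pm],
                       target_kl = d$target_kl, kl_tolerance = 1)
  f2 <- make_fit(est[pm, ])
  e1 <- parameter_errors(d, f1, match_components(d, f1))
  e2 <- parameter_errors(d2, f2, match_components(d2, f2))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("recovery scoring populates errors only for correct selections", {
  d <- build_design(2, 2, 5, seed = 5)
  good <- evaluate_recovery(d, make_fit(d$means, d$covariances))
  expect_true(good$correct)
  expect_equal(good$mae_means, 0)
  bad <- evaluate_recovery(d, make_fit(matrix(0, 3, 2)))
  expect_false(bad$correct)
  expect_true(is.na(bad$mae_means))
})

test_that("cell summaries aggregate accuracy and conditional errors", {
  res <- tibble::tibble(
    cell = rep(c("a", "b"), each = 10),
    correct = c(rep(TRUE, 7), rep(FALSE, 3), rep(FALSE, 10)),
    k_hat = rep(2L, 20),
    mae_means = ifelse(correct, 0.1, NA),
    mae_variances = ifelse(correct, 0.2, NA),
    mae_covariances = ifelse(correct, 0, NA),
    mae_weights = ifelse(correct, 0.05, NA)
  )
  s <- summarize_cells(res, cell)
  expect_equal(s$accuracy, c(0.7, 0))
  expect_equal(s$mae_means, c(0.1, NA))   # missing cell when never correct
  expect_equal(s$n_reps, c(10L, 10L))
})

test_that("k-hat distributions are consistent with accuracy", {
  res <- tibble::tibble(
    k_true = 2L,
    k_hat = c(1L, 2L, 2L, 3L, 2L),
    correct = k_hat == k_true
  )
  kd <- khat_distribution(res)
  expect_identical(sum(kd$n), 5L)
  expect_identical(kd$n[kd$k_hat == 2L], 3L)
  expect_equal(sum(res$correct) / nrow(res), 0.6)
})
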