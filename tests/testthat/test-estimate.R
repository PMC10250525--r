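test_that("parameter counts match direct enumeration", {
  expect_identical(n_params(1, 2, "spherical"), 3L)
  expect_identical(n_params(2, 4, "spherical"), 2L * 5L + 1L)   # K(p+1)+(K-1)
  expect_identical(n_params(1, 2, "shared_spherical"), 3L)
  expect_identical(n_params(2, 4, "shared_spherical"), 10L)
  expect_identical(n_params(2, 2, "full"), 11L)
})

test_that("the BIC convention is 2 loglik - m log n", {
  expect_equal(bic_score(-100, 3, 1000), -200 - 3 * log(1000), tolerance = 1e-12)
  expect_identical(bic_score(-100, 0, 50), -200)
  b <- vapply(1:5, function(m) bic_score(-100, m, 100), numeric(1))
  expect_true(all(diff(b) < 0))
})

test_that("the one-component fit is the closed-form MLE", {
  set.seed(1)
  X <- matrix(rnorm(600), 200, 3)
  f <- fit_gmm(X, 1)
  expect_equal(as.numeric(f$means), colMeans(X), tolerance = 1e-12)
  s2 <- sum(sweep(X, 2, colMeans(X))^2) / (200 * 3)
  expect_equal(f$covariances[[1]], diag(s2, 3), tolerance = 1e-12)
  expect_false(f$failed)
  expect_true(f$converged)
})

test_that("EM log-likelihood is non-decreasing on every run and family", {
  d <- build_design(3, 2, 3.5, seed = 2)
  smp <- sample_mixture(d, 800, seed = 3)
  for (fam in c("spherical", "shared_spherical", "full")) {
    for (k in 2:4) {
      f <- fit_gmm(smp, k, family = fam, control = gmm_control(seed = k))
      if (f$failed) next
      expect_gt(length(f$loglik_trace), 1)
      expect_true(all(diff(f$loglik_trace) > -1e-8))
    }
  }
})

test_that("responsibilities are a proper posterior", {
  d <- build_design(2, 2, 5, seed = 4)
  smp <- sample_mixture(d, 300, seed = 5)
  f <- fit_gmm(smp, 2, control = gmm_control(seed = 6))
  R <- responsibilities(f, smp)
  expect_equal(dim(R), c(300L, 2L))
  expect_lt(max(abs(rowSums(R) - 1)), 1e-12)
  expect_true(all(R >= 0))
})

test_that("permuting the initial components leaves the log-likelihood unchanged", {
  set.seed(7)
  X <- as.matrix(sample_mixture(build_design(2, 2, 5, seed = 7), 400,
                                seed = 8)[paste0("x", 1:2)])
  mu0 <- rbind(c(0, 0), c(1, 1))
  res1 <- ordgmm:::em_core(X, mu0, c(0.5, 0.5), c(1, 1),
                           array(diag(2), c(2, 2, 2)), 0L, 500L, 1e-8, 1e-10)
  res2 <- ordgmm:::em_core(X, mu0[2:1, ], c(0.5, 0.5), c(1, 1),
                           array(diag(2), c(2, 2, 2)), 0L, 500L, 1e-8, 1e-10)
  expect_equal(res1$loglik, res2$loglik, tolerance = 1e-8)
  expect_equal(res1$means, res2$means[2:1, ], tolerance = 1e-6)
})

test_that("component means are recovered consistently on continuous data", {
  d <- build_design(2, 3, 5, seed = 9)
  smp <- sample_mixture(d, 10000, seed = 10)
  f <- fit_gmm(smp, 2, control = gmm_control(seed = 11))
  pm <- match_components(d, f)
  expect_lt(max(abs(d$means - f$means[pm, ])), 0.05)
})

test_that("mean errors shrink as the sample grows", {
  errs <- sapply(1:6, function(i) {
    d <- build_design(2, 2, 3.5, seed = 20 + i)
    vapply(c(1e3, 1e5), function(n) {
      smp <- sample_mixture(d, n, seed = 30 + i)
      f <- fit_gmm(smp, 2, control = gmm_control(seed = i))
      parameter_errors(d, f)$mae_means
    }, numeric(1))
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})

test_that("best log-likelihood agrees with the reference implementation", {
  withr::local_package("mclust")   # Mclust resolves helpers when attached
  set.seed(40)
  for (i in 1:8) {
    d <- build_design(2, 2, sample(c(3.5, 5), 1), seed = 40 + i)
    X <- as.matrix(sample_mixture(d, 500, seed = 50 + i)[paste0("x", 1:2)])
    mine <- fit_gmm(X, 2, control = gmm_control(init = "kmeans", n_init = 10,
                                                seed = i))
    ref <- mclust::Mclust(X, G = 2, modelNames = "VII", verbose = FALSE)
    expect_false(mine$failed)
    # within 1e-3 per observation of the reference optimum
    expect_lt(abs(mine$loglik - ref$loglik), 1e-3 * 500)
  }
})

test_that("BIC selection recovers one component on single-Gaussian data", {
  hits <- vapply(1:8, function(i) {
    X <- matrix(rnorm(5000 * 3, mean = 0.5, sd = sqrt(0.5)), 5000, 3)
    select_k(X, control = gmm_control(seed = i))$k_hat
  }, integer(1))
  expect_gte(mean(hits == 1L), 7 / 8)
})

test_that("BIC selection recovers well-separated components on continuous data", {
  hits <- vapply(1:8, function(i) {
    d <- build_design(2, 3, 5, seed = 60 + i)
    smp <- sample_mixture(d, 10000, seed = 70 + i)
    select_k(smp, control = gmm_control(seed = i))$k_hat
  }, integer(1))
  expect_gte(mean(hits == 2L), 7 / 8)
})

test_that("degenerate fits are reported as failures, not errors", {
  # data supported on two points: any k > 2 spherical fit must collapse
  X <- cbind(rep(c(0, 1), each = 100), rep(c(0, 1), each = 100))
  X <- X + 0   # exact ties
  f <- fit_gmm(X, 4, control = gmm_control(seed = 1))
  expect_true(f$failed)
  expect_match(f$reason, "singular|collapsed|empty|initialization")
  sel <- select_k(X, k_max = 4, control = gmm_control(seed = 1))
  expect_true(sel$table$failed[4])
  expect_false(sel$table$failed[1])
})

test_that("tidy and glance methods expose the fit in tabular form", {
  d <- build_design(2, 2, 5, seed = 12)
  smp <- sample_mixture(d, 400, seed = 13)
  sel <- select_k(smp, k_max = 3, control = gmm_control(seed = 14))
  td <- tidy(sel$selected)
  expect_identical(nrow(td), as.integer(sel$k_hat))
  expect_true(all(c("component", "weight", "variance", "mean_1") %in% names(td)))
  gl <- glance(sel$selected)
  expect_identical(gl$k, sel$k_hat)
  expect_identical(nrow(tidy(sel)), 3L)
})
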