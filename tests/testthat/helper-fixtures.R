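# Random SPD matrix via A A' + diagonal jitter.
random_spd <- function(p, jitter = 0.1) {
  A <- matrix(rnorm(p * p), p, p)
  A %*% t(A) + diag(jitter, p)
}

# Monte-Carlo estimate of KL(N0 || N1) as the mean log-density ratio under
# N0, with its standard error. Independent of the closed form under test.
mc_kl <- function(mean0, cov0, mean1, cov1, n = 1e6) {
  p <- length(mean0)
  R0 <- chol(cov0)
  X <- matrix(rnorm(n * p), n, p) %*% R0
  X <- sweep(X, 2, mean0, "+")
  ld <- function(X, m, S) {
    R <- chol(S)
    z <- backsolve(R, t(sweep(X, 2, m)), transpose = TRUE)
    -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R)))) - 0.5 * colSums(z^2)
  }
  r <- ld(X, mean0, cov0) - ld(X, mean1, cov1)
  list(est = mean(r), se = sd(r) / sqrt(n))
}

# Recursive permutation-matching oracle, independent of the package's
# matcher: enumerates assignments depth-first and tracks the best total
# absolute mean difference.
brute_force_match <- function(true_means, est_means) {
  K <- nrow(true_means)
  best <- list(err = Inf, perm = NULL)
  recurse <- function(assigned, remaining) {
    if (!length(remaining)) {
      err <- mean(abs(true_means - est_means[assigned, , drop = FALSE]))
      if (err < best$err - 1e-15) best <<- list(err = err, perm = assigned)
      return(invisible())
    }
    for (r in remaining) recurse(c(assigned, r), setdiff(remaining, r))
  }
  recurse(integer(0), seq_len(K))
  best
}

fast_control <- function(seed = NULL) gmm_control(seed = seed)
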