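#' Draw a sample from a mixture design
#'
#' Each observation first draws a component label from the mixing weights,
#' then a multivariate Gaussian draw from that component. The returned
#' tibble keeps the true label in `component` and the coordinates in
#' columns `x1 ... xp`, so the whole pipeline stays in data frames.
#'
#' @param design A [mixture_design()].
#' @param n Number of observations.
#' @param seed Optional integer seed; the same `(design, n, seed)` always
#'   reproduces the same sample exactly.
#' @return A tibble with columns `component`, `x1`, ..., `xp` and
#'   attributes `design` and `seed`.
#' @examples
#' d <- build_design(2, 2, 5, seed = 1)
#' smp <- sample_mixture(d, 100, seed = 2)
#' dplyr::count(smp, component)
#' @export
sample_mixture <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "mixture_design"), n >= 1)
  K <- design$K
  p <- design$p
  with_seed(seed, {
    labels <- sample.int(K, n, replace = TRUE, prob = design$weights)
    vals <- matrix(0, n, p)
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (!length(idx)) next
      R <- chol(design$covariances[[k]])
      z <- matrix(stats::rnorm(length(idx) * p), length(idx), p) %*% R
      vals[idx, ] <- sweep(z, 2, design$means[k, ], "+")
    }
    out <- tibble::as_tibble(as.data.frame(vals, col.names = paste0("x", seq_len(p))))
    names(out) <- paste0("x", seq_len(p))
    out <- dplyr::bind_cols(tibble::tibble(component = labels), out)
    attr(out, "design") <- design
    attr(out, "seed") <- seed
    out
  })
}

#' Ordinal thresholds for one variable
#'
#' Computes the 0.5% and 99.5% empirical quantiles of `x`, divides the
#' interval between them into `n_categories` equal-width bins, and labels
#' each bin by its midpoint. For example, thresholds `-1, 0, 1` give the
#' two category labels `-0.5, 0.5`. Labeling categories by interval
#' midpoints keeps the ordinal data on the scale of the latent continuous
#' variable, so estimated component means remain comparable to the truth.
#'
#' @param x Numeric vector (not constant).
#' @param n_categories Number of ordinal categories, at least 2.
#' @param probs Lower and upper quantile levels delimiting the grid;
#'   default `c(0.005, 0.995)`.
#' @param type Quantile estimator passed to [stats::quantile()]; default
#'   the linear-interpolation type 7.
#' @return A list with fields `lower`, `upper`, `cuts` (length
#'   `n_categories + 1`, equally spaced) and `midpoints` (length
#'   `n_categories`).
#' @export
compute_thresholds <- function(x, n_categories, probs = c(0.005, 0.995),
                               type = 7) {
  stopifnot(n_categories >= 2, length(x) >= 2)
  q <- stats::quantile(x, probs, names = FALSE, type = type)
  if (!(q[2] > q[1])) {
    stop("variable is (nearly) constant: degenerate thresholds", call. = FALSE)
  }
  cuts <- seq(q[1], q[2], length.out = n_categories + 1)
  list(
    lower = q[1],
    upper = q[2],
    cuts = cuts,
    midpoints = (cuts[-1] + cuts[-(n_categories + 1)]) / 2
  )
}

#' Threshold table for every variable of a data frame
#'
#' @param data Data frame or matrix; all numeric columns except a
#'   true-label column named `component` are thresholded.
#' @inheritParams compute_thresholds
#' @return A tibble with one row per variable and list-columns `cuts` and
#'   `midpoints`.
#' @export
threshold_table <- function(data, n_categories, probs = c(0.005, 0.995),
                            type = 7) {
  X <- data_matrix(data)
  purrr::map_dfr(colnames(X) %||% paste0("x", seq_len(ncol(X))), function(v) {
    th <- compute_thresholds(X[, v], n_categories, probs, type)
    tibble::tibble(
      variable = v, lower = th$lower, upper = th$upper,
      cuts = list(th$cuts), midpoints = list(th$midpoints)
    )
  })
}

#' Map continuous variables onto midpoint-labeled ordinal categories
#'
#' Each variable is thresholded with its own empirical
#' 0.5%/99.5%-quantile grid (see [compute_thresholds()]): values in bin
#' `i` become that bin's midpoint, and the roughly 1% of values below the
#' lower or above the upper quantile are clamped into the nearest
#' (first or last) category. The mapping is monotone non-decreasing
#' within every column. Values exactly on an interior cut belong to the
#' right bin (half-open intervals, last bin closed).
#'
#' @param data Data frame (e.g. from [sample_mixture()]) or matrix; a
#'   `component` column is carried through unchanged.
#' @param n_categories Number of ordinal categories per variable.
#' @inheritParams compute_thresholds
#' @return A tibble shaped like `data` whose variable columns only take
#'   the per-column midpoint values; the threshold table is stored in
#'   attribute `thresholds`, the category count in `n_categories`.
#' @examples
#' d <- build_design(2, 2, 5, seed = 1)
#' smp <- sample_mixture(d, 500, seed = 2)
#' ord <- discretize(smp, 5)
#' lapply(dplyr::select(ord, -component), function(x) sort(unique(x)))
#' @export
discretize <- function(data, n_categories, probs = c(0.005, 0.995), type = 7) {
  X <- data_matrix(data)
  th <- threshold_table(X, n_categories, probs, type)
  Y <- X
  for (j in seq_len(ncol(X))) {
    cuts <- th$cuts[[j]]
    mids <- th$midpoints[[j]]
    idx <- findInterval(X[, j], cuts)          # [cut_i, cut_{i+1}) bins
    Y[, j] <- mids[pmin(pmax(idx, 1L), n_categories)]
  }
  out <- tibble::as_tibble(as.data.frame(Y))
  if (is.data.frame(data) && "component" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(component = data$component), out)
  }
  attr(out, "thresholds") <- th
  attr(out, "n_categories") <- n_categories
  attr(out, "design") <- attr(data, "design", exact = TRUE)
  out
}
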