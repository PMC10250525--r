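#' Enumerate a simulation condition grid
#'
#' Crosses the design factors into a tibble of conditions, one row each.
#' The full study grid — `K` in 2:4, `p` in 2:10, pairwise KL in
#' \{2, 3.5, 5\}, `n` in \{1000, 2500, 10000\} and category counts 2:12
#' plus continuous — has 2916 conditions. `n_categories = Inf` encodes
#' the continuous (no thresholding) condition.
#'
#' @param K,p,target_kl,n,n_categories Vectors of factor levels.
#' @param family Covariance family used at estimation.
#' @return A tibble with one row per condition and a `condition_id`.
#' @examples
#' nrow(condition_grid())  # 2916
#' @export
condition_grid <- function(K = c(2, 3, 4), p = 2:10,
                           target_kl = c(2, 3.5, 5),
                           n = c(1000, 2500, 10000),
                           n_categories = c(2:12, Inf),
                           family = "spherical") {
  grid <- tidyr::expand_grid(
    K = as.integer(K), p = as.integer(p), target_kl = as.numeric(target_kl),
    n = as.integer(n), n_categories = as.numeric(n_categories),
    family = family
  )
  dplyr::mutate(grid, condition_id = dplyr::row_number(), .before = 1)
}

#' Deterministic per-repetition seed
#'
#' Derives a 31-bit seed from the base seed, the condition factors and
#' the repetition index with an iterated linear congruential mix
#' (multiplier 69069, modulus 2^31 - 1). The category count is *not*
#' part of the seed, so every `n_categories` level of a condition shares
#' the same design and the same continuous sample within a repetition —
#' the ordinal datasets are nested discretizations of one latent draw.
#'
#' @param base_seed Integer base seed of the whole experiment.
#' @param K,p,target_kl,n Condition factors.
#' @param rep Repetition index (1-based).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
rep_seed <- function(base_seed, K, p, target_kl, n, rep) {
  m <- 2147483647
  h <- base_seed %% m
  for (v in c(K, p, round(1000 * target_kl), n, rep)) {
    h <- (h * 69069 + v + 1) %% m
  }
  as.integer(h)
}

#' Run one simulation repetition
#'
#' One full pass of the pipeline: build a fresh random design for the
#' condition, draw the continuous sample, discretize it (skipped when
#' `n_categories` is infinite), select the number of components by BIC
#' under `family`, and score recovery. Fully deterministic given
#' `(base_seed, condition, rep)`. Errors in any stage are caught and
#' recorded in the `error` column rather than aborting a grid run.
#'
#' @param K,p,target_kl,n,n_categories Condition factors (see
#'   [condition_grid()]).
#' @param rep Repetition index.
#' @param base_seed Experiment base seed.
#' @param family Covariance family at estimation.
#' @param k_max Largest number of components considered by [select_k()].
#' @param control A [gmm_control()]; its `seed` field is ignored (the
#'   repetition seed governs all randomness).
#' @param criterion Matching criterion for parameter errors.
#' @return A one-row tibble: the condition columns, `rep`, `seed`, the
#'   [evaluate_recovery()] columns, `n_failed_k` (number of degenerate
#'   fits among `k = 1..k_max`) and `error`.
#' @export
run_repetition <- function(K, p, target_kl, n, n_categories, rep,
                           base_seed = 1, family = "spherical", k_max = 7,
                           control = gmm_control(), criterion = "means") {
  seed <- rep_seed(base_seed, K, p, target_kl, n, rep)
  cond <- tibble::tibble(
    K = as.integer(K), p = as.integer(p), target_kl = target_kl,
    n = as.integer(n), n_categories = as.numeric(n_categories),
    rep = as.integer(rep), seed = seed, family = family
  )
  res <- tryCatch({
    with_seed(seed, {
      design <- build_design(K, p, target_kl)
      smp <- sample_mixture(design, n)
      dat <- if (is.finite(n_categories)) discretize(smp, n_categories) else smp
      control$seed <- NULL
      sel <- select_k(dat, family = family, k_max = k_max, control = control)
      scores <- evaluate_recovery(design, sel, criterion = criterion)
      dplyr::bind_cols(scores, tibble::tibble(
        n_failed_k = sum(sel$table$failed), error = NA_character_
      ))
    })
  }, error = function(e) {
    tibble::tibble(
      k_true = as.integer(K), k_hat = NA_integer_, correct = FALSE,
      mae_means = NA_real_, mae_variances = NA_real_,
      mae_covariances = NA_real_, mae_weights = NA_real_,
      n_failed_k = NA_integer_, error = conditionMessage(e)
    )
  })
  dplyr::bind_cols(cond, res)
}

#' Run a condition grid
#'
#' Executes `reps` repetitions of every condition row, optionally
#' appending each finished repetition to a CSV so an interrupted run can
#' resume. Determinism of the per-repetition seeds makes the resumed
#' table identical to an uninterrupted one.
#'
#' @param grid A [condition_grid()] (any subset of its columns' levels).
#' @param reps Repetitions per condition; the study uses 100.
#' @param base_seed Experiment base seed.
#' @param out_path Optional CSV path for incremental results.
#' @param resume If `TRUE` (default) and `out_path` exists, completed
#'   `(condition_id, rep)` rows are skipped and the file is extended.
#' @param verbose Print per-condition progress to stderr.
#' @inheritParams run_repetition
#' @return A tibble with `nrow(grid) * reps` rows (including any
#'   previously completed ones when resuming).
#' @export
run_grid <- function(grid, reps = 100, base_seed = 1, out_path = NULL,
                     resume = TRUE, verbose = FALSE, k_max = 7,
                     control = gmm_control(), criterion = "means") {
  done <- NULL
  if (!is.null(out_path) && resume && file.exists(out_path)) {
    done <- tibble::as_tibble(utils::read.csv(out_path))
  }
  rows <- tidyr::expand_grid(grid, rep = seq_len(reps))
  todo <- rows
  if (!is.null(done) && nrow(done)) {
    todo <- dplyr::anti_join(rows, done, by = c("condition_id", "rep"))
  }
  out <- purrr::pmap(todo, function(condition_id, K, p, target_kl, n,
                                    n_categories, family, rep, ...) {
    if (verbose) {
      message(sprintf("condition %d rep %d (K=%d p=%d kl=%g n=%d c=%s)",
                      condition_id, rep, K, p, target_kl, n,
                      format(n_categories)))
    }
    row <- run_repetition(K, p, target_kl, n, n_categories, rep,
                          base_seed = base_seed, family = family,
                          k_max = k_max, control = control,
                          criterion = criterion)
    row <- dplyr::bind_cols(tibble::tibble(condition_id = condition_id), row)
    if (!is.null(out_path)) {
      utils::write.table(row, out_path, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_path), append = file.exists(out_path))
    }
    row
  })
  res <- dplyr::bind_rows(done, out)
  dplyr::arrange(res, .data$condition_id, .data$rep)
}

#' Summary tables and figures for a results table
#'
#' Writes the study's standard summaries: accuracy by (categories,
#' variables) per sample size (averaged over `K` and the KL separation),
#' the distribution of the selected number of components by
#' (variables, categories), and matched parameter-error tables, as CSV
#' files plus PNG heatmaps/boxplots. Heatmap cell labels are rounded to
#' two decimals; cells in which no repetition recovered `K` stay blank.
#'
#' @param results Repetition-level tibble from [run_grid()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of the summary tibbles.
#' @export
make_summaries <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acc <- summarize_cells(results, .data$n, .data$p, .data$n_categories)
  khat <- khat_distribution(results, .data$n, .data$p, .data$n_categories)
  err <- summarize_cells(results, .data$n, .data$p, .data$n_categories)

  utils::write.csv(acc, file.path(out_dir, "accuracy_by_p_c.csv"), row.names = FALSE)
  utils::write.csv(khat, file.path(out_dir, "khat_distribution.csv"), row.names = FALSE)
  utils::write.csv(err, file.path(out_dir, "parameter_errors_by_p_c.csv"), row.names = FALSE)

  for (nn in unique(acc$n)) {
    ggplot2::ggsave(
      file.path(out_dir, sprintf("accuracy_heatmap_n%d.png", nn)),
      plot_accuracy_heatmap(dplyr::filter(acc, .data$n == nn)),
      width = 7, height = 5, dpi = 150
    )
    ggplot2::ggsave(
      file.path(out_dir, sprintf("mae_means_heatmap_n%d.png", nn)),
      plot_parameter_errors(dplyr::filter(err, .data$n == nn)),
      width = 7, height = 5, dpi = 150
    )
  }
  ggplot2::ggsave(file.path(out_dir, "khat_boxplots.png"),
                  plot_khat_distribution(results), width = 8, height = 5,
                  dpi = 150)
  invisible(list(accuracy = acc, khat = khat, errors = err))
}
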