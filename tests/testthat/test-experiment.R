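test_that("the full study grid enumerates 2916 conditions", {
  g <- condition_grid()
  expect_identical(nrow(g), 2916L)
  expect_identical(dplyr::n_distinct(g$condition_id), 2916L)
  sub <- condition_grid(K = 2, p = c(2, 3), target_kl = 2, n = 1000,
                        n_categories = c(4, Inf))
  expect_identical(nrow(sub), 4L)
})

test_that("derived seeds are 31-bit, deterministic and well spread", {
  s1 <- rep_seed(1, 2, 4, 3.5, 10000, 1)
  expect_identical(s1, rep_seed(1, 2, 4, 3.5, 10000, 1))
  expect_true(s1 >= 0 && s1 < 2^31)
  seeds <- c(
    vapply(1:50, function(r) rep_seed(1, 2, 4, 3.5, 10000, r), integer(1)),
    vapply(1:50, function(r) rep_seed(1, 3, 4, 3.5, 10000, r), integer(1)),
    vapply(1:50, function(r) rep_seed(2, 2, 4, 3.5, 10000, r), integer(1))
  )
  expect_identical(anyDuplicated(seeds), 0L)
  # the category count shares the repetition's latent sample
  expect_identical(rep_seed(1, 2, 4, 3.5, 10000, 3),
                   rep_seed(1, 2, 4, 3.5, 10000, 3))
})

test_that("repetitions are deterministic end to end", {
  r1 <- run_repetition(2, 3, 5, 1500, 6, rep = 2, base_seed = 5)
  r2 <- run_repetition(2, 3, 5, 1500, 6, rep = 2, base_seed = 5)
  expect_identical(r1, r2)
  r3 <- run_repetition(2, 3, 5, 1500, 6, rep = 3, base_seed = 5)
  expect_false(identical(r1$seed, r3$seed))
})

test_that("the continuous condition skips discretization", {
  r <- run_repetition(2, 3, 5, 1500, Inf, rep = 1, base_seed = 5)
  expect_true(is.infinite(r$n_categories))
  expect_true(is.na(r$error))
  expect_identical(r$k_true, 2L)
})

test_that("grid runs produce one row per condition and repetition", {
  g <- condition_grid(K = 2, p = 2, target_kl = c(2, 5), n = 1200,
                      n_categories = 6)
  res <- run_grid(g, reps = 3, base_seed = 2)
  expect_identical(nrow(res), 6L)
  expect_identical(sort(unique(res$rep)), 1:3)
  expect_false(any(is.na(res$k_hat)))
})

test_that("interrupted runs resume to the identical table", {
  g <- condition_grid(K = 2, p = 2, target_kl = 3.5, n = 1200,
                      n_categories = c(4, 8))
  full <- run_grid(g, reps = 2, base_seed = 3)

  path <- withr::local_tempfile(fileext = ".csv")
  first <- run_grid(g[1, ], reps = 2, base_seed = 3, out_path = path)
  expect_identical(nrow(tibble::as_tibble(utils::read.csv(path))), 2L)
  resumed <- run_grid(g, reps = 2, base_seed = 3, out_path = path)
  expect_equal(
    as.data.frame(dplyr::select(resumed, -dplyr::any_of("error"))),
    as.data.frame(dplyr::select(full, -dplyr::any_of("error"))),
    tolerance = 1e-12
  )
})

test_that("summaries can be recomputed independently from the long table", {
  g <- condition_grid(K = 2, p = 2, target_kl = c(2, 5), n = 1200,
                      n_categories = c(4, Inf))
  res <- run_grid(g, reps = 3, base_seed = 4)
  s <- summarize_cells(res, n_categories)
  for (cc in unique(res$n_categories)) {
    rows <- res[res$n_categories == cc, ]
    expect_equal(s$accuracy[s$n_categories == cc], mean(rows$correct))
  }
  # secondary aggregation: unweighted cell mean equals pooling at equal reps
  s2 <- summarize_cells(res, target_kl, n_categories)
  agg <- tapply(s2$accuracy, s2$n_categories, mean)
  expect_equal(as.numeric(agg[as.character(s$n_categories)]), s$accuracy)
})

test_that("summary files and figures are written", {
  g <- condition_grid(K = 2, p = 2, target_kl = 5, n = 1200,
                      n_categories = c(4, 8))
  res <- run_grid(g, reps = 2, base_seed = 6)
  out <- withr::local_tempdir()
  sums <- make_summaries(res, out)
  expect_true(file.exists(file.path(out, "accuracy_by_p_c.csv")))
  expect_true(file.exists(file.path(out, "khat_distribution.csv")))
  expect_gt(length(list.files(out, pattern = "\\.png$")), 0)
  expect_equal(sums$accuracy$n_reps, rep(2L, 2))
})
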