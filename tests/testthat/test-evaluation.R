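test_that("stratified folds partition the data with balanced classes", {
  labs <- rep(c("normal", "preictal", "ictal"), times = c(40, 40, 40))
  folds <- stratified_kfold(labs, k = 10L, seed = 3L)
  expect_length(folds, 120L)
  expect_setequal(unique(folds), 1:10)
  expect_true(all(table(folds) == 12L))
  for (f in 1:10) {
    expect_true(all(table(labs[folds == f]) == 4L))
  }
  expect_identical(folds, stratified_kfold(labs, k = 10L, seed = 3L))
  expect_false(identical(folds, stratified_kfold(labs, k = 10L, seed = 4L)))
  # uneven classes still differ by at most one per fold
  labs2 <- rep(c("a", "b"), times = c(23, 31))
  folds2 <- stratified_kfold(labs2, k = 5L, seed = 1L)
  per_class <- table(labs2, folds2)
  expect_lte(max(per_class["a", ]) - min(per_class["a", ]), 1L)
  expect_lte(max(per_class["b", ]) - min(per_class["b", ]), 1L)
  expect_error(stratified_kfold(rep(c("a", "b"), c(3, 50)), k = 5L),
               "fewer than k")
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  perfect <- compute_metrics(confusion_counts(50, 0, 50, 0))
  expect_equal(unlist(perfect), c(accuracy = 100, sensitivity = 100,
                                  specificity = 100, precision = 100,
                                  f1 = 100))
  m <- compute_metrics(confusion_counts(40, 5, 45, 10))
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 90)
  expect_equal(m$precision, 100 * 40 / 45)
  expect_equal(m$f1, 100 * 2 * (40 / 45) * 0.8 / (40 / 45 + 0.8))
  # harmonic-mean identity
  expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                 (m$precision + m$sensitivity))
  # undefined denominators are NA, not zero
  und <- compute_metrics(confusion_counts(0, 0, 10, 0))
  expect_true(is.na(und$precision))
  expect_true(is.na(und$f1))
  expect_equal(und$specificity, 100)
  expect_error(confusion_counts(-1, 0, 0, 1), "non-negative")
})

test_that("Kruskal-Wallis H matches the rank-sum oracle", {
  g1 <- list(c(1, 2, 3), c(10, 11, 12))
  kw <- kruskal_wallis(g1)
  expect_equal(kw$statistic, oracle_kruskal_h(g1), tolerance = 1e-9)
  expect_lt(kw$p_value, 0.05)
  # symmetric groups have identical mean ranks
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  # random groups, with ties, against the oracle
  for (s in 1:10) {
    gs <- withr::with_seed(s, {
      lapply(1:3, function(i) sample(1:6, sample(3:8, 1), replace = TRUE))
    })
    expect_equal(kruskal_wallis(gs)$statistic, oracle_kruskal_h(gs),
                 tolerance = 1e-9)
  }
  # degenerate all-identical observations use the documented convention
  deg <- kruskal_wallis(list(5, 5, 5))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2))), ">= 2 groups")
  expect_error(kruskal_wallis(list(numeric(0), c(1, 2))), "non-empty")
})

make_cv_result <- function(acc, seed = 1L) {
  per_fold <- withr::with_seed(seed, {
    data.frame(fold = seq_along(acc), accuracy = acc,
               sensitivity = acc + stats::rnorm(length(acc), 0, 0.1),
               specificity = acc, precision = acc, f1 = acc)
  })
  structure(list(folds = rep(seq_along(acc), 2), per_fold = per_fold,
                 summary = NULL, method = "toy"), class = "cv_result")
}

test_that("method comparison flags separated methods, not identical ones", {
  a <- make_cv_result(c(91, 92, 93, 94, 95))
  b <- make_cv_result(c(71, 72, 73, 74, 75), seed = 2L)
  tab <- compare_methods(list(a, b))
  expect_equal(nrow(tab), 5L)
  expect_true(tab$significant[tab$metric == "accuracy"])
  self <- compare_methods(list(a, a))
  expect_equal(self$H[self$metric == "accuracy"], 0, tolerance = 1e-9)
  expect_error(compare_methods(list(a)), ">= 2")
  short <- make_cv_result(c(91, 92))
  expect_error(compare_methods(list(a, short)), "mismatched fold counts")
})

test_that("a miniature pipeline run is deterministic and well-formed", {
  cfg <- pipeline_config(
    n_per_class = 12L, segment_lengths_s = 2, k = 3L,
    member_specs = list(list(conv_layer_spec(3L, 4L))),
    epochs = 2L, hso = hso_config(m = 5L, max_iterations = 5L),
    generator = generator_config(n_channels = 1L), seed = 42L
  )
  res <- run_pipeline(cfg)
  expect_s3_class(res, "pipeline_result")
  expect_equal(nrow(res$report), 5L)
  expect_setequal(res$report$metric,
                  c("accuracy", "sensitivity", "specificity", "precision", "f1"))
  cv <- res$cv[["2"]]
  expect_equal(nrow(cv$per_fold), 3L)
  # folds partition all samples
  expect_length(cv$folds, 36L)
  expect_true(all(table(cv$folds) == 12L))
  # report means equal the mean of per-fold values
  expect_equal(res$report$mean[res$report$metric == "accuracy"],
               mean(cv$per_fold$accuracy), tolerance = 1e-9)
  # per-fold F1 satisfies the harmonic identity where defined
  ok <- !is.na(cv$per_fold$f1)
  expect_equal(cv$per_fold$f1[ok],
               2 * cv$per_fold$precision[ok] * cv$per_fold$sensitivity[ok] /
                 (cv$per_fold$precision[ok] + cv$per_fold$sensitivity[ok]),
               tolerance = 1e-9)
  # end-to-end determinism
  res2 <- run_pipeline(cfg)
  expect_identical(res$report, res2$report)
  # CSV report writer round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(res, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(res$report))
})

test_that("pipeline configs survive a JSON round trip", {
  td <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(n_per_class = 15, segment_lengths_s = 4, k = 3,
         generator = list(seed = 9, n_channels = 2),
         hso = list(m = 6, max_iterations = 10)),
    td, auto_unbox = TRUE)
  cfg <- read_pipeline_config(td)
  expect_identical(cfg$n_per_class, 15L)
  expect_identical(cfg$generator$n_channels, 2L)
  expect_identical(cfg$hso$m, 6L)
})
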