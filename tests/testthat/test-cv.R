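test_that("folds partition the observed pairs and are seed-deterministic", {
  pairs <- random_pairs(12, 10, 0.6, seed = 2)
  fa <- build_folds(pairs, k = 5, seed = 3)
  expect_identical(nrow(fa), nrow(pairs))
  expect_true(all(fa$fold %in% 0:4))
  expect_identical(length(unique(fa$fold)), 5L)

  fa2 <- build_folds(pairs, k = 5, seed = 3)
  expect_identical(fa$fold, fa2$fold)
  fa3 <- build_folds(pairs, k = 5, seed = 4)
  expect_false(identical(fa$fold, fa3$fold))

  expect_error(build_folds(pairs[1:3, ], k = 5),
               class = "simdta_input_error")
  expect_error(build_folds(pairs, k = 3, min_folds_per_target = 4),
               class = "simdta_input_error")
})

test_that("every sufficiently observed target spans the required folds", {
  withr::with_seed(30, seeds <- sample.int(1e6, 25))
  for (s in seeds) {
    pairs <- random_pairs(sample(8:15, 1), sample(6:12, 1),
                          runif(1, 0.3, 0.9), seed = s)
    if (nrow(pairs) < 5) next
    for (k in c(3L, 5L)) {
      if (nrow(pairs) < k) next
      need <- default_min_folds(k)
      fa <- build_folds(pairs, k = k, seed = s)
      spread <- tapply(fa$fold, fa$target_index,
                       function(f) length(unique(f)))
      count <- tapply(fa$fold, fa$target_index, length)
      expect_true(all(spread >= pmin(need, count)))
    }
  }
})

test_that("a single-observation target occupies exactly one fold", {
  pairs <- random_pairs(10, 8, 0.5, seed = 6)
  lone <- pairs$target_index[!duplicated(pairs$target_index)][1]
  pairs <- pairs[pairs$target_index != lone | !duplicated(pairs$target_index), ]
  keep <- pairs$target_index == lone
  expect_identical(sum(keep), 1L)
  fa <- build_folds(pairs, k = 3, seed = 1)
  expect_identical(length(unique(fa$fold[keep])), 1L)
})

test_that("fold sizes stay within 10% of balance", {
  for (s in c(5, 17, 99)) {
    pairs <- random_pairs(15, 12, 0.7, seed = s)
    for (k in c(3L, 5L)) {
      fa <- build_folds(pairs, k = k, seed = s)
      sizes <- tabulate(fa$fold + 1L, nbins = k)
      expect_lte(max(sizes), ceiling(1.1 * nrow(pairs) / k))
    }
  }
})

test_that("fold assignments round-trip through CSV", {
  pairs <- random_pairs(8, 6, 0.6, seed = 9)
  fa <- build_folds(pairs, k = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_folds(fa, path)
  back <- read_folds(path)
  expect_identical(back$drug_id, fa$drug_id)
  expect_identical(back$target_id, fa$target_id)
  expect_identical(back$fold, fa$fold)
})

test_that("cross-validation yields disjoint test folds and reproducible reports", {
  spec <- synthetic_spec(n_drugs = 8, n_targets = 7, n_drug_clusters = 2,
                         n_target_clusters = 2, missing_rate = 0.05,
                         seed = 21)
  ds <- generate_dataset(spec)
  cv <- run_cv(ds, k = 3, cfg = fast_cfg(epochs = 2L), threshold = 5.9,
               n_bits = 256L, seed = 11)

  expect_identical(nrow(cv$per_fold), 3L)
  expect_identical(cv$per_fold$fold, 0:2)
  expect_identical(sum(cv$per_fold$n), nrow(cv$assignment))
  # disjoint coverage: each pair tested exactly once
  expect_identical(sort(unique(cv$assignment$fold)), 0:2)

  cv2 <- run_cv(ds, k = 3, cfg = fast_cfg(epochs = 2L), threshold = 5.9,
                n_bits = 256L, seed = 11)
  expect_identical(cv$per_fold, cv2$per_fold)

  # mean/SE summary equals hand aggregation of the per-fold values
  for (met in c("mse", "ci", "rm2", "aupr")) {
    vals <- cv$per_fold[[met]]
    row <- cv$summary[cv$summary$metric == met, ]
    expect_equal(row$mean, mean(vals, na.rm = TRUE))
    expect_equal(row$se,
                 sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals))))
  }

  gl <- glance(cv)
  expect_equal(gl$ci_mean, cv$summary$mean[cv$summary$metric == "ci"])
  td <- tidy(cv)
  expect_identical(td, cv$per_fold)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("cross-validation reports can be written for external statistics", {
  spec <- synthetic_spec(n_drugs = 8, n_targets = 7, n_drug_clusters = 2,
                         n_target_clusters = 2, missing_rate = 0.05,
                         seed = 21)
  ds <- generate_dataset(spec)
  cv <- run_cv(ds, k = 3, cfg = fast_cfg(epochs = 1L), threshold = 5.9,
               n_bits = 256L, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_cv_report(cv, file.path(dir, "folds.csv"),
                           file.path(dir, "summary.json"))
  folds_csv <- readr::read_csv(paths$csv, show_col_types = FALSE)
  expect_identical(nrow(folds_csv), 12L)  # 3 folds x 4 metrics
  summ <- jsonlite::read_json(paths$json, simplifyVector = TRUE)
  expect_identical(sort(names(summ)), sort(c("mse", "ci", "rm2", "aupr")))
  expect_equal(summ$ci$mean, cv$summary$mean[cv$summary$metric == "ci"])
})
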