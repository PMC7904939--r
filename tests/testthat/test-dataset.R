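test_that("Kd-to-pKd transform hits the anchor points and is decreasing", {
  expect_identical(kd_to_pkd(10000), 5)
  expect_identical(kd_to_pkd(1e9), 0)
  expect_identical(kd_to_pkd(1), 9)
  kd <- c(0.1, 1, 10, 1e4, 1e8)
  expect_true(all(diff(kd_to_pkd(kd)) < 0))
  expect_error(kd_to_pkd(0), class = "simdta_input_error")
  expect_error(kd_to_pkd(-5), class = "simdta_input_error")
})

test_that("KIBA transform follows the three-step recipe", {
  expect_identical(transform_kiba(c(3, 5, 10)), c(7, 5, 0))
  expect_identical(transform_kiba(4.7), 0)
  dec <- c(9, 6, 2, 0.5)
  expect_true(all(diff(transform_kiba(dec)) > 0))
  expect_error(transform_kiba(numeric(0)), class = "simdta_input_error")
})

test_that("KIBA transform is affine and order-reversing", {
  withr::with_seed(13, x <- rnorm(20, 10, 4))
  twice <- transform_kiba(transform_kiba(x))
  expect_equal(outer(twice, twice, "-"), outer(x, x, "-"))
  expect_identical(order(transform_kiba(x)), rev(order(x)))
  expect_identical(min(transform_kiba(x)), 0)
})

test_that("weighted imputation matches hand arithmetic and degrades safely", {
  expect_equal(impute_affinity(c(2, 4), c(0.5, 1)), 10 / 3)
  expect_equal(impute_affinity(c(2, 4, 9), c(1, 1, 1)), 5)
  expect_identical(impute_affinity(7.3, 0.2), 7.3)
  expect_warning(out <- impute_affinity(c(2, 4), c(0, 0)), "zero")
  expect_equal(out, 3)
  expect_error(impute_affinity(c(1, 2), c(1, -1)),
               class = "simdta_input_error")
  expect_error(impute_affinity(numeric(0), numeric(0)),
               class = "simdta_input_error")
})

test_that("dataset imputation fills missing cells from target similarity", {
  ds <- toy_dataset()
  k2 <- target_similarity_matrix(ds$targets)
  full <- impute_missing_affinities(ds, k2)
  expect_identical(dataset_density(full), 1)
  # the one missing cell: drug 2, target 2 imputed from targets 1 and 3
  want <- impute_affinity(ds$y[2, c(1, 3)], k2[2, c(1, 3)])
  expect_equal(full$y[2, 2], want)
  # observed cells untouched
  expect_identical(full$y[ds$observed], ds$y[ds$observed])
})

test_that("dataset constructor enforces shapes, ids and mask consistency", {
  expect_s3_class(toy_dataset(), "affinity_dataset")
  expect_error(
    affinity_dataset(toy_drugs(), toy_targets(), matrix(1, 2, 3)),
    "rosters", class = "simdta_input_error")
  d2 <- toy_drugs(); d2$drug_id[2] <- "eth"
  expect_error(affinity_dataset(d2, toy_targets(), matrix(1, 4, 3)),
               "Duplicate", class = "simdta_input_error")
  y <- matrix(1, 4, 3)
  obs <- matrix(TRUE, 4, 3); obs[1, 1] <- FALSE
  ds <- affinity_dataset(toy_drugs(), toy_targets(), y, obs)
  expect_true(is.na(ds$y[1, 1]))
})

test_that("observed pairs enumerate true cells in row-major order", {
  ds <- toy_dataset()
  pairs <- observed_pairs(ds)
  expect_identical(nrow(pairs), 11L)
  expect_identical(pairs$drug_index[1:3], c(1L, 1L, 1L))
  expect_identical(pairs$target_index[1:3], 1:3)
  # missing cell (2,2) skipped
  expect_false(any(pairs$drug_index == 2 & pairs$target_index == 2))
  expect_identical(pairs$affinity,
                   ds$y[cbind(pairs$drug_index, pairs$target_index)])

  one <- affinity_dataset(
    toy_drugs(), toy_targets(),
    matrix(c(NA, NA, 4.4, rep(NA, 9)), 4, 3), scale = "pKd")
  p1 <- observed_pairs(one)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$drug_index, 3L)
  expect_identical(p1$target_index, 1L)
})

test_that("density reflects the observed fraction", {
  expect_equal(dataset_density(toy_dataset()), 11 / 12)
  full <- affinity_dataset(toy_drugs(), toy_targets(), matrix(1, 4, 3))
  expect_identical(dataset_density(full), 1)
})

test_that("scale transforms apply only on their input scale", {
  kd <- affinity_dataset(toy_drugs(), toy_targets(),
                         matrix(10000, 4, 3), scale = "Kd_nM")
  pkd <- apply_pkd_transform(kd)
  expect_identical(pkd$scale, "pKd")
  expect_true(all(pkd$y == 5))
  expect_error(apply_pkd_transform(pkd), class = "simdta_input_error")

  raw <- affinity_dataset(toy_drugs(), toy_targets(),
                          matrix(c(3, 5, 10, rep(3, 9)), 4, 3),
                          scale = "KIBA_raw")
  tr <- apply_kiba_transform(raw)
  expect_identical(tr$scale, "KIBA_transformed")
  expect_identical(min(tr$y), 0)
})

test_that("datasets round-trip through the writers and loader", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- load_dataset(file.path(dir, "drugs.tsv"),
                       file.path(dir, "targets.fasta"),
                       file.path(dir, "affinities.csv"), scale = "pKd")
  expect_identical(back$y, ds$y)
  expect_identical(back$observed, ds$observed)
  expect_identical(back$drugs$drug_id, ds$drugs$drug_id)
  expect_identical(back$drugs$smiles, ds$drugs$smiles)
  expect_identical(back$targets$sequence, ds$targets$sequence)
  expect_identical(back$scale, "pKd")
})

test_that("the loader flags malformed affinity files with context", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  aff <- file.path(dir, "affinities.csv")

  # '.' and 'NA' also count as missing
  lines <- readLines(aff)
  lines[2] <- sub("^([^,]*),[^,]*", "\\1,.", lines[2])
  lines[3] <- sub("^([^,]*),[^,]*", "\\1,NA", lines[3])
  alt <- file.path(dir, "alt.csv")
  writeLines(lines, alt)
  back <- load_dataset(file.path(dir, "drugs.tsv"),
                       file.path(dir, "targets.fasta"), alt, scale = "pKd")
  expect_identical(sum(back$observed), sum(ds$observed) - 2L)

  # non-numeric cell errors with drug/target context
  lines2 <- readLines(aff)
  lines2[2] <- sub("^([^,]*),[^,]*", "\\1,abc", lines2[2])
  bad <- file.path(dir, "bad.csv")
  writeLines(lines2, bad)
  expect_error(load_dataset(file.path(dir, "drugs.tsv"),
                            file.path(dir, "targets.fasta"), bad,
                            scale = "pKd"),
               "abc", class = "simdta_input_error")

  # roster mismatch errors
  lines3 <- readLines(aff)
  lines3[2] <- sub("^[^,]*", "UNKNOWN", lines3[2])
  mis <- file.path(dir, "mis.csv")
  writeLines(lines3, mis)
  expect_error(load_dataset(file.path(dir, "drugs.tsv"),
                            file.path(dir, "targets.fasta"), mis,
                            scale = "pKd"),
               "UNKNOWN", class = "simdta_input_error")
})
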