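test_that("shape arithmetic matches valid convolution/pooling closed forms", {
  sh <- model_shapes(20, 20)
  expect_equal(sh$layers$height, c(20, 16, 15, 13, 12))
  expect_equal(sh$flatten_length, 12 * 12 * 18)

  sh2 <- model_shapes(68, 442)
  expect_equal(sh2$layers$height[5], 68 - 8)
  expect_equal(sh2$layers$width[5], 442 - 8)

  expect_error(model_shapes(8, 20), "receptive field",
               class = "simdta_config_error")
  expect_error(model_shapes(20, 5), class = "simdta_config_error")
})

test_that("parameter count matches closed-form layer arithmetic", {
  m <- build_model(20, 15)
  flat <- model_shapes(20, 15)$flatten_length
  want <- (5 * 5 * 1 * 32 + 32) + (3 * 3 * 32 * 18 + 18) +
    (flat * 128 + 128) + (128 * 1 + 1)
  expect_identical(n_parameters(m), as.integer(want))
})

test_that("training reduces loss below the constant-mean baseline", {
  withr::with_seed(2, {
    ex <- lapply(1:48, function(i) {
      g <- matrix(runif(9 * 8), 9, 8)
      list(grid = g, affinity = 10 * mean(g) + rnorm(1, 0, 0.05))
    })
  })
  cfg <- fast_cfg(epochs = 60L, seed = 9L)
  cfg$learning_rate <- 0.005
  m <- train(ex, cfg)
  expect_true(all(is.finite(m$history)))
  y <- vapply(ex, `[[`, numeric(1), "affinity")
  yhat <- predict(m, lapply(ex, `[[`, "grid"))
  expect_lt(mse(y, yhat), mse(y, rep(mean(y), length(y))))
})

test_that("training is deterministic under the seed and epochs=0 is the init", {
  withr::with_seed(6, {
    ex <- lapply(1:10, function(i)
      list(grid = matrix(runif(30), 6, 5), affinity = rnorm(1)))
  })
  m1 <- train(ex, fast_cfg(epochs = 2L, seed = 5L))
  m2 <- train(ex, fast_cfg(epochs = 2L, seed = 5L))
  expect_identical(m1$params, m2$params)
  m3 <- train(ex, fast_cfg(epochs = 2L, seed = 6L))
  expect_false(identical(m1$params, m3$params))

  m0 <- train(ex, fast_cfg(epochs = 0L, seed = 5L))
  built <- build_model(6, 5, fast_cfg(epochs = 0L, seed = 5L))
  expect_identical(m0$params, built$params)
  expect_false(m0$trained)
})

test_that("mismatched example grids are rejected", {
  ex <- list(list(grid = matrix(1, 6, 5), affinity = 1),
             list(grid = matrix(1, 5, 6), affinity = 2))
  expect_error(train(ex, fast_cfg()), class = "simdta_input_error")
})

test_that("prediction preserves order and is batch-partition invariant", {
  withr::with_seed(14, {
    ex <- lapply(1:9, function(i)
      list(grid = matrix(runif(42), 7, 6), affinity = rnorm(1)))
  })
  m <- train(ex, fast_cfg(epochs = 2L))
  grids <- lapply(ex, `[[`, "grid")
  all_at_once <- predict(m, grids)
  one_by_one <- vapply(grids, function(g) predict(m, g), numeric(1))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
  in_threes <- unlist(lapply(c(1, 4, 7), function(s)
    predict(m, grids[s:(s + 2)])))
  expect_equal(all_at_once, in_threes, tolerance = 1e-12)

  dup <- predict(m, list(grids[[1]], grids[[1]]))
  expect_identical(dup[1], dup[2])

  expect_error(predict(m, matrix(1, 3, 3)), class = "simdta_input_error")
})

test_that("dropout perturbs training but never prediction", {
  withr::with_seed(15, {
    ex <- lapply(1:12, function(i)
      list(grid = matrix(runif(30), 6, 5), affinity = rnorm(1)))
  })
  m <- train(ex, fast_cfg(epochs = 2L, dropout_rate = 0.5))
  g <- ex[[1]]$grid
  expect_identical(predict(m, g), predict(m, g))
})

test_that("fitted models rank candidates by predicted affinity, stably", {
  spec <- synthetic_spec(n_drugs = 9, n_targets = 9, n_drug_clusters = 3,
                         n_target_clusters = 3, seed = 4)
  ds <- generate_dataset(spec)
  m <- fit_affinity_model(ds, fast_cfg(epochs = 2L), n_bits = 256L)

  cands <- tibble::tibble(
    drug_id = c("c1", "c2", "c3"),
    smiles = c("CCc1ccccc1", "OCCC1CCNCC1", "ClCCC1CCOC1"))
  rk <- rank_candidates(m, cands, ds$targets$sequence[1])
  expect_identical(nrow(rk), 3L)
  expect_identical(rk$rank, 1:3)
  expect_true(all(diff(rk$predicted_affinity) <= 0))

  # duplicated candidate: equal scores, adjacent ranks, input order kept
  dup <- tibble::tibble(drug_id = c("a", "b"), smiles = rep("CCCO", 2))
  rk2 <- rank_candidates(m, dup, ds$targets$sequence[1])
  expect_identical(rk2$predicted_affinity[1], rk2$predicted_affinity[2])
  expect_identical(rk2$drug_id, c("a", "b"))

  # invalid SMILES skipped with a warning, valid ones still ranked
  bad <- tibble::tibble(drug_id = c("ok", "broken"),
                        smiles = c("CCO", "Qxx((("))
  expect_warning(rk3 <- rank_candidates(m, bad, ds$targets$sequence[1]),
                 "broken")
  expect_identical(rk3$drug_id, "ok")
})

test_that("models persist and reload with bitwise-identical predictions", {
  spec <- synthetic_spec(n_drugs = 9, n_targets = 9, n_drug_clusters = 3,
                         n_target_clusters = 3, seed = 4)
  ds <- generate_dataset(spec)
  m <- fit_affinity_model(ds, fast_cfg(epochs = 2L), n_bits = 256L)
  dir <- withr::local_tempdir()
  save_model(m, file.path(dir, "model"))
  m2 <- load_model(file.path(dir, "model"))

  k1 <- drug_similarity_matrix(ds$drugs, n_bits = 256L)
  k2 <- target_similarity_matrix(ds$targets)
  ex <- build_pair_inputs(ds, observed_pairs(ds)[1:5, ], k1, k2)
  expect_identical(predict(m, ex), predict(m2, ex))
  expect_identical(m2$drug_roster$drug_id, ds$drugs$drug_id)
  expect_identical(m2$target_roster$sequence, ds$targets$sequence)
  expect_identical(m2$n_bits, 256L)

  expect_error(load_model(file.path(dir, "nothing_here")),
               class = "simdta_input_error")
  corrupt <- file.path(dir, "corrupt")
  dir.create(corrupt)
  writeLines("not json{", file.path(corrupt, "manifest.json"))
  writeLines("x", file.path(corrupt, "weights.rds"))
  expect_error(load_model(corrupt), class = "simdta_input_error")
})

test_that("tidy and glance summarise training history", {
  withr::with_seed(16, {
    ex <- lapply(1:8, function(i)
      list(grid = matrix(runif(30), 6, 5), affinity = rnorm(1)))
  })
  m <- train(ex, fast_cfg(epochs = 3L))
  td <- tidy(m)
  expect_identical(td$epoch, 1:3)
  expect_true(all(is.finite(td$train_mse)))
  gl <- glance(m)
  expect_identical(gl$epochs, 3L)
  expect_identical(gl$n_train, 8L)
  expect_identical(gl$final_train_mse, td$train_mse[3])
  expect_s3_class(autoplot(m), "ggplot")
})
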