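#' Model configuration for the affinity CNN
#'
#' Architecture and optimisation constants of the two-layer 2D convolutional
#' regressor. The defaults are the published constants of the method: 32 and
#' 18 filters with 5x5 and 3x3 kernels (no padding), overlapping 2x2
#' max-pooling with stride 1 after each convolution, a 0.1-rate dropout before
#' a 128-unit ReLU layer and a linear scalar output, trained with Adam at
#' learning rate 0.001, batch size 32, 20 epochs under mean-squared-error
#' loss. `seed` governs weight initialisation, epoch shuffling and dropout.
#'
#' @param conv_filters Integer vector of length 2: filters per conv layer.
#' @param conv_kernels List of two length-2 integer vectors: kernel sizes.
#' @param pool_size,pool_stride Max-pooling window edge and stride.
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param fc_width Width of the hidden fully connected layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (0 returns the initialised model).
#' @param seed Integer RNG seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_filters = c(32L, 18L),
                         conv_kernels = list(c(5L, 5L), c(3L, 3L)),
                         pool_size = 2L, pool_stride = 1L,
                         dropout_rate = 0.1, fc_width = 128L,
                         learning_rate = 0.001, batch_size = 32L,
                         epochs = 20L, seed = 42L) {
  stopifnot(
    length(conv_filters) == 2L, all(conv_filters >= 1L),
    length(conv_kernels) == 2L,
    all(vapply(conv_kernels, length, 0L) == 2L),
    all(unlist(conv_kernels) >= 1L),
    pool_size >= 1L, pool_stride >= 1L,
    dropout_rate >= 0, dropout_rate < 1,
    fc_width >= 1L, learning_rate > 0, batch_size >= 1L, epochs >= 0L
  )
  structure(
    list(conv_filters = as.integer(conv_filters),
         conv_kernels = lapply(conv_kernels, as.integer),
         pool_size = as.integer(pool_size),
         pool_stride = as.integer(pool_stride),
         dropout_rate = as.numeric(dropout_rate),
         fc_width = as.integer(fc_width),
         learning_rate = as.numeric(learning_rate),
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Per-layer output shapes of the affinity CNN
#'
#' Valid-convolution and pooling arithmetic for an `n_d` x `n_t` input grid:
#' a k-kernel valid convolution maps n to n - k + 1 and a pooling window of
#' size p with stride s maps n to floor((n - p) / s) + 1. Errors if any
#' spatial extent would become nonpositive, stating the minimum input size.
#'
#' @param n_d,n_t Input grid height (drugs) and width (targets).
#' @param cfg A [model_config()].
#' @return A list with a `layers` tibble (layer, height, width, channels) and
#'   `flatten_length`.
#' @export
model_shapes <- function(n_d, n_t, cfg = model_config()) {
  # receptive-field minimum so that the final feature map is >= 1 x 1
  min_n <- cfg$conv_kernels[[1L]][1L] - 1L +
    (cfg$pool_size - 1L) + cfg$conv_kernels[[2L]][1L] - 1L +
    (cfg$pool_size - 1L) + 1L
  h <- as.integer(c(n_d, shrink_dim(n_d, cfg, 1L)))
  w <- as.integer(c(n_t, shrink_dim(n_t, cfg, 2L)))
  if (any(h[-1L] < 1L) || any(w[-1L] < 1L)) {
    abort(sprintf(
      "Input grid %d x %d too small for the receptive field; with this configuration both dimensions must be >= %d.",
      n_d, n_t, min_n), class = "simdta_config_error")
  }
  ch <- c(1L, cfg$conv_filters[1L], cfg$conv_filters[1L],
          cfg$conv_filters[2L], cfg$conv_filters[2L])
  layers <- tibble(
    layer = c("input", "conv1", "pool1", "conv2", "pool2"),
    height = h, width = w, channels = ch
  )
  list(layers = layers,
       flatten_length = as.integer(h[5L] * w[5L] * ch[5L]))
}

# spatial extent after each stage along dimension `dim` (1 = height/drugs,
# 2 = width/targets); pooling strides can differ from 1 only via config
shrink_dim <- function(n, cfg, dim) {
  n1 <- n - cfg$conv_kernels[[1L]][dim] + 1L
  n2 <- if (n1 >= cfg$pool_size) pool_out_len(n1, cfg$pool_size, cfg$pool_stride) else 0L
  n3 <- n2 - cfg$conv_kernels[[2L]][dim] + 1L
  n4 <- if (n3 >= cfg$pool_size) pool_out_len(n3, cfg$pool_size, cfg$pool_stride) else 0L
  c(n1, n2, n3, n4)
}

#' Build an untrained affinity CNN
#'
#' Initialises the network for `n_d` x `n_t` outer-product inputs with
#' Glorot-uniform weights (zero biases) under the configuration seed.
#'
#' @inheritParams model_shapes
#' @return An object of class `sim_cnn` with untrained weights.
#' @export
build_model <- function(n_d, n_t, cfg = model_config()) {
  shapes <- model_shapes(n_d, n_t, cfg)
  params <- withr::with_seed(cfg$seed, init_params(shapes, cfg))
  new_sim_cnn(params, cfg, c(n_d, n_t), shapes, history = numeric(0),
              trained = FALSE)
}

new_sim_cnn <- function(params, cfg, input_shape, shapes, history, trained,
                        drug_roster = NULL, target_roster = NULL,
                        n_bits = NULL, scoring = NULL, n_train = 0L) {
  structure(
    list(params = params, cfg = cfg, input_shape = as.integer(input_shape),
         shapes = shapes, history = history, trained = trained,
         drug_roster = drug_roster, target_roster = target_roster,
         n_bits = n_bits, scoring = scoring, n_train = as.integer(n_train)),
    class = "sim_cnn"
  )
}

#' @export
print.sim_cnn <- function(x, ...) {
  cat(sprintf(
    "<sim_cnn> %s, input %d x %d, %d parameters, %d epoch(s) trained on %d example(s)\n",
    if (x$trained) "trained" else "untrained",
    x$input_shape[1L], x$input_shape[2L], n_parameters(x),
    length(x$history), x$n_train))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `sim_cnn` object.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' Train the affinity CNN on outer-product examples
#'
#' Minimises mean-squared error with Adam. Examples are shuffled every epoch;
#' initialisation, shuffling and dropout all draw from one RNG stream seeded
#' by `cfg$seed`, so two runs with the same seed produce identical weights.
#' With `cfg$epochs = 0` the initialised model is returned unchanged.
#'
#' @param examples Outer-product training examples: output of
#'   [build_pair_inputs()] (a data frame with a `grid` list-column and an
#'   `affinity` column), or a list of `list(grid =, affinity =)` entries.
#' @param cfg A [model_config()].
#' @return A trained `sim_cnn` model.
#' @export
train <- function(examples, cfg = model_config()) {
  ex <- normalize_examples(examples)
  provider <- function(idx) {
    list(x = stack_grids(ex$grids[idx], ex$shape), y = ex$y[idx])
  }
  train_impl(provider, length(ex$y), ex$shape, cfg)
}

normalize_examples <- function(examples) {
  if (is.data.frame(examples)) {
    if (!all(c("grid", "affinity") %in% names(examples))) {
      abort("`examples` data frame needs `grid` and `affinity` columns.",
            class = "simdta_input_error")
    }
    grids <- examples$grid
    y <- examples$affinity
  } else if (is.list(examples)) {
    grids <- lapply(examples, `[[`, "grid")
    y <- vapply(examples, `[[`, numeric(1), "affinity")
  } else {
    abort("`examples` must be a data frame or a list.",
          class = "simdta_input_error")
  }
  if (length(grids) < 1L) {
    abort("Need at least one training example.", class = "simdta_input_error")
  }
  dims <- vapply(grids, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    abort("All example grids must share one shape.",
          class = "simdta_input_error")
  }
  list(grids = grids, y = as.numeric(y), shape = dims[, 1L])
}

stack_grids <- function(grids, shape) {
  X <- array(0, c(shape[1L], shape[2L], 1L, length(grids)))
  for (n in seq_along(grids)) X[, , 1L, n] <- grids[[n]]
  X
}

# Core loop over a batch provider: provider(idx) -> list(x = (h,w,1,n), y).
# Grids may equally be rebuilt per batch from similarity-matrix columns; the
# training trajectory is identical either way.
train_impl <- function(provider, n, shape, cfg, rosters = NULL) {
  shapes <- model_shapes(shape[1L], shape[2L], cfg)
  withr::with_seed(cfg$seed, {
    params <- init_params(shapes, cfg)
    state <- adam_init(params)
    history <- numeric(0)
    if (cfg$epochs > 0L) {
      for (ep in seq_len(cfg$epochs)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = cfg$batch_size)
        ep_sse <- 0
        for (s in starts) {
          idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
          batch <- provider(idx)
          fw <- nn_forward(params, batch$x, cfg, training = TRUE)
          resid <- fw$yhat - batch$y
          ep_sse <- ep_sse + sum(resid^2)
          dy <- 2 * resid / length(idx)
          grads <- nn_backward(params, fw$cache, dy, cfg)
          upd <- adam_step(params, grads, state, cfg$learning_rate)
          params <- upd$params
          state <- upd$state
        }
        history <- c(history, ep_sse / n)
        if (!all(is.finite(history))) {
          abort("Training loss diverged (non-finite).",
                class = "simdta_internal_error")
        }
      }
    }
  })
  new_sim_cnn(params, cfg, shape, shapes, history = history,
              trained = cfg$epochs > 0L,
              drug_roster = rosters$drugs, target_roster = rosters$targets,
              n_bits = rosters$n_bits, scoring = rosters$scoring,
              n_train = n)
}

#' Train from precomputed similarity matrices and pair records
#'
#' Streaming form of [train()]: instead of materialising every outer-product
#' grid up front, each minibatch's grids are rebuilt on the fly from the
#' columns of `k1` and `k2`. The trajectory is value-identical to training on
#' materialised grids; memory stays bounded by one batch.
#'
#' @param k1 Drug similarity matrix over the training drug roster.
#' @param k2 Target similarity matrix over the training target roster.
#' @param pairs Pair records with `drug_index`, `target_index`, `affinity`.
#' @param cfg A [model_config()].
#' @param rosters Optional list with elements `drugs`, `targets`, `n_bits`,
#'   `scoring` to embed in the model for later candidate ranking.
#' @return A trained `sim_cnn`.
#' @export
train_on_pairs <- function(k1, k2, pairs, cfg = model_config(),
                           rosters = NULL) {
  di <- pairs$drug_index
  ti <- pairs$target_index
  y <- pairs$affinity
  shape <- c(nrow(k1), nrow(k2))
  provider <- function(idx) {
    X <- array(0, c(shape[1L], shape[2L], 1L, length(idx)))
    for (n in seq_along(idx)) {
      X[, , 1L, n] <- outer(k1[, di[idx[n]]], k2[, ti[idx[n]]])
    }
    list(x = X, y = y[idx])
  }
  train_impl(provider, length(y), shape, cfg, rosters = rosters)
}

#' Fit the affinity model on a dataset
#'
#' End-to-end trainer: computes the drug and target similarity matrices over
#' the dataset rosters, enumerates the observed pairs (only measured
#' affinities are used) and trains the CNN on their outer-product grids. The
#' returned model carries the training rosters so that unseen drugs and
#' targets can later be scored against them.
#'
#' @param ds An [affinity_dataset()].
#' @param cfg A [model_config()].
#' @param scoring An [alignment_scoring()] scheme for target similarity.
#' @param n_bits Fingerprint length for drug similarity.
#' @return A trained `sim_cnn` carrying the rosters.
#' @export
fit_affinity_model <- function(ds, cfg = model_config(),
                               scoring = alignment_scoring(),
                               n_bits = 1024L) {
  stopifnot(inherits(ds, "affinity_dataset"))
  k1 <- drug_similarity_matrix(ds$drugs, n_bits = n_bits)
  k2 <- target_similarity_matrix(ds$targets, scoring = scoring)
  pairs <- observed_pairs(ds)
  if (nrow(pairs) < 1L) {
    abort("Dataset has no observed pairs to train on.",
          class = "simdta_input_error")
  }
  train_on_pairs(k1, k2, pairs, cfg,
                rosters = list(drugs = ds$drugs[, c("drug_id", "smiles")],
                               targets = ds$targets[, c("target_id", "sequence")],
                               n_bits = as.integer(n_bits), scoring = scoring))
}

#' Predict affinities for outer-product grids
#'
#' Deterministic forward pass (dropout disabled); output order follows input
#' order and is invariant to batch partitioning.
#'
#' @param object A `sim_cnn` model.
#' @param grids A single grid matrix, a list of grids, or a data frame with a
#'   `grid` list-column (e.g. from [build_pair_inputs()]).
#' @param batch_size Internal forward batch size.
#' @param ... Unused.
#' @return A numeric vector of predicted affinities.
#' @export
predict.sim_cnn <- function(object, grids, batch_size = 256L, ...) {
  if (is.matrix(grids)) grids <- list(grids)
  if (is.data.frame(grids)) grids <- grids$grid
  if (length(grids) == 0L) return(numeric(0))
  dims <- vapply(grids, dim, integer(2))
  if (any(dims[1L, ] != object$input_shape[1L]) ||
      any(dims[2L, ] != object$input_shape[2L])) {
    abort(sprintf("Grid shape must be %d x %d.",
                  object$input_shape[1L], object$input_shape[2L]),
          class = "simdta_input_error")
  }
  out <- numeric(length(grids))
  starts <- seq(1L, length(grids), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(grids))
    X <- stack_grids(grids[idx], object$input_shape)
    out[idx] <- nn_forward(object$params, X, object$cfg,
                           training = FALSE)$yhat
  }
  out
}

#' Rank candidate drugs against one target
#'
#' Builds each candidate's similarity vector against the model's training
#' drug roster and the target's vector against the training target roster,
#' predicts the affinity of every candidate-target grid and returns the
#' candidates sorted by predicted affinity, strongest first. Ties keep input
#' order (stable ranking). Candidates whose SMILES cannot be parsed are
#' skipped with a warning.
#'
#' @param model A `sim_cnn` fitted with [fit_affinity_model()] (it must carry
#'   rosters).
#' @param candidates Data frame with columns `drug_id`, `smiles`.
#' @param target A single amino-acid sequence, or a one-row data frame with a
#'   `sequence` column.
#' @param scoring Alignment scoring; defaults to the scheme stored in the
#'   model.
#' @return A tibble `drug_id`, `predicted_affinity`, `rank` sorted by rank.
#' @export
rank_candidates <- function(model, candidates, target, scoring = NULL) {
  stopifnot(inherits(model, "sim_cnn"))
  if (is.null(model$drug_roster) || is.null(model$target_roster)) {
    abort("Model carries no training rosters; fit it with `fit_affinity_model()`.",
          class = "simdta_input_error")
  }
  candidates <- check_drug_table(candidates)
  scoring <- scoring %||% model$scoring %||% alignment_scoring()
  tv <- similarity_vector_for_target(target, model$target_roster, scoring)
  roster_fps <- compute_fingerprints(model$drug_roster$smiles,
                                     n_bits = model$n_bits %||% 1024L,
                                     ids = model$drug_roster$drug_id)
  grids <- vector("list", nrow(candidates))
  ok <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fp <- tryCatch(
      compute_fingerprints(candidates$smiles[[i]],
                           n_bits = model$n_bits %||% 1024L,
                           ids = candidates$drug_id[[i]])[[1L]],
      error = function(e) {
        warn(sprintf("Skipping candidate '%s': %s",
                     candidates$drug_id[[i]], conditionMessage(e)))
        NULL
      })
    if (is.null(fp)) next
    dv <- vapply(roster_fps, function(f) tanimoto(fp, f), numeric(1))
    grids[[i]] <- outer_product(dv, tv)
    ok[i] <- TRUE
  }
  kept <- which(ok)
  if (length(kept) == 0L) {
    abort("No valid candidates to rank.", class = "simdta_input_error")
  }
  pred <- predict(model, grids[kept])
  ord <- order(-pred)  # stable: ties keep input order
  tibble(
    drug_id = candidates$drug_id[kept][ord],
    predicted_affinity = pred[ord],
    rank = seq_along(ord)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MODEL_FORMAT_VERSION <- 1L

#' Persist and restore a fitted model
#'
#' A model is saved as a directory holding a plain-text `manifest.json`
#' (format version, configuration, input shape, rosters, history) and a
#' `weights.rds` blob. A restored model predicts bit-identically to the
#' original.
#'
#' @param model A `sim_cnn` object.
#' @param path Directory to write (created if needed) or read.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `sim_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sim_cnn"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = MODEL_FORMAT_VERSION,
    config = model$cfg[setdiff(names(model$cfg), "conv_kernels")],
    conv_kernels = model$cfg$conv_kernels,
    input_shape = model$input_shape,
    trained = model$trained,
    n_train = model$n_train,
    history = model$history,
    n_bits = model$n_bits,
    scoring = if (!is.null(model$scoring))
      list(name = model$scoring$name, gap_open = model$scoring$gap_open,
           gap_extend = model$scoring$gap_extend),
    drug_roster = model$drug_roster,
    target_roster = model$target_roster
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  saveRDS(model$params, file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  w_path <- file.path(path, "weights.rds")
  if (!file.exists(mf_path) || !file.exists(w_path)) {
    abort(sprintf("No saved model at '%s'.", path),
          class = "simdta_input_error")
  }
  manifest <- tryCatch(jsonlite::read_json(mf_path, simplifyVector = TRUE),
                       error = function(e) NULL)
  params <- tryCatch(readRDS(w_path), error = function(e) NULL)
  if (is.null(manifest) || is.null(params)) {
    abort(sprintf("Corrupt saved model at '%s'.", path),
          class = "simdta_input_error")
  }
  if (!identical(as.integer(manifest$format_version), MODEL_FORMAT_VERSION)) {
    abort(sprintf("Unsupported model format version %s.",
                  manifest$format_version), class = "simdta_input_error")
  }
  cfgl <- manifest$config
  cfg <- model_config(
    conv_filters = cfgl$conv_filters,
    conv_kernels = if (is.matrix(manifest$conv_kernels))
      lapply(seq_len(nrow(manifest$conv_kernels)),
             function(i) manifest$conv_kernels[i, ])
    else manifest$conv_kernels,
    pool_size = cfgl$pool_size, pool_stride = cfgl$pool_stride,
    dropout_rate = cfgl$dropout_rate, fc_width = cfgl$fc_width,
    learning_rate = cfgl$learning_rate, batch_size = cfgl$batch_size,
    epochs = cfgl$epochs, seed = cfgl$seed
  )
  scoring <- if (!is.null(manifest$scoring) && length(manifest$scoring)) {
    alignment_scoring(manifest$scoring$name, manifest$scoring$gap_open,
                      manifest$scoring$gap_extend)
  }
  shapes <- model_shapes(manifest$input_shape[1L], manifest$input_shape[2L],
                         cfg)
  new_sim_cnn(params, cfg, manifest$input_shape, shapes,
              history = as.numeric(manifest$history %||% numeric(0)),
              trained = isTRUE(manifest$trained),
              drug_roster = roster_or_null(manifest$drug_roster),
              target_roster = roster_or_null(manifest$target_roster),
              n_bits = if (!is.null(manifest$n_bits))
                as.integer(manifest$n_bits),
              scoring = scoring, n_train = manifest$n_train %||% 0L)
}

roster_or_null <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
}

#' @export
tidy.sim_cnn <- function(x, ...) {
  tibble(epoch = seq_along(x$history), train_mse = x$history)
}

#' @export
glance.sim_cnn <- function(x, ...) {
  tibble(
    n_parameters = n_parameters(x),
    input_height = x$input_shape[1L], input_width = x$input_shape[2L],
    epochs = length(x$history),
    n_train = x$n_train,
    final_train_mse = if (length(x$history)) x$history[length(x$history)]
      else NA_real_
  )
}

#' @export
autoplot.sim_cnn <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$train_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Training MSE",
                  title = "Affinity CNN training loss")
}
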