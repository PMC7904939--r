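default_min_folds <- function(k) {
  if (k == 3L) 2L else if (k == 5L) 4L else max(2L, min(k, k - 1L))
}

#' Coverage-constrained fold assignment over observed pairs
#'
#' Partitions the observed drug-target pairs into `k` folds such that every
#' target's observations span at least `min_folds_per_target` distinct folds
#' (or all of them, when a target has fewer observations than that). This
#' guarantees no target is seen only in training or only in testing. The
#' construction deals each target's pairs round-robin into a randomly ordered
#' fold sequence and then moves unconstrained pairs out of overfull folds to
#' balance sizes; it is deterministic given `seed`. Defaults follow the k =
#' 3 / k = 5 convention of requiring 2 and 4 covered folds respectively.
#'
#' @param pairs Pair records from [observed_pairs()].
#' @param k Number of folds (>= 2, at most the number of pairs).
#' @param min_folds_per_target Required distinct folds per target.
#' @param seed Integer seed.
#' @return A `fold_assignment`: the `pairs` tibble with a `fold` column
#'   (labels 0 to k-1) plus attributes `k`, `seed`,
#'   `min_folds_per_target`.
#' @export
build_folds <- function(pairs, k, min_folds_per_target = default_min_folds(k),
                        seed = 1L) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("drug_index", "target_index") %in% names(pairs)))
  n <- nrow(pairs)
  k <- as.integer(k)
  if (k < 2L || k > n) {
    abort(sprintf("`k` must lie between 2 and the number of pairs (%d).", n),
          class = "simdta_input_error")
  }
  if (min_folds_per_target > k) {
    abort("`min_folds_per_target` cannot exceed `k`.",
          class = "simdta_input_error")
  }
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (tg in unique(pairs$target_index)) {
      idx <- which(pairs$target_index == tg)
      idx <- idx[sample.int(length(idx))]
      fold_order <- sample.int(k)
      fold[idx] <- fold_order[((seq_along(idx) - 1L) %% k) + 1L]
    }
    # rebalance: move pairs out of overfull folds when their target keeps a
    # foothold in the source fold (coverage can then only stay or grow)
    repeat {
      sizes <- tabulate(fold, nbins = k)
      a <- which.max(sizes)
      b <- which.min(sizes)
      if (sizes[a] - sizes[b] <= 1L) break
      in_a <- which(fold == a)
      tgt_counts <- table(pairs$target_index[in_a])
      movable <- in_a[pairs$target_index[in_a] %in%
                        as.integer(names(tgt_counts)[tgt_counts >= 2L])]
      if (length(movable) == 0L) break
      fold[movable[1L]] <- b
    }
  })
  pairs$fold <- fold - 1L
  structure(pairs, k = k, seed = as.integer(seed),
            min_folds_per_target = as.integer(min_folds_per_target),
            class = c("fold_assignment", class(pairs)))
}

#' Write / read a fold assignment as CSV
#'
#' Columns `drug_id`, `target_id`, `fold`, so that splits can be frozen and
#' shared between runs.
#'
#' @param folds A `fold_assignment` from [build_folds()].
#' @param path CSV file path.
#' @return `write_folds()` returns `path` invisibly; `read_folds()` a tibble.
#' @export
write_folds <- function(folds, path) {
  readr::write_csv(folds[, c("drug_id", "target_id", "fold")], path)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    drug_id = readr::col_character(), target_id = readr::col_character(),
    fold = readr::col_integer()))
}

#' Cross-validated evaluation of the affinity model
#'
#' Runs coverage-constrained k-fold cross-validation over the observed pairs
#' of a dataset: the similarity matrices are computed once over all dataset
#' entities (every entity appears in training folds by the coverage
#' constraint), then for each fold the CNN is trained on the out-of-fold
#' pairs and evaluated on the held-out fold with MSE, CI, rm2 and AUPR.
#' Hyperparameters are the fixed architecture constants; there is no inner
#' tuning loop. Per-fold seeds are derived deterministically from `seed`.
#'
#' @param ds An [affinity_dataset()].
#' @param k Number of folds.
#' @param cfg A [model_config()].
#' @param threshold Binarization threshold for AUPR (pKd 7.0 and transformed
#'   KIBA 12.1 are the conventional choices).
#' @param positive_is_high Orientation of the binarization (see [aupr()]).
#' @param scoring An [alignment_scoring()] scheme.
#' @param n_bits Fingerprint length.
#' @param min_folds_per_target Coverage constraint (see [build_folds()]).
#' @param seed Integer seed for fold construction and per-fold training.
#' @return An object of class `sim_cnn_cv` with per-fold metrics, a
#'   mean/standard-error summary, and the fold assignment. Access tidily via
#'   [tidy()] (per fold) and [glance()] (summary row).
#' @export
run_cv <- function(ds, k = 5L, cfg = model_config(), threshold = 7,
                   positive_is_high = TRUE, scoring = alignment_scoring(),
                   n_bits = 1024L,
                   min_folds_per_target = default_min_folds(k), seed = 1L) {
  stopifnot(inherits(ds, "affinity_dataset"))
  pairs <- observed_pairs(ds)
  if (nrow(pairs) < k) {
    abort("Dataset has fewer observed pairs than folds.",
          class = "simdta_input_error")
  }
  k1 <- drug_similarity_matrix(ds$drugs, n_bits = n_bits)
  k2 <- target_similarity_matrix(ds$targets, scoring = scoring)
  folds <- build_folds(pairs, k, min_folds_per_target, seed)

  per_fold <- purrr::map_dfr(0:(k - 1L), function(f) {
    train_pairs <- folds[folds$fold != f, ]
    test_pairs <- folds[folds$fold == f, ]
    fold_seed <- (as.integer(seed) + 7919L * (f + 1L)) %% 2147483647L
    fold_cfg <- cfg
    fold_cfg$seed <- fold_seed
    model <- train_on_pairs(k1, k2, train_pairs, fold_cfg)
    grids <- build_pair_inputs(ds, test_pairs, k1, k2)
    yhat <- predict(model, grids)
    rep <- evaluate_predictions(test_pairs$affinity, yhat, threshold,
                                positive_is_high)
    dplyr::bind_cols(tibble(fold = f), rep)
  })

  summary <- per_fold |>
    tidyr::pivot_longer(c("mse", "ci", "rm2", "aupr"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n_folds = sum(!is.na(.data$value)),
      .groups = "drop")

  structure(
    list(per_fold = per_fold, summary = summary, assignment = folds,
         k = k, threshold = threshold, positive_is_high = positive_is_high,
         seed = as.integer(seed), cfg = cfg),
    class = "sim_cnn_cv")
}

#' @export
print.sim_cnn_cv <- function(x, ...) {
  cat(sprintf("<sim_cnn_cv> %d-fold cross-validation, %d pairs\n",
              x$k, nrow(x$assignment)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.sim_cnn_cv <- function(x, ...) {
  x$per_fold
}

#' @export
glance.sim_cnn_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary[, c("metric", "mean", "se")],
    names_from = "metric", values_from = c("mean", "se"),
    names_glue = "{metric}_{.value}")
  dplyr::bind_cols(wide, tibble(k = x$k, n_pairs = nrow(x$assignment)))
}

#' @export
autoplot.sim_cnn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, c("mse", "ci", "rm2", "aupr"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Metric value", colour = "Fold",
                  title = sprintf("%d-fold cross-validation", object$k))
}

#' Write a cross-validation report to disk
#'
#' Emits the per-fold metric replicates as CSV (one row per fold per metric,
#' so external statistics can be reproduced) and a plain-text JSON summary
#' with the mean and standard error of each metric.
#'
#' @param cv A `sim_cnn_cv` from [run_cv()].
#' @param csv_path Path for the per-fold CSV.
#' @param json_path Path for the JSON summary.
#' @return Invisibly, a list of the two paths.
#' @export
write_cv_report <- function(cv, csv_path, json_path) {
  stopifnot(inherits(cv, "sim_cnn_cv"))
  long <- tidyr::pivot_longer(cv$per_fold, c("mse", "ci", "rm2", "aupr"),
                              names_to = "metric", values_to = "value")
  readr::write_csv(long[, c("fold", "metric", "value", "n")], csv_path)
  summ <- split(cv$summary[, c("mean", "se")], cv$summary$metric)
  summ <- lapply(summ, function(d) list(mean = d$mean[[1L]], se = d$se[[1L]]))
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv = csv_path, json = json_path))
}
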