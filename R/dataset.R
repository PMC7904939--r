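AFFINITY_SCALES <- c("Kd_nM", "pKd", "KIBA_raw", "KIBA_transformed")

#' Construct a drug-target affinity dataset
#'
#' Couples a drug roster, a target roster and a drugs-by-targets affinity
#' matrix with an observedness mask. Missing measurements are `NA` in `y` and
#' `FALSE` in `observed`. The declared scale records how the affinities are to
#' be interpreted; no transform is ever applied implicitly.
#'
#' @param drugs Data frame with columns `drug_id`, `smiles` (extra columns are
#'   kept).
#' @param targets Data frame with columns `target_id`, `sequence`.
#' @param y Numeric matrix, drugs in rows and targets in columns. `NA` marks a
#'   missing measurement.
#' @param observed Logical matrix of the same shape; defaults to `!is.na(y)`.
#' @param scale One of `"Kd_nM"`, `"pKd"`, `"KIBA_raw"`, `"KIBA_transformed"`.
#' @return An object of class `affinity_dataset`.
#' @export
affinity_dataset <- function(drugs, targets, y, observed = !is.na(y),
                             scale = c("pKd", "Kd_nM", "KIBA_raw",
                                       "KIBA_transformed")) {
  drugs <- check_drug_table(drugs)
  targets <- check_target_table(targets)
  scale <- match.arg(scale)
  if (!is.matrix(y) || !is.numeric(y)) {
    abort("`y` must be a numeric matrix.", class = "simdta_input_error")
  }
  if (!identical(dim(y), dim(observed)) || !is.logical(observed)) {
    abort("`observed` must be a logical matrix with the shape of `y`.",
          class = "simdta_input_error")
  }
  if (nrow(y) != nrow(drugs) || ncol(y) != nrow(targets)) {
    abort(sprintf(
      "Affinity matrix is %d x %d but rosters have %d drugs and %d targets.",
      nrow(y), ncol(y), nrow(drugs), nrow(targets)),
      class = "simdta_input_error")
  }
  if (any(observed & is.na(y))) {
    abort("Cells marked observed must carry a numeric affinity.",
          class = "simdta_input_error")
  }
  y[!observed] <- NA_real_
  dimnames(y) <- list(drugs$drug_id, targets$target_id)
  dimnames(observed) <- dimnames(y)
  if (!any(observed)) {
    warn("Dataset has no observed affinities.")
  }
  structure(
    list(drugs = drugs, targets = targets, y = y, observed = observed,
         scale = scale),
    class = "affinity_dataset"
  )
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat(sprintf(
    "<affinity_dataset> %d drugs x %d targets, %d observed pairs (density %.1f%%), scale %s\n",
    nrow(x$drugs), nrow(x$targets), sum(x$observed),
    100 * dataset_density(x), x$scale))
  invisible(x)
}

#' Fraction of observed drug-target cells
#'
#' @param ds An [affinity_dataset()].
#' @return Observed cells divided by total cells, in \[0, 1\].
#' @export
dataset_density <- function(ds) {
  stopifnot(inherits(ds, "affinity_dataset"))
  mean(ds$observed)
}

#' Observed drug-target pairs of a dataset
#'
#' One row per observed cell, in row-major order (drug by drug, targets in
#' roster order within each drug). These pair records are the training and
#' evaluation unit of the model: only measured affinities are ever used.
#'
#' @param ds An [affinity_dataset()].
#' @return A tibble with columns `drug_index`, `target_index`, `drug_id`,
#'   `target_id`, `affinity`.
#' @export
observed_pairs <- function(ds) {
  stopifnot(inherits(ds, "affinity_dataset"))
  idx <- which(t(ds$observed))  # transpose: row-major enumeration
  nt <- nrow(ds$targets)
  ti <- ((idx - 1L) %% nt) + 1L
  di <- ((idx - 1L) %/% nt) + 1L
  tibble(
    drug_index = di, target_index = ti,
    drug_id = ds$drugs$drug_id[di], target_id = ds$targets$target_id[ti],
    affinity = ds$y[cbind(di, ti)]
  )
}

#' Convert dissociation constants to pKd
#'
#' `pKd = -log10(Kd / 1e9)` with `Kd` in nanomolar, so 10,000 nM maps to 5
#' and 1 nM to 9; higher pKd means stronger binding.
#'
#' @param kd Positive dissociation constants in nM.
#' @return pKd values.
#' @examples
#' kd_to_pkd(c(10000, 1))
#' @export
kd_to_pkd <- function(kd) {
  if (!is.numeric(kd) || length(kd) == 0L) {
    abort("`kd` must be numeric.", class = "simdta_input_error")
  }
  if (any(!is.na(kd) & kd <= 0)) {
    abort("Kd values must be strictly positive.",
          class = "simdta_input_error")
  }
  -log10(kd / 1e9)
}

#' Reverse-orient KIBA scores
#'
#' Low raw KIBA scores mean strong binding; the model works with
#' higher-is-stronger affinities. The transform is the three-step recipe:
#' (1) negate every score, (2) take the minimum of the negated scores,
#' (3) add the absolute value of that minimum to all. For nonnegative raw
#' scores the minimum output is exactly 0 and the ordering is reversed.
#'
#' @param scores Numeric vector of raw KIBA scores; `NA`s (missing cells) are
#'   ignored when taking the minimum and returned as `NA`.
#' @return Transformed scores, same length.
#' @examples
#' transform_kiba(c(3, 5, 10))
#' @export
transform_kiba <- function(scores) {
  if (!is.numeric(scores) || length(scores) == 0L || all(is.na(scores))) {
    abort("`scores` must contain at least one observed value.",
          class = "simdta_input_error")
  }
  neg <- -scores
  neg + abs(min(neg, na.rm = TRUE))
}

#' Apply an affinity-scale transform to a dataset
#'
#' `apply_pkd_transform()` converts a `Kd_nM` dataset to `pKd`;
#' `apply_kiba_transform()` converts `KIBA_raw` to `KIBA_transformed` (the
#' minimum in the transform is taken over the dataset's observed entries).
#'
#' @param ds An [affinity_dataset()] on the matching input scale.
#' @return A new [affinity_dataset()] on the transformed scale.
#' @export
apply_pkd_transform <- function(ds) {
  stopifnot(inherits(ds, "affinity_dataset"))
  if (ds$scale != "Kd_nM") {
    abort("pKd transform requires a dataset on the Kd_nM scale.",
          class = "simdta_input_error")
  }
  y <- ds$y
  y[ds$observed] <- kd_to_pkd(y[ds$observed])
  affinity_dataset(ds$drugs, ds$targets, y, ds$observed, scale = "pKd")
}

#' @rdname apply_pkd_transform
#' @export
apply_kiba_transform <- function(ds) {
  stopifnot(inherits(ds, "affinity_dataset"))
  if (ds$scale != "KIBA_raw") {
    abort("KIBA transform requires a dataset on the KIBA_raw scale.",
          class = "simdta_input_error")
  }
  y <- ds$y
  y[ds$observed] <- transform_kiba(y[ds$observed])
  affinity_dataset(ds$drugs, ds$targets, y, ds$observed,
                   scale = "KIBA_transformed")
}

#' Similarity-weighted imputation of a missing affinity
#'
#' Weighted average of a drug's observed affinities, the weights being the
#' normalized Smith-Waterman similarities between the target of the missing
#' cell and the targets with measurements. If every weight is zero the
#' unweighted mean is returned with a warning.
#'
#' @param affinities Observed affinities of one drug.
#' @param weights Nonnegative similarity weights, same length.
#' @return The imputed affinity.
#' @examples
#' impute_affinity(c(2, 4), c(0.5, 1))
#' @export
impute_affinity <- function(affinities, weights) {
  if (length(affinities) == 0L || length(affinities) != length(weights)) {
    abort("Need >= 1 observed affinity and matching weights.",
          class = "simdta_input_error")
  }
  if (any(weights < 0)) {
    abort("Weights must be nonnegative.", class = "simdta_input_error")
  }
  if (sum(weights) == 0) {
    warn("All similarity weights are zero; falling back to unweighted mean.")
    return(mean(affinities))
  }
  sum(weights * affinities) / sum(weights)
}

#' Fill missing cells of a dataset by similarity-weighted imputation
#'
#' Optional preprocessing utility: every missing cell (i, j) is replaced by
#' the weighted mean of drug i's observed affinities, weighted by the target
#' similarity between j and the observed targets. Model training itself uses
#' observed pairs only; imputation exists for methods that need a dense
#' matrix.
#'
#' @param ds An [affinity_dataset()].
#' @param k2 Target-target similarity matrix over the dataset's target roster
#'   (see [target_similarity_matrix()]).
#' @return An [affinity_dataset()] with all imputable cells observed. Drugs
#'   with no measurement at all keep their row missing, with a warning.
#' @export
impute_missing_affinities <- function(ds, k2) {
  stopifnot(inherits(ds, "affinity_dataset"))
  validate_similarity_matrix(unclass(k2))
  if (!identical(rownames(k2), ds$targets$target_id)) {
    abort("`k2` roster does not match the dataset targets.",
          class = "simdta_input_error")
  }
  y <- ds$y
  obs <- ds$observed
  for (i in seq_len(nrow(y))) {
    have <- which(obs[i, ])
    miss <- which(!obs[i, ])
    if (length(miss) == 0L) next
    if (length(have) == 0L) {
      warn(sprintf("Drug '%s' has no observed affinity; left missing.",
                   ds$drugs$drug_id[[i]]))
      next
    }
    for (j in miss) {
      y[i, j] <- impute_affinity(y[i, have], k2[j, have])
    }
    obs[i, miss] <- TRUE
  }
  affinity_dataset(ds$drugs, ds$targets, y, obs, scale = ds$scale)
}
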