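#' Similarity vector of a drug against a training roster
#'
#' Tanimoto similarities between a query drug and every drug of a reference
#' roster, in roster order. Inside a cross-validation run these vectors are
#' simply columns of the drug similarity matrix; for drugs outside the roster
#' (candidate ranking) the vector is computed fresh against the training
#' roster, so a roster member carries a 1 at its own position.
#'
#' @param query A single SMILES string, or a one-row data frame with a
#'   `smiles` column.
#' @param roster Data frame with columns `drug_id`, `smiles` (the training
#'   drugs).
#' @param n_bits Fingerprint length (see [compute_fingerprint()]).
#' @return A numeric vector named by roster drug ids, values in \[0, 1\].
#' @export
similarity_vector_for_drug <- function(query, roster, n_bits = 1024L) {
  roster <- check_drug_table(roster)
  smiles <- query_field(query, "smiles")
  qfp <- compute_fingerprints(smiles, n_bits = n_bits, ids = "query")[[1L]]
  fps <- compute_fingerprints(roster$smiles, n_bits = n_bits,
                              ids = roster$drug_id)
  setNames(vapply(fps, function(f) tanimoto(qfp, f), numeric(1)),
           roster$drug_id)
}

#' Similarity vector of a target against a training roster
#'
#' Normalized Smith-Waterman similarities between a query protein and every
#' target of a reference roster, in roster order.
#'
#' @param query A single amino-acid sequence, or a one-row data frame with a
#'   `sequence` column.
#' @param roster Data frame with columns `target_id`, `sequence`.
#' @param scoring An [alignment_scoring()] scheme.
#' @return A numeric vector named by roster target ids.
#' @export
similarity_vector_for_target <- function(query, roster,
                                         scoring = alignment_scoring()) {
  roster <- check_target_table(roster)
  seq <- clean_protein(query_field(query, "sequence"), id = "query")
  vapply(
    setNames(roster$sequence, roster$target_id),
    function(s) normalized_sw(seq, s, scoring),
    numeric(1)
  )
}

query_field <- function(query, field) {
  if (is.data.frame(query)) {
    if (nrow(query) != 1L || !field %in% names(query)) {
      abort(sprintf("`query` data frame must have one row and a `%s` column.",
                    field), class = "simdta_input_error")
    }
    query <- query[[field]]
  }
  if (!is.character(query) || length(query) != 1L) {
    abort(sprintf("`query` must be a single %s string.", field),
          class = "simdta_input_error")
  }
  query
}

#' Outer product of a drug and a target similarity vector
#'
#' The pair input of the model: grid entry (a, b) is `dv[a] * tv[b]`. Because
#' a roster drug's own similarity is 1, row i of the grid for training pair
#' (i, j) reproduces the raw target similarity vector, and column j the drug
#' vector, so the grid carries both unimodal profiles plus all cross terms.
#'
#' @param dv Drug similarity vector (values in \[0, 1\]).
#' @param tv Target similarity vector.
#' @return A `length(dv)` by `length(tv)` matrix, named by the vector names.
#' @examples
#' outer_product(c(D1 = 1, D2 = 0.5), c(T1 = 1, T2 = 0.2, T3 = 0))
#' @export
outer_product <- function(dv, tv) {
  if (length(dv) == 0L || length(tv) == 0L) {
    abort("Similarity vectors must be nonempty.", class = "simdta_input_error")
  }
  outer(as.numeric(dv), as.numeric(tv)) |>
    structure(dimnames = list(names(dv), names(tv)))
}

#' Build outer-product inputs for a set of observed pairs
#'
#' Materializes one grid per pair record from the columns of the precomputed
#' similarity matrices. The matrices' rosters must coincide with the dataset
#' rosters. (Training can also rebuild these grids batch by batch from the
#' same columns; the results are value-identical.)
#'
#' @param ds An [affinity_dataset()].
#' @param pairs Pair records, e.g. from [observed_pairs()] (columns
#'   `drug_index`, `target_index`, `affinity`).
#' @param k1 Drug similarity matrix from [drug_similarity_matrix()].
#' @param k2 Target similarity matrix from [target_similarity_matrix()].
#' @return `pairs` with a list-column `grid` of outer-product matrices.
#' @export
build_pair_inputs <- function(ds, pairs, k1, k2) {
  check_rosters(ds, k1, k2)
  stopifnot(all(c("drug_index", "target_index", "affinity") %in% names(pairs)))
  pairs <- as_tibble(pairs)
  pairs$grid <- purrr::map2(pairs$drug_index, pairs$target_index,
                            function(i, j) outer_product(k1[, i], k2[, j]))
  pairs
}

check_rosters <- function(ds, k1, k2) {
  stopifnot(inherits(ds, "affinity_dataset"))
  validate_similarity_matrix(unclass(k1))
  validate_similarity_matrix(unclass(k2))
  if (!identical(rownames(k1), ds$drugs$drug_id)) {
    abort("Drug similarity matrix roster does not match the dataset drugs.",
          class = "simdta_input_error")
  }
  if (!identical(rownames(k2), ds$targets$target_id)) {
    abort("Target similarity matrix roster does not match the dataset targets.",
          class = "simdta_input_error")
  }
  invisible(TRUE)
}

#' Write pair grids to text files for inspection
#'
#' One whitespace-delimited dense matrix file per pair, named
#' `grid_<drug>_<target>.txt`. Off by default in all pipelines; intended for
#' debugging and inspection only.
#'
#' @param pair_inputs Output of [build_pair_inputs()].
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_pair_grids <- function(pair_inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    list(pair_inputs$drug_id, pair_inputs$target_id, pair_inputs$grid),
    function(d, t, g) {
      p <- file.path(dir, sprintf("grid_%s_%s.txt", d, t))
      utils::write.table(g, p, row.names = TRUE, col.names = NA, quote = FALSE)
      p
    })
  invisible(paths)
}
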