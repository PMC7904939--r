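#' Topological path fingerprint of a molecule
#'
#' Parses a SMILES string and computes a hashed path-based (topological)
#' fingerprint: every linear atom path of length 1--7 is enumerated and hashed
#' onto a fixed-length bit vector (OpenBabel's FP2 fingerprint, computed via
#' ChemmineR/ChemmineOB). The native fingerprint length is 1024 bits; smaller
#' powers of two are obtained by OR-folding the bit vector onto itself.
#'
#' @param smiles A single SMILES string.
#' @param n_bits Fingerprint length in bits. Must be a power of two between 8
#'   and 1024. Default 1024, the native length of the path fingerprint.
#' @return An object of class `chem_fp`: a list with `bits` (logical vector)
#'   and `n_bits`.
#' @examples
#' fp <- compute_fingerprint("CCO")
#' sum(fp$bits)
#' @export
compute_fingerprint <- function(smiles, n_bits = 1024L) {
  fps <- compute_fingerprints(smiles, n_bits = n_bits)
  fps[[1L]]
}

#' Fingerprints for a vector of SMILES
#'
#' Vectorised form of [compute_fingerprint()]. Each SMILES is parsed
#' independently so a failure is reported with the offending string and its
#' position.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Fingerprint length (see [compute_fingerprint()]).
#' @param ids Optional identifiers used in error messages; defaults to the
#'   element index.
#' @return A list of `chem_fp` objects.
#' @export
compute_fingerprints <- function(smiles, n_bits = 1024L, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  check_n_bits(n_bits)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  lapply(seq_along(smiles), function(i) {
    mat <- parse_smiles_fp(smiles[[i]], id = ids[[i]], row = i)
    bits <- fold_bits(as.logical(mat), n_bits)
    structure(list(bits = bits, n_bits = as.integer(n_bits)),
              class = "chem_fp")
  })
}

# Parse one SMILES via OpenBabel and return its raw 1024-bit FP2 row.
parse_smiles_fp <- function(smiles, id, row) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    abort(sprintf("Invalid SMILES for drug '%s' (row %s): empty or missing.",
                  id, row), class = "simdta_input_error")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, "q"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != 1L ||
      sum(suppressWarnings(ChemmineR::atomcount(sdf)[[1L]])) < 1L) {
    abort(sprintf("Unparseable SMILES '%s' for drug '%s' (row %s).",
                  smiles, id, row), class = "simdta_input_error")
  }
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  ChemmineR::as.matrix(fp)[1L, ]
}

check_n_bits <- function(n_bits) {
  ok <- is.numeric(n_bits) && length(n_bits) == 1L && n_bits >= 8 &&
    n_bits <= 1024 && bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) == 0L
  if (!ok) {
    abort("`n_bits` must be a power of two between 8 and 1024.",
          class = "simdta_input_error")
  }
  invisible(TRUE)
}

# OR-fold a 1024-bit vector down to n_bits.
fold_bits <- function(bits, n_bits) {
  while (length(bits) > n_bits) {
    half <- length(bits) / 2L
    bits <- bits[seq_len(half)] | bits[half + seq_len(half)]
  }
  bits
}

#' Tanimoto coefficient between two fingerprints
#'
#' The Jaccard index over set bits, `|a AND b| / |a OR b|`. Two all-zero
#' fingerprints are defined to have similarity 1 (identical objects) with a
#' warning, since 0/0 is otherwise undefined.
#'
#' @param a,b `chem_fp` objects of equal length.
#' @return A number in \[0, 1\].
#' @examples
#' tanimoto(compute_fingerprint("CCO"), compute_fingerprint("CCCO"))
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "chem_fp"), inherits(b, "chem_fp"))
  if (a$n_bits != b$n_bits) {
    abort(sprintf("Fingerprint length mismatch: %d vs %d bits.",
                  a$n_bits, b$n_bits), class = "simdta_input_error")
  }
  inter <- sum(a$bits & b$bits)
  union <- sum(a$bits | b$bits)
  if (union == 0L) {
    warn("Both fingerprints are all-zero; Tanimoto defined as 1.")
    return(1)
  }
  inter / union
}

#' Drug-drug Tanimoto similarity matrix
#'
#' Computes the square symmetric similarity matrix over a drug roster: entry
#' (i, j) is the Tanimoto coefficient between the topological fingerprints of
#' drugs i and j. The diagonal is exactly 1 and the matrix is used column-wise
#' as the drug similarity vectors fed to the affinity model.
#'
#' @param drugs A data frame with columns `drug_id` and `smiles`.
#' @param n_bits Fingerprint length (see [compute_fingerprint()]).
#' @return A numeric matrix with `drug_id` dimnames, class `similarity_matrix`.
#' @export
drug_similarity_matrix <- function(drugs, n_bits = 1024L) {
  drugs <- check_drug_table(drugs)
  fps <- compute_fingerprints(drugs$smiles, n_bits = n_bits,
                              ids = drugs$drug_id)
  n <- length(fps)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
      }
    }
  }
  dimnames(m) <- list(drugs$drug_id, drugs$drug_id)
  new_similarity_matrix(m, type = "tanimoto")
}

check_drug_table <- function(drugs) {
  if (!is.data.frame(drugs) || !all(c("drug_id", "smiles") %in% names(drugs))) {
    abort("`drugs` must be a data frame with columns `drug_id` and `smiles`.",
          class = "simdta_input_error")
  }
  if (nrow(drugs) < 1L) {
    abort("`drugs` must contain at least one drug.",
          class = "simdta_input_error")
  }
  if (anyDuplicated(drugs$drug_id)) {
    dup <- unique(drugs$drug_id[duplicated(drugs$drug_id)])
    abort(sprintf("Duplicate drug id(s): %s.",
                  paste(dup, collapse = ", ")),
          class = "simdta_input_error")
  }
  as_tibble(drugs)
}

new_similarity_matrix <- function(m, type) {
  structure(m, type = type, class = c("similarity_matrix", class(m)))
}

#' Validate similarity-matrix invariants
#'
#' Checks that a matrix is square, symmetric, has unit diagonal and all
#' entries in \[0, 1\]; errors otherwise.
#'
#' @param m A numeric matrix.
#' @param tol Numeric tolerance for the symmetry and diagonal checks.
#' @return `m`, invisibly.
#' @export
validate_similarity_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Similarity matrix must be square.", class = "simdta_input_error")
  }
  if (max(abs(m - t(m))) > tol) {
    abort("Similarity matrix must be symmetric.", class = "simdta_input_error")
  }
  if (max(abs(diag(m) - 1)) > tol) {
    abort("Similarity matrix diagonal must be 1.",
          class = "simdta_input_error")
  }
  if (min(m) < -tol || max(m) > 1 + tol) {
    abort("Similarity values must lie in [0, 1].",
          class = "simdta_input_error")
  }
  invisible(m)
}

#' Write / read a similarity matrix as CSV
#'
#' The full symmetric matrix is written with entity ids as the first row and
#' first column.
#'
#' @param m A similarity matrix with dimnames.
#' @param path File path.
#' @return `write_similarity_matrix()` returns `path` invisibly;
#'   `read_similarity_matrix()` returns a `similarity_matrix`.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  validate_similarity_matrix(m)
  new_similarity_matrix(m, type = "unknown")
}
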