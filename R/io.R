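MISSING_TOKENS <- c("", ".", "NA")

#' Load an affinity dataset from its three canonical files
#'
#' Reads a drug table (TSV or CSV with columns `drug_id`, `smiles`), a target
#' FASTA file (record id = target id; description after the first whitespace
#' is dropped; sequence lines are concatenated and upper-cased) and an
#' affinity matrix CSV whose first column holds drug ids and whose header
#' holds target ids. Blank cells, `.` and `NA` mark missing measurements.
#' The matrix ids must coincide with the rosters (any order); rows and
#' columns are reordered to roster order. The declared scale is recorded
#' as-is; no transform is applied.
#'
#' @param drug_table_path Path to the drug TSV/CSV.
#' @param fasta_path Path to the target FASTA.
#' @param affinity_csv_path Path to the affinity matrix CSV.
#' @param scale Affinity scale of the matrix values (see
#'   [affinity_dataset()]).
#' @return An [affinity_dataset()].
#' @export
load_dataset <- function(drug_table_path, fasta_path, affinity_csv_path,
                         scale = c("pKd", "Kd_nM", "KIBA_raw",
                                   "KIBA_transformed")) {
  scale <- match.arg(scale)
  drugs <- read_drug_table(drug_table_path)
  targets <- read_target_fasta(fasta_path)
  aff <- read_affinity_csv(affinity_csv_path)

  check_roster_match(rownames(aff), drugs$drug_id, "drug", affinity_csv_path)
  check_roster_match(colnames(aff), targets$target_id, "target",
                     affinity_csv_path)
  aff <- aff[drugs$drug_id, targets$target_id, drop = FALSE]
  affinity_dataset(drugs, targets, aff, scale = scale)
}

#' Read a drug table (TSV or CSV)
#'
#' @param path File path; tab-delimited unless the extension is `.csv`.
#' @return A tibble with columns `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    abort(sprintf("'%s' must have header columns `drug_id` and `smiles`.",
                  path), class = "simdta_input_error")
  }
  df$drug_id <- as.character(df$drug_id)
  check_drug_table(df)
}

#' Read protein targets from FASTA
#'
#' @param path FASTA file path.
#' @return A tibble with columns `target_id`, `sequence`.
#' @export
read_target_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    abort(sprintf("No FASTA records in '%s'.", path),
          class = "simdta_input_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  check_target_table(tibble(target_id = ids,
                            sequence = unname(toupper(as.character(set)))))
}

read_affinity_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE, trim_ws = TRUE)
  if (ncol(df) < 2L) {
    abort(sprintf("Affinity matrix '%s' needs an id column and >= 1 target.",
                  path), class = "simdta_input_error")
  }
  drug_ids <- as.character(df[[1L]])
  target_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[is.na(cells)] <- ""
  missing <- matrix(trimws(cells) %in% MISSING_TOKENS, nrow = nrow(cells))
  y <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!missing & is.na(y), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Non-numeric affinity cell '%s' at drug '%s', target '%s' in '%s'.",
      cells[bad[1L, , drop = FALSE]], drug_ids[bad[1L, 1L]],
      target_ids[bad[1L, 2L]], path), class = "simdta_input_error")
  }
  y[missing] <- NA_real_
  dimnames(y) <- list(drug_ids, target_ids)
  y
}

check_roster_match <- function(have, want, what, path) {
  if (anyDuplicated(have)) {
    abort(sprintf("Duplicate %s id(s) in affinity matrix '%s'.", what, path),
          class = "simdta_input_error")
  }
  extra <- setdiff(have, want)
  missing <- setdiff(want, have)
  if (length(extra) > 0L || length(missing) > 0L) {
    abort(sprintf(
      "Affinity matrix %s ids do not match the roster (missing: %s; unknown: %s).",
      what,
      if (length(missing)) paste(head(missing, 5L), collapse = ", ") else "none",
      if (length(extra)) paste(head(extra, 5L), collapse = ", ") else "none"),
      class = "simdta_input_error")
  }
}

#' Write an affinity dataset to its three canonical files
#'
#' Writes `drugs.tsv`, `targets.fasta` and `affinities.csv` (plus a small
#' JSON manifest recording the scale) under `dir`. Missing cells are written
#' as empty strings. Numbers are written with enough digits that finite
#' decimal inputs round-trip exactly through [load_dataset()].
#'
#' @param ds An [affinity_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "affinity_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(ds$drugs[, c("drug_id", "smiles")],
                   file.path(dir, "drugs.tsv"), progress = FALSE)
  seqs <- Biostrings::AAStringSet(setNames(ds$targets$sequence,
                                           ds$targets$target_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "targets.fasta"))
  cells <- matrix(num_chr(ds$y), nrow = nrow(ds$y))
  cells[!ds$observed] <- ""
  df <- data.frame(drug_id = ds$drugs$drug_id, cells, check.names = FALSE)
  colnames(df) <- c("drug_id", ds$targets$target_id)
  readr::write_csv(df, file.path(dir, "affinities.csv"), progress = FALSE)
  jsonlite::write_json(
    list(scale = ds$scale, n_drugs = nrow(ds$drugs),
         n_targets = nrow(ds$targets), observed = sum(ds$observed)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# shortest decimal representation that round-trips a double
num_chr <- function(x) {
  out <- vapply(as.vector(x), function(v) {
    if (is.na(v)) return(NA_character_)
    s <- as.character(v)
    if (as.numeric(s) == v) s else format(v, digits = 17)
  }, character(1))
  out
}
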