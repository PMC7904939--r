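#' Alignment scoring scheme for protein local alignment
#'
#' Bundles a substitution matrix with affine gap penalties. A gap of length L
#' costs `gap_open + L * gap_extend`. The default (BLOSUM62, open 10,
#' extend 0.5) is the common convention in chemogenomic target-similarity
#' work; the normalization only requires positive self-alignment scores to
#' be well defined.
#'
#' @param substitution Name of a substitution matrix shipped with Biostrings
#'   ("BLOSUM62", "BLOSUM50", "BLOSUM80", "PAM250", ...) or a symmetric
#'   numeric matrix covering the 20 standard amino acids.
#' @param gap_open Nonnegative penalty for opening a gap.
#' @param gap_extend Nonnegative per-position gap penalty; must not exceed
#'   `gap_open`.
#' @return An object of class `alignment_scoring`.
#' @examples
#' sc <- alignment_scoring()
#' sc$gap_open
#' @export
alignment_scoring <- function(substitution = "BLOSUM62", gap_open = 10,
                              gap_extend = 0.5) {
  if (is.character(substitution)) {
    name <- substitution
    env <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = env)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = env)) {
      abort(sprintf("Unknown substitution matrix '%s'.", name),
            class = "simdta_input_error")
    }
    substitution <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  if (!all(aa %in% rownames(substitution)) ||
      !all(aa %in% colnames(substitution))) {
    abort("Substitution matrix must cover the 20 standard amino acids.",
          class = "simdta_input_error")
  }
  sub <- substitution[rownames(substitution), rownames(substitution)]
  if (max(abs(sub - t(sub))) > 0) {
    abort("Substitution matrix must be symmetric.",
          class = "simdta_input_error")
  }
  if (!is.numeric(gap_open) || !is.numeric(gap_extend) ||
      gap_open < 0 || gap_extend < 0 || gap_extend > gap_open) {
    abort("Require 0 <= gap_extend <= gap_open.",
          class = "simdta_input_error")
  }
  structure(
    list(substitution = substitution, name = name,
         gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend)),
    class = "alignment_scoring"
  )
}

# Uppercase, map ambiguity codes onto standard residues (B->D, Z->E, U->C,
# O->K; X is kept and scored by the matrix's X column when present), error on
# anything else.
clean_protein <- function(seq, id = "?") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("Empty or missing sequence for target '%s'.", id),
          class = "simdta_input_error")
  }
  s <- toupper(gsub("[[:space:]]", "", seq))
  chars <- strsplit(s, "")[[1L]]
  amb <- c(B = "D", Z = "E", U = "C", O = "K")
  hit <- chars %in% names(amb)
  if (any(hit)) {
    warn(sprintf(
      "Target '%s': mapped ambiguity codes %s onto standard residues.",
      id, paste(unique(chars[hit]), collapse = ", ")))
    chars[hit] <- amb[chars[hit]]
  }
  allowed <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], "X")
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0L) {
    abort(sprintf("Target '%s': unknown residue code(s) %s.",
                  id, paste(bad, collapse = ", ")),
          class = "simdta_input_error")
  }
  paste(chars, collapse = "")
}

#' Smith-Waterman local alignment score
#'
#' Optimal local-alignment score between two protein sequences under affine
#' gap penalties, computed with Biostrings' pairwise aligner. The score is
#' nonnegative by the local-alignment empty-alignment floor.
#'
#' @param a,b Protein sequences (single strings over the amino-acid alphabet;
#'   ambiguity codes B/Z/U/O are mapped to standard residues with a warning).
#' @param scoring An [alignment_scoring()] scheme.
#' @return A nonnegative numeric score.
#' @examples
#' smith_waterman_score("HEAGAWGHEE", "PAWHEAE")
#' @export
smith_waterman_score <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(scoring, "alignment_scoring"))
  a <- clean_protein(a)
  b <- clean_protein(b)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = scoring$substitution,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE
  )
  max(as.numeric(pa), 0)
}

#' Normalized Smith-Waterman similarity
#'
#' The raw local-alignment score scaled by the geometric mean of the two
#' self-alignment scores: `SW(a, b) / sqrt(SW(a, a) * SW(b, b))`. Equals 1 for
#' identical sequences and is symmetric in its arguments.
#'
#' @inheritParams smith_waterman_score
#' @return A numeric similarity; 1 when `a == b`.
#' @export
normalized_sw <- function(a, b, scoring = alignment_scoring()) {
  saa <- smith_waterman_score(a, a, scoring)
  sbb <- smith_waterman_score(b, b, scoring)
  if (saa <= 0 || sbb <= 0) {
    abort("Self-alignment score is zero; cannot normalize.",
          class = "simdta_internal_error")
  }
  smith_waterman_score(a, b, scoring) / sqrt(saa * sbb)
}

#' Target-target normalized Smith-Waterman similarity matrix
#'
#' Square symmetric matrix of normalized local-alignment similarities over a
#' target roster; diagonal exactly 1. Only the upper triangle is computed.
#'
#' @param targets A data frame with columns `target_id` and `sequence`.
#' @param scoring An [alignment_scoring()] scheme.
#' @return A numeric matrix with `target_id` dimnames, class
#'   `similarity_matrix`.
#' @export
target_similarity_matrix <- function(targets, scoring = alignment_scoring()) {
  targets <- check_target_table(targets)
  seqs <- vapply(seq_len(nrow(targets)), function(i) {
    clean_protein(targets$sequence[[i]], id = targets$target_id[[i]])
  }, character(1))
  n <- length(seqs)
  self <- vapply(seqs, function(s) smith_waterman_score(s, s, scoring),
                 numeric(1))
  if (any(self <= 0)) {
    abort("Self-alignment score is zero; cannot normalize.",
          class = "simdta_internal_error")
  }
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- smith_waterman_score(seqs[[i]], seqs[[j]], scoring)
        m[i, j] <- m[j, i] <- s / sqrt(self[[i]] * self[[j]])
      }
    }
  }
  dimnames(m) <- list(targets$target_id, targets$target_id)
  new_similarity_matrix(m, type = "normalized_sw")
}

check_target_table <- function(targets) {
  if (!is.data.frame(targets) ||
      !all(c("target_id", "sequence") %in% names(targets))) {
    abort("`targets` must be a data frame with columns `target_id` and `sequence`.",
          class = "simdta_input_error")
  }
  if (nrow(targets) < 1L) {
    abort("`targets` must contain at least one target.",
          class = "simdta_input_error")
  }
  if (anyDuplicated(targets$target_id)) {
    dup <- unique(targets$target_id[duplicated(targets$target_id)])
    abort(sprintf("Duplicate target id(s): %s.", paste(dup, collapse = ", ")),
          class = "simdta_input_error")
  }
  as_tibble(targets)
}
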