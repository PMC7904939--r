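# Small in-code fixtures shared across test files.

toy_drugs <- function() {
  tibble::tibble(
    drug_id = c("eth", "prop", "benz", "tol"),
    smiles = c("CCO", "CCCO", "c1ccccc1", "Cc1ccccc1")
  )
}

toy_targets <- function() {
  tibble::tibble(
    target_id = c("t1", "t2", "t3"),
    sequence = c("MKVLAAGHEEWW", "MKVLAAGHEEWA", "PPPPGGGGSSSS")
  )
}

# fully specified tiny dataset (4 drugs x 3 targets) with one missing cell
toy_dataset <- function() {
  y <- matrix(c(5.0, 6.1, 4.2,
                5.5, NA,  4.8,
                7.2, 6.9, 5.1,
                6.0, 5.2, 4.4), nrow = 4, byrow = TRUE)
  affinity_dataset(toy_drugs(), toy_targets(), y, scale = "pKd")
}

# hand-built fingerprint from a set of 1-based bit positions
fp_from_bits <- function(on, n_bits = 16L) {
  bits <- rep(FALSE, n_bits)
  bits[on] <- TRUE
  structure(list(bits = bits, n_bits = as.integer(n_bits)),
            class = "chem_fp")
}

# compact config so unit tests train in milliseconds (2x2 kernels admit
# small grids; architecture logic is identical)
fast_cfg <- function(epochs = 3L, seed = 1L, dropout_rate = 0.1) {
  model_config(conv_filters = c(4L, 3L),
               conv_kernels = list(c(2L, 2L), c(2L, 2L)),
               dropout_rate = dropout_rate, fc_width = 16L,
               batch_size = 8L, epochs = epochs, seed = seed)
}

# random pair records over a synthetic drug/target grid (no chemistry needed
# for fold-construction tests)
random_pairs <- function(n_drugs, n_targets, density, seed) {
  withr::with_seed(seed, {
    obs <- which(matrix(runif(n_drugs * n_targets) < density,
                        n_drugs, n_targets), arr.ind = TRUE)
    tibble::tibble(
      drug_index = as.integer(obs[, 1]),
      target_index = as.integer(obs[, 2]),
      drug_id = sprintf("D%d", obs[, 1]),
      target_id = sprintf("T%d", obs[, 2]),
      affinity = rnorm(nrow(obs), 5, 1)
    )
  })
}
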