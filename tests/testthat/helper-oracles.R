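# Independent reference implementations used only to check the package.

# Exhaustive affine-gap local alignment (Gotoh three-matrix recursion).
# Convention: a gap of length L costs gap_open + L * gap_extend.
oracle_sw <- function(a, b, sub, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (vertical)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                     F[i - 1L, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + sub[av[i - 1L], bv[j - 1L]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force concordance index: explicit double loop over ordered pairs.
oracle_ci <- function(y, yhat) {
  num <- 0
  z <- 0
  for (i in seq_along(y)) {
    for (j in seq_along(y)) {
      if (y[i] > y[j]) {
        z <- z + 1
        d <- yhat[i] - yhat[j]
        num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
      }
    }
  }
  if (z == 0) stop("all labels tied")
  num / z
}

# Least-squares reference for the modified squared correlation: fits with and
# without intercept via lm() and combines explicitly.
oracle_rm2 <- function(y, yhat) {
  r2 <- summary(stats::lm(yhat ~ y))$r.squared
  k <- stats::coef(stats::lm(yhat ~ 0 + y))[[1L]]
  r02 <- 1 - sum((yhat - k * y)^2) / sum((yhat - mean(yhat))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

# Direct (per-position) valid 2D convolution of a single-channel image.
oracle_conv2d <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  oh <- nrow(img) - kh + 1L; ow <- ncol(img) - kw + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      out[i, j] <- sum(img[i:(i + kh - 1L), j:(j + kw - 1L)] * kernel)
    }
  }
  out
}

blosum <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

random_protein <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], len,
               replace = TRUE), collapse = "")
}
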