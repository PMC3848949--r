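# Independent oracles and small fixture builders. Oracles deliberately avoid
# the code paths they check: eigendecomposition instead of prcomp, explicit
# double loops instead of vectorized matrix algebra.

# random numeric descriptor table with k components
random_descriptor_table <- function(k, seed, name = paste0("rnd", seed)) {
  set.seed(seed)
  m <- matrix(rnorm(20 * k), nrow = 20,
              dimnames = list(aa_alphabet(), paste0("C", seq_len(k))))
  new_descriptor_table(m, name = name, kind = "physicochemical-PCA")
}

# random orthogonal k x k matrix
random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}

# brute-force Euclidean distance matrix by explicit loops
oracle_distance_matrix <- function(values) {
  n <- nrow(values)
  d <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (c in seq_len(ncol(values))) {
        s <- s + (values[i, c] - values[j, c])^2
      }
      d[i, j] <- sqrt(s)
    }
  }
  d
}

# brute-force mean/sd of |a - b| over every cell (population sd)
oracle_pair_stats <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  diffs <- numeric(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      diffs <- c(diffs, abs(a[i, j] - b[i, j]))
    }
  }
  list(n = length(diffs), mean = mean(diffs),
       sd = sqrt(mean((diffs - mean(diffs))^2)))
}

# explained-variance fractions via eigendecomposition of the covariance or
# correlation matrix (never prcomp)
oracle_variance_fractions <- function(x, scale = FALSE) {
  cm <- if (scale) stats::cor(x) else stats::cov(x)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

# 20 x 3 latent factor scores with exact sample variances `vars`,
# exactly mean-zero and mutually orthogonal
exact_latent_factors <- function(vars, seed) {
  set.seed(seed)
  a <- cbind(1, matrix(rnorm(20 * length(vars)), nrow = 20))
  q <- qr.Q(qr(a))[, -1, drop = FALSE]  # orthonormal, orthogonal to constant
  sweep(q, 2, sqrt(vars * (20 - 1)), `*`)
}

# tiny AAindex1 record whose data block holds `values` in file order
aaindex_record <- function(accession, values) {
  stopifnot(length(values) == 20)
  c(paste0("H ", accession),
    paste0("D synthetic test record ", accession),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("     ", paste(format(values[1:10]), collapse = "  ")),
    paste0("     ", paste(format(values[11:20]), collapse = "  ")),
    "//")
}
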