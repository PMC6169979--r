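# Independent brute-force oracles. These deliberately share no code
# with the package: statistics are recomputed from first principles
# (pairwise Hamming distances, direct formula transcriptions,
# exhaustive enumeration) so they can vouch for the fast paths.

# Mean pairwise difference over all sample pairs, from raw sequences.
oracle_pi <- function(mat) {
  n <- nrow(mat)
  usable <- colSums(mat == "N" | mat == "-") == 0
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(mat[i, usable] != mat[j, usable])
    }
  }
  tot / choose(n, 2)
}

# Segregating-site count from raw sequences (complete-case columns).
oracle_S <- function(mat) {
  usable <- colSums(mat == "N" | mat == "-") == 0
  sum(apply(mat[, usable, drop = FALSE], 2, function(col) length(unique(col)) > 1))
}

# Tajima (1989) D, written directly from the published constants.
oracle_tajima_d <- function(mat) {
  n <- nrow(mat)
  S <- oracle_S(mat)
  if (S == 0) return(NA_real_)
  k <- oracle_pi(mat)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Normalized Fay & Wu H (Zeng et al. 2006), from derived counts
# obtained by comparing each segregating column to an outgroup base.
oracle_fay_wu_h <- function(mat, outgroup) {
  n <- nrow(mat)
  usable <- colSums(mat == "N" | mat == "-") == 0
  xi <- c()
  for (j in which(usable)) {
    alleles <- unique(mat[, j])
    if (length(alleles) != 2) next
    anc <- outgroup[j]
    if (!(anc %in% alleles)) next
    xi <- c(xi, sum(mat[, j] != anc))
  }
  Sp <- length(xi)
  if (Sp == 0) return(NA_real_)
  pi_pol <- sum(2 * xi * (n - xi)) / (n * (n - 1))
  theta_l <- sum(xi) / (n - 1)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  bn1 <- sum(1 / (1:n)^2)
  th <- Sp / a1
  th2 <- Sp * (Sp - 1) / (a1^2 + a2)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  (pi_pol - theta_l) / sqrt(v)
}

# Haplotype homozygosity from raw sequences.
oracle_ew <- function(mat) {
  usable <- colSums(mat == "N" | mat == "-") == 0
  seg <- which(apply(mat[, usable, drop = FALSE], 2, function(c) length(unique(c)) > 1))
  sub <- mat[, which(usable)[seg], drop = FALSE]
  keys <- apply(sub, 1, paste, collapse = "")
  p <- as.numeric(table(keys)) / nrow(mat)
  sum(p^2)
}

# Two-sided Fisher's exact test by exhaustive hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  ntot <- a + b + c + d
  lo <- max(0, c1 - (ntot - r1))
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    stats::dhyper(x, c1, ntot - c1, r1)
  }, numeric(1))
  p_obs <- stats::dhyper(a, c1, ntot - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- 1
  for (k in m:1) {
    run_min <- min(run_min, p[o[k]] * m / k)
    adj[o[k]] <- run_min
  }
  pmin(adj, 1)
}

# Random alignment fixture: n sequences of length L with `n_var`
# variable columns, optional outgroup row.
random_alignment <- function(n, L, n_var, seed, with_outgroup = TRUE) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)
  mat <- matrix(backbone, n, L, byrow = TRUE)
  var_cols <- sample(L, n_var)
  for (j in var_cols) {
    alt <- sample(setdiff(bases, backbone[j]), 1)
    k <- sample(n - 1, 1)
    mat[sample(n, k), j] <- alt
  }
  out <- if (with_outgroup) list(out = backbone) else list()
  alignment(paste0("rnd", seed), mat, paste0("s", 1:n), outgroups = out)
}
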