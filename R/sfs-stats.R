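#' Per-gene site-frequency-spectrum and haplotype statistics
#'
#' These functions compute the classic per-gene neutrality statistics:
#' Watterson's theta, nucleotide diversity pi, Tajima's D, the
#' normalized Fay and Wu's H (outgroup-polarized by strict parsimony),
#' and Ewens-Watterson haplotype homozygosity. All per-gene quantities
#' (pi, theta) are summed over sites, not divided by length. Columns
#' containing missing data (`N` or `-`) in any retained sample are
#' excluded from every statistic so the sample size n is constant
#' across sites.
#'
#' @name sfs_stats
NULL

#' Segregating-site columns of an alignment
#'
#' Returns the variable (bi- or multiallelic) columns among in-group
#' samples, skipping columns flagged as excluded. A column where the
#' only heterogeneity involves `N` or a gap is not segregating.
#'
#' @param aln an [alignment()].
#' @return a list of site columns, each a list with `position` (0-based
#'   column index), `alleles` (named base counts) and `n_called`.
#' @export
segregating_sites <- function(aln) {
  idx <- segregating_positions(aln)
  lapply(idx, function(j) {
    counts <- table(aln$seqs[, j])
    counts <- counts[names(counts) %in% DNA_BASES]
    list(
      position = j - 1L,
      alleles = as.integer(counts) |> stats::setNames(names(counts)),
      n_called = sum(counts)
    )
  })
}

# 1-based indices of usable variable columns (vectorized scan).
segregating_positions <- function(aln) {
  mat <- aln$seqs
  n <- nrow(mat)
  excl <- excluded_columns(aln)
  if (n < 2L) return(integer(0))
  ref <- matrix(mat[1L, ], n, ncol(mat), byrow = TRUE)
  variable <- colSums(mat != ref) > 0L
  which(variable & !excl)
}

#' Watterson's estimator of the population mutation rate (per gene)
#'
#' `theta_w = S / a1` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @param S number of segregating sites.
#' @param n number of sampled haplotypes.
#' @return Watterson's theta on the per-gene scale.
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("watterson_theta requires n >= 2")
  stopifnot(S >= 0)
  S / harmonic_a1(n)
}

# Per-gene pi from allele counts of the segregating columns.
# Each column contributes 1 - sum(choose(c_j, 2)) / choose(n, 2),
# which handles multiallelic columns exactly.
pi_from_columns <- function(count_list, n) {
  if (length(count_list) == 0L) return(0)
  denom <- choose(n, 2)
  sum(vapply(count_list, function(cnt) {
    (denom - sum(choose(cnt, 2))) / denom
  }, numeric(1)))
}

#' Summarize per-gene polymorphism
#'
#' One pass over an alignment producing everything the neutrality
#' statistics need: n, S, pi, Watterson's theta, outgroup-polarized
#' derived-allele counts, haplotype frequencies and Ewens-Watterson
#' homozygosity.
#'
#' @param aln an [alignment()].
#' @param outgroup_names outgroups used for polarization (default: all
#'   attached outgroups; `character(0)` skips polarization).
#' @return an object of class `"polymorphism_summary"`.
#' @export
polymorphism_summary <- function(aln, outgroup_names = names(aln$outgroups)) {
  n <- n_samples(aln)
  idx <- segregating_positions(aln)
  counts <- lapply(idx, function(j) {
    cnt <- table(aln$seqs[, j])
    as.integer(cnt[names(cnt) %in% DNA_BASES]) |>
      stats::setNames(names(cnt)[names(cnt) %in% DNA_BASES])
  })
  S <- length(idx)
  pol <- if (length(outgroup_names) > 0L && S > 0L) {
    polarize_derived(aln, outgroup_names)
  } else {
    list(derived_counts = integer(0), n_unpolarized = S)
  }
  hf <- haplotype_frequencies(aln, idx)
  structure(
    list(
      gene_id = aln$gene_id,
      n = n,
      S = S,
      pi = pi_from_columns(counts, n),
      theta_w = if (n >= 2) S / harmonic_a1(n) else NA_real_,
      derived_counts = pol$derived_counts,
      n_unpolarized = pol$n_unpolarized,
      hap_freqs = hf,
      F_ew = sum(hf^2)
    ),
    class = "polymorphism_summary"
  )
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat(sprintf(
    "<polymorphism_summary> %s: n=%d S=%d pi=%.3f theta_w=%.3f EW=%.3f (%d unpolarized)\n",
    x$gene_id, x$n, x$S, x$pi, x$theta_w, x$F_ew, x$n_unpolarized
  ))
  invisible(x)
}

#' Polarize segregating sites against outgroups by strict parsimony
#'
#' The ancestral state of a biallelic segregating site is the outgroup
#' base when (i) every named outgroup carries the same, unambiguous
#' base there and (ii) that base is one of the two in-group alleles
#' (no reverse or convergent mutation assumed). Multiallelic sites and
#' sites failing either condition are counted as unpolarized and
#' excluded from the H statistic.
#'
#' @param aln an [alignment()] with outgroups attached.
#' @param outgroup_names names of the outgroups to use.
#' @return list with `derived_counts` (one derived-allele count in
#'   `[1, n-1]` per polarizable site) and `n_unpolarized`.
#' @export
polarize_derived <- function(aln, outgroup_names = names(aln$outgroups)) {
  missing_out <- setdiff(outgroup_names, names(aln$outgroups))
  if (length(missing_out)) {
    stop("lookup error: outgroup(s) not attached: ", paste(missing_out, collapse = ", "))
  }
  if (length(outgroup_names) == 0L) stop("polarize_derived requires >= 1 outgroup")
  idx <- segregating_positions(aln)
  derived <- integer(0)
  n_unpol <- 0L
  for (j in idx) {
    cnt <- table(aln$seqs[, j])
    cnt <- cnt[names(cnt) %in% DNA_BASES]
    if (length(cnt) != 2L) {
      n_unpol <- n_unpol + 1L
      next
    }
    obases <- vapply(aln$outgroups[outgroup_names], function(s) s[j], character(1))
    anc <- unique(obases)
    if (length(anc) != 1L || !(anc %in% DNA_BASES) || !(anc %in% names(cnt))) {
      n_unpol <- n_unpol + 1L
      next
    }
    derived <- c(derived, sum(cnt[names(cnt) != anc]))
  }
  list(derived_counts = derived, n_unpolarized = n_unpol)
}

# Tajima (1989) constants and statistic from (n, S, pi).
tajima_d_value <- function(n, S, pi) {
  if (S < 1L || n < 4L) return(NA_real_)
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Normalized difference between pairwise diversity pi and Watterson's
#' theta. Undefined (returned as `NA`) when there are no segregating
#' sites; negative values indicate an excess of rare variants.
#'
#' @param summary a [polymorphism_summary()].
#' @return Tajima's D, or `NA` when S = 0.
#' @export
tajimas_d <- function(summary) {
  tajima_d_value(summary$n, summary$S, summary$pi)
}

# Normalized H from polarized derived counts (Zeng et al. 2006
# variance with theta-hat = S/a1 and theta2-hat = S(S-1)/(a1^2+a2)).
fay_wu_h_value <- function(n, derived_counts) {
  Sp <- length(derived_counts)
  if (Sp < 1L || n < 3L) return(NA_real_)
  i <- derived_counts
  pi_pol <- sum(2 * i * (n - i)) / (n * (n - 1))
  theta_l <- sum(i) / (n - 1)
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  bn1 <- a2 + 1 / n^2 # sum(1/i^2) up to n
  th <- Sp / a1
  th2 <- Sp * (Sp - 1) / (a1^2 + a2)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  (pi_pol - theta_l) / sqrt(v)
}

#' Normalized Fay and Wu's H
#'
#' Contrasts pairwise diversity with the high-frequency-weighted
#' estimator `theta_L = sum(i * xi_i) / (n - 1)` over the polarizable
#' segregating sites; an excess of high-frequency derived alleles (the
#' sweep signature) drives the statistic negative. Normalization
#' follows the variance of `pi - theta_L` with the standard moment
#' plug-ins for theta and theta squared.
#'
#' @param summary a [polymorphism_summary()] with derived counts.
#' @return normalized H, or `NA` when no site could be polarized.
#' @export
fay_wu_h_normalized <- function(summary) {
  fay_wu_h_value(summary$n, summary$derived_counts)
}

# Haplotype relative frequencies over usable segregating columns.
haplotype_frequencies <- function(aln, idx = segregating_positions(aln)) {
  n <- n_samples(aln)
  if (length(idx) == 0L) return(1)
  sub <- aln$seqs[, idx, drop = FALSE]
  keys <- do.call(paste0, lapply(seq_along(idx), function(k) sub[, k]))
  as.numeric(table(keys)) / n
}

#' Ewens-Watterson haplotype homozygosity
#'
#' `F = sum(p_i^2)` over the distinct-haplotype relative frequencies,
#' with haplotypes built from the usable segregating columns only
#' (invariant columns cannot change homozygosity). `F = 1` when all
#' sequences are identical; high F relative to the neutral expectation
#' signals directional selection.
#'
#' @param aln an [alignment()].
#' @return homozygosity in `[1/n, 1]`.
#' @export
ew_homozygosity <- function(aln) {
  sum(haplotype_frequencies(aln)^2)
}

#' The (D, H, EW) statistic vector of a gene
#'
#' @param summary a [polymorphism_summary()].
#' @return list with `D`, `H_norm`, `F_ew` (`NA` where undefined).
#' @export
stat_vector <- function(summary) {
  list(
    D = tajimas_d(summary),
    H_norm = fay_wu_h_normalized(summary),
    F_ew = summary$F_ew
  )
}

#' Write per-gene statistics to TSV
#'
#' @param summaries list of [polymorphism_summary()] objects.
#' @param path output TSV path.
#' @return the data frame written, invisibly.
#' @export
write_stats_tsv <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    sv <- stat_vector(s)
    data.frame(
      gene_id = s$gene_id, n = s$n, S = s$S,
      theta_w = s$theta_w, pi = s$pi,
      TajD = sv$D, nFWH = sv$H_norm, EW = sv$F_ew
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
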