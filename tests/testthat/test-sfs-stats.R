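test_that("segregating sites respect missing-data and exclusion rules", {
  pad <- strrep("A", 18)
  # row c carries one N (5%, retained); its column is excluded, so the
  # A/C/N column is not segregating
  aln <- alignment("g", paste0(c("AA", "AC", "AN"), pad), c("a", "b", "c"))
  aln <- filter_missing(aln)
  expect_equal(n_samples(aln), 3)
  expect_length(segregating_sites(aln), 0)
  aln2 <- filter_missing(alignment("g", paste0(c("AA", "AC", "AC"), pad),
                                   c("a", "b", "c")))
  sites2 <- segregating_sites(aln2)
  expect_length(sites2, 1)
  expect_equal(sites2[[1]]$position, 1) # 0-based
  expect_equal(sort(unname(sites2[[1]]$alleles)), c(1, 2))
  expect_equal(sites2[[1]]$n_called, 3)
})

test_that("watterson_theta matches the harmonic-sum definition", {
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(10, 2), 10) # a1 = 1
  expect_equal(watterson_theta(3, 4), 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  expect_error(watterson_theta(3, 1), "n >= 2")
})

test_that("Tajima's D is NA at S=0, negative for all-singleton data, matches oracle", {
  invariant <- alignment("g", rep("ACGTACGTACGT", 4), paste0("s", 1:4))
  expect_true(is.na(tajimas_d(polymorphism_summary(invariant))))

  # every variant a singleton -> D < 0 at n=4
  seqs <- c("ACGTACGTACGT", "CCGTACGTACGT", "ACGAACGTACGT", "ACGTACCTACGT")
  s <- polymorphism_summary(alignment("g", seqs, paste0("s", 1:4)))
  expect_lt(tajimas_d(s), 0)

  # fixed toy alignment vs independent transcription of Tajima (1989)
  mat <- random_alignment(4, 12, 5, seed = 71)$seqs
  s2 <- polymorphism_summary(alignment("toy", mat, paste0("s", 1:4)))
  expect_equal(tajimas_d(s2), oracle_tajima_d(mat), tolerance = 1e-12)
})

test_that("polarization follows strict parsimony with outgroup agreement", {
  base <- strsplit("AAAAAAAAAAAAAA", "")[[1]]
  mat <- matrix(base, 14, 14, byrow = TRUE)
  mat[1:4, 2] <- "G" # derived count 4 if outgroups say A
  mat[1:7, 5] <- "C" # outgroups disagree here
  mat[1:3, 8] <- "T" # outgroup base not among in-group alleles
  og1 <- og2 <- base
  og1[5] <- "A"; og2[5] <- "G"
  og1[8] <- og2[8] <- "G"
  aln <- alignment("g", mat, paste0("s", 1:14),
                   outgroups = list(o1 = og1, o2 = og2))
  pol <- polarize_derived(aln, c("o1", "o2"))
  expect_equal(pol$derived_counts, 4L)
  expect_equal(pol$n_unpolarized, 2L)
  expect_error(polarize_derived(aln, "missing_og"), "lookup error")
})

test_that("normalized Fay & Wu's H has the right sign and matches the oracle", {
  # one derived singleton at n=4: pi = 0.5, theta_L = 1/3 -> positive
  base <- strsplit("ACGTACGTACGT", "")[[1]]
  mat <- matrix(base, 4, 12, byrow = TRUE)
  mat[1, 3] <- "T"
  aln <- alignment("g", mat, paste0("s", 1:4), outgroups = list(o = base))
  h <- fay_wu_h_normalized(polymorphism_summary(aln))
  expect_gt(h, 0)
  # one derived allele at count n-1: pi = 0.5, theta_L = 1 -> negative
  mat2 <- matrix(base, 4, 12, byrow = TRUE)
  mat2[1:3, 3] <- "T"
  aln2 <- alignment("g", mat2, paste0("s", 1:4), outgroups = list(o = base))
  expect_lt(fay_wu_h_normalized(polymorphism_summary(aln2)), 0)
  # richer fixture vs the independent implementation
  r <- random_alignment(8, 30, 10, seed = 12)
  expect_equal(
    fay_wu_h_normalized(polymorphism_summary(r)),
    oracle_fay_wu_h(r$seqs, r$outgroups$out),
    tolerance = 1e-12
  )
})

test_that("EW homozygosity handles identity, all-distinct and mixed cases", {
  same <- alignment("g", rep("ACGTAC", 5), paste0("s", 1:5))
  expect_equal(ew_homozygosity(same), 1)
  # 14 all-distinct haplotypes
  mat <- matrix("A", 14, 14)
  for (i in 1:13) mat[i, i] <- "G"
  distinct <- alignment("g", mat, paste0("s", 1:14))
  expect_equal(ew_homozygosity(distinct), 1 / 14, tolerance = 1e-12)
  # haplotype counts {100, 49} of 149
  mat2 <- matrix("A", 149, 9)
  mat2[101:149, 4] <- "T"
  aln2 <- alignment("g", mat2, paste0("s", 1:149))
  expect_equal(ew_homozygosity(aln2), (100 / 149)^2 + (49 / 149)^2, tolerance = 1e-12)
})

test_that("pi equals brute-force pairwise distances and theta_H/theta_L identity holds", {
  for (seed in 1:6) {
    r <- random_alignment(sample(4:8, 1), 24, sample(3:10, 1), seed = 100 + seed)
    s <- polymorphism_summary(r)
    expect_equal(s$pi, oracle_pi(r$seqs), tolerance = 1e-10)
    # pi - theta_H == 2 (pi - theta_L) on the polarized sites
    xi <- s$derived_counts
    n <- s$n
    if (length(xi) > 0) {
      pi_pol <- sum(2 * xi * (n - xi)) / (n * (n - 1))
      theta_h <- 2 * sum(xi^2) / (n * (n - 1))
      theta_l <- sum(xi) / (n - 1)
      expect_equal(pi_pol - theta_h, 2 * (pi_pol - theta_l), tolerance = 1e-12)
    }
  }
})

test_that("EW is invariant to sample order and haplotype relabeling", {
  r <- random_alignment(8, 30, 8, seed = 55)
  f0 <- ew_homozygosity(r)
  perm <- alignment("g", r$seqs[sample(8), ], paste0("p", 1:8))
  expect_equal(ew_homozygosity(perm), f0, tolerance = 1e-12)
  relabeled <- alignment("g", chartr("ACGT", "GTAC", r$seqs), paste0("s", 1:8))
  expect_equal(ew_homozygosity(relabeled), f0, tolerance = 1e-12)
})
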