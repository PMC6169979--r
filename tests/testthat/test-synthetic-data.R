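# Small sample sizes keep these distributional checks fast; the
# acceptance suite exercises the full study-scale conditions.

test_that("neutral generator: theta=0 is invariant, E[S] matches theta*a1, seeds reproduce", {
  cfg <- sim_config(n_lines = 12, n_sister = 0, missing_rate = 0, seed = 1)
  flat <- generate_neutral_gene(cfg, 7, L = 300, theta = 0)
  expect_equal(polymorphism_summary(flat)$S, 0)
  expect_identical(
    generate_neutral_gene(cfg, 7, L = 300, theta = 5)$seqs,
    generate_neutral_gene(cfg, 7, L = 300, theta = 5)$seqs
  )
  S_vals <- vapply(1:400, function(i) {
    polymorphism_summary(generate_neutral_gene(cfg, i, L = 600, theta = 4))$S
  }, numeric(1))
  a1 <- sum(1 / (1:11))
  se <- stats::sd(S_vals) / sqrt(length(S_vals))
  expect_lt(abs(mean(S_vals) - 4 * a1), 3 * se)
})

test_that("sweep generator produces the sweep signal classes", {
  cfg <- sim_config(n_lines = 30, n_sister = 0, missing_rate = 0,
                    sweep_f = 0.9, sweep_tau = 0.005, seed = 2)
  cfg0 <- sim_config(n_lines = 30, n_sister = 0, missing_rate = 0, seed = 2)
  # limiting case: all lineages captured at tau ~ 0 -> near-identical sample
  cfg_hard <- sim_config(n_lines = 30, n_sister = 0, missing_rate = 0,
                         sweep_f = 1, sweep_tau = 1e-6, seed = 3)
  hard <- generate_sweep_gene(cfg_hard, 5, L = 900, theta = 8)
  expect_gt(ew_homozygosity(hard), 0.95)
  # directional shift: swept genes have lower D and higher EW on average
  stats_for <- function(gen, config, seeds) {
    t(vapply(seeds, function(i) {
      a <- gen(config, i, L = 900, theta = 8)
      s <- polymorphism_summary(a)
      c(D = tajimas_d(s), EW = s$F_ew)
    }, c(D = 0, EW = 0)))
  }
  swept <- stats_for(generate_sweep_gene, cfg, 1:120)
  neut <- stats_for(generate_neutral_gene, cfg0, 201:320)
  expect_lt(mean(swept[, "D"], na.rm = TRUE), mean(neut[, "D"], na.rm = TRUE))
  expect_lt(mean(swept[, "D"], na.rm = TRUE), 0)
  expect_gt(mean(swept[, "EW"]), mean(neut[, "EW"]))
})

test_that("sweep generator with f=0 reduces to the neutral model (KS on D)", {
  cfg <- sim_config(n_lines = 15, n_sister = 0, missing_rate = 0,
                    sweep_f = 0, seed = 4)
  D_neutral <- vapply(1:250, function(i) {
    tajimas_d(polymorphism_summary(generate_neutral_gene(cfg, i, L = 600, theta = 6)))
  }, numeric(1))
  D_f0 <- vapply(1001:1250, function(i) {
    tajimas_d(polymorphism_summary(generate_sweep_gene(cfg, i, L = 600, theta = 6)))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(D_neutral, D_f0))
  expect_gt(ks$p.value, 0.01)
})

test_that("divergence generator bookkeeping matches the classifier exactly", {
  cfg <- sim_config(n_lines = 14, n_sister = 4, alpha_adaptive = 0.5,
                    missing_rate = 0, seed = 5)
  for (i in 1:15) {
    g <- generate_divergence_gene(cfg, 300 + i, L = 450)
    truth <- attr(g, "truth")
    tab <- classify_codon_changes(g)
    expect_equal(tab$Pn, unname(truth["Pn"]))
    expect_equal(tab$Ps, unname(truth["Ps"]))
    expect_equal(tab$Dn, unname(truth["Dn"]))
    expect_equal(tab$Ds, unname(truth["Ds"]))
  }
})

test_that("study bundles satisfy their own pairing rules and are reproducible", {
  cfg <- sim_config(n_lines = 10, n_sister = 3, n_focal = 6,
                    cds_length_range = c(300, 900), seed = 6)
  b1 <- generate_study_bundle(cfg)
  b2 <- generate_study_bundle(cfg)
  expect_identical(
    lapply(b1$alignments, `[[`, "seqs"),
    lapply(b2$alignments, `[[`, "seqs")
  )
  expect_equal(sum(b1$truth$role == "focal"), 6)
  expect_equal(sum(b1$truth$swept), round(0.3 * 6))
  # every pairing passes validate_controls by construction
  for (fid in unique(b1$pairings$focal_id)) {
    rows <- b1$pairings[b1$pairings$focal_id == fid, ]
    focal <- list(gene_id = fid, cds_length = rows$focal_cds_length[1],
                  start = rows$focal_start[1])
    cand <- data.frame(gene_id = rows$control_id,
                       cds_length = rows$control_cds_length,
                       start = rows$control_start)
    expect_false(is.null(validate_controls(focal, cand)))
  }
  # disk round trip
  dir <- file.path(tempdir(), "bundle_test")
  unlink(dir, recursive = TRUE)
  write_study_bundle(b1, dir)
  back <- read_study_bundle(dir)
  expect_setequal(names(back$alignments), names(b1$alignments))
  fid <- names(b1$alignments)[1]
  expect_equal(back$alignments[[fid]]$seqs, b1$alignments[[fid]]$seqs,
               ignore_attr = TRUE)
})
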