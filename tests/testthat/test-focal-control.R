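test_that("control validation enforces length-ratio, distance and count rules", {
  focal <- list(gene_id = "F", cds_length = 900, start = 100000)
  cand <- data.frame(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    cds_length = c(360, 900, 1200, 1800, 900, 1000), # a: 0.4x -> out
    start = c(100500, 39000, 120000, 99000, 161000, 130000) # b, e: 61kb away
  )
  gp <- validate_controls(focal, cand)
  expect_s3_class(gp, "gene_pairing")
  expect_equal(gp$control_ids, c("c", "d", "f"))
  # dropping one survivor leaves 2 of min 3 -> focal gene rejected
  expect_null(validate_controls(focal, cand[cand$gene_id != "f", ]))
  expect_equal(
    validate_controls(focal, cand[cand$gene_id != "f", ], min_controls = 2)$control_ids,
    c("c", "d")
  )
})

test_that("comparison_score subtracts the control median, even-count rule included", {
  expect_equal(comparison_score(-1.9, c(-0.5, 0.1, -0.2)), -1.7)
  expect_equal(comparison_score(0.3, c(0.1, 0.3, 0.9)), 0)
  expect_equal(comparison_score(3, c(1, 2, 3, 4)), 0.5) # median 2.5
  expect_true(is.na(comparison_score(1, c(NA_real_, NA_real_))))
  # translation equivariance
  sc <- comparison_score(0.7, c(0.1, -0.3, 0.5))
  expect_equal(comparison_score(0.7 + 5, c(0.1, -0.3, 0.5) + 5), sc, tolerance = 1e-12)
})

test_that("group_test reports both fits and flags degenerate inputs", {
  sym <- c(-2, -1, -0.5, 0.5, 1, 2)
  g <- group_test(sym)
  expect_gt(g$p_t, 0.5)
  expect_false(g$significant_t)
  zeros <- group_test(rep(0, 10))
  expect_true(zeros$degenerate)
  expect_true(is.na(zeros$p_t))
  shifted <- group_test(rnorm(50, mean = 2, sd = 0.3))
  expect_true(shifted$significant_t)
  expect_true(shifted$significant_w)
})

test_that("rank_scores uses dense extremeness ranks with percentile 100 at the top", {
  sc <- c(g1 = 0.9, g2 = 0.1, g3 = -0.4, g4 = 0.1)
  r <- rank_scores(sc, orientation = "high")
  expect_equal(r$rank[r$gene_id == "g1"], 1)
  expect_equal(r$percentile[r$gene_id == "g1"], 100)
  # ties share the smaller (more extreme) rank
  expect_equal(r$rank[r$gene_id == "g2"], r$rank[r$gene_id == "g4"])
  # low orientation flips the extreme end
  r2 <- rank_scores(sc, orientation = "low")
  expect_equal(r2$rank[r2$gene_id == "g3"], 1)
  # distinct scores yield a permutation of 1..N
  r3 <- rank_scores(c(a = 3, b = 1, c = 2), "high")
  expect_setequal(r3$rank, 1:3)
})

test_that("rank_against_null is deterministic and tops out at 100", {
  pairings <- lapply(1:5, function(i) {
    list(focal_id = paste0("F", i), control_values = c(0.1, -0.2, 0.3, 0))
  })
  true_scores <- stats::setNames(c(9, 0.05, -0.1, 0.2, 0), paste0("F", 1:5))
  r1 <- rank_against_null(true_scores, pairings, orientation = "high")
  expect_equal(r1$null_percentile[r1$gene_id == "F1"], 100)
  expect_equal(attr(r1, "null_size"), 20) # every control takes a turn
  rmc1 <- rank_against_null(true_scores, pairings, mode = "montecarlo",
                            n_perm = 50, seed = 4)
  rmc2 <- rank_against_null(true_scores, pairings, mode = "montecarlo",
                            n_perm = 50, seed = 4)
  expect_equal(rmc1$null_percentile, rmc2$null_percentile)
})

test_that("sweep calls require all three criteria and propagate missingness", {
  base <- data.frame(
    gene_id = "g", p_dhew = 0.002,
    p_D_corrected = 0.03, p_H_corrected = 0.4, p_EW_corrected = 0.013,
    pct_D = 100, nullpct_D = 99.6, pct_H = 60, nullpct_H = 50,
    pct_DoS = 70, nullpct_DoS = 60
  )
  # the printed profile of a called gene: DHEW 0.002, two corrected
  # components < 0.05, top-ranked D comparison score
  expect_true(unname(call_sweeps(base)))
  # criterion 1 fails
  g1 <- base; g1$p_dhew <- 0.2
  expect_false(unname(call_sweeps(g1)))
  # criterion 2 fails with only one significant corrected statistic
  g2 <- base; g2$p_EW_corrected <- 0.4
  expect_false(unname(call_sweeps(g2)))
  # criterion 3 fails when rank-against-null drops below the cutoff
  g3 <- base; g3$nullpct_D <- 90
  expect_false(unname(call_sweeps(g3)))
  # missing DHEW -> not callable
  g4 <- base; g4$p_dhew <- NA_real_
  expect_true(is.na(call_sweeps(g4)))
  # monotonicity: making evidence stronger never un-calls
  g5 <- base
  g5$p_D_corrected <- g5$p_D_corrected / 2
  g5$nullpct_D <- 100
  expect_true(unname(call_sweeps(g5)))
})

test_that("adaptive divergence calls follow corrected-p and DoS sign", {
  mk <- data.frame(
    gene_id = c("gb", "Ird1", "x", "y"),
    FET_corrected = c(0.047, 0.0005, 0.14, 0.01),
    DoS = c(0.396, -0.373, 0.4, NA)
  )
  calls <- call_adaptive_divergence(mk)
  expect_true(calls[["gb"]])
  expect_false(calls[["Ird1"]]) # significant but negative DoS
  expect_false(calls[["x"]]) # positive DoS but p too large
  expect_true(is.na(calls[["y"]]))
})

test_that("a planted pathway-wide shift survives trimming the strongest genes", {
  set.seed(77)
  # 68 pairings with a modest planted mean shift in the scores
  scores <- rnorm(68, mean = 0.08, sd = 0.15)
  full <- group_test(scores)
  trimmed <- group_test(scores[rank(-abs(scores)) > ceiling(0.1 * length(scores))])
  expect_gt(full$mean, 0)
  expect_gt(trimmed$mean, 0)
  expect_equal(sign(trimmed$mean), sign(full$mean))
})

test_that("null-rank percentiles are uniform under exchangeability", {
  set.seed(19)
  n_genes <- 400
  pairings <- lapply(seq_len(n_genes), function(i) {
    list(focal_id = paste0("F", i), control_values = rnorm(4))
  })
  true_scores <- vapply(pairings, function(p) {
    comparison_score(rnorm(1), p$control_values)
  }, numeric(1))
  names(true_scores) <- paste0("F", seq_len(n_genes))
  r <- rank_against_null(true_scores, pairings, orientation = "high")
  ks <- suppressWarnings(stats::ks.test(r$null_percentile / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})
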