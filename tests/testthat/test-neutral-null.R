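test_that("fixed-S conditioning, determinism, and E[S] under theta hold", {
  nd <- simulate_neutral(10, 7, 50, seed = 5)
  expect_true(all(nd$S == 7)) # every replicate carries exactly S mutations
  nd2 <- simulate_neutral(10, 7, 50, seed = 5)
  expect_equal(nd$D, nd2$D)
  expect_equal(nd$F, nd2$F)
  # unconditioned variant: E[S] = theta * a1
  un <- simulate_neutral(10, S_cond = NULL, reps = 4000, seed = 9, theta = 2)
  a1 <- sum(1 / (1:9))
  se <- stats::sd(un$S) / sqrt(un$reps)
  expect_lt(abs(mean(un$S) - 2 * a1), 3 * se)
})

test_that("neutral D and normalized H are centered near zero", {
  un <- simulate_neutral(20, S_cond = NULL, reps = 2000, seed = 13, theta = 5)
  expect_lt(abs(mean(un$D, na.rm = TRUE)), 0.1)
  expect_lt(abs(mean(un$H, na.rm = TRUE)), 0.1)
})

test_that("genealogy sampler reproduces the closed-form E[TMRCA]", {
  set.seed(31)
  tm <- replicate(3000, dhewscan:::sim_coalescent_tree(12)$tmrca)
  expect_lt(abs(mean(tm) - 2 * (1 - 1 / 12)), 3 * stats::sd(tm) / sqrt(3000))
})

test_that("empirical p-values use the pseudocount rule and the stated tails", {
  draws <- seq(-2, 2, length.out = 1000)
  expect_equal(pvalue_from_null(-5, draws, "lower"), 1 / 1001)
  expect_equal(pvalue_from_null(5, draws, "upper"), 1 / 1001)
  expect_equal(pvalue_from_null(0, draws, "lower"), 0.5, tolerance = 0.01)
  expect_error(pvalue_from_null(0, numeric(0), "lower"), "empty null")
  # deterministic p on re-run with a seeded null
  nd <- simulate_neutral(14, 10, 500, seed = 77)
  p1 <- pvalue_from_null(-1.5, nd$D, "lower")
  p2 <- pvalue_from_null(-1.5, simulate_neutral(14, 10, 500, seed = 77)$D, "lower")
  expect_equal(p1, p2)
})

test_that("DHEW compound p is 1 for a maximally ordinary vector and bounded below", {
  nd <- simulate_neutral(12, 8, 400, seed = 3)
  # observation milder than every draw in every component
  tame <- list(D = max(nd$D) + 1, H_norm = max(nd$H) + 1, F_ew = min(nd$F) - 0.01)
  expect_equal(dhew_compound(tame, nd), 1, tolerance = 2 / 401)
  # compound >= joint exceedance of the component minima (set inclusion)
  obs <- list(D = stats::quantile(nd$D, 0.1), H_norm = stats::quantile(nd$H, 0.2),
              F_ew = stats::quantile(nd$F, 0.9))
  pv <- null_pvalues(obs, nd)
  pmin_obs <- min(unlist(pv))
  npv <- dhewscan:::null_internal_pvalues(nd)
  joint_min <- (1 + sum(npv$p_D <= pmin_obs & npv$p_H <= pmin_obs & npv$p_EW <= pmin_obs)) /
    (nd$reps + 1)
  expect_gte(dhew_compound(obs, nd), joint_min)
  # undefined component propagates to NA
  expect_true(is.na(dhew_compound(list(D = NA, H_norm = 0, F_ew = 0.5), nd)))
})

test_that("null cache returns identical objects for identical keys", {
  a <- get_null_distribution(8, 5, reps = 50, seed = 2)
  b <- get_null_distribution(8, 5, reps = 50, seed = 2)
  expect_identical(a, b)
})

test_that("simulated D distribution matches an independent coalescent simulator", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  script <- tempfile(fileext = ".py")
  out_json <- tempfile(fileext = ".json")
  writeLines(c(
    "import json, sys, math",
    "import msprime, numpy as np",
    "rng = np.random.default_rng(2024)",
    "n, S, reps = 20, 20, 1500",
    "a1 = sum(1.0/i for i in range(1, n))",
    "a2 = sum(1.0/i**2 for i in range(1, n))",
    "b1 = (n+1)/(3*(n-1)); b2 = 2*(n*n+n+3)/(9*n*(n-1))",
    "c1 = b1 - 1/a1; c2 = b2 - (n+2)/(a1*n) + a2/a1**2",
    "e1 = c1/a1; e2 = c2/(a1*a1+a2)",
    "vals = []",
    "for ts in msprime.sim_ancestry(samples=n, ploidy=1, num_replicates=reps, random_seed=99):",
    "    t = ts.first()",
    "    edges = [(u, t.branch_length(u)) for u in t.nodes() if t.parent(u) != -1]",
    "    lens = np.array([e[1] for e in edges])",
    "    pick = rng.choice(len(edges), size=S, p=lens/lens.sum())",
    "    xi = np.array([len(list(t.samples(edges[j][0]))) for j in pick])",
    "    pi = float(np.sum(2*xi*(n-xi))) / (n*(n-1))",
    "    vals.append((pi - S/a1)/math.sqrt(e1*S + e2*S*(S-1)))",
    paste0("json.dump(vals, open(sys.argv[1], 'w'))")
  ), script)
  status <- system2("python", c(script, out_json), stdout = FALSE, stderr = FALSE)
  skip_if(status != 0, "msprime unavailable")
  ref <- unlist(jsonlite::read_json(out_json))
  mine <- simulate_neutral(20, 20, 1500, seed = 41)$D
  ks <- suppressWarnings(stats::ks.test(mine, ref))
  expect_gt(ks$p.value, 0.01)
})
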