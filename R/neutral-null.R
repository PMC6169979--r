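#' Neutral coalescent nulls and the DHEW compound test
#'
#' The null model is the standard Kingman coalescent with no
#' recombination, conditioned on the observed number of segregating
#' sites: a genealogy is drawn (exponential coalescence times with rate
#' choose(k, 2)), then exactly S mutations are placed on branches with
#' probability proportional to branch length. The root state is
#' ancestral, so every simulated site is polarized. Each replicate
#' yields the (D, H_norm, F_ew) statistic vector computed with the same
#' code paths as the observed data.
#'
#' @name neutral_null
NULL

# Draw one Kingman genealogy. Returns per-edge descendant tip sets and
# edge lengths. Optionally forces a partial sweep: a fraction f of the
# tips coalesces into a single ancestor at time tau (star-like recent
# coalescence), with the neutral coalescent running above it.
sim_coalescent_tree <- function(n, sweep_f = 0, sweep_tau = 0) {
  n_nodes <- 2L * n # generous upper bound (sweep node adds one)
  desc <- vector("list", n_nodes)
  node_time <- numeric(n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  edge_desc <- vector("list", n_nodes)
  edge_len <- numeric(n_nodes)
  n_edges <- 0L
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0

  add_edge <- function(child, parent_time) {
    n_edges <<- n_edges + 1L
    edge_desc[[n_edges]] <<- desc[[child]]
    edge_len[n_edges] <<- parent_time - node_time[child]
  }

  if (sweep_f > 0 && n >= 2L) {
    m <- max(2L, min(n, round(sweep_f * n)))
    swept <- sample.int(n, m)
    t <- sweep_tau
    for (ch in swept) add_edge(ch, t)
    desc[[nxt]] <- sort(swept)
    node_time[nxt] <- t
    active <- c(setdiff(active, swept), nxt)
    nxt <- nxt + 1L
  }

  k <- length(active)
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    c1 <- active[pair[1L]]
    c2 <- active[pair[2L]]
    add_edge(c1, t)
    add_edge(c2, t)
    desc[[nxt]] <- c(desc[[c1]], desc[[c2]])
    node_time[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  list(
    edge_desc = edge_desc[seq_len(n_edges)],
    edge_len = edge_len[seq_len(n_edges)],
    total_len = sum(edge_len[seq_len(n_edges)]),
    tmrca = t,
    n = n
  )
}

# Place S mutations on a genealogy (probability proportional to branch
# length); returns the derived tip set of each mutation.
place_mutations <- function(tree, S) {
  if (S == 0L) return(list())
  e <- sample.int(length(tree$edge_len), S, replace = TRUE, prob = tree$edge_len)
  tree$edge_desc[e]
}

# (D, H_norm, F_ew) of one simulated replicate from the derived sets.
sim_stat_vector <- function(n, derived_sets) {
  i_vec <- lengths(derived_sets)
  S <- length(i_vec)
  if (S == 0L) return(list(D = NA_real_, H_norm = NA_real_, F_ew = 1))
  pi <- sum(2 * i_vec * (n - i_vec)) / (n * (n - 1))
  mem <- matrix(FALSE, n, S)
  for (j in seq_len(S)) mem[derived_sets[[j]], j] <- TRUE
  keys <- do.call(paste0, lapply(seq_len(S), function(j) as.integer(mem[, j])))
  p <- as.numeric(table(keys)) / n
  list(
    D = tajima_d_value(n, S, pi),
    H_norm = fay_wu_h_value(n, i_vec),
    F_ew = sum(p^2)
  )
}

#' Simulate the neutral null distribution of (D, H, EW)
#'
#' Fixed-S conditioning: every replicate carries exactly `S_cond`
#' mutations. Alternatively, supply `theta` (and `S_cond = NULL`) for
#' an unconditioned run where each replicate draws a Poisson number of
#' mutations with mean `theta / 2` times the total tree length.
#'
#' @param n sample size (>= 2).
#' @param S_cond segregating-site count to condition on (>= 1), or
#'   `NULL` when `theta` is given.
#' @param reps number of replicates.
#' @param seed integer seed; draws are deterministic given the seed.
#' @param theta optional population mutation rate for the
#'   unconditioned variant.
#' @return an object of class `"null_distribution"`: vectors `D`, `H`,
#'   `F` of length `reps`, the realized `S` per replicate, and the
#'   conditioning metadata.
#' @export
simulate_neutral <- function(n, S_cond, reps, seed, theta = NULL) {
  stopifnot(n >= 2, reps >= 1)
  if (is.null(theta)) stopifnot(S_cond >= 1)
  D <- H <- F_ew <- S_out <- numeric(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      tree <- sim_coalescent_tree(n)
      S <- if (is.null(theta)) S_cond else stats::rpois(1L, theta / 2 * tree$total_len)
      sets <- place_mutations(tree, S)
      sv <- sim_stat_vector(n, sets)
      D[r] <- sv$D
      H[r] <- sv$H_norm
      F_ew[r] <- sv$F_ew
      S_out[r] <- S
    }
  })
  structure(
    list(n = n, S_cond = if (is.null(theta)) S_cond else NA_integer_,
         theta = theta, reps = reps, seed = seed,
         D = D, H = H, F = F_ew, S = S_out),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> n=%d %s reps=%d seed=%d\n", x$n,
    if (is.na(x$S_cond)) sprintf("theta=%.3g", x$theta) else sprintf("S=%d", x$S_cond),
    x$reps, x$seed
  ))
  invisible(x)
}

# Per-(n, S, reps, seed) cache so a null is simulated once per run.
.null_cache <- new.env(parent = emptyenv())

#' Fetch (and cache) a conditioned null distribution
#'
#' @inheritParams simulate_neutral
#' @return a `"null_distribution"`, computed once per (n, S, reps, seed).
#' @export
get_null_distribution <- function(n, S_cond, reps = 10000L, seed = 1L) {
  key <- paste(n, S_cond, reps, seed, sep = "_")
  if (is.null(.null_cache[[key]])) {
    .null_cache[[key]] <- simulate_neutral(n, S_cond, reps, seed)
  }
  .null_cache[[key]]
}

#' Empirical one-sided p-value against a simulated null
#'
#' Monte-Carlo p with pseudocount: `(1 + #draws at least as extreme) /
#' (reps + 1)`, so p is never 0. Sweep signals are extreme in the lower
#' tail for D and H (very negative) and in the upper tail for EW
#' homozygosity (very high).
#'
#' @param obs observed statistic.
#' @param null_draws numeric vector of null draws.
#' @param tail `"lower"` or `"upper"`.
#' @return p-value in (0, 1].
#' @export
pvalue_from_null <- function(obs, null_draws, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  null_draws <- null_draws[!is.na(null_draws)]
  if (length(null_draws) == 0L) stop("empty null distribution")
  if (is.na(obs)) return(NA_real_)
  extreme <- if (tail == "lower") sum(null_draws <= obs) else sum(null_draws >= obs)
  (1 + extreme) / (length(null_draws) + 1)
}

#' Component p-values of an observed statistic vector
#'
#' @param obs a [stat_vector()]-style list with `D`, `H_norm`, `F_ew`.
#' @param null a `"null_distribution"`.
#' @return list `p_D`, `p_H`, `p_EW`.
#' @export
null_pvalues <- function(obs, null) {
  list(
    p_D = pvalue_from_null(obs$D, null$D, "lower"),
    p_H = pvalue_from_null(obs$H_norm, null$H, "lower"),
    p_EW = pvalue_from_null(obs$F_ew, null$F, "upper")
  )
}

# Each replicate's own component p-values against the leave-one-out
# null, via ranks: #(other draws at least as extreme) + 1 == rank in
# the extreme direction, so p_j = rank_j / reps.
null_internal_pvalues <- function(null) {
  reps <- null$reps
  list(
    p_D = rank(null$D, ties.method = "max") / reps,
    p_H = rank(null$H, ties.method = "max") / reps,
    p_EW = rank(-null$F, ties.method = "max") / reps
  )
}

# Joint-exceedance statistic of a p-vector against the null's own
# p-vectors: the (pseudocounted) fraction of replicates whose
# (p_D, p_H, p_EW) is component-wise <= the given vector. Small T =
# jointly extreme. Not uniform under the null (the components are
# dependent), hence the second calibration step in dhew_compound().
joint_exceedance <- function(p_D, p_H, p_EW, npv, reps) {
  (1 + sum(npv$p_D <= p_D & npv$p_H <= p_H & npv$p_EW <= p_EW)) / (reps + 1)
}

# T for every null replicate, memoized per (n, S, reps, seed) cell
# since the O(reps^2) sweep is obs-independent.
null_joint_T <- function(null) {
  key <- paste("T", null$n, null$S_cond, null$reps, null$seed, sep = "_")
  cached <- .null_cache[[key]]
  if (!is.null(cached)) return(cached)
  npv <- null_internal_pvalues(null)
  reps <- null$reps
  Tn <- vapply(seq_len(reps), function(j) {
    joint_exceedance(npv$p_D[j], npv$p_H[j], npv$p_EW[j], npv, reps)
  }, numeric(1))
  .null_cache[[key]] <- Tn
  Tn
}

#' DHEW compound p-value
#'
#' Combines the three component p-values into a joint test in two
#' calibration steps. First, the observed (p_D, p_H, p_EW) vector is
#' reduced to the joint-exceedance statistic T: the fraction of null
#' replicates whose own p-vector (computed against the leave-one-out
#' null) is component-wise less than or equal to the observed one.
#' Because the three components are dependent, T is not uniform under
#' neutrality, so in the second step T is calibrated against its own
#' null distribution: the compound p is the (pseudocounted) fraction of
#' null replicates whose T is at most the observed T. Small compound p
#' means the triple is jointly more extreme than neutral replicates.
#'
#' @param obs a [stat_vector()]-style list with `D`, `H_norm`, `F_ew`.
#' @param null a `"null_distribution"`.
#' @return compound p-value in (0, 1], `NA` if any component is undefined.
#' @export
dhew_compound <- function(obs, null) {
  pv <- null_pvalues(obs, null)
  if (anyNA(unlist(pv))) return(NA_real_)
  npv <- null_internal_pvalues(null)
  T_obs <- joint_exceedance(pv$p_D, pv$p_H, pv$p_EW, npv, null$reps)
  Tn <- null_joint_T(null)
  (1 + sum(Tn <= T_obs)) / (null$reps + 1)
}
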