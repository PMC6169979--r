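#' Focal-versus-matched-control comparison framework
#'
#' The inference layer that separates locus-specific selection from
#' regional effects: every focal gene is paired with nearby control
#' genes of similar coding length, its statistic is contrasted with the
#' control median ("comparison score"), scores are tested at the group
#' level, ranked across pairings, and compared to a permutation null in
#' which control genes take the focal role. Explicit criteria then call
#' candidate sweeps and adaptive protein divergence per gene.
#'
#' @name focal_control
NULL

# Orientation of "extreme" per statistic: sweeps drive D and H very
# negative and DoS/EW comparison scores very positive.
STAT_ORIENTATION <- c(
  TajD = "low", nFWH = "low", EW = "high", DoS = "high", theta_w = "low"
)

#' Validate candidate control genes for a focal gene
#'
#' Controls must have a coding length within `ratio_range` times the
#' focal CDS length and a start coordinate within `max_distance` of the
#' focal start. Focal genes retaining fewer than `min_controls`
#' candidates are rejected from downstream analysis.
#'
#' @param focal list or one-row data frame with `gene_id`, `cds_length`,
#'   `start`.
#' @param candidates data frame with columns `gene_id`, `cds_length`,
#'   `start`.
#' @param ratio_range allowed control/focal CDS-length ratio
#'   (default `c(0.5, 2)`).
#' @param max_distance maximum |control start - focal start| in bp
#'   (default 60000).
#' @param min_controls minimum surviving controls (default 3).
#' @return a `"gene_pairing"` list (`focal_id`, `control_ids`,
#'   `focal_cds_length`, `control_cds_lengths`, `distances`), or `NULL`
#'   when the focal gene is rejected.
#' @export
validate_controls <- function(focal, candidates,
                              ratio_range = c(0.5, 2),
                              max_distance = 60000,
                              min_controls = 3L) {
  ratio <- candidates$cds_length / focal$cds_length
  dist <- abs(candidates$start - focal$start)
  keep <- ratio >= ratio_range[1L] & ratio <= ratio_range[2L] & dist <= max_distance
  if (sum(keep) < min_controls) return(NULL)
  structure(
    list(
      focal_id = focal$gene_id,
      control_ids = candidates$gene_id[keep],
      focal_cds_length = focal$cds_length,
      control_cds_lengths = candidates$cds_length[keep],
      distances = dist[keep]
    ),
    class = "gene_pairing"
  )
}

#' Comparison score of a focal gene against its controls
#'
#' Focal value minus the median of the defined control values (even
#' counts use the mean of the two central values).
#'
#' @param focal_value statistic value of the focal gene.
#' @param control_values statistic values of its controls.
#' @return the score, or `NA` when no control value is defined.
#' @export
comparison_score <- function(focal_value, control_values) {
  cv <- control_values[!is.na(control_values)]
  if (length(cv) == 0L || is.na(focal_value)) return(NA_real_)
  focal_value - stats::median(cv)
}

#' Group-level test of comparison scores
#'
#' Tests whether the mean of the comparison scores differs from 0 with
#' a one-sample two-sided t-test (mean + 95% CI) and a one-sample
#' Wilcoxon signed-rank test (pseudomedian + 95% CI). Significance is
#' read as the confidence interval excluding 0.
#'
#' @param scores numeric comparison scores (NA dropped).
#' @return list with `n`, `mean`, `ci_t`, `p_t`, `pseudomedian`,
#'   `ci_w`, `p_w`, `significant_t`, `significant_w`; the t components
#'   are `NA` when the scores are all identical.
#' @export
group_test <- function(scores) {
  x <- scores[!is.na(scores)]
  if (length(x) < 2L) stop("group_test requires >= 2 defined scores")
  degenerate <- stats::sd(x) == 0
  if (degenerate) {
    tt <- list(estimate = mean(x), conf.int = c(NA_real_, NA_real_), p.value = NA_real_)
  } else {
    tt <- stats::t.test(x, mu = 0)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, conf.int = TRUE, exact = FALSE))
  list(
    n = length(x),
    mean = unname(tt$estimate),
    ci_t = unname(tt$conf.int[1:2]),
    p_t = tt$p.value,
    pseudomedian = unname(wt$estimate),
    ci_w = unname(wt$conf.int[1:2]),
    p_w = wt$p.value,
    significant_t = !degenerate && (tt$conf.int[1] > 0 || tt$conf.int[2] < 0),
    significant_w = (wt$conf.int[1] > 0 || wt$conf.int[2] < 0),
    degenerate = degenerate
  )
}

# Map raw values onto the "extreme is large" axis for a statistic.
orient <- function(x, orientation) {
  if (orientation == "low") -x else x
}

#' Rank comparison scores across focal genes
#'
#' Scores are ranked by extremeness in the statistic's configured
#' orientation (`"low"`: most negative is most extreme, as for Tajima's
#' D and H; `"high"`: most positive, as for DoS). Dense ranking: the
#' most extreme score has rank 1 and tied scores share the smaller
#' rank. The percentile places the most extreme score at 100, so "top
#' 10%" means percentile >= 90. Genes with undefined scores are
#' excluded from the distribution rather than imputed.
#'
#' @param scores named numeric vector (names = gene ids).
#' @param orientation `"high"` or `"low"`.
#' @return data frame with `gene_id`, `score`, `rank`, `percentile`.
#' @export
rank_scores <- function(scores, orientation = c("high", "low")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(scores)
  x <- orient(scores[ok], orientation)
  N <- length(x)
  if (N == 0L) stop("rank_scores requires >= 1 defined score")
  pos <- match(-x, sort(unique(-x))) # dense rank, 1 = most extreme
  data.frame(
    gene_id = names(scores)[ok],
    score = unname(scores[ok]),
    rank = pos,
    percentile = 100 * (N - pos + 1) / N,
    row.names = NULL
  )
}

#' Percentile of true comparison scores against a permutation null
#'
#' Builds a pooled null of pseudo-scores by letting control genes act
#' as "focal": in the default `"enumerate"` mode every control of every
#' pairing takes a turn, scored against the remaining controls of its
#' pairing (a pairing with c controls contributes c pseudo-scores, so
#' 68 pairings of 3-4 controls pool roughly 245 values). In
#' `"montecarlo"` mode, `n_perm` replicates each draw one control per
#' pairing uniformly at random. Each true score is then placed within
#' the pooled null: the percentile is the percentage of pseudo-scores
#' that are no more extreme (orientation-aware), so 100 means the true
#' score exceeds the entire null.
#'
#' @param true_scores named numeric vector of true comparison scores.
#' @param pairing_values list (one element per pairing) of lists with
#'   `focal_id` and `control_values` (numeric).
#' @param orientation `"high"` or `"low"` (see [rank_scores()]).
#' @param mode `"enumerate"` or `"montecarlo"`.
#' @param n_perm Monte-Carlo replicates (montecarlo mode).
#' @param seed seed for the montecarlo mode.
#' @return data frame with `gene_id`, `score`, `null_percentile`, and
#'   the pooled null size as attribute `"null_size"`.
#' @export
rank_against_null <- function(true_scores, pairing_values,
                              orientation = c("high", "low"),
                              mode = c("enumerate", "montecarlo"),
                              n_perm = 100L, seed = 1L) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  pseudo_of <- function(cv, i) {
    rest <- cv[-i]
    rest <- rest[!is.na(rest)]
    if (length(rest) < 2L || is.na(cv[i])) return(NA_real_)
    cv[i] - stats::median(rest)
  }
  pool <- if (mode == "enumerate") {
    unlist(lapply(pairing_values, function(p) {
      cv <- p$control_values
      vapply(seq_along(cv), function(i) pseudo_of(cv, i), numeric(1))
    }))
  } else {
    with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(r) {
        vapply(pairing_values, function(p) {
          i <- sample.int(length(p$control_values), 1L)
          pseudo_of(p$control_values, i)
        }, numeric(1))
      }))
    })
  }
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0L) stop("empty permutation null")
  op <- orient(pool, orientation)
  ok <- !is.na(true_scores)
  os <- orient(true_scores[ok], orientation)
  res <- data.frame(
    gene_id = names(true_scores)[ok],
    score = unname(true_scores[ok]),
    null_percentile = vapply(os, function(s) 100 * mean(op <= s), numeric(1)),
    row.names = NULL
  )
  attr(res, "null_size") <- length(pool)
  res
}

#' Call candidate selective sweeps
#'
#' A gene is called a sweep candidate when all three criteria hold:
#' (1) the DHEW compound p-value is significant; (2) the corrected
#' p-values of at least two of the D, H, EW component tests are
#' significant; (3) at least one of the D, H, or DoS comparison scores
#' lies in the top `rank_top` percent of the rank distribution AND the
#' top `null_top` percent of the rank-against-null distribution. A gene
#' with any required component missing is not callable (`NA`), which is
#' distinct from a negative call.
#'
#' @param genes data frame with columns `gene_id`, `p_dhew`,
#'   `p_D_corrected`, `p_H_corrected`, `p_EW_corrected`, and per
#'   statistic `s` in D/H/DoS the percentiles `pct_<s>` and
#'   `nullpct_<s>` (missing statistics may be NA).
#' @param alpha significance threshold (default 0.05).
#' @param rank_top,null_top rank cutoffs in percent (defaults 10 and 5).
#' @return named logical vector (NA = not callable).
#' @export
call_sweeps <- function(genes, alpha = 0.05, rank_top = 10, null_top = 5) {
  out <- logical(nrow(genes))
  out[] <- NA
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    comp <- c(g$p_D_corrected, g$p_H_corrected, g$p_EW_corrected)
    if (is.na(g$p_dhew) || all(is.na(comp))) next
    c1 <- g$p_dhew < alpha
    c2 <- sum(comp < alpha, na.rm = TRUE) >= 2L
    c3 <- FALSE
    any_rank <- FALSE
    for (s in c("D", "H", "DoS")) {
      pr <- g[[paste0("pct_", s)]]
      pn <- g[[paste0("nullpct_", s)]]
      if (is.null(pr) || is.null(pn) || is.na(pr) || is.na(pn)) next
      any_rank <- TRUE
      if (pr >= 100 - rank_top && pn >= 100 - null_top) c3 <- TRUE
    }
    if (!any_rank) next
    out[i] <- c1 && c2 && c3
  }
  stats::setNames(out, genes$gene_id)
}

#' Call adaptive protein divergence per gene
#'
#' A gene is called when its corrected MK Fisher p-value is below
#' `alpha` and its DoS coefficient is positive. Genes with an undefined
#' DoS (or missing corrected p) are not callable (`NA`).
#'
#' @param mk data frame with columns `gene_id`, `FET_corrected`, `DoS`.
#' @param alpha significance threshold (default 0.05).
#' @return named logical vector (NA = not callable).
#' @export
call_adaptive_divergence <- function(mk, alpha = 0.05) {
  out <- ifelse(
    is.na(mk$FET_corrected) | is.na(mk$DoS),
    NA,
    mk$FET_corrected < alpha & mk$DoS > 0
  )
  stats::setNames(out, mk$gene_id)
}
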