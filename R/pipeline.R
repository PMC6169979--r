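#' Full-screen orchestration
#'
#' Runs the whole screen end to end on a study bundle: missing-data
#' filtering, subsampling to a standard number of lines, per-gene SFS
#' and haplotype statistics, coalescent-null p-values and the DHEW
#' compound test for focal genes, lineage-polarized MK tables with DoS,
#' the focal-versus-control comparison framework, and the sweep /
#' adaptive-divergence calls.
#'
#' @name pipeline_cli
NULL

#' Run configuration
#'
#' @param n_target number of in-group lines to subsample each gene to
#'   (149 for the large-sample species mode, 14 for the small).
#' @param max_missing per-sequence missing-data threshold.
#' @param reps coalescent-null replicates per (n, S) cell.
#' @param alpha significance threshold for all calls.
#' @param rank_top,null_top rank cutoffs in percent for the sweep call.
#' @param perm_mode permutation mode for [rank_against_null()].
#' @param n_perm Monte-Carlo permutation replicates.
#' @param compute_pvalues,compute_mk stage switches; disabling skips
#'   the coalescent-null or MK stage (their outputs become NA).
#' @param seed master seed, expanded into per-stage, per-gene seeds.
#' @return a `"run_config"` list.
#' @export
run_config <- function(n_target = 149L, max_missing = 0.10, reps = 10000L,
                       alpha = 0.05, rank_top = 10, null_top = 5,
                       perm_mode = c("enumerate", "montecarlo"), n_perm = 100L,
                       compute_pvalues = TRUE, compute_mk = TRUE,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, rank_top > 0, rank_top < 100,
            null_top > 0, null_top < 100)
  structure(
    list(
      n_target = n_target, max_missing = max_missing, reps = reps,
      alpha = alpha, rank_top = rank_top, null_top = null_top,
      perm_mode = match.arg(perm_mode), n_perm = n_perm,
      compute_pvalues = compute_pvalues, compute_mk = compute_mk,
      seed = seed
    ),
    class = "run_config"
  )
}

# Filter, subsample and summarize one gene; returns the summary row
# used by every later stage.
process_gene <- function(aln, config) {
  aln <- filter_missing(aln, config$max_missing)
  k <- min(config$n_target, n_samples(aln))
  aln <- subsample_lines(aln, k, derive_seed(config$seed, 10L, sum(utf8ToInt(aln$gene_id))))
  summ <- polymorphism_summary(aln)
  sv <- stat_vector(summ)
  list(aln = aln, summary = summ, stats = sv)
}

#' Run the full screen on a study bundle
#'
#' @param bundle a bundle list from [generate_study_bundle()] /
#'   [read_study_bundle()], or a directory path containing one.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, Table-1/2/3-style
#'   TSVs, a JSON file of all calls, and a run log (every seed and
#'   threshold) are written there.
#' @return list with `gene_stats`, `group_summary`, `sweep_table`,
#'   `divergence_table`, `calls`.
#' @export
run_full_screen <- function(bundle, config = run_config(), out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_study_bundle(bundle)
  pairings <- bundle$pairings
  focal_ids <- unique(pairings$focal_id)
  gene_ids <- unique(c(pairings$focal_id, pairings$control_id))

  processed <- list()
  for (id in gene_ids) {
    processed[[id]] <- tryCatch(
      process_gene(bundle$alignments[[id]], config),
      error = function(e) {
        stop("stage 'stats' failed for gene ", id, ": ", conditionMessage(e))
      }
    )
  }

  gene_stats <- do.call(rbind, lapply(gene_ids, function(id) {
    s <- processed[[id]]$summary
    sv <- processed[[id]]$stats
    data.frame(
      gene_id = id, n = s$n, S = s$S, theta_w = s$theta_w, pi = s$pi,
      TajD = sv$D, nFWH = sv$H_norm, EW = sv$F_ew
    )
  }))

  # Coalescent-null p-values + DHEW for focal genes, BH per statistic.
  pv <- data.frame(
    gene_id = focal_ids, p_D = NA_real_, p_H = NA_real_, p_EW = NA_real_,
    p_dhew = NA_real_
  )
  if (config$compute_pvalues) {
    for (i in seq_along(focal_ids)) {
      s <- processed[[focal_ids[i]]]$summary
      if (s$S < 1L) next
      null <- get_null_distribution(s$n, s$S, config$reps,
                                    derive_seed(config$seed, 20L))
      obs <- processed[[focal_ids[i]]]$stats
      p <- null_pvalues(obs, null)
      pv$p_D[i] <- p$p_D
      pv$p_H[i] <- p$p_H
      pv$p_EW[i] <- p$p_EW
      pv$p_dhew[i] <- dhew_compound(obs, null)
    }
  }
  pv$p_D_corrected <- bh_correct(pv$p_D)
  pv$p_H_corrected <- bh_correct(pv$p_H)
  pv$p_EW_corrected <- bh_correct(pv$p_EW)
  pv$p_dhew_corrected <- bh_correct(pv$p_dhew)

  # MK + DoS for every gene (controls feed the DoS comparison scores);
  # BH across the focal set only.
  mk <- data.frame(
    gene_id = gene_ids, Pn = NA_integer_, Ps = NA_integer_, Dn = NA_integer_,
    Ds = NA_integer_, MKcodons = NA_integer_, FETpval = NA_real_,
    FET_corrected = NA_real_, DoS = NA_real_
  )
  if (config$compute_mk) {
    for (i in seq_along(gene_ids)) {
      aln <- processed[[gene_ids[i]]]$aln
      if (is.null(aln$sister) || length(aln$outgroups) == 0L) next
      tab <- classify_codon_changes(aln)
      mk$Pn[i] <- tab$Pn; mk$Ps[i] <- tab$Ps
      mk$Dn[i] <- tab$Dn; mk$Ds[i] <- tab$Ds
      mk$MKcodons[i] <- tab$MKcodons
      mk$FETpval[i] <- mk_test(tab)
      mk$DoS[i] <- dos(tab)
    }
    focal_rows <- mk$gene_id %in% focal_ids
    mk$FET_corrected[focal_rows] <- bh_correct(mk$FETpval[focal_rows])
  }

  # Comparison framework over the five reported statistics.
  value_of <- function(id, stat) {
    if (stat == "DoS") mk$DoS[mk$gene_id == id] else gene_stats[[stat]][gene_stats$gene_id == id]
  }
  stats_used <- c("theta_w", "TajD", "nFWH", "EW", "DoS")
  scores <- list()
  pairing_values <- list()
  for (stat in stats_used) {
    sc <- numeric(0)
    pval_list <- list()
    for (fid in focal_ids) {
      cids <- pairings$control_id[pairings$focal_id == fid]
      cv <- vapply(cids, value_of, numeric(1), stat = stat)
      sc[fid] <- comparison_score(value_of(fid, stat), cv)
      pval_list[[fid]] <- list(focal_id = fid, control_values = cv)
    }
    scores[[stat]] <- sc
    pairing_values[[stat]] <- pval_list
  }

  group_summary <- do.call(rbind, lapply(stats_used, function(stat) {
    sc <- scores[[stat]]
    if (sum(!is.na(sc)) < 2L) {
      return(data.frame(
        statistic = stat, n = sum(!is.na(sc)), mean = NA, ci_t_lo = NA,
        ci_t_hi = NA, p_t = NA, pseudomedian = NA, ci_w_lo = NA,
        ci_w_hi = NA, p_w = NA
      ))
    }
    g <- group_test(sc)
    data.frame(
      statistic = stat, n = g$n, mean = g$mean, ci_t_lo = g$ci_t[1],
      ci_t_hi = g$ci_t[2], p_t = g$p_t, pseudomedian = g$pseudomedian,
      ci_w_lo = g$ci_w[1], ci_w_hi = g$ci_w[2], p_w = g$p_w
    )
  }))

  # Ranks and rank-against-null for the three calling statistics.
  rank_stats <- c(D = "TajD", H = "nFWH", DoS = "DoS")
  rk <- list()
  for (s in names(rank_stats)) {
    stat <- rank_stats[[s]]
    orientation <- unname(STAT_ORIENTATION[stat])
    sc <- scores[[stat]]
    if (all(is.na(sc))) {
      rk[[s]] <- NULL
      next
    }
    r1 <- rank_scores(sc, orientation)
    r2 <- rank_against_null(sc, pairing_values[[stat]],
                            orientation = orientation,
                            mode = config$perm_mode, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 30L))
    m <- merge(r1, r2[, c("gene_id", "null_percentile")], by = "gene_id")
    rk[[s]] <- m
  }

  sweep_table <- pv
  for (s in names(rank_stats)) {
    m <- rk[[s]]
    if (is.null(m)) {
      sweep_table[[paste0("pct_", s)]] <- NA_real_
      sweep_table[[paste0("nullpct_", s)]] <- NA_real_
    } else {
      idx <- match(sweep_table$gene_id, m$gene_id)
      sweep_table[[paste0("score_", s)]] <- m$score[idx]
      sweep_table[[paste0("pct_", s)]] <- m$percentile[idx]
      sweep_table[[paste0("nullpct_", s)]] <- m$null_percentile[idx]
    }
  }
  sweep_calls <- call_sweeps(sweep_table, alpha = config$alpha,
                             rank_top = config$rank_top,
                             null_top = config$null_top)
  sweep_table$candidate_sweep <- unname(sweep_calls)

  divergence_table <- mk[mk$gene_id %in% focal_ids, ]
  div_calls <- call_adaptive_divergence(divergence_table, alpha = config$alpha)
  divergence_table$adaptive_divergence <- unname(div_calls)

  result <- list(
    gene_stats = gene_stats,
    group_summary = group_summary,
    sweep_table = sweep_table,
    divergence_table = divergence_table,
    calls = list(
      candidate_sweep = sweep_calls,
      adaptive_divergence = div_calls
    )
  )
  if (!is.null(out_dir)) write_screen_results(result, config, out_dir)
  result
}

# Table-1/2/3-style TSVs, machine-readable calls, and a log recording
# every seed and threshold of the run.
write_screen_results <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$gene_stats, "gene_stats.tsv")
  wt(result$group_summary, "group_summary.tsv")
  wt(result$sweep_table, "sweep_table.tsv")
  wt(result$divergence_table, "divergence_table.tsv")
  jsonlite::write_json(
    lapply(result$calls, function(x) as.list(x)),
    file.path(out_dir, "calls.json"),
    auto_unbox = TRUE, null = "null", na = "null"
  )
  log_lines <- c(
    "dhewscan run log",
    paste0("seed: ", config$seed),
    paste0("n_target: ", config$n_target),
    paste0("max_missing: ", config$max_missing),
    paste0("reps: ", config$reps),
    paste0("alpha: ", config$alpha),
    paste0("rank_top: ", config$rank_top),
    paste0("null_top: ", config$null_top),
    paste0("perm_mode: ", config$perm_mode),
    paste0("n_perm: ", config$n_perm)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
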