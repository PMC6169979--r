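#' Synthetic study bundles
#'
#' Generates complete, self-contained study data sets emulating a
#' population-genomic screen: per-gene in-frame coding alignments for a
#' large in-group sample (default 149 haploid lines) with a small
#' sister-species sample (default 14 lines) and a single outgroup
#' sequence, organized into focal/control pairings on a synthetic
#' chromosome, with optional planted selective sweeps and planted
#' adaptive amino-acid divergence. Every generator is deterministic
#' given its seed, and a truth table records the planted signals so
#' recovery can be tested without re-deriving them from the data.
#'
#' @name synthetic_data
NULL

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

#' Simulation configuration
#'
#' Defaults describe the emulated study design: 149 in-group lines
#' (14 for the small-sample species mode), 14 sister lines, 68 focal
#' genes with 3-4 matched controls each, coding lengths 0.3-3 kb,
#' per-gene theta between 2 and 12 (per-gene scale), 30% of focal genes
#' carrying a planted sweep in which 90% of lineages are forced to
#' coalesce at time 0.005, outgroup divergence 10 and sister divergence
#' 5 coalescent time units, and a 0.1% per-base missing rate. The
#' missing rate is deliberately small: downstream statistics use
#' complete-case columns, so with ~150 lines the fraction of usable
#' columns is about `(1 - missing_rate)^n_lines`, and a rate of 0.001
#' retains ~86% of sites (and ~64% of codons for the MK stage).
#'
#' @param n_lines in-group haploid sample size.
#' @param n_sister sister-species sample size.
#' @param n_focal number of focal genes.
#' @param controls_per_focal candidate control counts (sampled per focal).
#' @param cds_length_range CDS length range in nt (rounded to codons).
#' @param theta_range per-gene theta range (uniform).
#' @param sweep_fraction fraction of focal genes with a planted sweep.
#' @param sweep_f fraction of lineages captured by the sweep.
#' @param sweep_tau time of the forced coalescence (coalescent units).
#' @param divergence_time outgroup divergence (coalescent units).
#' @param sister_divergence sister-species divergence (coalescent units).
#' @param alpha_adaptive fraction of non-synonymous substitutions
#'   planted as adaptive in divergence genes.
#' @param missing_rate per-base probability of an N in in-group lines.
#' @param seed master seed.
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(n_lines = 149L, n_sister = 14L, n_focal = 68L,
                       controls_per_focal = 3:4,
                       cds_length_range = c(300L, 3000L),
                       theta_range = c(2, 12),
                       sweep_fraction = 0.3, sweep_f = 0.9, sweep_tau = 0.005,
                       divergence_time = 10, sister_divergence = 5,
                       alpha_adaptive = 0, missing_rate = 0.001,
                       seed = 1L) {
  stopifnot(
    n_lines >= 2, sweep_fraction >= 0, sweep_fraction <= 1,
    sweep_f >= 0, sweep_f <= 1, alpha_adaptive >= 0, alpha_adaptive < 1,
    missing_rate >= 0, missing_rate <= 1
  )
  structure(
    list(
      n_lines = n_lines, n_sister = n_sister, n_focal = n_focal,
      controls_per_focal = controls_per_focal,
      cds_length_range = cds_length_range, theta_range = theta_range,
      sweep_fraction = sweep_fraction, sweep_f = sweep_f, sweep_tau = sweep_tau,
      divergence_time = divergence_time, sister_divergence = sister_divergence,
      alpha_adaptive = alpha_adaptive, missing_rate = missing_rate,
      seed = seed
    ),
    class = "sim_config"
  )
}

# Random in-frame backbone of sense codons, as a character vector.
gene_backbone <- function(L) {
  stopifnot(L %% 3L == 0L)
  unlist(strsplit(sample(SENSE_CODONS, L / 3L, replace = TRUE), "", fixed = TRUE),
         use.names = FALSE)
}

# Apply k substitutions at distinct random positions of a sequence.
mutate_lineage <- function(seq, k) {
  L <- length(seq)
  k <- min(k, L)
  if (k == 0L) return(seq)
  pos <- sample.int(L, k)
  for (p in pos) {
    seq[p] <- sample(setdiff(DNA_BASES, seq[p]), 1L)
  }
  seq
}

# Core nucleotide-level gene simulator shared by the neutral and sweep
# generators: coalescent genealogy, Poisson(theta/2 * branch length)
# mutations on a random in-frame backbone, outgroup and sister lineages
# diverged from the in-group ancestor, Ns injected at missing_rate.
sim_gene_alignment <- function(gene_id, n, L, theta, seed,
                               sweep_f = 0, sweep_tau = 0,
                               divergence_time = 10, sister_divergence = 5,
                               n_sister = 0L, sister_theta = theta,
                               missing_rate = 0) {
  with_seed(seed, {
    backbone <- gene_backbone(L) # ancestral sequence at the species split
    tree <- sim_coalescent_tree(n, sweep_f, sweep_tau)
    M <- min(stats::rpois(1L, theta / 2 * tree$total_len), L)
    # in-group stem: substitutions fixed along the focal lineage
    focal_root <- mutate_lineage(backbone, stats::rpois(1L, theta / 2 * sister_divergence))
    mat <- matrix(focal_root, n, L, byrow = TRUE)
    if (M > 0L) {
      pos <- sample.int(L, M)
      sets <- place_mutations(tree, M)
      for (j in seq_len(M)) {
        der <- sample(setdiff(DNA_BASES, focal_root[pos[j]]), 1L)
        mat[sets[[j]], pos[j]] <- der
      }
    }
    outgroup <- mutate_lineage(backbone, stats::rpois(1L, theta / 2 * divergence_time))
    sister <- NULL
    if (n_sister > 0L) {
      sb <- mutate_lineage(backbone, stats::rpois(1L, theta / 2 * sister_divergence))
      smat <- matrix(sb, n_sister, L, byrow = TRUE)
      if (n_sister >= 2L) {
        stree <- sim_coalescent_tree(n_sister)
        Ms <- min(stats::rpois(1L, sister_theta / 2 * stree$total_len), L)
        if (Ms > 0L) {
          spos <- sample.int(L, Ms)
          ssets <- place_mutations(stree, Ms)
          for (j in seq_len(Ms)) {
            der <- sample(setdiff(DNA_BASES, sb[spos[j]]), 1L)
            smat[ssets[[j]], spos[j]] <- der
          }
        }
      }
      sister <- smat
      rownames(sister) <- paste0(gene_id, "_sis", seq_len(n_sister))
    }
    if (missing_rate > 0) {
      k <- stats::rbinom(1L, n * L, missing_rate)
      if (k > 0L) mat[sample.int(n * L, k)] <- "N"
    }
    aln <- alignment(
      gene_id = gene_id, seqs = mat,
      sample_ids = paste0(gene_id, "_l", seq_len(n)),
      outgroups = list(out = outgroup), normalize = FALSE
    )
    aln$sister <- sister
    aln
  })
}

#' Generate one neutral gene alignment
#'
#' Standard neutral coalescent gene: no sweep, mutation rate theta/2
#' per unit branch length, outgroup and sister lineages attached.
#'
#' @param config a [sim_config()].
#' @param gene_seed integer seed for this gene.
#' @param L,theta optional overrides; by default drawn from the config
#'   ranges (deterministically from `gene_seed`).
#' @return an [alignment()] with outgroup (and sister when configured).
#' @export
generate_neutral_gene <- function(config, gene_seed, L = NULL, theta = NULL) {
  draws <- gene_draws(config, gene_seed, L, theta)
  sim_gene_alignment(
    gene_id = paste0("gene", gene_seed), n = config$n_lines,
    L = draws$L, theta = draws$theta, seed = gene_seed,
    divergence_time = config$divergence_time,
    sister_divergence = config$sister_divergence,
    n_sister = config$n_sister, missing_rate = config$missing_rate
  )
}

#' Generate one swept gene alignment
#'
#' As [generate_neutral_gene()], but a fraction `sweep_f` of the
#' sampled lineages is forced to coalesce into a single ancestor at
#' time `sweep_tau` (star-like recent coalescence), the genealogical
#' footprint of a recent hard sweep: excess rare variants, excess
#' high-frequency derived alleles and elevated haplotype homozygosity.
#'
#' @inheritParams generate_neutral_gene
#' @return an [alignment()] with outgroup (and sister when configured).
#' @export
generate_sweep_gene <- function(config, gene_seed, L = NULL, theta = NULL) {
  # sweep_f = 0 degenerates to the neutral model by construction
  draws <- gene_draws(config, gene_seed, L, theta)
  sim_gene_alignment(
    gene_id = paste0("gene", gene_seed), n = config$n_lines,
    L = draws$L, theta = draws$theta, seed = gene_seed,
    sweep_f = config$sweep_f, sweep_tau = config$sweep_tau,
    divergence_time = config$divergence_time,
    sister_divergence = config$sister_divergence,
    n_sister = config$n_sister, missing_rate = config$missing_rate
  )
}

gene_draws <- function(config, gene_seed, L, theta) {
  with_seed(derive_seed(gene_seed, 99L), {
    list(
      L = L %||% (3L * sample(
        (config$cds_length_range[1L] %/% 3L):(config$cds_length_range[2L] %/% 3L), 1L
      )),
      theta = theta %||% stats::runif(1L, config$theta_range[1L], config$theta_range[2L])
    )
  })
}

# Enumerate the single-base changes of a sense codon by class.
codon_changes <- function(codon) {
  out <- list(syn = list(), nonsyn = list())
  aa0 <- codon_aa(codon)
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, codon[p])) {
      cod <- codon
      cod[p] <- b
      aa <- codon_aa(cod)
      if (aa == "*") next
      cls <- if (aa == aa0) "syn" else "nonsyn"
      out[[cls]] <- c(out[[cls]], list(list(pos = p, base = b)))
    }
  }
  out
}

#' Generate a three-way codon alignment with planted divergence
#'
#' Codon-aware generator for McDonald-Kreitman recovery tests. Starting
#' from a random sense-codon backbone at the focal/sister/outgroup
#' ancestor, it plants Poisson numbers of synonymous and non-synonymous
#' events: fixed substitutions on the focal, sister and outgroup
#' lineages (non-synonymous at a purifying-reduced rate), focal-species
#' polymorphism with derived counts drawn from the neutral frequency
#' spectrum (P(i) proportional to 1/i), and - controlled by
#' `alpha_adaptive` - extra adaptive non-synonymous substitutions on
#' the focal lineage. Each codon receives at most one event and no stop
#' codons are created, so the planted counts equal the classifier's
#' counts exactly; they are recorded in the `truth` attribute.
#'
#' @param config a [sim_config()] (uses `n_lines`, `n_sister`,
#'   `alpha_adaptive`).
#' @param gene_seed integer seed for this gene.
#' @param L CDS length in nt (default drawn from the config range).
#' @param rates per-codon event rates: `syn_poly`, `nonsyn_poly`,
#'   `syn_div`, `nonsyn_div`, and the outgroup-branch factor
#'   `out_factor`.
#' @return an [alignment()] with `$sister` and an outgroup; attribute
#'   `"truth"` holds the planted `Pn`, `Ps`, `Dn`, `Ds`,
#'   `Dn_adaptive` counts.
#' @export
generate_divergence_gene <- function(config, gene_seed, L = NULL,
                                     rates = list(
                                       syn_poly = 0.12, nonsyn_poly = 0.03,
                                       syn_div = 0.05, nonsyn_div = 0.0125,
                                       out_factor = 3
                                     )) {
  L <- gene_draws(config, gene_seed, L, theta = 0)$L
  n <- config$n_lines
  with_seed(gene_seed, {
    C <- L %/% 3L
    codons <- sample(SENSE_CODONS, C, replace = TRUE)
    codon_mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
    used <- logical(C)
    focal_seq <- sister_seq <- out_seq <- as.vector(t(codon_mat))

    # Pick an unused codon admitting a change of the requested class;
    # returns NULL when none is left (the event is then dropped).
    place_event <- function(kind) {
      avail <- which(!used)
      if (length(avail) == 0L) return(NULL)
      for (ci in avail[sample.int(length(avail))]) {
        ch <- codon_changes(codon_mat[ci, ])[[kind]]
        if (length(ch) == 0L) next
        pick <- ch[[sample.int(length(ch), 1L)]]
        used[ci] <<- TRUE
        return(list(codon = ci, pos = 3L * (ci - 1L) + pick$pos, base = pick$base))
      }
      NULL
    }

    alpha <- config$alpha_adaptive
    n_events <- c(
      Ps = stats::rpois(1L, rates$syn_poly * C),
      Pn = stats::rpois(1L, rates$nonsyn_poly * C),
      Ds = stats::rpois(1L, rates$syn_div * C),
      Dn = stats::rpois(1L, rates$nonsyn_div * C),
      Dn_adaptive = if (alpha > 0) {
        stats::rpois(1L, alpha / (1 - alpha) * rates$nonsyn_div * C)
      } else 0L,
      Ds_sis = stats::rpois(1L, rates$syn_div * C),
      Dn_sis = stats::rpois(1L, rates$nonsyn_div * C),
      Ds_out = stats::rpois(1L, rates$out_factor * rates$syn_div * C),
      Dn_out = stats::rpois(1L, rates$out_factor * rates$nonsyn_div * C)
    )
    truth <- c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L, Dn_adaptive = 0L)
    poly_events <- list()
    apply_fixed <- function(target, kind) {
      ev <- place_event(kind)
      if (is.null(ev)) return(FALSE)
      if (target == "focal") focal_seq[ev$pos] <<- ev$base
      if (target == "sister") sister_seq[ev$pos] <<- ev$base
      if (target == "out") out_seq[ev$pos] <<- ev$base
      TRUE
    }
    for (i in seq_len(n_events["Ds"])) if (apply_fixed("focal", "syn")) truth["Ds"] <- truth["Ds"] + 1L
    for (i in seq_len(n_events["Dn"])) if (apply_fixed("focal", "nonsyn")) truth["Dn"] <- truth["Dn"] + 1L
    for (i in seq_len(n_events["Dn_adaptive"])) {
      if (apply_fixed("focal", "nonsyn")) {
        truth["Dn"] <- truth["Dn"] + 1L
        truth["Dn_adaptive"] <- truth["Dn_adaptive"] + 1L
      }
    }
    for (i in seq_len(n_events["Ds_sis"])) apply_fixed("sister", "syn")
    for (i in seq_len(n_events["Dn_sis"])) apply_fixed("sister", "nonsyn")
    for (i in seq_len(n_events["Ds_out"])) apply_fixed("out", "syn")
    for (i in seq_len(n_events["Dn_out"])) apply_fixed("out", "nonsyn")
    for (kind in c("syn", "nonsyn")) {
      k <- if (kind == "syn") n_events["Ps"] else n_events["Pn"]
      for (i in seq_len(k)) {
        ev <- place_event(kind)
        if (is.null(ev)) next
        d <- sample.int(n - 1L, 1L, prob = 1 / seq_len(n - 1L))
        poly_events <- c(poly_events, list(c(ev, list(count = d))))
        if (kind == "syn") truth["Ps"] <- truth["Ps"] + 1L else truth["Pn"] <- truth["Pn"] + 1L
      }
    }
    mat <- matrix(focal_seq, n, L, byrow = TRUE)
    for (ev in poly_events) {
      mat[sample.int(n, ev$count), ev$pos] <- ev$base
    }
    aln <- alignment(
      gene_id = paste0("div", gene_seed), seqs = mat,
      sample_ids = paste0("div", gene_seed, "_l", seq_len(n)),
      outgroups = list(out = out_seq), normalize = FALSE
    )
    aln$sister <- matrix(sister_seq, max(1L, config$n_sister), L, byrow = TRUE)
    rownames(aln$sister) <- paste0("div", gene_seed, "_sis", seq_len(nrow(aln$sister)))
    attr(aln, "truth") <- truth
    aln
  })
}

#' Generate a full synthetic study bundle
#'
#' Builds `n_focal` focal genes (a `sweep_fraction` of them swept) with
#' 3-4 matched neutral controls each. Controls share their focal gene's
#' theta, have coding lengths within 0.5-2x the focal length, and sit
#' within +/-60 kb of the focal start on a synthetic chromosome, so
#' every pairing passes [validate_controls()] by construction. Returns
#' the bundle in memory; when `dir` is given it is also written out as
#' one FASTA per gene plus `pairings.tsv`, `truth.tsv` and
#' `config.yaml`, byte-identical for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list with `alignments` (named list), `pairings` (data
#'   frame: focal_id, control_id, cds_length, start, chrom), `truth`
#'   (data frame of planted signals) and `config`.
#' @export
generate_study_bundle <- function(config, dir = NULL) {
  n_focal <- config$n_focal
  n_sweep <- round(config$sweep_fraction * n_focal)
  swept <- with_seed(derive_seed(config$seed, 1L), sample.int(n_focal, n_sweep))
  alignments <- list()
  pairings <- list()
  truth <- list()
  for (i in seq_len(n_focal)) {
    pseed <- derive_seed(config$seed, 2L, i)
    setup <- with_seed(pseed, {
      cmin <- config$cds_length_range[1L]
      cmax <- config$cds_length_range[2L]
      Lf <- 3L * sample((cmin %/% 3L):(cmax %/% 3L), 1L)
      nc <- sample(config$controls_per_focal, 1L)
      Lc <- 3L * round(stats::runif(nc, pmax(0.5 * Lf, cmin), pmin(2 * Lf, cmax)) / 3)
      list(
        Lf = Lf, nc = nc, Lc = pmin(Lc, 3L * (cmax %/% 3L)),
        theta = stats::runif(1L, config$theta_range[1L], config$theta_range[2L]),
        offsets = sample(c(-1L, 1L), nc, replace = TRUE) * sample.int(60000L, nc)
      )
    })
    focal_id <- sprintf("FOC%03d", i)
    focal_start <- (i - 1L) * 200000L + 70000L
    gen <- if (i %in% swept) generate_sweep_gene else generate_neutral_gene
    aln <- gen(config, derive_seed(config$seed, 3L, i),
               L = setup$Lf, theta = setup$theta)
    aln$gene_id <- focal_id
    alignments[[focal_id]] <- aln
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = focal_id, role = "focal", pairing = i,
      swept = i %in% swept, theta = setup$theta, cds_length = setup$Lf,
      start = focal_start
    )
    for (j in seq_len(setup$nc)) {
      ctl_id <- sprintf("CTL%03d_%d", i, j)
      caln <- generate_neutral_gene(config, derive_seed(config$seed, 4L, i, j),
                                    L = setup$Lc[j], theta = setup$theta)
      caln$gene_id <- ctl_id
      alignments[[ctl_id]] <- caln
      pairings[[length(pairings) + 1L]] <- data.frame(
        focal_id = focal_id, control_id = ctl_id,
        focal_cds_length = setup$Lf, control_cds_length = setup$Lc[j],
        focal_start = focal_start, control_start = focal_start + setup$offsets[j],
        chrom = "chrSim"
      )
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = ctl_id, role = "control", pairing = i,
        swept = FALSE, theta = setup$theta, cds_length = setup$Lc[j],
        start = focal_start + setup$offsets[j]
      )
    }
  }
  bundle <- list(
    alignments = alignments,
    pairings = do.call(rbind, pairings),
    truth = do.call(rbind, truth),
    config = config
  )
  if (!is.null(dir)) write_study_bundle(bundle, dir)
  bundle
}

#' Write a study bundle to disk
#'
#' @param bundle result of [generate_study_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in bundle$alignments) {
    write_fasta_alignment(aln, file.path(dir, paste0(aln$gene_id, ".fasta")))
  }
  utils::write.table(bundle$pairings, file.path(dir, "pairings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(bundle$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' @param dir directory written by [write_study_bundle()].
#' @return a bundle list as from [generate_study_bundle()].
#' @export
read_study_bundle <- function(dir) {
  pairings <- utils::read.delim(file.path(dir, "pairings.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) utils::read.delim(truth_path) else NULL
  ids <- unique(c(pairings$focal_id, pairings$control_id))
  alignments <- lapply(ids, function(id) {
    read_fasta_alignment(file.path(dir, paste0(id, ".fasta")), gene_id = id)
  })
  names(alignments) <- ids
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  list(alignments = alignments, pairings = pairings, truth = truth, config = config)
}
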