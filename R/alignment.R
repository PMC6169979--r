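#' In-frame per-gene haplotype alignment
#'
#' The central container of the package: an equal-length alignment of
#' in-group haplotype sequences for one gene, with optional aligned
#' outgroup sequences attached. Sequences are stored internally as a
#' character matrix (rows = samples, columns = alignment positions) over
#' the alphabet `A, C, G, T, N, -`; `N` and `-` are treated as missing
#' data throughout, never as alleles.
#'
#' @param gene_id gene identifier.
#' @param seqs character matrix (samples x positions) or character vector
#'   of equal-length sequence strings.
#' @param sample_ids sample identifiers, one per sequence.
#' @param outgroups named list of aligned outgroup sequences (character
#'   vectors or strings of the same alignment length).
#' @param normalize uppercase bases and map unknown characters to `N`
#'   (default). Internal callers constructing sequences from the clean
#'   alphabet may switch this off.
#' @return an object of class `"alignment"` with fields `gene_id`,
#'   `sample_ids`, `seqs` (character matrix), `outgroups` (named list of
#'   character vectors), `in_frame` (length divisible by 3) and
#'   `excluded_cols` (logical; columns flagged as unusable for
#'   statistics, set by [filter_missing()]).
#' @export
alignment <- function(gene_id, seqs, sample_ids = NULL, outgroups = list(),
                      normalize = TRUE) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      stop("alignment error: sequences have unequal lengths for gene ", gene_id)
    }
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (!is.matrix(seqs)) stop("seqs must be a character matrix or vector")
  if (nrow(seqs) == 0L) stop("input error: alignment has no sequences")
  if (normalize) seqs <- normalize_bases(seqs)
  if (is.null(sample_ids)) sample_ids <- rownames(seqs) %||% paste0("s", seq_len(nrow(seqs)))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  # rownames force a full matrix copy; skip them on the fast path
  if (normalize) rownames(seqs) <- sample_ids
  outgroups <- lapply(outgroups, function(s) {
    if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "", fixed = TRUE)[[1]]
    if (normalize) s <- normalize_bases(matrix(s, nrow = 1L))[1L, ]
    if (length(s) != ncol(seqs)) {
      stop("alignment error: outgroup length differs from alignment length")
    }
    s
  })
  structure(
    list(
      gene_id = gene_id,
      sample_ids = sample_ids,
      seqs = seqs,
      outgroups = outgroups,
      in_frame = ncol(seqs) %% 3L == 0L,
      excluded_cols = NULL
    ),
    class = "alignment"
  )
}

# Uppercase and map every character outside {A,C,G,T,-} to N.
normalize_bases <- function(mat) {
  up <- toupper(mat)
  up[!(up %in% c(DNA_BASES, "-"))] <- "N"
  dim(up) <- dim(mat)
  dimnames(up) <- dimnames(mat)
  up
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment> %s: %d samples x %d bp%s, %d outgroup(s)%s\n",
    x$gene_id, nrow(x$seqs), ncol(x$seqs),
    if (x$in_frame) " (in frame)" else "",
    length(x$outgroups),
    if (!is.null(x$excluded_cols)) sprintf(", %d excluded column(s)", sum(x$excluded_cols)) else ""
  ))
  invisible(x)
}

#' @export
dim.alignment <- function(x) dim(x$seqs)

#' Number of in-group samples
#' @param aln an [alignment()].
#' @return integer sample count.
#' @export
n_samples <- function(aln) nrow(aln$seqs)

#' Read a per-gene FASTA alignment
#'
#' Reads an equal-length multi-FASTA into an [alignment()]. Records
#' whose names start with `outgroup_prefix` are attached as outgroups
#' (name = text after the prefix); records starting with
#' `sister_prefix` are returned separately for three-way
#' (focal/sister/outgroup) codon analyses. Bases are uppercased and any
#' character outside `A,C,G,T,-` becomes `N`. CRLF line endings and
#' wrapped lines are tolerated.
#'
#' @param path path to a FASTA file.
#' @param gene_id gene identifier; default the file name without extension.
#' @param outgroup_prefix,sister_prefix record-name prefixes marking
#'   outgroup / sister-species records.
#' @return an [alignment()]; if sister records are present it carries a
#'   `sister` attribute-like field `$sister` (character matrix).
#' @export
read_fasta_alignment <- function(path, gene_id = NULL,
                                 outgroup_prefix = "outgroup|",
                                 sister_prefix = "sister|") {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("input error: cannot read FASTA ", path, ": ", conditionMessage(e))
  )
  if (length(recs) == 0L) stop("input error: empty FASTA file: ", path)
  if (length(unique(Biostrings::width(recs))) > 1L) {
    stop("alignment error: records in ", path, " have unequal lengths")
  }
  nms <- sub("\\s.*$", "", names(recs))
  seqs <- as.character(recs)
  is_out <- startsWith(nms, outgroup_prefix)
  is_sis <- startsWith(nms, sister_prefix)
  ing <- which(!is_out & !is_sis)
  if (length(ing) == 0L) stop("input error: no in-group records in ", path)
  outs <- as.list(seqs[is_out])
  names(outs) <- substring(nms[is_out], nchar(outgroup_prefix) + 1L)
  aln <- alignment(
    gene_id = gene_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path)),
    seqs = seqs[ing], sample_ids = nms[ing], outgroups = outs
  )
  if (any(is_sis)) {
    sis <- do.call(rbind, strsplit(seqs[is_sis], "", fixed = TRUE))
    rownames(sis) <- substring(nms[is_sis], nchar(sister_prefix) + 1L)
    aln$sister <- normalize_bases(sis)
  }
  aln
}

#' Write an alignment (with outgroups and sister records) back to FASTA
#'
#' @param aln an [alignment()].
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta_alignment <- function(aln, path, width = 70L) {
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  nms <- aln$sample_ids
  if (!is.null(aln$sister)) {
    seqs <- c(seqs, apply(aln$sister, 1L, paste, collapse = ""))
    nms <- c(nms, paste0("sister|", rownames(aln$sister)))
  }
  if (length(aln$outgroups)) {
    seqs <- c(seqs, vapply(aln$outgroups, paste, "", collapse = ""))
    nms <- c(nms, paste0("outgroup|", names(aln$outgroups)))
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- nms
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Filter sequences by missing data and flag unusable columns
#'
#' Removes every in-group sequence whose fraction of `N` bases exceeds
#' `max_missing`, then flags all columns in which any retained in-group
#' sequence still has an `N` or a gap. Flagged columns are excluded from
#' every downstream statistic (segregating sites, pi, theta, H,
#' haplotype construction), which keeps the effective sample size
#' constant across sites.
#'
#' @param aln an [alignment()].
#' @param max_missing maximum tolerated fraction of `N` per sequence
#'   (default 0.10).
#' @return the filtered alignment with `excluded_cols` set.
#' @export
filter_missing <- function(aln, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  bad <- aln$seqs == "N" | aln$seqs == "-"
  keep <- rowMeans(aln$seqs == "N") <= max_missing
  if (!any(keep)) stop("empty-alignment error: all sequences exceed the missing-data threshold")
  if (!all(keep)) {
    aln$seqs <- aln$seqs[keep, , drop = FALSE]
    aln$sample_ids <- aln$sample_ids[keep]
    bad <- bad[keep, , drop = FALSE]
  }
  aln$excluded_cols <- colSums(bad) > 0L
  aln
}

#' Subsample in-group lines uniformly without replacement
#'
#' Standardizes the number of lines surveyed per gene (e.g. to 149 or 14)
#' by a seeded uniform subsample. Input order of the retained samples is
#' preserved; outgroups and sister records are untouched.
#'
#' @param aln an [alignment()].
#' @param k number of lines to retain.
#' @param seed integer seed; the subsample is deterministic given the seed.
#' @return the subsampled alignment.
#' @export
subsample_lines <- function(aln, k, seed) {
  n <- n_samples(aln)
  if (k > n) stop("size error: cannot subsample ", k, " from ", n, " lines")
  if (k == n) return(aln)
  idx <- with_seed(seed, sort(sample.int(n, k)))
  aln$seqs <- aln$seqs[idx, , drop = FALSE]
  aln$sample_ids <- aln$sample_ids[idx]
  if (!is.null(aln$excluded_cols)) {
    aln$excluded_cols <- colSums(aln$seqs == "N" | aln$seqs == "-") > 0L
  }
  aln
}

# Columns unusable for statistics: any N or gap among in-group samples.
# Falls back to on-the-fly computation when filter_missing was not run.
excluded_columns <- function(aln) {
  aln$excluded_cols %||% (colSums(aln$seqs == "N" | aln$seqs == "-") > 0L)
}
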