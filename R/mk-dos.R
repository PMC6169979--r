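#' Lineage-polarized McDonald-Kreitman test and Direction of Selection
#'
#' Contrasts non-synonymous/synonymous polymorphism within a focal
#' species (Pn, Ps) with non-synonymous/synonymous fixed differences
#' assigned to the focal lineage (Dn, Ds) by strict-parsimony
#' polarization against an outgroup. An excess of Dn relative to the
#' polymorphism ratio indicates recurrent adaptive protein evolution;
#' the Direction of Selection coefficient summarizes the contrast as
#' `DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps)`.
#'
#' @name mk_dos
NULL

# Translate a codon written as a 3-character vector; "*" = stop.
codon_aa <- function(codon) {
  key <- paste(codon, collapse = "")
  aa <- Biostrings::GENETIC_CODE[[key]]
  if (is.null(aa)) NA_character_ else aa
}

#' Assign a fixed inter-species difference to a lineage
#'
#' Both species are monomorphic and differ at the site. Under strict
#' parsimony the lineage carrying the allele that differs from the
#' outgroup base is the one on which the substitution occurred; if the
#' outgroup matches neither allele the substitution cannot be assigned.
#'
#' @param focal_base,sister_base the fixed base in each species.
#' @param outgroup_base the aligned outgroup base.
#' @return `"focal"`, `"sister"`, or `"unassigned"`.
#' @export
assign_lineage_fixed_differences <- function(focal_base, sister_base, outgroup_base) {
  if (identical(outgroup_base, sister_base)) return("focal")
  if (identical(outgroup_base, focal_base)) return("sister")
  "unassigned"
}

#' Classify codon changes for the MK table
#'
#' Walks the in-frame alignment codon by codon. Codons containing
#' missing data, more than one variable or divergent nucleotide
#' position, a multiallelic position, or a fixed difference that cannot
#' be polarized are excluded entirely and do not count toward
#' `MKcodons`. In a fully analyzable codon, a position segregating in
#' the focal species is classified synonymous/non-synonymous in its
#' codon context (Ps/Pn), and a fixed difference assigned to the focal
#' lineage is classified against the ancestral codon (Ds/Dn).
#' Stop-codon-creating variants are never counted. Substitutions
#' assigned to the sister lineage and polymorphism private to the
#' sister species leave the focal table untouched.
#'
#' @param focal an [alignment()] of the focal species (in frame), or a
#'   character matrix.
#' @param sister character matrix (or single sequence) of sister-species
#'   samples; defaults to `focal$sister`.
#' @param outgroup aligned outgroup sequence (character vector or
#'   string); defaults to the first attached outgroup.
#' @param gene_id gene label for the output row.
#' @return an object of class `"mk_table"`: `gene_id`, `Pn`, `Ps`,
#'   `Dn`, `Ds`, `MKcodons`.
#' @export
classify_codon_changes <- function(focal, sister = NULL, outgroup = NULL,
                                   gene_id = NULL) {
  if (inherits(focal, "alignment")) {
    gene_id <- gene_id %||% focal$gene_id
    sister <- sister %||% focal$sister
    if (is.null(outgroup) && length(focal$outgroups)) outgroup <- focal$outgroups[[1L]]
    fmat <- focal$seqs
  } else {
    fmat <- focal
  }
  if (is.null(sister) || is.null(outgroup)) {
    stop("classify_codon_changes needs sister sequences and an outgroup")
  }
  if (is.character(sister) && is.null(dim(sister))) {
    sister <- do.call(rbind, strsplit(sister, "", fixed = TRUE))
  }
  if (length(outgroup) == 1L && nchar(outgroup) > 1L) {
    outgroup <- strsplit(outgroup, "", fixed = TRUE)[[1L]]
  }
  L <- ncol(fmat)
  if (L %% 3L != 0L) stop("frame violation: alignment length not divisible by 3")
  stopifnot(ncol(sister) == L, length(outgroup) == L)

  ok <- function(m) m %in% DNA_BASES
  bad_f <- matrix(!ok(fmat), nrow(fmat), L)
  bad_s <- matrix(!ok(sister), nrow(sister), L)
  col_bad <- colSums(bad_f) > 0L | colSums(bad_s) > 0L | !ok(outgroup)
  f1 <- fmat[1L, ]
  s1 <- sister[1L, ]
  var_f <- colSums(fmat != matrix(f1, nrow(fmat), L, byrow = TRUE)) > 0L
  var_s <- colSums(sister != matrix(s1, nrow(sister), L, byrow = TRUE)) > 0L
  fixed_diff <- !var_f & !var_s & (f1 != s1)
  event <- (var_f | var_s | fixed_diff) & !col_bad

  Pn <- Ps <- Dn <- Ds <- MKcodons <- 0L
  for (c0 in seq_len(L / 3L)) {
    pos <- (3L * c0 - 2L):(3L * c0)
    if (any(col_bad[pos])) next
    ev <- pos[event[pos]]
    if (length(ev) > 1L) next
    if (length(ev) == 0L) {
      MKcodons <- MKcodons + 1L
      next
    }
    p <- ev
    off <- p - (3L * c0 - 3L) # 1..3 within codon
    if (var_f[p]) {
      alleles <- unique(fmat[, p])
      if (length(alleles) != 2L) next # multiallelic: exclude codon
      base_codon <- f1[pos]
      cod1 <- cod2 <- base_codon
      cod1[off] <- alleles[1L]
      cod2[off] <- alleles[2L]
      aa1 <- codon_aa(cod1)
      aa2 <- codon_aa(cod2)
      MKcodons <- MKcodons + 1L
      if (aa1 == "*" || aa2 == "*") next # nonsense variant: not counted
      if (aa1 == aa2) Ps <- Ps + 1L else Pn <- Pn + 1L
    } else if (var_s[p]) {
      MKcodons <- MKcodons + 1L # sister-private polymorphism: no focal count
    } else {
      lin <- assign_lineage_fixed_differences(f1[p], s1[p], outgroup[p])
      if (lin == "unassigned") next # not fully analyzable
      MKcodons <- MKcodons + 1L
      if (lin == "focal") {
        anc <- f1[pos]
        anc[off] <- s1[p]
        aa_anc <- codon_aa(anc)
        aa_der <- codon_aa(f1[pos])
        if (aa_anc == "*" || aa_der == "*") next
        if (aa_anc == aa_der) Ds <- Ds + 1L else Dn <- Dn + 1L
      }
    }
  }
  mk_table(gene_id %||% "gene", Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds, MKcodons = MKcodons)
}

#' Construct an MK table row
#'
#' @param gene_id gene label.
#' @param Pn,Ps focal-species non-synonymous / synonymous polymorphism counts.
#' @param Dn,Ds non-synonymous / synonymous fixed differences on the
#'   focal lineage.
#' @param MKcodons number of fully analyzable codons.
#' @return an object of class `"mk_table"`.
#' @export
mk_table <- function(gene_id, Pn, Ps, Dn, Ds, MKcodons = NA_integer_) {
  stopifnot(Pn >= 0, Ps >= 0, Dn >= 0, Ds >= 0)
  structure(
    list(gene_id = gene_id, Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds, MKcodons = MKcodons),
    class = "mk_table"
  )
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf(
    "<mk_table> %s: Pn=%d Ps=%d Dn=%d Ds=%d MKcodons=%s\n",
    x$gene_id, x$Pn, x$Ps, x$Dn, x$Ds, as.character(x$MKcodons)
  ))
  invisible(x)
}

#' McDonald-Kreitman Fisher's exact test
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[Dn, Ds], [Pn, Ps]]`. Undefined (`NA`) when either the divergence
#' or the polymorphism margin is zero.
#'
#' @param table an [mk_table()].
#' @return two-sided p-value, or `NA`.
#' @export
mk_test <- function(table) {
  if ((table$Dn + table$Ds) == 0 || (table$Pn + table$Ps) == 0) return(NA_real_)
  m <- matrix(c(table$Dn, table$Ds, table$Pn, table$Ps), nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Direction of Selection coefficient
#'
#' `DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps)`. Positive values indicate adaptive
#' protein divergence; negative values indicate segregating
#' (slightly) deleterious amino-acid variants. Undefined (`NA`) when
#' either margin is zero.
#'
#' @param table an [mk_table()].
#' @return the DoS coefficient, or `NA`.
#' @export
dos <- function(table) {
  if ((table$Dn + table$Ds) == 0 || (table$Pn + table$Ps) == 0) return(NA_real_)
  table$Dn / (table$Dn + table$Ds) - table$Pn / (table$Pn + table$Ps)
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1),
#' applied per statistic across the focal gene set. `NA` p-values stay
#' `NA` and do not affect the other adjustments.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_correct <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Write MK results to TSV
#'
#' @param tables list of [mk_table()] rows.
#' @param path output TSV path.
#' @return the data frame written, invisibly.
#' @export
write_mk_tsv <- function(tables, path) {
  p <- vapply(tables, mk_test, numeric(1))
  df <- data.frame(
    gene_id = vapply(tables, `[[`, "", "gene_id"),
    Pn = vapply(tables, `[[`, 0L, "Pn"),
    Dn = vapply(tables, `[[`, 0L, "Dn"),
    Ps = vapply(tables, `[[`, 0L, "Ps"),
    Ds = vapply(tables, `[[`, 0L, "Ds"),
    MKcodons = vapply(tables, `[[`, NA_integer_, "MKcodons"),
    FETpval = p,
    FET_corrected = bh_correct(p),
    DoS = vapply(tables, dos, numeric(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
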