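#' Extract the longest-isoform CDS of a gene from a genome and GFF3
#'
#' Concatenates the CDS segments of the isoform with the longest total
#' coding length, in transcription order, reverse-complementing
#' minus-strand genes. Ties between isoforms of equal CDS length are
#' broken by the lexicographically smallest transcript ID so the choice
#' is deterministic.
#'
#' @param genome a `DNAStringSet` or path to a genome FASTA.
#' @param annotation a `GRanges` (as returned by
#'   `rtracklayer::import`) or path to a GFF3 file with `mRNA` and `CDS`
#'   features linked by `Parent` attributes.
#' @param gene_id the gene `ID` to extract.
#' @return a single uppercase character string; attribute
#'   `"frame_warning"` is `TRUE` when the CDS length is not divisible
#'   by 3.
#' @export
extract_cds <- function(genome, annotation, gene_id) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  gff <- if (is.character(annotation)) rtracklayer::import(annotation, format = "gff3") else annotation
  type <- as.character(gff$type)
  parents <- gff$Parent
  has_parent <- function(i, id) id %in% parents[[i]]

  mrna_idx <- which(type %in% c("mRNA", "transcript") &
    vapply(seq_along(gff), has_parent, logical(1), id = gene_id))
  if (length(mrna_idx) == 0L) stop("lookup error: gene not found in annotation: ", gene_id)
  mrna_ids <- gff$ID[mrna_idx]

  cds_for <- function(tx_id) {
    idx <- which(type == "CDS" & vapply(seq_along(gff), has_parent, logical(1), id = tx_id))
    gff[idx]
  }
  cds_sets <- lapply(mrna_ids, cds_for)
  total <- vapply(cds_sets, function(g) sum(GenomicRanges::width(g)), numeric(1))
  if (all(total == 0)) stop("lookup error: no CDS features for gene ", gene_id)
  ord <- order(-total, mrna_ids)
  cds <- cds_sets[[ord[1L]]]

  cds <- cds[order(GenomicRanges::start(cds))]
  chrom <- as.character(GenomicRanges::seqnames(cds))[1L]
  if (!chrom %in% names(genome)) stop("lookup error: sequence ", chrom, " absent from genome")
  pieces <- vapply(seq_along(cds), function(i) {
    as.character(Biostrings::subseq(
      genome[[chrom]],
      start = GenomicRanges::start(cds)[i], end = GenomicRanges::end(cds)[i]
    ))
  }, character(1))
  seq <- paste(pieces, collapse = "")
  if (as.character(GenomicRanges::strand(cds))[1L] == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  seq <- toupper(seq)
  frame_warning <- nchar(seq) %% 3L != 0L
  if (frame_warning) {
    warning("frame warning: CDS length of ", gene_id, " is not divisible by 3")
  }
  attr(seq, "frame_warning") <- frame_warning
  seq
}
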