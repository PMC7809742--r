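#' Extract cleavage positions from alignments
#'
#' The cleavage base of a PAS read is the alignment's 3'-most reference base
#' on the read's strand: the rightmost aligned base for \code{+} alignments,
#' the leftmost for \code{-}. Identical positions are aggregated into one
#' polyA site with a summed read count.
#'
#' @param alignments A \code{GRanges} of aligned read bodies (as from
#'   \code{\link{map_reads}}), or a BED file path (6 columns, as exported by
#'   genome browsers), or a coordinate-sorted BAM path (requires Rsamtools;
#'   unmapped/secondary/supplementary records are skipped).
#' @param total Total counted reads used for TPM; defaults to the number of
#'   alignments ingested.
#' @return A data.frame of class \code{pas_sites}: \code{chrom}, \code{pos}
#'   (0-based cleavage base), \code{strand}, \code{count}, \code{tpm}.
#' @export
extract_sites <- function(alignments, total = NULL) {
  if (is.character(alignments) && length(alignments) == 1L) {
    if (grepl("\\.bed$", alignments)) {
      alignments <- rtracklayer::import(alignments)
    } else if (grepl("\\.bam$", alignments)) {
      if (!requireNamespace("Rsamtools", quietly = TRUE)) {
        stop("BAM input requires the Rsamtools package")
      }
      fl <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
      b <- Rsamtools::scanBam(alignments, param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "qwidth", "strand"), flag = fl))[[1]]
      alignments <- GenomicRanges::GRanges(
        seqnames = b$rname,
        ranges = IRanges::IRanges(start = b$pos, width = b$qwidth),
        strand = b$strand)
    } else {
      stop("unrecognised alignment input: ", alignments)
    }
  }
  stopifnot(methods::is(alignments, "GRanges"))
  if (length(alignments) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0))
    return(compute_tpm(structure(out, class = c("pas_sites", "data.frame")),
                       total = 1))
  }
  str <- as.character(GenomicRanges::strand(alignments))
  if (any(str == "*")) stop("alignments must carry strand")
  pos0 <- ifelse(str == "+",
                 GenomicRanges::end(alignments) - 1L,
                 GenomicRanges::start(alignments) - 1L)
  key <- paste(as.character(GenomicRanges::seqnames(alignments)), pos0, str)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3], count = as.integer(agg$Freq),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$strand, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("pas_sites", "data.frame")
  compute_tpm(out, total = if (is.null(total)) length(alignments) else total)
}

#' Fill tags-per-million (TPM) values for a site table
#'
#' TPM of a site = count * 1e6 / total, where total is the number of counted
#' reads in the sample, so TPM sums to 1e6 over a complete site table.
#'
#' @param sites A \code{pas_sites} data.frame with a \code{count} column.
#' @param total Total counted reads (> 0); defaults to \code{sum(count)}.
#' @return The input with its \code{tpm} column (re)computed, order preserved.
#' @export
compute_tpm <- function(sites, total = sum(sites$count)) {
  if (is.na(total) || total <= 0) {
    if (nrow(sites) == 0L) { sites$tpm <- numeric(0); return(sites) }
    stop("total must be > 0")
  }
  sites$tpm <- sites$count * 1e6 / total
  sites
}

#' Per-gene RPKM and the cumulative-expression table
#'
#' RPKM = count * 1e9 / (length_nt * total reads).
#'
#' @param counts Named (by gene) vector of per-gene read counts.
#' @param lengths Gene lengths in nt (> 0), aligned with \code{counts}.
#' @param total Total mapped reads in the sample.
#' @return A list with \code{rpkm} (data.frame gene/count/length/rpkm) and
#'   \code{cumulative} (RPKM-sorted table with the cumulative fraction of
#'   genes, for cumulative-expression plots).
#' @export
compute_rpkm <- function(counts, lengths, total) {
  stopifnot(length(counts) == length(lengths), total > 0)
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  rpkm <- counts * 1e9 / (lengths * total)
  df <- data.frame(gene = if (!is.null(names(counts))) names(counts) else
                     seq_along(counts),
                   count = as.vector(counts), length = as.vector(lengths),
                   rpkm = as.vector(rpkm), stringsAsFactors = FALSE)
  cum <- df[order(df$rpkm), ]
  cum$gene_fraction <- seq_len(nrow(cum)) / nrow(cum)
  list(rpkm = df, cumulative = cum)
}

.category_rank <- c(UTR3 = 1L, CDS = 2L, UTR5 = 3L, intron = 4L,
                    antisense = 5L, intergenic = 6L)

#' Categorize polyA sites against the annotation
#'
#' Same-strand feature overlap wins with priority UTR3 > CDS > UTR5 > intron;
#' a site overlapping a gene only on the opposite strand is antisense;
#' anything else is intergenic. Sites on chromosomes absent from the
#' annotation are intergenic (with a warning).
#'
#' @param sites A \code{pas_sites} data.frame (or any data.frame with chrom /
#'   pos / strand).
#' @param annotation A \code{\link{read_annotation}} result.
#' @param utr3_extend Extend annotated 3'UTRs this many nt downstream
#'   (strand-aware) before categorizing; 0 by default (no extension).
#' @return The input with \code{category} and \code{gene} columns added.
#' @export
categorize_sites <- function(sites, annotation, utr3_extend = 0L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  n <- nrow(sites)
  sites$category <- rep("intergenic", n)
  sites$gene <- rep(NA_character_, n)
  if (n == 0L) return(sites)
  known <- unique(annotation$genes$chrom)
  if (any(!(sites$chrom %in% known)) && length(known) > 0) {
    warning("sites on chromosomes absent from the annotation: intergenic")
  }
  fe <- annotation$features
  if (utr3_extend > 0 && nrow(fe) > 0) {
    utr3 <- fe$type == "UTR3"
    fe$end[utr3 & fe$strand == "+"] <- fe$end[utr3 & fe$strand == "+"] +
      as.integer(utr3_extend)
    fe$start[utr3 & fe$strand == "-"] <- pmax(
      0L, fe$start[utr3 & fe$strand == "-"] - as.integer(utr3_extend))
  }
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L),
                                strand = sites$strand)
  if (nrow(fe) > 0) {
    fgr <- GenomicRanges::GRanges(fe$chrom,
                                  IRanges::IRanges(fe$start + 1L, fe$end),
                                  strand = fe$strand)
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(sgr, fgr, ignore.strand = FALSE))
    if (length(ov)) {
      hits <- data.frame(site = S4Vectors::queryHits(ov),
                         rank = .category_rank[fe$type[S4Vectors::subjectHits(ov)]],
                         gene = fe$gene[S4Vectors::subjectHits(ov)],
                         stringsAsFactors = FALSE)
      hits <- hits[order(hits$site, hits$rank, hits$gene), ]
      hits <- hits[!duplicated(hits$site), ]
      sites$category[hits$site] <- names(.category_rank)[hits$rank]
      sites$gene[hits$site] <- hits$gene
    }
  }
  # opposite-strand gene-span overlap for the remaining sites
  togo <- which(sites$category == "intergenic")
  if (length(togo) && nrow(annotation$genes) > 0) {
    ggr <- GenomicRanges::GRanges(
      annotation$genes$chrom,
      IRanges::IRanges(annotation$genes$start + 1L, annotation$genes$end),
      strand = annotation$genes$strand)
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      GenomicRanges::invertStrand(sgr[togo]), ggr, ignore.strand = FALSE))
    if (length(ov)) {
      hits <- data.frame(site = togo[S4Vectors::queryHits(ov)],
                         gene = annotation$genes$gene[S4Vectors::subjectHits(ov)],
                         stringsAsFactors = FALSE)
      hits <- hits[order(hits$site, hits$gene), ]
      hits <- hits[!duplicated(hits$site), ]
      sites$category[hits$site] <- "antisense"
      sites$gene[hits$site] <- hits$gene
    }
  }
  sites
}

#' Metagene profile of cleavage positions around a gene anchor
#'
#' Sums site counts at strand-oriented offsets (positive = 3' direction)
#' within \code{flank} nt of each gene's anchor.
#'
#' @param sites A categorized or plain \code{pas_sites} data.frame.
#' @param annotation A \code{\link{read_annotation}} result.
#' @param anchor \code{"stop_codon"} (last CDS base) or \code{"tts"}.
#' @param flank Window half-width in nt.
#' @return A data.frame (\code{offset}, \code{count}) covering
#'   \code{-flank..flank}; attributes \code{argmax} (offset of the maximum)
#'   and \code{n_skipped_genes} (genes lacking the anchor).
#' @export
metagene_profile <- function(sites, annotation, anchor = c("stop_codon", "tts"),
                             flank = 1000L) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(annotation, "genome_annotation"))
  ge <- annotation$genes
  apos <- if (anchor == "stop_codon") ge$stop_pos else ge$tts
  skipped <- sum(is.na(apos))
  acc <- stats::setNames(numeric(2L * flank + 1L),
                         as.character(seq(-flank, flank)))
  for (i in which(!is.na(apos))) {
    sel <- sites$chrom == ge$chrom[i] & sites$strand == ge$strand[i]
    if (!any(sel)) next
    off <- (sites$pos[sel] - apos[i]) * if (ge$strand[i] == "+") 1L else -1L
    keep <- abs(off) <= flank
    if (!any(keep)) next
    tab <- tapply(sites$count[sel][keep], off[keep], sum)
    acc[names(tab)] <- acc[names(tab)] + tab
  }
  out <- data.frame(offset = seq(-flank, flank), count = as.numeric(acc))
  attr(out, "argmax") <- out$offset[which.max(out$count)]
  attr(out, "n_skipped_genes") <- skipped
  out
}
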