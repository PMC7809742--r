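#' Read a GFF3 gene annotation
#'
#' Imports gene models (gene / mRNA / five_prime_UTR / CDS / three_prime_UTR)
#' and converts them to the package's internal representation: 0-based
#' half-open intervals, per-gene unions across isoforms, introns derived as
#' the uncovered gaps inside each gene span, plus stop-codon and TTS
#' (transcription terminal site) anchors.
#'
#' @param path GFF3 file path.
#' @return A list of class \code{genome_annotation} with \code{features}
#'   (gene, chrom, strand, type, start, end) and \code{genes} (gene, chrom,
#'   strand, start, end, stop_pos, tts); \code{stop_pos} is the genomic
#'   0-based coordinate of the last CDS base in transcript orientation and
#'   \code{tts} the last transcribed base.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   stringsAsFactors = FALSE)
  df$ID <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  par <- gr$Parent
  df$Parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_, "")
  genes_df <- df[df$type == "gene", ]
  mrna <- df[df$type == "mRNA", ]
  tx2gene <- stats::setNames(mrna$Parent, mrna$ID)
  fe <- df[df$type %in% c("five_prime_UTR", "CDS", "three_prime_UTR"), ]
  fe$gene <- unname(tx2gene[fe$Parent])
  fe$gene[is.na(fe$gene)] <- fe$Parent[is.na(fe$gene)]  # features on genes
  .build_annotation(
    genes = data.frame(gene = genes_df$ID, chrom = genes_df$chrom,
                       strand = genes_df$strand, start = genes_df$start,
                       end = genes_df$end, stringsAsFactors = FALSE),
    feats = data.frame(gene = fe$gene, chrom = fe$chrom, strand = fe$strand,
                       type = fe$type, start = fe$start, end = fe$end,
                       stringsAsFactors = FALSE))
}

#' Convert a simulated genome to a \code{genome_annotation}
#'
#' @param sim A \code{\link{generate_genome}} result.
#' @return A \code{genome_annotation}, as from \code{\link{read_annotation}}.
#' @export
annotation_from_sim <- function(sim) {
  stopifnot(inherits(sim, "sim_genome"))
  fe <- sim$features[sim$features$type != "intron", ]
  .build_annotation(
    genes = data.frame(gene = sim$genes$gene, chrom = sim$chrom,
                       strand = sim$genes$strand, start = sim$genes$start,
                       end = sim$genes$end, stringsAsFactors = FALSE),
    feats = data.frame(gene = fe$gene, chrom = sim$chrom, strand = fe$strand,
                       type = fe$type, start = fe$start, end = fe$end,
                       stringsAsFactors = FALSE))
}

# union per gene/type, derive introns, compute anchors
.build_annotation <- function(genes, feats) {
  stopifnot(nrow(genes) == 0 || !anyNA(genes$gene))
  out_feats <- list()
  genes$stop_pos <- NA_integer_
  genes$tts <- NA_integer_
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene[i]
    fb <- feats[feats$gene == gid, ]
    covered <- IRanges::IRanges()
    for (ty in c("five_prime_UTR", "CDS", "three_prime_UTR")) {
      ir <- IRanges::reduce(IRanges::IRanges(
        start = fb$start[fb$type == ty] + 1L, end = fb$end[fb$type == ty]))
      covered <- c(covered, ir)
      if (length(ir)) {
        out_feats[[length(out_feats) + 1L]] <- data.frame(
          gene = gid, chrom = genes$chrom[i], strand = genes$strand[i],
          type = c(five_prime_UTR = "UTR5", CDS = "CDS",
                   three_prime_UTR = "UTR3")[[ty]],
          start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
          stringsAsFactors = FALSE)
      }
    }
    span <- IRanges::IRanges(genes$start[i] + 1L, genes$end[i])
    gaps <- IRanges::setdiff(span, IRanges::reduce(covered))
    if (length(gaps)) {
      out_feats[[length(out_feats) + 1L]] <- data.frame(
        gene = gid, chrom = genes$chrom[i], strand = genes$strand[i],
        type = "intron", start = IRanges::start(gaps) - 1L,
        end = IRanges::end(gaps), stringsAsFactors = FALSE)
    }
    cds <- fb[fb$type == "CDS", ]
    if (nrow(cds)) {
      genes$stop_pos[i] <- if (genes$strand[i] == "+") max(cds$end) - 1L
        else min(cds$start)
    }
    genes$tts[i] <- if (genes$strand[i] == "+") genes$end[i] - 1L
      else genes$start[i]
  }
  feats_out <- if (length(out_feats)) do.call(rbind, out_feats) else
    data.frame(gene = character(0), chrom = character(0),
               strand = character(0), type = character(0),
               start = integer(0), end = integer(0))
  structure(list(genes = genes, features = feats_out),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d feature intervals\n",
              nrow(x$genes), nrow(x$features)))
  invisible(x)
}
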