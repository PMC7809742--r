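#' Build a k-mer index of a genome
#'
#' @param genome Genome sequence (character scalar) or a \code{sim_genome}.
#' @param k Seed length.
#' @return A list of class \code{kmer_index} with the position list, \code{k},
#'   the genome string and its length.
#' @export
kmer_index <- function(genome, k = 24L) {
  if (inherits(genome, "sim_genome")) genome <- genome$seq
  stopifnot(is.character(genome), length(genome) == 1L, nchar(genome) >= k)
  n <- nchar(genome) - k + 1L
  kmers <- substring(genome, 1:n, k:(nchar(genome)))
  pos_by_kmer <- split(seq_len(n), kmers)
  structure(list(pos = pos_by_kmer, keys = names(pos_by_kmer),
                 k = as.integer(k), genome = genome,
                 genome_len = nchar(genome)),
            class = "kmer_index")
}

.count_mismatch <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Map trimmed read bodies to a genome by seeded exact matching
#'
#' A deliberately small aligner for the synthetic benchmark: seeds each body
#' (and its reverse complement) with up to three non-overlapping k-mers,
#' verifies candidate loci by substitution count, and keeps the unique best
#' hit with at most \code{max_mismatch} substitutions. Reads with tied best
#' hits at different loci, or shorter than \code{k}, are dropped. No indels
#' are modelled.
#'
#' @param bodies Character vector of tail-stripped read sequences, or a FASTQ
#'   path.
#' @param index A \code{\link{kmer_index}} (or a genome to index on the fly).
#' @param max_mismatch Maximum substitutions allowed in a hit.
#' @return A \code{GenomicRanges::GRanges} of alignments (one per mapped
#'   read): the aligned span, strand (\code{-} means the reverse complement of
#'   the body matched the forward genome), \code{qname} and \code{mismatches}.
#'   Unmapped count is reported in \code{metadata(x)$n_unmapped}.
#' @export
map_reads <- function(bodies, index, max_mismatch = 2L) {
  if (!inherits(index, "kmer_index")) index <- kmer_index(index)
  if (length(bodies) == 1L && file.exists(bodies) &&
      grepl("\\.(fastq|fq)$", bodies)) {
    x <- Biostrings::readDNAStringSet(bodies, format = "fastq")
    qnames <- names(x)
    bodies <- as.character(x)
  } else {
    qnames <- if (!is.null(names(bodies))) names(bodies) else
      sprintf("read%06d", seq_along(bodies))
  }
  k <- index$k
  ub <- unique(bodies)
  len <- nchar(ub)
  mappable <- len >= k

  cand <- list()
  for (orient in c("+", "-")) {
    s <- if (orient == "+") ub else revcomp(ub)
    for (tier in 0:2) {
      off <- 1L + tier * k
      has <- mappable & (off + k - 1L <= len)
      if (!any(has)) next
      seeds <- substr(s[has], off, off + k - 1L)
      m <- match(seeds, index$keys)
      hit <- which(!is.na(m))
      if (length(hit) == 0L) next
      ii <- which(has)[hit]
      pos_lists <- index$pos[m[hit]]
      nrep <- lengths(pos_lists)
      cand[[length(cand) + 1L]] <- data.frame(
        body = rep(ii, nrep),
        g = unlist(pos_lists, use.names = FALSE) - (off - 1L),
        strand = orient, stringsAsFactors = FALSE)
    }
  }
  hits <- NULL
  cand <- if (length(cand) > 0) {
    unique(do.call(rbind, cand))
  } else {
    data.frame(body = integer(0), g = integer(0), strand = character(0))
  }
  cand <- cand[cand$g >= 1L &
                 cand$g + len[cand$body] - 1L <= index$genome_len, ,
               drop = FALSE]
  if (nrow(cand) > 0) {
    qseq <- ifelse(cand$strand == "+", ub[cand$body], revcomp(ub[cand$body]))
    ref <- substring(index$genome, cand$g, cand$g + len[cand$body] - 1L)
    mm <- integer(nrow(cand))
    ne <- which(qseq != ref)           # exact matches need no counting
    if (length(ne)) {
      mm[ne] <- vapply(ne, function(i) .count_mismatch(qseq[i], ref[i]), 0L)
    }
    cand$mm <- mm
    cand <- cand[cand$mm <= max_mismatch, ]
    if (nrow(cand) > 0) {
      # unique best hit per body; ties at distinct loci drop the read
      best <- do.call(rbind, lapply(split(cand, cand$body), function(d) {
        d <- d[d$mm == min(d$mm), , drop = FALSE]
        if (nrow(d) > 1L) NULL else d
      }))
      hits <- best
    }
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$n_unmapped <- length(bodies)
    return(gr)
  }
  # expand unique-body hits back to all reads
  bidx <- match(bodies, ub)
  take <- match(bidx, hits$body)
  mapped <- which(!is.na(take))
  n_unmapped <- length(bodies) - length(mapped)
  h <- hits[take[mapped], ]
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = h$g, width = len[h$body]),
    strand = h$strand)
  gr$qname <- qnames[mapped]
  gr$mismatches <- h$mm
  S4Vectors::metadata(gr)$n_unmapped <- n_unmapped
  gr
}
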