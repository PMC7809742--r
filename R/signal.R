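#' Extract fixed windows around cleavage sites
#'
#' Returns the 100-nt sense-strand (transcript-oriented) sequence around each
#' site: offsets -flank..(flank-1) with offset 0 at the cleavage base.
#' Minus-strand sites are reverse-complemented. Windows running off the
#' chromosome are padded with N and flagged.
#'
#' @param sites Data.frame with \code{chrom}, \code{pos} (0-based cleavage
#'   base), \code{strand} — e.g. a \code{pas_sites} table, or the \code{pacs}
#'   table of a \code{pac_set} (its \code{rep_pos} is used).
#' @param genome Named character vector / \code{DNAStringSet} of chromosome
#'   sequences, a FASTA path, or a \code{sim_genome}.
#' @param flank Upstream window size in nt (downstream gets \code{flank} nt
#'   too, so windows are \code{2*flank} long).
#' @return Character vector of windows, with attribute \code{padded}
#'   (logical: window extended past a chromosome end).
#' @export
extract_windows <- function(sites, genome, flank = 50L) {
  if (inherits(genome, "sim_genome")) {
    genome <- stats::setNames(genome$seq, genome$chrom)
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    names(x) <- sub("\\s.*", "", names(x))
    genome <- stats::setNames(as.character(x), names(x))
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (!is.null(sites$rep_pos) && is.null(sites$pos)) sites$pos <- sites$rep_pos
  if (any(!(sites$chrom %in% names(genome)))) {
    stop("site chromosome missing from genome")
  }
  n <- nrow(sites)
  win <- character(n)
  padded <- logical(n)
  for (i in seq_len(n)) {
    p <- sites$pos[i]
    g <- genome[[sites$chrom[i]]]
    L <- nchar(g)
    if (sites$strand[i] == "+") {
      s0 <- p - flank; s1 <- p + flank - 1L
    } else {
      s0 <- p - flank + 1L; s1 <- p + flank
    }
    lo <- max(s0, 0L); hi <- min(s1, L - 1L)
    core <- if (hi >= lo) substr(g, lo + 1L, hi + 1L) else ""
    seqi <- paste0(strrep("N", lo - s0), core, strrep("N", s1 - hi))
    padded[i] <- (lo > s0) || (hi < s1)
    if (sites$strand[i] == "-") seqi <- revcomp(seqi)
    win[i] <- seqi
  }
  attr(win, "padded") <- padded
  win
}

#' Per-offset nucleotide composition of cleavage-site windows
#'
#' @param windows Character vector of equal-length windows (see
#'   \code{\link{extract_windows}}); offset 0 is at position \code{flank+1}.
#' @param flank Upstream window size used to label offsets.
#' @return A 4 x width matrix (rows A, C, G, T) of frequencies per offset; N
#'   bases are excluded from the denominators. Columns are named by offset.
#' @export
base_composition <- function(windows, flank = nchar(windows[1]) %/% 2L) {
  stopifnot(length(windows) >= 1L, length(unique(nchar(windows))) == 1L)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows),
                                    baseOnly = TRUE)
  acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  denom <- colSums(acgt)
  freq <- sweep(acgt, 2L, pmax(denom, 1L), `/`)
  freq[, denom == 0] <- NA_real_
  colnames(freq) <- seq(-flank, ncol(freq) - flank - 1L)
  freq
}

#' Positional hexamer scan of cleavage-site windows
#'
#' Counts every overlapping k-mer occurrence at every start offset of the
#' windows (so homopolymer runs contribute one count per start), ranks
#' k-mers by total occurrences and retains the per-offset positional profile
#' of each.
#'
#' @param windows Character vector of equal-length windows.
#' @param k Motif length.
#' @param top_n Number of top-ranked k-mers reported.
#' @param flank Upstream window size used to label start offsets.
#' @return A list of class \code{signal_profile}: \code{counts} (k-mer x
#'   start-offset count matrix, offsets as column names), \code{ranking}
#'   (data.frame of the \code{top_n} k-mers with total counts),
#'   \code{n_sequences}, \code{k}.
#' @export
hexamer_scan <- function(windows, k = 6L, top_n = 30L,
                         flank = nchar(windows[1]) %/% 2L) {
  stopifnot(length(windows) >= 1L, length(unique(nchar(windows))) == 1L,
            nchar(windows[1]) >= k)
  W <- nchar(windows[1])
  nstart <- W - k + 1L
  offsets <- seq(-flank, nstart - flank - 1L)
  subs <- lapply(seq_len(nstart), function(i) substr(windows, i, i + k - 1L))
  kmer <- unlist(subs, use.names = FALSE)
  off <- rep(offsets, each = length(windows))
  ok <- !grepl("N", kmer, fixed = TRUE)
  tab <- table(kmer = kmer[ok], offset = factor(off[ok], levels = offsets))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), as.character(offsets)))
  totals <- rowSums(counts)
  o <- order(-totals, rownames(counts))
  counts <- counts[o, , drop = FALSE]
  ranking <- data.frame(kmer = rownames(counts)[seq_len(min(top_n, nrow(counts)))],
                        total = totals[o][seq_len(min(top_n, nrow(counts)))],
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  structure(list(counts = counts, ranking = ranking,
                 n_sequences = length(windows), k = as.integer(k)),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf("signal_profile: %d sequences, k=%d; top k-mers: %s\n",
              x$n_sequences, x$k,
              paste(utils::head(x$ranking$kmer, 5L), collapse = " ")))
  invisible(x)
}

#' Call a positional enrichment peak for one k-mer
#'
#' The k-mer is called present in the region when its maximum per-offset
#' count inside the region is at least \code{fold_threshold} times its median
#' count outside.
#'
#' @param profile A \code{\link{hexamer_scan}} result.
#' @param kmer The k-mer to test (e.g. \code{"AAAAAA"}).
#' @param region Integer vector of start offsets defining the region (e.g.
#'   \code{5:10} for downstream +5..+10).
#' @param fold_threshold Enrichment factor over the outside-median.
#' @return A list of class \code{peak_call}: \code{kmer}, \code{region},
#'   \code{present}, \code{peak_offset}, \code{peak_count},
#'   \code{outside_median}.
#' @export
call_peak <- function(profile, kmer, region, fold_threshold = 2) {
  stopifnot(inherits(profile, "signal_profile"))
  offsets <- as.integer(colnames(profile$counts))
  if (!all(region %in% offsets)) stop("region outside the profiled window")
  v <- if (kmer %in% rownames(profile$counts)) {
    profile$counts[kmer, ]
  } else stats::setNames(integer(length(offsets)), as.character(offsets))
  inside <- as.integer(names(v)) %in% region
  max_in <- max(v[inside])
  med_out <- stats::median(v[!inside])
  present <- max_in >= fold_threshold * max(med_out, 0.5)
  structure(list(kmer = kmer, region = range(region), present = present,
                 peak_offset = as.integer(names(v)[inside][
                   which.max(v[inside])]),
                 peak_count = max_in, outside_median = med_out),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("peak_call %s in [%d, %d]: %s (peak %d at %+d, outside median %.1f)\n",
              x$kmer, x$region[1], x$region[2],
              if (x$present) "PRESENT" else "absent",
              x$peak_count, x$peak_offset, x$outside_median))
  invisible(x)
}

#' Windows of shifted-gene PACs, split by condition of use
#'
#' For the signal analysis of shifted genes, each gene significant beyond the
#' minimum shift distance contributes the window of its control-dominant PAC
#' to one group and of its treatment-dominant PAC to the other.
#'
#' @param pac_set Annotated consensus \code{pac_set}.
#' @param shifts A \code{\link{call_shifts}} result.
#' @param genome Genome as accepted by \code{\link{extract_windows}}.
#' @param treatment,control Sample labels (defaults from the shift summary).
#' @param flank Window half-width.
#' @return A list with \code{control} and \code{treatment} window vectors.
#' @export
shifted_pac_windows <- function(pac_set, shifts, genome,
                                treatment = attr(shifts, "summary")$treatment,
                                control = attr(shifts, "summary")$control,
                                flank = 50L) {
  genes <- shifts$gene[shifts$motif_eligible]
  pp <- pac_set$pacs
  pick <- function(g, sample) {
    gp <- pp[!is.na(pp$gene) & pp$gene == g &
               !(pp$category %in% c("antisense", "intergenic")), ]
    gp[which.max(gp[[paste0("tpm_", sample)]]), ]
  }
  ctl <- do.call(rbind, lapply(genes, pick, sample = control))
  trt <- do.call(rbind, lapply(genes, pick, sample = treatment))
  list(control = if (is.null(ctl)) character(0) else
         extract_windows(data.frame(chrom = ctl$chrom, pos = ctl$rep_pos,
                                    strand = ctl$strand), genome, flank),
       treatment = if (is.null(trt)) character(0) else
         extract_windows(data.frame(chrom = trt$chrom, pos = trt$rep_pos,
                                    strand = trt$strand), genome, flank))
}
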