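#' Parameters for polyA-tail trimming
#'
#' Defaults reproduce the PAS-read preprocessing heuristic: anchor a run of at
#' least 8 consecutive A at the 3' side of the read, clip from the anchor to
#' the read end, then keep extending the clip 5'-ward across A-rich sequence
#' until at least \code{stop_non_a} consecutive non-A bases are met (those
#' bases stay in the body). Bodies longer than \code{min_body_len} nt
#' (strictly) are kept.
#'
#' @param anchor_len Minimum length of the anchoring A-run (nt).
#' @param stop_non_a Number of consecutive non-A bases that stop the upstream
#'   clip extension.
#' @param min_body_len Bodies must be strictly longer than this to be kept.
#' @param scan_5prime If \code{TRUE}, reads with no 3' anchor are also tried in
#'   reverse-complement orientation (handles reads sequenced from the opposite
#'   end, which carry the tail as a 5' T-run); the orientation yielding an
#'   anchor wins, with the forward (3') orientation preferred on ties.
#' @return A list of class \code{trim_params}.
#' @export
trim_params <- function(anchor_len = 8L, stop_non_a = 2L, min_body_len = 11L,
                        scan_5prime = TRUE) {
  stopifnot(anchor_len >= 1L, stop_non_a >= 1L, min_body_len >= 0L)
  structure(list(anchor_len = as.integer(anchor_len),
                 stop_non_a = as.integer(stop_non_a),
                 min_body_len = as.integer(min_body_len),
                 scan_5prime = isTRUE(scan_5prime)),
            class = "trim_params")
}

# core single-orientation clip; returns NULL when no anchor run exists
.trim_one_fwd <- function(chars, anchor_len, stop_non_a) {
  is_a <- chars == "A"
  r <- rle(is_a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= anchor_len)
  if (length(hit) == 0L) return(NULL)
  s <- starts[hit[length(hit)]]          # 3'-most qualifying A-run
  i <- s - 1L
  while (i >= 1L) {
    if (is_a[i]) { i <- i - 1L; next }
    j <- i
    while (j >= 1L && !is_a[j]) j <- j - 1L
    if (i - j >= stop_non_a) break       # non-A run long enough: it stays
    i <- j                               # isolated error inside the tail
  }
  list(body_end = i, anchor_start = s)
}

#' Anchor and clip the polyA tail of a single read
#'
#' @param read Uppercase A/C/G/T/N sequence (character scalar).
#' @param params A \code{\link{trim_params}} object.
#' @return A list with \code{body}, \code{tail_len}, \code{anchor_start}
#'   (0-based offset of the anchored A-run in the orientation that was
#'   clipped, \code{NA} if none), \code{orient} ("fwd" or "rev") and
#'   \code{kept}.
#' @examples
#' trim_polya(paste0("ACGTACGTACGTACGT", strrep("A", 10)))
#' @export
trim_polya <- function(read, params = trim_params()) {
  stopifnot(is.character(read), length(read) == 1L)
  if (nchar(read) == 0L) {
    return(list(body = "", tail_len = 0L, anchor_start = NA_integer_,
                orient = "fwd", kept = FALSE))
  }
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("read contains non-IUPAC characters (expected uppercase ACGTN)")
  }
  res <- .trim_one_fwd(chars, params$anchor_len, params$stop_non_a)
  orient <- "fwd"
  if (is.null(res) && params$scan_5prime) {
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
    res_rc <- .trim_one_fwd(unname(rc), params$anchor_len, params$stop_non_a)
    if (!is.null(res_rc)) {
      chars <- unname(rc)
      res <- res_rc
      orient <- "rev"
    }
  }
  if (is.null(res)) {
    return(list(body = read, tail_len = 0L, anchor_start = NA_integer_,
                orient = "fwd", kept = FALSE))
  }
  body <- if (res$body_end >= 1L) {
    paste(chars[seq_len(res$body_end)], collapse = "")
  } else ""
  list(body = body,
       tail_len = length(chars) - nchar(body),
       anchor_start = res$anchor_start - 1L,
       orient = orient,
       kept = nchar(body) > params$min_body_len)
}

#' Trim a vector of reads
#'
#' Vector convenience wrapper around \code{\link{trim_polya}}.
#'
#' @param reads Character vector of read sequences.
#' @param params A \code{\link{trim_params}} object.
#' @return A data.frame with one row per read: \code{body}, \code{tail_len},
#'   \code{anchor_start}, \code{orient}, \code{kept}.
#' @export
trim_reads <- function(reads, params = trim_params()) {
  out <- lapply(reads, trim_polya, params = params)
  data.frame(body = vapply(out, `[[`, "", "body"),
             tail_len = vapply(out, `[[`, 0L, "tail_len"),
             anchor_start = vapply(out, `[[`, 0L, "anchor_start"),
             orient = vapply(out, `[[`, "", "orient"),
             kept = vapply(out, `[[`, FALSE, "kept"),
             stringsAsFactors = FALSE)
}

#' Trim a FASTQ file of PAS-seq reads
#'
#' Reads a FASTQ file, clips polyA tails with \code{\link{trim_polya}}, writes
#' the kept bodies (qualities truncated in register with the bases; bodies
#' clipped in reverse-complement orientation get reversed qualities) and
#' returns summary counts.
#'
#' @param infile Input FASTQ path.
#' @param outfile Output FASTQ path for kept bodies.
#' @param params A \code{\link{trim_params}} object.
#' @return Invisibly, a list with \code{n_input}, \code{n_kept},
#'   \code{n_discarded} and \code{mean_tail_len} (over kept reads; \code{NaN}
#'   when none kept).
#' @export
trim_fastq <- function(infile, outfile, params = trim_params()) {
  reads <- Biostrings::readDNAStringSet(infile, format = "fastq",
                                        with.qualities = TRUE)
  n_in <- length(reads)
  if (n_in == 0L) {
    writeLines(character(0), outfile)
    return(invisible(list(n_input = 0L, n_kept = 0L, n_discarded = 0L,
                          mean_tail_len = NaN)))
  }
  tr <- trim_reads(as.character(reads), params)
  keep <- tr$kept
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  body <- tr$body[keep]
  qual <- quals[keep]
  orient <- tr$orient[keep]
  # rev-orientation bodies come from the reverse complement: reverse qualities
  qual <- ifelse(orient == "rev",
                 vapply(qual, function(q)
                   paste(rev(strsplit(q, "")[[1]]), collapse = ""), ""),
                 qual)
  qual <- substr(qual, 1L, nchar(body))
  out <- Biostrings::DNAStringSet(body)
  names(out) <- names(reads)[keep]
  Biostrings::writeXStringSet(out, outfile, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(list(n_input = n_in, n_kept = sum(keep),
                 n_discarded = n_in - sum(keep),
                 mean_tail_len = mean(tr$tail_len[keep])))
}
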