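#' Clustering parameters for PAC identification
#'
#' Defaults are the canonical thresholds of the analysis: single-base sites
#' with TPM > 0.5 are chained into clusters when within 20 nt of each other;
#' clusters from different libraries within 100 nt are merged; APA analysis
#' drops clusters with a single polyA site or TPM below 3; the combined PAC
#' catalogue uses a TPM cutoff of 5.
#'
#' @param site_min_tpm Sites must exceed this TPM (strict) to enter clustering.
#' @param within_link Maximum gap (nt) between consecutive member sites.
#' @param cross_link Maximum edge-to-edge gap (nt) between clusters merged
#'   across libraries.
#' @param apa_min_tpm Minimum per-sample TPM kept in APA mode (>=).
#' @param combined_min_tpm Minimum pooled TPM kept in combined mode (>=).
#' @return A list of class \code{cluster_params}.
#' @export
cluster_params <- function(site_min_tpm = 0.5, within_link = 20L,
                           cross_link = 100L, apa_min_tpm = 3,
                           combined_min_tpm = 5) {
  stopifnot(site_min_tpm >= 0, within_link >= 0, cross_link >= 0,
            apa_min_tpm >= 0, combined_min_tpm >= 0)
  structure(list(site_min_tpm = site_min_tpm,
                 within_link = as.integer(within_link),
                 cross_link = as.integer(cross_link),
                 apa_min_tpm = apa_min_tpm,
                 combined_min_tpm = combined_min_tpm),
            class = "cluster_params")
}

# representative site: highest count, ties broken to the most 3' position
.rep_pos <- function(pos, count, strand) {
  best <- which(count == max(count))
  p <- pos[best]
  if (strand == "+") max(p) else min(p)
}

#' Cluster polyA sites of one sample into PACs
#'
#' Discards sites with TPM at or below \code{site_min_tpm}, then chains
#' same-chromosome, same-strand sites whose consecutive gaps are at most
#' \code{within_link} nt (single linkage).
#'
#' @param sites A \code{pas_sites} data.frame for a single sample.
#' @param params A \code{\link{cluster_params}}.
#' @param sample Sample label recorded in the result.
#' @return A list of class \code{pac_set}: \code{pacs} (pac_id, chrom, strand,
#'   start, end as 0-based half-open span of member sites, rep_pos, n_sites,
#'   one \code{tpm_<sample>} column) and \code{sites} (member sites with
#'   pac_id and sample).
#' @export
cluster_sites <- function(sites, params = cluster_params(), sample = "S1") {
  keep <- sites$tpm > params$site_min_tpm
  s <- sites[keep, , drop = FALSE]
  s <- s[order(s$chrom, s$strand, s$pos), , drop = FALSE]
  if (nrow(s) == 0L) {
    return(.empty_pac_set(sample))
  }
  grp_key <- paste(s$chrom, s$strand)
  new_grp <- c(TRUE, grp_key[-1] != grp_key[-nrow(s)] |
                 diff(s$pos) > params$within_link)
  s$pac_local <- cumsum(new_grp)
  pacs <- do.call(rbind, lapply(split(s, s$pac_local), function(d) {
    data.frame(chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$pos), end = max(d$pos) + 1L,
               rep_pos = .rep_pos(d$pos, d$count, d$strand[1]),
               n_sites = nrow(d), tpm = sum(d$tpm),
               stringsAsFactors = FALSE)
  }))
  pacs$pac_id <- sprintf("PAC%05d", seq_len(nrow(pacs)))
  names(pacs)[names(pacs) == "tpm"] <- paste0("tpm_", sample)
  s$pac_id <- pacs$pac_id[s$pac_local]
  s$sample <- sample
  msites <- s[, c("pac_id", "chrom", "pos", "strand", "sample", "count", "tpm")]
  rownames(pacs) <- rownames(msites) <- NULL
  structure(list(pacs = pacs[, c("pac_id", "chrom", "strand", "start", "end",
                                 "rep_pos", "n_sites",
                                 paste0("tpm_", sample))],
                 sites = msites, samples = sample),
            class = "pac_set")
}

.empty_pac_set <- function(samples) {
  pacs <- data.frame(pac_id = character(0), chrom = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0), rep_pos = integer(0),
                     n_sites = integer(0), stringsAsFactors = FALSE)
  for (s in samples) pacs[[paste0("tpm_", s)]] <- numeric(0)
  structure(list(pacs = pacs,
                 sites = data.frame(pac_id = character(0), chrom = character(0),
                                    pos = integer(0), strand = character(0),
                                    sample = character(0), count = integer(0),
                                    tpm = numeric(0), stringsAsFactors = FALSE),
                 samples = samples),
            class = "pac_set")
}

#' @export
print.pac_set <- function(x, ...) {
  cat(sprintf("pac_set: %d PACs over samples [%s]\n", nrow(x$pacs),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Merge per-sample PACs into a consensus catalogue
#'
#' Same-strand clusters whose spans are within \code{cross_link} nt
#' (edge-to-edge gap) across libraries are merged; the consensus span is the
#' union, per-sample TPMs are carried into a TPM matrix, and the
#' representative position is recomputed from pooled member-site counts.
#'
#' @param pac_list List of per-sample \code{pac_set}s (as from
#'   \code{\link{cluster_sites}}).
#' @param params A \code{\link{cluster_params}}.
#' @return A consensus \code{pac_set} with one \code{tpm_<sample>} column per
#'   sample and \code{n_sites} = number of distinct pooled member positions.
#' @export
merge_pacs <- function(pac_list, params = cluster_params()) {
  stopifnot(length(pac_list) >= 1L,
            all(vapply(pac_list, inherits, TRUE, "pac_set")))
  samples <- unlist(lapply(pac_list, `[[`, "samples"))
  stopifnot(!anyDuplicated(samples))
  allp <- do.call(rbind, lapply(pac_list, function(ps) {
    tpm_col <- paste0("tpm_", ps$samples)
    data.frame(chrom = ps$pacs$chrom, strand = ps$pacs$strand,
               start = ps$pacs$start, end = ps$pacs$end,
               sample = ps$samples, pac_id = ps$pacs$pac_id,
               tpm = ps$pacs[[tpm_col]], stringsAsFactors = FALSE)
  }))
  alls <- do.call(rbind, lapply(pac_list, `[[`, "sites"))
  if (nrow(allp) == 0L) return(.empty_pac_set(samples))
  allp <- allp[order(allp$chrom, allp$strand, allp$start, allp$end), ]
  grp_key <- paste(allp$chrom, allp$strand)
  # interval single linkage: new group when the gap to everything before > link
  run_end <- allp$end[1]
  grp <- integer(nrow(allp))
  grp[1] <- 1L
  for (i in seq_len(nrow(allp))[-1]) {
    if (grp_key[i] != grp_key[i - 1L] ||
        allp$start[i] - run_end > params$cross_link) {
      grp[i] <- grp[i - 1L] + 1L
      run_end <- allp$end[i]
    } else {
      grp[i] <- grp[i - 1L]
      run_end <- max(run_end, allp$end[i])
    }
  }
  allp$grp <- grp
  skey <- paste(alls$sample, alls$pac_id)
  pkey <- paste(allp$sample, allp$pac_id)
  alls$grp <- allp$grp[match(skey, pkey)]
  cons <- do.call(rbind, lapply(split(allp, allp$grp), function(d) {
    ms <- alls[alls$grp == d$grp[1], ]
    pooled <- tapply(ms$count, ms$pos, sum)
    pool_pos <- as.integer(names(pooled))
    out <- data.frame(chrom = d$chrom[1], strand = d$strand[1],
                      start = min(d$start), end = max(d$end),
                      rep_pos = .rep_pos(pool_pos, as.vector(pooled),
                                         d$strand[1]),
                      n_sites = length(pool_pos), stringsAsFactors = FALSE)
    for (s in samples) out[[paste0("tpm_", s)]] <- sum(d$tpm[d$sample == s])
    out
  }))
  cons$pac_id <- sprintf("cPAC%05d", seq_len(nrow(cons)))
  msites <- alls[, c("chrom", "pos", "strand", "sample", "count", "tpm")]
  msites$pac_id <- cons$pac_id[alls$grp]
  rownames(cons) <- rownames(msites) <- NULL
  structure(list(pacs = cons[, c("pac_id", "chrom", "strand", "start", "end",
                                 "rep_pos", "n_sites",
                                 paste0("tpm_", samples))],
                 sites = msites[, c("pac_id", "chrom", "pos", "strand",
                                    "sample", "count", "tpm")],
                 samples = samples),
            class = "pac_set")
}

#' Filter a consensus PAC catalogue
#'
#' \code{mode = "apa"} drops PACs with a single member polyA site, and PACs
#' whose TPM is below \code{apa_min_tpm} in every compared sample.
#' \code{mode = "combined"} keeps PACs whose pooled TPM is at least
#' \code{combined_min_tpm}.
#'
#' @param pac_set A consensus \code{pac_set}.
#' @param mode \code{"apa"} or \code{"combined"}.
#' @param params A \code{\link{cluster_params}}.
#' @param samples Samples compared in APA mode; defaults to all.
#' @return The filtered \code{pac_set}.
#' @export
filter_pacs <- function(pac_set, mode = c("apa", "combined"),
                        params = cluster_params(), samples = NULL) {
  mode <- match.arg(mode)
  if (is.null(samples)) samples <- pac_set$samples
  stopifnot(all(samples %in% pac_set$samples))
  if (nrow(pac_set$pacs) == 0L) return(pac_set)
  tpm <- as.matrix(pac_set$pacs[, paste0("tpm_", samples), drop = FALSE])
  keep <- if (mode == "apa") {
    pac_set$pacs$n_sites > 1L & apply(tpm, 1L, max) >= params$apa_min_tpm
  } else {
    rowSums(as.matrix(
      pac_set$pacs[, paste0("tpm_", pac_set$samples), drop = FALSE])) >=
      params$combined_min_tpm
  }
  pac_set$pacs <- pac_set$pacs[keep, , drop = FALSE]
  pac_set$sites <- pac_set$sites[
    pac_set$sites$pac_id %in% pac_set$pacs$pac_id, , drop = FALSE]
  rownames(pac_set$pacs) <- rownames(pac_set$sites) <- NULL
  pac_set
}

#' Assign gene and region category to consensus PACs
#'
#' Categorizes each PAC's representative position with
#' \code{\link{categorize_sites}}.
#'
#' @param pac_set A \code{pac_set}.
#' @param annotation A \code{\link{read_annotation}} result.
#' @param utr3_extend Passed to \code{\link{categorize_sites}}.
#' @return The \code{pac_set} with \code{gene} and \code{category} columns.
#' @export
annotate_pacs <- function(pac_set, annotation, utr3_extend = 0L) {
  rep_sites <- data.frame(chrom = pac_set$pacs$chrom,
                          pos = pac_set$pacs$rep_pos,
                          strand = pac_set$pacs$strand,
                          stringsAsFactors = FALSE)
  cat <- categorize_sites(rep_sites, annotation, utr3_extend = utr3_extend)
  pac_set$pacs$gene <- cat$gene
  pac_set$pacs$category <- cat$category
  pac_set
}

#' Right-sided Fisher test of antisense-PAC enrichment
#'
#' For each treatment versus the control, forms the 2x2 table of
#' [antisense, non-antisense] x [treatment, control] PAC counts and computes
#' the right-sided Fisher exact p-value: the hypergeometric probability of at
#' least the observed number of antisense PACs in the treatment, given the
#' margins.
#'
#' @param antisense Named vector (by condition) of antisense PAC counts.
#' @param total Named vector of total PAC counts per condition.
#' @param control Name of the control condition.
#' @return A data.frame with one row per treatment: counts, fold change of
#'   the antisense fraction, and the right-sided p-value.
#' @export
antisense_test <- function(antisense, total, control) {
  stopifnot(control %in% names(antisense), control %in% names(total),
            all(names(antisense) %in% names(total)),
            all(antisense <= total[names(antisense)]))
  if (any(total == 0)) stop("empty condition: zero PACs")
  trts <- setdiff(names(antisense), control)
  a_c <- antisense[[control]]
  n_c <- total[[control]]
  out <- lapply(trts, function(tr) {
    a_t <- antisense[[tr]]
    n_t <- total[[tr]]
    p <- fisher_right_p(a_t, n_t, a_c, n_c)
    data.frame(condition = tr, antisense = a_t, total = n_t,
               control_antisense = a_c, control_total = n_c,
               fold = (a_t / n_t) / (a_c / n_c),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Right-sided Fisher exact p for a 2x2 table, vectorized
#'
#' The probability of at least \code{a_t} successes in the treatment row
#' given the table margins: \eqn{P[X \ge a_t]} with
#' \eqn{X \sim Hypergeom(N = n_t + n_c, K = a_t + a_c, n = n_t)}.
#'
#' @param a_t,n_t Successes and row total in the treatment.
#' @param a_c,n_c Successes and row total in the control.
#' @return Vector of right-sided p-values.
#' @export
fisher_right_p <- function(a_t, n_t, a_c, n_c) {
  stats::phyper(a_t - 1, a_t + a_c, (n_t - a_t) + (n_c - a_c), n_t,
                lower.tail = FALSE)
}

#' Count antisense and total PACs in annotated per-condition PAC sets
#'
#' Convenience builder for \code{\link{antisense_test}}.
#'
#' @param pac_list Named list (by condition) of annotated \code{pac_set}s.
#' @return A list with \code{antisense} and \code{total} named vectors.
#' @export
count_antisense <- function(pac_list) {
  stopifnot(!is.null(names(pac_list)))
  list(antisense = vapply(pac_list, function(ps)
         sum(ps$pacs$category == "antisense"), 0L),
       total = vapply(pac_list, function(ps) nrow(ps$pacs), 0L))
}
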