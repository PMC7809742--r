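#' Parameters for APA shift calling
#'
#' @param alpha Significance cutoff on the KS p-value (raw, per the method's
#'   convention; see \code{fdr}).
#' @param min_pacs Minimum PACs per gene entering the comparison.
#' @param motif_min_distance Genes must shift by more than this many nt to be
#'   exported for downstream signal profiling.
#' @param cap_n Cap on the effective KS sample size per condition (read
#'   counts, not TPM, support the test; the cap prevents significance from
#'   depth alone).
#' @param exact_max Use exact permutation enumeration when the pooled
#'   effective size is at most this value; asymptotic otherwise.
#' @param fdr If \code{TRUE}, also apply Benjamini-Hochberg across genes and
#'   call significance on the adjusted values.
#' @return A list of class \code{shift_params}.
#' @export
shift_params <- function(alpha = 0.01, min_pacs = 2L, motif_min_distance = 50L,
                         cap_n = 1000L, exact_max = 20L, fdr = FALSE) {
  stopifnot(alpha > 0, alpha < 1, min_pacs >= 2L)
  structure(list(alpha = alpha, min_pacs = as.integer(min_pacs),
                 motif_min_distance = as.integer(motif_min_distance),
                 cap_n = as.integer(cap_n), exact_max = as.integer(exact_max),
                 fdr = isTRUE(fdr)),
            class = "shift_params")
}

#' Positional usage distribution of one gene in one sample
#'
#' Member-site TPM weights of a gene's PACs laid out along the transcript's
#' 3'-oriented axis (increasing = downstream), normalized to sum 1.
#'
#' @param pac_set An annotated consensus \code{pac_set}.
#' @param gene Gene id.
#' @param sample Sample label.
#' @param exclude_categories PAC categories excluded from the gene's sense
#'   distribution.
#' @return A list with \code{axis} (3'-oriented coordinates), \code{pos}
#'   (genomic positions), \code{w} (normalized weights), \code{counts} (read
#'   counts) and \code{n} (total reads); \code{n = 0} when unexpressed.
#' @export
gene_site_distribution <- function(pac_set, gene, sample,
                                   exclude_categories = c("antisense",
                                                          "intergenic")) {
  pp <- pac_set$pacs
  sel <- !is.na(pp$gene) & pp$gene == gene &
    !(pp$category %in% exclude_categories)
  ids <- pp$pac_id[sel]
  ms <- pac_set$sites[pac_set$sites$pac_id %in% ids &
                        pac_set$sites$sample == sample, , drop = FALSE]
  if (nrow(ms) == 0L) {
    return(list(axis = numeric(0), pos = integer(0), w = numeric(0),
                counts = integer(0), n = 0L))
  }
  cnt <- tapply(ms$count, ms$pos, sum)
  pos <- as.integer(names(cnt))
  strand <- ms$strand[1]
  axis <- if (strand == "+") pos else -pos
  o <- order(axis)
  counts <- as.vector(cnt)[o]
  list(axis = axis[o], pos = pos[o], w = counts / sum(counts),
       counts = counts, n = sum(counts))
}

#' Shift score: sup-distance between usage cumulatives
#'
#' D = sup over positions of |F_t(x) - F_c(x)| where F are the 3'-oriented
#' cumulative usage fractions of the two conditions. Symmetric in its
#' arguments; 0 for identical distributions, 1 for disjoint point masses.
#'
#' @param dist_a,dist_b Distributions from
#'   \code{\link{gene_site_distribution}} (or lists with \code{axis} and
#'   \code{w}).
#' @return D in [0, 1].
#' @export
shift_score <- function(dist_a, dist_b) {
  if (length(dist_a$w) == 0L || length(dist_b$w) == 0L) {
    stop("shift_score is undefined for an empty distribution")
  }
  grid <- sort(unique(c(dist_a$axis, dist_b$axis)))
  Fa <- cumsum(vapply(grid, function(x) sum(dist_a$w[dist_a$axis == x]), 0))
  Fb <- cumsum(vapply(grid, function(x) sum(dist_b$w[dist_b$axis == x]), 0))
  max(abs(Fa - Fb))
}

# Kolmogorov asymptotic survival function with the Stephens small-sample
# correction on the argument
.ks_pvalue_asymptotic <- function(D, n_a, n_b) {
  ne <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  # the series is truncated at 100 terms; below lambda ~ 0.2 the survival
  # probability is 1 to machine precision and the truncated sum misbehaves
  if (lambda < 0.2) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(p, 1e-300))
}

.ks_D <- function(axis_a, axis_b) {
  grid <- sort(unique(c(axis_a, axis_b)))
  Fa <- cumsum(vapply(grid, function(x) sum(axis_a == x), 0)) / length(axis_a)
  Fb <- cumsum(vapply(grid, function(x) sum(axis_b == x), 0)) / length(axis_b)
  max(abs(Fa - Fb))
}

#' Two-sample KS p-value for a usage shift
#'
#' Effective sample sizes are the read counts supporting the gene in each
#' condition (capped at \code{cap_n}). Uses exact enumeration over all splits
#' of the pooled reads when the pooled size is at most \code{exact_max},
#' otherwise the asymptotic Kolmogorov distribution.
#'
#' @param dist_t,dist_c Distributions from
#'   \code{\link{gene_site_distribution}}.
#' @param params A \code{\link{shift_params}}.
#' @return A list with \code{D}, \code{p}, \code{n_t}, \code{n_c} and
#'   \code{method} ("exact" or "asymptotic").
#' @export
ks_shift_test <- function(dist_t, dist_c, params = shift_params()) {
  if (dist_t$n == 0L || dist_c$n == 0L) stop("zero supporting reads")
  D <- shift_score(dist_t, dist_c)
  n_t <- min(dist_t$n, params$cap_n)
  n_c <- min(dist_c$n, params$cap_n)
  if (dist_t$n + dist_c$n <= params$exact_max) {
    xt <- rep(dist_t$axis, dist_t$counts)
    xc <- rep(dist_c$axis, dist_c$counts)
    pooled <- c(xt, xc)
    nt <- length(xt)
    splits <- utils::combn(length(pooled), nt)
    dperm <- apply(splits, 2L, function(idx)
      .ks_D(pooled[idx], pooled[-idx]))
    p <- mean(dperm >= D - 1e-12)
    return(list(D = D, p = p, n_t = nt, n_c = length(xc), method = "exact"))
  }
  list(D = D, p = .ks_pvalue_asymptotic(D, n_t, n_c),
       n_t = n_t, n_c = n_c, method = "asymptotic")
}

#' Call APA shifts between a treatment and the control
#'
#' For every gene with at least \code{min_pacs} APA-filtered PACs expressed
#' in both conditions: computes the shift score (KS D on usage cumulatives),
#' its p-value, the direction (movement of the usage-weighted mean cleavage
#' position along the 3' axis: downstream = lengthening), the distance
#' between the dominant (highest-TPM) PAC representative positions, and
#' whether the shift impacts the ORF (a dominant PAC in CDS, or dominance
#' moving between CDS and 3'UTR).
#'
#' @param pac_set An annotated consensus \code{pac_set} (see
#'   \code{\link{annotate_pacs}}).
#' @param treatment,control Sample labels.
#' @param params A \code{\link{shift_params}}.
#' @param cluster_par A \code{\link{cluster_params}} used for the APA filter.
#' @return A data.frame of class \code{shift_result}, one row per eligible
#'   gene: \code{gene}, \code{n_pacs}, \code{D}, \code{p} (and \code{q} when
#'   \code{params$fdr}), \code{direction}, \code{distance},
#'   \code{orf_impact}, \code{significant}, \code{motif_eligible}
#'   (significant and distance > \code{motif_min_distance}). Skipped genes
#'   and tallies are in \code{attr(x, "summary")}.
#' @export
call_shifts <- function(pac_set, treatment, control,
                        params = shift_params(),
                        cluster_par = cluster_params()) {
  stopifnot(inherits(pac_set, "pac_set"),
            "category" %in% names(pac_set$pacs))
  if (!all(c(treatment, control) %in% pac_set$samples)) {
    stop("condition label absent from the PAC set")
  }
  ps <- filter_pacs(pac_set, "apa", cluster_par,
                    samples = c(treatment, control))
  pp <- ps$pacs
  sense <- !is.na(pp$gene) & !(pp$category %in% c("antisense", "intergenic"))
  genes <- names(which(table(pp$gene[sense]) >= params$min_pacs))
  rows <- list(); skipped <- character(0)
  for (g in genes) {
    dt <- gene_site_distribution(ps, g, treatment)
    dc <- gene_site_distribution(ps, g, control)
    if (dt$n == 0L || dc$n == 0L) {
      skipped <- c(skipped, g)
      next
    }
    ks <- ks_shift_test(dt, dc, params)
    mean_t <- sum(dt$axis * dt$w)
    mean_c <- sum(dc$axis * dc$w)
    sel <- sense & pp$gene == g
    gp <- pp[sel, , drop = FALSE]
    dom_t <- gp[which.max(gp[[paste0("tpm_", treatment)]]), ]
    dom_c <- gp[which.max(gp[[paste0("tpm_", control)]]), ]
    moved <- dom_t$pac_id != dom_c$pac_id
    rows[[g]] <- data.frame(
      gene = g, n_pacs = nrow(gp), D = ks$D, p = ks$p,
      direction = if (mean_t >= mean_c) "lengthening" else "shortening",
      distance = abs(dom_t$rep_pos - dom_c$rep_pos),
      orf_impact = dom_t$category == "CDS" || dom_c$category == "CDS" ||
        (moved && dom_t$category != dom_c$category &&
           all(c(dom_t$category, dom_c$category) %in% c("CDS", "UTR3"))),
      significant = ks$p < params$alpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), n_pacs = integer(0), D = numeric(0),
               p = numeric(0), direction = character(0),
               distance = integer(0), orf_impact = logical(0),
               significant = logical(0), stringsAsFactors = FALSE)
  if (params$fdr && nrow(out)) {
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$q < params$alpha
  }
  out$motif_eligible <- out$significant &
    out$distance > params$motif_min_distance
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    treatment = treatment, control = control,
    n_tested = nrow(out), n_significant = sum(out$significant),
    directions = table(out$direction[out$significant]),
    n_orf_impact = sum(out$orf_impact & out$significant),
    distance_hist = if (nrow(out)) table(cut(out$distance[out$significant],
      breaks = c(0, 50, 100, 250, 500, Inf), right = TRUE)) else NULL,
    skipped_unexpressed = skipped)
  class(out) <- c("shift_result", "data.frame")
  out
}

#' @export
print.shift_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("shift_result %s vs %s: %d genes tested, %d significant (%d ORF-impacting)\n",
              s$treatment, s$control, s$n_tested, s$n_significant,
              s$n_orf_impact))
  NextMethod()
}

#' Overlap of significant shifted-gene sets across treatments
#'
#' @param shift_list Named list (by treatment) of \code{\link{call_shifts}}
#'   results.
#' @return A list with per-treatment significant gene sets, all pairwise
#'   intersections, and the common intersection.
#' @export
shift_overlap <- function(shift_list) {
  stopifnot(!is.null(names(shift_list)))
  sets <- lapply(shift_list, function(sr) sr$gene[sr$significant])
  prs <- utils::combn(names(sets), 2L, simplify = FALSE)
  pairwise <- lapply(prs, function(pr) intersect(sets[[pr[1]]], sets[[pr[2]]]))
  names(pairwise) <- vapply(prs, paste, "", collapse = ":")
  list(sets = sets, pairwise = pairwise,
       common = Reduce(intersect, sets))
}
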