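#' Hypergeometric over-representation test for gene sets
#'
#' For each term with at least one background gene, tests whether the query
#' over-represents the term: p = P[X >= k] with X ~ Hypergeometric(N, K, n),
#' where N is the universe size, K the background genes in the term, n the
#' query size and k the query genes in the term. P-values are corrected
#' across terms by FDR (Benjamini-Hochberg by default) and rows are sorted by
#' the adjusted value. The enrichment ratio is k / K (query genes in the
#' pathway over all pathway genes).
#'
#' @param query Character vector of query gene ids (subset of the universe).
#' @param annotation Data.frame with columns \code{gene}, \code{term} and
#'   optionally \code{name} and \code{namespace} (e.g. GO-BP / KEGG).
#' @param universe Background gene ids; defaults to all annotated genes.
#' @param method Multiple-testing correction: \code{"BH"} (FDR step-up) or
#'   \code{"hochberg"}.
#' @param namespace Restrict to one namespace when the annotation has several.
#' @return A data.frame with one row per term: \code{term}, \code{name},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{ratio}, \code{p},
#'   \code{q}; sorted by \code{q} then \code{p}.
#' @export
hypergeom_enrich <- function(query, annotation, universe = NULL,
                             method = c("BH", "hochberg"),
                             namespace = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (!is.null(namespace)) {
    annotation <- annotation[annotation$namespace %in% namespace, ,
                             drop = FALSE]
  }
  if (is.null(universe)) universe <- unique(annotation$gene)
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0L || length(universe) == 0L) {
    stop("empty query or universe")
  }
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(query)
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    gset <- unique(annotation$gene[annotation$term == tm])
    K <- length(gset)
    if (K == 0L) return(NULL)
    k <- sum(query %in% gset)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    nm <- if ("name" %in% names(annotation)) {
      annotation$name[annotation$term == tm][1]
    } else tm
    data.frame(term = tm, name = nm, k = k, K = K, n = n, N = N,
               ratio = k / K, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = method)
  out <- out[order(out$q, out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic gene-to-term annotation table
#'
#' Random term memberships for testing and for end-to-end pipeline runs when
#' no real GO/KEGG table is supplied. Term sizes are drawn log-uniformly
#' between \code{size_range} bounds.
#'
#' @param genes Universe of gene ids.
#' @param n_terms Number of terms.
#' @param size_range Min/max genes per term.
#' @param namespace Namespace label stored in the table.
#' @param seed Seed for reproducibility.
#' @return A data.frame with \code{gene}, \code{term}, \code{name},
#'   \code{namespace}.
#' @export
generate_term_annotation <- function(genes, n_terms = 50L,
                                     size_range = c(5L, 50L),
                                     namespace = "KEGG", seed = 1L) {
  set.seed(seed)
  stopifnot(length(genes) >= size_range[1])
  rows <- lapply(seq_len(n_terms), function(i) {
    sz <- min(length(genes),
              round(exp(stats::runif(1, log(size_range[1]),
                                     log(min(size_range[2], length(genes)))))))
    data.frame(gene = sample(genes, sz),
               term = sprintf("T%04d", i),
               name = sprintf("synthetic term %d", i),
               namespace = namespace, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
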