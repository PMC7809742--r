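# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different code paths (regex / adjacency closure /
# log-choose sums / subset enumeration) from the functions under test.

# literal re-application of the tail-clipping rules via regex stripping
oracle_trim <- function(read, anchor_len = 8L, stop_non_a = 2L,
                        min_body_len = 11L) {
  if (nchar(read) == 0L) return(list(body = read, kept = FALSE))
  m <- gregexpr(sprintf("A{%d,}", anchor_len), read)[[1]]
  if (m[1] == -1L) return(list(body = read, kept = FALSE))
  s <- m[length(m)]                      # 3'-most qualifying run
  body <- substr(read, 1L, s - 1L)
  repeat {
    body2 <- sub("A+$", "", body)        # strip trailing As
    if (nchar(body2) == 0L) { body <- body2; break }
    run <- nchar(body2) - nchar(sub("[^A]+$", "", body2))
    if (run >= stop_non_a) { body <- body2; break }
    body <- substr(body2, 1L, nchar(body2) - 1L)   # isolated non-A clipped
  }
  list(body = body, kept = nchar(body) > min_body_len)
}

random_read_mix <- function(n, len = 60L) {
  vapply(seq_len(n), function(i) {
    body <- paste(sample(c("A", "C", "G", "T"), sample(10:len, 1L),
                         replace = TRUE, prob = c(0.35, 0.2, 0.2, 0.25)),
                  collapse = "")
    kind <- sample(3L, 1L)
    if (kind == 1L) return(body)                       # maybe no tail at all
    tail <- strrep("A", sample(8:30, 1L))
    if (kind == 3L && nchar(tail) > 10L) {             # error inside tail
      k <- sample(2:(nchar(tail) - 2L), 1L)
      substr(tail, k, k) <- sample(c("C", "G", "T"), 1L)
    }
    paste0(body, tail)
  }, "")
}

# transitive closure of |pos_i - pos_j| <= link, as a partition of indices
oracle_point_components <- function(pos, link) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, `-`)) <= link
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# same closure on intervals [start, end) with edge gap start_j - end_i
oracle_interval_components <- function(start, end, link) {
  n <- length(start)
  gap <- function(i, j) max(start[i], start[j]) - min(end[i], end[j])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) adj[i, j] <- gap(i, j) <= link
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# upper-tail hypergeometric probability by explicit log-choose term sums
oracle_hyper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  j <- j[n - j <= N - K]
  if (length(j) == 0L) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# exact two-sample KS p by enumeration of all splits of the pooled sample
oracle_ks_perm <- function(xt, xc) {
  pooled <- c(xt, xc)
  nt <- length(xt)
  Dof <- function(a, b) {
    grid <- sort(unique(pooled))
    max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  }
  D0 <- Dof(xt, xc)
  splits <- utils::combn(length(pooled), nt)
  dperm <- apply(splits, 2L, function(idx) Dof(pooled[idx], pooled[-idx]))
  mean(dperm >= D0 - 1e-12)
}

# pas_sites builder for hand-made fixtures
make_sites <- function(pos, count, strand = "+", chrom = "chr1",
                       total = sum(count)) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                   count = as.integer(count), stringsAsFactors = FALSE)
  class(df) <- c("pas_sites", "data.frame")
  compute_tpm(df, total = total)
}

# distribution object as gene_site_distribution would return it
make_dist <- function(axis, counts) {
  o <- order(axis)
  list(axis = axis[o], pos = axis[o], w = counts[o] / sum(counts),
       counts = counts[o], n = sum(counts))
}
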