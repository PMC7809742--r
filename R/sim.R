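#' Configuration for the synthetic PAS-seq data generator
#'
#' Builds and validates the full parameter set of the simulator: a toy genome
#' with annotated genes, planted polyA-site clusters (PACs) with
#' condition-dependent usage, planted polyadenylation signals, antisense
#' sites, and polyA-tailed reads. Identical configurations (same seed) yield
#' byte-identical outputs.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_genes Number of genes to place.
#' @param genome_len Genome length in nt, or \code{NULL} to size automatically
#'   from the placed genes.
#' @param conditions Condition labels; the first is the control.
#' @param pacs_per_gene Probabilities for 1, 2 or 3 sense 3'UTR PACs per gene.
#' @param utr3_len,utr5_len,cds_len,intron_len,intergenic_gap Length ranges
#'   (nt, inclusive); CDS lengths are rounded to codon multiples.
#' @param n_introns Range of intron counts per gene.
#' @param tail_len PolyA tail length model: list with \code{mean}, \code{sd},
#'   \code{min} (>= 8 so tails are anchorable) and \code{max}.
#' @param reads_per_gene Mean reads per gene per condition (Poisson).
#' @param shift_fraction Fraction of multi-PAC genes whose usage shifts in a
#'   given treatment relative to control.
#' @param shift_effect Change in proximal-usage proportion for shifted genes
#'   (e.g. 0.4 turns 0.7/0.3 into 0.3/0.7).
#' @param antisense_fraction_control,antisense_fraction_treatment Proportions
#'   of genes carrying an expressed antisense site in control / treatments.
#' @param cds_site_fraction,utr5_site_fraction,intron_site_fraction
#'   Proportions of genes receiving one extra non-canonical sense site.
#' @param extra_site_usage Usage slice allocated to an extra (non-canonical or
#'   antisense) site; sense 3'UTR usage is rescaled accordingly.
#' @param nue_motif,nue_offset Near-upstream element hexamer and the transcript
#'   offset of its first base relative to the cleavage base (0 = cleavage).
#' @param downstream_motif,downstream_offset Downstream signal hexamer and its
#'   start offset (positive = downstream of cleavage).
#' @param downstream_motif_mode \code{"all"} plants the downstream motif at
#'   every site; \code{"control_only"} omits it at treatment-dominant sites of
#'   shifted genes (a heat-like fixture lacking the downstream signal at
#'   stress-induced PACs).
#' @param site_scatter Probabilities of cleavage micro-heterogeneity offsets
#'   -2..+2 nt along the transcript.
#' @param proximal_offset Transcript offset of the proximal PAC into the 3'UTR.
#' @param distal_gap Distance of the distal PAC from the 3'UTR end.
#' @param noise_rate Per-base substitution probability applied to reads.
#' @param read_len Read length (nt).
#' @param base_probs Background nucleotide composition.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, genome_len = NULL,
                       conditions = c("CK", "HT", "LT"),
                       pacs_per_gene = c(0.35, 0.45, 0.20),
                       utr3_len = c(320L, 450L), utr5_len = c(100L, 200L),
                       cds_len = c(300L, 900L), n_introns = c(0L, 2L),
                       intron_len = c(60L, 120L),
                       intergenic_gap = c(200L, 500L),
                       tail_len = list(mean = 35, sd = 12, min = 8, max = 60),
                       reads_per_gene = 100,
                       shift_fraction = 0.3, shift_effect = 0.4,
                       antisense_fraction_control = 0.05,
                       antisense_fraction_treatment = 0.10,
                       cds_site_fraction = 0.04, utr5_site_fraction = 0.02,
                       intron_site_fraction = 0.02, extra_site_usage = 0.1,
                       nue_motif = "AATAAA", nue_offset = -25L,
                       downstream_motif = "AAAAAA", downstream_offset = 5L,
                       downstream_motif_mode = c("all", "control_only"),
                       site_scatter = c(0.1, 0.2, 0.4, 0.2, 0.1),
                       proximal_offset = 45L, distal_gap = 20L,
                       noise_rate = 0.005, read_len = 100L,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  downstream_motif_mode <- match.arg(downstream_motif_mode)
  props <- c(shift_fraction, antisense_fraction_control,
             antisense_fraction_treatment, cds_site_fraction,
             utr5_site_fraction, intron_site_fraction, extra_site_usage,
             noise_rate)
  stopifnot(all(props >= 0 & props <= 1),
            tail_len$min >= 8,
            tail_len$max < read_len,
            length(pacs_per_gene) == 3, abs(sum(pacs_per_gene) - 1) < 1e-8,
            length(site_scatter) == 5, abs(sum(site_scatter) - 1) < 1e-8,
            shift_effect > 0, shift_effect <= 0.8,
            length(conditions) >= 2,
            antisense_fraction_control <= antisense_fraction_treatment,
            nchar(nue_motif) == 6, nchar(downstream_motif) == 6)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              genome_len = if (is.null(genome_len)) NULL else as.integer(genome_len),
              conditions = conditions, pacs_per_gene = pacs_per_gene,
              utr3_len = as.integer(utr3_len), utr5_len = as.integer(utr5_len),
              cds_len = as.integer(cds_len), n_introns = as.integer(n_introns),
              intron_len = as.integer(intron_len),
              intergenic_gap = as.integer(intergenic_gap),
              tail_len = tail_len, reads_per_gene = reads_per_gene,
              shift_fraction = shift_fraction, shift_effect = shift_effect,
              antisense_fraction_control = antisense_fraction_control,
              antisense_fraction_treatment = antisense_fraction_treatment,
              cds_site_fraction = cds_site_fraction,
              utr5_site_fraction = utr5_site_fraction,
              intron_site_fraction = intron_site_fraction,
              extra_site_usage = extra_site_usage,
              nue_motif = nue_motif, nue_offset = as.integer(nue_offset),
              downstream_motif = downstream_motif,
              downstream_offset = as.integer(downstream_offset),
              downstream_motif_mode = downstream_motif_mode,
              site_scatter = site_scatter,
              proximal_offset = as.integer(proximal_offset),
              distal_gap = as.integer(distal_gap),
              noise_rate = noise_rate, read_len = as.integer(read_len),
              base_probs = base_probs)
  class(cfg) <- "sim_config"
  cfg
}

.rint <- function(n, range) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a character vector of sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Plant `motif` (given in transcript orientation) so that its first base sits
# at transcript offset `offset` relative to cleavage base `p` (0-based genomic)
# on `strand`. Writes complemented bases for "-" sites. Returns edited chars.
.plant_motif <- function(chars, p, strand, offset, motif) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  dir <- if (strand == "+") 1L else -1L
  g <- p + dir * (offset + seq_along(m) - 1L)
  ok <- g >= 0L & g < length(chars)
  if (strand == "-") m <- unname(.comp[m])
  chars[g[ok] + 1L] <- m[ok]
  chars
}

# genomic position of transcript-offset `o` within a block [s,e) on `strand`
.block_pos <- function(s, e, o, strand) {
  if (strand == "+") s + o else e - 1L - o
}

#' Generate a toy genome with annotated genes and planted polyA sites
#'
#' Places non-overlapping genes on both strands, each with 5'UTR, CDS
#' (codon-multiple length, ATG start, TAA stop, GT..AG introns) and 3'UTR.
#' Plans every planted cleavage site (sense 3'UTR PACs, optional CDS / 5'UTR /
#' intronic / antisense extras), per-condition usage proportions and shifted
#' genes, and plants the sequence signals: a T,C guard immediately upstream of
#' the cleavage base (so tail clipping lands deterministically), the NUE
#' hexamer upstream, and the downstream signal hexamer.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{sim_genome} with \code{seq} (genome string),
#'   \code{chrom}, \code{features} / \code{genes} data frames (0-based
#'   half-open coordinates) and \code{truth} (planted sites with per-condition
#'   usage, shifted genes, antisense sites).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  conds <- config$conditions
  treatments <- conds[-1]

  genes <- list(); feats <- list(); sites <- list(); shifts <- list()
  cursor <- 0L
  for (i in seq_len(max(n, 0L))) {
    gid <- sprintf("g%04d", i)
    strand <- sample(c("+", "-"), 1L)
    u5 <- .rint(1L, config$utr5_len)
    cds_total <- 3L * .rint(1L, c(ceiling(config$cds_len[1] / 3),
                                  floor(config$cds_len[2] / 3)))
    nint <- .rint(1L, config$n_introns)
    ilens <- if (nint > 0) .rint(nint, config$intron_len) else integer(0)
    u3 <- .rint(1L, config$utr3_len)
    gap <- .rint(1L, config$intergenic_gap)

    # CDS split into nint+1 chunks, each >= 60 nt, genomically interleaved
    nchunk <- nint + 1L
    base <- cds_total %/% nchunk
    clens <- rep(base, nchunk)
    clens[nchunk] <- clens[nchunk] + cds_total - sum(clens)
    tx_types <- c("five_prime_UTR",
                  as.vector(rbind(rep("CDS", nchunk),
                                  c(rep("intron", nint), NA))),
                  "three_prime_UTR")
    tx_types <- tx_types[!is.na(tx_types)]
    tx_lens <- c(u5, as.vector(rbind(clens, c(ilens, NA))), u3)
    tx_lens <- as.integer(tx_lens[!is.na(tx_lens)])
    gene_len <- sum(tx_lens)
    cursor <- cursor + gap
    g0 <- cursor
    cursor <- cursor + gene_len

    gen_order <- if (strand == "+") seq_along(tx_lens) else rev(seq_along(tx_lens))
    gen_lens <- tx_lens[gen_order]
    gen_starts <- g0 + cumsum(c(0L, head(gen_lens, -1L)))
    bl <- data.frame(type = tx_types[gen_order], start = gen_starts,
                     end = gen_starts + gen_lens, tx_rank = gen_order,
                     stringsAsFactors = FALSE)
    bl <- bl[order(bl$tx_rank), ]            # back in transcript order
    feats[[i]] <- data.frame(gene = gid, type = bl$type, start = bl$start,
                             end = bl$end, strand = strand,
                             stringsAsFactors = FALSE)
    genes[[i]] <- data.frame(gene = gid, strand = strand, start = g0,
                             end = g0 + gene_len, stringsAsFactors = FALSE)

    # ---- plan sense 3'UTR PACs along the transcript axis of the 3'UTR
    ub <- bl[bl$type == "three_prime_UTR", ]
    npac <- sample(1:3, 1L, prob = config$pacs_per_gene)
    tx_off <- switch(npac,
      `1` = u3 - 1L - config$distal_gap,
      `2` = c(config$proximal_offset, u3 - 1L - config$distal_gap),
      `3` = {
        pd <- c(config$proximal_offset, u3 - 1L - config$distal_gap)
        c(pd[1], (pd[1] + pd[2]) %/% 2L, pd[2])
      })
    pac_pos <- vapply(tx_off, function(o)
      .block_pos(ub$start, ub$end, o, strand), 0L)
    site_df <- data.frame(gene = gid, pos = pac_pos, strand = strand,
                          category = "UTR3",
                          role = c("proximal", "middle", "distal")[
                            if (npac == 1) 3L else if (npac == 2) c(1L, 3L)
                            else 1:3],
                          stringsAsFactors = FALSE)

    # ---- usage: control dominance end chosen at random; shifts flip it
    e <- config$shift_effect
    dom_prox <- sample(c(TRUE, FALSE), 1L)
    # flipping dominance between the end sites changes proximal usage by
    # exactly shift_effect
    usage_for <- function(prox_dominant) {
      if (npac == 1) return(1)
      mid <- if (npac == 3) 0.2 else 0
      ends <- c((1 - mid) / 2 + e / 2, (1 - mid) / 2 - e / 2)
      if (!prox_dominant) ends <- rev(ends)
      if (npac == 2) ends else c(ends[1], mid, ends[2])
    }
    usage <- matrix(rep(usage_for(dom_prox), length(conds)),
                    ncol = length(conds),
                    dimnames = list(NULL, conds))
    shifted_in <- if (npac >= 2) {
      treatments[stats::runif(length(treatments)) < config$shift_fraction]
    } else character(0)
    for (tr in shifted_in) {
      usage[, tr] <- usage_for(!dom_prox)
      dom_c <- site_df$pos[which.max(usage[, conds[1]])]
      dom_t <- site_df$pos[which.max(usage[, tr])]
      shifts[[length(shifts) + 1L]] <- data.frame(
        gene = gid, condition = tr,
        direction = if (dom_prox) "lengthening" else "shortening",
        distance = abs(dom_t - dom_c), stringsAsFactors = FALSE)
    }

    # ---- one optional extra site: CDS / 5'UTR / intron / antisense lottery
    pr <- c(config$cds_site_fraction, config$utr5_site_fraction,
            if (nint > 0) config$intron_site_fraction else 0,
            config$antisense_fraction_treatment)
    pick <- sample.int(5L, 1L, prob = c(pr, max(0, 1 - sum(pr))))
    extra <- NULL
    if (pick <= 4L) {
      kind <- c("CDS", "UTR5", "intron", "antisense")[pick]
      blk <- switch(kind,
        CDS = bl[bl$type == "CDS", ][1L, ],
        UTR5 = bl[bl$type == "five_prime_UTR", ],
        intron = bl[bl$type == "intron", ][1L, ],
        antisense = bl[bl$type == "CDS", ][1L, ])
      mid <- (blk$end - blk$start) %/% 2L
      estrand <- if (kind == "antisense") setdiff(c("+", "-"), strand) else strand
      epos <- .block_pos(blk$start, blk$end, mid,
                         if (kind == "antisense") estrand else strand)
      active <- if (kind == "antisense") {
        act <- rep(TRUE, length(conds)); names(act) <- conds
        keep_ctl <- stats::runif(1) <
          config$antisense_fraction_control / config$antisense_fraction_treatment
        act[conds[1]] <- keep_ctl
        # antisense induction is a treatment effect: active in treatments
        act
      } else {
        stats::setNames(rep(TRUE, length(conds)), conds)
      }
      extra <- list(pos = epos, strand = estrand, category = kind,
                    active = active)
    }
    if (!is.null(extra)) {
      eu <- ifelse(extra$active[conds], config$extra_site_usage, 0)
      usage <- sweep(usage, 2L, 1 - eu, `*`)
      usage <- rbind(usage, eu)
      site_df <- rbind(site_df, data.frame(
        gene = gid, pos = extra$pos, strand = extra$strand,
        category = if (extra$category == "antisense") "antisense" else extra$category,
        role = "extra", stringsAsFactors = FALSE))
    }
    colnames(usage) <- conds
    site_df <- cbind(site_df, as.data.frame(usage))
    sites[[i]] <- site_df
  }

  genes <- if (n > 0) do.call(rbind, genes) else
    data.frame(gene = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  feats <- if (n > 0) do.call(rbind, feats) else
    data.frame(gene = character(0), type = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  truth_sites <- if (n > 0) do.call(rbind, sites) else
    data.frame(gene = character(0), pos = integer(0), strand = character(0),
               category = character(0), role = character(0))
  truth_shifts <- if (length(shifts) > 0) do.call(rbind, shifts) else
    data.frame(gene = character(0), condition = character(0),
               direction = character(0), distance = integer(0))

  needed <- cursor + if (n > 0) config$intergenic_gap[2] else 0L
  glen <- if (is.null(config$genome_len)) max(needed, 1000L) else config$genome_len
  if (glen < needed) {
    stop(sprintf("genome_len %d too small for %d genes (need >= %d)",
                 glen, n, needed))
  }
  chars <- sample(names(config$base_probs), glen, replace = TRUE,
                  prob = config$base_probs)

  if (n > 0) {
    # codon landmarks and splice dinucleotides
    for (gid in genes$gene) {
      fb <- feats[feats$gene == gid, ]
      strand <- fb$strand[1]
      cds <- fb[fb$type == "CDS", ]
      tx_first <- if (strand == "+") cds[1L, ] else cds[nrow(cds), ]
      tx_last <- if (strand == "+") cds[nrow(cds), ] else cds[1L, ]
      chars <- .plant_motif(chars, .block_pos(tx_first$start, tx_first$end, 0L, strand),
                            strand, 0L, "ATG")
      stop_first <- .block_pos(tx_last$start, tx_last$end,
                               (tx_last$end - tx_last$start) - 3L, strand)
      chars <- .plant_motif(chars, stop_first, strand, 0L, "TAA")
      for (k in which(fb$type == "intron")) {
        s <- fb$start[k]; e <- fb$end[k]
        chars <- .plant_motif(chars, .block_pos(s, e, 0L, strand), strand, 0L, "GT")
        chars <- .plant_motif(chars, .block_pos(s, e, e - s - 2L, strand), strand, 0L, "AG")
      }
    }
    # cleavage-site signals
    skip_downstream <- character(0)
    if (config$downstream_motif_mode == "control_only" &&
        nrow(truth_shifts) > 0) {
      for (r in seq_len(nrow(truth_shifts))) {
        gid <- truth_shifts$gene[r]; tr <- truth_shifts$condition[r]
        sd0 <- truth_sites[truth_sites$gene == gid & truth_sites$category == "UTR3", ]
        dom_t <- sd0$pos[which.max(sd0[[tr]])]
        skip_downstream <- c(skip_downstream, paste0(gid, ":", dom_t))
      }
    }
    for (r in seq_len(nrow(truth_sites))) {
      p <- truth_sites$pos[r]; s <- truth_sites$strand[r]
      chars <- .plant_motif(chars, p, s, -2L, "TCA")
      chars <- .plant_motif(chars, p, s, config$nue_offset, config$nue_motif)
      key <- paste0(truth_sites$gene[r], ":", p)
      if (!(key %in% skip_downstream)) {
        chars <- .plant_motif(chars, p, s, config$downstream_offset,
                              config$downstream_motif)
      }
    }
  }

  structure(list(config = config, chrom = "chr1",
                 seq = paste(chars, collapse = ""),
                 features = feats, genes = genes,
                 truth = list(sites = truth_sites, shifts = truth_shifts,
                              antisense = truth_sites[
                                truth_sites$category == "antisense",
                                c("gene", "pos", "strand")])),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d nt, %d genes, %d planted sites (%d antisense), %d planted shifts\n",
              nchar(x$seq), nrow(x$genes), nrow(x$truth$sites),
              nrow(x$truth$antisense), nrow(x$truth$shifts)))
  invisible(x)
}

#' Generate PAS-seq reads from a simulated genome
#'
#' Draws per-gene read counts (Poisson), allocates them to the gene's planted
#' sites by a multinomial on that condition's usage proportions, applies
#' cleavage micro-heterogeneity, appends a truncated-normal polyA tail,
#' truncates to the read length and applies substitution noise. Reads whose
#' body would run off the chromosome are skipped with a warning.
#'
#' @param config The \code{\link{sim_config}} used to build \code{sim}.
#' @param sim A \code{\link{generate_genome}} result.
#' @return A list of class \code{sim_reads}: per condition a data.frame with
#'   \code{id} and \code{seq}; plus \code{truth} carried over and
#'   \code{n_skipped}.
#' @export
generate_reads <- function(config, sim) {
  stopifnot(inherits(sim, "sim_genome"))
  set.seed(config$seed + 1000003L)
  glen <- nchar(sim$seq)
  ts <- sim$truth$sites
  scatter_off <- -2:2
  out <- list()
  n_skipped <- 0L
  for (cond in config$conditions) {
    recs <- list()
    for (gid in unique(ts$gene)) {
      sd0 <- ts[ts$gene == gid, ]
      usage <- sd0[[cond]]
      nr <- stats::rpois(1L, config$reads_per_gene)
      if (nr == 0L || sum(usage) <= 0) next
      cnt <- as.vector(stats::rmultinom(1L, nr, usage))
      for (j in seq_len(nrow(sd0))) {
        if (cnt[j] == 0L) next
        p <- sd0$pos[j]; strand <- sd0$strand[j]
        delta <- sample(scatter_off, cnt[j], replace = TRUE,
                        prob = config$site_scatter)
        tl <- pmin(pmax(round(stats::rnorm(cnt[j], config$tail_len$mean,
                                           config$tail_len$sd)),
                        config$tail_len$min), config$tail_len$max)
        blen <- config$read_len - tl
        q <- if (strand == "+") p + delta else p - delta
        if (strand == "+") {
          s0 <- q - blen + 1L; s1 <- q
        } else {
          s0 <- q; s1 <- q + blen - 1L
        }
        ok <- s0 >= 0L & s1 < glen
        n_skipped <- n_skipped + sum(!ok)
        if (!any(ok)) next
        body <- substring(sim$seq, s0[ok] + 1L, s1[ok] + 1L)
        if (strand == "-") body <- revcomp(body)
        recs[[length(recs) + 1L]] <-
          paste0(body, strrep("A", tl[ok]))
      }
    }
    seqs <- unlist(recs)
    if (is.null(seqs)) seqs <- character(0)
    # substitution noise, batched over reads that draw >= 1 error
    if (config$noise_rate > 0 && length(seqs) > 0) {
      nerr <- stats::rbinom(length(seqs), nchar(seqs), config$noise_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(nchar(seqs[i]), nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    out[[cond]] <- data.frame(
      id = sprintf("%s:read%06d", cond, seq_along(seqs)),
      seq = seqs, stringsAsFactors = FALSE)
  }
  if (n_skipped > 0) {
    warning(sprintf("%d reads skipped: body extends past chromosome bounds",
                    n_skipped))
  }
  structure(list(reads = out, truth = sim$truth, n_skipped = n_skipped),
            class = "sim_reads")
}

#' Write simulator outputs to disk
#'
#' Emits genome FASTA, annotation GFF3 (1-based inclusive), one FASTQ per
#' condition (Phred+33, constant quality) and the truth ledger as TSV files.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the \code{sim_genome}, \code{sim_reads} and
#'   all file \code{paths}.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome(config)
  rd <- generate_reads(config, sim)
  paths <- list(genome = file.path(dir, "genome.fasta"),
                annotation = file.path(dir, "annotation.gff3"),
                truth_sites = file.path(dir, "truth_sites.tsv"),
                truth_shifts = file.path(dir, "truth_shifts.tsv"),
                truth_antisense = file.path(dir, "truth_antisense.tsv"))
  g <- Biostrings::DNAStringSet(sim$seq)
  names(g) <- sim$chrom
  Biostrings::writeXStringSet(g, paths$genome)
  write_gff3(sim, paths$annotation)
  for (cond in config$conditions) {
    fp <- file.path(dir, sprintf("reads_%s.fastq", cond))
    paths[[paste0("reads_", cond)]] <- fp
    rr <- rd$reads[[cond]]
    x <- Biostrings::DNAStringSet(rr$seq)
    names(x) <- rr$id
    Biostrings::writeXStringSet(x, fp, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  strrep("I", nchar(rr$seq))))
  }
  wtsv <- function(df, fp) utils::write.table(
    df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(cbind(chrom = sim$chrom, sim$truth$sites), paths$truth_sites)
  wtsv(sim$truth$shifts, paths$truth_shifts)
  wtsv(sim$truth$antisense, paths$truth_antisense)
  invisible(list(sim = sim, reads = rd, paths = paths))
}

#' Write a simulated annotation as GFF3
#'
#' @param sim A \code{\link{generate_genome}} result.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(sim, path) {
  lines <- "##gff-version 3"
  fe <- sim$features
  for (gid in sim$genes$gene) {
    ge <- sim$genes[sim$genes$gene == gid, ]
    fb <- fe[fe$gene == gid & fe$type != "intron", ]
    lines <- c(lines,
      sprintf("%s\tpacshift_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              sim$chrom, ge$start + 1L, ge$end, ge$strand, gid),
      sprintf("%s\tpacshift_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              sim$chrom, ge$start + 1L, ge$end, ge$strand, gid, gid),
      sprintf("%s\tpacshift_sim\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s.1",
              sim$chrom, fb$type, fb$start + 1L, fb$end, fb$strand,
              ifelse(fb$type == "CDS", "0", "."), gid))
  }
  writeLines(lines, path)
  invisible(path)
}
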