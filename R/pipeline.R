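#' Build (or load) a pipeline configuration
#'
#' A single configuration object drives \code{\link{run_pipeline}}: input
#' paths (or the synthetic generator), per-stage parameters and the seed.
#' Configurations serialize losslessly to YAML via \code{\link{write_config}}
#' / \code{\link{read_config}}.
#'
#' @param outdir Output directory.
#' @param simulate If \code{TRUE}, generate the inputs with the synthetic
#'   module using \code{sim} (a \code{\link{sim_config}} or argument list).
#' @param sim Simulator configuration (used when \code{simulate}).
#' @param genome,annotation,reads Paths to genome FASTA, GFF3 annotation and
#'   a named list (by condition) of FASTQ files; required when
#'   \code{simulate = FALSE}.
#' @param control Control condition label (default: first read set).
#' @param trim,cluster,shift Stage parameter objects (or argument lists).
#' @param term_annotation Optional gene-to-term TSV (gene, term, name,
#'   namespace) for enrichment; a synthetic table is generated when absent.
#' @param seed Seed for every stochastic stage.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(outdir, simulate = TRUE, sim = sim_config(),
                            genome = NULL, annotation = NULL, reads = NULL,
                            control = NULL, trim = trim_params(),
                            cluster = cluster_params(),
                            shift = shift_params(),
                            term_annotation = NULL, seed = 1L) {
  if (is.list(sim) && !inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  if (is.list(trim) && !inherits(trim, "trim_params")) trim <- do.call(trim_params, trim)
  if (is.list(cluster) && !inherits(cluster, "cluster_params")) cluster <- do.call(cluster_params, cluster)
  if (is.list(shift) && !inherits(shift, "shift_params")) shift <- do.call(shift_params, shift)
  cfg <- structure(list(outdir = outdir, simulate = isTRUE(simulate),
                        sim = sim, genome = genome, annotation = annotation,
                        reads = reads, control = control, trim = trim,
                        cluster = cluster, shift = shift,
                        term_annotation = term_annotation,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration before any stage runs
#'
#' @param config A \code{pipeline_config}.
#' @return Invisibly \code{TRUE}; errors describe the first problem found.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$simulate) {
    for (fld in c("genome", "annotation")) {
      if (is.null(config[[fld]])) {
        stop("config missing required path: ", fld)
      }
      if (!file.exists(config[[fld]])) {
        stop("config path does not exist: ", fld, " = ", config[[fld]])
      }
    }
    if (is.null(config$reads) || length(config$reads) < 2L ||
        is.null(names(config$reads))) {
      stop("config must name >= 2 per-condition FASTQ files in `reads`")
    }
    missing <- !vapply(config$reads, file.exists, TRUE)
    if (any(missing)) {
      stop("read files do not exist: ",
           paste(unlist(config$reads[missing]), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns the reconstructed \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  for (f in c("sim", "trim", "cluster", "shift")) x[[f]] <- unclass(x[[f]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$sim
  if (!is.null(sim$tail_len)) sim$tail_len <- as.list(sim$tail_len)
  if (!is.null(sim$base_probs)) sim$base_probs <- unlist(sim$base_probs)
  pipeline_config(outdir = x$outdir, simulate = x$simulate,
                  sim = do.call(sim_config, sim),
                  genome = x$genome, annotation = x$annotation,
                  reads = x$reads, control = x$control,
                  trim = do.call(trim_params, x$trim),
                  cluster = do.call(cluster_params, x$cluster),
                  shift = do.call(shift_params, x$shift),
                  term_annotation = x$term_annotation, seed = x$seed)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full PAS-seq analysis pipeline
#'
#' Executes (optionally) simulate, then trim, map/ingest, site extraction,
#' categorization, per-sample clustering, cross-sample consensus, APA shift
#' calling per treatment, signal profiling, the antisense test and functional
#' enrichment, writing plain-text tables for every stage plus a YAML run
#' manifest (parameters, seed, input checksums). A stage failure halts with
#' the stage name; completed outputs are retained.
#'
#' @param config A \code{\link{pipeline_config}} (or path to its YAML).
#' @return Invisibly, a list with the main in-memory results
#'   (\code{consensus} PAC set, \code{shifts}, \code{antisense},
#'   \code{enrichment}, \code{recovery} when simulated) and \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  truth <- NULL
  if (config$simulate) {
    simdir <- file.path(config$outdir, "sim")
    ds <- stage("simulate", simulate_dataset(config$sim, simdir))
    config$genome <- ds$paths$genome
    config$annotation <- ds$paths$annotation
    config$reads <- stats::setNames(
      lapply(config$sim$conditions, function(cd)
        ds$paths[[paste0("reads_", cd)]]),
      config$sim$conditions)
    truth <- ds$sim$truth
  }
  control <- if (!is.null(config$control)) config$control else
    names(config$reads)[1]
  conds <- names(config$reads)
  treatments <- setdiff(conds, control)

  ann <- stage("annotation", read_annotation(config$annotation))
  genome_set <- Biostrings::readDNAStringSet(config$genome)
  idx <- stage("index", kmer_index(unname(as.character(genome_set))[1]))

  per_cond <- list()
  trim_stats <- list()
  for (cd in conds) {
    body_fq <- file.path(config$outdir, sprintf("bodies_%s.fastq", cd))
    st <- stage("trim", trim_fastq(config$reads[[cd]], body_fq, config$trim))
    trim_stats[[cd]] <- data.frame(condition = cd, n_input = st$n_input,
                                   n_kept = st$n_kept,
                                   n_discarded = st$n_discarded,
                                   mean_tail_len = st$mean_tail_len)
    aln <- stage("map", map_reads(body_fq, idx))
    sites <- stage("sites", extract_sites(aln))
    sites <- categorize_sites(sites, ann)
    .write_tsv(sites, file.path(config$outdir, sprintf("sites_%s.tsv", cd)))
    clustered <- stage("cluster",
                       cluster_sites(sites, config$cluster, sample = cd))
    clustered <- annotate_pacs(clustered, ann)
    per_cond[[cd]] <- list(sites = sites, pacs = clustered)
  }
  .write_tsv(do.call(rbind, trim_stats),
             file.path(config$outdir, "trim_stats.tsv"))

  consensus <- stage("merge", merge_pacs(
    lapply(per_cond, `[[`, "pacs"), config$cluster))
  consensus <- annotate_pacs(consensus, ann)
  combined <- filter_pacs(consensus, "combined", config$cluster)
  .write_tsv(combined$pacs, file.path(config$outdir, "pacs_combined.tsv"))

  shifts <- list()
  for (tr in treatments) {
    sr <- stage("shift", call_shifts(consensus, tr, control,
                                     config$shift, config$cluster))
    .write_tsv(sr, file.path(config$outdir,
                             sprintf("shifts_%s_vs_%s.tsv", tr, control)))
    shifts[[tr]] <- sr
  }
  overlap <- if (length(shifts) >= 2L) shift_overlap(shifts) else NULL

  genome_seq <- as.character(genome_set)
  names(genome_seq) <- sub("\\s.*", "", names(genome_set))
  prof <- stage("motif", {
    win <- extract_windows(combined$pacs, genome_seq)
    hx <- hexamer_scan(win)
    .write_tsv(hx$ranking, file.path(config$outdir, "hexamer_top30.tsv"))
    comp <- base_composition(win)
    .write_tsv(data.frame(offset = colnames(comp), t(comp)),
               file.path(config$outdir, "base_composition.tsv"))
    hx
  })

  antis <- stage("antisense", {
    cn <- count_antisense(lapply(per_cond, `[[`, "pacs"))
    at <- antisense_test(cn$antisense, cn$total, control)
    .write_tsv(at, file.path(config$outdir, "antisense_test.tsv"))
    at
  })

  enr <- stage("enrich", {
    term_ann <- if (!is.null(config$term_annotation)) {
      utils::read.delim(config$term_annotation, stringsAsFactors = FALSE)
    } else {
      generate_term_annotation(ann$genes$gene, seed = config$seed)
    }
    universe <- unique(stats::na.omit(consensus$pacs$gene))
    out <- list()
    for (tr in names(shifts)) {
      q <- intersect(shifts[[tr]]$gene[shifts[[tr]]$significant], universe)
      if (length(q)) {
        e <- hypergeom_enrich(q, term_ann, universe = universe)
        .write_tsv(e, file.path(config$outdir,
                                sprintf("enrichment_%s.tsv", tr)))
        out[[tr]] <- e
      }
    }
    out
  })

  recovery <- if (!is.null(truth)) {
    benchmark_recovery(truth$sites, consensus)
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("pacshift")),
    seed = config$seed,
    control = control, conditions = conds,
    parameters = list(trim = unclass(config$trim),
                      cluster = unclass(config$cluster),
                      shift = unclass(config$shift)),
    input_md5 = as.list(tools::md5sum(c(genome = config$genome,
                                        annotation = config$annotation,
                                        unlist(config$reads)))),
    n_consensus_pacs = nrow(consensus$pacs),
    n_combined_pacs = nrow(combined$pacs),
    n_significant_shifts = vapply(shifts, function(s) sum(s$significant), 0L))
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))

  invisible(list(annotation = ann, per_condition = per_cond,
                 consensus = consensus, combined = combined,
                 shifts = shifts, overlap = overlap, signal = prof,
                 antisense = antis, enrichment = enr, recovery = recovery,
                 truth = truth, manifest = manifest))
}

#' Planted-versus-called PAC recovery
#'
#' Matches every planted cleavage site against the consensus PAC catalogue:
#' a site is recovered when a same-strand PAC representative position lies
#' within \code{tol} nt.
#'
#' @param truth_sites The generator's planted-site table.
#' @param pac_set Consensus \code{pac_set} called from the simulated reads.
#' @param tol Matching tolerance in nt.
#' @return A list with \code{n_planted}, \code{n_recovered},
#'   \code{recovery} (fraction), \code{n_called} and \code{n_unplanted}
#'   (called PACs matching no planted site).
#' @export
benchmark_recovery <- function(truth_sites, pac_set, tol = 5L) {
  pp <- pac_set$pacs
  hit <- vapply(seq_len(nrow(truth_sites)), function(i) {
    any(pp$strand == truth_sites$strand[i] &
          abs(pp$rep_pos - truth_sites$pos[i]) <= tol)
  }, TRUE)
  called_hit <- vapply(seq_len(nrow(pp)), function(j) {
    any(truth_sites$strand == pp$strand[j] &
          abs(truth_sites$pos - pp$rep_pos[j]) <= tol)
  }, TRUE)
  list(n_planted = nrow(truth_sites), n_recovered = sum(hit),
       recovery = mean(hit), n_called = nrow(pp),
       n_unplanted = sum(!called_hit))
}
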