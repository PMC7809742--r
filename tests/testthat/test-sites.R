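# small two-gene annotation used across these tests:
#   gA on + : UTR5 [100,150) CDS [150,300) intron [300,360) CDS [360,450)
#             UTR3 [450,600); TTS 599, stop codon last base 449
#   gB on - : span [800,1100); UTR3 [800,950) CDS [950,1050) UTR5 [1050,1100)
#             TTS 800, stop codon last base 950
toy_annotation <- function() {
  genes <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), start = c(100L, 800L),
                      end = c(600L, 1100L), stringsAsFactors = FALSE)
  feats <- data.frame(
    gene = c("gA", "gA", "gA", "gA", "gB", "gB", "gB"),
    chrom = "chr1",
    strand = c(rep("+", 4), rep("-", 3)),
    type = c("five_prime_UTR", "CDS", "CDS", "three_prime_UTR",
             "three_prime_UTR", "CDS", "five_prime_UTR"),
    start = c(100L, 150L, 360L, 450L, 800L, 950L, 1050L),
    end = c(150L, 300L, 450L, 600L, 950L, 1050L, 1100L),
    stringsAsFactors = FALSE)
  pacshift:::.build_annotation(genes, feats)
}

test_that("cleavage position is the 3'-most aligned base on the read strand", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = 101L, end = 150L),
                               strand = c("+"))
  s <- extract_sites(gr)
  expect_equal(s$pos, 149L)
  expect_equal(s$count, 1L)
  gr_minus <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(start = 101L, end = 150L),
                                     strand = "-")
  expect_equal(extract_sites(gr_minus)$pos, 100L)
})

test_that("identical positions aggregate and TPM normalizes to a million", {
  gr <- rep(GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 150L),
                                   strand = "+"), 1000L)
  s <- extract_sites(gr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$count, 1000L)
  expect_equal(s$tpm, 1e6)

  set.seed(21)
  st <- make_sites(pos = sample(1e5, 50), count = sample(1:500, 50, TRUE))
  expect_equal(sum(st$tpm), 1e6, tolerance = 1e-6)
})

test_that("TPM and RPKM formulas match hand-computed values", {
  s <- make_sites(pos = 10L, count = 50L, total = 1e6)
  expect_equal(s$tpm, 50)
  s2 <- make_sites(pos = 10L, count = 10L, total = 10L)
  expect_equal(s2$tpm, 1e6)
  expect_error(compute_tpm(data.frame(count = 1L), total = 0), "total")

  r <- compute_rpkm(c(g1 = 200), c(2000), total = 1e6)
  expect_equal(r$rpkm$rpkm, 100)
  expect_equal(compute_rpkm(c(0), c(500), 1e6)$rpkm$rpkm, 0)
  expect_error(compute_rpkm(c(5), c(0), 1e6), "length")
})

test_that("RPKM > 1 gene counts match a brute-force recount", {
  set.seed(22)
  counts <- rpois(200, 30)
  lens <- sample(500:5000, 200, TRUE)
  total <- 5e4
  r <- compute_rpkm(counts, lens, total)
  brute <- sum(counts * 1e9 / (lens * total) > 1)
  expect_equal(sum(r$rpkm$rpkm > 1), brute)
  expect_equal(max(r$cumulative$gene_fraction), 1)
  expect_false(is.unsorted(r$cumulative$rpkm))
})

test_that("region priority and antisense assignment behave as specified", {
  ann <- toy_annotation()
  s <- data.frame(chrom = "chr1",
                  pos = c(500L, 200L, 120L, 320L, 900L, 1000L, 700L, 250L),
                  strand = c("+", "+", "+", "+", "-", "-", "+", "-"),
                  stringsAsFactors = FALSE)
  out <- categorize_sites(s, ann)
  expect_equal(out$category,
               c("UTR3", "CDS", "UTR5", "intron", "UTR3", "CDS",
                 "intergenic", "antisense"))
  expect_equal(out$gene,
               c("gA", "gA", "gA", "gA", "gB", "gB", NA, "gA"))
})

test_that("unknown chromosomes categorize as intergenic with a warning", {
  ann <- toy_annotation()
  s <- data.frame(chrom = "chr9", pos = 500L, strand = "+")
  expect_warning(out <- categorize_sites(s, ann), "absent")
  expect_equal(out$category, "intergenic")
})

test_that("category tallies equal a brute-force interval scan", {
  ann <- toy_annotation()
  set.seed(23)
  s <- data.frame(chrom = "chr1", pos = sample(0:1200, 500, TRUE),
                  strand = sample(c("+", "-"), 500, TRUE),
                  stringsAsFactors = FALSE)
  out <- categorize_sites(s, ann)
  prio <- c(UTR3 = 1L, CDS = 2L, UTR5 = 3L, intron = 4L)
  brute <- vapply(seq_len(nrow(s)), function(i) {
    fe <- ann$features
    same <- fe[fe$chrom == s$chrom[i] & fe$strand == s$strand[i] &
                 fe$start <= s$pos[i] & s$pos[i] < fe$end, ]
    if (nrow(same)) return(names(prio)[min(prio[same$type])])
    ge <- ann$genes
    opp <- ge[ge$chrom == s$chrom[i] & ge$strand != s$strand[i] &
                ge$start <= s$pos[i] & s$pos[i] < ge$end, ]
    if (nrow(opp)) "antisense" else "intergenic"
  }, "")
  expect_equal(out$category, brute)
})

test_that("the optional 3'UTR extension absorbs just-downstream sites", {
  ann <- toy_annotation()
  s <- data.frame(chrom = "chr1", pos = c(620L, 780L), strand = c("+", "-"))
  expect_equal(categorize_sites(s, ann)$category, rep("intergenic", 2))
  ext <- categorize_sites(s, ann, utr3_extend = 50L)
  expect_equal(ext$category, rep("UTR3", 2))
})

test_that("strand symmetry: mirrored genome leaves categories unchanged", {
  ann <- toy_annotation()
  L <- 1500L
  flip <- function(x) c("+" = "-", "-" = "+")[x]
  genes2 <- ann$genes
  genes2$start <- L - ann$genes$end
  genes2$end <- L - ann$genes$start
  genes2$strand <- unname(flip(ann$genes$strand))
  feats2 <- ann$features[ann$features$type != "intron", ]
  tmp <- feats2
  feats2$start <- L - tmp$end
  feats2$end <- L - tmp$start
  feats2$strand <- unname(flip(tmp$strand))
  feats2$type <- c(UTR5 = "five_prime_UTR", CDS = "CDS",
                   UTR3 = "three_prime_UTR")[feats2$type]
  ann2 <- pacshift:::.build_annotation(genes2, feats2)
  set.seed(24)
  s <- data.frame(chrom = "chr1", pos = sample(0:1400, 300, TRUE),
                  strand = sample(c("+", "-"), 300, TRUE),
                  stringsAsFactors = FALSE)
  s2 <- data.frame(chrom = "chr1", pos = L - 1L - s$pos,
                   strand = unname(flip(s$strand)), stringsAsFactors = FALSE)
  o1 <- categorize_sites(s, ann)
  o2 <- categorize_sites(s2, ann2)
  expect_equal(o1$category, o2$category)
  expect_equal(o1$gene, o2$gene)
})

test_that("category counts conserve the total number of sites", {
  ann <- toy_annotation()
  set.seed(25)
  s <- data.frame(chrom = "chr1", pos = sample(0:1300, 200, TRUE),
                  strand = sample(c("+", "-"), 200, TRUE))
  out <- categorize_sites(s, ann)
  expect_equal(sum(table(out$category)), 200L)
})

test_that("metagene offsets are strand-oriented around both anchors", {
  ann <- toy_annotation()
  # gA (+): stop codon last base 449; gB (-): stop codon last base 950
  s <- make_sites(pos = c(459L, 940L), count = c(1L, 1L),
                  strand = c("+", "-"))
  mg <- metagene_profile(s, ann, anchor = "stop_codon", flank = 100L)
  expect_equal(mg$count[mg$offset == 10L], 2)
  expect_equal(sum(mg$count), 2)
  expect_equal(attr(mg, "argmax"), 10L)
  # TTS anchor: gA tts 599, gB tts 800
  s2 <- make_sites(pos = c(579L, 820L), count = c(3L, 3L),
                   strand = c("+", "-"))
  mg2 <- metagene_profile(s2, ann, anchor = "tts", flank = 100L)
  expect_equal(mg2$count[mg2$offset == -20L], 6)
})

test_that("metagene recovers the planted distance past the stop codon", {
  cfg <- sim_config(seed = 26L, n_genes = 30L, conditions = c("CK", "HT"),
                    utr3_len = c(140L, 140L), pacs_per_gene = c(1, 0, 0),
                    distal_gap = 20L, cds_site_fraction = 0,
                    utr5_site_fraction = 0, intron_site_fraction = 0,
                    antisense_fraction_control = 0,
                    antisense_fraction_treatment = 0)
  sim <- generate_genome(cfg)
  ann <- annotation_from_sim(sim)
  ts <- sim$truth$sites
  s <- make_sites(pos = ts$pos, count = rep(1L, nrow(ts)), strand = ts$strand)
  mg <- metagene_profile(s, ann, anchor = "stop_codon", flank = 300L)
  # distal site at 3'UTR offset 140-1-20 = 119, i.e. 120 nt past the stop
  expect_equal(attr(mg, "argmax"), 120L)
})

test_that("BED ingestion matches GRanges ingestion", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t150\tr1\t0\t+",
               "chr1\t100\t150\tr2\t0\t-"), bed)
  s <- extract_sites(bed)
  expect_equal(sort(s$pos), c(100L, 149L))
})
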