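test_that("within-sample clustering follows the 20-nt gap rule", {
  s <- make_sites(pos = c(100L, 115L), count = c(5L, 3L), total = 10L)
  ps <- cluster_sites(s)
  expect_equal(nrow(ps$pacs), 1L)
  expect_equal(ps$pacs$start, 100L)
  expect_equal(ps$pacs$end, 116L)

  s2 <- make_sites(pos = c(100L, 121L), count = c(5L, 3L), total = 10L)
  expect_equal(nrow(cluster_sites(s2)$pacs), 2L)

  # chained sites merge by single linkage even when the ends are > 20 apart
  s3 <- make_sites(pos = c(100L, 118L, 136L), count = c(2L, 2L, 2L),
                   total = 6L)
  expect_equal(nrow(cluster_sites(s3)$pacs), 1L)
})

test_that("sites at or below the TPM threshold are excluded before linking", {
  s <- make_sites(pos = c(100L, 110L), count = c(4L, 100L), total = 1e7)
  # counts 4 and 100 at total 1e7: tpm 0.4 and 10
  ps <- cluster_sites(s)
  expect_equal(nrow(ps$pacs), 1L)
  expect_equal(ps$pacs$n_sites, 1L)
  expect_equal(ps$sites$pos, 110L)
  # boundary: tpm exactly 0.5 is excluded ("over 0.5")
  s2 <- make_sites(pos = 100L, count = 5L, total = 1e7)
  expect_equal(nrow(cluster_sites(s2)$pacs), 0L)
})

test_that("representative site is the highest count, ties to the 3' side", {
  s <- make_sites(pos = c(100L, 110L, 120L), count = c(5L, 9L, 5L), total = 19L)
  expect_equal(cluster_sites(s)$pacs$rep_pos, 110L)
  tie <- make_sites(pos = c(100L, 120L), count = c(7L, 7L), total = 14L)
  expect_equal(cluster_sites(tie)$pacs$rep_pos, 120L)
  tie_minus <- make_sites(pos = c(100L, 120L), count = c(7L, 7L),
                          strand = "-", total = 14L)
  expect_equal(cluster_sites(tie_minus)$pacs$rep_pos, 100L)
})

test_that("clustering is order-invariant and conserves sites and TPM", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:25, 1L)
    s <- make_sites(pos = sort(sample(1:500, n)),
                    count = sample(1:50, n, TRUE),
                    strand = sample(c("+", "-"), 1L))
    ps1 <- cluster_sites(s)
    ps2 <- cluster_sites(s[sample(n), ])
    expect_equal(ps1$pacs$start, ps2$pacs$start)
    expect_equal(ps1$pacs$rep_pos, ps2$pacs$rep_pos)
    kept <- s[s$tpm > 0.5, ]
    expect_equal(nrow(ps1$sites), nrow(kept))
    expect_equal(sum(ps1$sites$tpm), sum(kept$tpm))
    tpm_cols <- grep("^tpm_", names(ps1$pacs), value = TRUE)
    expect_equal(sum(ps1$pacs[[tpm_cols]]), sum(kept$tpm))
    # each retained site belongs to exactly one PAC
    expect_false(anyNA(ps1$sites$pac_id))
    expect_equal(anyDuplicated(paste(ps1$sites$pos, ps1$sites$strand)), 0L)
  }
})

test_that("cross-sample merging honours the 100-nt edge gap", {
  s1 <- make_sites(pos = c(100L, 110L), count = c(10L, 10L), total = 20L)
  s2 <- make_sites(pos = c(100L, 110L), count = c(20L, 2L), total = 22L)
  ps1 <- cluster_sites(s1, sample = "CK")
  ps2 <- cluster_sites(s2, sample = "HT")
  cons <- merge_pacs(list(ps1, ps2))
  expect_equal(nrow(cons$pacs), 1L)
  expect_equal(cons$pacs$tpm_CK, 1e6)
  expect_equal(cons$pacs$tpm_HT, 1e6)
  expect_equal(cons$pacs$n_sites, 2L)
  # pooled counts decide the representative: 30 at 100 vs 12 at 110
  expect_equal(cons$pacs$rep_pos, 100L)

  far1 <- cluster_sites(make_sites(pos = 100L, count = 10L), sample = "CK")
  far2 <- cluster_sites(make_sites(pos = 250L, count = 10L), sample = "HT")
  expect_equal(nrow(merge_pacs(list(far1, far2))$pacs), 2L)
})

test_that("APA and combined filters implement the stated thresholds", {
  mk <- function(pos_counts_ck, pos_counts_ht, total = 1e5) {
    ps1 <- cluster_sites(make_sites(pos = pos_counts_ck$pos,
                                    count = pos_counts_ck$count,
                                    total = total), sample = "CK")
    ps2 <- cluster_sites(make_sites(pos = pos_counts_ht$pos,
                                    count = pos_counts_ht$count,
                                    total = total), sample = "HT")
    merge_pacs(list(ps1, ps2))
  }
  # single-site PAC: dropped in apa mode regardless of TPM
  cons <- mk(list(pos = 100L, count = 1000L), list(pos = 100L, count = 1000L))
  expect_equal(nrow(filter_pacs(cons, "apa")$pacs), 0L)
  # two sites but TPM below 3 in both samples: dropped
  cons2 <- mk(list(pos = c(100L, 105L), count = c(100L, 100L)),
              list(pos = c(100L, 105L), count = c(100L, 100L)), total = 1e8)
  expect_equal(nrow(filter_pacs(cons2, "apa")$pacs), 0L)
  # pooled TPM exactly 5 is kept in combined mode (>=)
  cons3 <- mk(list(pos = 100L, count = 250L), list(pos = 100L, count = 250L),
              total = 1e8)
  expect_equal(cons3$pacs$tpm_CK + cons3$pacs$tpm_HT, 5)
  expect_equal(nrow(filter_pacs(cons3, "combined")$pacs), 1L)
  expect_error(filter_pacs(cons3, "bogus"))
})

test_that("filtered surviving set equals an independent recount", {
  set.seed(32)
  ps <- lapply(c("CK", "HT"), function(cd) {
    n <- 60L
    s <- make_sites(pos = sort(sample(seq(1, 1e5, by = 40), n)),
                    count = sample(1:80, n, TRUE), total = 3000L)
    cluster_sites(s, sample = cd)
  })
  cons <- merge_pacs(ps)
  surv <- filter_pacs(cons, "apa")$pacs$pac_id
  manual <- cons$pacs$pac_id[cons$pacs$n_sites > 1L &
                               pmax(cons$pacs$tpm_CK, cons$pacs$tpm_HT) >= 3]
  expect_equal(surv, manual)
  surv2 <- filter_pacs(cons, "combined")$pacs$pac_id
  manual2 <- cons$pacs$pac_id[cons$pacs$tpm_CK + cons$pacs$tpm_HT >= 5]
  expect_equal(surv2, manual2)
})

test_that("antisense test matches fisher.test and behaves at the extremes", {
  r <- antisense_test(c(CK = 10L, HT = 10L), c(CK = 100L, HT = 100L), "CK")
  expect_equal(r$fold, 1)
  expect_gt(r$p, 0.5)

  # depletion in the treatment: right-sided p near 1
  r2 <- antisense_test(c(CK = 50L, HT = 0L), c(CK = 100L, HT = 100L), "CK")
  expect_equal(r2$p, 1)

  r3 <- antisense_test(c(CK = 15L, HT = 30L), c(CK = 100L, HT = 100L), "CK")
  ft <- stats::fisher.test(matrix(c(30L, 70L, 15L, 85L), 2L, byrow = TRUE),
                           alternative = "greater")
  expect_equal(r3$p, ft$p.value, tolerance = 1e-12)

  expect_error(antisense_test(c(CK = 0L, HT = 0L), c(CK = 0L, HT = 10L), "CK"),
               "empty")
})

test_that("count_antisense tallies annotated PAC categories", {
  s1 <- make_sites(pos = c(100L, 400L), count = c(10L, 10L))
  ps <- cluster_sites(s1, sample = "CK")
  ps$pacs$category <- c("UTR3", "antisense")
  ps$pacs$gene <- c("gA", "gB")
  cn <- count_antisense(list(CK = ps))
  expect_equal(cn$antisense[["CK"]], 1L)
  expect_equal(cn$total[["CK"]], 2L)
})
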