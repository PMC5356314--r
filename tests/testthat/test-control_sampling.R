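genes_one_tss <- function(tss = 5000L) {
  data.frame(gene_id = "g1", chrom = "chr1", tss = tss, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("random scheme keeps only af-matched, TSS-proximal candidates", {
  genes <- genes_one_tss()
  cases <- data.frame(chrom = "chr1", pos = 5100L, id = "case1", af = 0.30,
                      gwas_p = NA_real_, stringsAsFactors = FALSE)
  pool <- data.frame(chrom = "chr1", pos = c(5200L, 5300L, 5400L),
                     id = c("p10", "p28", "p50"), af = c(0.10, 0.28, 0.50),
                     gwas_p = NA_real_, stringsAsFactors = FALSE)
  set <- sample_random_tss_controls(cases, pool, genes, seed = 1)
  expect_equal(set$pairs$control_id, "p28")
})

test_that("a pool SNP beyond 10 kb of every TSS is never selected", {
  genes <- genes_one_tss(5000L)
  cases <- data.frame(chrom = "chr1", pos = 5100L, id = "case1", af = 0.30,
                      gwas_p = NA_real_, stringsAsFactors = FALSE)
  pool <- data.frame(chrom = "chr1", pos = c(15001L, 15000L),
                     id = c("far", "edge"), af = c(0.30, 0.30),
                     gwas_p = NA_real_, stringsAsFactors = FALSE)
  # "far" is 10001 bp from the TSS, "edge" exactly 10000
  for (s in 1:10) {
    set <- sample_random_tss_controls(cases, pool, genes, seed = s)
    expect_equal(set$pairs$control_id, "edge")
  }
})

test_that("the same seed reproduces the same control set", {
  fx <- generate_fixture(fixture_config(seed = 31, n_snps = 600,
                                        n_genes = 40))
  causal <- fx$truth$is_causal == 1L
  cases <- fx$variants[causal, ][1:40, ]
  pool <- fx$variants[!causal, ]
  a <- sample_random_tss_controls(cases, pool, fx$genes, seed = 99)
  b <- sample_random_tss_controls(cases, pool, fx$genes, seed = 99)
  expect_identical(a$pairs, b$pairs)
  c <- sample_random_tss_controls(cases, pool, fx$genes, seed = 100)
  expect_false(identical(a$pairs, c$pairs))
})

test_that("strict scheme enforces all four filters", {
  genes <- genes_one_tss(5000L)
  cases <- data.frame(chrom = "chr1", pos = 5100L, id = "case1", af = 0.30,
                      gwas_p = NA_real_, stringsAsFactors = FALSE)
  # candidate a: r2 = 0.81 with the case -> excluded
  # candidate b: TSS-distance differs by 999 bp, af dev 0.04 -> eligible
  # candidate c: TSS-distance differs by 1001 bp -> excluded
  pool <- data.frame(chrom = "chr1", pos = c(5150L, 6099L, 6201L),
                     id = c("a", "b", "c"), af = c(0.30, 0.34, 0.30),
                     gwas_p = NA_real_, stringsAsFactors = FALSE)
  ld <- data.frame(snp_a = "case1", snp_b = "a", r = 0.9)
  gc <- c(case1 = 0.5, a = 0.5, b = 0.5, c = 0.5)
  set <- sample_strict_controls(cases, pool, genes, ld, seed = 1, gc = gc)
  expect_equal(set$pairs$control_id, "b")

  # GC mismatch knocks out the last candidate -> unmatched, run continues
  gc2 <- c(case1 = 0.5, a = 0.5, b = 0.56, c = 0.5)
  expect_message(
    set2 <- sample_strict_controls(cases, pool, genes, ld, seed = 1, gc = gc2),
    "unmatched"
  )
  expect_equal(set2$unmatched, "case1")
  expect_equal(nrow(set2$pairs), 0L)
})

test_that("controls may not sit in high LD with the case's LD proxies", {
  genes <- genes_one_tss(5000L)
  cases <- data.frame(chrom = "chr1", pos = 5100L, id = "case1", af = 0.30,
                      gwas_p = NA_real_, stringsAsFactors = FALSE)
  pool <- data.frame(chrom = "chr1", pos = c(5150L, 5160L),
                     id = c("proxy", "shadow"), af = c(0.30, 0.30),
                     gwas_p = NA_real_, stringsAsFactors = FALSE)
  # shadow has low LD with the case but high LD with the case's proxy
  ld <- data.frame(snp_a = c("case1", "proxy"), snp_b = c("proxy", "shadow"),
                   r = c(0.95, 0.95))
  expect_message(
    set <- sample_strict_controls(cases, pool, genes, ld, seed = 1),
    "unmatched"
  )
  expect_equal(nrow(set$pairs), 0L)
})

test_that("GC matching without sequence or gc input is an error", {
  genes <- genes_one_tss()
  cases <- make_variants(5100L, prefix = "case")
  pool <- make_variants(c(5200L, 5300L), prefix = "pool")
  expect_error(
    sample_strict_controls(cases, pool, genes, NULL, seed = 1,
                           match_gc = TRUE),
    "no reference sequence"
  )
})

test_that("gc_window computes the GC fraction of the 101-bp window", {
  s <- paste(rep("ACGT", 100), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = s))
  gc_of <- function(lo, hi) { # independent substring count
    chars <- strsplit(substr(s, lo, hi), "")[[1]]
    mean(chars %in% c("C", "G"))
  }
  v <- make_variants(200L)
  expect_equal(gc_window(v, seqs), gc_of(150, 250))
  # near the left edge the window is clipped
  v2 <- make_variants(3L)
  expect_equal(gc_window(v2, seqs), gc_of(1, 53))
})

test_that("independent verifier passes sampler output on a generated fixture", {
  fx <- generate_fixture(fixture_config(seed = 13, n_snps = 900, n_genes = 60))
  causal <- fx$truth$is_causal == 1L
  cases <- fx$variants[causal, ][1:60, ]
  pool <- fx$variants[!causal, ]
  rs <- suppressMessages(
    sample_random_tss_controls(cases, pool, fx$genes, seed = 5))
  expect_true(all(verify_controls(rs, cases, pool, fx$genes)))
  ss <- suppressMessages(
    sample_strict_controls(cases, pool, fx$genes, fx$ld, seed = 5, gc = fx$gc))
  expect_gt(nrow(ss$pairs), 0L)
  expect_true(all(verify_controls(ss, cases, pool, fx$genes, ld = fx$ld,
                                  gc = fx$gc)))
  # no control reused within a draw
  expect_false(any(duplicated(rs$pairs$control_id)))
  expect_false(any(duplicated(ss$pairs$control_id)))
})

test_that("matched controls track the case allele-frequency distribution", {
  fx <- generate_fixture(fixture_config(seed = 17, n_snps = 6000,
                                        n_genes = 300, n_cell_types = 1,
                                        causal_fraction = 0.1))
  # cases with a skewed (high) allele-frequency spectrum, so that matched
  # sampling is distinguishable from unmatched random sampling, but not so
  # extreme that the eligible pool is exhausted
  ord <- order(-fx$variants$af)
  case_idx <- ord[1001:1500]
  cases <- fx$variants[case_idx, ]
  pool <- fx$variants[setdiff(seq_len(nrow(fx$variants)), case_idx), ]
  set <- suppressMessages(
    sample_random_tss_controls(cases, pool, fx$genes, seed = 3))
  expect_gte(nrow(set$pairs), 500L - 5L)
  dev <- abs(set$pairs$af_case - set$pairs$af_control)
  expect_lt(mean(dev), 0.05)
  ks_matched <- suppressWarnings(
    stats::ks.test(set$pairs$af_case, set$pairs$af_control)$statistic)
  set.seed(4)
  ks_random <- suppressWarnings(
    stats::ks.test(set$pairs$af_case,
                   sample(pool$af, nrow(set$pairs)))$statistic)
  expect_lt(ks_matched, ks_random)
})

test_that("control sets round-trip through their TSV writer", {
  fx <- generate_fixture(fixture_config(seed = 23, n_snps = 600, n_genes = 40))
  causal <- fx$truth$is_causal == 1L
  set <- suppressMessages(sample_random_tss_controls(
    fx$variants[causal, ][1:20, ], fx$variants[!causal, ], fx$genes, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_controls(set, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(set$pairs))
  expect_equal(unique(back$scheme), "random_tss")
})
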