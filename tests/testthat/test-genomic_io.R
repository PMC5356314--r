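test_that("narrowPeak reader maps fields, falls back on summit, handles empty files", {
  tmp <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "chr1\t100\t200\tp1\t0\t.\t7.5\t-1\t-1\t20",
    "chr1\t300\t450\tp2\t0\t.\t2.25\t-1\t-1\t-1"
  ), tmp)
  tr <- read_narrowpeak(tmp, "DHS", "CT1")
  expect_s3_class(tr, "peak_track")
  expect_equal(tr$intervals$start, c(100L, 300L))
  expect_equal(tr$intervals$signal, c(7.5, 2.25))
  expect_equal(tr$intervals$summit_offset[1L], 20L)
  # summit -1 replaced by floor of the midpoint offset
  expect_equal(tr$intervals$summit_offset[2L], (450L - 300L) %/% 2L)

  writeLines(character(0), tmp)
  empty <- read_narrowpeak(tmp, "DHS", "CT1")
  expect_equal(nrow(empty$intervals), 0L)
})

test_that("narrowPeak reader reports malformed lines by number", {
  tmp <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "chr1\t100\t200\tp1\t0\t.\t7.5\t-1\t-1\t20",
    "chr1\t500\t400\tp2\t0\t.\t1.0\t-1\t-1\t-1"
  ), tmp)
  expect_error(read_narrowpeak(tmp, "DHS", "CT1"), "start >= end at line 2")
  writeLines("chr1\t100\t200\tp1\t0\t.\tabc\t-1\t-1\t20", tmp)
  expect_error(read_narrowpeak(tmp, "DHS", "CT1"), "non-numeric signalValue at line 1")
  writeLines("chr1\t100\t200\tp1", tmp)
  expect_error(read_narrowpeak(tmp, "DHS", "CT1"), "has 4 fields")
  expect_error(read_narrowpeak(file.path(tempdir(), "nope.np"), "DHS", "CT1"),
               "not found")
})

test_that("overlapping intervals are merged with max signal and its summit", {
  tmp <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "chr1\t100\t250\tp1\t0\t.\t3.0\t-1\t-1\t10",
    "chr1\t200\t400\tp2\t0\t.\t9.0\t-1\t-1\t50",
    "chr1\t600\t700\tp3\t0\t.\t1.0\t-1\t-1\t5"
  ), tmp)
  merged <- read_narrowpeak(tmp, "H3K4me1", "CT1", merge = TRUE)
  expect_equal(nrow(merged$intervals), 2L)
  expect_equal(merged$intervals$end[1L], 400L)
  expect_equal(merged$intervals$signal[1L], 9.0)
  # summit of the strongest member, re-expressed from the merged start
  expect_equal(merged$intervals$summit_offset[1L], 200L + 50L - 100L)
  unmerged <- read_narrowpeak(tmp, "H3K4me1", "CT1", merge = FALSE)
  expect_equal(nrow(unmerged$intervals), 3L)
})

test_that("peak tracks and variant tables round-trip exactly", {
  tr <- make_track("H3K27ac", list(
    c(100, 200, 7.5, 20), c(1000, 1234, 1 / 3, 100)
  ))
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(tr, f)
  back <- read_narrowpeak(f, "H3K27ac", "CT1")
  expect_identical(back$intervals$start, as.integer(tr$intervals$start))
  expect_identical(back$intervals$signal, tr$intervals$signal)
  expect_identical(back$intervals$summit_offset,
                   as.integer(tr$intervals$summit_offset))

  v <- make_variants(c(11L, 507L, 90001L), af = c(1 / 7, 0.25, 0.9999),
                     gwas_p = c(0.003, 1, 2e-16))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, f2)
  back2 <- read_variants(f2)
  expect_identical(back2$pos, v$pos)
  expect_identical(back2$af, v$af)
  expect_identical(back2$gwas_p, v$gwas_p)
  expect_identical(back2$id, v$id)
})

test_that("variant reader validates af, pos and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tid\taf",
               "chr1\t100\trs1\t0.2",
               "chr1\t200\trs2\t0.4",
               "chr1\t300\trs3\t0.6"), f)
  v <- read_variants(f)
  expect_equal(nrow(v), 3L)
  expect_true(all(is.na(v$gwas_p)))

  writeLines(c("chrom\tpos\tid\taf", "chr1\t100\trs1\t1.2"), f)
  expect_error(read_variants(f), "af outside \\[0,1\\] at row 1")
  writeLines(c("chrom\tpos\tid\taf", "chr1\t0\trs1\t0.2"), f)
  expect_error(read_variants(f), "pos < 1")
  writeLines(c("chrom\tpos\tid\taf", "chr1\t5\trs1\t0.2", "chr2\t9\trs1\t0.3"), f)
  expect_error(read_variants(f), "duplicated")
  writeLines(c("chrom\tpos\tid\taf\tp", "chr1\t5\trs1\t0.2\t0.01"), f)
  expect_equal(read_variants(f)$gwas_p, 0.01)
})

test_that("GWAS summary reader enforces P in (0,1] and unique ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tchrom\tpos\tp", "rs1\tchr1\t500\t0.003"), f)
  expect_equal(read_gwas_summary(f)$gwas_p, 0.003)
  writeLines(c("id\tchrom\tpos\tp", "rs1\tchr1\t500\t0"), f)
  expect_error(read_gwas_summary(f), "outside \\(0,1\\]")
  writeLines(c("id\tchrom\tpos\tp", "rs1\tchr1\t500\t1"), f)
  expect_equal(read_gwas_summary(f)$gwas_p, 1)
  writeLines(c("id\tchrom\tpos\tp", "rs1\tchr1\t500\t0.5",
               "rs1\tchr2\t600\t0.1"), f)
  expect_error(read_gwas_summary(f), "duplicated")
})

test_that("1-based/0-based conversion matches a brute-force per-base scan", {
  set.seed(11)
  for (rep in 1:50) {
    start <- sample.int(500L, 1L)
    end <- start + sample.int(50L, 1L)
    pos <- sample.int(600L, 20L)
    expect_identical(
      pos_overlaps_interval(pos, start, end),
      vapply(pos, brute_force_hit, TRUE, starts = start, ends = end)
    )
  }
})

test_that("chromosome names compare after chr-prefix normalization", {
  expect_equal(norm_chrom(c("chr1", "Chr2", "CHRX", "3")),
               c("1", "2", "X", "3"))
})

test_that("TSS BED round-trips and defaults strand", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(1000L, 5000L), strand = c("+", "-"),
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_tss_bed(g, f)
  back <- read_tss_bed(f)
  expect_identical(back$tss, g$tss)
  expect_identical(back$strand, g$strand)
  writeLines("chr1\t99\t100\tg3", f)
  expect_equal(read_tss_bed(f)$strand, "+")
  expect_equal(read_tss_bed(f)$tss, 100L)
})

test_that("LD matrix is symmetric with unit diagonal and zero for absent pairs", {
  ld <- data.frame(snp_a = c("a", "b"), snp_b = c("b", "c"), r = c(0.9, -0.4))
  R <- ld_matrix(c("a", "b", "c", "d"), ld)
  expect_identical(R, t(R))
  expect_equal(diag(R), setNames(rep(1, 4), c("a", "b", "c", "d")))
  expect_equal(R["a", "c"], 0)
  expect_equal(R["b", "c"], -0.4)
})

test_that("score panel IO keeps explicit NA sentinels and round-trips", {
  m <- matrix(c(0.1, NA, 2.5, 1 / 3), 2, 2,
              dimnames = list(c("rs1", "rs2"), c("cadd", "funseq")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(m, f)
  back <- read_scores(f)
  expect_identical(back, m)
})
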