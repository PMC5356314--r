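#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

#' Chromatin marks recognized by the feature extractor
#'
#' DNase I hypersensitivity plus the eleven histone modification marks whose
#' narrow peak calls the pipeline consumes.
#'
#' @format Character vector of 12 mark names.
#' @export
REGPOT_MARKS <- c(
  "DHS", "H2AFZ", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1",
  "H3K4me2", "H3K4me3", "H3K79me2", "H3K9ac", "H3K9me3", "H4K20me1"
)

## shortest decimal string that round-trips to the same double, so
## write-then-read reproduces numeric fields exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in c(15L, 16L, 17L)) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    s
  }, "")
}

#' Normalize chromosome names
#'
#' Strips an optional "chr" prefix case-insensitively so that "chr1", "Chr1"
#' and "1" compare equal everywhere in the package.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

#' Does a 1-based variant position overlap a 0-based half-open interval?
#'
#' The single place where the two coordinate conventions meet: a variant at
#' 1-based position `pos` overlaps the half-open interval `[start, end)`
#' (0-based, BED convention) iff `start < pos <= end`.
#'
#' @param pos 1-based position(s).
#' @param start,end 0-based half-open interval bounds.
#' @return logical vector.
#' @export
pos_overlaps_interval <- function(pos, start, end) {
  start < pos & pos <= end
}

## 1-based summit position of a peak row (start + offset is 0-based)
peak_summit_pos <- function(start, summit_offset) {
  start + summit_offset + 1L
}

new_peak_track <- function(mark, cell_type, intervals) {
  stopifnot(is.data.frame(intervals))
  structure(
    list(mark = mark, cell_type = cell_type, intervals = intervals),
    class = "peak_track"
  )
}

#' @export
print.peak_track <- function(x, ...) {
  cat(sprintf(
    "<peak_track> mark=%s cell_type=%s intervals=%d\n",
    x$mark, x$cell_type, nrow(x$intervals)
  ))
  invisible(x)
}

empty_intervals <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    signal = numeric(0), summit_offset = integer(0),
    stringsAsFactors = FALSE
  )
}

## Merge overlapping intervals of one track (per chromosome).  Signal of a
## merged interval is the max of its members; the summit is the summit of the
## member with maximal signal, re-expressed relative to the merged start.
merge_track_intervals <- function(iv) {
  if (nrow(iv) < 2L) return(iv)
  out <- lapply(split(iv, norm_chrom(iv$chrom)), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    runs <- list()
    cur <- d[1L, , drop = FALSE]
    cur_summit_abs <- cur$start + cur$summit_offset
    for (i in seq_len(nrow(d))[-1L]) {
      row <- d[i, , drop = FALSE]
      if (row$start < cur$end) { # overlap under half-open coords
        if (row$signal > cur$signal) {
          cur$signal <- row$signal
          cur_summit_abs <- row$start + row$summit_offset
        }
        cur$end <- max(cur$end, row$end)
      } else {
        cur$summit_offset <- cur_summit_abs - cur$start
        runs[[length(runs) + 1L]] <- cur
        cur <- row
        cur_summit_abs <- cur$start + cur$summit_offset
      }
    }
    cur$summit_offset <- cur_summit_abs - cur$start
    runs[[length(runs) + 1L]] <- cur
    do.call(rbind, runs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read an ENCODE narrowPeak file into a peak track
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, summit offset ("peak", -1 when absent). A summit of -1 is
#' replaced by the interval midpoint (floor). Malformed lines raise an error
#' naming the line number.
#'
#' @param path path to a narrowPeak file (plain text, tab- or space-separated).
#' @param mark mark name, one of [REGPOT_MARKS].
#' @param cell_type cell-type label.
#' @param merge merge overlapping intervals within the track (default TRUE);
#'   the merged interval keeps the maximal signal and that member's summit.
#' @return an object of class `peak_track` with fields `mark`, `cell_type`
#'   and `intervals` (data frame: chrom, start, end, signal, summit_offset;
#'   0-based half-open coordinates).
#' @export
read_narrowpeak <- function(path, mark, cell_type, merge = TRUE) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  mark <- match.arg(mark, REGPOT_MARKS)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_peak_track(mark, cell_type, empty_intervals()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 10L)
  if (length(bad)) {
    stop(sprintf(
      "narrowPeak parse error in %s: line %d has %d fields (need 10)",
      path, bad[1L], n_fields[bad[1L]]
    ))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  signal <- suppressWarnings(as.numeric(m[, 7L]))
  summit <- suppressWarnings(as.integer(m[, 10L]))
  for (col in list(
    list(v = start, what = "start"), list(v = end, what = "end"),
    list(v = signal, what = "signalValue"), list(v = summit, what = "summit")
  )) {
    if (anyNA(col$v)) {
      stop(sprintf(
        "narrowPeak parse error in %s: non-numeric %s at line %d",
        path, col$what, which(is.na(col$v))[1L]
      ))
    }
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf(
      "narrowPeak parse error in %s: start >= end at line %d", path, bad[1L]
    ))
  }
  if (any(signal < 0)) {
    stop(sprintf(
      "narrowPeak parse error in %s: negative signal at line %d",
      path, which(signal < 0)[1L]
    ))
  }
  no_summit <- summit < 0L
  summit[no_summit] <- ((end - start) %/% 2L)[no_summit]
  iv <- data.frame(
    chrom = m[, 1L], start = start, end = end,
    signal = signal, summit_offset = summit, stringsAsFactors = FALSE
  )
  if (merge) iv <- merge_track_intervals(iv)
  new_peak_track(mark, cell_type, iv)
}

#' Write a peak track as narrowPeak
#'
#' @param track a `peak_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(track, path) {
  iv <- track$intervals
  out <- data.frame(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    name = sprintf("%s_%s_%d", track$mark, track$cell_type, seq_len(nrow(iv))),
    score = 0L, strand = ".",
    signalValue = fmt_num(iv$signal), pValue = -1, qValue = -1,
    peak = iv$summit_offset, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_variants <- function(df, where = "variant table") {
  req <- c("chrom", "pos", "id", "af")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(where, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$af <- as.numeric(df$af)
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) stop(where, ": pos < 1 or non-numeric at row ", bad[1L])
  bad <- which(is.na(df$af) | df$af < 0 | df$af > 1)
  if (length(bad)) stop(where, ": af outside [0,1] at row ", bad[1L])
  dup <- duplicated(df$id)
  if (any(dup)) {
    stop(where, ": duplicated variant id: ", df$id[which(dup)[1L]])
  }
  if (!is.null(df$gwas_p)) {
    df$gwas_p <- as.numeric(df$gwas_p)
    present <- !is.na(df$gwas_p)
    bad <- which(present & (df$gwas_p <= 0 | df$gwas_p > 1))
    if (length(bad)) stop(where, ": gwas_p outside (0,1] at row ", bad[1L])
  } else {
    df$gwas_p <- NA_real_
  }
  df[c("chrom", "pos", "id", "af", "gwas_p")]
}

#' Read a variant table
#'
#' Tab-separated with a header; required columns `chrom`, `pos` (1-based),
#' `id`, `af`; optional column `p` (GWAS P value) populates `gwas_p`.
#'
#' @param path path to the TSV.
#' @return data frame with columns chrom, pos, id, af, gwas_p (NA when the
#'   file has no `p` column), one row per variant in file order.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("p" %in% names(df) && !"gwas_p" %in% names(df)) {
    df$gwas_p <- df$p
  }
  validate_variants(df, where = basename(path))
}

#' Write a variant table
#'
#' @param variants data frame with columns chrom, pos, id, af and optionally
#'   gwas_p; `gwas_p` is written as a `p` column when any value is present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- variants[c("chrom", "pos", "id")]
  out$af <- fmt_num(variants$af)
  if (!is.null(variants$gwas_p) && any(!is.na(variants$gwas_p))) {
    out$p <- fmt_num(variants$gwas_p)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with header columns `id` (SNP), `chrom`, `pos`, `p`.
#' Every record must carry a P value in (0, 1]; P = 0 is rejected because
#' downstream statistics log-transform P values.
#'
#' @param path path to the TSV.
#' @return variant data frame (chrom, pos, id, af, gwas_p); `af` is taken
#'   from an `af` column when present, NA otherwise.
#' @export
read_gwas_summary <- function(path) {
  if (!file.exists(path)) stop("GWAS summary file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "p")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"af" %in% names(df)) df$af <- NA_real_
  df$gwas_p <- as.numeric(df$p)
  bad <- which(is.na(df$gwas_p) | df$gwas_p <= 0 | df$gwas_p > 1)
  if (length(bad)) {
    stop(basename(path), ": P value outside (0,1] at row ", bad[1L])
  }
  dup <- duplicated(df$id)
  if (any(dup)) stop(basename(path), ": duplicated SNP id: ", df$id[which(dup)[1L]])
  out <- df[c("chrom", "pos", "id", "af", "gwas_p")]
  out$pos <- as.integer(out$pos)
  bad <- which(is.na(out$pos) | out$pos < 1L)
  if (length(bad)) stop(basename(path), ": pos < 1 at row ", bad[1L])
  out
}

#' Read TSS annotation from BED
#'
#' BED4 (chrom, start, end, name) or BED6 (plus score, strand). Each record
#' is a single-base TSS interval; the 1-based TSS is `start + 1`. Without a
#' strand column strand defaults to "+".
#'
#' @param path path to the BED file.
#' @return data frame with columns gene_id, chrom, tss (1-based), strand.
#' @export
read_tss_bed <- function(path) {
  if (!file.exists(path)) stop("TSS BED file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(raw), "[ \t]+")
  if (any(lengths(fields) < 4L)) {
    stop(basename(path), ": BED line with fewer than 4 fields at line ",
         which(lengths(fields) < 4L)[1L])
  }
  m <- lapply(fields, function(f) f[seq_len(min(6L, length(f)))])
  chrom <- vapply(m, `[`, "", 1L)
  start <- as.integer(vapply(m, `[`, "", 2L))
  name <- vapply(m, `[`, "", 4L)
  strand <- vapply(m, function(f) if (length(f) >= 6L) f[6L] else "+", "")
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(gene_id = name, chrom = chrom, tss = start + 1L,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write TSS annotation as BED
#'
#' @param genes data frame with gene_id, chrom, tss (1-based), strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(genes, path) {
  out <- data.frame(
    chrom = genes$chrom, start = genes$tss - 1L, end = genes$tss,
    name = genes$gene_id, score = 0L, strand = genes$strand,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pairwise LD
#'
#' Tab-separated with header columns `snp_a`, `snp_b`, `r` (the genotype
#' correlation, in [-1, 1]). Pairs absent from the table are treated as
#' r = 0 downstream.
#'
#' @param path path to the TSV.
#' @return data frame with columns snp_a, snp_b, r.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("LD file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("snp_a", "snp_b", "r"), names(df))
  if (length(miss)) {
    stop(basename(path), ": missing column(s): ", paste(miss, collapse = ", "))
  }
  df$r <- as.numeric(df$r)
  bad <- which(is.na(df$r) | abs(df$r) > 1 + 1e-9)
  if (length(bad)) stop(basename(path), ": r outside [-1,1] at row ", bad[1L])
  df[c("snp_a", "snp_b", "r")]
}

#' Build a symmetric LD matrix for a set of SNPs
#'
#' @param snp_ids SNP identifiers (row/column order of the result).
#' @param ld LD table as returned by [read_ld()]; absent pairs get r = 0.
#' @return numeric matrix with unit diagonal.
#' @export
ld_matrix <- function(snp_ids, ld) {
  n <- length(snp_ids)
  R <- diag(1, n)
  dimnames(R) <- list(snp_ids, snp_ids)
  if (!is.null(ld) && nrow(ld)) {
    keep <- ld$snp_a %in% snp_ids & ld$snp_b %in% snp_ids
    ld <- ld[keep, , drop = FALSE]
    if (nrow(ld)) {
      ia <- match(ld$snp_a, snp_ids)
      ib <- match(ld$snp_b, snp_ids)
      R[cbind(ia, ib)] <- ld$r
      R[cbind(ib, ia)] <- ld$r
    }
  }
  R
}

#' Read an external predictor score panel
#'
#' Tab-separated with header: an `id` column plus one numeric column per
#' predictor. Missing scores are the literal `NA` (explicit sentinel), never
#' silently zero.
#'
#' @param path path to the TSV.
#' @return numeric matrix, rows named by variant id, columns by predictor.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop(basename(path), ": missing `id` column")
  if (anyDuplicated(df$id)) stop(basename(path), ": duplicated variant id")
  preds <- setdiff(names(df), "id")
  if (!length(preds)) stop(basename(path), ": no predictor columns")
  m <- as.matrix(df[preds])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' Write a predictor score panel
#'
#' @param scores numeric matrix, rows named by variant id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(id = rownames(scores),
                    apply(scores, 2L, fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
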