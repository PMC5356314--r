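#' @importFrom stats rnorm rchisq pchisq rlnorm
NULL

#' Configuration for the synthetic fixture generator
#'
#' Defines a small genome with regularly spaced SNPs, LD blocks, gene TSSs,
#' cell-type-specific peak landscapes with planted enrichment at causal
#' SNPs, external predictor scores, and gene-structured GWAS P values. The
#' defaults emulate the statistical structure of a fine-mapped eQTL study:
#' a modest causal fraction, a strong but not deterministic overlap
#' enrichment of causal variants in active marks of the matched cell type,
#' block-wise LD that decays geometrically, and GWAS signal concentrated in
#' the genes that harbour planted causal SNPs.
#'
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param n_snps number of SNPs (default 2000).
#' @param n_genes number of genes/TSSs (default 100, giving a TSS roughly
#'   every 20 kb at the default spacing so every SNP is TSS-proximal).
#' @param n_cell_types number of cell types (default 2; enrichment is
#'   planted in the first, the "matched" cell type).
#' @param marks marks to simulate (default all of [REGPOT_MARKS]).
#' @param informative_marks marks carrying the planted causal enrichment
#'   (default DHS, H3K4me1, H3K4me3, H3K27ac — active-chromatin marks).
#' @param causal_fraction fraction of SNPs planted causal (default 0.1).
#' @param enrichment_odds odds multiplier for a causal SNP overlapping an
#'   informative mark in the matched cell type, relative to the baseline
#'   hit rate (default 5; 1 = null generator).
#' @param baseline_hit_rate probability that a non-causal SNP (or any SNP at
#'   an uninformative mark) sits in a peak (default 0.2).
#' @param snp_spacing distance between consecutive SNPs in bp (default
#'   1000).
#' @param ld_block_size SNPs per LD block (default 10).
#' @param ld_rho within-block LD decay: r = rho^d at rank distance d
#'   (default 0.9); blocks are independent.
#' @param effect_ncp non-centrality of the 1-df chi-square generating the
#'   GWAS P value of a planted causal SNP (default 25, i.e. a clearly
#'   sub-genome-wide to genome-wide signal).
#' @param n_predictors number of external predictor scores (default 3).
#' @param predictor_shift mean shift (in SD units) of causal variants'
#'   predictor scores (default 1).
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_snps = 2000L, n_genes = 100L,
                           n_cell_types = 2L, marks = REGPOT_MARKS,
                           informative_marks = c("DHS", "H3K4me1",
                                                 "H3K4me3", "H3K27ac"),
                           causal_fraction = 0.1, enrichment_odds = 5,
                           baseline_hit_rate = 0.2, snp_spacing = 1000L,
                           ld_block_size = 10L, ld_rho = 0.9,
                           effect_ncp = 25, n_predictors = 3L,
                           predictor_shift = 1) {
  stopifnot(n_snps >= 1L, n_genes >= 1L, n_cell_types >= 1L,
            causal_fraction > 0, causal_fraction < 1,
            enrichment_odds >= 1, baseline_hit_rate > 0,
            baseline_hit_rate < 1, ld_block_size >= 1L,
            ld_rho >= 0, ld_rho < 1, snp_spacing >= 400L)
  marks <- match.arg(marks, REGPOT_MARKS, several.ok = TRUE)
  informative_marks <- intersect(informative_marks, marks)
  if (round(n_snps * causal_fraction) < 1L) {
    stop("config infeasible: fewer than one causal SNP")
  }
  structure(list(
    seed = as.integer(seed), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
    marks = marks, informative_marks = informative_marks,
    causal_fraction = causal_fraction, enrichment_odds = enrichment_odds,
    baseline_hit_rate = baseline_hit_rate,
    snp_spacing = as.integer(snp_spacing),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    effect_ncp = effect_ncp, n_predictors = as.integer(n_predictors),
    predictor_shift = predictor_shift
  ), class = "fixture_config")
}

#' @export
print.fixture_config <- function(x, ...) {
  cat(sprintf(
    "<fixture_config> seed=%d n_snps=%d n_genes=%d cells=%d odds=%.1f causal=%.2f\n",
    x$seed, x$n_snps, x$n_genes, x$n_cell_types, x$enrichment_odds,
    x$causal_fraction))
  invisible(x)
}

## random genome with GC drifting per kb so GC matching is non-trivial
simulate_genome <- function(len) {
  chunk <- 1000L
  n_chunks <- ceiling(len / chunk)
  gcp <- runif(n_chunks, 0.3, 0.7)
  parts <- vapply(seq_len(n_chunks), function(i) {
    nlet <- if (i == n_chunks) len - (i - 1L) * chunk else chunk
    paste(sample(c("A", "C", "G", "T"), nlet, replace = TRUE,
                 prob = c((1 - gcp[i]) / 2, gcp[i] / 2, gcp[i] / 2,
                          (1 - gcp[i]) / 2)), collapse = "")
  }, "")
  paste(parts, collapse = "")
}

#' Generate a coupled synthetic fixture with known ground truth
#'
#' Produces, in memory and optionally on disk, every input the pipeline
#' reads: per-mark/per-cell-type narrowPeak tracks, a variant table with
#' allele frequencies, a TSS BED, a block-structured pairwise LD table,
#' external predictor scores, GWAS summary statistics, the reference genome
#' (FASTA) with per-SNP window GC, and a truth table recording every
#' planted label. Causal SNPs overlap the informative marks of the matched
#' (first) cell type with the configured odds enrichment; the planted
#' causal SNP of each causal gene carries the gene's smallest GWAS P value.
#' The whole bundle is a pure function of the config seed.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed); NULL for in-memory
#'   only.
#' @param write_fasta also write the genome FASTA when `dir` is given
#'   (default TRUE).
#' @return (invisibly when `dir` is given) a list: `variants`, `genes`,
#'   `tracks` (cell type -> list of `peak_track`), `ld`, `scores`, `gwas`,
#'   `truth`, `gc` (named per-SNP GC), `genome` (DNAStringSet), `config`,
#'   and `paths` when written.
#' @export
generate_fixture <- function(config, dir = NULL, write_fasta = TRUE) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  n <- config$n_snps
  spacing <- config$snp_spacing
  jitter_max <- max(1L, spacing %/% 10L)
  pos <- 500L + seq_len(n) * spacing +
    sample.int(jitter_max, n, replace = TRUE)
  ids <- sprintf("snp%06d", seq_len(n))
  af <- round(runif(n, 0.05, 0.95), 4)
  chrom <- "chr1"
  glen <- max(pos) + spacing

  ## planted causal labels
  n_causal <- round(n * config$causal_fraction)
  causal_idx <- sort(sample.int(n, n_causal))
  is_causal <- seq_len(n) %in% causal_idx

  ## genes: TSS at every (n / n_genes)-th SNP, jittered
  step <- max(1L, n %/% config$n_genes)
  tss_anchor <- seq(1L, n, by = step)[seq_len(min(config$n_genes, ceiling(n / step)))]
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_along(tss_anchor)),
    chrom = chrom,
    tss = pos[tss_anchor] + sample(-200L:200L, length(tss_anchor), replace = TRUE),
    strand = sample(c("+", "-"), length(tss_anchor), replace = TRUE),
    stringsAsFactors = FALSE
  )
  ## SNP -> nearest gene
  nearest_gene <- genes$gene_id[
    vapply(pos, function(p) which.min(abs(genes$tss - p)), 0L)
  ]

  ## hit probabilities: odds multiplier at informative marks of cell type 1
  p0 <- config$baseline_hit_rate
  odds1 <- config$enrichment_odds * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)

  cells <- sprintf("CT%d", seq_len(config$n_cell_types))
  tracks <- list()
  planted <- vector("list", n)
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    cell_tracks <- list()
    for (mk in config$marks) {
      informative <- ci == 1L && mk %in% config$informative_marks
      p_hit <- ifelse(is_causal & informative, p1, p0)
      hit <- runif(n) < p_hit
      if (informative) {
        for (i in which(hit & is_causal)) {
          planted[[i]] <- c(planted[[i]], mk)
        }
      }
      idx <- which(hit)
      if (length(idx)) {
        wmin <- 100L
        wmax <- spacing %/% 2L - 100L # config enforces wmax >= wmin
        width <- wmin + sample.int(wmax - wmin + 1L, length(idx),
                                   replace = TRUE) - 1L
        offset <- vapply(width, function(w) sample.int(w - 20L, 1L) + 10L, 0L)
        start <- pos[idx] - offset # 0-based start; SNP inside since offset >= 1
        end <- start + width
        summit_jit <- sample(-20L:20L, length(idx), replace = TRUE)
        summit_pos <- pmin(pmax(pos[idx] + summit_jit, start + 1L), end)
        signal <- round(rlnorm(length(idx), log(5), 0.5) *
                          ifelse(is_causal[idx] & informative, 1.5, 1), 3)
        iv <- data.frame(chrom = chrom, start = start, end = end,
                         signal = signal,
                         summit_offset = summit_pos - start - 1L,
                         stringsAsFactors = FALSE)
        iv <- iv[order(iv$start), , drop = FALSE]
        rownames(iv) <- NULL
      } else {
        iv <- empty_intervals()
      }
      cell_tracks[[mk]] <- new_peak_track(mk, cell, iv)
    }
    tracks[[cell]] <- cell_tracks
  }

  ## LD: blocks of consecutive SNPs, r = rho^d within, 0 across
  blocks <- split(seq_len(n), (seq_len(n) - 1L) %/% config$ld_block_size)
  ld_rows <- lapply(blocks, function(b) {
    m <- length(b)
    if (m < 2L) return(NULL)
    pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    data.frame(
      snp_a = ids[b[pr[, 1L]]], snp_b = ids[b[pr[, 2L]]],
      r = config$ld_rho^(pr[, 2L] - pr[, 1L]),
      stringsAsFactors = FALSE
    )
  })
  ld <- do.call(rbind, ld_rows[!vapply(ld_rows, is.null, TRUE)])
  rownames(ld) <- NULL

  ## GWAS P values: causal genes get a non-central signal at the causal SNP
  gwas_p <- runif(n)
  for (g in unique(nearest_gene[is_causal])) {
    members <- which(nearest_gene == g)
    cs <- members[is_causal[members]][1L]
    stat <- rchisq(1L, df = 1, ncp = config$effect_ncp)
    p_causal_snp <- pchisq(stat, df = 1, lower.tail = FALSE)
    ## the planted causal SNP carries the gene's strictly smallest P value
    others <- gwas_p[setdiff(members, cs)]
    floor_p <- if (length(others)) min(others) / 2 else 1
    gwas_p[cs] <- min(p_causal_snp, floor_p)
  }
  gwas_p <- pmin(pmax(gwas_p, 1e-300), 1)

  ## external predictor scores: causal variants shifted upward
  scores <- matrix(rnorm(n * config$n_predictors), nrow = n)
  scores <- scores + config$predictor_shift * is_causal
  scores <- round(scores, 4)
  colnames(scores) <- sprintf("pred%d", seq_len(config$n_predictors))
  rownames(scores) <- ids

  ## genome and per-SNP window GC
  genome <- Biostrings::DNAStringSet(setNames(simulate_genome(glen), chrom))

  variants <- data.frame(chrom = chrom, pos = pos, id = ids, af = af,
                         gwas_p = gwas_p, stringsAsFactors = FALSE)
  gc <- setNames(gc_window(variants, genome), ids)
  truth <- data.frame(
    snp_id = ids, is_causal = as.integer(is_causal),
    gene_id = nearest_gene,
    planted_marks = vapply(planted, function(x)
      if (is.null(x)) "" else paste(x, collapse = ","), ""),
    stringsAsFactors = FALSE
  )

  bundle <- list(variants = variants, genes = genes, tracks = tracks,
                 ld = ld, scores = scores,
                 gwas = variants[c("chrom", "pos", "id", "af", "gwas_p")],
                 truth = truth, gc = gc, genome = genome, config = config)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    paths <- list(
      variants = file.path(dir, "variants.tsv"),
      tss = file.path(dir, "tss.bed"),
      ld = file.path(dir, "ld.tsv"),
      scores = file.path(dir, "scores.tsv"),
      gwas = file.path(dir, "gwas.tsv"),
      truth = file.path(dir, "truth.tsv"),
      gc = file.path(dir, "gc.tsv")
    )
    write_variants(variants, paths$variants)
    write_tss_bed(genes, paths$tss)
    ld_out <- ld
    ld_out$r <- fmt_num(ld_out$r)
    write.table(ld_out, paths$ld, sep = "\t", quote = FALSE, row.names = FALSE)
    write_scores(scores, paths$scores)
    gw <- data.frame(id = ids, chrom = chrom, pos = pos,
                     af = fmt_num(af), p = fmt_num(gwas_p))
    write.table(gw, paths$gwas, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(id = ids, gc = fmt_num(gc)), paths$gc, sep = "\t",
                quote = FALSE, row.names = FALSE)
    peak_paths <- character(0)
    for (cell in cells) {
      for (mk in config$marks) {
        pth <- file.path(dir, "peaks",
                         sprintf("%s_%s.narrowPeak", cell, mk))
        write_narrowpeak(tracks[[cell]][[mk]], pth)
        peak_paths <- c(peak_paths, pth)
      }
    }
    paths$peaks <- peak_paths
    if (write_fasta) {
      paths$fasta <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, paths$fasta, width = 80L)
    }
    bundle$paths <- paths
    return(invisible(bundle))
  }
  bundle
}
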