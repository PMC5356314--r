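#' @importFrom stats qchisq median quantile ppoints
NULL

#' Fisher's combined statistic
#'
#' \eqn{-2 \sum_i \ln p_i}; chi-square with 2n df under the null of
#' independent uniform P values. P values of exactly 1 contribute nothing.
#'
#' @param pvalues numeric vector of P values in (0, 1].
#' @return the combined statistic (nonnegative).
#' @export
fisher_stat <- function(pvalues) {
  if (!length(pvalues)) stop("empty P value vector")
  if (any(pvalues <= 0 | pvalues > 1)) stop("P values must lie in (0, 1]")
  -2 * sum(log(pvalues))
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda} = median of the 1-df chi-square statistics implied by the
#' P values, divided by the null median `qchisq(0.5, 1)` (0.4549...).
#'
#' @param pvalues numeric vector of P values in (0, 1].
#' @return the inflation factor.
#' @export
inflation_lambda <- function(pvalues) {
  if (!length(pvalues)) stop("empty P value vector")
  if (any(pvalues <= 0 | pvalues > 1)) stop("P values must lie in (0, 1]")
  median(qchisq(pvalues, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

rank_by_score <- function(ids, scores) {
  ids[order(-scores, ids, method = "radix")]
}

#' Permutation test of GWAS signal enrichment in top-prioritized SNPs
#'
#' Ranks SNPs by `score` (descending, ties broken by id), takes the top
#' `top_frac` fraction, and combines their GWAS P values with Fisher's
#' method. The observed statistic is compared against `B` permuted draws of
#' equally many SNPs: drawn uniformly from all SNPs (`scheme = "uniform"`)
#' or allele-frequency matched to each top SNP within a deviation of 0.05
#' (`scheme = "af_matched"`). When `p_floor_filter < 1`, SNPs with GWAS
#' P > `p_floor_filter` are pruned from the observed and every permuted draw
#' alike (they contribute nothing to the statistic). The empirical P value
#' uses the add-one estimator `(1 + #\{perm >= obs\}) / (B + 1)`, so it is
#' never zero.
#'
#' @param snps variant data frame with columns `id`, `gwas_p` and (for the
#'   af_matched scheme) `af`.
#' @param score named numeric vector of prioritization scores covering
#'   `snps$id` (e.g. combined probabilities).
#' @param top_frac fraction of SNPs considered top-ranked (0 < f < 1;
#'   default 0.05).
#' @param B number of permutations (default 10000).
#' @param scheme `"uniform"` or `"af_matched"`.
#' @param seed integer seed.
#' @param p_floor_filter prune SNPs with GWAS P above this value (default 1
#'   = no pruning; 0.001 matches genome-scale practice).
#' @param af_tol allele-frequency matching tolerance (default 0.05).
#' @return object of class `enrichment_result`: `observed_stat`,
#'   `perm_stats`, `empirical_p`, `lambda_inflation` (of the unpruned top
#'   set), `n_top`, `scheme`, `seed`.
#' @export
permutation_enrichment <- function(snps, score, top_frac = 0.05, B = 10000L,
                                   scheme = c("uniform", "af_matched"),
                                   seed = 1L, p_floor_filter = 1,
                                   af_tol = 0.05) {
  scheme <- match.arg(scheme)
  stopifnot(top_frac > 0, top_frac < 1, B >= 1L)
  if (anyNA(snps$gwas_p)) stop("every SNP needs a GWAS P value")
  miss <- setdiff(snps$id, names(score))
  if (length(miss)) stop("score missing for SNP(s): ",
                         paste(head(miss, 3L), collapse = ", "))
  set.seed(as.integer(seed))
  n <- nrow(snps)
  n_top <- max(1L, floor(top_frac * n))
  ranked <- rank_by_score(snps$id, score[snps$id])
  top_ids <- ranked[seq_len(n_top)]
  p_all <- setNames(snps$gwas_p, snps$id)
  keep <- p_all <= p_floor_filter
  ## pruned SNPs contribute 0 to the Fisher sum
  v <- ifelse(keep, -2 * log(p_all), 0)
  top_p_kept <- p_all[top_ids][keep[top_ids]]
  if (!length(top_p_kept)) stop("top set empty after P value pruning")
  observed <- sum(v[top_ids])
  perm <- numeric(B)
  if (scheme == "uniform") {
    for (b in seq_len(B)) {
      perm[b] <- sum(v[sample.int(n, n_top)])
    }
  } else {
    if (anyNA(snps$af)) stop("af_matched scheme needs allele frequencies")
    af <- setNames(snps$af, snps$id)
    vv <- unname(v)
    for (tid in top_ids) {
      cand <- which(abs(snps$af - af[tid]) < af_tol)
      draw <- cand[sample.int(length(cand), B, replace = TRUE)]
      perm <- perm + vv[draw]
    }
  }
  structure(list(
    observed_stat = observed,
    perm_stats = perm,
    empirical_p = (1 + sum(perm >= observed)) / (B + 1),
    lambda_inflation = inflation_lambda(p_all[top_ids]),
    n_top = n_top,
    scheme = scheme,
    seed = as.integer(seed)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> scheme=%s n_top=%d observed=%.2f empirical_p=%.4g lambda=%.3f\n",
    x$scheme, x$n_top, x$observed_stat, x$empirical_p, x$lambda_inflation))
  invisible(x)
}

#' Per-chromosome ratio of effective marker numbers
#'
#' \eqn{Ratio(chr) = M_e(\text{sub-genome-wide SNPs}) /
#' M_e(\text{top SNPs})}, where the sub-genome-wide set is the subset of the
#' top-prioritized SNPs reaching sub-genome-wide GWAS significance, and
#' \eqn{M_e} is the effective number of independent markers from
#' [effective_number()], computed chromosome by chromosome. Chromosomes
#' without any sub-genome-wide SNP report 0.
#'
#' @param top_ids SNP ids of the top-prioritized set.
#' @param sub_gw_ids SNP ids of the sub-genome-wide subset (must be a subset
#'   of `top_ids`).
#' @param variants variant data frame giving each SNP's chromosome.
#' @param ld pairwise LD table (snp_a, snp_b, r) or NULL (independence).
#' @return named numeric vector, one ratio in [0, 1] per chromosome with top
#'   SNPs.
#' @export
effective_marker_ratio <- function(top_ids, sub_gw_ids, variants, ld = NULL) {
  if (!length(top_ids)) stop("empty top SNP set")
  if (!all(sub_gw_ids %in% top_ids)) {
    stop("sub-genome-wide set must be a subset of the top set")
  }
  chrom <- setNames(norm_chrom(variants$chrom), variants$id)
  miss <- setdiff(top_ids, names(chrom))
  if (length(miss)) stop("variant table lacks SNP(s): ",
                         paste(head(miss, 3L), collapse = ", "))
  out <- c()
  for (chr in sort(unique(chrom[top_ids]), method = "radix")) {
    tc <- top_ids[chrom[top_ids] == chr]
    sc <- sub_gw_ids[chrom[sub_gw_ids] == chr]
    me_top <- effective_number(ld_matrix(tc, ld))
    ratio <- if (length(sc)) effective_number(ld_matrix(sc, ld)) / me_top else 0
    out[chr] <- ratio
  }
  out
}

#' eQTL coverage as a function of top-ranked fraction
#'
#' Ranks all scored variants (descending score, ties broken by id) and, at
#' each fraction of the grid, reports the fraction of benchmark eQTLs found
#' among the top-ranked variants.
#'
#' @param score named numeric vector of scores over the variant universe.
#' @param benchmark character vector of benchmark eQTL ids (subset of
#'   `names(score)`).
#' @param grid fractions in (0, 1] (default 1%..100% in 1% steps).
#' @return data frame of class `coverage_curve`: columns fraction, coverage.
#' @export
coverage_curve <- function(score, benchmark,
                           grid = seq(0.01, 1, by = 0.01)) {
  if (!length(benchmark)) stop("empty benchmark set")
  miss <- setdiff(benchmark, names(score))
  if (length(miss)) stop("benchmark id(s) missing from scores: ",
                         paste(head(miss, 3L), collapse = ", "))
  ranked <- rank_by_score(names(score), score)
  in_bench <- ranked %in% benchmark
  cum <- cumsum(in_bench)
  n <- length(ranked)
  cov <- vapply(grid, function(f) cum[max(1L, ceiling(f * n))], 0) /
    length(benchmark)
  structure(data.frame(fraction = grid, coverage = cov),
            class = c("coverage_curve", "data.frame"))
}

#' Q-Q table of observed vs expected -log10 P with permutation envelope
#'
#' Tabular replacement for a Q-Q plot: sorted observed \eqn{-\log_{10} P}
#' against the uniform expectation, optionally with a per-rank envelope
#' (2.5%/97.5% quantiles) from `envelope_B` uniform resamples.
#'
#' @param pvalues observed P values in (0, 1].
#' @param envelope_B number of null resamples for the envelope (0 = none).
#' @param seed seed for the envelope resampling.
#' @return data frame: expected, observed, and (with an envelope) lower,
#'   upper; all on the -log10 scale, sorted by expected.
#' @export
qq_table <- function(pvalues, envelope_B = 0L, seed = 1L) {
  if (any(pvalues <= 0 | pvalues > 1)) stop("P values must lie in (0, 1]")
  n <- length(pvalues)
  obs <- -log10(sort(pvalues))
  exp_ <- -log10(ppoints(n))
  out <- data.frame(expected = exp_, observed = obs)
  if (envelope_B > 0L) {
    set.seed(as.integer(seed))
    sims <- matrix(-log10(apply(matrix(runif(n * envelope_B), n), 2L, sort)),
                   nrow = n)
    out$lower <- apply(sims, 1L, quantile, probs = 0.025)
    out$upper <- apply(sims, 1L, quantile, probs = 0.975)
  }
  out
}

#' Write an enrichment report as TSV
#'
#' Columns: cell_type, n_top, observed_stat, empirical_p, lambda.
#'
#' @param results named list of `enrichment_result` objects, names = cell
#'   types.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(results, path) {
  out <- do.call(rbind, lapply(names(results), function(ct) {
    r <- results[[ct]]
    data.frame(cell_type = ct, n_top = r$n_top,
               observed_stat = r$observed_stat,
               empirical_p = r$empirical_p,
               lambda = r$lambda_inflation, stringsAsFactors = FALSE)
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
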