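#' Rescale prior weights to a fixed max/min ratio of ten
#'
#' Affine map `w = 1 + 9 (x - min) / (max - min)` so the smallest weight is
#' 1 and the largest is 10; a mis-specified weight therefore cannot change
#' any SNP's contribution by more than a factor of ten. Constant input maps
#' to all ones.
#'
#' @param raw nonnegative finite numeric vector (e.g. combined
#'   probabilities).
#' @return numeric vector of weights in [1, 10].
#' @export
rescale_weights <- function(raw) {
  if (!length(raw)) stop("need at least one value")
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("weights must be finite and nonnegative")
  }
  rng <- range(raw)
  if (diff(rng) == 0) return(rep(1, length(raw)))
  1 + 9 * (raw - rng[1L]) / (rng[2L] - rng[1L])
}

## nearest-PSD projection of a correlation-like matrix (eigenvalue clipping
## + unit-diagonal rescale)
nearest_psd_corr <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol) return(R)
  warning("correlation matrix not positive semidefinite; projecting to nearest PSD")
  lam <- pmax(e$values, 0)
  B <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(B), tol))
  R2 <- B / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

## P-value correlation from genotype LD; default rho_p = r^2
pvalue_correlation <- function(r, transform = function(r) r^2) {
  R <- transform(r)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  nearest_psd_corr((R + t(R)) / 2)
}

#' Effective number of independent P values among the top j SNPs
#'
#' Derives the P-value correlation matrix from the genotype LD matrix
#' (default \eqn{\rho_p = r^2}; the transform is a swappable hook), takes
#' the leading `top_j` x `top_j` submatrix (rows assumed sorted by ascending
#' P), and returns \eqn{m_e(j) = j - \sum_{\lambda_i > 1} (\lambda_i - 1)}
#' over its eigenvalues. By definition `m_e(0) = 0`.
#'
#' @param r LD matrix (genotype correlations, symmetric, unit diagonal).
#' @param top_j submatrix size (default: all SNPs); `0` returns 0.
#' @param transform map from LD r to P-value correlation (default
#'   `function(r) r^2`).
#' @return the effective number, a real in [1, top_j] (0 for `top_j = 0`).
#' @export
effective_number <- function(r, top_j = NULL, transform = function(r) r^2) {
  r <- as.matrix(r)
  m <- nrow(r)
  if (is.null(top_j)) top_j <- m
  if (top_j == 0L) return(0)
  stopifnot(top_j >= 1L, top_j <= m)
  rho <- pvalue_correlation(r, transform)
  sub <- rho[seq_len(top_j), seq_len(top_j), drop = FALSE]
  lam <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
  top_j - sum(pmax(lam - 1, 0))
}

#' Gene-based association P value (GATES, optionally prior-weighted)
#'
#' Sorts the gene's SNPs by ascending GWAS P value (ties broken by SNP id),
#' computes the effective numbers of independent P values
#' \eqn{m_e(1) \dots m_e(m)} from the LD matrix, and forms per-SNP weights
#' \deqn{w_{(i)} = c\,(m_e(i) - m_e(i-1))\,r_{(i)}, \qquad
#'   c = \frac{m_e}{\sum_i (m_e(i) - m_e(i-1))\,r_{(i)}}}
#' where \eqn{r_{(i)}} is the SNP's prior weight (all 1 in unweighted mode,
#' so the weights sum to \eqn{m_e} by construction). The gene P value is
#' \deqn{P_G = \min_j \frac{m_e\,p_{(j)}}{\sum_{k \le j} w_{(k)}}}
#' capped at 1. With independent SNPs and uniform weights this is exactly
#' the Simes test.
#'
#' @param p GWAS P values, named by SNP id (names optional but needed for
#'   deterministic tie-breaks and weighted mode).
#' @param ld LD matrix over the same SNPs (genotype r; default: identity =
#'   independent SNPs). Row/column order must match `p`.
#' @param prior_weights positive per-SNP prior weights named like `p`
#'   (e.g. rescaled combined probabilities); NULL for the unweighted test.
#' @param transform LD-to-P-value-correlation hook (see
#'   [effective_number()]).
#' @return list of class `gates_result`: `p_gene`, `m_e`, `m_e_j`
#'   (cumulative effective numbers), `w` (final weights, sorted order),
#'   `order` (SNP order used), `n_snps`, `weighted`.
#' @export
gates_p <- function(p, ld = NULL, prior_weights = NULL,
                    transform = function(r) r^2) {
  m <- length(p)
  if (!m) stop("empty SNP block")
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]")
  ids <- names(p)
  if (is.null(ids)) ids <- sprintf("snp%0*d", nchar(m), seq_len(m))
  if (is.null(ld)) ld <- diag(1, m)
  ld <- as.matrix(ld)
  stopifnot(nrow(ld) == m, ncol(ld) == m)
  weighted <- !is.null(prior_weights)
  rw <- if (weighted) {
    if (is.null(names(prior_weights))) {
      stopifnot(length(prior_weights) == m)
      setNames(prior_weights, ids)
    } else {
      miss <- setdiff(ids, names(prior_weights))
      if (length(miss)) stop("prior weight missing for SNP(s): ",
                             paste(miss, collapse = ", "))
      prior_weights[ids]
    }
  } else {
    setNames(rep(1, m), ids)
  }
  if (any(rw <= 0)) stop("prior weights must be positive")
  ord <- order(p, ids, method = "radix")
  ps <- p[ord]
  rs <- unname(rw[ord])
  rho <- pvalue_correlation(ld[ord, ord, drop = FALSE], transform)
  m_e_j <- vapply(seq_len(m), function(j) {
    lam <- eigen(rho[seq_len(j), seq_len(j), drop = FALSE],
                 symmetric = TRUE, only.values = TRUE)$values
    j - sum(pmax(lam - 1, 0))
  }, 0)
  m_e <- m_e_j[m]
  dm <- diff(c(0, m_e_j))
  cc <- m_e / sum(dm * rs)
  w <- cc * dm * rs
  p_gene <- min(1, min(m_e * ps / cumsum(w)))
  structure(list(
    p_gene = p_gene, m_e = m_e, m_e_j = m_e_j, w = w,
    order = ids[ord], n_snps = m, weighted = weighted
  ), class = "gates_result")
}

#' @export
print.gates_result <- function(x, ...) {
  cat(sprintf("<gates_result> %s P = %.4g over %d SNPs (m_e = %.3f)\n",
              if (x$weighted) "weighted" else "unweighted",
              x$p_gene, x$n_snps, x$m_e))
  invisible(x)
}

#' Run weighted and unweighted GATES for one gene
#'
#' @param gene_id gene identifier.
#' @param p named GWAS P values of the gene's SNPs.
#' @param ld LD matrix (genotype r) over the same SNPs, or NULL.
#' @param prior_weights raw per-SNP prior weights (combined probabilities);
#'   rescaled internally by [rescale_weights()].
#' @param transform LD-to-P-value-correlation hook.
#' @return one-row data frame: gene_id, n_snps, m_e, p_unweighted,
#'   p_weighted.
#' @export
gene_test <- function(gene_id, p, ld = NULL, prior_weights = NULL,
                      transform = function(r) r^2) {
  unw <- gates_p(p, ld, transform = transform)
  w <- if (!is.null(prior_weights)) {
    rs <- rescale_weights(prior_weights[names(p)])
    names(rs) <- names(p)
    gates_p(p, ld, prior_weights = rs, transform = transform)
  } else {
    unw
  }
  data.frame(gene_id = gene_id, n_snps = unw$n_snps, m_e = unw$m_e,
             p_unweighted = unw$p_gene, p_weighted = w$p_gene,
             stringsAsFactors = FALSE)
}

#' Classify genes as improved, worsened or unchanged by weighting
#'
#' A gene is improved when (1) it crosses the significance threshold
#' (unweighted P at or above `alpha`, weighted P below it), or (2) it was
#' already significant and its P value decreased by more than the `fold`
#' factor (weighted P < fold x unweighted P). It is worsened when it was
#' significant but the weighted P exceeds the unweighted one. Everything
#' else is unchanged.
#'
#' @param weighted named numeric vector of weighted gene P values (names =
#'   gene ids), or the data frame from [gene_test()] rows.
#' @param unweighted named numeric vector of unweighted gene P values;
#'   ignored when `weighted` is a data frame.
#' @param alpha significance threshold (default 1e-5).
#' @param fold improvement fold factor (default 0.8).
#' @return data frame: gene_id, p_unweighted, p_weighted, status. Genes
#'   present in only one run are dropped with a warning.
#' @export
classify_genes <- function(weighted, unweighted = NULL, alpha = 1e-5,
                           fold = 0.8) {
  if (is.data.frame(weighted)) {
    tab <- weighted
    pw <- setNames(tab$p_weighted, tab$gene_id)
    pu <- setNames(tab$p_unweighted, tab$gene_id)
  } else {
    pw <- weighted
    pu <- unweighted
  }
  common <- intersect(names(pw), names(pu))
  only <- c(setdiff(names(pw), common), setdiff(names(pu), common))
  if (length(only)) {
    warning("gene(s) present in only one run, excluded: ",
            paste(only, collapse = ", "))
  }
  pw <- pw[common]; pu <- pu[common]
  status <- rep("unchanged", length(common))
  status[(pu >= alpha & pw < alpha) | (pu < alpha & pw < fold * pu)] <- "improved"
  status[pu < alpha & pw > pu] <- "worsened"
  data.frame(gene_id = common, p_unweighted = unname(pu),
             p_weighted = unname(pw), status = status,
             stringsAsFactors = FALSE)
}

#' Gene-based association over a gene-SNP map
#'
#' Convenience driver: runs [gene_test()] for every gene and appends the
#' [classify_genes()] status.
#'
#' @param gwas GWAS variant data frame (needs `id` and `gwas_p`).
#' @param gene_map data frame (gene_id, snp_id) assigning SNPs to genes.
#' @param ld pairwise LD table (snp_a, snp_b, r) or NULL.
#' @param prior_weights named raw prior weights per SNP (combined
#'   probabilities) or NULL for unweighted-only.
#' @param alpha,fold classification thresholds (see [classify_genes()]).
#' @param transform LD-to-P-value-correlation hook.
#' @return data frame: gene_id, n_snps, m_e, p_unweighted, p_weighted,
#'   status.
#' @export
gene_test_table <- function(gwas, gene_map, ld = NULL, prior_weights = NULL,
                            alpha = 1e-5, fold = 0.8,
                            transform = function(r) r^2) {
  stopifnot(all(c("gene_id", "snp_id") %in% names(gene_map)))
  pmap <- setNames(gwas$gwas_p, gwas$id)
  rows <- lapply(split(gene_map$snp_id, gene_map$gene_id), function(snps) snps)
  out <- lapply(names(rows), function(g) {
    snps <- intersect(rows[[g]], names(pmap))
    snps <- snps[!is.na(pmap[snps])]
    if (!length(snps)) return(NULL)
    R <- ld_matrix(snps, ld)
    pw <- if (!is.null(prior_weights)) {
      if (!all(snps %in% names(prior_weights))) return(NULL)
      prior_weights[snps]
    } else {
      NULL
    }
    gene_test(g, pmap[snps], R, pw, transform = transform)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) stop("no gene with scorable SNPs")
  cls <- classify_genes(out, alpha = alpha, fold = fold)
  merge(out, cls[c("gene_id", "status")], by = "gene_id", sort = TRUE)
}

#' Write per-gene test results as TSV
#'
#' Columns: gene_id, n_snps, m_e, p_unweighted, p_weighted, status.
#'
#' @param results data frame from [gene_test_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
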