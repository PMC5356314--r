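#' @importFrom stats hclust dist as.dendrogram
NULL

#' Disease-by-cell-type specificity matrix of mean regulatory potentials
#'
#' For each disease SNP set and each cell type, the mean predicted
#' regulatory potential of the disease's SNPs under that cell type's
#' chromatin features; each row is then normalized by its mean across cell
#' types so that rows centre at 1 and the most relevant cell types stand
#' out above 1.
#'
#' @param snp_sets named list (disease -> variant data frame).
#' @param model a `regpot_logit` (typically the generalized model).
#' @param tracks_by_cell named list (cell type -> list of `peak_track`).
#' @param sentinel,zero_fill passed to [feature_matrix()]; marks without a
#'   track are zero-filled by default so every cell type is scorable.
#' @return object of class `specificity_matrix`: `raw` and `normalized`
#'   (diseases x cell types matrices), `n_snps` (per disease). Diseases
#'   without a scorable SNP are dropped with a warning.
#' @export
specificity_matrix <- function(snp_sets, model, tracks_by_cell,
                               sentinel = 10000, zero_fill = TRUE) {
  stopifnot(length(snp_sets) >= 1L, length(tracks_by_cell) >= 1L)
  cells <- names(tracks_by_cell)
  diseases <- names(snp_sets)
  keep <- vapply(snp_sets, function(v) is.data.frame(v) && nrow(v) > 0L, TRUE)
  if (any(!keep)) {
    warning("dropping disease(s) without scorable SNPs: ",
            paste(diseases[!keep], collapse = ", "))
  }
  snp_sets <- snp_sets[keep]
  diseases <- diseases[keep]
  if (!length(diseases)) stop("no disease with scorable SNPs")
  raw <- matrix(NA_real_, length(diseases), length(cells),
                dimnames = list(diseases, cells))
  for (ct in cells) {
    for (dz in diseases) {
      fm <- feature_matrix(snp_sets[[dz]], tracks_by_cell[[ct]],
                           marks = REGPOT_MARKS, sentinel = sentinel,
                           zero_fill = zero_fill)
      raw[dz, ct] <- mean(predict_potential(model, fm))
    }
  }
  normalized <- raw / rowMeans(raw)
  structure(list(
    raw = raw, normalized = normalized,
    n_snps = vapply(snp_sets, nrow, 0L)
  ), class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("<specificity_matrix> %d disease(s) x %d cell type(s)\n",
              nrow(x$raw), ncol(x$raw)))
  invisible(x)
}

#' Most relevant cell type per disease
#'
#' Argmax of each normalized row; exact ties are broken by cell-type name
#' (lexicographically first) and flagged.
#'
#' @param x a `specificity_matrix`.
#' @return data frame: disease, cell_type, normalized_mean, tie (logical).
#' @export
most_relevant_tissue <- function(x) {
  stopifnot(inherits(x, "specificity_matrix"))
  nm <- x$normalized
  cells <- colnames(nm)
  out <- lapply(rownames(nm), function(dz) {
    v <- nm[dz, ]
    best <- max(v)
    hits <- sort(cells[v == best], method = "radix")
    data.frame(disease = dz, cell_type = hits[1L], normalized_mean = best,
               tie = length(hits) > 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hierarchical clustering of cell types by specificity profile
#'
#' Average-linkage agglomerative clustering on the Euclidean distance
#' between the normalized cell-type columns.
#'
#' @param x a `specificity_matrix` (needs at least 2 cell types).
#' @return list: `hclust` (the tree), `leaves` (cell types in dendrogram
#'   order), `newick` (the tree as a Newick string).
#' @export
cluster_cell_types <- function(x) {
  stopifnot(inherits(x, "specificity_matrix"))
  nm <- x$normalized
  if (ncol(nm) < 2L) stop("need at least 2 cell types")
  ## stable input order so identical profiles merge deterministically
  nm <- nm[, sort(colnames(nm), method = "radix"), drop = FALSE]
  hc <- hclust(dist(t(nm)), method = "average")
  list(
    hclust = hc,
    leaves = hc$labels[hc$order],
    newick = ape::write.tree(ape::as.phylo(hc))
  )
}

#' Write a specificity matrix as TSV
#'
#' Disease rows, cell-type columns, normalized values.
#'
#' @param x a `specificity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specificity_matrix <- function(x, path) {
  out <- data.frame(disease = rownames(x$normalized), x$normalized,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the disease-to-cell-type mapping as TSV
#'
#' @param mapping data frame from [most_relevant_tissue()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tissue_mapping <- function(mapping, path) {
  write.table(mapping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
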