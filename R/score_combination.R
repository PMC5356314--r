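check_pi <- function(pi) {
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1) {
    stop("prior `pi` must be a single number in (0, 1)")
  }
  pi
}

#' Empirical class-conditional score densities
#'
#' For each external predictor, histogram estimates of P(s | causal) and
#' P(s | neutral) on a shared equal-width binning over the pooled training
#' range, with a Laplace pseudocount per bin so no occupied-range bin has
#' zero density. A predictor whose scores are constant across both classes
#' is flagged uninformative (its likelihood ratio is 1 everywhere).
#'
#' @param train_scores numeric matrix of training scores, rows = variants,
#'   columns = predictors (see [read_scores()]); NA = missing score.
#' @param labels 1 = causal, 0 = neutral; at least 20 of each.
#' @param bins number of histogram bins (default 20).
#' @param pseudocount Laplace pseudocount added to each bin (default 1).
#' @return list of `score_density` objects (fields: predictor, edges,
#'   p_causal, p_neutral, pseudocount, uninformative), one per predictor.
#' @export
fit_score_densities <- function(train_scores, labels, bins = 20L,
                                pseudocount = 1) {
  train_scores <- as.matrix(train_scores)
  y <- as_label01(labels)
  if (sum(y == 1L) < 20L || sum(y == 0L) < 20L) {
    stop("need at least 20 labeled variants per class")
  }
  lapply(colnames(train_scores), function(pred) {
    s <- train_scores[, pred]
    keep <- !is.na(s)
    sv <- s[keep]; yv <- y[keep]
    rng <- range(sv)
    uninformative <- FALSE
    if (diff(rng) == 0) {
      rng <- rng + c(-0.5, 0.5)
      uninformative <- TRUE
      warning("predictor `", pred, "` has constant scores; flagged uninformative")
    }
    edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    bin_of <- function(x) pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1L), bins)
    cnt <- function(x) tabulate(bin_of(x), nbins = bins) + pseudocount
    pc <- cnt(sv[yv == 1L]); pn <- cnt(sv[yv == 0L])
    structure(list(
      predictor = pred, edges = edges,
      p_causal = pc / sum(pc), p_neutral = pn / sum(pn),
      pseudocount = pseudocount, uninformative = uninformative
    ), class = "score_density")
  })
}

#' @export
print.score_density <- function(x, ...) {
  cat(sprintf("<score_density> %s: %d bins over [%.4g, %.4g]%s\n",
              x$predictor, length(x$p_causal), x$edges[1L],
              x$edges[length(x$edges)],
              if (x$uninformative) " [uninformative]" else ""))
  invisible(x)
}

density_lookup <- function(d, s) {
  bins <- length(d$p_causal)
  i <- pmin(pmax(findInterval(s, d$edges, all.inside = TRUE), 1L), bins)
  list(causal = d$p_causal[i], neutral = d$p_neutral[i])
}

#' Composite causal probability from external predictor scores
#'
#' The context-free component: a product over predictors of per-score
#' two-class posteriors,
#' \deqn{P(causal \mid S) = \prod_i
#'   \frac{P(s_i \mid causal)\,\pi}{P(s_i \mid causal)\,\pi +
#'   P(s_i \mid neutral)\,(1-\pi)}}
#' with flat prior \eqn{\pi} (default 0.5). Scores outside a density's
#' support are clamped to its edge bins; missing scores contribute no factor
#' (all missing is an error). Note the product over several predictors is a
#' score in (0, 1), not itself a normalized posterior.
#'
#' @param scores named numeric vector of one variant's predictor scores, or
#'   a matrix (rows = variants, columns = predictors).
#' @param densities list of `score_density` objects from
#'   [fit_score_densities()].
#' @param pi prior causal probability (default 0.5).
#' @return numeric vector of composite probabilities in (0, 1).
#' @export
composite_probability <- function(scores, densities, pi = 0.5) {
  check_pi(pi)
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1L,
                     dimnames = list(NULL, names(scores)))
  }
  preds <- vapply(densities, function(d) d$predictor, "")
  miss <- setdiff(preds, colnames(scores))
  if (length(miss)) stop("scores missing predictor column(s): ",
                         paste(miss, collapse = ", "))
  out <- rep(1, nrow(scores))
  any_factor <- rep(FALSE, nrow(scores))
  for (d in densities) {
    s <- scores[, d$predictor]
    ok <- !is.na(s)
    if (!any(ok)) next
    lk <- density_lookup(d, s[ok])
    f <- lk$causal * pi / (lk$causal * pi + lk$neutral * (1 - pi))
    out[ok] <- out[ok] * f
    any_factor <- any_factor | ok
  }
  if (!all(any_factor)) {
    stop("variant(s) with all scores missing: row ",
         paste(head(which(!any_factor), 3L), collapse = ", "))
  }
  out
}

#' Combined probability: fuse composite score and regulatory potential
#'
#' Treats the context-free composite probability `p_s` and the
#' context-dependent regulatory potential `p_x` as independent measurements
#' and returns the normalized two-hypothesis posterior
#' \deqn{\frac{q}{q + \bar q}, \quad q = \frac{p_s\,p_x}{\pi}, \quad
#'  \bar q = \frac{(1-p_s)(1-p_x)}{1-\pi}.}
#' The normalization realizes the proportionality constant of the naive-
#' Bayes fusion so the result is a proper probability; with \eqn{\pi = 0.5}
#' and both inputs 0.5 the result is 0.5, and an uninformative context
#' (\eqn{p_x = \pi}) returns `p_s` unchanged.
#'
#' @param p_s composite probability (vectorized, values in (0, 1)).
#' @param p_x regulatory potential (vectorized, values in (0, 1)).
#' @param pi prior causal probability (default 0.5).
#' @return numeric vector of combined probabilities in (0, 1).
#' @export
combined_probability <- function(p_s, p_x, pi = 0.5) {
  check_pi(pi)
  eps <- 1e-12
  clamp <- function(p, what) {
    if (any(p <= 0 | p >= 1)) {
      warning(what, " outside (0,1); clamped to [", eps, ", 1-", eps, "]")
      p <- pmin(pmax(p, eps), 1 - eps)
    }
    p
  }
  p_s <- clamp(p_s, "p_s")
  p_x <- clamp(p_x, "p_x")
  q <- p_s * p_x / pi
  qbar <- (1 - p_s) * (1 - p_x) / (1 - pi)
  q / (q + qbar)
}

#' Serialize score densities as JSON
#'
#' @param densities list from [fit_score_densities()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_densities <- function(densities, path) {
  obj <- lapply(densities, function(d) {
    list(predictor = d$predictor, edges = d$edges,
         p_causal = d$p_causal, p_neutral = d$p_neutral,
         pseudocount = d$pseudocount, uninformative = d$uninformative)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Reload score densities written by [write_score_densities()]
#'
#' @param path path to the JSON file.
#' @return list of `score_density` objects.
#' @export
read_score_densities <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i) {
    structure(list(
      predictor = obj$predictor[i],
      edges = as.numeric(obj$edges[[i]]),
      p_causal = as.numeric(obj$p_causal[[i]]),
      p_neutral = as.numeric(obj$p_neutral[[i]]),
      pseudocount = as.numeric(obj$pseudocount[i]),
      uninformative = isTRUE(obj$uninformative[i])
    ), class = "score_density")
  })
}

#' Write per-variant combined scores as TSV
#'
#' Columns: variant_id, composite_p, regulatory_potential, combined_p,
#' cell_type.
#'
#' @param variant_id character vector.
#' @param composite_p,regulatory_potential,combined_p numeric vectors.
#' @param cell_type cell-type label (recycled).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_combined_scores <- function(variant_id, composite_p,
                                  regulatory_potential, combined_p,
                                  cell_type, path) {
  out <- data.frame(variant_id = variant_id, composite_p = composite_p,
                    regulatory_potential = regulatory_potential,
                    combined_p = combined_p, cell_type = cell_type,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
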